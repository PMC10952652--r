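test_that("golden means satisfy their defining identities and printed values", {
  gm <- compute_golden_means()
  expect_lt(abs(gm[["phi2"]]^3 + gm[["phi2"]] - 1), 1e-12)
  expect_lt(abs(gm[["phi1"]] - gm[["phi2"]]^2), 1e-12)
  expect_equal(round(gm[["phi1"]], 4), 0.4656)
  expect_equal(round(gm[["phi2"]], 4), 0.6823)
  expect_true(all(gm > 0 & gm < 1))
})

test_that("spoke orientation follows the even/odd golden-means construction", {
  o0 <- spoke_orientation(0)
  expect_equal(o0$theta, pi / 2)
  expect_equal(o0$phi, 0)
  # frozen values from direct evaluation with high-precision roots
  o1 <- spoke_orientation(1)
  expect_equal(o1$theta, 2.055076, tolerance = 1e-5)
  expect_equal(o1$phi, 1.145599, tolerance = 1e-5)
  o2 <- spoke_orientation(2)
  expect_equal(o2$theta, 0.373263, tolerance = 1e-5)
  expect_error(spoke_orientation(-1), "nonnegative")
})

test_that("fractional parts stay in [0,1) out to very large counters", {
  gm <- compute_golden_means()
  m <- c(0, 1, 2, 10^(1:6), 10^6 - 1)
  for (phi in gm) {
    f <- m * phi - floor(m * phi)
    expect_true(all(f >= 0 & f < 1))
  }
  ori <- spoke_orientation(m)
  expect_true(all(ori$theta >= 0 & ori$theta <= pi))
  expect_true(all(ori$phi >= 0 & ori$phi < 2 * pi))
})

test_that("spoke counter interleaves preparations M apart", {
  expect_equal(spoke_counter(1, 1, 36), 0)
  expect_equal(spoke_counter(5, 3, 36), 76)
  # the first t_max window tiles seamlessly across preparations
  expect_equal(spoke_counter(36, 1, 36, N = 216), 35)
  expect_equal(spoke_counter(1, 2, 36, N = 216), 36)
  expect_error(spoke_counter(0, 1, 36), "out of range")
  expect_error(spoke_counter(217, 1, 36, N = 216), "out of range")
  expect_error(spoke_counter(1, 0, 36), ">= 1")
})

test_that("acquisition config derives interval, M and readout samples", {
  cfg <- acquisition_config()
  expect_equal(cfg$spoke_interval, 1.9397 / 216)
  expect_equal(cfg$spokes_per_tmax, 36L)
  expect_equal(cfg$readout_samples, round(0.79 * 160))
  expect_equal(cfg$voxel_size, 183 / 160)
  expect_error(acquisition_config(pf_factor = 0.5), "pf_factor")
  expect_error(acquisition_config(t_max = 0.1), "multiple")
})

test_that("full schedule enumerates counters and pairs label/control exactly", {
  cfg <- acquisition_config(matrix = 16, n_pairs = 5)
  sch <- build_schedule(cfg)
  expect_equal(nrow(sch), 2 * 5 * 216)
  lab <- dplyr::filter(sch, cond == "label")
  ctl <- dplyr::filter(sch, cond == "control")
  expect_identical(lab$m, ctl$m)
  expect_identical(lab$theta, ctl$theta)
  # counters per prep: i - 1 + (n-1) M
  expect_setequal(unique(lab$m[lab$pair == 3]), (0:215) + 2 * 36)
  # timestamps
  expect_equal(lab$t[lab$pair == 2][1], cfg$tau)
  expect_equal(diff(lab$t[lab$pair == 1])[1], cfg$spoke_interval)
})

test_that("when N = M every counter is used exactly once per condition", {
  cfg <- acquisition_config(matrix = 16, n_pairs = 4,
                            readout_duration_after_label = 0.3233,
                            n_spokes_per_prep = 36, t_max = 0.3233)
  sch <- build_schedule(cfg)
  lab <- dplyr::filter(sch, cond == "label")
  expect_equal(sort(lab$m), 0:(4 * 36 - 1))
})

test_that("even/odd direction reversal balances the hemispheres", {
  ori <- spoke_orientation(0:9999)
  cz <- cos(ori$theta)
  expect_true(all(cz[ori$m %% 2 == 0] >= 0))
  expect_true(all(cz[ori$m %% 2 == 1] <= 0))
  expect_lt(abs(mean(cz)), 0.02)
})

test_that("contiguous golden-means runs cover the sphere near-uniformly", {
  # nearest-neighbour angular gaps for golden-means runs vs uniform draws
  max_nn_gap <- function(theta, phi) {
    d <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
    gram <- pmin(pmax(tcrossprod(d), -1), 1)
    diag(gram) <- -1
    max(acos(apply(gram, 1, max)))
  }
  W <- 60
  set.seed(42)
  starts <- sample.int(5e4, 20)
  gaps <- vapply(starts, function(m0) {
    ori <- spoke_orientation(m0 + 0:(W - 1))
    max_nn_gap(ori$theta, ori$phi)
  }, numeric(1))
  unif <- vapply(seq_len(40), function(k) {
    z <- runif(W, -1, 1); az <- runif(W, 0, 2 * pi)
    max_nn_gap(acos(z), az)
  }, numeric(1))
  expect_true(all(gaps <= 1.5 * median(unif)))
})

test_that("readout coordinates span the partial-Fourier asymmetric echo", {
  cfg <- acquisition_config(matrix = 160, n_pairs = 2)
  k <- readout_sample_coords(pi / 3, pi / 5, cfg)
  expect_equal(nrow(k), round(0.79 * 160))
  r <- sqrt(rowSums(k^2)) * sign(k %*% c(sin(pi/3)*cos(pi/5), sin(pi/3)*sin(pi/5), cos(pi/3)))
  k_max <- 160 / (2 * cfg$fov)
  expect_equal(min(r), -(2 * 0.79 - 1) * k_max)
  expect_true(all(sqrt(rowSums(k^2)) <= k_max + 0.5 / cfg$fov))
  # full echo: symmetric span
  cfg1 <- acquisition_config(matrix = 160, n_pairs = 2, pf_factor = 1)
  k1 <- readout_sample_coords(0.2, 0.4, cfg1)
  r1 <- k1 %*% c(sin(0.2)*cos(0.4), sin(0.2)*sin(0.4), cos(0.2))
  expect_equal(min(r1), -k_max)
  expect_equal(max(r1), k_max - 1 / cfg1$fov)
  # spacing is 1/fov
  expect_equal(diff(sort(r1))[1], 1 / cfg1$fov)
})

test_that("undersampling factor matches the diameter-spoke Nyquist count", {
  expect_equal(round(undersampling_factor(160, 24 * 88), 1), 19.0)
  expect_equal(round(undersampling_factor(52, 36 * 88), 1), 1.3)
  m <- 40
  expect_equal(undersampling_factor(m, pi * m^2 / 2), 1.0)
  expect_error(undersampling_factor(160, 0), "positive")
})

test_that("frame binning tiles the readout and uses window-center PLDs", {
  cfg <- acquisition_config(matrix = 16, n_pairs = 2)
  fr <- bin_frames(cfg, 36 * cfg$spoke_interval)
  expect_equal(nrow(fr), 6)
  expect_equal(fr$pld, (1:6 - 0.5) * 36 * 1.9397 / 216, tolerance = 1e-9)
  expect_equal(round(fr$pld, 3), c(0.162, 0.485, 0.808, 1.132, 1.455, 1.778),
               tolerance = 1e-3)
  expect_equal(nrow(bin_frames(cfg, 24 * cfg$spoke_interval)), 9)
  # t_max window gives N/M frames
  expect_equal(nrow(bin_frames(cfg, cfg$t_max)), 216 / 36)
  expect_error(bin_frames(cfg, 25 * cfg$spoke_interval), "nearest valid")
  expect_error(bin_frames(cfg, 2 * cfg$t_max), "exceeds")
})

test_that("schedules round-trip through delimited text", {
  cfg <- acquisition_config(matrix = 16, n_pairs = 2)
  sch <- build_schedule(cfg)
  path <- tempfile(fileext = ".csv")
  write_schedule(sch, path)
  back <- read_schedule(path)
  expect_equal(back$m, sch$m)
  expect_equal(back$theta, sch$theta, tolerance = 1e-12)
  unlink(path)
})
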