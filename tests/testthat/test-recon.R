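test_that("sensitivity estimation recovers the true maps on the object support", {
  s <- tiny_setup(noise_sigma = 0, n_coils = 3L, grid = 16L, n_pairs = 4L)
  est <- estimate_sensitivities(s$raw, matrix = 16, n_iters = 15)
  rss_t <- sqrt(apply(Mod(s$coils)^2, 1:3, sum))
  sens_t <- unclass(s$coils) / array(rss_t, dim(s$coils))
  supp <- est$mask & phantom_brain_mask(s$spec)
  expect_gt(sum(supp), 50)
  for (c in 1:3) {
    a <- est$sens[, , , c][supp]
    b <- sens_t[, , , c][supp]
    ph <- Arg(sum(b * Conj(a)))  # global phase is unobservable
    expect_lt(mean(Mod(a * exp(1i * ph) - b)) / mean(Mod(b)), 0.05)
  }
  # mask excludes voxels below the RSS threshold
  expect_true(all(est$rss[!est$mask] <= 0.1 * max(est$rss)))
  # all-zero data rejected
  zero <- s$raw; zero$label[] <- 0i; zero$control[] <- 0i
  expect_error(estimate_sensitivities(zero, 16), "all-zero")
})

test_that("coil compression is lossless at full rank and on rank-limited data", {
  s <- tiny_setup(noise_sigma = 0, n_coils = 4L)
  # full-rank "compression" is a unitary rotation: with consistently rotated
  # data and sensitivities the normal equations (and so the CG iterates) are
  # unchanged
  full <- suppressMessages(compress_coils(s$raw, 4))
  d0 <- phase_align_subtract(s$raw)
  d1 <- phase_align_subtract(full)
  frames <- bin_frames(s$cfg, s$cfg$t_max)
  op0 <- build_encoding(d0$schedule, s$cfg, frames, s$raw$coils)
  op1 <- build_encoding(d1$schedule, s$cfg, frames, full$coils)
  r0 <- cg_sense(d0, op0, recon_config("cg-sense", n_iters = 8))
  r1 <- cg_sense(d1, op1, recon_config("cg-sense", n_iters = 8))
  expect_lt(nrmse(r1$data, r0$data), 1e-6)
  expect_equal(full$provenance$compression_energy, 1, tolerance = 1e-10)
  # data synthesized from 2 distinct coil profiles compress to 2 channels
  # without losing energy, and the discarded channels are empty
  mix <- s$raw
  A <- matrix(complex(real = c(1, 0.3, -0.2, 0.5, 0.2, -0.4, 0.8, 0.1),
                      imaginary = c(0, 0.1, 0.4, -0.3, -0.2, 0.3, 0, 0.2)),
              4, 2)
  mix$label <- array(matrix(s$raw$label, ncol = 4)[, 1:2] %*% t(A),
                     dim(s$raw$label))
  mix$control <- array(matrix(s$raw$control, ncol = 4)[, 1:2] %*% t(A),
                       dim(s$raw$control))
  mix$coils <- NULL
  cmp2 <- suppressMessages(compress_coils(mix, 2))
  expect_equal(cmp2$provenance$compression_energy, 1, tolerance = 1e-10)
  cmp4 <- suppressMessages(compress_coils(mix, 4))
  expect_lt(sum(Mod(cmp4$label[, , 3:4])^2) / sum(Mod(cmp4$label)^2), 1e-12)
  expect_error(compress_coils(s$raw, 0), ">= 1")
  expect_error(compress_coils(s$raw, 9), "exceeds")
})

test_that("phase alignment recovers simulated per-preparation drift", {
  drift <- 0.15
  noisy <- tiny_setup(noise_sigma = 0, phase_drift = drift, n_pairs = 3L)
  clean <- tiny_setup(noise_sigma = 0, phase_drift = 0, n_pairs = 3L)
  dks_d <- phase_align_subtract(noisy$raw)
  dks_c <- phase_align_subtract(clean$raw)
  # recovered rotation equals the applied drift per preparation
  sch <- noisy$raw$schedule
  for (p in 1:3) {
    expect_lt(max(abs(dks_d$phase[sch$pair == p] - drift * (p - 1))), 1e-3)
  }
  # aligned difference matches the drift-free difference
  expect_lt(nrmse(dks_d$diff, dks_c$diff), 1e-3)
  # without drift, alignment is nearly a no-op relative to naive subtraction
  # (the estimated rotation is not exactly zero because the ASL difference
  # itself contributes a small phase to the k-space center)
  naive <- clean$raw$control - clean$raw$label
  expect_lt(max(abs(dks_c$phase)), 5e-3)
  # a phi-sized rotation of the static-dominated control leaks O(phi*static)
  # into the difference, so the no-op bound is proportional to static/ASL
  expect_lt(nrmse(dks_c$diff, naive), 0.05)
  # pure-noise input survives without exceptions
  pn <- clean$raw
  set.seed(1)
  pn$label[] <- complex(real = rnorm(length(pn$label)),
                        imaginary = rnorm(length(pn$label)))
  pn$control[] <- complex(real = rnorm(length(pn$control)),
                          imaginary = rnorm(length(pn$control)))
  expect_true(all(is.finite(Mod(phase_align_subtract(pn)$diff))))
})

test_that("CG-SENSE solves the Nyquist-sampled problem to high accuracy", {
  # independent oracle: data generated by the direct non-uniform DFT of a
  # smooth static image; the solver must invert them
  cfg <- acquisition_config(matrix = 12, n_pairs = 8,
                            readout_duration_after_label = 0.3233,
                            n_spokes_per_prep = 36, t_max = 0.3233,
                            pf_factor = 1)
  sched <- build_schedule(cfg)
  spec <- phantom_spec(grid = 12, n_coils = 2, seed = 5)
  coils <- coil_model(spec)
  x <- smooth_blobs(12, cfg$fov)
  dks <- static_dks_direct(x, coils, cfg, sched)
  frames <- bin_frames(cfg, cfg$t_max)
  op <- build_encoding(dks$schedule, cfg, frames, coils)
  expect_lt(adjoint_test(op, seed = 2), 1e-6)
  res <- cg_sense(dks, op, recon_config("cg-sense", n_iters = 30))
  expect_lt(nrmse(res$data[, , , 1], x), 0.05)
  # the quadratic objective is monotone nonincreasing over CG iterations
  expect_true(all(diff(res$trace[, "objective"]) <= 1e-8 * res$trace[1, 1]))
})

test_that("large temporal weight drives frames toward their temporal mean", {
  s <- tiny_setup(noise_sigma = 0.02)
  dks <- phase_align_subtract(s$raw)
  frames <- bin_frames(s$cfg, 12 * s$cfg$spoke_interval)
  op <- build_encoding(dks$schedule, s$cfg, frames, s$coils)
  res <- cg_sense(dks, op, recon_config("cg-sense", n_iters = 20,
                                        lambda_temporal = 1e8))
  x <- res$data
  mu <- apply(x, 1:3, mean)
  spread <- max(vapply(seq_len(dim(x)[4]),
                       function(k) max(Mod(x[, , , k] - mu)), numeric(1)))
  expect_lt(spread, 1e-2 * max(Mod(mu)))
})

test_that("singular-value soft-thresholding zeroes matrices below threshold", {
  set.seed(8)
  M <- matrix(complex(real = rnorm(9), imaginary = rnorm(9)), 3, 3)
  smax <- max(svd(M)$d)
  expect_equal(capria:::svt(M, smax * 1.01), matrix(0i, 3, 3))
  # partial threshold reduces each singular value by exactly the threshold
  th <- 0.3 * smax
  d0 <- svd(M)$d
  d1 <- svd(capria:::svt(M, th))$d
  expect_equal(d1, pmax(d0 - th, 0), tolerance = 1e-10)
})

test_that("LLR with zero penalty matches the least-squares CG solution", {
  cfg <- acquisition_config(matrix = 12, n_pairs = 8,
                            readout_duration_after_label = 0.3233,
                            n_spokes_per_prep = 36, t_max = 0.3233,
                            pf_factor = 1)
  sched <- build_schedule(cfg)
  spec <- phantom_spec(grid = 12, n_coils = 2, seed = 5)
  coils <- coil_model(spec)
  x <- smooth_blobs(12, cfg$fov)
  dks <- static_dks_direct(x, coils, cfg, sched)
  frames <- bin_frames(cfg, cfg$t_max)
  op <- build_encoding(dks$schedule, cfg, frames, coils)
  cg <- cg_sense(dks, op, recon_config("cg-sense", n_iters = 30))
  ll <- llr_recon(dks, op, recon_config("llr", lambda_llr = 0, n_iters = 60,
                                        patch_size = 4, seed = 3))
  expect_lt(nrmse(ll$data, cg$data), 0.02)
  # best-iterate objective is nonincreasing by construction
  expect_true(all(diff(cummin(ll$trace[, "objective"])) <= 0))
})

test_that("LLR beats CG-SENSE on a locally rank-1 series at matched noise", {
  # every patch of the series is rank-1 in space x time by construction
  cfg <- acquisition_config(matrix = 12, n_pairs = 2,
                            readout_duration_after_label = 0.3233,
                            n_spokes_per_prep = 36, t_max = 0.3233)
  sched <- build_schedule(cfg)
  spec <- phantom_spec(grid = 12, n_coils = 3, seed = 5)
  coils <- coil_model(spec)
  frames <- bin_frames(cfg, 12 * cfg$spoke_interval)
  lab <- dplyr::arrange(dplyr::filter(sched, cond == "label"), pair, i)
  op <- build_encoding(lab, cfg, frames, coils)
  xs <- smooth_blobs(12, cfg$fov)
  tc <- c(1, 0.7, 0.4)
  x4 <- array(0i, c(12, 12, 12, 3))
  for (k in 1:3) x4[, , , k] <- xs * tc[k]
  y <- op$forward(x4)
  set.seed(17)
  sigma <- 0.1 * sd(Mod(unlist(y)))
  y <- lapply(y, function(m) m + complex(real = rnorm(length(m), 0, sigma),
                                         imaginary = rnorm(length(m), 0, sigma)))
  # wrap as a difference container
  ns <- length(capria:::spoke_radial_coords(cfg))
  diff <- array(0i, c(nrow(lab), ns, 3))
  for (k in 1:3) {
    rows <- op$frame_rows[[k]]
    diff[rows, , ] <- array(aperm(array(y[[k]], c(ns, length(rows), 3)),
                                  c(2, 1, 3)), c(length(rows), ns, 3))
  }
  dks <- structure(list(diff = diff, phase = rep(0, nrow(lab)), schedule = lab,
                        config = cfg, radial_coords = capria:::spoke_radial_coords(cfg)),
                   class = "capria_diff")
  cg <- cg_sense(dks, op, recon_config("cg-sense", n_iters = 12))
  ll <- llr_recon(dks, op, recon_config("llr", lambda_llr = 0.02,
                                        patch_size = 4, n_iters = 25, seed = 3))
  expect_lt(nrmse(Mod(ll$data), Mod(x4)), nrmse(Mod(cg$data), Mod(x4)))
})

test_that("low-resolution perfusion recon uses central k-space consistently", {
  fa <- make_schedule("constant", 1, 1, 36)
  s <- tiny_setup(noise_sigma = 0, grid = 16L, n_pairs = 4L, n_coils = 2L,
                  fa = fa)
  dks <- phase_align_subtract(s$raw)
  frames <- bin_frames(s$cfg, s$cfg$t_max)
  sens_lo <- estimate_sensitivities(s$raw, matrix = 8)
  res <- recon_lowres_perfusion(dks, 8, frames, sens_lo$sens,
                                recon_config("cg-sense", n_iters = 15))
  expect_equal(dim(res$data)[1], 8)
  expect_equal(attr(res, "undersampling"),
               undersampling_factor(8, 4 * 36))
  # low matrix = full matrix reproduces the standard recon
  sens_f <- estimate_sensitivities(s$raw, matrix = 16)
  full_lo <- recon_lowres_perfusion(dks, 16, frames, sens_f$sens,
                                    recon_config("cg-sense", n_iters = 10))
  op_f <- build_encoding(dks$schedule, s$cfg, frames, sens_f$sens)
  full <- cg_sense(dks, op_f, recon_config("cg-sense", n_iters = 10))
  expect_lt(nrmse(full_lo$data, full$data), 1e-10)
  # low-pass consistency: the low-res recon approximates the Fourier-cropped
  # full recon once intensities are put on the same per-voxel convention
  # (a coarse voxel integrates (m/m_low)^3 fine voxels)
  ds <- array(0i, c(8, 8, 8, dim(full$data)[4]))
  for (k in seq_len(dim(full$data)[4]))
    ds[, , , k] <- fourier_downsample(full$data[, , , k], 8) * (16 / 8)^3
  expect_lt(nrmse(Mod(res$data), Mod(ds)), 0.10)
  expect_error(recon_lowres_perfusion(dks, 32, frames, sens_lo$sens),
               "must not exceed")
})

test_that("the density-compensated quick look shows the object", {
  fa <- make_schedule("constant", 1, 1, 36)
  s <- tiny_setup(noise_sigma = 0, n_pairs = 4L, n_coils = 2L, fa = fa)
  dks <- phase_align_subtract(s$raw)
  img <- quicklook_gridded(dks, matrix = 12)
  frames <- bin_frames(s$cfg, s$cfg$t_max)
  truth <- apply(truth_frame_average(s$spec, s$cfg, fa$alpha, frames), 1:3, mean)
  expect_gt(cor(as.vector(img), as.vector(abs(truth))), 0.7)
  # raw-condition quick look is dominated by the static anatomy
  img_lab <- quicklook_gridded(s$raw, matrix = 12, what = "label")
  expect_gt(cor(as.vector(img_lab), as.vector(capria:::static_background(s$spec))),
            0.7)
})

test_that("series tidiers and NIfTI export round-trip metadata", {
  s <- tiny_setup(noise_sigma = 0, n_coils = 2L)
  dks <- phase_align_subtract(s$raw)
  frames <- bin_frames(s$cfg, 18 * s$cfg$spoke_interval)
  op <- build_encoding(dks$schedule, s$cfg, frames, s$coils)
  res <- cg_sense(dks, op, recon_config("cg-sense", n_iters = 5))
  td <- tidy(res)
  expect_equal(nrow(td), 2)
  expect_named(td, c("frame", "pld", "mean_abs", "max_abs"))
  gl <- glance(res)
  expect_equal(gl$solver, "cg-sense")
  expect_equal(gl$n_frames, 2L)
  path <- tempfile(fileext = ".nii.gz")
  write_series_nifti(res, path)
  img <- RNifti::readNifti(path)
  expect_equal(dim(img), c(12, 12, 12, 2))
  expect_equal(RNifti::pixdim(img)[1], res$voxel_size, tolerance = 1e-6)
  expect_true(file.exists(paste0(path, ".json")))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$solver, "cg-sense")
  # sidecar validates against the shipped schema; a mangled one does not
  expect_true(validate_provenance(paste0(path, ".json")))
  bad <- meta; bad$solver <- "magic"
  expect_error(validate_provenance(bad), "unknown solver")
  expect_error(validate_provenance(meta[setdiff(names(meta), "window_s")]),
               "missing fields")
  unlink(c(path, paste0(path, ".json")))
})
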