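test_that("phantom truth respects the kinetic models voxelwise", {
  spec <- phantom_spec(grid = 12, n_coils = 2, seed = 1)
  cfg <- acquisition_config(matrix = 12, n_pairs = 2)
  fa <- make_schedule("quadratic", 2, 9, 216)
  times <- cfg$tau + (0:215) * cfg$spoke_interval
  idx <- c(1, 60, 140, 216)
  truth <- truth_difference_series(spec, times[idx], fa$alpha[idx], cfg$tau)
  comps <- capria:::phantom_components(spec)
  # every voxel is the component-map sum weighted by the kinetic models:
  # cross-check the full series against independent per-component evaluation
  expected <- array(0, dim(truth))
  for (comp in comps) {
    w <- if (comp$kind == "vessel") {
      p <- kinetic_params(delta_t = comp$delta_t, v = 1)
      angio_signal(p, fa$alpha[idx], times[idx], cfg$tau)
    } else {
      p <- kinetic_params(Delta_t = comp$Delta_t, T1t = comp$T1t, f = comp$f)
      perfusion_signal(p, fa$alpha[idx], times[idx], cfg$tau)
    }
    for (k in seq_along(idx))
      expected[, , , k] <- expected[, , , k] + comp$map * w[k]
  }
  expect_equal(truth, expected, tolerance = 1e-12)
  # the brightest tissue voxel's timecourse is dominated by perfusion_signal
  tis <- comps[[which(vapply(comps, `[[`, "", "kind") == "tissue")[1]]]
  vox <- which.max(tis$map)
  p <- kinetic_params(Delta_t = tis$Delta_t, T1t = tis$T1t, f = tis$f)
  pure <- tis$map[vox] * perfusion_signal(p, fa$alpha[idx], times[idx], cfg$tau)
  got <- vapply(seq_along(idx), function(k) truth[, , , k][vox], numeric(1))
  expect_equal(got[3:4], pure[3:4], tolerance = 0.15)
  # zero flip angles give a zero series
  z <- truth_difference_series(spec, times[idx], rep(0, 4), cfg$tau)
  expect_true(all(z == 0))
  # a vessel arriving after the readout contributes nothing: the series
  # equals the tissue-only phantom's
  spec2 <- spec
  spec2$vessel_segments$delta_t <- 10
  spec3 <- spec
  spec3$vessel_segments <- spec3$vessel_segments[0, ]
  z2 <- truth_difference_series(spec2, times[idx], fa$alpha[idx], cfg$tau)
  z3 <- truth_difference_series(spec3, times[idx], fa$alpha[idx], cfg$tau)
  expect_equal(z2, z3, tolerance = 1e-12)
})

test_that("simulated k-space is seeded, linear and condition-differenced", {
  s1 <- tiny_setup(noise_sigma = 0.05, seed = 21)
  s2 <- tiny_setup(noise_sigma = 0.05, seed = 21)
  expect_identical(s1$raw$label, s2$raw$label)
  expect_identical(s1$raw$control, s2$raw$control)
  s3 <- tiny_setup(noise_sigma = 0.05, seed = 22)
  expect_false(identical(s1$raw$label, s3$raw$label))
  # doubling a vessel's blood volume doubles its difference-domain signal
  base <- tiny_setup(noise_sigma = 0)
  spec2 <- base$spec
  spec2$vessel_segments$v[1] <- 2 * spec2$vessel_segments$v[1]
  raw2 <- simulate_kspace(spec2, base$coils, base$sched, base$cfg, base$fa)
  d1 <- base$raw$control - base$raw$label
  d2 <- raw2$control - raw2$label
  # subtract the contribution of unchanged components: the residual is the
  # first vessel's signal, which must exactly double
  spec_only1 <- base$spec
  spec_only1$tissue_regions <- spec_only1$tissue_regions[0, ]
  spec_only1$vessel_segments <- spec_only1$vessel_segments[1, ]
  raw_only1 <- simulate_kspace(spec_only1, base$coils, base$sched, base$cfg, base$fa)
  dv <- raw_only1$control - raw_only1$label
  expect_equal(d2 - d1, dv, tolerance = 1e-10)
})

test_that("mismatched schedule and config are rejected", {
  s <- tiny_setup()
  bad_cfg <- acquisition_config(matrix = 12, n_pairs = 3,
                                readout_duration_after_label = 0.3233,
                                n_spokes_per_prep = 36, t_max = 0.3233)
  expect_error(simulate_kspace(s$spec, s$coils, s$sched, bad_cfg, s$fa),
               "spoke count")
  expect_error(simulate_kspace(s$spec, s$coils, s$sched, s$cfg, rep(6, 10)),
               "length")
})

test_that("coil model covers the object with nonzero sensitivity", {
  spec <- phantom_spec(grid = 12, n_coils = 5, seed = 1)
  coils <- coil_model(spec)
  rss <- sqrt(apply(Mod(coils)^2, 1:3, sum))
  expect_true(all(rss > 0))
  expect_equal(dim(coils)[4], 5)
})

test_that("splitting halves partitions pairs and concatenates back exactly", {
  s <- tiny_setup(noise_sigma = 0.05, n_pairs = 4L)
  h <- split_halves(s$raw)
  expect_equal(h$first$config$n_pairs, 2L)
  expect_equal(h$second$config$n_pairs, 2L)
  expect_identical(abind_spokes(h), s$raw$label)
  # 2 pairs split 1/1
  s2 <- tiny_setup(n_pairs = 2L)
  h2 <- split_halves(s2$raw)
  expect_equal(h2$first$config$n_pairs, 1L)
  # odd pair count warns
  s3 <- tiny_setup(n_pairs = 3L)
  expect_warning(split_halves(s3$raw), "odd")
  expect_error(split_halves(tiny_setup(n_pairs = 1L)$raw), "at least 2")
})

test_that("the first half of a long scan is bit-identical to a short scan", {
  long <- tiny_setup(noise_sigma = 0.05, n_pairs = 4L, seed = 33)
  short <- tiny_setup(noise_sigma = 0.05, n_pairs = 2L, seed = 33)
  h <- split_halves(long$raw)
  expect_identical(h$first$label, short$raw$label)
  expect_identical(h$first$control, short$raw$control)
  expect_equal(h$first$schedule$m, short$raw$schedule$m)
  expect_equal(h$first$schedule$t, short$raw$schedule$t)
})

test_that("adjoint of the simulated data reproduces the truth's dominant structure", {
  # near-static difference (constant 1 deg flip, bolus spanning the readout)
  # at full Nyquist sampling reconstructs the window-averaged truth closely
  cfg <- acquisition_config(matrix = 16, n_pairs = 12,
                            readout_duration_after_label = 0.3233,
                            n_spokes_per_prep = 36, t_max = 0.3233,
                            pf_factor = 1)
  sched <- build_schedule(cfg)
  fa <- make_schedule("constant", 1, 1, 36)
  vs <- default_vessels(183)
  vs$delta_t <- c(0.5, 0.6, 0.7)
  spec <- phantom_spec(grid = 16, vessel_segments = vs,
                       tissue_regions = default_tissue(183)[0, ],
                       noise_sigma = 0, n_coils = 2, seed = 5)
  coils <- coil_model(spec)
  raw <- simulate_kspace(spec, coils, sched, cfg, fa)
  dks <- phase_align_subtract(raw)
  frames <- bin_frames(cfg, cfg$t_max)
  op <- build_encoding(dks$schedule, cfg, frames, coils)
  expect_lte(undersampling_factor(16, 12 * 36), 1)
  res <- cg_sense(dks, op, recon_config("cg-sense", n_iters = 40))
  truth <- truth_frame_average(spec, cfg, fa, frames)
  expect_lt(nrmse(res$data[, , , 1], truth[, , , 1]), 0.05)
})
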