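# small shared fixtures: a 12^3 phantom acquisition that exercises the whole
# simulate -> subtract -> reconstruct chain in a few seconds

tiny_setup <- function(noise_sigma = 0, n_pairs = 2L, n_coils = 3L,
                       phase_drift = 0, seed = 11L, grid = 12L,
                       fa = NULL) {
  cfg <- acquisition_config(matrix = grid, n_pairs = n_pairs,
                            readout_duration_after_label = 0.3233,
                            n_spokes_per_prep = 36, t_max = 0.3233)
  sched <- build_schedule(cfg)
  if (is.null(fa)) fa <- make_schedule("constant", 6, 6, 36)
  spec <- phantom_spec(grid = grid, noise_sigma = noise_sigma,
                       phase_drift = phase_drift, n_coils = n_coils,
                       seed = seed)
  coils <- coil_model(spec)
  raw <- simulate_kspace(spec, coils, sched, cfg, fa)
  list(cfg = cfg, sched = sched, fa = fa, spec = spec, coils = coils,
       raw = raw)
}

# a static "difference" dataset generated by the direct slow DFT, for solver
# oracle tests: the data correspond exactly to one time-invariant image
static_dks_direct <- function(x_true, coils, cfg, schedule) {
  lab <- dplyr::arrange(dplyr::filter(schedule, cond == "label"), pair, i)
  r <- capria:::spoke_radial_coords(cfg)
  ns <- length(r)
  nsp <- nrow(lab)
  dirs <- cbind(sin(lab$theta) * cos(lab$phi),
                sin(lab$theta) * sin(lab$phi), cos(lab$theta))
  coords <- dirs[rep(seq_len(nsp), each = ns), , drop = FALSE] * rep(r, nsp)
  C <- dim(coils)[4]
  diff <- array(0i, c(nsp, ns, C))
  for (c in seq_len(C)) {
    y <- ndft_direct((x_true + 0i) * coils[, , , c], coords, cfg$fov)
    diff[, , c] <- matrix(y, nsp, ns, byrow = TRUE)
  }
  structure(list(diff = diff, phase = rep(0, nsp), schedule = lab,
                 config = cfg, radial_coords = r),
            class = "capria_diff")
}

# reassemble the label k-space of two split halves along the spoke axis
abind_spokes <- function(halves) {
  a <- halves$first$label; b <- halves$second$label
  out <- array(0i, c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

# smooth multi-blob test image on the phantom grid
smooth_blobs <- function(m, fov) {
  p <- ((0:(m - 1)) - m / 2) * (fov / m)
  g <- expand.grid(x = p, y = p, z = p)
  blob <- function(cx, cy, cz, s, a)
    a * exp(-((g$x - cx)^2 + (g$y - cy)^2 + (g$z - cz)^2) / (2 * s^2))
  array(blob(-0.2 * fov / 2, 0.1 * fov / 2, 0, 0.2 * fov, 1) +
          blob(0.25 * fov / 2, -0.15 * fov / 2, -0.1 * fov / 2, 0.15 * fov, 0.7) +
          blob(0, 0.2 * fov / 2, 0.15 * fov / 2, 0.25 * fov, 0.4),
        rep(m, 3))
}
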