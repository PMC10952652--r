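#' Dynamic digital head phantom specification
#'
#' A compact head-like phantom carrying the signal structure the reconstruction
#' assumes: tubular vessel segments with macrovascular transit delays `delta_t`
#' and blood volumes `v` following the angiographic model, ellipsoidal tissue
#' regions with perfusion `f` and tissue arrival `Delta_t` following the Buxton
#' model, and a static background (an ellipsoidal "head" with internal
#' contrast) that exercises sensitivity estimation and phase alignment. The
#' seed fully determines the simulated raw data.
#'
#' Vessel centerlines are polylines in mm (origin at the grid center); any
#' voxel within `radius` of a segment belongs to the vessel. Voxels claimed by
#' both a vessel and a tissue region are resolved vessel-first.
#'
#' @param grid Isotropic ground-truth matrix size (even; default 48).
#' @param fov Field of view (mm).
#' @param vessel_segments Tibble/data.frame with columns `x0,y0,z0,x1,y1,z1`
#'   (mm), `radius` (mm), `delta_t` (s), `v`.
#' @param tissue_regions Tibble with columns `cx,cy,cz` (mm), `rx,ry,rz` (mm),
#'   `f` (s^-1), `Delta_t` (s), `T1t` (s).
#' @param static_intensity Peak static background intensity (arbitrary units;
#'   large relative to the ASL difference so central k-space phase is
#'   static-dominated, as in vivo).
#' @param smooth_sigma Partial-volume rendering width (mm): every rasterized
#'   structure map is Gaussian-smoothed with this standard deviation so the
#'   phantom is resolved at the simulation grid rather than aliased binary
#'   masks. Default one voxel.
#' @param noise_sigma Complex-noise standard deviation per k-space sample.
#' @param phase_drift Per-preparation phase increment applied to the control
#'   condition (rad per pair; 0 disables drift).
#' @param n_coils Number of receive coils.
#' @param seed Integer seed that fully determines the simulation.
#' @return Object of class `capria_phantom` (named list).
#' @export
phantom_spec <- function(grid = 48L, fov = 183,
                         vessel_segments = default_vessels(fov),
                         tissue_regions = default_tissue(fov),
                         static_intensity = 10,
                         smooth_sigma = fov / grid,
                         noise_sigma = 0.2,
                         phase_drift = 0,
                         n_coils = 8L,
                         seed = 1L) {
  stopifnot(grid %% 2 == 0, fov > 0, n_coils >= 1, smooth_sigma >= 0)
  if (any(vessel_segments$v < 0) || any(tissue_regions$f < 0))
    abort("blood volumes and perfusion must be nonnegative.")
  structure(list(grid = as.integer(grid), fov = fov,
                 vessel_segments = as_tibble(vessel_segments),
                 tissue_regions = as_tibble(tissue_regions),
                 static_intensity = static_intensity,
                 smooth_sigma = smooth_sigma,
                 noise_sigma = noise_sigma,
                 phase_drift = phase_drift,
                 n_coils = as.integer(n_coils),
                 seed = as.integer(seed)),
            class = "capria_phantom")
}

# isotropic Gaussian smoothing (sigma in mm) by Fourier multiplication; exact
# for the periodic grid and fast enough to apply per structure map
gaussian_smooth3 <- function(x, sigma_mm, fov) {
  if (sigma_mm <= 0) return(x)
  m <- dim(x)[1]
  k <- (c(0:(m / 2 - 1), -(m / 2):-1)) / fov  # cycles/mm, unshifted order
  h1 <- exp(-2 * pi^2 * sigma_mm^2 * k^2)
  H <- outer(outer(h1, h1), h1)
  Re(stats::fft(stats::fft(x + 0i) * H, inverse = TRUE)) / m^3
}

#' @rdname phantom_spec
#' @export
default_vessels <- function(fov = 183) {
  r <- fov / 2
  tibble(
    x0 = c(0.05, -0.30, 0.02) * r, y0 = c(-0.55, -0.45, 0.10) * r,
    z0 = c(-0.55, -0.35, -0.10) * r,
    x1 = c(0.05, -0.45, 0.40) * r, y1 = c(-0.10, 0.15, 0.35) * r,
    z1 = c(0.30, 0.25, 0.35) * r,
    radius = c(0.055, 0.045, 0.04) * fov / 2,
    delta_t = c(0.30, 0.55, 0.85),
    v = c(0.030, 0.022, 0.015)
  )
}

#' @rdname phantom_spec
#' @export
default_tissue <- function(fov = 183) {
  r <- fov / 2
  tibble(
    cx = c(-0.25, 0.30) * r, cy = c(0.15, 0.05) * r, cz = c(0.15, 0.05) * r,
    rx = c(0.38, 0.30) * r, ry = c(0.40, 0.35) * r, rz = c(0.35, 0.38) * r,
    f = c(50, 35) / 100 / 60,
    Delta_t = c(1.0, 1.5),
    T1t = c(1.3, 1.3)
  )
}

# cell-centered voxel center coordinates (mm), origin at grid center
voxel_positions <- function(grid, fov) {
  ((0:(grid - 1)) - grid / 2) * (fov / grid)
}

# distance from every voxel to a 3D line segment; returns logical mask array
segment_mask <- function(grid, fov, x0, y0, z0, x1, y1, z1, radius) {
  p <- voxel_positions(grid, fov)
  g <- expand.grid(x = p, y = p, z = p)
  d <- c(x1 - x0, y1 - y0, z1 - z0)
  len2 <- sum(d^2)
  wx <- g$x - x0; wy <- g$y - y0; wz <- g$z - z0
  t <- if (len2 > 0) pmin(1, pmax(0, (wx * d[1] + wy * d[2] + wz * d[3]) / len2)) else 0
  dist2 <- (wx - t * d[1])^2 + (wy - t * d[2])^2 + (wz - t * d[3])^2
  array(dist2 <= radius^2, rep(grid, 3))
}

ellipsoid_mask <- function(grid, fov, cx, cy, cz, rx, ry, rz) {
  p <- voxel_positions(grid, fov)
  g <- expand.grid(x = p, y = p, z = p)
  q <- ((g$x - cx) / rx)^2 + ((g$y - cy) / ry)^2 + ((g$z - cz) / rz)^2
  array(q <= 1, rep(grid, 3))
}

# Decompose the phantom into separable components Delta_M_i(x) =
# sum_c S_c(x) w_c(i): each vessel/tissue structure has one spatial map and one
# per-pulse temporal weight. Vessel-first assignment: tissue maps exclude
# vessel voxels.
phantom_components <- function(spec) {
  m <- spec$grid
  vs <- spec$vessel_segments
  vessel_masks <- purrr::pmap(vs, function(x0, y0, z0, x1, y1, z1, radius, ...)
    segment_mask(m, spec$fov, x0, y0, z0, x1, y1, z1, radius))
  all_vessel <- Reduce(`|`, vessel_masks, array(FALSE, rep(m, 3)))
  sm <- function(map) gaussian_smooth3(map, spec$smooth_sigma, spec$fov)
  comps <- purrr::map2(vessel_masks, seq_len(nrow(vs)), function(mask, k) {
    list(kind = "vessel",
         map = sm(mask * vs$v[k]),   # blood volume folded into the spatial map
         delta_t = vs$delta_t[k], v = vs$v[k],
         core = mask)
  })
  ts <- spec$tissue_regions
  tissue <- purrr::map(seq_len(nrow(ts)), function(k) {
    mask <- ellipsoid_mask(m, spec$fov, ts$cx[k], ts$cy[k], ts$cz[k],
                           ts$rx[k], ts$ry[k], ts$rz[k]) & !all_vessel
    list(kind = "tissue", map = sm(mask * 1),
         f = ts$f[k], Delta_t = ts$Delta_t[k], T1t = ts$T1t[k],
         core = mask)
  })
  c(comps, tissue)
}

#' True vessel voxel mask of a phantom
#'
#' The unsmoothed rasterized union of all vessel segments, for mask-coverage
#' and time-to-peak evaluations.
#'
#' @param spec A [phantom_spec()].
#' @return Logical array.
#' @export
phantom_vessel_voxels <- function(spec) {
  vs <- spec$vessel_segments
  masks <- purrr::pmap(vs, function(x0, y0, z0, x1, y1, z1, radius, ...)
    segment_mask(spec$grid, spec$fov, x0, y0, z0, x1, y1, z1, radius))
  Reduce(`|`, masks, array(FALSE, rep(spec$grid, 3)))
}

# per-pulse temporal weight for one component (unit amplitude spatially)
component_weight <- function(comp, times, alpha, tau) {
  if (comp$kind == "vessel") {
    p <- kinetic_params(delta_t = comp$delta_t, v = 1)
    angio_signal(p, alpha, times, tau)
  } else {
    p <- kinetic_params(Delta_t = comp$Delta_t, T1t = comp$T1t, f = comp$f)
    perfusion_signal(p, alpha, times, tau)
  }
}

# static background: head ellipsoid with a dimmer inner ellipsoid for
# contrast, rendered with the same partial-volume smoothing
static_background <- function(spec) {
  m <- spec$grid; fov <- spec$fov; r <- fov / 2
  head <- ellipsoid_mask(m, fov, 0, 0, 0, 0.7 * r, 0.8 * r, 0.75 * r)
  inner <- ellipsoid_mask(m, fov, 0.1 * r, 0, 0.05 * r, 0.3 * r, 0.35 * r, 0.3 * r)
  gaussian_smooth3(spec$static_intensity * (head * 1 - 0.35 * inner),
                   spec$smooth_sigma, fov)
}

#' Smooth complex coil sensitivity maps
#'
#' Gaussian receive lobes centered on a ring around the object with a smooth
#' linear phase ramp per coil; deterministic given the geometry.
#'
#' @param spec A [phantom_spec()].
#' @return Complex array `grid x grid x grid x n_coils` of class
#'   `capria_coils`; root-sum-of-squares is positive over the whole grid.
#' @export
coil_model <- function(spec) {
  m <- spec$grid; fov <- spec$fov
  p <- voxel_positions(m, fov)
  g <- expand.grid(x = p, y = p, z = p)
  C <- spec$n_coils
  ang <- 2 * pi * (seq_len(C) - 1) / C
  rad <- 0.75 * fov / 2
  sig <- 0.6 * fov
  sens <- array(0i, c(m, m, m, C))
  for (c in seq_len(C)) {
    cx <- rad * cos(ang[c]); cy <- rad * sin(ang[c])
    cz <- rad * 0.3 * sin(2 * ang[c])
    mag <- 0.2 + exp(-((g$x - cx)^2 + (g$y - cy)^2 + (g$z - cz)^2) / (2 * sig^2))
    ph <- 0.8 * pi * (g$x * cos(ang[c]) + g$y * sin(ang[c])) / fov + ang[c] / 3
    sens[, , , c] <- array(complex(modulus = mag, argument = ph), rep(m, 3))
  }
  structure(sens, class = "capria_coils")
}

#' Ground-truth ASL difference image series
#'
#' Evaluates the voxelwise difference magnetization at each requested pulse
#' time, with the flip-angle/RF-attenuation weighting of the corresponding
#' pulse index, so the series is non-stationary within a reconstruction window
#' exactly as in the acquired sequence.
#'
#' @param spec A [phantom_spec()].
#' @param times Pulse times since labeling onset (s), one per requested frame
#'   sample (typically the within-preparation pulse times).
#' @param fa_schedule Flip angles (degrees) aligned with `times`.
#' @param tau Labeling duration (s).
#' @return Real array `grid x grid x grid x length(times)`.
#' @export
truth_difference_series <- function(spec, times, fa_schedule, tau) {
  comps <- phantom_components(spec)
  alpha <- schedule_degrees(fa_schedule)
  out <- array(0, c(rep(spec$grid, 3), length(times)))
  for (comp in comps) {
    w <- component_weight(comp, times, alpha, tau)
    nz <- which(w != 0)
    for (k in nz) out[, , , k] <- out[, , , k] + comp$map * w[k]
  }
  out
}

#' Window-averaged ground-truth frames
#'
#' The reconstruction estimates, per frame, the temporal average of the
#' difference signal over the spokes in its window; this returns that average
#' for direct comparison with reconstructed frames.
#'
#' @param spec A [phantom_spec()].
#' @param config [acquisition_config()].
#' @param fa_schedule Flip angles (degrees), length `N`.
#' @param frames A [bin_frames()] tibble.
#' @return Real array `grid^3 x n_frames`.
#' @export
truth_frame_average <- function(spec, config, fa_schedule, frames) {
  N <- config$n_spokes_per_prep
  times <- config$tau + config$post_label_gap + (seq_len(N) - 1) * config$spoke_interval
  comps <- phantom_components(spec)
  alpha <- schedule_degrees(fa_schedule)
  out <- array(0, c(rep(spec$grid, 3), nrow(frames)))
  for (comp in comps) {
    w <- component_weight(comp, times, alpha, config$tau)
    for (k in seq_len(nrow(frames))) {
      wk <- mean(w[frames$first_i[k]:frames$last_i[k]])
      if (wk != 0) out[, , , k] <- out[, , , k] + comp$map * wk
    }
  }
  out
}

# deterministic per-preparation seed stream so that simulating P pairs and
# simulating the first P/2 pairs produce bit-identical k-space for the shared
# preparations (split-scan equivalence)
prep_seed <- function(seed, pair) {
  as.integer((as.numeric(seed) * 10007 + 7919 * as.numeric(pair)) %% 2147483647)
}

#' Simulate multi-coil radial label/control k-space
#'
#' Forward-simulates the phantom along the exact golden-means trajectory:
#' label/control images are `static -/+ DeltaM/2` (so control - label equals
#' the truth difference), multiplied by each coil sensitivity, sampled with the
#' gridding NUFFT at every spoke's readout coordinates with the per-pulse
#' flip-angle weighting of that spoke's acquisition time, plus i.i.d. complex
#' Gaussian noise drawn from a per-preparation seed stream (so discarding late
#' preparations is bit-identical to a shorter simulated scan). An optional
#' per-preparation phase drift is applied to the control condition.
#'
#' @param spec A [phantom_spec()]; `spec$grid` must match... the simulation grid.
#' @param coils A [coil_model()] array (or compatible complex array).
#' @param schedule A [build_schedule()] tibble.
#' @param config The [acquisition_config()] used for `schedule`.
#' @param fa_schedule Flip angles (degrees), length `N`.
#' @return Object of class `capria_raw`: list with complex arrays `label`,
#'   `control` (`n_spokes x n_samples x n_coils`), the label-side `schedule`,
#'   `config`, `fa_schedule`, `coils`, `spec`, and provenance.
#' @export
simulate_kspace <- function(spec, coils, schedule, config, fa_schedule) {
  stopifnot(inherits(config, "capria_config"))
  if (dim(coils)[1] != spec$grid)
    abort("coil grid does not match phantom grid.")
  m <- spec$grid
  alpha <- schedule_degrees(fa_schedule)
  if (length(alpha) != config$n_spokes_per_prep)
    abort("flip-angle schedule length does not match config N.")
  N <- config$n_spokes_per_prep
  P <- config$n_pairs
  lab <- dplyr::filter(schedule, .data$cond == "label")
  lab <- dplyr::arrange(lab, .data$pair, .data$i)
  n_spokes <- nrow(lab)
  if (n_spokes != N * P) abort("schedule does not match config (spoke count).")
  r <- spoke_radial_coords_scaled(config, m)
  ns <- length(r)
  C <- dim(coils)[4]
  # all sample coordinates, spoke-major (sample index fastest)
  dirs <- cbind(sin(lab$theta) * cos(lab$phi),
                sin(lab$theta) * sin(lab$phi),
                cos(lab$theta))
  coords <- cbind(rep(r, n_spokes) * dirs[rep(seq_len(n_spokes), each = ns), 1],
                  rep(r, n_spokes) * dirs[rep(seq_len(n_spokes), each = ns), 2],
                  rep(r, n_spokes) * dirs[rep(seq_len(n_spokes), each = ns), 3])
  op <- make_nufft(coords, m, spec$fov)
  comps <- phantom_components(spec)
  weights <- lapply(comps, component_weight, times = lab$t[seq_len(N)],
                    alpha = alpha, tau = config$tau)
  static <- static_background(spec)
  i_of_sample <- rep(lab$i, each = ns)  # within-prep pulse index per sample
  label <- array(0i, c(n_spokes, ns, C))
  control <- array(0i, c(n_spokes, ns, C))
  for (c in seq_len(C)) {
    sc <- coils[, , , c]
    f_static <- op$forward(static * sc)
    delta <- complex(real = numeric(length(f_static)))
    for (k in seq_along(comps)) {
      w <- weights[[k]]
      if (all(w == 0)) next
      f_comp <- op$forward(comps[[k]]$map * sc)
      delta <- delta + f_comp * w[i_of_sample]
    }
    label[, , c] <- matrix(f_static - 0.5 * delta, n_spokes, ns, byrow = TRUE)
    control[, , c] <- matrix(f_static + 0.5 * delta, n_spokes, ns, byrow = TRUE)
  }
  # per-preparation noise and drift
  for (p in seq_len(P)) {
    rows <- which(lab$pair == p)
    set.seed(prep_seed(spec$seed, p))
    if (spec$noise_sigma > 0) {
      nvals <- 2L * length(rows) * ns * C
      nn <- spec$noise_sigma * complex(real = rnorm(nvals), imaginary = rnorm(nvals))
      half <- nvals / 2
      label[rows, , ] <- label[rows, , ] +
        array(nn[seq_len(half)], c(length(rows), ns, C))
      control[rows, , ] <- control[rows, , ] +
        array(nn[half + seq_len(half)], c(length(rows), ns, C))
    }
    if (spec$phase_drift != 0)
      control[rows, , ] <- control[rows, , ] * exp(1i * spec$phase_drift * (p - 1))
  }
  structure(list(label = label, control = control,
                 schedule = lab, config = config,
                 fa_schedule = alpha, coils = coils, spec = spec,
                 radial_coords = r,
                 provenance = list(seed = spec$seed,
                                   noise_sigma = spec$noise_sigma,
                                   phase_drift = spec$phase_drift)),
            class = "capria_raw")
}

# radial sample positions for simulation/reconstruction at matrix size m
# (<= config$matrix): the acquired samples, possibly truncated to the central
# band for a low-resolution grid
spoke_radial_coords_scaled <- function(config, m) {
  r <- spoke_radial_coords(config)
  if (m < config$matrix) r <- r[abs(r) <= m / (2 * config$fov) + 1e-12]
  r
}

#' @export
print.capria_raw <- function(x, ...) {
  cat(sprintf("<capria_raw> %d spokes x %d samples x %d coils per condition (%d pairs)\n",
              dim(x$label)[1], dim(x$label)[2], dim(x$label)[3], x$config$n_pairs))
  cat(sprintf("  phantom grid %d, noise sigma %.3g, seed %d\n",
              x$spec$grid, x$spec$noise_sigma, x$spec$seed))
  invisible(x)
}

#' Split a raw container into two independent halves
#'
#' Partitions by preparation order: the first `floor(P/2)` pairs versus the
#' rest. Because the golden-means counter continues across preparations, the
#' first half is exactly the container a prospectively half-length scan would
#' produce; each half reconstructs independently.
#'
#' @param raw A [simulate_kspace()] container.
#' @return List of two `capria_raw` objects (`first`, `second`).
#' @export
split_halves <- function(raw) {
  P <- raw$config$n_pairs
  if (P < 2) abort("need at least 2 pairs to split.")
  if (P %% 2 == 1) warn("odd pair count: splitting floor/ceil.")
  take <- function(pairs, n_pairs) {
    rows <- which(raw$schedule$pair %in% pairs)
    cfg <- raw$config
    cfg$n_pairs <- as.integer(n_pairs)
    sch <- raw$schedule[rows, ]
    sch$pair <- match(sch$pair, pairs)  # renumber for standalone use
    out <- raw
    out$label <- raw$label[rows, , , drop = FALSE]
    out$control <- raw$control[rows, , , drop = FALSE]
    out$schedule <- sch
    out$config <- cfg
    out
  }
  h <- P %/% 2
  list(first = take(seq_len(h), h), second = take((h + 1):P, P - h))
}
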