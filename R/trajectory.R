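#' Acquisition configuration for a 4D radial ASL sequence
#'
#' Bundles the sequence timing and geometry constants that define a CAPRIA-style
#' acquisition: a PCASL preparation of duration `tau` followed by a continuous
#' train of `n_spokes_per_prep` non-selective excitations, each reading one
#' radial spoke ("koosh-ball" sampling). All times in seconds, lengths in mm.
#'
#' The excitation interval is stored as
#' `spoke_interval = readout_duration_after_label / n_spokes_per_prep`, which is
#' treated as authoritative (a protocol card typically prints the rounded TR).
#' `spokes_per_tmax` is derived as `round(t_max / spoke_interval)` and
#' `n_spokes_per_prep` must be an integer multiple of it so reconstruction
#' frames tile the readout.
#'
#' @param tau PCASL labeling duration (s).
#' @param readout_duration_after_label Total imaging time after labeling (s).
#' @param n_spokes_per_prep Spokes acquired per ASL preparation, `N`.
#' @param n_pairs Number of label/control pairs.
#' @param t_max Maximum temporal reconstruction window (s).
#' @param matrix Isotropic acquired matrix size (voxels).
#' @param fov Isotropic field of view (mm).
#' @param pf_factor Readout partial Fourier (asymmetric echo) fraction in (0.5, 1].
#' @param post_label_gap Dead time between end of labeling and the first
#'   excitation (s); not a printed protocol value, default 0.
#' @param interleave `"label-first"` (label prep immediately followed by its
#'   control prep, minimizing label/control separation) or `"alternate"`
#'   (control first).
#'
#' @return An object of class `capria_config` (a named list).
#' @examples
#' cfg <- acquisition_config()
#' cfg$spokes_per_tmax
#' @export
acquisition_config <- function(tau = 1.4,
                               readout_duration_after_label = 1.9397,
                               n_spokes_per_prep = 216L,
                               n_pairs = 88L,
                               t_max = 0.3233,
                               matrix = 160L,
                               fov = 183,
                               pf_factor = 0.79,
                               post_label_gap = 0,
                               interleave = c("label-first", "alternate")) {
  interleave <- match.arg(interleave)
  stopifnot(tau > 0, readout_duration_after_label > 0,
            n_spokes_per_prep >= 1, n_pairs >= 1, t_max > 0,
            matrix >= 2, fov > 0, post_label_gap >= 0)
  if (pf_factor <= 0.5 || pf_factor > 1)
    abort("`pf_factor` must lie in (0.5, 1] (<= 0.5 leaves no echo).")
  N <- as.integer(n_spokes_per_prep)
  spoke_interval <- readout_duration_after_label / N
  M <- as.integer(round(t_max / spoke_interval))
  if (M < 1L || N %% M != 0L)
    abort(sprintf(
      "`n_spokes_per_prep` (%d) must be an integer multiple of spokes_per_tmax (%d = round(t_max / spoke_interval)).",
      N, M))
  readout_samples <- as.integer(round(pf_factor * matrix))
  structure(list(
    tau = tau,
    readout_duration_after_label = readout_duration_after_label,
    spoke_interval = spoke_interval,
    n_spokes_per_prep = N,
    n_pairs = as.integer(n_pairs),
    t_max = t_max,
    spokes_per_tmax = M,
    matrix = as.integer(matrix),
    fov = fov,
    voxel_size = fov / matrix,
    pf_factor = pf_factor,
    readout_samples = readout_samples,
    post_label_gap = post_label_gap,
    interleave = interleave
  ), class = "capria_config")
}

#' @export
print.capria_config <- function(x, ...) {
  cat("<capria_config>\n")
  cat(sprintf("  labeling tau           %.4g s\n", x$tau))
  cat(sprintf("  readout                %.4g s  (%d spokes @ %.4f ms)\n",
              x$readout_duration_after_label, x$n_spokes_per_prep,
              1e3 * x$spoke_interval))
  cat(sprintf("  t_max                  %.4g s  (M = %d spokes)\n",
              x$t_max, x$spokes_per_tmax))
  cat(sprintf("  pairs                  %d\n", x$n_pairs))
  cat(sprintf("  matrix / FOV           %d / %.4g mm  (%.2f mm voxels)\n",
              x$matrix, x$fov, x$voxel_size))
  cat(sprintf("  partial Fourier        %.2f (%d readout samples)\n",
              x$pf_factor, x$readout_samples))
  invisible(x)
}

#' Multi-dimensional golden means for 3D radial sampling
#'
#' The two irrational increments that generate the polar and azimuthal angles of
#' a 3D golden-means radial trajectory. `phi2` is the real root of
#' \eqn{x^3 + x - 1 = 0} and `phi1` is its square; incrementing the fractional parts
#' of \eqn{m\,\phi_1} and \eqn{m\,\phi_2} distributes any contiguous run of
#' spokes near-uniformly over the sphere.
#'
#' @return Named numeric vector with elements `phi1` and `phi2`, both in (0, 1).
#' @examples
#' compute_golden_means()
#' @export
compute_golden_means <- function() {
  roots <- polyroot(c(-1, 1, 0, 1))  # x^3 + x - 1
  phi2 <- Re(roots[which.min(abs(Im(roots)))])
  # one Newton polish so the defining identity holds to machine precision
  phi2 <- phi2 - (phi2^3 + phi2 - 1) / (3 * phi2^2 + 1)
  c(phi1 = phi2^2, phi2 = phi2)
}

frac1 <- function(x) x - floor(x)

#' Orientation of the m-th golden-means radial spoke
#'
#' Polar angle \eqn{\theta = \arccos\{m\phi_1\}} and azimuth
#' \eqn{\varphi = 2\pi\{m\phi_2\}} for even `m`; for odd `m` the spoke direction
#' is reversed (\eqn{\theta = \arccos(-\{m\phi_1\})},
#' \eqn{\varphi = 2\pi\{m\phi_2 + 1/2\}}) so that an asymmetric (partial
#' Fourier) readout still covers both hemispheres evenly.
#'
#' @param m Nonnegative integer spoke counter (vectorized).
#' @param gm Golden means as returned by [compute_golden_means()].
#' @return Tibble with columns `m`, `theta` (rad, in \[0, pi\]) and `phi`
#'   (rad, in \[0, 2pi)).
#' @export
spoke_orientation <- function(m, gm = compute_golden_means()) {
  if (any(m < 0)) abort("spoke counter `m` must be nonnegative.")
  m <- as.numeric(m)
  f1 <- frac1(m * gm[["phi1"]])
  f2 <- frac1(m * gm[["phi2"]])
  odd <- (m %% 2) == 1
  theta <- ifelse(odd, acos(-f1), acos(f1))
  phi <- ifelse(odd, 2 * pi * frac1(f2 + 0.5), 2 * pi * f2)
  tibble(m = m, theta = theta, phi = phi)
}

#' Golden-ratio spoke counter
#'
#' Counter `m = i - 1 + (n - 1) * M` for the `i`-th spoke of the `n`-th
#' preparation, with `M` spokes per maximum temporal window. Consecutive
#' preparations thus continue the golden-means sequence only after `M` steps,
#' so any window up to `t_max` assembled across preparations is contiguous in
#' `m`.
#'
#' @param i Within-preparation spoke index, 1..N (vectorized).
#' @param n Preparation index, >= 1 (vectorized).
#' @param M Spokes per maximum temporal window.
#' @param N Spokes per preparation (used for range validation; default `Inf`).
#' @return Integer-valued numeric vector of counters.
#' @export
spoke_counter <- function(i, n, M, N = Inf) {
  if (any(i < 1) || any(i > N)) abort("`i` out of range 1..N.")
  if (any(n < 1)) abort("`n` must be >= 1.")
  (i - 1) + (n - 1) * M
}

#' Build the full interleaved spoke schedule
#'
#' Expands an acquisition configuration into the ordered list of acquired
#' spokes: every preparation contributes `N` spokes whose counters follow
#' [spoke_counter()], and each label preparation is immediately followed (or
#' preceded, for `interleave = "alternate"`) by a control preparation acquiring
#' the identical spokes, so label/control pairs match spoke-for-spoke and
#' complex subtraction needs no regridding. Timestamps are
#' `t_i = tau + post_label_gap + (i - 1) * spoke_interval` relative to labeling
#' onset.
#'
#' @param config A [acquisition_config()] object.
#' @return A tibble of class `capria_schedule` with columns `pair`, `cond`
#'   (`"label"`/`"control"`), `i`, `m`, `theta`, `phi`, `t`, ordered as
#'   acquired.
#' @export
build_schedule <- function(config) {
  stopifnot(inherits(config, "capria_config"))
  N <- config$n_spokes_per_prep
  M <- config$spokes_per_tmax
  P <- config$n_pairs
  gm <- compute_golden_means()
  conds <- if (config$interleave == "label-first") c("label", "control") else c("control", "label")
  one_prep <- function(pair) {
    i <- seq_len(N)
    m <- spoke_counter(i, pair, M, N)
    ori <- spoke_orientation(m, gm)
    t <- config$tau + config$post_label_gap + (i - 1) * config$spoke_interval
    tibble(pair = pair, i = i, m = m, theta = ori$theta, phi = ori$phi, t = t)
  }
  sched <- purrr::map_dfr(seq_len(P), function(p) {
    prep <- one_prep(p)
    dplyr::bind_rows(
      dplyr::mutate(prep, cond = conds[1], .before = "i"),
      dplyr::mutate(prep, cond = conds[2], .before = "i")
    )
  })
  sched <- dplyr::relocate(sched, "pair", "cond", "i", "m", "theta", "phi", "t")
  # pairing invariant: label and control entries identical up to condition
  lab <- dplyr::filter(sched, .data$cond == "label")
  ctl <- dplyr::filter(sched, .data$cond == "control")
  stopifnot(identical(lab[c("pair", "i", "m")], ctl[c("pair", "i", "m")]))
  class(sched) <- c("capria_schedule", class(sched))
  attr(sched, "config") <- config
  sched
}

#' Radial readout sample coordinates for one spoke
#'
#' Samples lie on the diameter line through the k-space origin with direction
#' `(sin theta cos phi, sin theta sin phi, cos theta)`, spaced `1/fov` apart.
#' With readout partial Fourier fraction `pf`, the radial coordinate runs from
#' `-(2 pf - 1) k_max` upward in `round(pf * matrix)` steps, where
#' `k_max = matrix / (2 fov)` (cycles/mm).
#'
#' @param theta,phi Spoke orientation (rad).
#' @param config A [acquisition_config()] object.
#' @return Matrix `readout_samples x 3` of k-space coordinates (cycles/mm).
#' @export
readout_sample_coords <- function(theta, phi, config) {
  stopifnot(inherits(config, "capria_config"))
  r <- spoke_radial_coords(config)
  dir <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  outer(r, dir)
}

# radial sample positions (cycles/mm) shared by all spokes
spoke_radial_coords <- function(config) {
  dk <- 1 / config$fov
  k_max <- config$matrix / (2 * config$fov)
  n <- config$readout_samples
  -(2 * config$pf_factor - 1) * k_max + dk * (seq_len(n) - 1)
}

#' Radial undersampling factor
#'
#' Ratio of the diameter-spoke count needed for Nyquist sampling of a 3D radial
#' trajectory, \eqn{\pi \cdot matrix^2 / 2}, to the number of spokes actually
#' acquired in a reconstruction window.
#'
#' @param matrix Reconstructed matrix size (voxels).
#' @param spokes_per_frame Spokes contributing to one frame.
#' @return Undersampling factor `R` (dimensionless).
#' @examples
#' undersampling_factor(160, 24 * 88)  # ~19.0
#' undersampling_factor(52, 36 * 88)   # ~1.3
#' @export
undersampling_factor <- function(matrix, spokes_per_frame) {
  stopifnot(matrix > 0)
  if (any(spokes_per_frame <= 0)) abort("`spokes_per_frame` must be positive.")
  (pi * matrix^2 / 2) / spokes_per_frame
}

#' Bin the readout into contiguous temporal frames
#'
#' Partitions the `N` within-preparation spoke indices into frames of
#' `W = round(window / spoke_interval)` contiguous spokes. Data from all
#' preparations sharing a window are pooled at reconstruction. The frame
#' post-labeling delay follows the window-center convention,
#' `PLD_k = (k - 1/2) W spoke_interval`.
#'
#' @param config A [acquisition_config()] object.
#' @param window Temporal window (s); must not exceed `t_max` and
#'   `round(window / spoke_interval)` must divide `N`.
#' @return A tibble of class `capria_frames` with columns `frame`, `first_i`,
#'   `last_i`, `pld` (s); attribute `window` holds the realized window (s).
#' @export
bin_frames <- function(config, window) {
  stopifnot(inherits(config, "capria_config"))
  if (window > config$t_max + 1e-9)
    abort(sprintf("`window` (%.4g s) exceeds t_max (%.4g s).", window, config$t_max))
  N <- config$n_spokes_per_prep
  W <- as.integer(round(window / config$spoke_interval))
  if (W < 1L) abort("`window` shorter than one spoke interval.")
  if (N %% W != 0L) {
    divs <- Filter(function(w) N %% w == 0L, seq_len(min(N, config$spokes_per_tmax)))
    abort(sprintf(
      "window of %d spokes does not tile N = %d; nearest valid windows: %s s",
      W, N, paste(sprintf("%.4f", divs * config$spoke_interval), collapse = ", ")))
  }
  k <- seq_len(N %/% W)
  out <- tibble(
    frame = k,
    first_i = (k - 1L) * W + 1L,
    last_i = k * W,
    pld = (k - 0.5) * W * config$spoke_interval
  )
  class(out) <- c("capria_frames", class(out))
  attr(out, "window") <- W * config$spoke_interval
  attr(out, "spokes_per_frame") <- W
  out
}

#' Export a spoke schedule as delimited text
#'
#' @param schedule A [build_schedule()] tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(path)
}

#' Read a spoke schedule written by [write_schedule()]
#' @param path CSV path.
#' @return A tibble with the schedule columns.
#' @export
read_schedule <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
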