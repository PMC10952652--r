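#' Mean angiographic signal metric for one schedule
#'
#' For each macrovascular transit time in `delta_t_grid`, the per-pulse
#' angiographic signal is averaged over the pulses acquired while labeled blood
#' is present in the voxel (\eqn{\delta_t \le t_i < \tau + \delta_t}); the
#' result is then averaged across the transit-time grid. Blood volume and
#' `M0b` only scale the metric, so they need not be optimized over.
#'
#' @param schedule [make_schedule()] or numeric flip angles (degrees).
#' @param times Pulse times since labeling onset (s).
#' @param tau Labeling duration (s).
#' @param delta_t_grid Macrovascular transit times to average over (s).
#' @param params Baseline [kinetic_params()] (transit times overridden).
#' @return Scalar mean signal (arbitrary units).
#' @export
mean_angio_metric <- function(schedule, times, tau,
                              delta_t_grid = seq(0.2, 1.0, length.out = 9),
                              params = kinetic_params()) {
  vals <- purrr::map_dbl(delta_t_grid, function(dt) {
    p <- params; p$delta_t <- dt
    win <- times >= dt & times < tau + dt
    if (!any(win))
      abort(sprintf("no pulses fall in the bolus window for delta_t = %.3g s.", dt))
    mean(angio_signal(p, schedule, times, tau)[win])
  })
  mean(vals)
}

#' Mean perfusion signal metric for one schedule
#'
#' For each tissue transit time in `Delta_t_grid`, the per-pulse perfusion
#' signal is averaged over pulses acquired after all labeled blood water has
#' arrived (\eqn{t_i \ge \tau + \Delta_t}), where the signal is approximately
#' proportional to flow; then averaged across the grid. A transit time whose
#' window extends past the end of the readout contributes an explicit zero with
#' a warning.
#'
#' @inheritParams mean_angio_metric
#' @param Delta_t_grid Tissue transit times to average over (s).
#' @return Scalar mean signal (arbitrary units).
#' @export
mean_perf_metric <- function(schedule, times, tau,
                             Delta_t_grid = seq(0.5, 2.0, length.out = 7),
                             params = kinetic_params()) {
  vals <- purrr::map_dbl(Delta_t_grid, function(Dt) {
    p <- params; p$Delta_t <- Dt
    win <- times >= tau + Dt
    if (!any(win)) {
      warn(sprintf(
        "Delta_t = %.3g s: no pulses after tau + Delta_t; contributes 0.", Dt))
      return(0)
    }
    mean(perfusion_signal(p, schedule, times, tau)[win])
  })
  mean(vals)
}

#' Combine normalized angiographic and perfusion metrics
#'
#' Weighted sum \eqn{\frac{1}{2}\bar S_{angio} + \bar S_{perf}} renormalized to
#' a maximum of one. The 1/2 down-weights angiography because the perfusion
#' signal is the lower-SNR of the two and should dominate the compromise.
#'
#' @param S_angio_bar,S_perf_bar Grid-normalized metric fields (max 1).
#' @param weight Weight on the angiographic term (default 0.5).
#' @return Renormalized combined field, max 1.
#' @export
combined_metric <- function(S_angio_bar, S_perf_bar, weight = 0.5) {
  s <- weight * S_angio_bar + S_perf_bar
  s / max(s)
}

#' Evaluate the metric grid over flip-angle schedules
#'
#' Evaluates the mean angiographic and perfusion metrics for every quadratic
#' schedule with `alpha1 <= alphaN` on a regular grid (the diagonal
#' `alpha1 == alphaN` being the constant-flip-angle family), normalizes each
#' field to its grid maximum, and forms the combined metric.
#'
#' @param config [acquisition_config()]; supplies `N`, `tau` and pulse timing.
#' @param alpha_range Flip-angle range (degrees).
#' @param step Grid step (degrees).
#' @param delta_t_grid,Delta_t_grid Physiological averaging grids (s).
#' @param params Baseline [kinetic_params()].
#' @param weight Angiography weight in the combined metric.
#' @return A tibble of class `capria_metric_grid` with columns `alpha1`,
#'   `alphaN`, `S_angio_bar`, `S_perf_bar`, `S_combined_bar`.
#' @examples
#' \donttest{
#' grid <- metric_grid(acquisition_config(), step = 2)
#' select_cfa(grid)
#' }
#' @export
metric_grid <- function(config,
                        alpha_range = c(1, 20), step = 1,
                        delta_t_grid = seq(0.2, 1.0, length.out = 9),
                        Delta_t_grid = seq(0.5, 2.0, length.out = 7),
                        params = kinetic_params(),
                        weight = 0.5) {
  stopifnot(inherits(config, "capria_config"))
  N <- config$n_spokes_per_prep
  times <- config$tau + config$post_label_gap +
    (seq_len(N) - 1) * config$spoke_interval
  axis <- seq(alpha_range[1], alpha_range[2], by = step)
  grid <- tidyr::expand_grid(alpha1 = axis, alphaN = axis)
  grid <- dplyr::filter(grid, .data$alpha1 <= .data$alphaN)
  i <- seq_len(N)
  vals <- purrr::map2(grid$alpha1, grid$alphaN, function(a1, aN) {
    alpha <- a1 + (aN - a1) * ((i - 1) / (N - 1))^2
    c(mean_angio_metric(alpha, times, config$tau, delta_t_grid, params),
      suppressWarnings(
        mean_perf_metric(alpha, times, config$tau, Delta_t_grid, params)))
  })
  grid$S_angio_bar <- purrr::map_dbl(vals, 1)
  grid$S_perf_bar <- purrr::map_dbl(vals, 2)
  grid$S_angio_bar <- grid$S_angio_bar / max(grid$S_angio_bar)
  grid$S_perf_bar <- grid$S_perf_bar / max(grid$S_perf_bar)
  grid$S_combined_bar <- combined_metric(grid$S_angio_bar, grid$S_perf_bar, weight)
  structure(grid, class = c("capria_metric_grid", class(grid)),
            weight = weight, step = step)
}

#' Optimal constant flip angle
#'
#' Argmax of the combined metric along the constant-flip-angle diagonal
#' `alpha1 == alphaN`. Ties are broken toward the smaller angle.
#'
#' @param grid A [metric_grid()] result.
#' @param metric Column to maximize (default `"S_combined_bar"`).
#' @return Optimal flip angle (degrees).
#' @export
select_cfa <- function(grid, metric = "S_combined_bar") {
  diag <- dplyr::filter(grid, .data$alpha1 == .data$alphaN)
  if (nrow(diag) == 0) abort("grid contains no diagonal (alpha1 == alphaN) points.")
  diag <- dplyr::arrange(diag, .data$alpha1)
  diag$alpha1[which.max(diag[[metric]])]
}

#' Optimal variable flip-angle pair
#'
#' The combined-metric surface has a broad peak, so rather than the raw argmax
#' the schedule chosen is the grid point within `threshold` of the peak that is
#' closest to the origin in (alpha1, alphaN) Euclidean distance (degrees),
#' minimizing attenuation of late-arriving blood. Ties are broken by smaller
#' `alphaN`, then smaller `alpha1`.
#'
#' @param grid A [metric_grid()] result.
#' @param threshold Fraction of the peak metric (default 0.95).
#' @param metric Column to use.
#' @return Named numeric vector `c(alpha1, alphaN)` (degrees).
#' @export
select_vfa <- function(grid, threshold = 0.95, metric = "S_combined_bar") {
  ok <- grid[[metric]] >= threshold * max(grid[[metric]])
  cand <- grid[ok, ]
  cand <- dplyr::arrange(cand,
                         sqrt(.data$alpha1^2 + .data$alphaN^2),
                         .data$alphaN, .data$alpha1)
  c(alpha1 = cand$alpha1[1], alphaN = cand$alphaN[1])
}

#' @export
print.capria_metric_grid <- function(x, ...) {
  cat(sprintf("<capria_metric_grid> %d schedules, step %.2g deg, angio weight %.2g\n",
              nrow(x), attr(x, "step"), attr(x, "weight")))
  cat(sprintf("  CFA optimum %g deg; VFA optimum (%g, %g) deg [95%% rule]\n",
              select_cfa(x), select_vfa(x)[1], select_vfa(x)[2]))
  NextMethod()
}
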