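#' Contour plot of the flip-angle optimization surfaces
#'
#' Reproduces the familiar optimization layout: normalized angiographic,
#' perfusion and combined metrics over (alpha1, alphaN), with the
#' constant-flip-angle diagonal dashed and the selected CFA/VFA optima marked.
#'
#' @param object A [metric_grid()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.capria_metric_grid <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              cols = c("S_angio_bar", "S_perf_bar", "S_combined_bar"),
                              names_to = "metric", values_to = "value")
  long$metric <- factor(long$metric,
                        levels = c("S_angio_bar", "S_perf_bar", "S_combined_bar"),
                        labels = c("angiography", "perfusion", "combined"))
  cfa <- select_cfa(object)
  vfa <- select_vfa(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$alpha1, y = .data$alphaN)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$value),
                          colour = "white", alpha = 0.6, bins = 8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::annotate("point", x = cfa, y = cfa, shape = 21, size = 3,
                      fill = "black") +
    ggplot2::annotate("point", x = vfa[["alpha1"]], y = vfa[["alphaN"]],
                      shape = 21, size = 3, fill = "red") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = expression(alpha[1] ~ "(deg)"),
                  y = expression(alpha[N] ~ "(deg)"),
                  fill = "normalized\nmetric") +
    ggplot2::theme_minimal()
}

#' Plot simulated signal timecourses
#'
#' Flip angles, angiographic and perfusion signals against time for one
#' schedule.
#'
#' @param object A [signal_timecourse()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.capria_timecourse <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              cols = c("alpha", "angio", "perfusion"),
                              names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time since labeling onset (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot split-scan repeatability against post-labeling delay
#'
#' @param object A `capria_repeatability` tibble (or the combined
#'   [capria_assess()] table).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.capria_repeatability <- function(object, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$pld, y = .data$r)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "post-labeling delay (s)",
                  y = "split-scan repeatability r") +
    ggplot2::theme_minimal()
  p
}

#' Montage of one frame of a dynamic series
#'
#' Central orthogonal slices of the magnitude image for a quick look at a
#' reconstruction.
#'
#' @param series A `capria_series`.
#' @param frame Frame index.
#' @return A ggplot object.
#' @export
plot_series_frame <- function(series, frame = 1) {
  x <- Mod(series$data[, , , frame])
  m <- dim(x)[1]
  mid <- m %/% 2
  slices <- dplyr::bind_rows(
    tibble(i = rep(seq_len(m), m), j = rep(seq_len(m), each = m),
           v = as.vector(x[, , mid]), plane = "axial"),
    tibble(i = rep(seq_len(m), m), j = rep(seq_len(m), each = m),
           v = as.vector(x[, mid, ]), plane = "coronal"),
    tibble(i = rep(seq_len(m), m), j = rep(seq_len(m), each = m),
           v = as.vector(x[mid, , ]), plane = "sagittal"))
  ggplot2::ggplot(slices, ggplot2::aes(x = .data$i, y = .data$j,
                                       fill = .data$v)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~plane) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "|signal|",
                  title = sprintf("frame %d (PLD %.3f s)", frame,
                                  series$pld[frame])) +
    ggplot2::theme_void()
}
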