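#' Tidy a repeatability result
#'
#' @param x A `capria_repeatability` tibble.
#' @param ... Unused.
#' @return A plain tibble with columns `frame`, `pld`, `r`, `z`, `mask`,
#'   `n_voxels`.
#' @export
tidy.capria_repeatability <- function(x, ...) {
  out <- as_tibble(unclass(x)[c("frame", "pld", "r", "z")])
  out$mask <- attr(x, "mask_id")
  out$n_voxels <- attr(x, "n_voxels")
  out
}

#' One-row summary of a repeatability result
#' @param x A `capria_repeatability` tibble.
#' @param ... Unused.
#' @return One-row tibble: mean/min z, frame count, mask provenance.
#' @export
glance.capria_repeatability <- function(x, ...) {
  tibble(n_frames = nrow(x),
         mean_z = mean(x$z, na.rm = TRUE),
         min_r = min(x$r, na.rm = TRUE),
         max_r = max(x$r, na.rm = TRUE),
         mask = attr(x, "mask_id"),
         n_voxels = attr(x, "n_voxels"))
}

#' Per-frame summary of a reconstructed series
#'
#' @param x A `capria_series`.
#' @param ... Unused.
#' @return Tibble with `frame`, `pld`, `mean_abs`, `max_abs`.
#' @export
tidy.capria_series <- function(x, ...) {
  F <- dim(x$data)[4]
  tibble(frame = seq_len(F),
         pld = x$pld,
         mean_abs = vapply(seq_len(F), function(k) mean(Mod(x$data[, , , k])),
                           numeric(1)),
         max_abs = vapply(seq_len(F), function(k) max(Mod(x$data[, , , k])),
                          numeric(1)))
}

#' One-row provenance summary of a reconstructed series
#' @param x A `capria_series`.
#' @param ... Unused.
#' @return One-row tibble: solver, acceleration, frames, window, voxel size,
#'   iterations run, final objective, undersampling factor (if recorded).
#' @export
glance.capria_series <- function(x, ...) {
  tr <- x$trace
  tibble(solver = x$solver,
         accel = x$accel,
         n_frames = dim(x$data)[4],
         window_s = x$window,
         voxel_mm = x$voxel_size,
         n_iters = if (is.null(tr)) NA_integer_ else nrow(tr),
         final_objective = if (is.null(tr)) NA_real_ else tr[nrow(tr), "objective"],
         undersampling = attr(x, "undersampling") %||% NA_real_)
}

#' One-row summary of a flip-angle metric grid
#' @param x A [metric_grid()] tibble.
#' @param ... Unused.
#' @return One-row tibble with the selected CFA and VFA optima.
#' @export
glance.capria_metric_grid <- function(x, ...) {
  v <- select_vfa(x)
  tibble(cfa_opt = select_cfa(x),
         vfa_alpha1 = v[["alpha1"]],
         vfa_alphaN = v[["alphaN"]],
         step = attr(x, "step"),
         weight = attr(x, "weight"))
}
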