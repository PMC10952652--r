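#' Write a dynamic series as a 4D NIfTI volume
#'
#' Magnitude is taken at export (complex frames are stored in memory only);
#' the voxel size is recorded in the header and a JSON sidecar carries the
#' solver provenance (solver, acceleration method, regularization, seed,
#' per-frame PLDs).
#'
#' @param series A `capria_series`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param sidecar Write `<path>.json` provenance (default TRUE).
#' @return `path`, invisibly.
#' @export
write_series_nifti <- function(series, path, sidecar = TRUE) {
  img <- Mod(series$data)
  nii <- RNifti::asNifti(img)
  RNifti::pixdim(nii) <- c(rep(series$voxel_size, 3), series$window)
  RNifti::writeNifti(nii, path)
  if (sidecar) {
    meta <- list(solver = series$solver,
                 accel = series$accel,
                 pld_s = series$pld,
                 window_s = series$window,
                 voxel_mm = series$voxel_size,
                 undersampling = attr(series, "undersampling"),
                 config = series$config[c("lambda_spatial", "lambda_temporal",
                                          "lambda_llr", "patch_size",
                                          "n_iters", "cycle_spinning", "seed")])
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' Validate a reconstruction provenance sidecar
#'
#' Checks a provenance list (or sidecar JSON path) against the shipped schema
#' (`inst/schema/provenance-schema.json`): required fields present with the
#' right types, solver and acceleration restricted to known values.
#'
#' @param x A provenance list, or a path to a sidecar JSON file.
#' @return `TRUE` invisibly; errors with the offending field otherwise.
#' @export
validate_provenance <- function(x) {
  if (is.character(x)) x <- jsonlite::read_json(x)
  schema <- jsonlite::read_json(system.file("schema", "provenance-schema.json",
                                            package = "capria"))
  req <- unlist(schema$required)
  missing <- setdiff(req, names(x))
  if (length(missing))
    abort(sprintf("provenance missing fields: %s", paste(missing, collapse = ", ")))
  if (!x$solver %in% unlist(schema$properties$solver$enum))
    abort(sprintf("unknown solver '%s' in provenance.", x$solver))
  if (!is.null(x$accel) && !is.na(x$accel) &&
      !x$accel %in% unlist(schema$properties$accel$enum))
    abort(sprintf("unknown acceleration method '%s' in provenance.", x$accel))
  for (f in c("window_s", "voxel_mm"))
    if (f %in% names(x) && !is.numeric(unlist(x[[f]])))
      abort(sprintf("provenance field '%s' must be numeric.", f))
  invisible(TRUE)
}

#' Write a logical mask as NIfTI
#' @param mask Logical 3D array.
#' @param path Output path.
#' @param voxel_size Voxel size (mm).
#' @return `path`, invisibly.
#' @export
write_mask_nifti <- function(mask, path, voxel_size) {
  nii <- RNifti::asNifti(mask * 1L)
  RNifti::pixdim(nii) <- rep(voxel_size, 3)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Export a repeatability table as delimited text
#'
#' Tidy columns (`image`, `frame`, `pld`, `mask`, `r`, `z`) ready for external
#' statistics tools.
#'
#' @param tbl A tibble from [capria_assess()] or [split_half_repeatability()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_repeatability <- function(tbl, path) {
  utils::write.csv(as.data.frame(tbl), path, row.names = FALSE)
  invisible(path)
}

#' Export simulated signal timecourses as delimited text
#' @param tc A [signal_timecourse()] tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  utils::write.csv(as.data.frame(tc), path, row.names = FALSE)
  invisible(path)
}
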