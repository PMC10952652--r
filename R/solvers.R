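#' Reconstruction configuration
#'
#' Regularization weights, iteration budgets and locally-low-rank settings.
#' None of these are protocol constants; defaults are deliberately mild and
#' every run records the values used in its provenance.
#'
#' @param solver `"cg-sense"` or `"llr"`.
#' @param lambda_spatial,lambda_temporal L2 weights on spatial/temporal
#'   forward differences (CG-SENSE).
#' @param lambda_llr Nuclear-norm weight per patch (LLR), specified relative
#'   to the squared operator norm `||E||^2`: the effective weight is
#'   `lambda_llr * ||E||^2`, which puts the singular-value threshold on the
#'   image intensity scale regardless of how many spokes and coils the
#'   operator sums over.
#' @param patch_size Cubic patch edge (voxels); each patch is unfolded as a
#'   `patch_size^3 x n_frames` matrix.
#' @param n_iters Iteration budget.
#' @param tolerance Relative change stopping tolerance (0 disables).
#' @param cycle_spinning Randomize the patch-grid offset each iteration.
#' @param accel `"pogm"` (primary) or `"fista"` (fallback; recorded in output
#'   metadata).
#' @param seed Seed for cycle-spinning offsets and power-method start.
#' @return Object of class `capria_recon_config`.
#' @export
recon_config <- function(solver = c("cg-sense", "llr"),
                         lambda_spatial = 0, lambda_temporal = 0,
                         lambda_llr = 1e-4, patch_size = 8L,
                         n_iters = 20L, tolerance = 0,
                         cycle_spinning = TRUE,
                         accel = c("pogm", "fista"),
                         seed = 1L) {
  solver <- match.arg(solver)
  accel <- match.arg(accel)
  stopifnot(lambda_spatial >= 0, lambda_temporal >= 0, lambda_llr >= 0,
            patch_size >= 1, n_iters >= 1)
  structure(list(solver = solver, lambda_spatial = lambda_spatial,
                 lambda_temporal = lambda_temporal, lambda_llr = lambda_llr,
                 patch_size = as.integer(patch_size),
                 n_iters = as.integer(n_iters), tolerance = tolerance,
                 cycle_spinning = cycle_spinning, accel = accel,
                 seed = as.integer(seed)),
            class = "capria_recon_config")
}

# zero-padded forward difference along the first axis of a 4D array
# (d_i = x_{i+1} - x_i for i < n, d_n = -x_n) and its adjoint
# ((D^T d)_i = d_{i-1} - d_i with d_0 = 0)
fdiff1 <- function(x) {
  n <- dim(x)[1]
  d <- x
  d[-n, , , ] <- x[-1, , , , drop = FALSE] - x[-n, , , , drop = FALSE]
  d[n, , , ] <- -x[n, , , , drop = FALSE]
  d
}
fdiff1_adj <- function(d) {
  n <- dim(d)[1]
  out <- -d
  out[-1, , , ] <- out[-1, , , , drop = FALSE] + d[-n, , , , drop = FALSE]
  out
}

# zero-padded forward spatial differences per frame, one array per direction
spatial_diff <- function(x) {
  list(dx = fdiff1(x),
       dy = aperm(fdiff1(aperm(x, c(2, 1, 3, 4))), c(2, 1, 3, 4)),
       dz = aperm(fdiff1(aperm(x, c(3, 2, 1, 4))), c(3, 2, 1, 4)))
}

# Ds^T Ds x, built from the matched forward/adjoint pair above
spatial_diff_gram <- function(x) {
  g1 <- fdiff1_adj(fdiff1(x))
  xp <- aperm(x, c(2, 1, 3, 4))
  g2 <- aperm(fdiff1_adj(fdiff1(xp)), c(2, 1, 3, 4))
  xp <- aperm(x, c(3, 2, 1, 4))
  g3 <- aperm(fdiff1_adj(fdiff1(xp)), c(3, 2, 1, 4))
  g1 + g2 + g3
}

# temporal forward differences between adjacent frames (interior only, so a
# large temporal weight drives frames toward their common temporal mean rather
# than zero); gram operator Dt^T Dt
temporal_diff_gram <- function(x) {
  F <- dim(x)[4]
  out <- x; out[] <- 0i
  if (F < 2) return(out)
  d <- x[, , , -1, drop = FALSE] - x[, , , -F, drop = FALSE]  # F-1 diffs
  out[, , , -F] <- out[, , , -F, drop = FALSE] - d
  out[, , , -1] <- out[, , , -1, drop = FALSE] + d
  out
}

#' CG-SENSE reconstruction with L2 gradient regularization
#'
#' Minimizes
#' \deqn{\|E x - y\|^2 + \lambda_s \|D_s x\|^2 + \lambda_t \|D_t x\|^2}
#' by conjugate gradients on the normal equations, where `E` is the
#' multi-coil radial encoding operator, `D_s` stacks zero-padded forward
#' spatial differences within each frame and `D_t` takes differences between
#' adjacent frames. The quadratic objective is recorded per iteration and is
#' nonincreasing (CG minimizes over nested Krylov subspaces); a rise sustained
#' over 5 iterations aborts with diagnostics.
#'
#' @param dks A [phase_align_subtract()] difference container.
#' @param op A [build_encoding()] operator.
#' @param config A [recon_config()].
#' @return A `capria_series` object (see [as_capria_series()]) with the
#'   objective trace and solver provenance attached.
#' @export
cg_sense <- function(dks, op, config = recon_config("cg-sense")) {
  y <- frame_data(dks, op)
  b <- op$adjoint(y)
  ls <- config$lambda_spatial
  lt <- config$lambda_temporal
  A <- function(x) {
    out <- op$adjoint(op$forward(x))
    if (ls > 0) out <- out + ls * spatial_diff_gram(x)
    if (lt > 0) out <- out + lt * temporal_diff_gram(x)
    out
  }
  ynorm2 <- sum(vapply(y, function(m) sum(Mod(m)^2), numeric(1)))
  x <- array(0i, c(rep(op$matrix, 3), op$n_frames))
  r <- b  # b - A(0)
  p <- r
  rs <- sum(Mod(r)^2)
  # the quadratic objective ||Ex-y||^2 + reg = <x,Ax> - 2Re<b,x> + ||y||^2
  # decreases by exactly alpha*rs per CG step, so it can be tracked without
  # extra operator applications
  obj_now <- ynorm2
  obj <- numeric(config$n_iters)
  rises <- 0
  n_done <- 0
  for (it in seq_len(config$n_iters)) {
    Ap <- A(p)
    denom <- Re(sum(Conj(p) * Ap))
    if (denom <= .Machine$double.eps * rs) {
      if (denom < 0) {
        rises <- rises + 1
        if (rises >= 5)
          abort("cg_sense diverging: indefinite curvature over 5 iterations.")
      }
      break
    }
    alpha <- rs / denom
    x <- x + alpha * p
    r <- r - alpha * Ap
    obj_now <- obj_now - alpha * rs
    obj[it] <- obj_now
    n_done <- it
    rs_new <- sum(Mod(r)^2)
    if (config$tolerance > 0 && sqrt(rs_new / ynorm2) < config$tolerance) break
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  Ex <- op$forward(x)
  data_res <- sqrt(sum(vapply(seq_along(y),
                              function(k) sum(Mod(Ex[[k]] - y[[k]])^2),
                              numeric(1))))
  out <- as_capria_series(x, op, solver = "cg-sense", config = config,
                          trace = cbind(objective = obj[seq_len(n_done)]))
  out$data_residual <- data_res
  out
}

# singular-value soft-thresholding of one unfolded patch matrix
svt <- function(M, thresh) {
  s <- svd(M)
  d <- pmax(s$d - thresh, 0)
  keep <- d > 0
  if (!any(keep)) return(matrix(0i, nrow(M), ncol(M)))
  s$u[, keep, drop = FALSE] %*% (d[keep] * Conj(t(s$v[, keep, drop = FALSE])))
}

# apply patchwise SVT to a 4D series with a circular patch-grid shift
llr_prox <- function(x, thresh, patch, shift) {
  d <- dim(x)
  m <- d[1]; F <- d[4]
  xs <- x
  if (any(shift != 0))
    xs <- xs[((seq_len(m) - 1 + shift[1]) %% m) + 1,
             ((seq_len(m) - 1 + shift[2]) %% m) + 1,
             ((seq_len(m) - 1 + shift[3]) %% m) + 1, , drop = FALSE]
  np <- m %/% patch
  for (ix in seq_len(np)) for (iy in seq_len(np)) for (iz in seq_len(np)) {
    rx <- (ix - 1) * patch + seq_len(patch)
    ry <- (iy - 1) * patch + seq_len(patch)
    rz <- (iz - 1) * patch + seq_len(patch)
    blk <- matrix(xs[rx, ry, rz, ], patch^3, F)
    xs[rx, ry, rz, ] <- array(svt(blk, thresh), c(patch, patch, patch, F))
  }
  if (any(shift != 0))
    xs <- xs[((seq_len(m) - 1 - shift[1]) %% m) + 1,
             ((seq_len(m) - 1 - shift[2]) %% m) + 1,
             ((seq_len(m) - 1 - shift[3]) %% m) + 1, , drop = FALSE]
  xs
}

# largest eigenvalue of E^H E by power iteration
power_method <- function(op, n_iters = 10L, seed = 1L) {
  set.seed(seed)
  m <- op$matrix; F <- op$n_frames
  x <- array(complex(real = rnorm(m^3 * F), imaginary = rnorm(m^3 * F)),
             c(m, m, m, F))
  x <- x / sqrt(sum(Mod(x)^2))
  ev <- 0
  for (i in seq_len(n_iters)) {
    x <- op$adjoint(op$forward(x))
    ev <- sqrt(sum(Mod(x)^2))
    x <- x / ev
  }
  ev
}

#' Locally-low-rank reconstruction via POGM with cycle spinning
#'
#' Solves
#' \deqn{\min_x \tfrac12 \|E x - y\|^2 +
#'   \lambda \sum_p \|\mathrm{unfold}_p(x)\|_*}
#' where each patch of the image series is unfolded as a space-by-time matrix
#' and penalized by its nuclear norm, exploiting the strong spatiotemporal
#' correlation of ASL timecourses. The proximal optimized gradient method
#' (POGM) supplies acceleration; the proximal step is patchwise singular-value
#' soft-thresholding, and with cycle spinning the patch grid is circularly
#' shifted by a seeded random offset each iteration to suppress blocking
#' artifacts. The step size comes from a power-method estimate of
#' \eqn{\|E\|^2}. A FISTA fallback is available and recorded in the output
#' metadata. The best-iterate (running minimum) objective, evaluated at the
#' unshifted patch grid, is tracked; if the iterate at the budget is not the
#' best seen, the best iterate is returned with a warning.
#'
#' @inheritParams cg_sense
#' @return A `capria_series` object with objective trace and provenance.
#' @export
llr_recon <- function(dks, op, config = recon_config("llr")) {
  y <- frame_data(dks, op)
  patch <- config$patch_size
  m <- op$matrix; F <- op$n_frames
  if (m %% patch != 0)
    abort(sprintf("patch_size %d does not tile matrix %d.", patch, m))
  L <- power_method(op, seed = config$seed)
  lam <- config$lambda_llr * L  # weight relative to ||E||^2
  step <- 1 / L
  nuc_norm <- function(x) {
    nuc <- 0
    np <- m %/% patch
    for (ix in seq_len(np)) for (iy in seq_len(np)) for (iz in seq_len(np)) {
      blk <- matrix(x[(ix - 1) * patch + seq_len(patch),
                      (iy - 1) * patch + seq_len(patch),
                      (iz - 1) * patch + seq_len(patch), ], patch^3, F)
      nuc <- nuc + sum(svd(blk, nu = 0, nv = 0)$d)
    }
    nuc
  }
  set.seed(config$seed)
  dims4 <- c(m, m, m, F)
  x <- array(0i, dims4)
  w_prev <- x; z_prev <- x; x_prev <- x
  th_prev <- 1; gam_prev <- step
  best <- x; best_obj <- Inf
  trace <- numeric(config$n_iters)
  for (it in seq_len(config$n_iters)) {
    shift <- if (config$cycle_spinning) sample.int(patch, 3, replace = TRUE) - 1L
             else c(0L, 0L, 0L)
    # one forward evaluation serves both the gradient at x_prev and the
    # objective trace at x_prev (the reference objective uses the unshifted
    # patch grid)
    Ex <- op$forward(x_prev)
    resid <- purrr::map2(Ex, y, `-`)
    g <- op$adjoint(resid)
    trace[it] <- 0.5 * sum(vapply(resid, function(r2) sum(Mod(r2)^2),
                                  numeric(1))) +
      lam * nuc_norm(x_prev)
    if (trace[it] < best_obj) { best_obj <- trace[it]; best <- x_prev }
    if (config$accel == "fista") {
      th <- (1 + sqrt(1 + 4 * th_prev^2)) / 2
      w <- x_prev - step * g
      z <- w + ((th_prev - 1) / th) * (w - w_prev)
      x <- if (lam > 0) llr_prox(z, lam * step, patch, shift) else z
      w_prev <- w
    } else {
      th <- if (it < config$n_iters)
        (1 + sqrt(4 * th_prev^2 + 1)) / 2
      else
        (1 + sqrt(8 * th_prev^2 + 1)) / 2
      w <- x_prev - step * g
      z <- w + ((th_prev - 1) / th) * (w - w_prev) +
        (th_prev / th) * (w - x_prev) +
        ((th_prev - 1) / (L * gam_prev * th)) * (z_prev - x_prev)
      gam <- step * (2 * th_prev + th - 1) / th
      x <- if (lam > 0) llr_prox(z, lam * gam, patch, shift) else z
      w_prev <- w; z_prev <- z; gam_prev <- gam
    }
    if (config$tolerance > 0 && nrmse(x, x_prev) < config$tolerance) {
      x_prev <- x; trace <- trace[seq_len(it)]; break
    }
    x_prev <- x; th_prev <- th
  }
  # objective at the final iterate
  Ex <- op$forward(x_prev)
  final_obj <- 0.5 * sum(vapply(seq_along(y),
                                function(k) sum(Mod(Ex[[k]] - y[[k]])^2),
                                numeric(1))) + lam * nuc_norm(x_prev)
  trace <- c(trace, final_obj)
  if (final_obj < best_obj) { best_obj <- final_obj; best <- x_prev }
  if (final_obj > best_obj * (1 + 1e-12)) {
    warn("llr_recon: final iterate is not the best seen; returning best iterate.")
    x_prev <- best
  }
  as_capria_series(x_prev, op, solver = "llr", config = config,
                   trace = cbind(objective = trace))
}

#' Low-resolution perfusion reconstruction from central k-space
#'
#' Retains only readout samples with `|k| <= low_matrix / (2 fov)`, builds the
#' encoding operator on the low-resolution grid (same k-space units, smaller
#' extent), and reconstructs at the broader perfusion temporal window with the
#' requested solver. The resulting undersampling factor (Nyquist diameter-spoke
#' count over acquired spokes per frame) is recorded in the provenance.
#'
#' @param dks A [phase_align_subtract()] difference container.
#' @param low_matrix Low-resolution matrix size (< acquisition matrix).
#' @param frames A [bin_frames()] tibble for the perfusion window.
#' @param sens_low Sensitivities at `low_matrix` (from
#'   [estimate_sensitivities()] with `matrix = low_matrix`).
#' @param config A [recon_config()].
#' @return A `capria_series`; `glance()` reports the undersampling factor.
#' @export
recon_lowres_perfusion <- function(dks, low_matrix, frames, sens_low,
                                   config = recon_config("cg-sense")) {
  if (low_matrix > dks$config$matrix)
    abort("`low_matrix` must not exceed the acquisition matrix.")
  keep <- abs(dks$radial_coords) <= low_matrix / (2 * dks$config$fov) + 1e-12
  if (!any(keep)) abort("no samples fall in the requested central region.")
  op <- build_encoding(dks$schedule, dks$config, frames, sens_low,
                       matrix = low_matrix)
  out <- if (config$solver == "llr") llr_recon(dks, op, config)
         else cg_sense(dks, op, config)
  spf <- length(op$frame_rows[[1]])
  attr(out, "undersampling") <- undersampling_factor(low_matrix, spf)
  out
}

#' Dynamic image series container
#'
#' Complex reconstructed frames plus the temporal metadata needed to interpret
#' them. Magnitude is taken only at export/analysis.
#'
#' @param x Complex array `m x m x m x F`.
#' @param op The encoding operator used (supplies frame PLDs and geometry).
#' @param solver,config,trace Provenance.
#' @return Object of class `capria_series`.
#' @export
as_capria_series <- function(x, op, solver, config = NULL, trace = NULL) {
  structure(list(data = x,
                 pld = op$frames$pld,
                 window = attr(op$frames, "window"),
                 voxel_size = op$config$fov / op$matrix,
                 solver = solver,
                 accel = if (!is.null(config) && solver == "llr") config$accel else NA_character_,
                 config = config, trace = trace),
            class = "capria_series")
}

#' @export
print.capria_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<capria_series> %dx%dx%d voxels x %d frames (%s)\n",
              d[1], d[2], d[3], d[4], x$solver))
  cat(sprintf("  PLD %s s; window %.4g s; voxel %.2f mm\n",
              paste(sprintf("%.3f", x$pld), collapse = ", "),
              x$window, x$voxel_size))
  invisible(x)
}

#' Normalized root-mean-square error between two arrays
#' @param x,ref Numeric/complex arrays of equal size (`ref` is the reference).
#' @return `||x - ref|| / ||ref||`.
#' @export
nrmse <- function(x, ref) {
  sqrt(sum(Mod(x - ref)^2) / sum(Mod(ref)^2))
}
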