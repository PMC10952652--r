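#' Multi-frame multi-coil radial encoding operator
#'
#' The forward model maps a complex dynamic image series `x` (array
#' `m x m x m x F`) to non-Cartesian k-space: frame by frame, each coil image
#' `x_f * S_c` is evaluated at that frame's spoke sample coordinates with the
#' gridding NUFFT. The adjoint applies conjugate sensitivities to the NUFFT
#' adjoint. Data are handled as a list (one per frame) of complex
#' `n_samples x n_coils` matrices.
#'
#' @param schedule Label-side spoke schedule (tibble with `i`, `theta`, `phi`).
#' @param config [acquisition_config()] describing the readout.
#' @param frames A [bin_frames()] tibble.
#' @param sens Complex sensitivity array `m x m x m x C`.
#' @param matrix Reconstruction matrix size (defaults to the sensitivity grid).
#' @return Object of class `capria_encoding` with `forward`, `adjoint`,
#'   `frame_rows` (spoke rows per frame), `n_frames`, `matrix`.
#' @export
build_encoding <- function(schedule, config, frames, sens,
                           matrix = dim(sens)[1]) {
  m <- as.integer(matrix)
  stopifnot(dim(sens)[1] == m)
  C <- dim(sens)[4]
  r <- spoke_radial_coords_scaled(config, m)
  ns <- length(r)
  F <- nrow(frames)
  frame_rows <- lapply(seq_len(F), function(k)
    which(schedule$i >= frames$first_i[k] & schedule$i <= frames$last_i[k]))
  ops <- lapply(seq_len(F), function(k) {
    rows <- frame_rows[[k]]
    th <- schedule$theta[rows]; ph <- schedule$phi[rows]
    nsp <- length(rows)
    dirs <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    coords <- dirs[rep(seq_len(nsp), each = ns), , drop = FALSE] * rep(r, nsp)
    make_nufft(coords, m, config$fov)
  })
  sens_conj <- Conj(sens)
  forward <- function(x) {
    lapply(seq_len(F), function(k) {
      xf <- x[, , , k]
      vapply(seq_len(C), function(c) ops[[k]]$forward(xf * sens[, , , c]),
             complex(ops[[k]]$n_samples))
    })
  }
  adjoint <- function(y) {
    x <- array(0i, c(m, m, m, F))
    for (k in seq_len(F)) {
      acc <- array(0i, c(m, m, m))
      for (c in seq_len(C))
        acc <- acc + sens_conj[, , , c] * ops[[k]]$adjoint(y[[k]][, c])
      x[, , , k] <- acc
    }
    x
  }
  structure(list(forward = forward, adjoint = adjoint,
                 frame_rows = frame_rows, n_frames = F, matrix = m,
                 n_coils = C, n_readout = ns, nuffts = ops,
                 frames = frames, config = config),
            class = "capria_encoding")
}

#' Adjoint dot-product test for an encoding operator
#'
#' Checks `|<Ax, y> - <x, A^H y>| / (||Ax|| ||y||)` on seeded random inputs.
#'
#' @param op A [build_encoding()] (or [make_nufft()]) operator.
#' @param seed Seed for the random test vectors.
#' @return The relative discrepancy (numeric scalar).
#' @export
adjoint_test <- function(op, seed = 1L) {
  set.seed(seed)
  if (inherits(op, "capria_nufft")) {
    m <- op$matrix
    x <- array(complex(real = rnorm(m^3), imaginary = rnorm(m^3)), rep(m, 3))
    y <- complex(real = rnorm(op$n_samples), imaginary = rnorm(op$n_samples))
    Ax <- op$forward(x)
    lhs <- sum(Conj(y) * Ax)
    rhs <- sum(Conj(op$adjoint(y)) * x)
    return(Mod(lhs - rhs) / (sqrt(sum(Mod(Ax)^2)) * sqrt(sum(Mod(y)^2))))
  }
  m <- op$matrix; F <- op$n_frames; C <- op$n_coils
  x <- array(complex(real = rnorm(m^3 * F), imaginary = rnorm(m^3 * F)),
             c(m, m, m, F))
  y <- lapply(seq_len(F), function(k) {
    n <- length(op$frame_rows[[k]]) * op$n_readout
    matrix(complex(real = rnorm(n * C), imaginary = rnorm(n * C)), n, C)
  })
  Ax <- op$forward(x)
  lhs <- sum(vapply(seq_len(F), function(k) sum(Conj(y[[k]]) * Ax[[k]]),
                    complex(1)))
  rhs <- sum(Conj(op$adjoint(y)) * x)
  nAx <- sqrt(sum(purrr::map_dbl(Ax, function(a) sum(Mod(a)^2))))
  ny <- sqrt(sum(purrr::map_dbl(y, function(a) sum(Mod(a)^2))))
  Mod(lhs - rhs) / (nAx * ny)
}

#' Estimate coil sensitivity maps from raw data
#'
#' Pools every spoke of both conditions (their mean removes most of the ASL
#' difference), applies a radial Hann taper in k-space to suppress aliasing
#' from the undersampled periphery, reconstructs one image per coil with a
#' short conjugate-gradient NUFFT reconstruction at the target matrix,
#' normalizes by the root-sum-of-squares image, and masks voxels whose RSS
#' falls below `mask_threshold` of its maximum.
#'
#' @param raw A [simulate_kspace()] container.
#' @param matrix Target matrix size.
#' @param n_iters CG iterations for the per-coil images.
#' @param mask_threshold Fraction of the maximum RSS below which voxels are
#'   masked out.
#' @return List of class `capria_sens`: `sens` (complex `m^3 x C`), `mask`
#'   (logical array), `rss` (real array).
#' @export
estimate_sensitivities <- function(raw, matrix = raw$spec$grid,
                                   n_iters = 10L, mask_threshold = 0.1) {
  m <- as.integer(matrix)
  mean_ks <- (raw$label + raw$control) / 2
  if (all(Mod(mean_ks) == 0)) abort("raw container holds all-zero data.")
  cfg <- raw$config
  r_full <- raw$radial_coords
  keep <- abs(r_full) <= m / (2 * cfg$fov) + 1e-12
  r <- r_full[keep]
  kmax <- m / (2 * cfg$fov)
  hann <- 0.5 * (1 + cos(pi * r / kmax))
  sch <- raw$schedule
  nsp <- nrow(sch); ns <- length(r); C <- dim(mean_ks)[3]
  dirs <- cbind(sin(sch$theta) * cos(sch$phi),
                sin(sch$theta) * sin(sch$phi), cos(sch$theta))
  coords <- dirs[rep(seq_len(nsp), each = ns), , drop = FALSE] * rep(r, nsp)
  op <- make_nufft(coords, m, cfg$fov)
  w <- rep(hann, nsp)
  imgs <- array(0i, c(m, m, m, C))
  for (c in seq_len(C)) {
    y <- as.vector(t(mean_ks[, keep, c])) * w
    imgs[, , , c] <- cg_solve_normal(
      function(x) op$adjoint(op$forward(x)), op$adjoint(y), n_iters)
  }
  rss <- sqrt(apply(Mod(imgs)^2, 1:3, sum))
  mask <- rss > mask_threshold * max(rss)
  sens <- imgs / array(pmax(rss, 1e-12 * max(rss)), c(m, m, m, C))
  sens <- sens * array(mask, c(m, m, m, C))
  structure(list(sens = sens, mask = mask, rss = rss), class = "capria_sens")
}

# plain CG for SPD normal equations A x = b on complex arrays
cg_solve_normal <- function(A, b, n_iters, tol = 0, x0 = NULL,
                            trace = FALSE) {
  x <- if (is.null(x0)) array(0i, dim(b)) else x0
  r <- b - A(x)
  p <- r
  rs <- sum(Mod(r)^2)
  hist <- numeric(0)
  for (it in seq_len(n_iters)) {
    Ap <- A(p)
    denom <- Re(sum(Conj(p) * Ap))
    if (denom <= 0) break
    alpha <- rs / denom
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(Mod(r)^2)
    hist <- c(hist, sqrt(rs_new))
    if (tol > 0 && sqrt(rs_new) < tol) break
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  if (trace) attr(x, "residual_history") <- hist
  x
}

#' SVD-based coil compression
#'
#' Computes a linear compression from the data covariance across channels and
#' applies it consistently to both conditions and (when present) the stored
#' sensitivity maps. The retained-energy fraction is reported via `message()`.
#'
#' @param raw A [simulate_kspace()] container.
#' @param n_virtual Number of virtual channels to keep (1..n_coils).
#' @return The compressed `capria_raw` container, with attribute
#'   `compression_energy` on the result.
#' @export
compress_coils <- function(raw, n_virtual) {
  C <- dim(raw$label)[3]
  if (n_virtual < 1) abort("`n_virtual` must be >= 1.")
  if (n_virtual > C) abort("`n_virtual` exceeds the number of channels.")
  Y <- rbind(matrix(raw$label, ncol = C), matrix(raw$control, ncol = C))
  cov <- crossprod(Conj(Y), Y)  # C x C Hermitian
  eg <- eigen(cov, symmetric = TRUE)
  V <- eg$vectors[, seq_len(n_virtual), drop = FALSE]
  energy <- sum(eg$values[seq_len(n_virtual)]) / sum(eg$values)
  message(sprintf("coil compression %d -> %d channels: %.4f of energy retained",
                  C, n_virtual, energy))
  apply_rot <- function(arr) {
    d <- dim(arr)
    out <- matrix(arr, ncol = C) %*% V
    array(out, c(d[1], d[2], n_virtual))
  }
  out <- raw
  out$label <- apply_rot(raw$label)
  out$control <- apply_rot(raw$control)
  if (!is.null(raw$coils)) {
    d <- dim(raw$coils)
    sc <- matrix(raw$coils, ncol = C) %*% V
    out$coils <- array(sc, c(d[1:3], n_virtual))
  }
  out$provenance$compression_energy <- energy
  out
}

#' Phase-aligned complex label/control subtraction in k-space
#'
#' For each matched label/control spoke pair, the relative phase is estimated
#' from the central readout samples as the argument of the magnitude-weighted
#' sum of `control * conj(label)` (static tissue dominates the k-space center,
#' so this tracks scanner drift rather than the ASL signal); the control spoke
#' is rotated back by that phase before complex subtraction `control - label`.
#' Spokes whose central samples are all zero fall back to zero rotation with a
#' warning.
#'
#' @param raw A [simulate_kspace()] container.
#' @param n_central Number of central samples used for the phase estimate
#'   (those with the smallest `|k|`).
#' @return Object of class `capria_diff`: list with complex `diff`
#'   (`n_spokes x n_samples x n_coils`), `phase` (per-spoke rotation, rad),
#'   `schedule`, `config`, `radial_coords`.
#' @export
phase_align_subtract <- function(raw, n_central = 5L) {
  r <- raw$radial_coords
  cen <- order(abs(r))[seq_len(min(n_central, length(r)))]
  cross <- raw$control[, cen, , drop = FALSE] *
    Conj(raw$label[, cen, , drop = FALSE])
  s <- apply(cross, 1, sum)
  zero <- Mod(s) == 0
  if (any(zero)) {
    warn(sprintf("%d spoke pairs have zero-magnitude centers; using zero rotation.",
                 sum(zero)))
    s[zero] <- 1
  }
  phase <- Arg(s)
  rot <- exp(-1i * phase)
  diff <- raw$control * array(rot, dim(raw$control)) - raw$label
  structure(list(diff = diff, phase = phase,
                 schedule = raw$schedule, config = raw$config,
                 radial_coords = r, spec = raw$spec,
                 provenance = raw$provenance),
            class = "capria_diff")
}

#' Density-compensated gridding adjoint (quick look)
#'
#' A single-pass reconstruction for inspection only: weights each radial
#' sample by an r^2 density compensation (with the DC sample weighted as a
#' half-voxel sphere), applies the NUFFT adjoint per coil, and combines by
#' root-sum-of-squares. Iterative solvers in this package do not use density
#' compensation; this exists for quick looks at raw data quality.
#'
#' @param dks A [phase_align_subtract()] difference container (or a
#'   `capria_raw` whose `label` array should be imaged — pass
#'   `what = "label"`).
#' @param matrix Reconstruction matrix.
#' @param what For raw containers, which condition to image.
#' @return Real 3D array (RSS-combined magnitude).
#' @export
quicklook_gridded <- function(dks, matrix = dks$config$matrix,
                              what = c("diff", "label", "control")) {
  what <- match.arg(what)
  dat <- if (inherits(dks, "capria_raw")) dks[[what]] else dks$diff
  cfg <- dks$config
  keep <- abs(dks$radial_coords) <= matrix / (2 * cfg$fov) + 1e-12
  r <- dks$radial_coords[keep]
  sch <- dks$schedule
  nsp <- nrow(sch); ns <- length(r); C <- dim(dat)[3]
  dirs <- cbind(sin(sch$theta) * cos(sch$phi),
                sin(sch$theta) * sin(sch$phi), cos(sch$theta))
  coords <- dirs[rep(seq_len(nsp), each = ns), , drop = FALSE] * rep(r, nsp)
  op <- make_nufft(coords, matrix, cfg$fov)
  dk <- 1 / cfg$fov
  w <- pmax(r^2, (dk / 2)^2)
  acc <- array(0, rep(matrix, 3))
  for (c in seq_len(C)) {
    y <- as.vector(t(dat[, keep, c])) * rep(w, nsp)
    acc <- acc + Mod(op$adjoint(y))^2
  }
  sqrt(acc)
}

# assemble the per-frame data list expected by the encoding operator from a
# difference container, truncating readout samples to the operator's band
frame_data <- function(dks, op) {
  keep <- abs(dks$radial_coords) <= op$matrix / (2 * op$config$fov) + 1e-12
  lapply(seq_len(op$n_frames), function(k) {
    rows <- op$frame_rows[[k]]
    d <- dks$diff[rows, keep, , drop = FALSE]
    # spoke-major, sample-fastest to match operator coordinate order
    matrix(aperm(d, c(2, 1, 3)), ncol = dim(d)[3])
  })
}
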