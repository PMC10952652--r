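#' @keywords internal
#' @name nufft-internal
#' @noRd
NULL

# circular shifts moving DC between index 1 and the center (even sizes only,
# where fftshift and its inverse coincide)
fftshift3 <- function(x) {
  d <- dim(x)
  idx <- lapply(d, function(n) c((n / 2 + 1):n, 1:(n / 2)))
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# smallest even integer >= n whose prime factors are all <= 7 (keeps base-R
# FFTs fast)
next_fft_size <- function(n) {
  n <- as.integer(ceiling(n))
  if (n %% 2L == 1L) n <- n + 1L
  smooth <- function(k) {
    for (p in c(2L, 3L, 5L, 7L)) while (k %% p == 0L) k <- k %/% p
    k == 1L
  }
  while (!smooth(n)) n <- n + 2L
  n
}

# Fourier transform of the Kaiser-Bessel interpolation kernel
# (support width W grid samples), evaluated at normalized position p
# (cycles per grid sample); used for deapodization.
kb_ft <- function(p, width, beta) {
  arg2 <- beta^2 - (pi * width * p)^2
  out <- numeric(length(arg2))
  pos <- arg2 > 0
  s <- sqrt(arg2[pos])
  out[pos] <- sinh(s) / s
  s2 <- sqrt(-arg2[!pos])
  out[!pos] <- ifelse(s2 < 1e-12, 1, sin(s2) / s2)
  width * out
}

#' Non-uniform FFT operator for one set of k-space sample points
#'
#' Builds a type-2 (image to non-Cartesian samples) NUFFT and its exact
#' algebraic adjoint using Kaiser-Bessel gridding on an oversampled FFT grid.
#' The forward model approximates the direct sum
#' \eqn{y(k) = \sum_j x_j e^{-2\pi i k \cdot r_j}} with cell-centered voxel
#' positions \eqn{r_j} and DC at the grid center. The `adjoint` is the exact
#' conjugate transpose of `forward` (spreading is the transpose of
#' interpolation and deapodization is real), so adjoint dot-product tests hold
#' to machine precision while the approximation error relative to the direct
#' sum is set by the kernel width and oversampling (~1e-4 relative at the
#' defaults).
#'
#' @param coords `n x 3` matrix of k-space coordinates (cycles/mm).
#' @param matrix Image matrix size (isotropic, even).
#' @param fov Field of view (mm).
#' @param oversampling Grid oversampling factor (default 1.5).
#' @param width Kernel support width in oversampled grid samples (default 5).
#' @return A list of class `capria_nufft` with elements `forward(x)` (complex
#'   3D array -> complex vector), `adjoint(y)`, `n_samples`, `matrix`.
#' @export
make_nufft <- function(coords, matrix, fov, oversampling = 1.5, width = 5) {
  stopifnot(is.matrix(coords), ncol(coords) == 3)
  m <- as.integer(matrix)
  if (m %% 2L != 0L) abort("`matrix` must be even.")
  G <- next_fft_size(oversampling * m)
  # Beatty et al. kernel shape parameter for this width/oversampling
  a <- G / m
  beta <- pi * sqrt((width / a)^2 * (a - 0.5)^2 - 0.8)
  # fractional 0-based grid coordinates, DC at G/2
  gcoords <- coords * fov * a + G / 2
  dims <- c(G, G, G)
  # separable deapodization over the m-voxel centered crop
  p <- ((0:(m - 1)) - m / 2) / G
  ap1 <- kb_ft(p, width, beta)
  apod <- outer(outer(ap1, ap1), ap1)
  pad_idx <- (G - m) / 2 + seq_len(m)
  forward <- function(x) {
    stopifnot(all(dim(x) == c(m, m, m)))
    X <- array(0i, dims)
    X[pad_idx, pad_idx, pad_idx] <- x / apod
    Y <- fftshift3(stats::fft(fftshift3(X)))
    nufft_interp3(Y, gcoords, dims, width, beta)
  }
  adjoint <- function(y) {
    Yg <- nufft_spread3(gcoords, as.complex(y), dims, width, beta)
    X <- fftshift3(stats::fft(fftshift3(Yg), inverse = TRUE))
    X[pad_idx, pad_idx, pad_idx] / apod
  }
  structure(list(forward = forward, adjoint = adjoint,
                 n_samples = nrow(coords), matrix = m, fov = fov,
                 grid = G, width = width, beta = beta),
            class = "capria_nufft")
}

#' Restrict an image to the spherically sampled k-space band
#'
#' Radial trajectories sample the ball `|k| <= matrix/(2 fov)`; the Cartesian
#' corner frequencies outside it are invisible to the acquisition, so a
#' reconstruction can only be expected to match the truth after both are
#' restricted to that band. This zeroes all spectral content outside the
#' sphere.
#'
#' @param x Real or complex 3D array.
#' @param fov Field of view (mm).
#' @return Complex array of the same size.
#' @export
bandlimit_sphere <- function(x, fov) {
  m <- dim(x)[1]
  Fk <- fftshift3(stats::fft(fftshift3(x + 0i)))
  k <- ((0:(m - 1)) - m / 2) / fov
  K2 <- outer(outer(k^2, k^2, `+`), k^2, `+`)
  Fk[K2 > (m / (2 * fov))^2] <- 0i
  fftshift3(stats::fft(fftshift3(Fk), inverse = TRUE)) / m^3
}

#' Downsample an image to a smaller matrix by Fourier cropping
#'
#' Retains the central `m_low^3` block of the centered spectrum, i.e., the
#' ideal low-pass representation of the image at the coarser grid (intensity
#' preserved as mean-per-voxel).
#'
#' @param x Real or complex 3D array (even size).
#' @param m_low Target matrix size (even, <= current).
#' @return Complex array `m_low^3`.
#' @export
fourier_downsample <- function(x, m_low) {
  m <- dim(x)[1]
  stopifnot(m_low <= m, m_low %% 2 == 0)
  Fk <- fftshift3(stats::fft(fftshift3(x + 0i)))
  idx <- (m - m_low) / 2 + seq_len(m_low)
  Fl <- Fk[idx, idx, idx]
  fftshift3(stats::fft(fftshift3(Fl), inverse = TRUE)) / m^3
}

#' Direct (slow) non-uniform DFT, for validation only
#'
#' Evaluates \eqn{y(k) = \sum_j x_j e^{-2\pi i k\cdot r_j}} by explicit
#' summation. Useful as an oracle for the gridding NUFFT on tiny problems.
#'
#' @inheritParams make_nufft
#' @param x Complex image array.
#' @return Complex vector of samples.
#' @export
ndft_direct <- function(x, coords, fov) {
  m <- dim(x)[1]
  pos <- ((0:(m - 1)) - m / 2) * (fov / m)
  g <- expand.grid(x = pos, y = pos, z = pos)
  phase <- coords %*% t(as.matrix(g))  # n x nvox, cycles
  as.vector(exp(-2i * pi * phase) %*% as.vector(x))
}
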