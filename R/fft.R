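#' Centered, orthonormal discrete Fourier transforms
#'
#' The package uses a single Fourier convention throughout: transforms are
#' unitary (scaled by `1/sqrt(N)` in both directions) and centered, with the
#' k-space origin at index `floor(n/2)` (0-based) along each transformed axis.
#' [fft2c()] maps an image to k-space, [ifft2c()] maps k-space back to an
#' image. For 3D arrays the transform is applied independently to each slice
#' along the third (coil) dimension.
#'
#' @param x complex (or numeric) matrix, or 3D array `[ny, nx, ncoil]`.
#' @return complex array of the same shape.
#' @examples
#' img <- matrix(rnorm(64), 8, 8)
#' max(Mod(ifft2c(fft2c(img)) - img)) < 1e-12
#' @export
fft2c <- function(x) {
  d <- dim2d(x)
  shift12(fftn12(ishift12(x)), fwd = TRUE) / sqrt(prod(d))
}

#' @rdname fft2c
#' @export
ifft2c <- function(x) {
  d <- dim2d(x)
  shift12(fftn12(ishift12(x), inverse = TRUE), fwd = TRUE) / sqrt(prod(d))
}

dim2d <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) < 2L) stop("expected a matrix or 3D array", call. = FALSE)
  d[1:2]
}

# plain (uncentered, unscaled) DFT along dims 1 and 2 of a 2D/3D array
fftn12 <- function(x, inverse = FALSE) {
  d <- dim(x)
  if (length(d) == 2L) {
    return(t(stats::mvfft(t(stats::mvfft(x, inverse = inverse)), inverse = inverse)))
  }
  y <- stats::mvfft(matrix(x, d[1], d[2] * d[3]), inverse = inverse)
  dim(y) <- d
  y <- aperm(y, c(2L, 1L, 3L))
  y <- stats::mvfft(matrix(y, d[2], d[1] * d[3]), inverse = inverse)
  dim(y) <- c(d[2], d[1], d[3])
  aperm(y, c(2L, 1L, 3L))
}

# fftshift index permutation for length n: moves DC (index 1) to floor(n/2)+1
shift_idx <- function(n, fwd = TRUE) {
  k <- if (fwd) ceiling(n / 2) else floor(n / 2)
  ((seq_len(n) - 1 + k) %% n) + 1
}

shift12 <- function(x, fwd = TRUE) {
  d <- dim(x)
  i <- shift_idx(d[1], fwd)
  j <- shift_idx(d[2], fwd)
  if (length(d) == 2L) x[i, j, drop = FALSE] else x[i, j, , drop = FALSE]
}

ishift12 <- function(x) shift12(x, fwd = FALSE)

# complex white Gaussian noise with total (complex) std sigma per entry
cgnoise <- function(n, sigma) {
  complex(real = stats::rnorm(n, sd = sigma / sqrt(2)),
          imaginary = stats::rnorm(n, sd = sigma / sqrt(2)))
}
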