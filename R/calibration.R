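#' SVD-based coil compression
#'
#' Fits a linear coil-compression matrix on the calibration data (principal
#' coil modes of the calibration samples) and applies it consistently to all
#' shots, navigators and the calibration scan of a shot set. The compression
#' matrix has orthonormal columns.
#'
#' @param x a `kspace_shotset` or a `ny x nx x ncoil` complex array.
#' @param n_target number of virtual coils to keep.
#' @param cmat optional precomputed compression matrix (`ncoil x n_target`);
#'   when supplied it is applied instead of refit.
#' @return for an array input, a list with `data` and `cmat`; for a shot set,
#'   the compressed `kspace_shotset` with a `cmat` element attached.
#' @export
compress_coils <- function(x, n_target, cmat = NULL) {
  if (n_target <= 0) stop("n_target must be positive", call. = FALSE)
  apply_cmat <- function(arr, cm) {
    d <- dim(arr)
    out <- matrix(arr, prod(d[1:2]), d[3]) %*% cm
    array(out, c(d[1:2], ncol(cm)))
  }
  if (inherits(x, "kspace_shotset")) {
    if (n_target > x$n_coils) stop("n_target exceeds the number of coils", call. = FALSE)
    if (is.null(cmat)) cmat <- coil_basis(x$calibration, n_target)
    x$shots <- lapply(x$shots, apply_cmat, cm = cmat)
    x$navigators <- lapply(x$navigators, apply_cmat, cm = cmat)
    x$calibration <- apply_cmat(x$calibration, cmat)
    x$n_coils <- as.integer(n_target)
    x$cmat <- cmat
    x$truth$sens <- NULL   # physical-coil truth no longer applies
    return(x)
  }
  d <- dim(x)
  if (length(d) != 3L) stop("expected a ny x nx x ncoil array", call. = FALSE)
  if (n_target > d[3]) stop("n_target exceeds the number of coils", call. = FALSE)
  if (is.null(cmat)) cmat <- coil_basis(x, n_target)
  list(data = apply_cmat(x, cmat), cmat = cmat)
}

coil_basis <- function(calib, n_target) {
  d <- dim(calib)
  m <- matrix(calib, prod(d[1:2]), d[3])
  sv <- svd(m, nu = 0, nv = d[3])
  sv$v[, seq_len(n_target), drop = FALSE]
}

#' Calibrate a SPIRiT kernel
#'
#' Least-squares fit of every calibration k-space sample from its cross-coil
#' neighborhood (`kernel_size` square, the sample's own-coil center excluded),
#' ridge-regularized. The resulting kernel `G` expresses the self-consistency
#' of fully sampled multi-coil k-space: `G x ~ x`.
#'
#' @param calib `ncal x ncal x ncoil` complex calibration k-space (the
#'   central, fully sampled region).
#' @param kernel_size odd kernel side length.
#' @param tikhonov ridge weight relative to the scale of the normal matrix.
#' @return an object of class `spirit_kernel`: list with `weights` (array
#'   `kernel_size x kernel_size x ncoil x ncoil`, `[dy, dx, in, out]`, own
#'   center fixed at 0), `kernel_size`, `n_coils`, `tikhonov`.
#' @export
calibrate_spirit_kernel <- function(calib, kernel_size = 5, tikhonov = 0.01) {
  d <- dim(calib)
  if (length(d) != 3L) stop("calibration must be ncal x ncal x ncoil", call. = FALSE)
  ks <- as.integer(kernel_size)
  if (ks %% 2L != 1L) stop("kernel_size must be odd", call. = FALSE)
  h <- ks %/% 2L
  nc <- d[3]
  nfit <- (d[1] - 2L * h) * (d[2] - 2L * h)
  ncol_a <- ks * ks * nc
  if (nfit < ncol_a) {
    stop("insufficient calibration region for the kernel fit", call. = FALSE)
  }
  if (max(Mod(calib)) == 0) stop("calibration data are all zero", call. = FALSE)
  # block-Hankel predictor matrix: rows = interior positions, cols = (dy, dx, coil)
  A <- matrix(0i, nfit, ncol_a)
  col <- 0L
  for (c in seq_len(nc)) {
    for (dx in -h:h) {
      for (dy in -h:h) {
        col <- col + 1L
        A[, col] <- as.vector(calib[(1L + h + dy):(d[1] - h + dy),
                                    (1L + h + dx):(d[2] - h + dx), c])
      }
    }
  }
  M <- Conj(t(A)) %*% A
  lam <- tikhonov * mean(Re(diag(M)))
  weights <- array(0i, c(ks, ks, nc, nc))
  center_of <- function(c) (c - 1L) * ks * ks + (h) * ks + h + 1L  # (dy=0, dx=0) of coil c
  for (cout in seq_len(nc)) {
    idx <- center_of(cout)
    Mi <- M[-idx, -idx]
    rhs <- M[-idx, idx]
    w <- solve(Mi + lam * diag(nrow(Mi)), rhs)
    full <- complex(length.out = ncol_a)
    full[-idx] <- w
    weights[, , , cout] <- array(full, c(ks, ks, nc))
  }
  structure(list(weights = weights, kernel_size = ks, n_coils = nc,
                 tikhonov = tikhonov),
            class = "spirit_kernel")
}

#' Apply a SPIRiT kernel to multi-coil k-space
#'
#' `(G x)[p, q, out] = sum over (dy, dx, in) of w[dy, dx, in, out] *
#' x[p + dy, q + dx, in]` with circular boundary. The default implementation
#' multiplies in the image domain with precomputed transfer maps; `direct =
#' TRUE` uses the literal convolution (slow; used to validate the fast path).
#'
#' @param kernel a [calibrate_spirit_kernel()] result.
#' @param x `ny x nx x ncoil` complex k-space array.
#' @param adjoint apply the adjoint operator instead.
#' @param direct use the explicit k-space convolution.
#' @param gmaps optional precomputed [spirit_gmaps()] output.
#' @return array of the same shape as `x`.
#' @export
apply_spirit <- function(kernel, x, adjoint = FALSE, direct = FALSE, gmaps = NULL) {
  stopifnot(inherits(kernel, "spirit_kernel"))
  d <- dim(x)
  if (direct) {
    stopifnot(!adjoint)
    h <- kernel$kernel_size %/% 2L
    out <- array(0i, d)
    for (cout in seq_len(kernel$n_coils)) {
      acc <- matrix(0i, d[1], d[2])
      for (cin in seq_len(kernel$n_coils)) {
        for (dx in -h:h) for (dy in -h:h) {
          w <- kernel$weights[dy + h + 1L, dx + h + 1L, cin, cout]
          if (w != 0) {
            ri <- ((seq_len(d[1]) - 1L + dy) %% d[1]) + 1L
            ci <- ((seq_len(d[2]) - 1L + dx) %% d[2]) + 1L
            acc <- acc + w * x[ri, ci, cin]
          }
        }
      }
      out[, , cout] <- acc
    }
    return(out)
  }
  if (is.null(gmaps)) gmaps <- spirit_gmaps(kernel, d[1:2])
  img <- fftn12(x, inverse = TRUE) / prod(d[1:2])      # plain ifft per coil
  out <- array(0i, d)
  nc <- kernel$n_coils
  if (!adjoint) {
    for (cout in seq_len(nc)) {
      acc <- matrix(0i, d[1], d[2])
      for (cin in seq_len(nc)) acc <- acc + gmaps[, , cin, cout] * img[, , cin]
      out[, , cout] <- acc
    }
  } else {
    for (cin in seq_len(nc)) {
      acc <- matrix(0i, d[1], d[2])
      for (cout in seq_len(nc)) acc <- acc + Conj(gmaps[, , cin, cout]) * img[, , cout]
      out[, , cin] <- acc
    }
  }
  fftn12(out)                                          # plain fft per coil
}

#' Image-domain transfer maps of a SPIRiT kernel
#'
#' @param kernel a [calibrate_spirit_kernel()] result.
#' @param shape target grid `c(ny, nx)`.
#' @return `ny x nx x ncoil x ncoil` complex array of pointwise transfer
#'   functions (`[, , in, out]`).
#' @export
spirit_gmaps <- function(kernel, shape) {
  ks <- kernel$kernel_size
  h <- ks %/% 2L
  nc <- kernel$n_coils
  g <- array(0i, c(shape[1], shape[2], nc, nc))
  for (cout in seq_len(nc)) for (cin in seq_len(nc)) {
    w <- matrix(0i, shape[1], shape[2])
    for (dx in -h:h) for (dy in -h:h) {
      w[((dy) %% shape[1]) + 1L, ((dx) %% shape[2]) + 1L] <-
        kernel$weights[dy + h + 1L, dx + h + 1L, cin, cout]
    }
    g[, , cin, cout] <- stats::fft(w)
  }
  g
}

#' Estimate coil sensitivity maps from calibration data
#'
#' Low-resolution coil images are formed by zero-padding the apodized
#' calibration k-space to the target grid; maps are their ratio to the root
#' sum of squares, which makes the output RSS exactly 1 wherever the
#' calibration image has support.
#'
#' @param calib `ncal x ncal x ncoil` complex calibration k-space.
#' @param shape target grid `c(ny, nx)`.
#' @param apodize apply a Hamming taper to the calibration window before
#'   zero-padding (reduces ringing).
#' @return an object of class `coil_model` (see [make_sensitivities()]) with
#'   an extra `lowres` element holding the low-resolution coil images.
#' @export
estimate_sensitivities <- function(calib, shape, apodize = TRUE) {
  d <- dim(calib)
  if (length(d) != 3L) stop("calibration must be ncal x ncal x ncoil", call. = FALSE)
  if (max(Mod(calib)) == 0) stop("calibration data are all zero", call. = FALSE)
  ny <- shape[1]; nx <- shape[2]; nc <- d[3]
  if (apodize) {
    w <- outer(hamming_win(d[1]), hamming_win(d[2]))
    for (c in seq_len(nc)) calib[, , c] <- calib[, , c] * w
  }
  k <- array(0i, c(ny, nx, nc))
  rows <- ny %/% 2 + 1 + seq(-d[1] %/% 2, d[1] - d[1] %/% 2 - 1)
  cols <- nx %/% 2 + 1 + seq(-d[2] %/% 2, d[2] - d[2] %/% 2 - 1)
  k[rows, cols, ] <- calib
  lowres <- ifft2c(k) * sqrt(prod(shape) / prod(d[1:2]))
  rss <- sqrt(apply(Mod(lowres)^2, c(1, 2), sum))
  floor_val <- 0.01 * max(rss)
  sens <- array(0i, c(ny, nx, nc))
  for (c in seq_len(nc)) sens[, , c] <- lowres[, , c] / pmax(rss, floor_val)
  structure(list(sens = sens, n_coils = nc, lowres = lowres), class = "coil_model")
}

hamming_win <- function(n) 0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1))
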