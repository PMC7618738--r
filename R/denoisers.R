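.denoisers <- new.env(parent = emptyenv())

#' Register a denoiser plug-in
#'
#' A denoiser is a shape-preserving callable `function(image, sigma_hint,
#' opts)` returning an image of identical dimensions; it must be
#' deterministic given its inputs and options. `accepts` declares whether the
#' plug-in operates on complex images directly or on magnitudes only (in the
#' latter case [apply_denoiser()] denoises `Mod(image)` and restores the
#' input phase).
#'
#' @param id character identifier.
#' @param fn the callable.
#' @param accepts `"complex"` or `"magnitude"`.
#' @export
register_denoiser <- function(id, fn, accepts = c("complex", "magnitude")) {
  accepts <- match.arg(accepts)
  stopifnot(is.character(id), length(id) == 1L, is.function(fn))
  assign(id, list(fn = fn, accepts = accepts), envir = .denoisers)
  invisible(id)
}

#' List registered denoisers
#' @return character vector of ids.
#' @export
list_denoisers <- function() ls(.denoisers)

#' Apply a registered denoiser
#'
#' Dispatches to the registered plug-in, handling the magnitude/complex
#' contract and validating that the plug-in preserved the image shape and
#' returned finite values.
#'
#' @param id denoiser identifier (see [list_denoisers()]).
#' @param image complex or real matrix (or array).
#' @param sigma_hint optional noise standard deviation hint.
#' @param opts list of plug-in options.
#' @return denoised image of the same shape and type domain as the input.
#' @export
apply_denoiser <- function(id, image, sigma_hint = NULL, opts = list()) {
  if (!exists(id, envir = .denoisers, inherits = FALSE)) {
    stop(sprintf("unregistered denoiser '%s'", id), call. = FALSE)
  }
  spec <- get(id, envir = .denoisers)
  if (spec$accepts == "magnitude" && is.complex(image)) {
    mag <- spec$fn(Mod(image), sigma_hint, opts)
    out <- mag * exp(1i * Arg(image))
  } else {
    out <- spec$fn(image, sigma_hint, opts)
  }
  if (!identical(dim(out), dim(image)) || length(out) != length(image)) {
    stop(sprintf("denoiser '%s' violated the shape-preservation contract", id),
         call. = FALSE)
  }
  if (any(!is.finite(Mod(out)))) {
    stop(sprintf("denoiser '%s' returned non-finite values", id), call. = FALSE)
  }
  out
}

#' Locally-low-rank denoiser with Marchenko-Pastur thresholding
#'
#' Sliding patches are rearranged into Casorati matrices (the patch itself
#' for a single image; `patch-pixels x n_images` for a stack), singular
#' values below the random-matrix noise floor `sigma (sqrt(m) + sqrt(n))` are
#' zeroed, and overlapping reconstructions are averaged. When `sigma` is not
#' supplied it is estimated from a Laplacian pseudo-residual of the image,
#' which is insensitive to smooth structure.
#'
#' @param image complex or real matrix, or `ny x nx x n_images` stack.
#' @param patch patch side length.
#' @param stride patch stride (patch/2 by default).
#' @param sigma noise standard deviation (complex std for complex input);
#'   estimated when `NULL`.
#' @param threshold_scale multiplier on the Marchenko-Pastur edge.
#' @return denoised image of the same shape.
#' @export
denoise_llr <- function(image, patch = 8, stride = max(1, patch %/% 2),
                        sigma = NULL, threshold_scale = 1) {
  d <- dim(image)
  is_stack <- length(d) == 3L
  ny <- d[1]; nx <- d[2]
  if (patch > ny || patch > nx) stop("patch larger than the image", call. = FALSE)
  if (is.null(sigma)) sigma <- estimate_noise_sigma(if (is_stack) image[, , 1] else image)
  starts <- function(n) unique(c(seq(1L, n - patch + 1L, by = stride), n - patch + 1L))
  acc <- array(0i, d)
  cnt <- array(0, d)
  thr_mn <- if (is_stack) c(patch * patch, d[3]) else c(patch, patch)
  tau <- threshold_scale * sigma * (sqrt(thr_mn[1]) + sqrt(thr_mn[2]))
  for (i in starts(ny)) for (j in starts(nx)) {
    ri <- i:(i + patch - 1L); ci <- j:(j + patch - 1L)
    if (is_stack) {
      m <- matrix(image[ri, ci, ], patch * patch, d[3])
    } else {
      m <- image[ri, ci]
    }
    sv <- svd(m)
    keep <- sv$d > tau
    rec <- if (any(keep)) {
      sv$u[, keep, drop = FALSE] %*% (sv$d[keep] * t(Conj(sv$v[, keep, drop = FALSE])))
    } else {
      m * 0
    }
    if (is_stack) {
      acc[ri, ci, ] <- acc[ri, ci, ] + array(rec, c(patch, patch, d[3]))
      cnt[ri, ci, ] <- cnt[ri, ci, ] + 1
    } else {
      acc[ri, ci] <- acc[ri, ci] + rec
      cnt[ri, ci] <- cnt[ri, ci] + 1
    }
  }
  out <- acc / cnt
  if (!is.complex(image)) out <- Re(out)
  out
}

#' Noise level estimate from a Laplacian pseudo-residual
#'
#' `e = (4 x - up - down - left - right) / sqrt(20)` removes locally linear
#' structure; a robust (median-based) scale of `e` estimates the per-pixel
#' noise standard deviation (complex std for complex input).
#'
#' @param image real or complex matrix.
#' @return scalar noise standard deviation.
#' @export
estimate_noise_sigma <- function(image) {
  n <- nrow(image); m <- ncol(image)
  up <- image[c(1, seq_len(n - 1)), ]
  dn <- image[c(seq_len(n - 1) + 1, n), ]
  lf <- image[, c(1, seq_len(m - 1))]
  rt <- image[, c(seq_len(m - 1) + 1, m)]
  e <- (4 * image - up - dn - lf - rt) / sqrt(20)
  if (is.complex(image)) {
    s_re <- stats::median(abs(Re(e))) / 0.6745
    s_im <- stats::median(abs(Im(e))) / 0.6745
    sqrt(s_re^2 + s_im^2)
  } else {
    stats::median(abs(e)) / 0.6745
  }
}

register_builtin_denoisers <- function() {
  register_denoiser("identity", function(image, sigma_hint, opts) image,
                    accepts = "complex")
  register_denoiser("llr", function(image, sigma_hint, opts) {
    args <- c(list(image = image, sigma = sigma_hint), opts)
    do.call(denoise_llr, args)
  }, accepts = "complex")
}

.onLoad <- function(libname, pkgname) {
  register_builtin_denoisers()
}
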