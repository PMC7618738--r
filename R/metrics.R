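#' Noise standard deviation from two repeated acquisitions
#'
#' `sigma = sd(rep1 - rep2, within mask) / sqrt(2)`: the difference of two
#' independent repeats doubles the noise variance and cancels the signal.
#'
#' @param rep1,rep2 images (real; magnitudes are taken for complex input).
#' @param mask logical mask of the same shape.
#' @return scalar noise standard deviation.
#' @export
noise_std_from_repeats <- function(rep1, rep2, mask) {
  if (!all(dim(rep1) == dim(rep2)) || !all(dim(rep1) == dim(mask))) {
    stop("repeats and mask must share a shape", call. = FALSE)
  }
  if (!any(mask)) stop("empty mask", call. = FALSE)
  if (is.complex(rep1)) rep1 <- Mod(rep1)
  if (is.complex(rep2)) rep2 <- Mod(rep2)
  stats::sd((rep1 - rep2)[mask]) / sqrt(2)
}

#' SNR and angular CNR
#'
#' SNR is the mean signal within the mask divided by the noise standard
#' deviation. The angular CNR of a set of diffusion-weighted images is the
#' mask mean of the per-voxel standard deviation across diffusion directions,
#' divided by the noise standard deviation.
#'
#' @param b0 b = 0 image (real or complex; magnitude used).
#' @param dwis `ny x nx x n_directions` array of DWI magnitudes.
#' @param sigma noise standard deviation (must be positive).
#' @param mask logical mask.
#' @return list with `snr_b0`, `snr_dwi` (per direction), `snr_dwi_mean`,
#'   `cnr_dwi`.
#' @export
snr_and_cnr <- function(b0, dwis, sigma, mask) {
  if (sigma <= 0) stop("undefined metric: sigma must be positive", call. = FALSE)
  if (is.complex(b0)) b0 <- Mod(b0)
  if (is.complex(dwis)) dwis <- Mod(dwis)
  snr_b0 <- mean(b0[mask]) / sigma
  nd <- dim(dwis)[3]
  snr_dwi <- vapply(seq_len(nd), function(k) mean(dwis[, , k][mask]) / sigma, numeric(1))
  vox <- matrix(dwis, prod(dim(dwis)[1:2]), nd)[as.vector(mask), , drop = FALSE]
  cnr <- mean(apply(vox, 1, stats::sd)) / sigma
  list(snr_b0 = snr_b0, snr_dwi = snr_dwi, snr_dwi_mean = mean(snr_dwi),
       cnr_dwi = cnr)
}

#' Tenengrad sharpness
#'
#' Mean gradient magnitude `sqrt(Gx^2 + Gy^2 (+ Gz^2))` over the mask, with
#' central differences in the interior and one-sided differences at the
#' array borders; optionally normalized by the noise standard deviation.
#' `squared = TRUE` averages the squared gradient magnitude instead.
#'
#' @param image 2D or 3D real array (magnitude taken for complex input).
#' @param mask logical mask (defaults to everything).
#' @param sigma noise standard deviation for the normalized value (`NA` to
#'   skip).
#' @param squared use the squared-gradient variant.
#' @return list with `raw` and `normalized` (`NA` when no sigma given).
#' @export
tenengrad_sharpness <- function(image, mask = NULL, sigma = NA, squared = FALSE) {
  if (is.complex(image)) image <- Mod(image)
  d <- dim(image)
  if (is.null(mask)) mask <- array(TRUE, d)
  grad1 <- function(x, along) {
    dd <- dim(x)
    n <- dd[along]
    idx_p <- pmin(seq_len(n) + 1L, n)
    idx_m <- pmax(seq_len(n) - 1L, 1L)
    h <- pmax(idx_p - idx_m, 1L)
    hr <- array(rep(h, each = prod(dd[seq_len(along - 1)])), dd)
    diffd <- if (along == 1L) {
      if (length(dd) == 2L) x[idx_p, , drop = FALSE] - x[idx_m, , drop = FALSE]
      else x[idx_p, , , drop = FALSE] - x[idx_m, , , drop = FALSE]
    } else if (along == 2L) {
      if (length(dd) == 2L) x[, idx_p, drop = FALSE] - x[, idx_m, drop = FALSE]
      else x[, idx_p, , drop = FALSE] - x[, idx_m, , drop = FALSE]
    } else {
      x[, , idx_p, drop = FALSE] - x[, , idx_m, drop = FALSE]
    }
    diffd / hr
  }
  g2 <- grad1(image, 1L)^2 + grad1(image, 2L)^2
  if (length(d) == 3L) g2 <- g2 + grad1(image, 3L)^2
  raw <- if (squared) mean(g2[mask]) else mean(sqrt(g2)[mask])
  list(raw = raw, normalized = if (is.na(sigma)) NA_real_ else raw / sigma)
}

#' Normalized root-mean-square error
#'
#' `||image - reference|| / ||reference||` over the mask.
#'
#' @param image,reference arrays of the same shape (magnitudes are compared
#'   when either is complex).
#' @param mask logical mask (defaults to everything).
#' @return scalar NRMSE.
#' @export
nrmse <- function(image, reference, mask = NULL) {
  if (!all(dim(image) == dim(reference))) stop("shape mismatch", call. = FALSE)
  if (is.complex(image) || is.complex(reference)) {
    image <- Mod(image); reference <- Mod(reference)
  }
  if (is.null(mask)) mask <- array(TRUE, dim(image))
  ref_n <- sqrt(sum(reference[mask]^2))
  if (ref_n == 0) stop("zero reference norm", call. = FALSE)
  sqrt(sum((image[mask] - reference[mask])^2)) / ref_n
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Maximum absolute difference of the two empirical CDFs over the pooled
#' support.
#'
#' @param a,b numeric samples.
#' @return the KS statistic in `[0, 1]`.
#' @export
ks_statistic <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty sample", call. = FALSE)
  pooled <- sort(unique(c(a, b)))
  fa <- stats::ecdf(a)(pooled)
  fb <- stats::ecdf(b)(pooled)
  max(abs(fa - fb))
}

#' Log-linear diffusion tensor fit
#'
#' Per-voxel least squares on `log(S_g / S_0) = -b g' D g` over at least six
#' non-collinear directions. FA is computed from the eigenvalues with
#' negative eigenvalues clamped to zero; MD is the mean eigenvalue
#' (unclamped trace / 3).
#'
#' @param b0 b = 0 image (magnitude used).
#' @param dwis `ny x nx x n_directions` DWI array (magnitudes used).
#' @param bvecs `n_directions x 3` unit direction matrix.
#' @param b_value diffusion weighting (s/mm^2).
#' @param mask logical mask of voxels to fit.
#' @return list with `fa`, `md` matrices and `tensors`
#'   (`ny x nx x 6`, order Dxx, Dyy, Dzz, Dxy, Dxz, Dyz); voxels outside the
#'   mask are `NA`.
#' @export
fit_dti <- function(b0, dwis, bvecs, b_value, mask = NULL) {
  if (is.complex(b0)) b0 <- Mod(b0)
  if (is.complex(dwis)) dwis <- Mod(dwis)
  nd <- dim(dwis)[3]
  if (is.null(nd) || nd < 6L) stop("at least 6 diffusion directions are required", call. = FALSE)
  bvecs <- as.matrix(bvecs)
  if (qr(bvecs)$rank < 3L) stop("diffusion directions are collinear", call. = FALSE)
  d <- dim(b0)
  if (is.null(mask)) mask <- b0 > 0
  X <- b_value * cbind(bvecs[, 1]^2, bvecs[, 2]^2, bvecs[, 3]^2,
                       2 * bvecs[, 1] * bvecs[, 2],
                       2 * bvecs[, 1] * bvecs[, 3],
                       2 * bvecs[, 2] * bvecs[, 3])
  Xp <- solve(crossprod(X), t(X))                   # 6 x nd
  vox <- which(mask & b0 > 0)
  S <- matrix(dwis, prod(d), nd)[vox, , drop = FALSE]
  S <- pmax(S, 1e-12 * max(S))
  Y <- -log(S / b0[vox])                            # nvox x nd
  D <- Y %*% t(Xp)                                  # nvox x 6
  ev <- eigvals_sym3(D)
  md_v <- rowMeans(ev)
  evc <- pmax(ev, 0)
  num <- (evc[, 1] - evc[, 2])^2 + (evc[, 2] - evc[, 3])^2 + (evc[, 1] - evc[, 3])^2
  den <- 2 * rowSums(evc^2)
  fa_v <- ifelse(den > 0, sqrt(num / den), 0)
  fa <- md <- array(NA_real_, d)
  fa[vox] <- fa_v
  md[vox] <- md_v
  tensors <- array(NA_real_, c(d, 6L))
  for (k in 1:6) {
    tk <- array(NA_real_, d)
    tk[vox] <- D[, k]
    tensors[, , k] <- tk
  }
  list(fa = fa, md = md, tensors = tensors)
}

# analytic eigenvalues of symmetric 3x3 matrices, rows = (xx, yy, zz, xy, xz, yz)
eigvals_sym3 <- function(D) {
  a <- D[, 1]; b <- D[, 2]; c <- D[, 3]
  d <- D[, 4]; e <- D[, 5]; f <- D[, 6]
  q <- (a + b + c) / 3
  p2 <- (a - q)^2 + (b - q)^2 + (c - q)^2 + 2 * (d^2 + e^2 + f^2)
  p <- sqrt(pmax(p2 / 6, 0))
  ev <- cbind(q, q, q)
  nz <- p > 1e-30
  if (any(nz)) {
    a1 <- (a - q) / p; b1 <- (b - q) / p; c1 <- (c - q) / p
    d1 <- d / p; e1 <- e / p; f1 <- f / p
    detB <- a1 * (b1 * c1 - f1^2) - d1 * (d1 * c1 - f1 * e1) + e1 * (d1 * f1 - b1 * e1)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    l1 <- q + 2 * p * cos(phi)
    l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
    l2 <- 3 * q - l1 - l3
    ev[nz, 1] <- l1[nz]; ev[nz, 2] <- l2[nz]; ev[nz, 3] <- l3[nz]
  }
  ev
}

#' Collect the image-quality report for a reconstruction
#'
#' Convenience wrapper combining the individual metrics into one list
#' mirroring the quantitative comparison used for the reconstruction study:
#' noise sigma from the two b = 0 repeats, SNR of b = 0 and DWIs, angular
#' CNR, noise-normalized Tenengrad sharpness, and DTI-derived FA/MD bias
#' against a reference fit.
#'
#' @param b0_reps list of two reconstructed b = 0 magnitude images.
#' @param dwis `ny x nx x n_directions` reconstructed DWI magnitudes.
#' @param bvecs,b_value diffusion scheme.
#' @param wm_mask,brain_mask white-matter and brain masks.
#' @param ref_fa,ref_md reference FA (white matter) and MD (brain) values to
#'   compare distribution means against; optional.
#' @return list of metrics (`noise_sigma`, `snr_b0`, `snr_dwi_mean`,
#'   `cnr_dwi`, `tenengrad_normalized`, `fa_mean`, `md_mean`, `delta_fa`,
#'   `delta_md`, `ks_fa`, `ks_md` when references are given).
#' @export
metrics_report <- function(b0_reps, dwis, bvecs, b_value, wm_mask, brain_mask,
                           ref_fa = NULL, ref_md = NULL) {
  sigma <- noise_std_from_repeats(b0_reps[[1]], b0_reps[[2]], brain_mask)
  b0 <- (Mod(b0_reps[[1]]) + Mod(b0_reps[[2]])) / 2
  sc <- snr_and_cnr(b0, dwis, sigma, wm_mask)
  ten <- mean(vapply(seq_len(dim(dwis)[3]), function(k) {
    tenengrad_sharpness(dwis[, , k], brain_mask, sigma)$normalized
  }, numeric(1)))
  fit <- fit_dti(b0, dwis, bvecs, b_value, mask = brain_mask)
  fa_wm <- fit$fa[wm_mask & !is.na(fit$fa)]
  md_br <- fit$md[brain_mask & !is.na(fit$md)]
  out <- list(noise_sigma = sigma, snr_b0 = sc$snr_b0,
              snr_dwi_mean = sc$snr_dwi_mean, cnr_dwi = sc$cnr_dwi,
              tenengrad_normalized = ten,
              fa_mean = mean(fa_wm), md_mean = mean(md_br))
  if (!is.null(ref_fa)) {
    out$delta_fa <- abs(out$fa_mean - mean(ref_fa))
    out$ks_fa <- ks_statistic(fa_wm, ref_fa)
  }
  if (!is.null(ref_md)) {
    out$delta_md <- abs(out$md_mean - mean(ref_md))
    out$ks_md <- ks_statistic(md_br, ref_md)
  }
  out
}
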