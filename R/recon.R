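#' Estimate per-shot motion-induced phase maps from navigators
#'
#' Each navigator is smoothed with a centered k-space Hamming window
#' (default 32 x 32), inverse transformed, and the per-shot phase is taken
#' relative to the first shot by coil-wise correlation
#' `sum_c img_i,c * Conj(img_1,c)`, which cancels coil and object phase.
#' The first shot is the zero-phase reference.
#'
#' @param navigators list of full-grid `ny x nx x ncoil` navigator k-space
#'   arrays (one per shot), as produced by [encode_acquisition()].
#' @param window_size side of the k-space Hamming window.
#' @param window apply the Hamming taper (`FALSE` uses the raw navigator).
#' @return an object of class `phase_maps`: list with `phi` (list of real
#'   phase maps, rad; first is all zero) and `P` (list of unit-magnitude
#'   complex maps).
#' @export
estimate_phase_maps <- function(navigators, window_size = 32, window = TRUE) {
  if (length(navigators) == 0L) stop("no navigators supplied", call. = FALSE)
  d <- dim(navigators[[1]])
  rows <- d[1] %/% 2 + 1 + seq(-window_size %/% 2, window_size %/% 2 - 1)
  cols <- d[2] %/% 2 + 1 + seq(-window_size %/% 2, window_size %/% 2 - 1)
  w2 <- outer(hamming_win(window_size), hamming_win(window_size))
  imgs <- lapply(navigators, function(nav) {
    if (is.null(nav)) stop("missing navigator for a shot", call. = FALSE)
    k <- array(0i, d)
    win <- nav[rows, cols, , drop = FALSE]
    if (window) for (c in seq_len(d[3])) win[, , c] <- win[, , c] * w2
    k[rows, cols, ] <- win
    ifft2c(k)
  })
  phi <- vector("list", length(imgs))
  phi[[1]] <- matrix(0, d[1], d[2])
  ref <- imgs[[1]]
  for (i in seq_along(imgs)[-1]) {
    corr <- matrix(0i, d[1], d[2])
    for (c in seq_len(d[3])) corr <- corr + imgs[[i]][, , c] * Conj(ref[, , c])
    phi[[i]] <- Arg(corr)
  }
  structure(list(phi = phi, P = lapply(phi, function(p) exp(1i * p))),
            class = "phase_maps")
}

#' Ground-truth phase maps as a `phase_maps` object
#'
#' Wraps generator phases (referenced to shot 1) in the container used by the
#' reconstruction, e.g. to isolate reconstruction error from navigator
#' estimation error.
#'
#' @param phases a [make_shot_phases()] result or list of phase matrices.
#' @param n_shots number of shots to keep.
#' @return a `phase_maps` object.
#' @export
true_phase_maps <- function(phases, n_shots = NULL) {
  phi <- if (inherits(phases, "shot_phase_model")) phases$phases else phases
  if (!is.null(n_shots)) phi <- phi[seq_len(n_shots)]
  phi <- lapply(phi, function(p) p - phi[[1]])
  structure(list(phi = phi, P = lapply(phi, function(p) exp(1i * p))),
            class = "phase_maps")
}

# ---- forward model ---------------------------------------------------------

# E_i x = D_i F (P_i . F^-1 x); these helpers operate on the multi-coil image
mul_phase <- function(img, P) {
  for (c in seq_len(dim(img)[3])) img[, , c] <- img[, , c] * P
  img
}

mask_data <- function(k, mask) {
  for (c in seq_len(dim(k)[3])) {
    kc <- k[, , c]
    kc[!mask] <- 0i
    k[, , c] <- kc
  }
  k
}

#' Multi-shot forward operator and its adjoint
#'
#' `forward_shots()` maps the phase-free multi-coil k-space `x` to the list
#' of per-shot acquisitions `D_i F (P_i . F^-1 x)`; `adjoint_shots()` is its
#' exact adjoint under the unitary Fourier convention. These are the building
#' blocks of the normal equations solved by [cg_solve_normal()].
#'
#' @param x multi-coil k-space array `ny x nx x ncoil`.
#' @param ys list of per-shot k-space arrays.
#' @param masks list of logical sampling masks.
#' @param phases a `phase_maps` object.
#' @return `forward_shots()`: list of arrays; `adjoint_shots()`: one array.
#' @export
forward_shots <- function(x, masks, phases) {
  img <- ifft2c(x)
  lapply(seq_along(masks), function(i) {
    mask_data(fft2c(mul_phase(img, phases$P[[i]])), masks[[i]])
  })
}

#' @rdname forward_shots
#' @export
adjoint_shots <- function(ys, masks, phases) {
  acc <- NULL
  for (i in seq_along(ys)) {
    t <- ifft2c(mask_data(ys[[i]], masks[[i]]))
    t <- mul_phase(t, Conj(phases$P[[i]]))
    acc <- if (is.null(acc)) t else acc + t
  }
  fft2c(acc)
}

# per-pixel Hermitian matrices H = (g - I)^H (g - I) for the SPIRiT penalty
spirit_normal_maps <- function(kernel, shape) {
  g <- spirit_gmaps(kernel, shape)
  nc <- kernel$n_coils
  for (c in seq_len(nc)) g[, , c, c] <- g[, , c, c] - 1
  # apply_pixelwise computes y_out = sum_in maps[, , in, out] x_in, so
  # maps[, , in, out] must hold ((g-I)^H (g-I))[out, in]
  H <- array(0i, dim(g))
  for (a in seq_len(nc)) for (b in seq_len(nc)) {
    acc <- matrix(0i, shape[1], shape[2])
    for (k in seq_len(nc)) acc <- acc + Conj(g[, , b, k]) * g[, , a, k]
    H[, , a, b] <- acc
  }
  H
}

apply_pixelwise <- function(maps, x) {
  # y_out = sum_in maps[,,in,out] x_in in the plain-DFT image domain
  d <- dim(x)
  img <- fftn12(x, inverse = TRUE) / prod(d[1:2])
  out <- array(0i, d)
  for (cout in seq_len(d[3])) {
    acc <- matrix(0i, d[1], d[2])
    for (cin in seq_len(d[3])) acc <- acc + maps[, , cin, cout] * img[, , cin]
    out[, , cout] <- acc
  }
  fftn12(out)
}

#' Solve the regularized multi-shot normal equations by conjugate gradient
#'
#' Minimizes
#' `sum_i ||D_i F P_i F^-1 x - y_i||^2 + lambda1 ||(G - I) x||^2 +
#'  lambda2 ||F^-1 x - z||^2`
#' over the multi-coil k-space `x`, by running CG on the (Hermitian positive
#' semi-definite) normal equations. The SPIRiT penalty is applied through
#' precomputed per-pixel image-domain transfer maps.
#'
#' @param ys list of per-shot acquired k-space arrays (`ny x nx x ncoil`).
#' @param masks list of logical sampling masks.
#' @param phases a `phase_maps` object.
#' @param kernel a [calibrate_spirit_kernel()] result (may be `NULL` when
#'   `lambda1 = 0`).
#' @param lambda1 SPIRiT self-consistency weight.
#' @param lambda2 denoiser-prior weight.
#' @param z_prev multi-coil image-domain prior (required when `lambda2 > 0`).
#' @param cg_tol relative-residual stopping tolerance.
#' @param cg_max_iter iteration cap.
#' @param x0 warm-start iterate (defaults to zero).
#' @param normal_maps optional precomputed [spirit_normal_maps()] output.
#' @return list with `x` (solution), `iters`, `resid` (relative-residual log)
#'   and `diverged` flag.
#' @export
cg_solve_normal <- function(ys, masks, phases, kernel, lambda1 = 0,
                            lambda2 = 0, z_prev = NULL, cg_tol = 1e-6,
                            cg_max_iter = 100, x0 = NULL, normal_maps = NULL) {
  if (any(!vapply(ys, function(y) all(is.finite(Mod(y))), logical(1)))) {
    stop("non-finite values in the shot data", call. = FALSE)
  }
  d <- dim(ys[[1]])
  shape <- d[1:2]
  if (lambda1 > 0 && is.null(normal_maps)) {
    if (is.null(kernel)) stop("lambda1 > 0 requires a SPIRiT kernel", call. = FALSE)
    normal_maps <- spirit_normal_maps(kernel, shape)
  }
  if (lambda2 > 0 && is.null(z_prev)) stop("lambda2 > 0 requires z_prev", call. = FALSE)

  nop <- function(x) {
    img <- ifft2c(x)
    acc <- array(0i, d)
    for (i in seq_along(ys)) {
      t <- fft2c(mul_phase(img, phases$P[[i]]))
      t <- ifft2c(mask_data(t, masks[[i]]))
      acc <- acc + mul_phase(t, Conj(phases$P[[i]]))
    }
    out <- fft2c(acc)
    if (lambda1 > 0) out <- out + lambda1 * apply_pixelwise(normal_maps, x)
    if (lambda2 > 0) out <- out + lambda2 * x
    out
  }
  rhs <- adjoint_shots(ys, masks, phases)
  if (lambda2 > 0) rhs <- rhs + lambda2 * fft2c(z_prev)

  x <- if (is.null(x0)) array(0i, d) else x0
  r <- rhs - nop(x)
  p <- r
  rs <- Re(sum(Conj(r) * r))
  rhs_n <- sqrt(Re(sum(Conj(rhs) * rhs)))
  if (rhs_n == 0) return(list(x = array(0i, d), iters = 0L, resid = numeric(0), diverged = FALSE))
  resid <- numeric(0)
  diverged <- FALSE
  for (it in seq_len(cg_max_iter)) {
    Ap <- nop(p)
    alpha <- rs / Re(sum(Conj(p) * Ap))
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- Re(sum(Conj(r) * r))
    rel <- sqrt(rs_new) / rhs_n
    if (length(resid) > 0 && rel > 10 * min(resid)) diverged <- TRUE
    resid <- c(resid, rel)
    if (rel < cg_tol) break
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  if (diverged) warning("CG residual increased substantially; check conditioning")
  list(x = x, iters = length(resid), resid = resid, diverged = diverged)
}

#' Combine multi-coil images
#'
#' @param img `ny x nx x ncoil` complex array.
#' @param sens sensitivity array for `mode = "sense"`.
#' @param mode `"sos"` (root sum of squares, magnitude) or `"sense"`
#'   (`sum Conj(s) img / sum |s|^2`, complex).
#' @return a matrix (real for `"sos"`, complex for `"sense"`).
#' @export
combine_coils <- function(img, sens = NULL, mode = c("sos", "sense")) {
  mode <- match.arg(mode)
  if (mode == "sos") return(sqrt(apply(Mod(img)^2, c(1, 2), sum)))
  if (is.null(sens)) stop("sense combination requires sensitivity maps", call. = FALSE)
  den <- apply(Mod(sens)^2, c(1, 2), sum)
  if (max(den) == 0) stop("all-zero sensitivities", call. = FALSE)
  num <- matrix(0i, dim(img)[1], dim(img)[2])
  for (c in seq_len(dim(img)[3])) num <- num + Conj(sens[, , c]) * img[, , c]
  num / pmax(den, 1e-12 * max(den))
}

expand_coils <- function(z, sens) {
  out <- array(0i, dim(sens))
  for (c in seq_len(dim(sens)[3])) out[, , c] <- z * sens[, , c]
  out
}

#' Standard SPIRiT reconstruction with shot-phase correction
#'
#' Solves the multi-shot data-consistency problem with the SPIRiT
#' self-consistency penalty only (`lambda2 = 0`); equivalent to the first
#' outer iteration of [dnspirit_recon()].
#'
#' @param shotset a `kspace_shotset`.
#' @param kernel SPIRiT kernel; calibrated from the set's calibration data
#'   when `NULL`.
#' @param phases `phase_maps`; estimated from the navigators when `NULL`.
#' @param sens sensitivities for the combined output; estimated from the
#'   calibration data when `NULL`.
#' @param lambda1 SPIRiT weight.
#' @param combine `"sense"` or `"sos"` output combination.
#' @param cg_tol,cg_max_iter CG controls.
#' @return an object of class `recon_result`: list with `x` (multi-coil
#'   k-space), `image` (combined), `multicoil` (image domain), `diagnostics`.
#' @export
spirit_recon <- function(shotset, kernel = NULL, phases = NULL, sens = NULL,
                         lambda1 = 10, combine = c("sense", "sos"),
                         cg_tol = 1e-6, cg_max_iter = 100) {
  combine <- match.arg(combine)
  ctx <- recon_context(shotset, kernel, phases, sens)
  sol <- cg_solve_normal(shotset$shots, shotset$masks, ctx$phases, ctx$kernel,
                         lambda1 = lambda1, cg_tol = cg_tol,
                         cg_max_iter = cg_max_iter,
                         normal_maps = ctx$normal_maps)
  mc <- ifft2c(sol$x)
  img <- combine_coils(mc, ctx$sens, mode = combine)
  structure(list(x = sol$x, image = img, multicoil = mc,
                 diagnostics = list(cg_iters = sol$iters, resid = sol$resid,
                                    objective = recon_objective(sol$x, shotset, ctx, lambda1, 0, NULL))),
            class = "recon_result")
}

recon_context <- function(shotset, kernel, phases, sens) {
  stopifnot(inherits(shotset, "kspace_shotset"))
  if (is.null(kernel)) kernel <- calibrate_spirit_kernel(shotset$calibration)
  if (is.null(phases)) phases <- estimate_phase_maps(shotset$navigators,
                                                    window_size = shotset$nav_size)
  if (is.null(sens)) sens <- estimate_sensitivities(shotset$calibration, shotset$shape)$sens
  list(kernel = kernel, phases = phases, sens = sens,
       normal_maps = spirit_normal_maps(kernel, shotset$shape))
}

recon_objective <- function(x, shotset, ctx, lambda1, lambda2, z_mc) {
  pred <- forward_shots(x, shotset$masks, ctx$phases)
  data_term <- sum(vapply(seq_along(pred), function(i) {
    sum(Mod(pred[[i]] - shotset$shots[[i]])^2)
  }, numeric(1)))
  sp <- if (lambda1 > 0) {
    gx <- apply_spirit(ctx$kernel, x) - x
    lambda1 * sum(Mod(gx)^2)
  } else 0
  pr <- if (lambda2 > 0 && !is.null(z_mc)) lambda2 * sum(Mod(ifft2c(x) - z_mc)^2) else 0
  data_term + sp + pr
}

#' Reconstruction configuration for DnSPIRiT
#'
#' @param lambda1 SPIRiT self-consistency weight.
#' @param lambda2 denoiser-prior weight.
#' @param n_outer number of outer (plug-and-play) iterations; the first is a
#'   plain SPIRiT solve.
#' @param cg_tol,cg_max_iter inner CG controls.
#' @param denoiser denoiser id (see [apply_denoiser()]).
#' @param denoiser_opts options forwarded to the denoiser.
#' @param mode denoiser recombination: `"complex_sense"` (sensitivity-combine
#'   the complex image, denoise, re-multiply by the sensitivities) or
#'   `"magnitude_sos"` (denoise the root-sum-of-squares magnitude, multiply
#'   by the sensitivities).
#' @param sigma_hint optional noise level forwarded to the denoiser.
#' @return a `recon_config` list.
#' @export
recon_config <- function(lambda1 = 10, lambda2 = 2, n_outer = 5,
                         cg_tol = 1e-6, cg_max_iter = 100,
                         denoiser = "llr", denoiser_opts = list(),
                         mode = c("complex_sense", "magnitude_sos"),
                         sigma_hint = NULL) {
  mode <- match.arg(mode)
  if (lambda1 < 0 || lambda2 < 0) stop("lambda weights must be non-negative", call. = FALSE)
  if (n_outer < 1) stop("n_outer must be at least 1", call. = FALSE)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, n_outer = n_outer,
                 cg_tol = cg_tol, cg_max_iter = cg_max_iter,
                 denoiser = denoiser, denoiser_opts = denoiser_opts,
                 mode = mode, sigma_hint = sigma_hint),
            class = "recon_config")
}

#' Denoiser-regularized SPIRiT reconstruction (DnSPIRiT)
#'
#' Plug-and-play outer loop: the first iteration is a standard phase-corrected
#' SPIRiT solve; each subsequent iteration denoises the coil-combined image,
#' re-expands it through the coil sensitivities, and re-solves the normal
#' equations with the denoised image as a quadratic prior
#' (`lambda2 ||F^-1 x - z||^2`), warm-starting CG from the previous iterate.
#'
#' @inheritParams spirit_recon
#' @param config a [recon_config()].
#' @return a `recon_result` with the final combined image (complex for
#'   `"complex_sense"`, real magnitude for `"magnitude_sos"`) and an
#'   objective trace over outer iterations in `diagnostics`.
#' @export
dnspirit_recon <- function(shotset, config = recon_config(), kernel = NULL,
                           phases = NULL, sens = NULL) {
  stopifnot(inherits(config, "recon_config"))
  ctx <- recon_context(shotset, kernel, phases, sens)
  objective <- numeric(0)
  cg_iters <- integer(0)
  sol <- cg_solve_normal(shotset$shots, shotset$masks, ctx$phases, ctx$kernel,
                         lambda1 = config$lambda1, cg_tol = config$cg_tol,
                         cg_max_iter = config$cg_max_iter,
                         normal_maps = ctx$normal_maps)
  x <- sol$x
  cg_iters <- c(cg_iters, sol$iters)
  objective <- c(objective, recon_objective(x, shotset, ctx, config$lambda1, 0, NULL))
  z_mc <- NULL
  if (config$n_outer > 1) {
    for (k in 2:config$n_outer) {
      mc <- ifft2c(x)
      if (config$mode == "complex_sense") {
        combined <- combine_coils(mc, ctx$sens, mode = "sense")
      } else {
        combined <- combine_coils(mc, mode = "sos")
      }
      z <- apply_denoiser(config$denoiser, combined,
                          sigma_hint = config$sigma_hint,
                          opts = config$denoiser_opts)
      z_mc <- expand_coils(z, ctx$sens)
      sol <- cg_solve_normal(shotset$shots, shotset$masks, ctx$phases, ctx$kernel,
                             lambda1 = config$lambda1, lambda2 = config$lambda2,
                             z_prev = z_mc, cg_tol = config$cg_tol,
                             cg_max_iter = config$cg_max_iter, x0 = x,
                             normal_maps = ctx$normal_maps)
      x <- sol$x
      cg_iters <- c(cg_iters, sol$iters)
      objective <- c(objective,
                     recon_objective(x, shotset, ctx, config$lambda1,
                                     config$lambda2, z_mc))
    }
  }
  mc <- ifft2c(x)
  img <- if (config$mode == "complex_sense") {
    combine_coils(mc, ctx$sens, mode = "sense")
  } else {
    combine_coils(mc, mode = "sos")
  }
  structure(list(x = x, image = img, multicoil = mc,
                 diagnostics = list(objective = objective, cg_iters = cg_iters),
                 config = config),
            class = "recon_result")
}

#' Fill the unsampled partial-Fourier band
#'
#' @param kspace `ny x nx` or `ny x nx x ncoil` complex array with the early
#'   ky band unsampled (zero).
#' @param pf partial-Fourier fraction in `(0.5, 1]`.
#' @param mode `"zp"` leaves the band zero; `"cs"` fills it with the
#'   conjugate-symmetric copy after removing the zeroth-order (DC) phase.
#' @return array of the same shape.
#' @export
partial_fourier_fill <- function(kspace, pf, mode = c("zp", "cs")) {
  mode <- match.arg(mode)
  if (pf <= 0.5 || pf > 1) stop("pf must lie in (0.5, 1]", call. = FALSE)
  if (pf == 1 || mode == "zp") return(kspace)
  d <- dim(kspace)
  nc <- if (length(d) == 3L) d[3] else 1L
  ny <- d[1]; nx <- d[2]
  n0 <- as.integer(ceiling((1 - pf) * ny))
  if (n0 == 0L) return(kspace)
  part_row <- ((ny - (seq_len(ny) - 1L)) %% ny) + 1L
  part_col <- ((nx - (seq_len(nx) - 1L)) %% nx) + 1L
  fill_one <- function(k) {
    phi0 <- Arg(k[ny %/% 2 + 1, nx %/% 2 + 1])
    k0 <- k * exp(-1i * phi0)
    filled <- Conj(k0[part_row, part_col])
    k0[seq_len(n0), ] <- filled[seq_len(n0), ]
    k0 * exp(1i * phi0)
  }
  if (length(d) == 2L) return(fill_one(kspace))
  for (c in seq_len(nc)) kspace[, , c] <- fill_one(kspace[, , c])
  kspace
}

#' Retrospective shot under-sampling
#'
#' Keeps `n_keep` evenly spaced shots of a fully sampled shot set, emulating
#' a prospectively accelerated acquisition with
#' `R_eff = n_seg / n_keep`.
#'
#' @param shotset a `kspace_shotset`.
#' @param n_keep number of shots to keep; must divide the number of shots.
#' @return the under-sampled `kspace_shotset` (updated `scheme$r_eff`).
#' @examples
#' # keeping 3 of 6 segments gives R_eff = 2; keeping 2 gives R_eff = 3
#' @export
retrospective_undersample <- function(shotset, n_keep) {
  stopifnot(inherits(shotset, "kspace_shotset"))
  n <- length(shotset$shots)
  if (n_keep < 1 || n %% n_keep != 0) {
    stop("n_keep must evenly divide the number of shots", call. = FALSE)
  }
  idx <- seq(1L, n, by = n %/% n_keep)
  shotset$shots <- shotset$shots[idx]
  shotset$masks <- shotset$masks[idx]
  shotset$navigators <- shotset$navigators[idx]
  shotset$truth$phases <- shotset$truth$phases[idx]
  sc <- shotset$scheme
  sc$segments <- sc$segments[idx]
  sc$lines <- sc$lines[idx]
  sc$times <- sc$times[idx]
  sc$n_acq <- as.integer(n_keep)
  sc$r_eff <- sc$n_seg / n_keep
  shotset$scheme <- sc
  shotset
}
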