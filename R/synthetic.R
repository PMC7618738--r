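#' Brain-like digital diffusion phantom
#'
#' Builds a 2D piecewise-smooth phantom (nested ellipses with gyral-like
#' ribbon structures) with a complex baseline (b = 0) image and a symmetric
#' positive-definite diffusion tensor per voxel. Diffusion-weighted contrast
#' follows the tensor model `S_g = baseline * exp(-b g' D g)`. White-matter
#' structures receive the anisotropy levels in `fa_levels` with in-plane
#' principal directions following the local ribbon orientation; gray matter
#' and CSF are nearly isotropic.
#'
#' @param shape image size, `c(ny, nx)` (a single value is recycled); each
#'   axis must be at least 32.
#' @param n_directions number of diffusion-encoding directions (0 for a
#'   b = 0-only phantom; 6 gives a classic icosahedral DTI scheme).
#' @param b_value diffusion weighting (s/mm^2).
#' @param fa_levels fractional anisotropy of the white-matter structures
#'   (recycled over structures).
#' @param seed RNG seed; the phantom is bit-reproducible given
#'   `(parameters, seed)`.
#' @param directions optional `n_directions x 3` matrix of unit vectors
#'   overriding the built-in scheme.
#' @return an object of class `digital_phantom` with fields `baseline`
#'   (complex matrix), `tensors` (`ny x nx x 6` array, order
#'   Dxx, Dyy, Dzz, Dxy, Dxz, Dyz, in mm^2/s), `directions`, `b_value`,
#'   `mask` (brain), `wm_mask`, `fa` (ground-truth FA map) and `seed`.
#' @export
make_phantom <- function(shape = c(128, 128), n_directions = 6, b_value = 1000,
                         fa_levels = c(0.8, 0.55, 0.3), seed = 1,
                         directions = NULL) {
  if (length(shape) == 1L) shape <- rep(shape, 2L)
  if (any(shape < 32)) stop("phantom shape must be at least 32 per axis", call. = FALSE)
  if (n_directions < 0) stop("n_directions must be non-negative", call. = FALSE)
  ny <- shape[1]; nx <- shape[2]
  if (is.null(directions)) {
    directions <- dti_directions(n_directions, seed)
  } else {
    directions <- as.matrix(directions)
    if (ncol(directions) != 3L || nrow(directions) != n_directions) {
      stop("directions must be an n_directions x 3 matrix", call. = FALSE)
    }
    if (any(abs(sqrt(rowSums(directions^2)) - 1) > 1e-8)) {
      stop("diffusion directions must be unit vectors", call. = FALSE)
    }
  }

  y <- (seq_len(ny) - ny / 2 - 0.5) / (ny / 2)
  x <- (seq_len(nx) - nx / 2 - 0.5) / (nx / 2)
  Y <- matrix(y, ny, nx); X <- matrix(x, ny, nx, byrow = TRUE)
  r2 <- (X / 0.84)^2 + (Y / 0.92)^2
  mask <- r2 <= 1
  csf <- r2 <= 0.12^2 | ((X / 0.84)^2 + (Y / 0.92)^2 >= 0.88^2 & mask)
  theta <- atan2(Y, X)
  # annular white-matter ribbon plus gyral-like radial ribbons
  rr <- sqrt(r2)
  wm_ring <- mask & rr > 0.38 & rr < 0.62
  ribbons <- mask & !csf & rr >= 0.62 & rr < 0.84 &
    (sin(5 * theta + 2.2 * rr)^2 > 0.55)
  deep <- mask & !csf & rr <= 0.30 & abs(Y) < 0.18
  wm <- (wm_ring | ribbons | deep) & !csf
  gm <- mask & !wm & !csf

  fa_levels <- rep_len(fa_levels, 3L)
  structures <- list(wm_ring, ribbons, deep)

  baseline_mag <- 0.1 + 0.55 * gm + 0.45 * wm + 1.0 * csf
  baseline_mag[!mask] <- 0
  phase <- 0.6 * X + 0.4 * Y + 0.5 * X * Y
  baseline <- baseline_mag * exp(1i * phase)

  # tensor field: axially symmetric tensors from (FA, MD)
  md <- matrix(0.75e-3, ny, nx)
  md[gm] <- 0.85e-3
  md[csf] <- 2.8e-3
  md[!mask] <- 0.3e-3
  fa_map <- matrix(0.05, ny, nx)
  for (k in seq_along(structures)) fa_map[structures[[k]]] <- fa_levels[k]
  fa_map[csf] <- 0.02
  fa_map[!mask] <- 0
  # principal in-plane orientation: tangential in the ring, radial in ribbons
  ang <- theta + pi / 2
  ang[ribbons] <- theta[ribbons]
  ang[deep] <- 0

  tensors <- tensors_from_fa_md(fa_map, md, ang)

  structure(list(baseline = baseline, tensors = tensors,
                 directions = directions, b_value = b_value,
                 mask = mask, wm_mask = wm, fa = fa_map, md = md,
                 shape = shape, seed = seed),
            class = "digital_phantom")
}

# axially symmetric eigenvalues matching (FA, MD):
# lambda1 = MD(1+2f), lambda2 = lambda3 = MD(1-f), f = FA / sqrt(3 - 2 FA^2)
tensors_from_fa_md <- function(fa, md, angle) {
  f <- fa / sqrt(3 - 2 * fa^2)
  l1 <- md * (1 + 2 * f)
  l2 <- md * (1 - f)
  c2 <- cos(angle)^2; s2 <- sin(angle)^2; cs <- cos(angle) * sin(angle)
  d <- array(0, c(dim(fa), 6L))
  d[, , 1] <- l1 * c2 + l2 * s2          # Dxx
  d[, , 2] <- l1 * s2 + l2 * c2          # Dyy
  d[, , 3] <- l2                         # Dzz
  d[, , 4] <- (l1 - l2) * cs             # Dxy
  d
}

dti_directions <- function(n, seed) {
  if (n == 0L) return(matrix(numeric(0), 0, 3))
  if (n == 6L) {
    g <- rbind(c(1, 1, 0), c(1, -1, 0), c(1, 0, 1),
               c(1, 0, -1), c(0, 1, 1), c(0, 1, -1))
    return(g / sqrt(2))
  }
  withr::with_seed(seed, {
    g <- matrix(stats::rnorm(3 * n), n, 3)
    g / sqrt(rowSums(g^2))
  })
}

#' Diffusion-weighted volumes of a phantom
#'
#' @param phantom a [make_phantom()] result.
#' @param direction direction index (`0` or `"b0"` for the baseline).
#' @return complex matrix; for `b = 0` exactly the baseline.
#' @export
phantom_dwi <- function(phantom, direction = 0) {
  stopifnot(inherits(phantom, "digital_phantom"))
  if (identical(direction, "b0") || identical(direction, 0) || identical(direction, 0L)) {
    return(phantom$baseline)
  }
  g <- phantom$directions[direction, ]
  q <- c(g[1]^2, g[2]^2, g[3]^2, 2 * g[1] * g[2], 2 * g[1] * g[3], 2 * g[2] * g[3])
  att <- exp(-phantom$b_value *
               (phantom$tensors[, , 1] * q[1] + phantom$tensors[, , 2] * q[2] +
                phantom$tensors[, , 3] * q[3] + phantom$tensors[, , 4] * q[4] +
                phantom$tensors[, , 5] * q[5] + phantom$tensors[, , 6] * q[6]))
  phantom$baseline * att
}

#' Smooth complex coil sensitivity maps
#'
#' Coils are Gaussian lobes placed on a ring around the FOV with a smooth
#' linear phase per coil; maps are normalized so the root sum of squares over
#' coils is exactly 1 everywhere. A single coil gives a constant
#' unit-magnitude map.
#'
#' @param shape image size `c(ny, nx)` (single value recycled).
#' @param n_coils number of receive coils.
#' @param smoothness lobe width relative to the image extent (larger is
#'   smoother).
#' @param seed RNG seed (jitters lobe placement).
#' @return an object of class `coil_model`: list with `sens`
#'   (`ny x nx x n_coils` complex) and `n_coils`.
#' @export
make_sensitivities <- function(shape = c(128, 128), n_coils = 8,
                               smoothness = 0.8, seed = 1) {
  if (length(shape) == 1L) shape <- rep(shape, 2L)
  if (n_coils < 1) stop("n_coils must be at least 1", call. = FALSE)
  ny <- shape[1]; nx <- shape[2]
  if (n_coils == 1L) {
    sens <- array(1 + 0i, c(ny, nx, 1L))
    return(structure(list(sens = sens, n_coils = 1L), class = "coil_model"))
  }
  y <- (seq_len(ny) - ny / 2 - 0.5) / (ny / 2)
  x <- (seq_len(nx) - nx / 2 - 0.5) / (nx / 2)
  Y <- matrix(y, ny, nx); X <- matrix(x, ny, nx, byrow = TRUE)
  sens <- array(0i, c(ny, nx, n_coils))
  withr::with_seed(seed, {
    jitter <- stats::runif(n_coils, -0.15, 0.15)
    for (c in seq_len(n_coils)) {
      a <- 2 * pi * (c - 1) / n_coils + jitter[c]
      cy <- 1.25 * sin(a); cx <- 1.25 * cos(a)
      mag <- exp(-((X - cx)^2 + (Y - cy)^2) / (2 * smoothness^2))
      ph <- 0.9 * (cos(a) * X + sin(a) * Y) + 0.25 * a
      sens[, , c] <- mag * exp(1i * ph)
    }
  })
  rss <- sqrt(apply(Mod(sens)^2, c(1, 2), sum))
  for (c in seq_len(n_coils)) sens[, , c] <- sens[, , c] / rss
  structure(list(sens = sens, n_coils = as.integer(n_coils)), class = "coil_model")
}

#' Per-shot smooth motion-induced phase maps
#'
#' Generates spatially smooth (band-limited) random phase fields, one per
#' shot, scaled so that `max |phase| = amplitude`. Shot 1 is the zero-phase
#' reference: only relative shot phases matter in the forward model.
#'
#' @param shape image size `c(ny, nx)`.
#' @param n_shots number of shots.
#' @param amplitude maximum absolute phase (rad).
#' @param seed RNG seed.
#' @param bandwidth side length of the central k-space support of the random
#'   field (must stay well inside the navigator window).
#' @return an object of class `shot_phase_model`: list with `phases` (list of
#'   real matrices, rad), `amplitude`, `bandwidth`, `seed`.
#' @export
make_shot_phases <- function(shape = c(128, 128), n_shots = 6, amplitude = pi / 2,
                             seed = 1, bandwidth = 6) {
  if (length(shape) == 1L) shape <- rep(shape, 2L)
  if (amplitude < 0) stop("amplitude must be non-negative", call. = FALSE)
  ny <- shape[1]; nx <- shape[2]
  phases <- vector("list", n_shots)
  phases[[1]] <- matrix(0, ny, nx)
  withr::with_seed(seed, {
    for (i in seq_len(n_shots)[-1]) {
      if (amplitude == 0) { phases[[i]] <- matrix(0, ny, nx); next }
      k <- matrix(0i, ny, nx)
      rows <- ny %/% 2 + 1 + seq(-bandwidth %/% 2, bandwidth %/% 2 - 1)
      cols <- nx %/% 2 + 1 + seq(-bandwidth %/% 2, bandwidth %/% 2 - 1)
      k[rows, cols] <- cgnoise(bandwidth^2, 1)
      f <- Re(ifft2c(k))
      phases[[i]] <- amplitude * f / max(abs(f))
    }
  })
  structure(list(phases = phases, amplitude = amplitude,
                 bandwidth = bandwidth, n_shots = as.integer(n_shots),
                 shape = shape, seed = seed),
            class = "shot_phase_model")
}

#' Interleaved ky sampling scheme
#'
#' Segment `s` (0-based) acquires ky lines `{s, s + n_seg, s + 2 n_seg, ...}`
#' intersected with the partial-Fourier window. When `n_acq < n_seg` the
#' acquired segments are evenly spaced (`n_acq` must divide `n_seg`). Per-line
#' acquisition time stamps reflect the intra-shot ordering.
#'
#' @param n_pe number of ky lines.
#' @param n_seg number of designed segments.
#' @param n_acq number of acquired segments.
#' @param pf partial-Fourier fraction in `(0.5, 1]`.
#' @param ordering `"ky-kz"` or `"kz-ky"` sampling-order tag.
#' @param es echo spacing (ms) used for the time stamps.
#' @return an object of class `sampling_scheme`: list with `segments`
#'   (0-based acquired segment indices), `lines` (list of 1-based acquired ky
#'   row indices per shot), `times` (list of per-line acquisition times, ms),
#'   `n_pe`, `n_seg`, `n_acq`, `pf`, `ordering`, `r_eff`.
#' @examples
#' make_sampling_scheme(24, 6, 3)$segments  # 0 2 4
#' @export
make_sampling_scheme <- function(n_pe, n_seg, n_acq = n_seg, pf = 1,
                                 ordering = c("ky-kz", "kz-ky"), es = 1) {
  ordering <- match.arg(ordering)
  if (n_acq > n_seg || n_acq < 1) stop("need 1 <= n_acq <= n_seg", call. = FALSE)
  if (n_acq < n_seg && n_seg %% n_acq != 0) {
    stop("n_acq must divide n_seg for evenly spaced segments", call. = FALSE)
  }
  if (pf <= 0.5 || pf > 1) stop("pf must lie in (0.5, 1]", call. = FALSE)
  segments <- as.integer(seq(0L, n_seg - 1L, by = n_seg %/% n_acq))
  n0 <- as.integer(ceiling((1 - pf) * n_pe))
  lines <- lapply(segments, function(s) {
    l <- seq(s, n_pe - 1L, by = n_seg)
    l <- l[l >= n0]
    as.integer(l + 1L)                      # 1-based rows
  })
  times <- lapply(lines, function(l) (seq_along(l) - 1) * es)
  structure(list(segments = segments, lines = lines, times = times,
                 n_pe = as.integer(n_pe), n_seg = as.integer(n_seg),
                 n_acq = as.integer(n_acq), pf = pf, ordering = ordering,
                 es = es, r_eff = n_seg / n_acq),
            class = "sampling_scheme")
}

#' Encode a multi-shot, multi-coil acquisition
#'
#' Forward model `y_i = D_i F (exp(i phi_i) * sens * image) + noise`: each
#' shot sees the image through its motion-induced phase, the coil
#' sensitivities, the centered unitary Fourier transform and its ky sampling
#' mask. Complex Gaussian noise of standard deviation `noise_sigma` is added
#' to the acquired samples only; unacquired entries are exactly zero. Each
#' shot also produces a fully sampled low-resolution navigator (central
#' `nav_size` k-space window, same phase, with noise), and the set carries a
#' noise-free low-resolution calibration scan of the phase-free
#' sensitivity-weighted image.
#'
#' @param image complex matrix to encode, or a [make_phantom()] object
#'   (combined with `direction`).
#' @param coils a [make_sensitivities()] result.
#' @param phases a [make_shot_phases()] result (one phase map per shot).
#' @param scheme a [make_sampling_scheme()] result.
#' @param noise_sigma complex noise standard deviation per k-space sample.
#' @param seed RNG seed for the noise.
#' @param direction forwarded to [phantom_dwi()] when `image` is a phantom.
#' @param nav_size side of the fully sampled navigator window.
#' @param calib_size side of the calibration window.
#' @param calib_image image used for the calibration scan; defaults to the
#'   phantom baseline (or `image` itself).
#' @return an object of class `kspace_shotset`: list with `shots` (list of
#'   `ny x nx x ncoil` complex arrays), `masks` (list of logical matrices),
#'   `navigators` (list of full-grid arrays, zero outside the window),
#'   `calibration` (`calib_size x calib_size x ncoil`), `scheme`, `shape`,
#'   `n_coils`, `noise_sigma`, `seed` and ground `truth` (image, sens,
#'   phases).
#' @export
encode_acquisition <- function(image, coils, phases, scheme, noise_sigma = 0,
                               seed = 1, direction = 0, nav_size = 32,
                               calib_size = 32, calib_image = NULL) {
  stopifnot(inherits(coils, "coil_model"), inherits(phases, "shot_phase_model"),
            inherits(scheme, "sampling_scheme"))
  if (inherits(image, "digital_phantom")) {
    if (is.null(calib_image)) calib_image <- image$baseline
    image <- phantom_dwi(image, direction)
  }
  if (is.null(calib_image)) calib_image <- image
  ny <- nrow(image); nx <- ncol(image)
  nc <- coils$n_coils
  if (!all(dim(coils$sens)[1:2] == c(ny, nx)) ||
      !all(dim(phases$phases[[1]]) == c(ny, nx)) ||
      scheme$n_pe != ny) {
    stop("image, coils, phases and scheme shapes are inconsistent", call. = FALSE)
  }
  n_shots <- length(scheme$lines)
  if (phases$n_shots < n_shots) stop("fewer phase maps than shots", call. = FALSE)
  nav_rows <- ny %/% 2 + 1 + seq(-nav_size %/% 2, nav_size %/% 2 - 1)
  nav_cols <- nx %/% 2 + 1 + seq(-nav_size %/% 2, nav_size %/% 2 - 1)
  shots <- masks <- navigators <- vector("list", n_shots)
  withr::with_seed(seed, {
    for (i in seq_len(n_shots)) {
      obj <- image * exp(1i * phases$phases[[i]])
      imc <- array(0i, c(ny, nx, nc))
      for (c in seq_len(nc)) imc[, , c] <- obj * coils$sens[, , c]
      k <- fft2c(imc)
      mask <- matrix(FALSE, ny, nx)
      mask[scheme$lines[[i]], ] <- TRUE
      y <- array(0i, c(ny, nx, nc))
      for (c in seq_len(nc)) {
        kc <- k[, , c]
        if (noise_sigma > 0) kc[mask] <- kc[mask] + cgnoise(sum(mask), noise_sigma)
        kc[!mask] <- 0i
        y[, , c] <- kc
      }
      nav <- array(0i, c(ny, nx, nc))
      nav[nav_rows, nav_cols, ] <- k[nav_rows, nav_cols, ] +
        if (noise_sigma > 0) cgnoise(nav_size^2 * nc, noise_sigma) else 0i
      shots[[i]] <- y; masks[[i]] <- mask; navigators[[i]] <- nav
    }
  })
  cal_rows <- ny %/% 2 + 1 + seq(-calib_size %/% 2, calib_size %/% 2 - 1)
  cal_cols <- nx %/% 2 + 1 + seq(-calib_size %/% 2, calib_size %/% 2 - 1)
  cal_src <- array(0i, c(ny, nx, nc))
  for (c in seq_len(nc)) cal_src[, , c] <- calib_image * coils$sens[, , c]
  kcal <- fft2c(cal_src)
  calibration <- kcal[cal_rows, cal_cols, , drop = FALSE]
  structure(list(shots = shots, masks = masks, navigators = navigators,
                 calibration = calibration, scheme = scheme,
                 shape = c(ny, nx), n_coils = nc, nav_size = nav_size,
                 noise_sigma = noise_sigma, seed = seed,
                 truth = list(image = image, sens = coils$sens,
                              phases = phases$phases[seq_len(n_shots)])),
            class = "kspace_shotset")
}
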