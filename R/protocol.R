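#' @keywords internal
"_PACKAGE"

# gyromagnetic ratio of 1H
GAMMA_HZ_PER_T <- 42.5774e6            # Hz/T
GAMMA_RAD_PER_S_T <- 2 * pi * GAMMA_HZ_PER_T

#' Scanner hardware description
#'
#' Bundles the hardware parameters entering the EPI timing model.
#'
#' @param B0 main field strength (T).
#' @param Gmax maximum gradient amplitude (mT/m), used for diffusion encoding.
#' @param slew gradient slew rate (T/m/s), used for the readout ramps.
#' @param t_exc excitation RF duration (ms).
#' @param t_ref refocusing RF duration (ms).
#' @return an object of class `hardware_spec`.
#' @examples
#' hw <- hardware_spec(B0 = 3)
#' @export
hardware_spec <- function(B0 = 3, Gmax = 80, slew = 200, t_exc = 6, t_ref = 10) {
  vals <- c(B0 = B0, Gmax = Gmax, slew = slew, t_exc = t_exc, t_ref = t_ref)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all hardware parameters must be finite and strictly positive", call. = FALSE)
  }
  structure(as.list(vals), class = "hardware_spec")
}

#' Tissue relaxation parameters
#'
#' `T2prime` is derived from `1/T2' = 1/T2* - 1/T2` and never stored
#' independently. [tissue_white_matter()] returns the white-matter values used
#' throughout the simulator: T1/T2/T2* = 832/79.6/53.2 ms at 3T and
#' 1220/47/26.8 ms at 7T.
#'
#' @param T1,T2,T2star relaxation times (ms); must satisfy
#'   `0 < T2* <= T2 <= T1`.
#' @return an object of class `tissue_relaxation` with elements `T1`, `T2`,
#'   `T2star` and derived `T2prime` (ms; `Inf` when `T2star == T2`).
#' @export
tissue_relaxation <- function(T1, T2, T2star) {
  if (!(T2star > 0 && T2star <= T2 && T2 <= T1)) {
    stop("relaxation times must satisfy 0 < T2* <= T2 <= T1", call. = FALSE)
  }
  inv <- 1 / T2star - 1 / T2
  structure(list(T1 = T1, T2 = T2, T2star = T2star,
                 T2prime = if (inv > 0) 1 / inv else Inf),
            class = "tissue_relaxation")
}

#' @param field `"3T"` or `"7T"`.
#' @rdname tissue_relaxation
#' @export
tissue_white_matter <- function(field = c("3T", "7T")) {
  field <- match.arg(field)
  if (field == "3T") tissue_relaxation(832, 79.6, 53.2)
  else tissue_relaxation(1220, 47, 26.8)
}

#' Acquisition protocol for segmented 3D diffusion EPI
#'
#' @param fov field of view `c(x, y, z)` in mm (a single value is recycled).
#' @param res nominal isotropic resolution (mm).
#' @param n_seg number of in-plane ky segments (interleaved shots).
#' @param n_acq number of acquired segments (`n_acq <= n_seg`); the effective
#'   acceleration is `R_eff = n_seg / n_acq`.
#' @param pf partial-Fourier fraction in `(0.5, 1]`.
#' @param pf_mode `"none"`, `"zp"` (zero padding) or `"cs"` (conjugate
#'   symmetric filling) for the unsampled ky band.
#' @param bw_pixel receiver bandwidth per pixel (Hz/pixel).
#' @param tr repetition time (ms).
#' @param b_value diffusion weighting (s/mm^2).
#' @return an object of class `sequence_protocol`.
#' @examples
#' p <- sequence_protocol(res = 0.65, n_seg = 6, bw_pixel = 992)
#' @export
sequence_protocol <- function(fov = c(220, 220, 120), res = 0.65, n_seg = 6,
                              n_acq = n_seg, pf = 1,
                              pf_mode = c("none", "zp", "cs"),
                              bw_pixel = 992, tr = 2500, b_value = 1000) {
  pf_mode <- match.arg(pf_mode)
  if (length(fov) == 1L) fov <- rep(fov, 3L)
  if (any(fov <= 0) || !is.finite(res) || res <= 0) {
    stop("fov and res must be strictly positive", call. = FALSE)
  }
  if (n_seg < 1 || n_acq < 1 || n_acq > n_seg) {
    stop("need 1 <= n_acq <= n_seg", call. = FALSE)
  }
  if (pf <= 0.5 || pf > 1) stop("pf must lie in (0.5, 1]", call. = FALSE)
  if (bw_pixel <= 0 || tr <= 0 || b_value < 0) {
    stop("bw_pixel and tr must be positive, b_value non-negative", call. = FALSE)
  }
  structure(list(fov = fov, res = res, n_seg = as.integer(n_seg),
                 n_acq = as.integer(n_acq), pf = pf, pf_mode = pf_mode,
                 bw_pixel = bw_pixel, tr = tr, b_value = b_value,
                 r_eff = n_seg / n_acq),
            class = "sequence_protocol")
}

#' Matrix size from field of view and resolution
#'
#' The phase-encode and readout matrix sizes are the nearest multiple of
#' `n_seg` to `fov/res`, so that every segment acquires the same number of
#' lines; the number of kz partitions is `round(fov_z/res)`.
#'
#' @param protocol a [sequence_protocol()].
#' @return list with integer `n_pe`, `n_x`, `n_par`.
#' @examples
#' derive_matrix(sequence_protocol(res = 0.65, n_seg = 6))$n_pe  # 336
#' @export
derive_matrix <- function(protocol) {
  stopifnot(inherits(protocol, "sequence_protocol"))
  ns <- protocol$n_seg
  near_mult <- function(x) as.integer(max(1, round(x / ns)) * ns)
  list(n_pe = near_mult(protocol$fov[2] / protocol$res),
       n_x = near_mult(protocol$fov[1] / protocol$res),
       n_par = as.integer(round(protocol$fov[3] / protocol$res)))
}

#' Diffusion gradient timing from the Stejskal-Tanner relation
#'
#' Finds the smallest gradient duration `delta` such that a pulsed-gradient
#' spin-echo pair at amplitude `Gmax` reaches the requested b-value,
#' `b = gamma^2 G^2 delta^2 (Delta - delta/3)`, with the lobe separation
#' `Delta = delta + t_ref + 2 * gap` (the refocusing pulse plus a safety gap
#' on each side).
#'
#' @param protocol a [sequence_protocol()].
#' @param hardware a [hardware_spec()].
#' @param gap safety gap between diffusion lobes and RF pulses (ms).
#' @return list with `delta` and `Delta` in ms (both 0 when `b_value = 0`).
#' @export
solve_diffusion_timing <- function(protocol, hardware, gap = 1) {
  stopifnot(inherits(protocol, "sequence_protocol"), inherits(hardware, "hardware_spec"))
  b <- protocol$b_value
  if (b == 0) return(list(delta = 0, Delta = 0))
  G <- hardware$Gmax * 1e-3                      # T/m
  tref <- hardware$t_ref * 1e-3                  # s
  g <- gap * 1e-3
  b_si <- b * 1e6                                # s/m^2
  f <- function(d) GAMMA_RAD_PER_S_T^2 * G^2 * d^2 * (d + tref + 2 * g - d / 3) - b_si
  if (f(1) < 0) stop("requested b-value is not reachable within the TE budget", call. = FALSE)
  d <- stats::uniroot(f, c(1e-9, 1), tol = 1e-15)$root
  list(delta = d * 1e3, Delta = (d + tref + 2 * g) * 1e3)
}

#' EPI timing for a segmented acquisition
#'
#' Derives matrix sizes, echo spacing, echo time and related timing for an
#' in-plane segmented spin-echo EPI readout. The readout gradient is a
#' ramp-sampled trapezoid: the area-equivalent acquisition time per line
#' (flat-top plus one ramp) is `1/bw_pixel`, which fixes the readout gradient
#' amplitude `G_read = bw_pixel / (gamma * res)`; the echo spacing is
#' `1/bw_pixel` plus the remaining ramp `G_read/slew`. The echo time places
#' the spin echo at the k-space center line:
#' `TE = 2 * max(t_exc/2 + delta + t_ref/2, t_ref/2 + delta + t_center)`
#' plus the safety gaps, where `t_center = (pf - 0.5) * n_pe/n_seg * es`.
#'
#' @inheritParams solve_diffusion_timing
#' @param tissue a [tissue_relaxation()] (carried along for downstream use).
#' @param gap safety gap around RF and diffusion lobes (ms).
#' @return an object of class `epi_timing` with fields `n_pe`, `n_par`,
#'   `n_x`, `es`, `es_eff`, `lines_per_shot`, `t_center`, `te`, `delta`,
#'   `Delta`, `readout_dur` (all times in ms).
#' @examples
#' tm <- compute_epi_timing(sequence_protocol(res = 0.65, n_seg = 6),
#'                          hardware_spec(), tissue_white_matter("3T"))
#' tm$te  # close to 102 ms
#' @export
compute_epi_timing <- function(protocol, hardware, tissue, gap = 1) {
  stopifnot(inherits(protocol, "sequence_protocol"), inherits(hardware, "hardware_spec"))
  m <- derive_matrix(protocol)
  dt <- solve_diffusion_timing(protocol, hardware, gap = gap)
  t_acq <- 1e3 / protocol$bw_pixel                         # ms, area-equivalent
  g_read <- protocol$bw_pixel / (GAMMA_HZ_PER_T * protocol$res * 1e-3)  # T/m
  if (g_read > hardware$Gmax * 1e-3) {
    stop("readout gradient exceeds Gmax; lower the bandwidth or resolution", call. = FALSE)
  }
  ramp <- g_read / hardware$slew * 1e3                     # ms
  es <- t_acq + ramp
  lines_per_shot <- as.integer(ceiling(protocol$pf * m$n_pe / protocol$n_seg))
  t_center <- (protocol$pf - 0.5) * m$n_pe / protocol$n_seg * es
  half1 <- hardware$t_exc / 2 + gap + dt$delta + gap + hardware$t_ref / 2
  half2 <- hardware$t_ref / 2 + gap + dt$delta + gap + t_center
  te <- 2 * max(half1, half2)
  if (te > protocol$tr) {
    stop("infeasible protocol: TE exceeds TR", call. = FALSE)
  }
  structure(list(n_pe = m$n_pe, n_par = m$n_par, n_x = m$n_x,
                 es = es, es_eff = es / protocol$n_seg,
                 lines_per_shot = lines_per_shot, t_center = t_center,
                 te = te, delta = dt$delta, Delta = dt$Delta,
                 readout_dur = lines_per_shot * es),
            class = "epi_timing")
}
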