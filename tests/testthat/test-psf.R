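hw3 <- hardware_spec(B0 = 3)
wm3 <- tissue_white_matter("3T")

psf_for <- function(res = 0.6, n_seg = 3, bw = 992, tissue = wm3, pf = 1,
                    pf_mode = "none", hw = hw3) {
  pr <- sequence_protocol(res = res, n_seg = n_seg, bw_pixel = bw, pf = pf,
                          pf_mode = pf_mode)
  tm <- compute_epi_timing(pr, hw, tissue)
  list(psf = simulate_psf(tm, tissue, pr), timing = tm, protocol = pr)
}

test_that("no-decay modulation is flat and gives zero grid-normalized blurring", {
  no_decay <- tissue_relaxation(1e9, 1e8, 1e8 - 1e-6)
  s <- psf_for(tissue = no_decay)
  expect_lt(max(abs(Mod(s$psf$modulation) / Mod(s$psf$modulation[1]) - 1)), 1e-5)
  fm <- measure_fwhm(s$psf)
  expect_lt(abs(fm$blurring_rel), 1e-6)
  expect_lt(abs(fm$eff_res_rel_mm - 0.6), 1e-6)
  # raw FWHM of the sinc-shaped ideal PSF is about 1.21 voxels
  expect_equal(fm$fwhm_voxels, 1.2067, tolerance = 1e-3)
})

test_that("the k-space center line carries the spin-echo weight exp(-TE/T2)", {
  s <- psf_for()
  center <- s$psf$n_pe %/% 2 + 1
  expect_equal(Mod(s$psf$modulation[center]), exp(-s$timing$te / wm3$T2),
               tolerance = 1e-12)
})

test_that("Gaussian modulation reproduces the closed-form Fourier width", {
  n <- 256
  sgm <- 20                                  # lines
  l <- 0:(n - 1)
  m <- exp(-(l - n / 2)^2 / (2 * sgm^2))
  psf <- structure(list(modulation = as.complex(m),
                        psf = dnspirit:::psf_from_modulation(m, 16),
                        pad = 16, n_pe = n, res = 1), class = "psf_profile")
  fw <- measure_fwhm(psf)$fwhm_voxels
  # |FT| of a Gaussian of std sigma (lines) has std n/(2 pi sigma) voxels
  expected <- 2 * sqrt(2 * log(2)) * n / (2 * pi * sgm)
  expect_lt(abs(fw - expected) / expected, 0.01)
})

test_that("FWHM is invariant under ky reversal of a symmetric modulation", {
  s <- psf_for()
  m <- Mod(s$psf$modulation)
  sym <- (m + rev(m)) / 2
  f1 <- dnspirit:::fwhm_interp(Mod(dnspirit:::psf_from_modulation(sym, 16)))
  f2 <- dnspirit:::fwhm_interp(Mod(dnspirit:::psf_from_modulation(rev(sym), 16)))
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("degenerate profiles without a half-maximum crossing error out", {
  expect_error(dnspirit:::fwhm_interp(rep(1, 64)), "degenerate")
})

test_that("relative SNR limiting cases and monotonicities hold", {
  s <- psf_for()
  # te = 0, tr >> T1 makes the relaxation factor 1
  fake_tm <- s$timing; fake_tm$te <- 0
  long_tr <- sequence_protocol(res = 0.6, n_seg = 3, bw_pixel = 992, tr = 1e9)
  sn <- compute_snr(long_tr, fake_tm, wm3, hw3)
  expect_equal(sn$factors$relaxation, 1, tolerance = 1e-12)

  # doubling the voxel volume doubles SNR at fixed timing/sampling
  s1 <- compute_snr(s$protocol, s$timing, wm3, hw3, eff_res = 0.6)
  s2 <- compute_snr(s$protocol, s$timing, wm3, hw3, eff_res = 1.2)
  expect_equal(s2$rel_snr / s1$rel_snr, 2, tolerance = 1e-12)
  expect_equal(s1$rel_snr,
               with(s1$factors, field * voxel * sampling * relaxation))

  # monotone decreasing in TE, increasing in TR
  te_grid <- seq(50, 150, by = 25)
  snr_te <- vapply(te_grid, function(te) {
    tm <- s$timing; tm$te <- te
    compute_snr(s$protocol, tm, wm3, hw3)$rel_snr
  }, numeric(1))
  expect_true(all(diff(snr_te) < 0))

  # 1 mm vs 0.6 mm at 3T, n_seg = 6: close to threefold SNR gap
  s06 <- psf_for(res = 0.6, n_seg = 6, bw = 992)
  s10 <- psf_for(res = 1.0, n_seg = 6, bw = 1384)
  r06 <- compute_snr(s06$protocol, s06$timing, wm3, hw3,
                     eff_res = measure_fwhm(s06$psf)$eff_res_mm)$rel_snr
  r10 <- compute_snr(s10$protocol, s10$timing, wm3, hw3,
                     eff_res = measure_fwhm(s10$psf)$eff_res_mm)$rel_snr
  expect_gt(r10 / r06, 2)
  expect_lt(r10 / r06, 4.5)
})

test_that("off-resonance displacement is linear and scales with segmentation", {
  s <- psf_for()
  expect_identical(compute_displacement(0, s$timing, s$protocol), 0)
  d1 <- compute_displacement(50, s$timing, s$protocol)
  expect_equal(compute_displacement(100, s$timing, s$protocol), 2 * d1)
  s6 <- psf_for(n_seg = 6)
  # doubling n_seg halves the displacement up to the matrix-rounding change
  d6 <- compute_displacement(50, s6$timing, s6$protocol)
  expect_equal(d6 / d1, 0.5, tolerance = 0.01)
})

test_that("protocol sweeps are consistent with direct calls and flag failures", {
  grid <- data.frame(res = 0.6, n_seg = 3, pf = 1, pf_mode = "none", bw_pixel = 992)
  tab <- sweep_protocols(grid, hw3, wm3)
  s <- psf_for()
  expect_equal(tab$te, s$timing$te)
  expect_equal(tab$displacement_mm, compute_displacement(50, s$timing, s$protocol))
  expect_equal(tab$blurring_frac, measure_fwhm(s$psf)$blurring_frac)

  bad <- data.frame(res = 0.6, n_seg = c(3, 1), pf = 1, pf_mode = "none",
                    bw_pixel = 992, tr = c(2500, 200))
  tab2 <- sweep_protocols(bad, hw3, wm3)
  expect_identical(tab2$feasible, c(TRUE, FALSE))
})
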