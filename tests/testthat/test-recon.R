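test_that("navigator phase estimation recovers the generator phases", {
  fx <- tiny_phase_fixture()
  s <- fx$b0_sets[[1]]
  ph <- estimate_phase_maps(s$navigators, window_size = 32)
  expect_true(all(ph$phi[[1]] == 0))
  m <- fx$phantom$mask
  for (i in 2:4) {
    err <- Arg(exp(1i * (ph$phi[[i]] - fx$phases$phases[[i]])))
    expect_lt(sqrt(mean(err[m]^2)), 0.05)
  }
  # identical navigators give all-zero relative phases
  same <- estimate_phase_maps(rep(s$navigators[1], 3))
  for (i in 2:3) expect_lt(max(abs(same$phi[[i]])), 1e-10)
  expect_error(estimate_phase_maps(list()), "navigator")
})

test_that("Hamming windowing reduces navigator phase error under noise", {
  fx <- tiny_phase_fixture()
  m <- fx$phantom$mask
  sigma <- mean(Mod(fx$phantom$baseline)[m]) / 10    # SNR 10
  errs <- vapply(1:20, function(r) {
    s <- encode_acquisition(fx$phantom, fx$coils, fx$phases, fx$scheme,
                            noise_sigma = sigma, seed = 100 + r)
    rms <- function(ph) {
      e <- Arg(exp(1i * (ph$phi[[3]] - fx$phases$phases[[3]])))
      sqrt(mean(e[m]^2))
    }
    c(win = rms(estimate_phase_maps(s$navigators, window = TRUE)),
      raw = rms(estimate_phase_maps(s$navigators, window = FALSE)))
  }, numeric(2))
  expect_lt(mean(errs["win", ]), mean(errs["raw", ]))
})

test_that("CG solves the identity system and matches a dense direct solve", {
  # identity: full masks, no phases, no regularization
  y <- rand_carray(c(16, 16, 2), seed = 2)
  masks <- list(matrix(TRUE, 16, 16))
  ph <- true_phase_maps(list(matrix(0, 16, 16)))
  sol <- cg_solve_normal(list(y), masks, ph, NULL, cg_tol = 1e-12, cg_max_iter = 10)
  expect_lt(rel_diff(sol$x, y), 1e-8)

  # dense oracle on a 16 x 16 plane with 2 coils and 2 phase-encoded shots
  fx <- make_reference_fixture(seed = 13, shape = 32, n_coils = 2, n_shots = 2,
                               snr = 20, n_directions = 1)
  s <- fx$b0_sets[[1]]
  sub <- function(a) a[9:24, 9:24, , drop = FALSE]
  ys <- lapply(s$shots, sub)
  masks <- lapply(s$masks, function(m) m[9:24, 9:24])
  phm <- true_phase_maps(lapply(fx$phases$phases, function(p) p[9:24, 9:24]))
  kern <- calibrate_spirit_kernel(s$calibration)
  nm <- dnspirit:::spirit_normal_maps(kern, c(16, 16))
  lambda1 <- 2
  n <- 16 * 16 * 2
  # build the dense normal operator column by column
  apply_op <- function(v) {
    x <- array(v, c(16, 16, 2))
    img <- ifft2c(x)
    acc <- array(0i, dim(x))
    for (i in seq_along(ys)) {
      t <- fft2c(dnspirit:::mul_phase(img, phm$P[[i]]))
      t <- ifft2c(dnspirit:::mask_data(t, masks[[i]]))
      acc <- acc + dnspirit:::mul_phase(t, Conj(phm$P[[i]]))
    }
    out <- fft2c(acc) + lambda1 * dnspirit:::apply_pixelwise(nm, x)
    as.vector(out)
  }
  A <- matrix(0i, n, n)
  for (j in seq_len(n)) {
    e <- complex(length.out = n); e[j] <- 1
    A[, j] <- apply_op(e)
  }
  rhs <- as.vector(adjoint_shots(ys, masks, phm))
  x_dense <- solve(A, rhs)
  sol2 <- cg_solve_normal(ys, masks, phm, kern, lambda1 = lambda1,
                          cg_tol = 1e-14, cg_max_iter = 3000, normal_maps = nm)
  expect_lt(rel_diff(as.vector(sol2$x), x_dense), 1e-8)
  # the residual log trends monotonically downward
  r <- sol2$resid
  expect_lt(tail(r, 1), 1e-10)
  expect_true(all(r <= cummin(r) * 10))
  expect_false(sol2$diverged)
  expect_error(cg_solve_normal(list(array(NaN + 0i, c(4, 4, 1))),
                               list(matrix(TRUE, 4, 4)),
                               true_phase_maps(list(matrix(0, 4, 4))), NULL),
               "non-finite")
})

test_that("noiseless self-consistent shots reconstruct to the ground truth", {
  fx <- tiny_clean_fixture()
  s <- fx$b0_sets[[1]]
  sp <- spirit_recon(s, phases = true_phase_maps(fx$phases, 4),
                     cg_tol = 1e-8, cg_max_iter = 300)
  expect_lt(nrmse(sp$image, fx$phantom$baseline, fx$phantom$mask), 0.01)
})

test_that("ground-truth phase correction makes the error phase-amplitude independent", {
  errs <- vapply(c(0, pi / 4, pi / 2, pi), function(amp) {
    fx <- make_reference_fixture(seed = 11, shape = 64, n_coils = 4, n_shots = 4,
                                 snr = 0, n_directions = 1, phase_amplitude = amp)
    s <- fx$b0_sets[[1]]
    sp <- spirit_recon(s, phases = true_phase_maps(fx$phases, 4),
                       cg_tol = 1e-8, cg_max_iter = 300)
    nrmse(sp$image, fx$phantom$baseline, fx$phantom$mask)
  }, numeric(1))
  expect_lt(diff(range(errs)), 0.01)
})

test_that("shot under-sampling at R_eff = 2 beats the zero-filled reconstruction", {
  fx <- tiny_phase_fixture()
  s <- retrospective_undersample(fx$b0_sets[[1]], 2)
  expect_equal(s$scheme$r_eff, 2)
  sp <- spirit_recon(s, phases = true_phase_maps(s$truth$phases),
                     cg_tol = 1e-6, cg_max_iter = 150)
  # zero-filled: adjoint of the phase-corrected acquisition, coil-combined
  zf <- combine_coils(ifft2c(adjoint_shots(s$shots, s$masks,
                                           true_phase_maps(s$truth$phases))),
                      mode = "sos")
  scale <- mean(zf[fx$phantom$mask]) / mean(Mod(fx$phantom$baseline)[fx$phantom$mask])
  e_sp <- nrmse(sp$image, fx$phantom$baseline, fx$phantom$mask)
  e_zf <- nrmse(zf / scale, fx$phantom$baseline, fx$phantom$mask)
  expect_lt(e_sp, e_zf)
})

test_that("an identity denoiser leaves DnSPIRiT at the SPIRiT fixed point", {
  fx <- make_reference_fixture(seed = 17, shape = 64, n_coils = 4, n_shots = 4,
                               snr = 20, n_directions = 1)
  s <- fx$b0_sets[[1]]
  ph <- estimate_phase_maps(s$navigators)
  sens <- fx$coils$sens                 # RSS-1 maps make combine/expand a projection
  sp <- spirit_recon(s, phases = ph, sens = sens, cg_tol = 1e-8, cg_max_iter = 200)
  dn <- dnspirit_recon(s, recon_config(denoiser = "identity", n_outer = 5,
                                       cg_tol = 1e-8, cg_max_iter = 200),
                       phases = ph, sens = sens)
  expect_lt(rel_diff(dn$image, sp$image), 0.01)
})

test_that("partial-Fourier filling restores Hermitian k-space of real images", {
  y <- (1:64 - 32.5) / 32; g2 <- outer(y^2, y^2, `+`)
  real_img <- exp(-g2 / 0.08)           # smooth: negligible Nyquist-row energy
  k <- fft2c(real_img)
  n0 <- ceiling((1 - 6 / 8) * 64)
  trunc <- k; trunc[seq_len(n0), ] <- 0i
  expect_identical(partial_fourier_fill(k, 1, "cs"), k)
  filled <- partial_fourier_fill(trunc, 6 / 8, "cs")
  expect_lt(rel_diff(filled, k), 1e-10)
  zp <- partial_fourier_fill(trunc, 6 / 8, "zp")
  expect_identical(zp, trunc)
  expect_error(partial_fourier_fill(k, 0.4, "zp"), "pf")
  # zero-padded PF blurs more than conjugate-symmetric filling
  prof_width <- function(kk) {
    img <- Mod(ifft2c(kk))
    p <- img[, 33]
    dnspirit:::fwhm_interp(stats::approx(seq_along(p), p, n = 16 * 64)$y) / 16
  }
  delta <- matrix(0, 64, 64); delta[33, 33] <- 1
  kd <- fft2c(delta)
  kd_t <- kd; kd_t[seq_len(n0), ] <- 0i
  w_zp <- prof_width(partial_fourier_fill(kd_t, 6 / 8, "zp"))
  w_cs <- prof_width(partial_fourier_fill(kd_t, 6 / 8, "cs"))
  expect_gt(w_zp, w_cs)
})

test_that("retrospective under-sampling keeps evenly spaced shots and counts", {
  fx <- tiny_phase_fixture()
  s <- fx$b0_sets[[1]]
  same <- retrospective_undersample(s, 4)
  expect_identical(same$scheme$segments, s$scheme$segments)
  half <- retrospective_undersample(s, 2)
  expect_identical(half$scheme$segments, c(0L, 2L))
  n_full <- sum(vapply(s$masks, sum, numeric(1)))
  n_half <- sum(vapply(half$masks, sum, numeric(1)))
  expect_equal(n_half / n_full, 1 / 2)
  expect_error(retrospective_undersample(s, 3), "divide")
})

test_that("coil combination modes behave algebraically", {
  fx <- tiny_clean_fixture()
  sens <- fx$coils$sens
  img <- fx$phantom$baseline
  mc <- dnspirit:::expand_coils(img, sens)
  rec <- combine_coils(mc, sens, mode = "sense")
  expect_lt(rel_diff(rec, img), 1e-10)
  sos <- combine_coils(mc, mode = "sos")
  expect_true(all(sos >= 0))
  one <- array(img, c(64, 64, 1))
  unit <- array(1 + 0i, c(64, 64, 1))
  expect_lt(rel_diff(combine_coils(one, unit, mode = "sense"), img), 1e-12)
  expect_equal(combine_coils(one, mode = "sos"), Mod(img))
  expect_error(combine_coils(one, array(0i, c(64, 64, 1)), mode = "sense"), "zero")
})

test_that("all-zero shots reconstruct to zeros without error", {
  fx <- tiny_clean_fixture()
  s <- fx$b0_sets[[1]]
  for (i in seq_along(s$shots)) s$shots[[i]][] <- 0i
  for (i in seq_along(s$navigators)) s$navigators[[i]][] <- 0i
  sp <- spirit_recon(s, cg_max_iter = 10)
  expect_true(all(Mod(sp$x) == 0))
})
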