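test_that("phantom diffusion contrast follows the tensor model", {
  ph <- make_phantom(c(64, 64), n_directions = 6, seed = 3)
  expect_identical(phantom_dwi(ph, 0), ph$baseline)
  for (k in 1:6) {
    expect_true(all(Mod(phantom_dwi(ph, k)) <= Mod(ph$baseline) + 1e-12))
  }
  # FA computed in closed form from the generated tensors matches the request
  ev <- dnspirit:::eigvals_sym3(matrix(ph$tensors, 64 * 64, 6))
  fa <- {
    num <- (ev[, 1] - ev[, 2])^2 + (ev[, 2] - ev[, 3])^2 + (ev[, 1] - ev[, 3])^2
    sqrt(num / (2 * rowSums(ev^2)))
  }
  expect_lt(max(abs(fa - as.vector(ph$fa))), 1e-6)
  # anisotropy makes the attenuation direction-dependent
  wm_vox <- which(ph$wm_mask)[1]
  att <- vapply(1:6, function(k) Mod(phantom_dwi(ph, k))[wm_vox], numeric(1))
  expect_gt(diff(range(att)), 1e-4)
  expect_error(make_phantom(c(64, 64), n_directions = 2,
                            directions = matrix(c(2, 0, 0, 0, 2, 0), 2, 3, byrow = TRUE)),
               "unit")
  expect_error(make_phantom(c(16, 16)), "32")
})

test_that("phantoms are bit-reproducible given parameters and seed", {
  a <- make_phantom(c(64, 64), seed = 9)
  b <- make_phantom(c(64, 64), seed = 9)
  expect_identical(a$baseline, b$baseline)
  expect_identical(a$tensors, b$tensors)
  c1 <- make_sensitivities(c(64, 64), 4, seed = 5)
  c2 <- make_sensitivities(c(64, 64), 4, seed = 5)
  expect_identical(c1$sens, c2$sens)
  p1 <- make_shot_phases(c(64, 64), 4, seed = 5)
  p2 <- make_shot_phases(c(64, 64), 4, seed = 5)
  expect_identical(p1$phases, p2$phases)
})

test_that("coil sensitivities are RSS-normalized, smooth, and trivial for one coil", {
  one <- make_sensitivities(c(64, 64), 1)
  expect_true(all(one$sens == 1 + 0i))
  cm <- make_sensitivities(c(64, 64), 8, seed = 2)
  rss <- sqrt(apply(Mod(cm$sens)^2, c(1, 2), sum))
  expect_lt(max(abs(rss - 1)), 1e-6)
  # spectral energy outside the 32x32 calibration band is under 1%
  for (c in c(1, 5)) {
    k <- fft2c(cm$sens[, , c])
    cutoff <- 16
    rows <- 33 + seq(-cutoff, cutoff - 1)
    inner <- sum(Mod(k[rows, rows])^2)
    expect_gt(inner / sum(Mod(k)^2), 0.99)
  }
})

test_that("shot phases are bounded, referenced to shot 1 and navigator-band-limited", {
  z <- make_shot_phases(c(64, 64), 4, amplitude = 0, seed = 1)
  expect_true(all(vapply(z$phases, function(p) all(p == 0), logical(1))))
  pm <- make_shot_phases(c(64, 64), 4, amplitude = pi / 3, seed = 1)
  expect_true(all(pm$phases[[1]] == 0))
  for (p in pm$phases) expect_lte(max(abs(p)), pi / 3 + 1e-12)
  # exp(i phase) fits in the 32x32 navigator window to 99% energy
  for (i in 2:4) {
    k <- fft2c(exp(1i * pm$phases[[i]]))
    rows <- 33 + seq(-16, 15)
    expect_gt(sum(Mod(k[rows, rows])^2) / sum(Mod(k)^2), 0.99)
  }
})

test_that("sampling schemes interleave evenly and tile k-space", {
  sc <- make_sampling_scheme(24, 6, 3)
  expect_identical(sc$segments, c(0L, 2L, 4L))
  expect_equal(sc$r_eff, 2)

  full <- make_sampling_scheme(24, 4, 4)
  all_lines <- sort(unlist(full$lines))
  expect_identical(all_lines, 1:24)                     # covers once
  expect_identical(anyDuplicated(unlist(full$lines)), 0L)

  pf <- make_sampling_scheme(48, 4, 4, pf = 3 / 4)
  frac <- length(unlist(pf$lines)) / 48
  expect_lt(abs(frac - 0.75), 1 / 48 + 1e-9)
  expect_error(make_sampling_scheme(24, 4, 5), "n_acq")
  expect_error(make_sampling_scheme(24, 6, 4), "divide")
})

test_that("noise-free encoding inverts exactly and masks are exact zeros", {
  fx <- tiny_clean_fixture()
  s <- fx$b0_sets[[1]]
  ks <- Reduce(`+`, s$shots)
  img <- ifft2c(ks)
  ref <- array(0i, dim(img))
  for (c in seq_len(fx$coils$n_coils)) ref[, , c] <- fx$phantom$baseline * fx$coils$sens[, , c]
  expect_lt(rel_diff(img, ref), 1e-10)
  for (i in seq_along(s$shots)) {
    off <- !s$masks[[i]]
    for (c in seq_len(dim(s$shots[[i]])[3])) {
      expect_true(all(s$shots[[i]][, , c][off] == 0i))
    }
  }
})

test_that("encoded image-domain noise level matches the injected sigma", {
  ph <- make_phantom(c(64, 64), n_directions = 0, seed = 2)
  coils <- make_sensitivities(c(64, 64), 2, seed = 2)
  phases <- make_shot_phases(c(64, 64), 1, amplitude = 0)
  sc <- make_sampling_scheme(64, 1, 1)
  sigma <- 0.05
  devs <- vapply(1:3, function(r) {
    clean <- encode_acquisition(ph$baseline, coils, phases, sc, 0)
    noisy <- encode_acquisition(ph$baseline, coils, phases, sc, sigma, seed = r)
    n_img <- ifft2c(noisy$shots[[1]] - clean$shots[[1]])
    stats::sd(c(Re(n_img), Im(n_img))) * sqrt(2)   # complex std
  }, numeric(1))
  expect_lt(abs(mean(devs) - sigma) / sigma, 0.03)
})

test_that("the multi-shot forward operator passes the adjoint identity", {
  fx <- tiny_phase_fixture()
  s <- fx$b0_sets[[1]]
  ph <- true_phase_maps(fx$phases, length(s$shots))
  x <- rand_carray(c(64, 64, 4), seed = 21)
  ys <- lapply(1:4, function(i) rand_carray(c(64, 64, 4), seed = 30 + i))
  Ax <- forward_shots(x, s$masks, ph)
  Aty <- adjoint_shots(ys, s$masks, ph)
  lhs <- sum(vapply(1:4, function(i) sum(Conj(ys[[i]]) * Ax[[i]]), complex(1)))
  rhs <- sum(Conj(Aty) * x)
  expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-10)
})
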