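test_that("repeat-difference noise estimation is unbiased and linear", {
  img <- matrix(5, 100, 100)
  expect_identical(noise_std_from_repeats(img, img, img > 0), 0)
  withr::with_seed(8, {
    n <- 316
    a <- matrix(stats::rnorm(n^2), n)             # ~1e5 voxels
    b <- matrix(stats::rnorm(n^2), n)
    sig <- noise_std_from_repeats(10 + a, 10 + b, matrix(TRUE, n, n))
    expect_lt(abs(sig - 1), 0.02)
    expect_equal(noise_std_from_repeats(3 * (10 + a), 3 * (10 + b), matrix(TRUE, n, n)),
                 3 * sig, tolerance = 1e-12)
  })
  expect_error(noise_std_from_repeats(img, img, img > 10), "mask")
})

test_that("SNR and angular CNR follow their definitions", {
  expect_error(snr_and_cnr(matrix(1, 4, 4), array(1, c(4, 4, 6)), 0,
                           matrix(TRUE, 4, 4)), "sigma")
  withr::with_seed(9, {
    mu <- 8; sigma <- 0.5
    b0 <- matrix(mu + stats::rnorm(256^2, sd = sigma), 256)
    dwis <- array(2, c(256, 256, 6))
    out <- snr_and_cnr(b0, dwis, sigma, matrix(TRUE, 256, 256))
    expect_lt(abs(out$snr_b0 - mu / sigma) / (mu / sigma), 0.03)
    # direction-independent signal has zero angular variance
    expect_identical(out$cnr_dwi, 0)
  })
})

test_that("Tenengrad matches ramps, constants and a brute-force loop", {
  expect_identical(tenengrad_sharpness(matrix(3, 16, 16))$raw, 0)
  ramp <- 0.7 * matrix(seq_len(20), 20, 20)      # slope 0.7 along the row axis
  # interior voxels of a ramp of slope s along x have gradient exactly s
  interior <- matrix(FALSE, 20, 20); interior[2:19, 2:19] <- TRUE
  expect_equal(tenengrad_sharpness(ramp, interior)$raw, 0.7, tolerance = 1e-12)
  expect_equal(tenengrad_sharpness(ramp, interior, sigma = 0.35)$normalized, 2,
               tolerance = 1e-12)

  withr::with_seed(10, {
    img <- matrix(stats::rnorm(24 * 24), 24)
    got <- tenengrad_sharpness(img)$raw
    # naive per-voxel loop oracle
    acc <- 0
    for (i in 1:24) for (j in 1:24) {
      ip <- min(i + 1, 24); im <- max(i - 1, 1)
      jp <- min(j + 1, 24); jm <- max(j - 1, 1)
      gx <- (img[ip, j] - img[im, j]) / max(ip - im, 1)
      gy <- (img[i, jp] - img[i, jm]) / max(jp - jm, 1)
      acc <- acc + sqrt(gx^2 + gy^2)
    }
    expect_lt(abs(got - acc / 576), 1e-12)
  })
})

test_that("NRMSE normalization and oracle agree", {
  ref <- matrix(stats::runif(64) + 1, 8)
  expect_identical(nrmse(ref, ref), 0)
  expect_equal(nrmse(2 * ref, ref), 1, tolerance = 1e-12)
  withr::with_seed(11, {
    a <- matrix(stats::rnorm(64), 8); b <- matrix(stats::rnorm(64) + 2, 8)
    expect_lt(abs(nrmse(a, b) - sqrt(sum((a - b)^2)) / sqrt(sum(b^2))), 1e-12)
  })
  expect_error(nrmse(ref, ref * 0), "zero")
})

test_that("the KS statistic matches brute force and stats::ks.test", {
  x <- c(1, 2, 3); expect_identical(ks_statistic(x, x), 0)
  expect_identical(ks_statistic(c(1, 2), c(10, 11)), 1)
  withr::with_seed(12, {
    a <- stats::rnorm(80); b <- stats::rnorm(60, mean = 0.4)
    got <- ks_statistic(a, b)
    # O(n^2) pooled-grid scan
    grid <- c(a, b)
    brute <- max(vapply(grid, function(t) abs(mean(a <= t) - mean(b <= t)), numeric(1)))
    expect_lt(abs(got - brute), 1e-12)
    expect_equal(got, unname(stats::ks.test(a, b)$statistic), tolerance = 1e-12)
  })
  expect_error(ks_statistic(numeric(0), 1), "empty")
})

test_that("the log-linear DTI fit recovers constructed tensors", {
  ph <- make_phantom(c(48, 48), n_directions = 6, seed = 13)
  b0 <- Mod(ph$baseline)
  dwis <- vapply(1:6, function(k) Mod(phantom_dwi(ph, k)), matrix(0, 48, 48))
  fit <- fit_dti(b0, dwis, ph$directions, ph$b_value, mask = ph$mask)
  m <- ph$mask & b0 > 0
  for (k in 1:6) {
    expect_lt(max(abs(fit$tensors[, , k][m] - ph$tensors[, , k][m])), 1e-8)
  }
  expect_lt(max(abs(fit$fa[m] - ph$fa[m])), 1e-6)
  expect_lt(max(abs(fit$md[m] - ph$md[m])), 1e-9)

  # noiseless isotropic tensor: FA = 0, MD = d
  dirs <- ph$directions
  s0 <- matrix(1, 8, 8)
  d_iso <- 1e-3
  iso <- array(exp(-1000 * d_iso), c(8, 8, 6))
  f <- fit_dti(s0, iso, dirs, 1000, matrix(TRUE, 8, 8))
  expect_lt(max(abs(f$fa)), 1e-9)
  expect_lt(max(abs(f$md - d_iso)), 1e-12)

  expect_error(fit_dti(s0, iso[, , 1:5], dirs[1:5, ], 1000), "6 diffusion")
})

test_that("magnitude metrics ignore a global complex phase", {
  fx <- tiny_clean_fixture()
  img <- fx$phantom$baseline
  rot <- img * exp(1i * 1.1)
  expect_equal(nrmse(rot, img, fx$phantom$mask), 0, tolerance = 1e-12)
  expect_equal(tenengrad_sharpness(rot)$raw, tenengrad_sharpness(img)$raw,
               tolerance = 1e-12)
})
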