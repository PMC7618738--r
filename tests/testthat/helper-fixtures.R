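# Shared fixtures, memoized so heavy objects are built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small noiseless acquisition (zero shot phases)
tiny_clean_fixture <- function() memo("tiny_clean", {
  make_reference_fixture(seed = 11, shape = 64, n_coils = 4, n_shots = 4,
                         snr = 0, n_directions = 1, phase_amplitude = 0)
})

# small noiseless acquisition with shot phases
tiny_phase_fixture <- function() memo("tiny_phase", {
  make_reference_fixture(seed = 11, shape = 64, n_coils = 4, n_shots = 4,
                         snr = 0, n_directions = 1, phase_amplitude = pi / 2)
})

# the reference noisy study (128^2, 8 coils, 6 shots, SNR 5, seed 7)
reference_compare <- function() memo("reference_compare", {
  experiment_recon_compare(seed = 7, shape = 128, snr = 5)
})

reference_undersampling <- function() memo("reference_undersampling", {
  experiment_undersampling(seed = 7, shape = 128, snr = 5)
})

# ground-truth multi-coil k-space of a fixture's baseline
truth_kspace <- function(fx) {
  nc <- fx$coils$n_coils
  a <- array(0i, c(fx$phantom$shape, nc))
  for (c in seq_len(nc)) a[, , c] <- fx$phantom$baseline * fx$coils$sens[, , c]
  fft2c(a)
}

rand_carray <- function(d, seed = 1) {
  withr::with_seed(seed, {
    array(complex(real = stats::rnorm(prod(d)), imaginary = stats::rnorm(prod(d))), d)
  })
}

rel_diff <- function(a, b) sqrt(sum(Mod(a - b)^2) / max(sum(Mod(b)^2), 1e-300))
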