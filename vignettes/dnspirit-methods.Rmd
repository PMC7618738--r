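---
title: "Segmented diffusion EPI simulation and DnSPIRiT reconstruction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmented diffusion EPI simulation and DnSPIRiT reconstruction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnspirit)
```

This vignette documents the models behind the package, the design choices
made where the design was genuinely open, and what the synthetic experiments
do and do not demonstrate.

## 1. Protocol simulator

### Timing model

Submillimeter EPI needs many phase-encode lines; in-plane segmentation
spreads them over `N_seg` interleaved shots. The simulator derives all
timing from a small set of protocol and hardware parameters.

* **Matrix sizes.** `N_PE` and `N_x` are the nearest multiple of `N_seg` to
  `FOV/Δ`, so every segment acquires the same number of lines; `N_par =
  round(FOV_z/Δ)`. This rounding rule reproduces the reference protocol matrix sizes
  of the three validation protocols (336/414/360) exactly.
* **Echo spacing.** The readout is modeled as a ramp-sampled trapezoid. The
  area-equivalent acquisition time per line (flat-top plus one ramp) is tied
  to the receiver bandwidth, `T_acq = 1/BW`, which fixes the readout
  gradient `G_read = BW/(γΔx)`; the echo spacing adds the remaining
  gradient transition, `ES = 1/BW + G_read/slew`. The default slew rate is
  200 T/m/s (a typical clinical-gradient limit) and is configurable. With
  counting both ramps instead, simulated displacements overshoot the
  reference desk-scale values by ~16–20%; with the ramp-sampled model they
  agree to ~1%, and the simulated minimum TE of the 0.65 mm protocol lands
  within 0.2% of the reference protocol's 102 ms — which is why this model was adopted.
* **Diffusion encoding.** Stejskal–Tanner pulsed gradients at `G_max` with
  `b = γ²G²δ²(Δ−δ/3)` and `Δ = δ + t_ref + 2 gap` (1 ms safety gap on each
  side of the refocusing pulse); `δ` is found by root-finding on the
  monotone `b(δ)` curve.
* **Echo time.** The spin echo is placed at the k-space center line:
  `TE = 2·max(t_exc/2 + gap + δ + gap + t_ref/2,
  t_ref/2 + gap + δ + gap + t_center)` with
  `t_center = (pf − 1/2)·N_PE/N_seg·ES`. Partial Fourier therefore shortens
  TE, which is its SNR benefit.

### PSF, effective resolution and blurring

Each acquired ky line is weighted by the standard spin-echo envelope at its
acquisition time,

$$w(t) = e^{-t/T_2}\, e^{-|t-TE|/T_2'}, \qquad 1/T_2' = 1/T_2^* - 1/T_2,$$

with all interleaved segments sharing the intra-shot timing. The PSF is the
inverse Fourier transform of this ky modulation on a 16-fold zero-padded
grid (padding makes the half-maximum interpolation error negligible), and
its FWHM is measured by linear interpolation on the magnitude.

Two conventions for "effective resolution" are exposed and deliberately kept
apart:

* `eff_res_mm = Δ · FWHM(voxels)` and `blurring_frac = FWHM − 1`: the FWHM
  relative to one nominal voxel. Even the decay-free sinc PSF has
  FWHM ≈ 1.207 voxels, so the baseline "blurring" is ~20.7%. This is the
  convention in which the desk-scale results are quoted (41.3%/25.3% at
  0.6/1 mm, 3 segments, 3T), and the one consistent with the validated
  protocols reaching ~0.8 mm effective resolution
  at ~0.6 mm nominal.
* `eff_res_rel_mm` and `blurring_rel`: the same FWHM normalized by the
  ideal same-grid PSF, so the no-decay, fully sampled case gives exactly the
  nominal resolution and zero blurring. This variant is the clean baseline
  for invariance tests (its zero point is exact) and for comparing
  protocols on the same grid.

Partial Fourier is simulated by either zero-filling the unsampled band
(`pf_mode = "zp"`) or mirroring it by conjugate symmetry (`"cs"`, assuming a
real object; phase-corrupted conjugate symmetry belongs to the
reconstruction layer, not the PSF). The resulting blurring ordering — ZP ≥
CS ≥ no-PF at every segmentation factor — is asserted by the sweep tests.

### SNR model

`rel_snr = B0^1.65 · Δx Δy_eff Δz · sqrt(N_PE N_par / BW) · exp(-TE/T2) ·
(1 − exp(-TR/T1))`. The supralinear field exponent reflects measured
field-dependence of intrinsic SNR; `Δy_eff` comes from the PSF FWHM while
`Δx`, `Δz` stay nominal. The square root is taken over the total sampling
time `N_PE·N_par/BW` (the standard Fourier-averaging form; the rendering of
this factor is ambiguous in some sources, and this form reproduces the
expected monotone SNR improvement with `N_seg` and the ~3x SNR gap between
1 mm and 0.6 mm acquisitions). The model assumes unaccelerated acquisitions
and therefore contains no g-factor term.

## 2. Synthetic data

The generator is first-class, seeded code — every reconstruction claim in
the test suite is made against its ground truth.

* **Phantom**: nested ellipses with gyral-like ribbons; complex baseline
  with a smooth polynomial phase; an axially symmetric diffusion tensor per
  voxel built in closed form from requested (FA, MD) via
  `f = FA/sqrt(3 − 2FA²)`, `λ₁ = MD(1+2f)`, `λ⊥ = MD(1−f)`, oriented along
  the local structure. DWI contrast is `baseline · exp(-b gᵀDg)`.
* **Coils**: Gaussian lobes on a ring with smooth per-coil phase,
  RSS-normalized to exactly 1 — so sensitivity-weighted combination is an
  orthogonal projection onto the coil subspace. Their spectra fit in the
  32×32 calibration band to >99% energy (audited).
* **Shot phases**: band-limited random fields (default 6×6 k-space support,
  far inside the 32×32 navigator window), scaled to a maximum amplitude
  (default π/2 rad); shot 1 is the zero-phase reference since only relative
  phases enter the forward model.
* **Sampling**: segment `s` acquires lines `{s, s+N_seg, …}` inside the
  partial-Fourier window; retained segments are evenly spaced when
  under-sampled.
* **Encoding**: `y_i = D_i F (e^{iφ_i} · sens · image) + ε` with centered
  unitary FFTs (k-space origin at `n/2`, 0-based) and i.i.d. complex
  Gaussian noise on acquired samples only. Navigators are fully sampled
  central 32×32 windows (with noise); since they are fully sampled, no
  GRAPPA step is needed to reconstruct them — a documented simplification.
  The calibration scan is the noise-free central window of the phase-free
  sensitivity-weighted baseline.

The reference fixture (128², 8 coils, 6 shots, image SNR 5, seed 7, two
b = 0 repeats plus 6 DWIs) defines noise through the sensitivity-combined
image: `σ = mean(|baseline|)/SNR`, which with RSS-1 maps is exactly the
combined-image noise level.

What the phantom does **not** emulate: realistic anatomy and texture,
spatially varying or coil-correlated noise, B0-induced distortion,
slab-excitation profiles, eddy currents, and motion beyond the per-shot
phase model. Passing tests demonstrate algorithmic correctness and the
relative ordering of methods under controlled conditions, not in-vivo
performance.

## 3. Reconstruction

Reconstruction is per 2D plane (planes are independent, mirroring per
ky–kz-plane processing after a readout-direction Fourier transform).

* **Phase maps** are estimated from navigators smoothed with a 32×32
  k-space Hamming window; the per-shot phase is the argument of the
  coil-wise correlation with shot 1, which cancels coil and object phase.
  The forward model applies `P_i = e^{iφ_i}` exactly as the generator does,
  so data consistency removes the shot phases; the sign convention is fixed
  by the phase-exactness property test, not typography.
* **SPIRiT kernel**: 5×5 cross-coil least-squares fit on the calibration
  region (own-coil center excluded), ridge-regularized with weight
  `0.01 · mean diag` of the normal matrix (the literature is silent on the
  exact weight; it is exposed). The kernel is applied through precomputed
  image-domain transfer maps (pointwise multiplication), validated against
  the literal k-space convolution to machine precision; the quadratic
  penalty uses per-pixel Hermitian `(g−I)ᴴ(g−I)` maps so one application
  costs two FFT sets.
* **CG**: conjugate gradient on the normal equations with relative-residual
  tolerance 1e-6 and a 100-iteration cap by default; outer iterations warm
  start from the previous iterate, which roughly halves the inner
  iterations in practice.
* **Outer loop**: iteration 1 is plain SPIRiT; afterwards the coil-combined
  image is denoised and re-expanded through the sensitivities as the prior
  `λ₂‖F⁻¹x − z‖²`. Both recombination modes are implemented:
  `magnitude_sos` (denoise the root-sum-of-squares magnitude, multiply by
  sensitivities) and `complex_sense` (sensitivity-combine the complex
  image, denoise, re-multiply). The synthetic experiments use
  `complex_sense` because the phantom carries object phase that a magnitude
  path would fold into the prior; the weights follow the reference setting
  λ₁ = 10, λ₂ = 2, 5 outer iterations, treated as relative to
  unit-normalized data. The objective is evaluated and logged per outer
  iteration; plug-and-play iterations have no convexity guarantee, so the
  trace is reported, not asserted, and in practice it plateaus after 2–3
  iterations.
* **Partial Fourier** is filled before the solve by zero-padding or by
  conjugate symmetry after zeroth-order phase removal (a stated
  simplification relative to low-rank structured-matrix completion, which
  is out of scope). For even grids the most negative ky row is its own
  Hermitian partner and cannot be recovered by symmetry; it is left as is.
* **Degenerate inputs**: all-zero shot data reconstruct to zeros without
  error; non-finite inputs are rejected; CG divergence raises a diagnostic
  warning rather than an abort.

### The built-in denoiser

The role of the block-matching and random-matrix denoisers used with
in-vivo data is played by a locally-low-rank denoiser: 8×8 patches with
stride 4 (boundary patches snapped inside), Casorati matrices (the patch
itself for a single image, patch-pixels × images for a stack), singular
values hard-thresholded at the Marchenko–Pastur edge `σ(√m + √n)`, and
overlap averaging. The noise level comes from a `σ` hint or a robust
Laplacian pseudo-residual estimate; `σ` is spatially uniform, a stated
fidelity gap relative to g-factor-aware random-matrix denoisers.
Third-party denoisers attach through a registry
(`register_denoiser()`); the contract (shape preservation, determinism,
finiteness) is enforced at call time, and magnitude-only plug-ins have the
input phase restored.

## 4. Metrics

All image metrics work on magnitudes, so they are invariant to a global
complex phase. Tenengrad uses the mean gradient magnitude (the
mean-of-squares variant is available via a flag, since the rendering of the
metric varies between sources) with central differences and one-sided
differences at borders; normalization is by each method's own per-volume
noise σ. The DTI fit is per-voxel log-linear least squares with eigenvalues
from the closed-form symmetric-3×3 solution; negative eigenvalues are
clamped for FA, MD keeps the raw trace/3. The KS statistic is the exact
maximum ECDF difference over the pooled support (validated against both a
brute-force scan and `stats::ks.test`), computed over all mask voxels
without binning.

## 5. Problem sizes and numerical choices

The packaged experiments use sizes chosen to exercise every code path at
desk scale: the reference fixture is 128² with 8 coils and 6 shots and the
fixture experiments run CG to tolerance 1e-4 with at most 25 iterations
(the method comparison involves 24 solves; warm starts make later outer
iterations converge in under 10 iterations). Oracle tests run the tiny
16×16/2-coil system against a dense direct solve at tolerance 1e-8 and the
operator adjoint identities at 1e-10. Seeds are fixed everywhere; all
generators restore the RNG state, and identical seeds produce bit-identical
fixtures and reports.

## 6. Known limitations

* The timing model is one plausible sequence-timing layout among several;
  it matches the reference desk-scale numbers to a few percent but is
  validated only at that level (±10% for TE, ±15% for derived quantities).
* 2D planes only; kz encoding, slab combination and slab-boundary
  correction are out of scope.
* The sensitivity estimator is a smoothed low-resolution ratio map, not an
  eigenvector method; with full-support synthetic coils this is accurate to
  a few percent, and an eigenvector-based estimator can be plugged in where
  real calibration data demand it.
* The identity-denoiser fixed-point property (DnSPIRiT → SPIRiT) holds
  exactly when coil combination/expansion is a projection, i.e. with RSS-1
  sensitivity maps; with estimated maps the support floor perturbs the
  projection and the agreement degrades gracefully (~2% at SNR 20).
* No coil noise covariance, no g-factor modeling, no trained denoisers.
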