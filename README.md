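# dnspirit

Simulation and reconstruction tools for **in-plane segmented 3D multi-slab
diffusion EPI** at submillimeter resolution:

* a deterministic **protocol simulator** — EPI timing, point-spread function
  (PSF), effective resolution, off-resonance displacement and relative SNR as
  functions of the in-plane segmentation factor and partial-Fourier strategy;
* **DnSPIRiT**, a denoiser-regularized multi-shot SPIRiT reconstruction with
  navigator-based correction of motion-induced shot phases;
* a seeded **synthetic-data layer** (diffusion phantom, coil sensitivities,
  shot phases, segmented noisy k-space) so that every reconstruction stage is
  testable without any external data;
* **image-quality metrics**: repeat-based noise sigma, SNR, angular CNR,
  noise-normalized Tenengrad sharpness, NRMSE, the Kolmogorov–Smirnov
  statistic, and a log-linear diffusion tensor fit for FA/MD bias.

## The model

Segmented EPI splits the `N_PE` phase-encode lines into `N_seg` interleaved
shots, shortening the effective echo spacing `ES_eff = ES / N_seg`, the
per-shot readout and the echo time. The simulator quantifies the resulting
trade-offs:

* **distortion** — bulk displacement `Δf · ES_eff · N_PE · Δy` for an
  off-resonance `Δf`;
* **T2\* blurring** — each ky line is weighted by the spin-echo envelope
  `exp(-t/T2) · exp(-|t−TE|/T2′)` at its acquisition time; the PSF is the
  Fourier transform of this modulation and the effective resolution is its
  FWHM in units of the nominal voxel;
* **SNR** — `B0^1.65 · Δx Δy_eff Δz · sqrt(N_PE N_par / BW) · exp(-TE/T2) ·
  (1 − exp(-TR/T1))`.

The reconstruction solves, per ky–kx plane and over the multi-coil k-space
`x`,

```
min_x  Σ_i ‖D_i F P_i F⁻¹ x − y_i‖² + λ₁‖(G − I) x‖² + λ₂‖F⁻¹ x − Φ(F⁻¹ x)‖²
```

where `D_i`, `P_i`, `y_i` are the sampling mask, motion-induced phase and
data of shot `i`, `G` is the SPIRiT self-consistency kernel calibrated from
a fully sampled scan, and `Φ` is a plug-in denoiser (a locally-low-rank /
Marchenko–Pastur denoiser is built in). The problem is solved plug-and-play:
conjugate-gradient data-consistency solves alternate with denoising of the
coil-combined image.

## Worked example

```r
library(dnspirit)

# protocol trade-offs at 3T for 0.6 mm vs 1 mm, 3 segments, no partial Fourier
experiment_protocol_numbers()
#>   res     te_ms displacement_mm blurring_pct t2_signal_pct
#> 1 0.6 182.04071        4.400128     42.03951      10.15764
#> 2 1.0  99.97995        3.230509     27.00256      28.47825
```

At 0.6 mm a 50 Hz off-resonance displaces the image by 4.4 mm, T2\* decay
widens the PSF by 42% of a voxel, and only 10% of the T2 signal survives to
the echo — the quantitative case for using more segments at submillimeter
resolution.

```r
# reconstruction comparison on the reference noisy fixture
# (128x128, 8 coils, 6 shots, SNR 5, seed 7; ~3 min on one CPU)
rc <- experiment_recon_compare(seed = 7)
rc$metrics[, c("method", "snr_b0", "cnr_dwi", "tenengrad_normalized", "nrmse", "delta_fa")]
#>           method   snr_b0  cnr_dwi tenengrad_normalized     nrmse   delta_fa
#> 1         spirit 4.955984 1.087793            0.8175814 0.4155236 0.12726413
#> 2 spirit_denoise 9.953604 1.621578            0.6702617 0.2156862 0.04699283
#> 3       dnspirit 9.412756 1.486646            0.7073537 0.1986154 0.03352800
```

Plain SPIRiT is noisy but sharp; SPIRiT followed by standalone denoising
roughly doubles the SNR at the cost of the largest sharpness loss; DnSPIRiT
keeps most of the SNR gain while staying sharper and giving the smallest
error and FA bias — the ordering the method is designed to achieve.

A thin command-line front end over the same functions is provided at
`inst/cli/dnspirit.R` (subcommands `simulate-protocol`, `phantom`, `recon`,
`evaluate`, `reproduce`).

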