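Package: dnspirit
Title: Segmented Diffusion EPI Simulation and Denoiser-Regularized SPIRiT
    Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and evaluating in-plane segmented 3D
    multi-slab diffusion EPI acquisitions and for reconstructing multi-shot,
    multi-coil k-space data with a denoiser-regularized SPIRiT method
    (DnSPIRiT). Includes a deterministic EPI timing, point-spread-function,
    displacement and relative-SNR simulator; a seeded synthetic-data layer
    generating brain-like diffusion phantoms, coil sensitivities, per-shot
    motion-induced phase errors and noisy segmented k-space; SPIRiT kernel
    calibration, coil compression and sensitivity estimation; a conjugate
    gradient solver for the phase-corrected multi-shot forward model with
    plug-and-play denoiser regularization; a locally-low-rank denoiser with
    Marchenko-Pastur thresholding; and image-quality metrics (SNR, angular
    CNR, Tenengrad sharpness, NRMSE, Kolmogorov-Smirnov statistic, DTI fit).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    RNifti,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
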