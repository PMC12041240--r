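# lfrecon

Light-field microscopy (LFM) records one 2D sensor frame behind a microlens
array and thereby encodes a whole 3D volume: the lenslet gives lateral
position, the pixel behind it gives angle. `lfrecon` is an R toolkit for
studying the resulting reconstruction problem end to end at desk scale:

* a **wave-optics forward model** — per-depth, per-lenslet-phase PSF kernel
  banks `H[d, i, j, ·, ·]`, an exactly linear, energy-conserving projector
  `LF = P(V)` with exact adjoint, and the bit-exact sub-aperture view
  decomposition (`N²` views from `N×N` pixels per lenslet);
* **classical baselines** — synthetic-aperture (shift-and-add) refocusing
  with the geometry-derived disparity slope, and Richardson–Lucy light-field
  deconvolution `V ← V · Pᵀ(LF / P(V))`;
* a **GAN reconstruction network** — an encoder-decoder generator mapping
  view stacks to depth stacks (even-channel skip connections at stages 1 and
  3, blended bicubic + pixel-shuffle upsampling) and a convolutional
  discriminator, trained with the composite objective

  `α·BerHu(G(x), y) + β·(1 − MS-SSIM(G(x), y)) + γ·BCE(D(G(x)), 1)`

  (defaults α = 3, β = 1, γ = 0.5, BerHu c = 0.1) under alternating AdamW
  updates (lr 1e-6/1e-7, weight decay 1e-2, 0.95 decay every 5 epochs,
  batch 2), running on a package-internal reverse-mode autodiff engine with
  compiled convolution kernels;
* **seeded phantoms** — filaments with controlled diameter, beads with known
  positions, cortical soma volumes with 10 Hz calcium traces, and
  particle fields at a stated particles-per-microlens density advected by
  analytic flows (uniform / shear / vortex);
* **metrics** — PSNR, SSIM, MS-SSIM, a perceptual feature distance, MSE,
  Pearson ρ, FWHM, decorrelation cut-off frequency `k_c`, and ΔF/F₀ trace
  extraction;
* a **PIV stage** — 3D particle localization, position-error scoring,
  variational 3D optical flow (Horn–Schunck, coarse-to-fine), and velocity
  error statistics.

Everything runs from synthetic phantoms on one CPU with no downloads; the
methods vignette (`vignettes/lfrecon-methods.Rmd`) documents the models,
parameter choices and limitations.

## Worked example

Simulate beads, project them to a light field, reconstruct with the
baselines and a briefly trained network, and compare:

```r
library(lfrecon)

cfg <- optical_config(pixels_per_lenslet = 4L,
                      z_planes = seq(-6, 6, length.out = 5))
psf <- build_psf(cfg)

ph <- make_beads(phantom_spec(shape = c(64L, 64L, 5L), seed = 1L,
                              n_beads = 5L, diameter_um = 2.5,
                              min_separation_um = 8))
lf <- lf_project(ph$volume, psf)          # 64 x 64 sensor frame
views <- decompose_views(lf)              # 16 views of 16 x 16

vol_ref <- refocus(lf, cfg)               # shift-and-add stack
vol_lfd <- lfd_deconvolve(lf, psf, recon_params(n_iterations = 50L))

det <- localize_particles(vol_lfd, threshold = 0.25, min_distance = 5)
position_error(det, ph$particles)$mean    # mean 3D error in micrometers
```

The one-command demonstration (phantoms → projection → 40 training steps →
prediction → metrics) is deterministic in its seed:

```sh
Rscript exec/lfrecon demo --seed 7
```

which ends with (numbers printed by this exact command):

```
demo (seed 7): network psnr 23.93 dB vs refocusing 25.46 dB
```

Both numbers are brightness-calibrated PSNRs of the two reconstructions of a
held-out bead phantom against its ground-truth volume. The demo is a smoke
test: after only 40 optimization steps the partially trained generator is
still below the refocusing baseline; the package's full scaled-down study
(200 alternating steps, run by `scripts/acceptance.R` and the test suite)
brings the network to parity and, at the pinned study seed, slightly ahead —
while its decisive advantage shows up in axial particle localization rather
than raw PSNR (see the acceptance outputs below). The full metric reports
(`psnr`, `ssim`, `msssim`, `lpips`, `mse`, `pearson`) for both
reconstructions are in the returned object of `run_demo()`.

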