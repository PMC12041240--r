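---
title: "Light-field reconstruction with lfrecon: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Light-field reconstruction with lfrecon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfrecon)
```

## The problem

A light-field microscope places a microlens array at the image plane, so a
single 2D sensor exposure encodes both the lateral position (which lenslet)
and the propagation angle (which pixel behind that lenslet) of the collected
light. One frame therefore contains a full — but entangled — 3D snapshot.
Recovering the volume from that frame is an ill-posed inverse problem:
classical answers are synthetic-aperture refocusing (fast, but with poor
axial resolution) and Richardson–Lucy light-field deconvolution (better, but
slow and still diffraction-limited by the lenslet sampling). `lfrecon`
implements, at desk scale, a learned alternative: a generative-adversarial
encoder–decoder that maps the stack of sub-aperture views directly to a
depth stack, trained on simulated pairs produced by a wave-optics forward
model — together with the classical baselines, the evaluation metrics, and a
particle-velocimetry analysis stage, so the whole comparison can be run
end-to-end from synthetic phantoms on one CPU.

## Forward model

The forward operator is a kernel bank `H[d, i, j, ·, ·]`: the sensor response
of a unit point source at depth plane `d` sitting at sub-lenslet phase
`(i, j)`. The light-field PSF is shift-invariant only over integer lenslet
pitches, which is why the phase indices are part of the kernel index. Two
models are provided:

* `wave_optics` — scalar diffraction: the defocused pupil field is propagated
  to the native image plane (angular-spectrum defocus with cutoff NA/λ),
  multiplied by the microlens quadratic phase (focal length
  `p / (2 tan θ_max)` with `sin θ_max = NA / n`), Fresnel-propagated to the
  sensor, squared, and binned into sensor pixels (`psf_oversample` sub-samples
  per pixel, default 4).
* `gaussian_defocus` — a fast parametric surrogate with the same geometric
  skeleton: each view `(u, v)` sees the source displaced by the disparity
  `slope · z · (u − c)` (the slope follows from the marginal-ray tangent) and
  its energy is partitioned over lenslet cells by an integrated Gaussian of
  width `psf_sigma_px` (default 0.7 px). At focus essentially all mass stays
  under the source lenslet; away from focus the parallax spreads it — the
  same structure refocusing inverts, which makes this model the right unit
  for fast, exactly analyzable tests.

Each `(depth, phase)` kernel is normalized to unit mass, so projection
conserves total intensity exactly; `lf_project()` uses circular convolution,
making the operator linear, energy conserving, and shift-equivariant over
one pitch to machine precision, with `lf_backproject()` its exact adjoint
(verified to 1e-6 relative in the tests — the precondition for the
Richardson–Lucy update to be correct).

Depth-plane count and spacing are configuration (`z_planes`), never
constants: published examples range from a 61-slice microscale stack to
centimeter-scale PIV volumes.

## Phantoms: what the generator emulates, and what it does not

All phantom generators are pure functions of their `phantom_spec()` (seed
included) and return the machine-readable ground truth needed to score any
downstream stage:

* **Filaments** (`make_tubulins`): random gently-curved cubic splines
  rasterized with a Gaussian cross-section whose FWHM equals the requested
  diameter. The source work never describes its filament generator, so the
  curve law (spline through uniform control points, `wiggle` amplitude) is
  this package's choice; density levels are likewise free parameters.
* **Beads** (`make_beads`): isolated Gaussian spots with rejection-sampled
  minimum separation; centroids coincide with the returned positions to
  sub-voxel accuracy. Physical 100-nm beads are below the voxel scale, so a
  floor of 0.7 voxel on the rasterized width keeps them representable.
* **Cortical stand-in** (`make_neuro_volume`): ellipsoidal somata whose
  brightness follows calcium traces (Poisson spikes convolved with a
  single-exponential kernel, 10 Hz frame rate, baseline 1), with optional
  neuropil haze and dark vessel tubes. This reproduces only the statistical
  structure the mesoscale test needs — it is *not* a tissue simulator: no
  scattering, no hemodynamics, no realistic background spectra.
* **Particle fields** (`make_particle_pair`): frame-1 counts are Poisson with
  mean `density × lenslet count` (the particles-per-microlens convention,
  e.g. 0.03 PPM), advected by an analytic flow — uniform, a
  lid-driven-cavity-like shear, or a solid-body vortex in the row–z plane
  (rotation applied exactly, not by an Euler step). The analytic flow sampled
  at voxel centers is the ground truth; no turbulence, boundary layers, or
  CFD are emulated.

Consequently, passing tests demonstrate correctness of the algorithms under
known, noise-free or mildly noisy conditions; they do not certify performance
on experimental data with camera noise, aberrations, or model mismatch (a
Poisson/read-noise hook exists in the phantoms but is off by default).

## The network

The generator consumes the `N²` sub-aperture views as input channels
(`decompose_views()` is a bit-exact bijection with `recompose_views()`).
Encoder: three 3×3 convolution + batch-normalization + ReLU blocks with
widths `C, 2C, 4C` (`base_channels = C`, configurable; the source does not
state widths). Decoder: the mirror image, with skip connections at stages 1
and 3 that concatenate the *even-indexed channels* of the encoder stage onto
the decoder stage input (`skip_channel_rule = "even_channels"`; the
alternative full-channel rule is selectable, since the phrase in the source
is ambiguous). Upsampling to factor `N` runs two parallel branches — bicubic
interpolation + 3×3 convolution, and sub-pixel (pixel-shuffle) convolution —
blended 0.5/0.5. The blend is what suppresses the checkerboard harmonic:
with constant input, an untrained pixel-shuffle branch tiles per-channel
constants at the shuffle period, and averaging it with the smooth bicubic
branch halves that harmonic (a property test averages over ten seeds).
Non-power-of-two factors (e.g. 13) are realized by greedy 2/3 shuffle stages
plus an exact bicubic resize to the target size, so the output-shape
contract (`h·N × w·N × D`) holds for any integer factor.

The discriminator scores volumes in (0, 1): five two-convolution blocks
(second convolution stride 2), first block as wide as the slice count, later
blocks `20·2^k` with `k = 1` at the second block, then global average
pooling and two dense (1×1 convolution) layers — 20 ReLU units and a sigmoid
output. Per the printed adversarial objective it sees volumes only
(unconditioned on the light field).

Because no deep-learning framework exists in this R environment, both
networks run on a package-internal reverse-mode autodiff engine: a global
tape of op nodes over plain R arrays (layout `H × W × C × batch`), with the
convolution forward/backward passes in compiled code. Gradients of every op
(including batch normalization and the windowed MS-SSIM) are checked against
finite differences and closed forms in the test suite.

## The objective

The generator minimizes

```
alpha * BerHu(G(x), y) + beta * (1 - MS-SSIM(G(x), y)) + gamma * BCE(D(G(x)), 1)
```

with defaults `alpha = 3`, `beta = 1`, `gamma = 0.5`. BerHu (reverse Huber)
is L1 inside `|d| ≤ c` and `(d² + c²)/(2c)` outside, `c = 0.1`; both branches
meet at `c`, and the sum convention over pixels is kept. MS-SSIM multiplies
contrast and structure factors over `M` dyadic scales (luminance only at the
coarsest), computed from Gaussian-window local statistics (window 11,
σ = 1.5, all configurable) with the published five-scale exponents,
truncated and renormalized for smaller `M`; the *loss* is `1 − MS-SSIM`,
since the printed expression is a similarity. For 3-D stacks the component
maps are pooled across slices before exponentiation — a deliberate
simplification of the per-slice-average alternative that keeps the loss a
single smooth scalar. Factor means are clamped at `1e-6` before fractional
exponentiation, and scores are clamped to `[1e-7, 1 − 1e-7]` inside
logarithms. The discriminator maximizes
`½ log D(y) + ½ log(1 − D(G(x)))` (labels hard 1/0), and the generator's
adversarial term is the non-saturating `−log D(G(x))`.

Every training pair is min-max normalized to (−1, 1)
(`2(x − min)/(max − min) − 1`) before entering the network; predictions are
mapped back to `[0, 1]`.

## Training procedure and its desk-scale parameters

`train_gan()` alternates one discriminator step (on a detached generator
output, so the generator is frozen) with one generator step (gradients flow
through the critic but only generator parameters are updated), using AdamW
(β = 0.9/0.999, decoupled weight decay 1e-2) with the staircase schedule
`lr · 0.95^⌊epoch/5⌋` and batch size 2 — all the published defaults.
Training is fully deterministic under a fixed seed (single device, seeded
shuffling, deterministic kernels), every loss term is logged per step, and a
non-finite loss aborts with the last checkpoint.

The published learning rates (1e-6 generator / 1e-7 discriminator) are tuned
for a 400-hour full-scale run; they remain the defaults, but the package's
own scaled-down study — 8 bead-phantom pairs, 16×16 views, 5 depth slices,
200 alternating steps, `base_channels = 16`, one convolution per block —
uses 1e-2 / 1e-3, without which a freshly initialized network cannot move
measurably in 200 steps. The staircase decay is also idle there
(`lr_decay_every` beyond the run length): an "epoch" over 8 pairs at batch 2
is only 4 steps, so the published every-5-epochs decay would otherwise halve
the rate over a 200-step run, a regime it was never meant for. At these
sizes a full run takes a few minutes on one CPU. The comparison against the
refocusing baseline applies a least-squares affine brightness calibration to
*both* volumes before PSNR, because reconstruction intensity scales are
arbitrary; a min-max stretch was rejected as it asymmetrically amplifies the
residual texture of near-flat predictions. Across independent phantom
families the 200-step network sits at PSNR parity with the
(oracle-disparity) refocusing baseline — slightly ahead at the pinned study
seed — whereas its axial-localization advantage (next section) is large and
holds for every family tried; a short toy run demonstrates the training
machinery, not the full-scale model's superiority.

## Metrics

`compute_metrics()` reports PSNR (`10 log10(MAX_I²/MSE)`, with identical
inputs capped at 99 dB and flagged rather than infinite), SSIM (the printed
global-statistics form by default; a sliding-window mode is available),
MS-SSIM, MSE (mean convention), Pearson correlation, and a perceptual
feature distance: layer-weighted squared differences of channel-normalized
feature maps from a *seeded random* convolutional stack. That backbone keeps
the metric deterministic and download-free and preserves the pseudometric
properties (non-negative, symmetric, zero on identity), but its absolute
values are not comparable to published numbers obtained with pretrained
backbones — only rankings within one configuration are meaningful.

`decorrelation_kc()` estimates resolution as the largest refined peak of the
decorrelation curves `d(r) = Σ_{|k|<r}|A| / sqrt(Σ|A|²·N(r))` under a series
of ten log-spaced Gaussian high-pass filters, with Hann apodization, plateau
handling (rightmost near-maximal radius), and parabolic peak refinement;
`k_c = 1` is Nyquist. `fwhm_profile()` linearly interpolates the half-maximum
crossings; `dff_traces()` computes `ΔF/F0` with `F0` the time average of the
per-frame ROI mean — the source text describes `F` both as a per-frame value
and a time average, and the per-frame reading is the only one that yields a
trace.

## PIV stage

`localize_particles()` finds thresholded local maxima with greedy
non-maximum suppression and refines them to background-suppressed intensity
centroids; `position_error()` matches detections to ground truth greedily by
nearest distance (closest pairs first, optional gate) and reports per-pair
Euclidean errors — the axial-resolution comparison places five beads on a
depth column and shows deconvolution (or the network) localizing them
several times better than refocusing. `optical_flow_3d()` is a 3-D
Horn–Schunck solver: linearized brightness constancy plus quadratic
smoothness, Jacobi fixed-point iterations on the flow increment, two warping
passes per level on a Gaussian pyramid. The smoothness weight `lambda`,
iteration count and pyramid depth are free parameters; at the defaults the
solver recovers a unit shift of a smooth particle volume within 10% and the
angular speed of a vortex phantom within 15% in the particle-weighted core
annulus. Velocities carry explicit units (`vox/frame` vs `um/s`) and are
converted only at reporting.

## Numerical choices and degenerate inputs

* Richardson–Lucy: uniform positive initialization, `1e-12` division guard,
  flat-field (adjoint-of-ones) normalization, optional KL data-fit trace
  (non-increasing on noiseless input).
* Refocusing: bilinear view shifts with edge clamping; the disparity slope is
  derived from the same geometry as the PSF, so the baseline and the
  simulator agree by construction; refocused planes are bicubically upsampled
  to sensor resolution by default.
* `normalize_unit()` refuses constant inputs; Pearson refuses constant
  signals; `fwhm_profile()` requires an interior maximum and both half
  crossings; `decorrelation_kc()` refuses constant images; empty volumes
  localize to an empty particle set (not an error).
* Bicubic resizing uses Catmull-Rom weights with edge clamping and
  renormalization, implemented as two cached matrix contractions so its
  adjoint (needed for backpropagation) is exact.

## Known limitations

* The wave-optics PSF is scalar and aberration-free; no vectorial high-NA
  effects, no camera noise physics.
* The autodiff engine is single-threaded and define-by-run; it is sized for
  desk-scale experiments (minutes per 200-step run), not for the published
  full-scale training (2164 pairs of 208×208×61 volumes over hundreds of
  hours), and no attempt is made to reproduce published headline metric
  values, which require the authors' acquired datasets and GPU-scale
  training.
* The Horn–Schunck flow underestimates large displacements when the pyramid
  is too shallow; parameters must be chosen per problem scale.
* The perceptual metric's absolute scale is backbone-specific (see above).
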