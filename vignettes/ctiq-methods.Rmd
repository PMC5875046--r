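---
title: "ctiq: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ctiq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctiq)
```

## What the package models

Iterative CT reconstruction (ASiR blends, model-based iterative
reconstruction / MBIR) trades reconstruction complexity for noise, and the
standard way to quantify that trade is a phantom study: scan a Catphan 600
(plus a fat-equivalent oval ring, to mimic an adult abdomen) and an
anthropomorphic abdomen phantom across a CTDIvol x pitch grid, reconstruct
with each algorithm, and measure noise, contrast-to-noise ratio (CNR),
insert Hounsfield units and the modulation transfer function (MTF) from
repeated acquisitions. `ctiq` re-creates that entire analysis chain on
*synthetic* phantom images with known ground truth, so every stage — ROI
statistics, the edge-method MTF, the log-scale condition comparison with
Dunnett adjustment — is verifiable against analytic oracles instead of
proprietary scanner data.

What is deliberately **not** modelled: tomographic reconstruction itself
(no sinograms; FBP/ASiR/MBIR are emulated in the image domain), beam
hardening, helical cone-beam geometry, scanner dosimetry, noise-power
spectra and texture realism, and anatomically realistic anatomy (the
abdomen layout is an ellipse with organ disks). Passing tests therefore
demonstrate that the *measurement and statistics pipeline* is correct and
well calibrated, not that the generator reproduces any particular
scanner's images.

## The synthetic generator

A `phantom_layout` is a scene of HU-labelled primitives: an elliptical
body, an optional annular ring (fat-equivalent, -90 HU), and features
(disks, annuli, bar patterns). `render_layout()` rasterizes the scene at
`dfov * 10 / matrix` mm/pixel with pixel centres at `(i - 0.5) * spacing`
from the top-left corner; edge pixels are area-weighted on a 4x4 subpixel
grid (the rendered area of a 12.2 mm disk matches `pi r^2` to < 0.5%).

`simulate_stack()` turns a rendered layout into `N` replicate acquisitions
under a `scan_condition` (algorithm, CTDIvol, pitch) and an
`algorithm_model`:

1. **HU bias** `hu_bias(HU, dose)` is added pixelwise (MBIR defaults to
   -10 HU for |HU| <= 400, attenuated in proportion to 400/|HU| above
   that, and doubled at 1 mGy fading to nominal at >= 3 mGy — the
   "material HU sensitivity at low dose" behaviour reported for MBIR).
2. **Blur**: isotropic Gaussian PSF of `psf_sigma(dose)` mm, applied as a
   separable truncated-kernel convolution (kernel renormalized to unit
   sum, so flat regions are preserved exactly; replicate-edge padding).
3. **Noise**: zero-mean Gaussian with standard deviation
   `sigma(d) = noise_factor(d) * noise_ref * (dose_ref/d)^0.5` combined in
   quadrature with an electronic floor — the standard quantum-noise
   scaling; the floor is available to emulate low-dose anomalies and
   defaults to 0. White noise is optionally shaped by a Gaussian of
   correlation length 0.6 mm (renormalized so the *marginal* SD is exact);
   the correlation length is a free texture parameter, recorded with the
   stack, since no noise-power spectrum is being matched.

Noise is drawn per replicate from counter-based substreams of the master
seed, so replicate `k` is bit-reproducible in isolation and a longer stack
shares its leading replicates with a shorter one.

### Default calibration

The defaults in `builtin_algorithm_models()` were fixed once, against the
published summary scale of a Catphan 600 iterative-reconstruction study
(the tables bundled as `catphan_benchmark_means()`):

* FBP: `noise_ref = exp(4.20)` HU at 1 mGy — the published FBP log-noise
  at 1 mGy; the published FBP column follows `dose^-1/2` almost exactly,
  so the default exponent is 0.5.
* ASiR 20/40/70%: noise factors 0.85 / 0.75 / 0.60 (consistent with the
  reported 1.2/1.3/1.8-fold CNR gains).
* MBIR: noise factor 0.2 at <= 3 mGy (the five-fold low-dose advantage),
  rising log-linearly to 0.5 at 24 mGy.
* PSFs: FBP/ASiR are dose-insensitive (0.60-0.64 mm Gaussian sigma); the
  MBIR PSF improves log-linearly from 0.66 mm at 1 mGy to 0.12 mm at
  24 mGy, which reproduces the reported pattern of MBIR resolution
  improving with dose and a several-fold MTF ratio over FBP at high dose.
* The CTP515 "1%" supraslice target is rendered at +10 HU over the 100 HU
  background — the conventional reading of 1% contrast on a 1000-HU
  scale; the true value is not published, so it is a constructor argument.

All of these are ordinary arguments and can be overridden per model.

## ROI metrics

* **Noise** (`measure_noise`): the mean of the sample SDs (n-1
  denominator) of three 0.4 cm^2 circular ROIs in the background material,
  averaged over replicates. A pixel belongs to an ROI iff its centre lies
  in the circle; ROIs under 10 pixels are rejected as unstable.
* **CNR** (`measure_cnr`): `|object HU - background HU| / background SD`
  with the target ROI on the low-contrast disk and three identical ROIs in
  the immediate background. The background SD pools the background pixels
  by default — the source protocol does not say whether the three ROI SDs
  were pooled or averaged, pooling is more stable, and `pooled_sd = FALSE`
  switches to the average.
* **Insert HU** (`measure_hu`): mean and SD per material over interior
  ROIs (70% of the insert radius), pooled across replicates;
  `hu_difference_from_reference()` subtracts the FBP @ 24 mGy reference
  per material.
* **Fold improvement** (`fold_improvement`): noise ratios are
  reference/value and CNR ratios value/reference, so > 1 always reads
  "better than FBP".

## Edge-method MTF

`extract_edge_profiles()` draws four 14 mm profiles from the centre of the
air insert outward — two horizontal, two diagonal (45/225 degrees; the
source method does not specify the diagonal angles) — sampling by bilinear
interpolation at half-pixel steps. The ESF is differentiated by central
differences (`esf_to_lsf`), the far-field tail mean (last 10% of samples)
is subtracted so an unsettled edge keeps a finite DC, and `lsf_to_mtf`
normalizes the zero-padded FFT magnitude at zero frequency.
`aggregate_mtf()` sums FFT magnitudes over all profiles and replicates
*before* normalizing (sum-then-normalize), which is the published
smoothing order and is regression-tested against the
normalize-then-average alternative.

### Why `measure_mtf()` self-calibrates

The raw chain attenuates the spectrum by factors that have nothing to do
with the reconstruction PSF: the area-weighted raster acts as a pixel
aperture (~ `sinc(f * spacing)`), bilinear interpolation as a
phase-dependent triangle kernel, and the central difference as
`sinc(2 f step)`; together ~0.6 at the frequencies of interest. Because
every step is linear and discrete-kernel blur commutes exactly with
interpolation (both are convolutions), running the *identical* chain on
the noiseless, unblurred render of the same layout measures exactly those
factors, and dividing the two curves isolates the PSF transfer. With
`correction = "none"` the uncorrected system curve is returned instead.

Two further estimator choices control noise:

* replicates image the same deterministic geometry, so their complex
  spectra are averaged coherently per orientation, and the residual noise
  power (estimated from the across-replicate scatter) is removed from the
  squared magnitude — summed noisy magnitudes are otherwise biased upward
  where modulation is low (Rician folding);
* the zero-frequency magnitude is anchored on the ESF plateau contrast
  (first vs last 10% of samples, replicate-averaged) rather than the raw
  DC bin, whose tail-baseline noise would multiply the entire normalized
  curve.

With these choices the recovered curve matches the analytic Gaussian
transform `exp(-2 pi^2 sigma^2 f^2)` of a 0.8 mm PSF to a few hundredths
of modulation under the default calibrated noise (asserted in the test
suite); the remaining systematic (< 0.04 modulation) is edge-curvature
and discretization residue. The corrected curve is set to `NA` where the
reference falls below 0.05 — beyond that the deconvolution is ill
conditioned.

MTF comparisons are evaluated at 5 lp/cm by linear interpolation
(`mtf_at_frequency`); 5.625 lp/cm, the other conventional grid point,
is just as accessible since the argument is free. Bar patterns
(`bar_pattern_modulation`) report peak-to-trough modulation at the known
bar/gap centres relative to the plateau contrast, validated against a
brute-force convolution oracle.

## Statistics

Noise and MTF are analyzed on the natural-log scale (positive,
right-skewed; the published log-noise magnitudes are natural-log), CNR on
the raw scale. `estimate_condition_means()` is the balanced-design
closed form a mixed model degenerates to on single-level replicate data:
per-condition mean with a t interval from between-replicate variance. The
full mixed-model machinery (unbalanced designs, REML, explicit covariance
structures) is out of scope, and the source analysis does not state its
covariance structure.

`difference_vs_reference()` contrasts every condition against a reference
cell (image-quality baseline MBIR @ 1 mGy; MTF ratios use FBP within each
pitch x dose cell and are back-transformed with
`exp(difference of log means)` — exactly the ratio of geometric means).
With replicate records it pools the within-condition variance; fed a
published summary table (estimate/LCL/UCL only) it recovers SEs from CI
half-widths, which reproduces the published contrast tables exactly on
the estimates and to ~±0.01 on the intervals (printed-rounding noise).

The Dunnett single-step two-sided adjustment,
`P(max_j |T_j| >= |t|)` under the equicorrelated multivariate t null, is
computed by deterministic quadrature: Gauss–Hermite (96 nodes) over the
shared normal factor crossed with a 256-point quantile-midpoint rule over
the chi scale. `k = 1` reduces exactly to `2 * pt(-|t|, df)`; rho = 0 at
large df reproduces the Sidak bound; the balanced shared-reference
correlation 0.5 is the default and overridable. The implementation is
cross-checked in the tests against `mvtnorm::pmvt` and a 10^7-draw
Monte-Carlo oracle, and the end-to-end null pipeline holds the family-wise
error at 5% over 500 reseeded runs.

## Numerical and scale choices

* Rasterization supersampling 4x4; Gaussian kernels truncated at 4 sigma
  and renormalized; probabilities clamped to [0, 1].
* Degenerate inputs: zero noise and zero PSF reproduce the biased render
  bit-exactly; zero background SD makes CNR error out rather than return
  infinity; zero-variance cells give ratio tables with p in {0, 1}.
* Test and validation runs use 128–512 pixel matrices and 1–20
  replicates, chosen so that each tolerance sits at >= 3 sampling
  standard deviations under the stated conditions; sigma-recovery checks
  use uncorrelated noise because their chi-bound tolerances assume
  independent pixels, and the fold-improvement check uses a
  high-contrast (dHU = 100) disk so contrast-estimation error is
  negligible next to the noise ratio under test.
* The portable stack container stores rounded int16 HU rasters plus a
  JSON sidecar; rounding is lossless for integer-valued HU (real CT data)
  but not for the generator's fractional anti-aliased edge values.

## Known limitations

* The emulation is linear and shift-invariant per condition; real
  iterative reconstruction is neither, which is precisely why FFT metrics
  on it are debated. The package measures what the protocol measures.
* The MTF sampling correction assumes the layout (hence the reference
  render) is known — true for synthetic stacks; for imported scanner
  stacks only the uncorrected system curve is meaningful.
* Pitch is metadata unless per-pitch multipliers are configured; no
  attempt is made to model pitch physics.
* The abdomen layout supports the protocol's ROI placements but is not
  anatomically realistic.
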