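# ctiq

CT image-quality evaluation for reconstruction-algorithm dose studies, on
synthetic phantoms with known ground truth.

Phantom studies of iterative CT reconstruction (ASiR blends, model-based
iterative reconstruction) quantify how much dose can be removed before
image quality degrades: a Catphan 600 wrapped in a fat-equivalent ring is
scanned repeatedly across a CTDIvol × pitch grid, and noise, CNR, insert
HU and spatial resolution are compared across algorithms. `ctiq`
implements that entire analysis chain — and a synthetic phantom-image
generator that emulates it — so every stage can be validated against
analytic oracles rather than proprietary scanner data. It is aimed at
medical-physics and image-analysis developers who need a tested, seedable
reference implementation of the standard phantom metrics.

The core quantities, in the field's notation:

* **Noise** — mean of the sample SDs of three 0.4 cm² background ROIs.
* **CNR** — `|object HU − background HU| / background SD` (low-contrast
  supraslice target, three identical background ROIs).
* **MTF** — edge method: 14 mm profiles from the centre of the air insert
  (two horizontal, two diagonal) give the ESF; the LSF is its derivative;
  `MTF(f) = |FFT(LSF)|` normalized to zero frequency, with FFT magnitudes
  summed over 10 replicates × 4 profiles before normalization. Evaluated
  at 5 lp/cm for cross-algorithm ratios.
* **Statistics** — noise and MTF analyzed as natural logs; per-condition
  means with 95% t intervals; differences against a reference cell
  (MBIR @ 1 mGy baseline, or FBP for MTF ratios, back-transformed to
  ratios); Dunnett single-step adjustment for the family of contrasts,
  computed by deterministic quadrature of the equicorrelated
  multivariate-t max-|T| probability.
* **Generator** — HU-labelled geometric scenes rendered with
  area-weighted edges; per-algorithm emulation models with noise
  `σ(d) = factor(d)·σ_ref·(d_ref/d)^½ ⊕ floor`, Gaussian PSF `σ_psf(d)`,
  material HU bias, and optionally correlated noise texture.

## Worked example

Simulate ten replicate acquisitions of the sensitometry module at 3 mGy
with the calibrated FBP and MBIR models, then measure noise, insert HU
and the MTF:

```r
library(ctiq)
models <- builtin_algorithm_models()
layout <- builtin_layouts("ctp404")
stacks <- lapply(c(FBP = "FBP", MBIR = "MBIR"), function(alg) {
  simulate_stack(layout, scan_condition(alg, 3), models[[alg]],
                 n_replicates = 10, seed = 42)
})

rois <- background_rois(area_cm2 = 0.4, radius_mm = 30)
round(sapply(stacks, function(s) measure_noise(s, rois)$summary), 2)
#>   FBP  MBIR
#> 36.58  7.32

hu <- do.call(rbind, lapply(stacks, measure_hu, rois = insert_rois(layout)))
subset(hu, material %in% c("acrylic", "Teflon"))[, 1:4]
#>  material algorithm  mean   sd
#>   acrylic       FBP 118.7 38.4
#>    Teflon       FBP 992.1 40.1
#>   acrylic      MBIR 109.7  7.7
#>    Teflon      MBIR 986.4  8.0

round(mtf_at_frequency(measure_mtf(stacks$MBIR), 5), 3)
#> [1] 0.363
round(mtf_at_frequency(measure_mtf(stacks$FBP), 5), 3)
#> [1] 0.148
```

Read: at 3 mGy the MBIR emulation is five-fold less noisy than FBP
(36.6 → 7.3 HU — `fold_improvement()` reports the ratio directly), its
acrylic HU sits ~10 HU below FBP's (the configured MBIR bias), and its
MTF at 5 lp/cm is higher (the MBIR PSF sharpens with dose while FBP's is
fixed). `run_experiment()` executes the full algorithm × dose × pitch
grid and emits the comparison tables (noise/CNR vs the MBIR @ 1 mGy
baseline with Dunnett-adjusted p-values, fold-improvement, HU deltas vs
FBP @ 24 mGy, MTF ratio tables) as CSV plus a checksummed manifest via
`write_report()`; `inst/cli/ctiq.R` wraps the same functions as
`simulate` / `measure` / `compare` / `run-all` verbs.

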