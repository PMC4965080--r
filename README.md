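# dkihisto

Diffusional kurtosis imaging (DKI) parameter mapping with Rician
noise-floor compensation, positive-pixel histology segmentation, and the
ROI-level statistics that connect them — plus calibrated synthetic-data
generators so the whole pipeline runs and validates without patient data.

## Who this is for

Imaging–pathology correlation studies of the prostate ask whether
non-invasive diffusion MRI parameters track the tissue composition seen on
whole-mount histology after surgery. `dkihisto` implements the quantitative
machinery of such a study as reusable, tested R functions:

* **Kurtosis model** — signal decay
  `S(b) = S0 · exp(−b·D_app + (1/6)·b²·D_app²·K_app)` at b-values
  150/600/1050/1500 s/mm²; `D_app` (×10⁻³ mm²/s) falls in dense tissue,
  `K_app` (unitless) rises with tissue heterogeneity.
* **Noise compensation** — the noise level `n` is estimated from a
  noise-only acquisition (25×25 adaptive Wiener smoothing, then a
  convention converting the Rayleigh mean to `n`), and voxels are fitted
  against the biased signal `√(S² + n²)` by box-bounded
  Levenberg–Marquardt least squares.
* **Histology composition** — H&E pixels inside an ROI are classified by a
  hue/saturation/value rule (hue centre 0.7, window 0.35) into cellularity
  (positive), fibromuscular stroma (negative) and luminal space
  (unstained); fractional areas partition the ROI and sum to one.
* **Statistics** — Wilcoxon rank-sum comparisons (tumor vs normal,
  high-grade vs low-grade Gleason groups) and Spearman correlations
  between each tissue fraction and each DKI median, as a tidy 22-row
  results table.
* **Synthetic data** — DWI phantoms with Rician noise and matched
  noise-only volumes, exact-count histology images, and 20-patient cohorts
  whose group medians and correlation signs are calibrated to published
  prostate operating points.

## Worked example

```r
library(dkihisto)

# Forward-generate a voxel at normal peripheral-zone operating values and
# fit it back
b <- c(150, 600, 1050, 1500)
signals <- dki_signal(b, s0 = 100, d_app = 2.07e-3, k_app = 0.59)
round(signals, 3)
#> [1] 74.006 33.611 18.105 11.568

fit <- fit_dki_voxel(signals, b)
round(fit$params, 6)
#>       s0    d_app    k_app
#> 1.00e+02 2.07e-03 5.90e-01

# Synthetic histology at a programmed composition, recovered by
# positive-pixel segmentation
h <- simulate_histology_image(c(100, 100), c(0.39, 0.52, 0.09), seed = 1)
compute_tissue_fractions(classify_pixels(h$image))
#> # A tibble: 1 × 4
#>   cellularity   fsm luminal n_pixels
#> 1        0.39  0.52    0.09    10000

# A simulated 20-patient cohort and its significant correlations
co <- simulate_cohort(n_patients = 20, seed = 42)
res <- run_study_analyses(co)
dplyr::filter(res, p_value < 0.05, comparison == "correlation",
              stratum == "tumor")
#>   comparison  variable                 stratum statistic p_value    n1
#> 1 correlation median_d_app~luminal     tumor       0.593 4.48e-5    41
#> 2 correlation median_k_app~cellularity tumor       0.413 7.24e-3    41
#> 3 correlation median_k_app~fsm         tumor      -0.466 2.13e-3    41
```

The fitted voxel returns the generating parameters (`D_app` 2.07 ×10⁻³
mm²/s, `K_app` 0.59) to solver precision; the segmentation returns exactly
the programmed fractions because the generator paints exact class counts;
and the simulated tumor ROIs show the expected positive kurtosis–cellularity
and negative kurtosis–stroma rank correlations.

`run_pipeline(pipeline_config(n_patients = 20, seed = 7))` chains
everything end to end: cohort simulation → per-ROI noisy phantom fitting →
per-ROI histology segmentation → the 22-row analysis grid. A thin CLI over
the same functions lives at `inst/scripts/dki-pipeline.R`
(`simulate-dwi`, `simulate-histology`, `simulate-cohort`, `fit`, `segment`,
`analyze`, `pipeline`).

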