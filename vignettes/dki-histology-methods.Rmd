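---
title: "Methods: kurtosis parameter mapping, tissue-composition segmentation, and the simulated study pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kurtosis parameter mapping, tissue-composition segmentation, and the simulated study pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dkihisto)
```

`dkihisto` implements the quantitative core of a prostate imaging–pathology
comparison: diffusional kurtosis imaging (DKI) parameter maps computed from
multi-b diffusion-weighted MRI with Rician noise-floor compensation,
fractional tissue composition measured from H&E-stained whole-mount sections
by positive-pixel colour segmentation, and the region-of-interest (ROI)
level statistics linking the two. Because the patient data behind such a
study cannot be redistributed, the package ships calibrated synthetic-data
generators that emulate each data type, so every stage is exercised and
validated end to end by code alone.

## The kurtosis signal model

Diffusion-weighted signal decay is modelled to second order in the
diffusion weighting $b$ (s/mm²):

$$S(b) = S_0 \exp\!\left(-b\,D_{app} + \tfrac{1}{6} b^2 D_{app}^2 K_{app}\right),$$

with $S_0$ the unattenuated signal, $D_{app}$ the apparent diffusion
coefficient (mm²/s; reported in $10^{-3}$ mm²/s), and $K_{app}$ the unitless
apparent kurtosis. $K_{app} = 0$ recovers the monoexponential (ADC) limit.
Three distinct b-values are the minimum for a determined fit; the default
acquisition scheme is $b = \{150, 600, 1050, 1500\}$ s/mm², which starts
above the pseudoperfusion regime ($b > 100$) and stops where the model is
still informative.

Being a truncated expansion, the model is non-monotone: beyond
$b^* = 3/(D_{app} K_{app})$ the predicted signal turns upward, which is
unphysical. `max_valid_bvalue()` computes $b^*$; volume fitting flags voxels
whose acquisition extends past the fitted $b^*$ (`beyond_bstar` status)
rather than constraining the fit, since the flag is a property of the
solution, not of the data.

## Rician noise and the compensation conventions

Magnitude MRI noise is Rician: for complex channel noise of standard
deviation $\sigma$, a measured magnitude with true signal $S$ has second
moment $S^2 + 2\sigma^2$, creating a positive floor that flattens the decay
at high $b$. The noise level is estimated from a noise-only acquisition
(Rayleigh-distributed, mean $m = \sigma\sqrt{\pi/2}$): the image is smoothed
with a pixelwise adaptive Wiener filter (the local linear minimum-MSE
"Lee" filter, 25×25 window by default, reflection padding, noise power
taken as the mean of the local variances — the filter family is standard
but the exact formula had to be fixed here), the smoothed mean $m$ is
taken, and $m$ is converted to the compensation parameter $n$ used in the
biased-signal model $S_n = \sqrt{S^2 + n^2}$.

Three conversion conventions are provided:

| convention | $n$ | matched quantity |
|---|---|---|
| `rician_mean` (default) | $m\sqrt{2/\pi} = \sigma$ | mean of Rician magnitudes, $E[M] \approx \sqrt{S^2+\sigma^2}$ |
| `rayleigh_rms` | $2m/\sqrt{\pi} = \sqrt{2}\,\sigma$ | RMS of Rician magnitudes, $\sqrt{S^2+2\sigma^2}$ |
| `paper_literal` | $m\,\pi/2$ | literal "divide by $2/\pi$" convention of some legacy pipelines |

The default deserves a word. The fit minimises squared deviations between
the *measured* magnitudes and $\sqrt{\text{model}^2+n^2}$; least squares
estimates the conditional *mean* of the data. The Rician mean is
$\approx\sqrt{S^2+\sigma^2}$ down to quite low signal-to-noise, so
$n = \sigma$ makes the biased model track what least squares actually fits.
The RMS-matched choice $n = \sqrt{2}\sigma$ is self-consistent with the
second moment instead, and therefore overcorrects a mean-fitted model by
almost exactly as much as no compensation undercorrects it. The test suite
makes this concrete by fitting exact Rician expectation values (closed
form, no Monte-Carlo noise): at $S_0/\sigma = 50$ the systematic $K_{app}$
error is $+0.006$ uncompensated, $-0.006$ with the RMS convention, and
$\approx 0$ with `rician_mean`; at $S_0/\sigma = 12$ the uncompensated
error grows to $+0.10$ while `rician_mean` stays at $+0.015$. All three
conventions remain selectable because published pipelines differ, and the
noise-only-image estimation path itself is identical across them.

A consequence worth stating plainly: with four b-values and three free
parameters, the noise floor's systematic damage is absorbed almost
entirely by the curvature term, i.e. by $K_{app}$. $D_{app}$ is nearly
unbiased with or without compensation at clinical SNR — at
$S_0/\sigma = 50$ the systematic compensated-vs-uncompensated difference
in $D_{app}$ is of order $10^{-7}$ mm²/s, more than an order of magnitude
below the Monte-Carlo spread of a 500-voxel median. A simulation of
realistic size therefore cannot rank the two estimators on $D_{app}$ bias;
one acceptance check phrased that way remains unmet by design rather than
by defect, while the deterministic expectation-fit ordering above, and the
end-to-end recovery bounds below, are both verified.

## Voxelwise fitting

Each voxel is fitted independently (no spatial regularisation) by
box-bounded least squares on
$\sum_b \big(S_b^{meas} - \sqrt{S(b)^2 + n^2}\big)^2$ using a bounded
Levenberg–Marquardt solver; with $n = 0$ this is ordinary least squares on
the noise-free model. Accepted steps decrease the cost monotonically
(`rss_trace` records it), and identical inputs give bit-identical maps.

* **Initialisation.** Linear least squares on
  $\log S = c_0 + c_1 b + c_2 b^2$ gives $S_0 = e^{c_0}$, $D = -c_1$,
  $K = 6c_2/D^2$ — exact for noiseless model data, so noiseless recovery
  holds to $10^{-6}$ relative by construction plus solver tolerance.
  Non-positive signals fall back to fixed mid-range defaults
  ($D = 1.5\times10^{-3}$, $K = 0.8$).
* **Bounds.** $S_0 \in (0, 10\,\max S]$,
  $D \in [10^{-5}, 4\times10^{-3}]$ mm²/s, $K \in [0, 3]$: generous around
  reported prostate values while excluding the degenerate large-$K$ ridge.
* **Tolerances.** Relative cost/parameter tolerance $10^{-8}$, 200
  iterations — cheap at four data points and sufficient for the $10^{-6}$
  recovery contract.
* **Masking.** Voxels whose lowest-b signal is at or below $3n$ are
  skipped: they are background or noise-floor-dominated, and a pure-noise
  voxel is fitted (correctly, but uselessly) by model signal $\approx 0$.
* **Status codes.** `ok`, `skipped`, `non_converged`, `at_bound`,
  `beyond_bstar`. Skipped and non-converged voxels carry `NA` in the
  parameter maps; at-bound and beyond-$b^*$ voxels keep their values and
  are flagged, since those conditions are advisories about a usable
  solution, not failures.

## Positive-pixel segmentation

ROI pixels are converted to hue/saturation/value (hexcone transform, hue on
the circular $[0,1)$ axis). A pixel is **background** (unstained luminal
space) if saturation $< 0.05$ or value $\ge 0.94$; otherwise **positive**
(hematoxylin-stained cellularity) if its circular hue distance to the hue
centre is at most half the window, else **negative** (eosin-stained
fibromuscular stroma, FSM). Defaults: hue centre 0.7, window 0.35 — the
blue-purple band on the Aperio-style hue axis. The three labels partition
the ROI exactly, so the fractional areas
(cellularity, FSM, luminal) = (positive, negative, background)/|ROI| sum to
one identically; luminal space is equivalently the complement of the
stained classes, matching its operational definition as the difference
between total and stained area. Vendor-style weak/medium/strong positivity
tiers are deliberately collapsed to one positive class, and the per-slide
manual hue retuning used in practice is represented only as per-image
settings overrides — no auto-tuning is attempted because the original
procedure was visual. The saturation/value thresholds are declared package
defaults, not reconstructions of any vendor rule.

ROI polygons are rasterized by the even-odd rule applied to pixel centres
(0-based coordinates, centres at integer + 0.5), stated explicitly so that
fixtures are reproducible to the pixel.

## ROI statistics

The unit of analysis is the ROI, not the patient; within-patient clustering
is not modelled, and the tumor-vs-normal contrast uses the unpaired
rank-sum test despite the matched design — both choices replicate the
analysis being reimplemented and are flagged in the report header. The
rank-sum p-value is exact (full enumeration) when $n_1+n_2 \le 20$ with no
ties, otherwise a tie-corrected normal approximation with continuity
correction; the reported statistic is the rank sum $W$ of the first group.
Spearman's $\rho$ is the Pearson correlation of midranks with a
$t$-reference p-value on $n-2$ degrees of freedom. The full grid is always
22 rows: tumor-vs-normal and high-vs-low-grade comparisons of three
fractions and two DKI medians (10), plus $\rho$ for each fraction × DKI
parameter within each tissue stratum (12). No multiplicity correction is
applied, matching the original univariate analysis. A per-patient
aggregation switch is intentionally *not* defaulted on, since the original
aggregation level is not documented.

## Synthetic data: what is emulated and what is not

**DWI phantoms.** Regions (boxes/ellipsoids) carry true
$(S_0, D_{app}, K_{app})$; signals follow the forward model; Rician noise
is applied as $|(S+\varepsilon_1) + i\varepsilon_2|$ with per-channel sd
$\sigma/\sqrt{\text{averages}}$ (complex-domain averaging of 8 excitations
by default); a matched noise-only volume is generated identically with
$S = 0$. Not emulated: EPI distortion, motion, coil-combination
(non-central-$\chi$) noise, partial volume.

**Histology images.** Three clean class colours (blue-purple cellularity,
pink stroma, near-white lumina) are laid out as blobs by thresholding a
smoothed random field at the exact class counts (largest-remainder
rounding), so programmed fractions are realized to the pixel;
`textured` mode adds colour jitter. Not emulated: staining gradients,
nuclear texture, slide artifacts — so segmentation recovering the
programmed fractions exactly validates the counting logic and colour rule,
not robustness to real-slide variability.

**Cohorts.** Twenty patients by default; per patient a Gleason group
(probabilities 0.15/0.45/0.30/0.10 for 6, 3+4, 4+3, ≥8, split into
low ≤3+4 / high ≥4+3), 1–4 tumor ROIs (mean ≈ 2) with matched normal ROIs,
and ROI areas log-normal within 3.1–365.4 mm². Compositions are scaled Beta
draws matched to the reported group medians with support on the reported
ranges (concentration 8; stroma by complement, rejection-sampled into its
range). DKI medians follow linear links calibrated once from the group
median operating points (`scripts/calibrate-cohort.R` derives them):

$$D_{app} = 1.785 + 3.0\,\text{lum} - 1.3125\,\text{cell} + \varepsilon_{0.13}, \qquad
K_{app} = 0.96 + 0.75\,\text{cell} - 1.0\,\text{fsm} + \varepsilon_{0.12},$$

with $D$ in $10^{-3}$ mm²/s and noise sds chosen for within-stratum rank
correlations near the reported significant magnitudes (≈0.5–0.65). The
generator claims only to match the reported medians, ranges, and
correlation signs — the true joint law of composition and diffusion
parameters is unknown.

One composition deserves its own note. The reference tumor composition
prints as cellularity 0.39, stroma 0.5, luminal 0.09 — two decimals, one
decimal, two decimals — and sums to 0.98 as printed. The package's
reference experiments use (0.39, 0.52, 0.09): it reproduces every printed
value at its printed precision (0.52 prints as 0.5 at one decimal), sums
to one as a composition must, and leaves the two precisely-printed
components untouched. Renormalising by 0.98 instead would perturb all
three components away from their printed values.

## Pipeline and problem sizes

`run_pipeline()` chains the stages: simulate a truth cohort; per ROI,
simulate and fit a noisy DWI phantom (default 5×5 in-plane ROI,
$S_0/\sigma_{eff} = 50$, noise level estimated from a simulated 48×48
noise-only scan) and take ROI medians; simulate and segment a 60×60
exact-count histology image; assemble the measured cohort and run the
22-row analysis grid. All randomness flows from the single configured
seed, and two runs with the same configuration are bit-identical. The
default sizes keep a full 20-patient pipeline run around a minute on one
core while leaving ROI medians accurate to a few percent; they are
configuration, not constants, and scale up cleanly.

## Limitations

Scalar (direction-averaged) DKI only — no diffusion tensors or directional
kurtosis; single-coil Rician noise only; no histology↔MRI registration
(the simulator provides alignment by construction, which real studies must
earn with manual co-registration); segmentation thresholds are package
defaults rather than recovered vendor parameters; and the cohort
simulator's linear links are a calibration device, not a biophysical
model.
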