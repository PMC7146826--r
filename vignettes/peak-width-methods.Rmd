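---
title: "Peak-width biomarkers of skeletonized diffusion metrics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peak-width biomarkers of skeletonized diffusion metrics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pswm)
```

## The scientific problem

Preterm birth is associated with diffuse, generalized alterations of
white-matter microstructure that are visible in water diffusion MRI at
term-equivalent age. Rather than testing thousands of voxels, the
peak-width family of biomarkers summarises a whole-brain diffusion
metric by one number: the width of the histogram of its values over the
core white-matter skeleton, measured as the difference between the 95th
and 5th percentiles. A wider histogram means more heterogeneous tissue.
`pswm` computes six such biomarkers per subject — PSMD, PSFA, PSAD and
PSRD from the diffusion tensor, and PSNDI and PSODI from the NODDI
biophysical model — and runs the accompanying cohort analysis: age
residualization, correlation with gestational age (GA) at birth,
normality-gated group comparison with false-discovery-rate control, and
repeated stratified cross-validated logistic classification of preterm
versus term infants.

The package assumes all subject maps already live on a common voxel
grid. Registration and template construction are deliberately out of
scope: they are performed upstream with dedicated tools, and nothing in
the peak-width computation depends on how the alignment was obtained.

## Models

### Diffusion tensor

Per voxel the signal model is \(S = S_0 \exp(-b\, g^\top D g)\) with
\(D\) symmetric positive semi-definite in units of
\(10^{-3}\,\mathrm{mm^2/s}\). `fit_tensor()` estimates \(D\) by
two-pass weighted least squares on the log signal: an ordinary
least-squares pass, then a re-weighted pass with weights equal to the
squared predicted signal, the standard correction for the
heteroscedasticity that the log transform induces. Only volumes with
\(b \le 1000\,\mathrm{s/mm^2}\) enter by default, because the Gaussian
(mono-exponential) tensor approximation degrades at strong diffusion
weighting; `max_bval` is a configuration knob, and which shells fed the
tensor in any given acquisition should be reported alongside results.
Negative eigenvalues are clamped to zero after decomposition rather
than re-fit — simple, standard, and testable. From the eigenvalues
\(\lambda_1 \ge \lambda_2 \ge \lambda_3 \ge 0\):

* MD \(= (\lambda_1+\lambda_2+\lambda_3)/3\), AD \(= \lambda_1\),
  RD \(= (\lambda_2+\lambda_3)/2\);
* FA \(= \sqrt{3/2}\,\sqrt{\sum_i(\lambda_i-\mathrm{MD})^2} /
  \sqrt{\sum_i \lambda_i^2}\), defined as 0 when all eigenvalues vanish.

Voxels with non-positive signals in some volumes are fit on the
positive subset when at least 7 usable volumes remain, otherwise
flagged invalid (NaN in the output maps).

### NODDI

The three-compartment NODDI model decomposes the normalized signal as

\[
S/S_0 = (1-v_{iso})\left[v_{ic} A_{ic} + (1-v_{ic}) A_{ec}\right]
        + v_{iso} e^{-b d_{iso}},
\]

where \(A_{ic}\) is the Watson-dispersed stick integral
\(\int W(n;\mu,\kappa)\, e^{-b d_\parallel (g^\top n)^2}\, dn\) and
\(A_{ec}\) a Gaussian compartment whose tensor is the Watson average of
a zeppelin with the tortuosity constraint
\(d_\perp = d_\parallel (1 - v_{ic})\). NDI is \(v_{ic}\) and the
orientation dispersion index is
\(\mathrm{ODI} = (2/\pi)\arctan(1/\kappa)\).

Numerical choices:

* **Dispersion model.** Watson (a single dispersion index), not
  Bingham. The downstream biomarker is one scalar dispersion value, and
  a single-\(\kappa\) Watson model is the simplest model that produces
  it. Acquisitions analysed with a Bingham variant will produce a
  closely related but not identical "total" ODI; this is a known
  fidelity limitation of the package.
* **Fixed diffusivities.** \(d_\parallel = 1.7\) and
  \(d_{iso} = 3.0 \times 10^{-3}\,\mathrm{mm^2/s}\), both overridable —
  neonatal tissue may warrant a different \(d_\parallel\), and any
  change must be reported with the results.
* **Quadrature.** The Watson sphere integral is evaluated by a fixed
  product rule: Gauss–Legendre in \(\cos\theta\) times a uniform
  azimuth grid, order 48 × 48 by default. Because the integrand depends
  on the node only through its angles to \(\mu\) and \(g\), the rule is
  exactly invariant under joint rotation of \(\mu\) and the gradients.
  Convergence is fast: order 48 agrees with order 128 to ~1e-14
  relative on neonatal two-shell schemes.
* **Fitting.** \(\mu\) is fixed at the principal eigenvector of a
  tensor fit on the low-b shell; \((v_{ic}, \mathrm{ODI}, v_{iso})\)
  are estimated per voxel by a coarse grid search (10 × 8 × 5 points)
  followed by bounded L-BFGS-B refinement of the sum of squared
  normalized-signal residuals. \(\kappa\) is capped at 64
  (ODI ≥ 0.00995). The fit is deterministic: no random starts.
  On noiseless signals it recovers NDI and ODI to ~1e-4 over
  \(v_{ic} \in [0.2, 0.8]\), \(\mathrm{ODI} \in [0.04, 0.8]\),
  \(v_{iso} \in \{0, 0.1, 0.3\}\).

### Skeletonization and projection

The white-matter skeleton is the ridge of the template FA map: a voxel
is kept when its FA clears the threshold (default 0.15, the value
appropriate for incompletely myelinated neonatal white matter, versus
0.2 in adults) and it is a local maximum of FA along the direction
perpendicular to the local tract sheet. That direction is estimated
per voxel as the FA-weighted centre-of-gravity offset of the 3×3×3
neighbourhood when the offset is informative (> 0.1 voxel), otherwise
as the strongest-curvature line among the 13 axis/diagonal directions,
with the second difference normalized by squared step length and ties
broken in a fixed axis-first order. Both choices are deterministic and
documented because the resulting voxel sets, not just the values, are
compared in tests.

Projection is FA-driven: for each skeleton voxel, the subject FA is
searched along the stored perpendicular direction up to `search_radius`
voxels (default 4) both ways; the located voxel with maximal subject FA
supplies the skeletonized FA, and every other metric is sampled at that
same located voxel. Ties prefer the smallest step so that an exactly
aligned subject reproduces its on-skeleton values. The full
distance-map-constrained projection of the original tract-based
skeleton framework is not re-implemented; on phantom geometry the
unconstrained perpendicular search is exact, and this is flagged as a
fidelity limitation for convoluted real-brain geometry.

The custom analysis mask (in practice: skeleton minus CSF/GM
contaminated areas, cerebellum, brainstem, subcortical grey) is applied
as a *set restriction*, never as value multiplication: literal
multiplication would inject zeros into the value set and corrupt the
5th percentile. This is the only reading of "multiplying by the mask"
consistent with the biomarker's definition.

### Peak width

The peak width of a masked skeletonized value set is
\(P_{95} - P_5\) with percentiles computed by linear interpolation
between order statistics at positions \(q(n-1)\) (the `type = 7`
convention, also the default of the major array libraries). No
histogram binning is performed despite the biomarker's name —
binning would introduce an arbitrary bandwidth. At least 20 finite
values are required; fewer is an error, as is any non-finite value
(masking must already have removed them). For Gaussian values the
width estimates \(2 z_{0.95}\sigma \approx 3.2897\sigma\), a useful
calibration check.

### Cohort statistics

All metrics are first adjusted for age at scan by ordinary least
squares of each metric on GA at scan over the whole sample, retaining
residuals. Whether residualization should be fit pooled or within
group is genuinely open; the pooled fit is used because the analysis
reports whole-sample correlations, and the choice is exposed by
construction (the residualizer returns its coefficients).

* **Correlation.** Pearson r of each residualized metric with GA at
  birth, two-sided p.
* **Group comparison.** A D'Agostino–Pearson omnibus test (K² combining
  sample-size-corrected skewness and kurtosis z-scores) on the pooled
  residuals gates the choice between the equal-variance two-sample
  t-test and the Mann–Whitney U test, at gate level 0.05 per metric.
  The gate level and pooling are design choices; the equal-variance
  t-statistic is used because the analysis it mirrors reports a plain
  two-sample t. With fewer than 8 subjects in a group the moment tests
  are unreliable and the Mann–Whitney branch is taken with a warning.
  Raw p-values are Benjamini–Hochberg adjusted across the six metrics.
* **Classification.** Unregularized logistic regression with an
  intercept, features standardized inside each training fold (no
  leakage), evaluated by 30-repeated 10-fold stratified
  cross-validation. Every repetition draws a fresh partition from the
  master seed; fold class counts deviate from proportionality by at
  most one subject. Reported accuracy is the mean of the 300
  fold-level accuracies and the ± value their standard deviation —
  the convention behind "± " in such tables is rarely stated, so the
  package's convention is fixed and documented here.

## The synthetic data generators

Because no neonatal cohort can ship with a package, every stage is
testable against two generators whose defaults *are* the study
conditions the package targets.

**DWI phantoms** (`phantom_spec()`, `simulate_dwi()`) place axis-aligned
tube tracts with known tensor eigenvalues and NODDI parameters in a
CSF-like isotropic background (diffusivity 3.0 × 10⁻³ mm²/s) on a
shared grid — no registration, mirroring the pipeline's contract. A
Gaussian radial blend of the tract tensor toward the background
produces a smooth FA ridge whose analytic centerline is the ground
truth for skeleton tests. Signals follow either the exact tensor
forward model (so the tensor fitter must recover eigenvalues to
machine precision) or the NODDI forward model; Rician noise
\(\sqrt{(S+\epsilon_1)^2 + \epsilon_2^2}\),
\(\epsilon \sim N(0, S_0/\mathrm{SNR})\), models magnitude MRI, with a
Gaussian option for fitter unit tests. Gradient schemes are generated
by seeded electrostatic repulsion with antipodal symmetry;
`neonatal_scheme()` reproduces a two-acquisition neonatal protocol
(16 b0 + 3@200 + 6@500 + 64@750 + 64@2500 s/mm²). What the phantoms do
*not* emulate: realistic head geometry, crossing-fibre complexity,
motion/eddy artifacts, or partial-volume anatomy — so passing phantom
tests validates the algorithms, not their behaviour on any particular
scanner's data.

**Cohorts** (`cohort_spec()`, `simulate_cohort()`) draw the six
peak-width metrics per subject as
`location(group) + slope · (GA_scan − mean) + Gaussian noise`. The
default locations are the published term/preterm medians of the six
metrics (e.g. PSMD 0.50 vs 0.60 × 10⁻³ mm²/s) and the default scales
their IQR/1.349 — the only printed distributional anchors, under a
normal approximation. PSFA's equal group locations make it the built-in
null feature. Default group sizes are 59 term / 76 preterm. Published
analyses give no per-metric age-at-scan slopes, so the defaults are a
free choice: −0.005 per week for all metrics except PSFA (0), a small
maturational narrowing; GA ranges follow the published demographics,
with scan age truncated below at birth age.

## Tunable parameters at a glance

| Parameter | Default | Units | Why |
|---|---|---|---|
| `fa_threshold` | 0.15 | FA | neonatal skeleton threshold |
| `search_radius` | 4 | voxels | projection search cap (unstated upstream; bounded for locality) |
| `max_bval` | 1000 | s/mm² | tensor validity regime |
| `d_par` | 1.7e-3 | mm²/s | NODDI intrinsic parallel diffusivity |
| `d_iso` | 3.0e-3 | mm²/s | free-water diffusivity |
| `quad` | 48 × 48 | nodes | Watson quadrature order |
| `alpha_norm` | 0.05 | — | normality gate level |
| `n_repeats`, `n_folds` | 30, 10 | — | CV design |
| b0 threshold | 50 | s/mm² | scanners report small nonzero b0 values |

## Problem sizes

The test-suite and demo problem sizes are deliberately small, chosen so
the whole validation runs comfortably on a laptop: phantoms of
~20 × 16 × 8 voxels with one or two tracts, a 12-subject demo cohort
fit from 44-volume two-shell data with a 16 × 12 quadrature and a
loosened optimizer (the defaults remain 48 × 48 and full convergence
for analyses), statistical checks on 135-subject synthetic cohorts
across 100 seeds, and noiseless fit-recovery grids of 75 voxels. None
of these sizes is a statistical claim; they are the smallest
configurations at which each property is non-trivially exercised.

## Known limitations

* Watson, not Bingham, dispersion; no primary/secondary dispersion
  split.
* No distance-map constraint in the projection; adequate for phantom
  and well-separated tract geometry, approximate for dense real-brain
  skeletons.
* The tensor and NODDI fits assume co-registered maps and clean,
  positively valued signals; no outlier rejection (RESTORE-style) is
  implemented.
* The cohort generator draws metrics from independent Gaussians per
  group: it reproduces locations and scales, not the inter-metric
  correlation structure of real cohorts, so multivariate-classifier
  results on synthetic cohorts are optimistic relative to real data.
* The custom mask for real data is inherently manual; the package
  accepts any user-supplied binary mask and ships only phantom masks.

## A minimal worked example

```{r example, eval = FALSE}
library(pswm)

# synthetic two-group cohort at the published scale
co <- simulate_cohort(cohort_spec(seed = 1))
report <- stat_report(co, seed = 1)
print(report)

# full image pipeline on a phantom cohort
res <- run_demo("demo-out", seed = 1)
res$ps_table
```
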