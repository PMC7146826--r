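# pswm — peak width of skeletonized white-matter diffusion MRI metrics

`pswm` computes histogram-width biomarkers of white-matter
microstructure from diffusion MRI, targeted at the neonatal brain, and
runs the cohort analysis that accompanies them. It is aimed at
researchers studying generalized white-matter dysmaturation — for
example the diffuse alterations associated with preterm birth — who
want one robust number per subject and metric instead of voxelwise
statistics.

## What it computes

For each subject, six **peak-width-of-skeletonized-metric** values:

* **PSMD, PSFA, PSAD, PSRD** from the diffusion tensor (mean
  diffusivity, fractional anisotropy, axial and radial diffusivity);
* **PSNDI, PSODI** from the NODDI three-compartment model (neurite
  density index and orientation dispersion index).

Each biomarker is the width of the histogram of one metric over the
core white-matter skeleton:

```
PSx = P95(x | skeleton ∩ custom mask) − P5(x | skeleton ∩ custom mask)
```

with the skeleton built by thresholding a template FA map at 0.15 and
keeping the ridge voxels (local FA maxima along the locally
perpendicular direction), subject maps projected onto the skeleton by
an FA-driven perpendicular maximum search, and a custom mask removing
CSF/GM-contaminated and infratentorial voxels. Diffusivity widths are
in 10⁻³ mm²/s; FA/NDI/ODI widths are dimensionless.

At cohort level the package reproduces the standard analysis: each
metric is residualized on gestational age (GA) at scan, correlated
with GA at birth (Pearson), compared between term and preterm groups
with a D'Agostino–Pearson-gated choice of equal-variance t-test or
Mann–Whitney U and Benjamini–Hochberg FDR correction, and used as
predictor in a logistic classifier evaluated by 30-repeated 10-fold
stratified cross-validation.

Everything is testable without any data download: seeded phantom
generators produce multi-shell DWI from known tensor/NODDI ground
truth (with Rician noise), template FA ridges with analytic
centerlines, custom masks, and synthetic two-group cohorts whose
per-metric locations and scales default to the published term/preterm
summary statistics.

## Worked example

```r
library(pswm)

# a synthetic cohort of 59 term + 76 preterm subjects whose PSMD
# locations follow the published group medians (0.50 vs 0.60)
co <- simulate_cohort(cohort_spec(seed = 1))
report <- stat_report(co, seed = 1)
print(report)
```

```
Cohort statistics (metrics residualized on GA at scan)
Metric     Corr. with GA birth           Group comparison     Classification
PSMD    r = -0.53, p = 3.41e-11  t =  9.05526, p = 8.93e-15  0.78 +/- 0.11
PSFA    r =  0.06, p = 0.474     t = -0.987798, p = 0.325     0.54 +/- 0.07
PSAD    r = -0.53, p = 2.68e-11  u =     3681, p = 3.52e-10  0.70 +/- 0.12
PSRD    r = -0.44, p = 1.19e-07  t =  6.65368, p = 1.02e-09  0.69 +/- 0.12
PSNDI   r = -0.53, p = 5.12e-11  u =     3684, p = 3.52e-10  0.72 +/- 0.12
PSODI   r = -0.35, p = 2.71e-05  u =     3169, p = 4.75e-05  0.69 +/- 0.11
Multivariate models:
  dti    accuracy 0.88 +/- 0.08
  noddi  accuracy 0.80 +/- 0.11
  all    accuracy 0.91 +/- 0.08
```

Reading the output: PSMD correlates negatively with GA at birth
(more premature → wider MD histogram at term-equivalent age), the
term/preterm difference survives FDR correction (second p-value
column, adjusted), PSFA behaves as a null feature, and a univariate
PSMD classifier separates the groups at 78% cross-validated accuracy.
The group-comparison column reports `t` when the residuals pass the
normality gate and the Mann–Whitney `u` otherwise.

The full image pipeline — phantom DWI simulation, tensor and NODDI
fitting, skeletonization, projection, masking, peak widths, statistics
— runs end to end with one call:

```r
res <- run_demo("demo-out", seed = 1)   # 12-subject phantom cohort
res$ps_table                            # six widths per subject
```

A thin command-line wrapper with subcommands (`simulate-phantom`,
`simulate-cohort`, `fit-dti`, `fit-noddi`, `skeletonize`, `run`,
`demo`) is installed at `inst/cli/pswm.R`:

```sh
Rscript inst/cli/pswm.R demo --out demo-out --seed 1
```

See `vignettes/peak-width-methods.Rmd` for the models, the numerical
choices and the generators' fidelity limits.

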