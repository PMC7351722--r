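# cordvcm

Tract-specific, along-cord statistical analysis of spinal cord diffusion
MRI. For imaging scientists studying diseases with level- and
pathway-localized degeneration (the motivating case is ALS and the
corticospinal tract), `cordvcm` turns per-subject imaging products into
continuous C2–C6 profiles and tests group effects *at every position along
the cord* with family-wise error control, instead of collapsing each
vertebral level into a single mean.

## What it does

**Profile extraction.** From scalar metric volumes (FA, MD, RD, AD), a
cord mask, probabilistic tract confidence maps and tractography
streamlines: sample metrics along streamlines, drop samples in voxels with
tract confidence < 0.1, bin by arc length to a canonical C2–C6 grid,
smooth with a five-point sliding mean window, average left/right
homologues (mean of per-side means), and compute cord cross-sectional area
per slice as voxel count × in-plane voxel area. NIfTI volumes, TrackVis
`.trk` streamlines, and TSV tables are the on-disk formats.

**The model.** Profiles are analysed with a varying coefficient model

    Y_i(s) = x_i' B(s) + eta_i(s) + eps_i(s)

where `x_i` holds intercept, disease status, age and scanner, `B(s)` is a
coefficient curve per covariate, `eta_i(s)` a smooth subject-specific
curve process and `eps_i(s)` measurement error. `vcm()` estimates `B(s)`
by local-linear kernel weighted least squares (Epanechnikov kernel,
bandwidth in mm) and returns a classed model object with `print`,
`summary`, `coef`, `predict`, `plot` and `residuals` methods.

**Inference.** `vcm_test()` computes a local Wald statistic
`T(s) = b(s)' Sigma_b(s)^{-1} b(s)` for the disease coefficient with a
cluster-robust covariance, and calibrates it with a wild bootstrap under
the null: each bootstrap sample multiplies every subject's null-model
residual curve by one Rademacher multiplier, refits, and records the
curve-wide maximum statistic. Corrected p-values compare `T(s)` against
the bootstrap maxima, controlling the family-wise error over positions
along the cord. Variants: a joint 2-df multimodal FA+CSA test
(per-position standardization, shared multipliers, cross-metric residual
covariance) and a longitudinal group-difference-in-change test
(`vcm_change_test`).

**Clinical statistics.** ALSFRS-R sub-scores (items 4–12 spinal, 10–12
respiratory), Pearson correlations of imaging summaries with scores,
paired t-tests on per-subject means, and exploratory onset-site subgroup
summaries with Welch comparisons.

**Synthetic data.** `simulate_cohort()` draws cohorts from exactly the
model above (Gaussian-process subject curves, configurable level-localized
effects, multi-metric correlation); `simulate_cord_phantom()` builds voxel
phantoms (1.12 × 1.12 mm² in-plane, 3.3 mm slices) with schematic tract
maps and streamlines for end-to-end pipeline validation;
`simulate_clinical_scores()` couples item tables to imaging summaries with
a target correlation.

## Worked example

```r
library(cordvcm)

grid <- cord_grid()                       # 50 positions, C2-C6, 1.5 mm
spec <- cohort_spec(
  n_per_group = c(20, 20), grid = grid,
  coefficient_functions = default_coefficients(
    group_effect = level_effect(grid, c("C2", "C3"), -0.045)),
  eta_sd = 0.03, eps_sd = 0.01, seed = 7)
cohort <- simulate_cohort(spec)

fit <- vcm(~ group + age_years + scanner, cohort, bandwidth = 6)
tst <- vcm_test(~ group + age_years + scanner, cohort, B = 1000, seed = 42)
print(tst)
```

```
Wild-bootstrap local test: metric FA, tested: group (df 1)
40 subjects, B = 1000 (rademacher multipliers, seed 42), bandwidth 6 mm
min corrected p = 0.000999 at C2
significant (corrected p < 0.05) at levels: C2, C3
```

The simulated cohort carries a −0.045 FA deficit in patients at C2–C3
only; the corrected p-value profile flags exactly those levels (`0.000999`
is the smallest value `(1 + 0)/(B + 1)` the bootstrap convention can
produce at B = 1000) and stays non-significant where no effect was
programmed. `plot(tst)` draws the statistic and p-value profiles;
`plot(fit)` the coefficient curves with ±2 SE bands.

The same machinery runs end to end from voxel data:

```r
co <- phantom_cohort(n_per_group = c(20, 20), deficit = -0.05,
                     levels = c("C2", "C3"), seed = 1)   # 40 voxel phantoms
tst <- vcm_test(~ group, co, metric = "lateral_CST", B = 500, seed = 2)
```

A YAML-configurable driver (`run_pipeline()`, `report_summary()`, and the
`inst/scripts/cordvcm` command line with `simulate` / `extract` /
`analyze` / `report` / `run-all` subcommands) orchestrates full runs and
writes results TSVs, a metadata JSON and a log.

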