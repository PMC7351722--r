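---
title: "Along-cord tractometry with varying coefficient models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Along-cord tractometry with varying coefficient models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cordvcm)
```

## The problem

Diffusion MRI of the cervical spinal cord yields scalar microstructure maps
(FA, MD, RD, AD) and cord cross-sectional area (CSA) that change along the
rostro-caudal axis. In diseases with tract-specific degeneration — ALS and
its corticospinal tract involvement is the motivating case — group
differences are not uniform along the cord: they concentrate at particular
vertebral levels and in particular pathways. Averaging a whole level (or the
whole cord) into one number discards exactly the localization that carries
the biology. This package implements the alternative: extract a
*continuous along-cord profile* per subject, tract and metric, and test
group effects *at every position* while controlling the family-wise error
over positions.

## Profile extraction

Per subject, the extraction stage consumes scalar metric volumes, a cord
mask, per-tract probabilistic confidence maps, and tractography streamlines
(3-D polylines, one point per slice in the phantom case). The steps, each
an exported function:

1. **Streamline sampling** (`sample_along_streamline`): the metric volume is
   sampled at every streamline point (trilinear by default) and arc length
   is accumulated from Euclidean segment lengths.
2. **Confidence thresholding**: samples in voxels whose tract confidence is
   below 0.1 are discarded. The lookup is nearest-voxel by design — a voxel
   either survives the cut or it does not; interpolating a confidence value
   would blur the exclusion boundary.
3. **Arc-length binning** (`tract_profile`): surviving samples are assigned
   to the nearest grid position (ties go rostral) and averaged per
   position.
4. **Left/right averaging**: homologous tracts are combined as the mean of
   per-side means, not a pooled sample mean, so a subject with many more
   left than right streamlines is not biased toward one side.
5. **Sliding-window smoothing** (`sliding_mean_window`): a five-point
   truncated mean window (half-width 2; about 6 mm at typical sampling)
   suppresses sampling noise. The width is specified in points; the log
   reports the mm equivalent computed from the actual grid spacing.
6. **CSA** (`cord_csa_profile`): per slice, voxel count times in-plane
   voxel area (1.12 x 1.12 = 1.2544 mm^2 at the default acquisition
   geometry), then resampled within each vertebral level onto the
   canonical grid (`level_align`, linear, no extrapolation past the first
   and last native slice of a level). How CSA should be interpolated
   between 3.3 mm slices is a genuine free choice; linear within-level
   resampling is this package's.

The canonical grid (`cord_grid`) covers C2-C6. C7 is excluded by default
(edge-of-field coverage is unreliable there in practice), which is a
configuration default, not a hard restriction.

## The varying coefficient model

For subject $i$ with covariates $x_i$ (intercept, disease status, age,
scanner; sex optionally — off by default) and metric profile $Y_i(s)$ at
arc-length position $s$:

$$Y_i(s) = x_i^T B(s) + \eta_i(s) + \varepsilon_i(s),$$

where $B(s)$ is one coefficient curve per covariate, $\eta_i$ a smooth
subject-specific curve process, and $\varepsilon_i$ measurement error.
`vcm()` estimates $B(s)$ by **local-linear kernel weighted least squares**:
at each grid position $s_0$ it minimizes

$$\sum_{i}\sum_{m} K\!\left(\frac{s_m - s_0}{h}\right)
  \left(Y_i(s_m) - x_i^T(\beta_0 + \beta_1 (s_m - s_0))\right)^2$$

and reports $\hat B(s_0) = \hat\beta_0$. Local-linear (rather than
local-constant) smoothing is the standard choice for its boundary behavior;
the default kernel is Epanechnikov. With complete data the minimization
factorizes into per-subject local-linear smoothing followed by
position-wise ordinary least squares across subjects, which is the fast
vectorized path; the two paths are identical and tested against each
other. Missing values drop the corresponding $(i, s_m)$ terms from the
local sums; positions with fewer than 3 contributing subjects are reported
missing. As $h \to 0$ the fit reduces to independent per-position least
squares (the test suite pins this against an independently coded OLS).

**Coefficient covariance.** The per-position covariance of $\hat B(s_0)$
uses the cluster-robust (by subject) sandwich built from the local-fit
residuals. On complete data this equals the heteroskedasticity-robust
covariance of the position-wise OLS on the smoothed subject values — the
internally consistent variance of the actual estimator, and exactly the
quantity the wild bootstrap replicates. Degenerate positions (zero
coefficient and zero variance, e.g. identically-zero change profiles)
define $T = 0$.

**Bandwidth.** The default is 6 mm, comparable to the five-point
extraction window. `select_bandwidth()` offers leave-one-subject-out
cross-validation on the predicted mean curve, with ties resolved toward
the smallest candidate.

## Local testing and family-wise correction

The local statistic is the Wald form
$T(s) = \hat b(s)^T \hat\Sigma_b(s)^{-1} \hat b(s)$ on the tested
coefficient sub-vector (disease status in all the headline analyses).
Different implementations of this model family define the local statistic
differently; the Wald-on-local-WLS form with cluster-robust covariance is
this package's own definition, and outputs are labeled accordingly.

p-values come from a **wild bootstrap under the null**
(`vcm_test`): fit the null model (tested columns removed), and for each of
$B$ bootstrap samples multiply every subject's entire null-model residual
curve by a single mean-0, variance-1 multiplier (Rademacher by default;
Gaussian optional), refit, and record $T^*_b(s)$ and
$M_b = \max_s T^*_b(s)$. Then

$$p_{\text{corrected}}(s) = \frac{1 + \#\{b : M_b \ge T(s)\}}{B + 1},
\qquad
p_{\text{pointwise}}(s) = \frac{1 + \#\{b : T^*_b(s) \ge T(s)\}}{B + 1}.$$

Comparing each position against the curve-wide maximum corrects for
multiple testing along the cord; the $+1/(B+1)$ convention avoids zero
p-values. Corrected p-values dominate pointwise ones and are
non-increasing in $T$ by construction. Multiplying a whole residual curve
by one multiplier preserves each subject's within-curve correlation
structure, which is what makes the scheme valid under the smooth
$\eta_i(s)$ process.

**Multimodal extension.** With two metrics (FA and CSA) the tested
coefficients are stacked into a 2-vector whose 2x2 covariance is estimated
from the paired residual curves, capturing cross-metric correlation; the
same per-subject multiplier drives both metrics' bootstrap curves. Because
FA is unitless and CSA is in mm^2, each metric is standardized by its
per-position pooled standard deviation before fitting (the statistic is
scale-invariant, so this only matters for reporting and numerical
conditioning). A numerically singular stacked covariance (e.g. a
duplicated metric) is ridge-stabilized; in the duplicated-metric limit the
joint statistic provably collapses to the unimodal one, which the tests
verify.

**Longitudinal variant.** `vcm_change_test()` replaces the metric by the
within-subject change (follow-up minus baseline) and runs the same
machinery with disease status as the tested covariate — a
group-difference-in-change analysis. Unpaired subjects are excluded with a
warning. Identical baseline and follow-up give $T \equiv 0$ and corrected
p identically 1.

## The synthetic cohort generator

`simulate_cohort()` draws from exactly the model above, so estimator and
generator share no code but share the data-generating equation:

* Default cohort 20 patients + 20 controls, the size of a typical
  single-site ALS imaging study; ALS onset-site labels split 10/5/5
  (upper limb / lower limb / bulbar), the composition of a limb-majority
  clinic cohort. Age is centered near 57.5 years; scanner and sex are
  balanced binary.
* $\eta_i(s)$ is a zero-mean Gaussian process with squared-exponential
  covariance, variance `eta_sd`^2 (default 0.03 on the FA scale) and
  length-scale `eta_lengthscale_mm` (default 15 mm — smooth over roughly
  one vertebral level). The smoothness class of real subject curves is
  unknown; the squared-exponential kernel encodes "smooth individual curve
  variation" and nothing more.
* $\varepsilon$ is iid Gaussian, default SD 0.01.
* With two metrics, the subject-curve draws are correlated across metrics
  by `cross_metric_corr` at each position, and per-metric scales can be
  set by named `eta_sd` / `eps_sd` vectors (CSA lives near 70 mm^2, FA
  near 0.5).
* The default FA intercept declines rostral-to-caudal (healthy cords show
  higher FA at C2 than C6); `level_effect()` builds level-localized
  disease effects.

The generator reproduces smooth between-subject curve variation, localized
group effects, covariate structure and metric coupling. It does **not**
emulate scanner artifacts, distortion residuals, tractography failure
modes, crossing-fiber FA bias, or dropout — so passing validation here
demonstrates the statistical machinery is correct under its assumed model,
not that the pipeline is robust to real-world acquisition pathology.

The voxel phantom (`simulate_cord_phantom`) is schematic by design: a
cylindrical cord (1.12 x 1.12 mm in-plane, 3.3 mm slices, 30 slices over
C2-C6), Gaussian confidence bumps at anatomically inspired in-plane
offsets (lateral CST lateral, posterior column dorsal, spinal lemniscus
anterolateral), piecewise-constant metric values per tract, and
axis-parallel streamlines snapped to voxel centers so that noise-free
extraction is interpolation-exact. It exercises thresholding, left/right
averaging, binning, CSA arithmetic and overlap warnings — it is not an
atlas. Distinct tracts whose centers fall closer than a configurable
minimum distance are flagged in the output metadata (a warning, not an
error), mirroring the practical problem of overlapping tract segmentations
that forces exclusion of small contaminated pathways.

Clinical tables couple a continuous spinal sub-score (items 4-12 of the
12-item, 0-4-per-item functional scale) to a chosen imaging summary with
an exact pre-rounding target correlation, split the sub-score over the
nine spinal items with zero-sum noise, then clip to [0, 4] and round.
Rounding and clipping attenuate the realized correlation slightly (about
2% at a target of 0.8); this bias is accepted and measured in the tests
rather than corrected.

## Numerical choices and degenerate inputs

* Kernel support smaller than two distinct positions (tiny bandwidth, grid
  edges) falls back to local-constant weights, giving the per-position OLS
  limit instead of a rank error.
* Rank-deficient local systems raise an error naming the position;
  numerically singular test covariances are ridge-stabilized
  (lambda = 1e-8 x mean diagonal) with the duplicated-metric identity as
  the test anchor.
* All-zero tensors get FA = 0 plus a degenerate flag; eigenvalue order is
  validated.
* Zero-variance paired differences flag the paired t-test degenerate
  (p = 0 or 1 by the mean); zero-variance correlation inputs flag r
  undefined.
* Bootstrap seeds are mandatory, never defaulted silently, and logged in
  run metadata.

## Validation study sizes

The packaged validation studies (test suite and `scripts/acceptance.R`)
use: 200 null cohorts at B = 500 for the family-wise error rate; 100
replicates per amplitude for the power curve; 100 replicates for the
multimodal comparison at B = 300; 50 seeds per cohort size for recovery
error; 50 phantom cohorts (40 subjects each, full extraction) for
end-to-end localization; 30 replicates for the longitudinal study. These
sizes put Monte-Carlo standard errors near 0.015-0.07 on the reported
rates, tight enough to separate the hypotheses under test while keeping
each study in the minutes range on one core.

## Known limitations

* The local statistic and weighting scheme are this package's definitions
  (Wald on local-linear WLS with cluster-robust covariance); other
  implementations in this model family may weight differently.
* The max-statistic correction controls the family-wise error over
  positions *within one curve*; testing many tracts and metrics still
  multiplies families, as it does in the motivating studies.
* With a true effect present somewhere on the curve, positions outside the
  effect are not protected at the nominal level (the null-model residuals
  absorb the effect); localization claims in the validation are therefore
  phrased against far levels and untouched tracts.
* The longitudinal generator exposes a single between-timepoint
  correlation for the subject-curve process; the within-subject
  correlation structure of real repeated scans is not claimed.
* `run_pipeline` analyses profiles; tensor fitting, tractography,
  distortion correction and atlas registration are upstream of this
  package and out of scope.
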