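---
title: "Quantile-index biomarkers: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantile-index biomarkers: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quindex)
```

This vignette is the package's account of what it computes, which knobs
matter, and where the genuinely open design choices were resolved.

## The statistical problem

Single-cell imaging yields, for each subject, thousands of per-cell signal
intensities nested in clusters (regions of interest or tissue-microarray
cores). The scientific question is whether the *distribution* of these
intensities — not just its mean — predicts a subject-level outcome. The
package represents each subject's distribution by its empirical quantile
function `Q_i(p)`, a functional object on [0, 1], and fits scalar-on-function
regressions of the outcome on `Q_i`:

* linear: `QI_i = ∫ β(p) Q_i(p) dp`, a functional GLM or linear functional
  Cox model;
* nonlinear: `nlQI_i = ∫ F(p, Q_i(p)) dp`, a functional GAM or additive
  functional Cox model, where the smooth bivariate `F` lets the effect vary
  both along the probability axis and with the quantile's value.

Both reduce, after fitting, to an *integrand surface* `S(p, q)` (`β̂(p)·q`
or `F̂(p, q)`), defined for `p ∈ [0, 1]` and `q` in the training quantile
range. Any subject is scored by integrating the surface along their quantile
path; this works identically for training subjects and for an independent
test cohort, which is where predictive claims should be evaluated (training
indices are optimized on the same data and are optimistically biased —
`evaluate_predictor(..., training = TRUE)` labels them as such).

Key modelling assumptions: cells within a cluster are exchangeable
(spatial information is deliberately not used); clusters are nested in
subjects (exactly two grouping levels — deeper hierarchies are rejected
rather than half-supported); subjects are independent; and the outcome
depends on the intensity distribution only through a functional of the
quantile function.

## Step 1: quantiles and aggregation

* **Quantile estimator.** The linear-interpolation order-statistic rule
  (position `1 + (n − 1)p` between sorted values — R's default type 7),
  chosen for reproducibility against the dominant ecosystem default.
* **Grid.** `K = 100` midpoints `p_k = (k − ½)/K`. Midpoints avoid the
  extreme order statistics at `p = 0, 1`, whose sampling instability would
  otherwise leak into every downstream integral, and make every quadrature
  weight exactly `1/K`. The grid is user-overridable; irregular grids get
  cell-width weights that reduce to `1/K` in the midpoint case.
* **Aggregation.** Cluster quantile functions are combined *point-wise*
  (mean by default; median/min/max available) at the subject level.
  Aggregation on the quantile scale preserves monotonicity — the point-wise
  min/mean/median/max of non-decreasing functions is non-decreasing — and
  never pools cells across clusters, which would conflate within- and
  between-cluster variation. With a single cluster all four aggregates
  coincide with the cluster's quantile function.
* **Scale.** Intensities are used as given; any log-transform is the
  caller's explicit step (`--log`, `log_intensity`). Signal-intensity data
  are usually analyzed on the log scale, and all survival examples in this
  package do so.

## Step 2: penalized scalar-on-function fitting

* **Bases.** Cubic B-splines: 10 basis functions for `β(p)`; 8 × 8
  marginal bases for `F(p, q)` (q-basis spanning the observed training
  range, slightly padded). Small bases suffice because the penalty, not the
  dimension, controls effective complexity — appropriate for the modest
  cohort sizes of biomedical imaging studies.
* **Penalty.** Second-order difference penalties on the coefficients
  (the P-spline construction), and their tensor-sum analogue with one
  smoothing parameter per direction. The null space is affine: heavy
  smoothing shrinks `β̂(p)` to a straight line, not to zero.
* **Design.** Functional terms are discretized by the grid quadrature:
  `X_ij = Σ_k w_k B_j(p_k) Q_i(p_k)` (linear) or
  `Σ_k w_k T_j(p_k, Q_i(p_k))` (tensor). Columns are centered, with an
  explicit unpenalized intercept for gaussian/binomial; the offsets are
  stored and re-applied at prediction. The Cox model has no intercept (the
  baseline hazard absorbs it) but columns are centered for numerical
  stability.
* **Fitting.** Penalized IRLS (gaussian solves in one step) or penalized
  Newton with step halving on the Breslow partial likelihood. Convergence:
  relative change of the penalized objective below `1e-8`, at most 200
  iterations; non-convergence, quasi-separation (binomial) and monotone
  partial likelihoods (Cox; refitted with a small smoothing floor) are
  flagged on the object rather than fatal.
* **Smoothing-parameter selection.** GCV `n·D/(n − edf)²` over a
  logarithmic grid (`10^−8…10^8`, 25 points; a 7 × 7 two-dimensional grid
  for tensor smooths) for gaussian/binomial; 5-fold cross-validated partial
  likelihood (Verweij–van Houwelingen) over `10^−6…10^6` for Cox. Fold
  membership is assigned by rank of survival time — deterministic,
  stratified over the time axis, and consuming no random numbers, which
  keeps whole-pipeline runs byte-reproducible. Grid candidates whose
  penalized system is singular are skipped.
* **Degenerate directions.** Tensor surfaces have components that neither
  the likelihood nor the penalty can see: any `g(p)` added to `F`
  contributes the subject-constant `∫g`, absorbed by the intercept, and its
  affine part is also penalty-null. The solver resolves such exactly flat
  directions to the minimum-norm solution (an escalating, scale-relative
  ridge applied only when a plain solve fails).

## Step 3: sign adjustment and scoring

The sign factor `ĉ = sign(corr(Q_i(p̃), index_i))` (Pearson; `p̃` snapped
to the nearest grid point, default 0.5) multiplies the surface so indices
correlate positively with the median-level quantile. Tie-breaks are
explicit: exactly zero or undefined correlation (constant `Q_i(p̃)`) keeps
`ĉ = +1`, which also makes the adjustment idempotent. `ĉ` is estimated
once on the training data and reused for test data — re-estimating it on
test outcomes would leak information.

Scoring integrates the adjusted surface along each subject's path with the
same midpoint weights used in fitting, so training indices reproduce the
fitted linear predictor's functional contribution exactly (up to the
centering constant). Test subjects whose quantiles leave the training
q-range are flagged; for tensor surfaces the path is clamped to the
training range (tensor splines extrapolate unreliably), while the linear
surface `β̂(p)·q` extends naturally and is only flagged.

## Identifiability of the nonlinear surface

`F̂` is informed only along the observed quantile paths, and only up to an
additive p-only component. Interpret the surface on the band of the data
(the overlaid integration paths in `plot_integrand_surface()` show exactly
that region) and read q-profiles relative to their per-p level; the
*indices* are unaffected by this indeterminacy up to a constant shared by
all subjects. The package's tests check surface recovery exactly in this
identified sense.

## The synthetic-data generator

`sim_config()`/`simulate_study()` emulate the nested structure of CSI
studies: log-normal per-cell intensities (`meanlog = 0`, `sdlog = 0.5` —
positive, right-skewed, moderate tail weight), subject-level log-location
shifts (`τ = 0.5`), cluster-level shifts (`κ = 0.2`), 4 clusters of 200
cells per subject by default, with Poisson/negative-binomial count options.
Outcomes are linked to a *known* functional of the subject's quantile
function (gaussian with noise at a stated fraction of the signal SD;
logistic link; exponential survival with independent exponential censoring
whose rate is solved numerically to hit the requested censoring fraction).
Identical seed and configuration give byte-identical output; cells and
outcomes use deterministic seed substreams.

Scenario notes:

* The **tail** scenario adds subject-level *scale* heterogeneity
  (`scale_sd = 0.6` against `τ = 0.2`) and analyzes log-scale intensities.
  Both choices are what the scenario is for: with location-only shifts every
  quantile and the mean are monotone in the same subject effect, so a
  tail-weighted functional cannot carry information beyond the mean and a
  comparison against a mean-intensity predictor would be vacuous; and on the
  raw scale the tail functional of log-normal quantiles is so heavy-tailed
  that rank-based evaluation degenerates. Shape-dominated heterogeneity on
  the log scale is precisely the "heterogeneity beyond the mean" regime the
  method targets.
* What the generator does **not** emulate: spatial cell coordinates,
  multi-marker correlation, batch effects, measurement error in
  segmentation, or non-log-normal intensity laws. Passing recovery tests on
  these simulations shows the estimation machinery is correct under the
  stated model, not that real tissues satisfy it.

## Problem sizes and numerical tolerances used in the checks

The test-suite and `scripts/acceptance.R` use: 1000 random vectors for the
quantile oracle (agreement to `1e-12`); 100 random grouped datasets for the
aggregation laws; subjects of 2000 log-normal cells for the 1%
quadrature-identity check; 20 seeds of the linear scenario (n = 200,
K = 100, noise at 10% of signal SD) for index recovery (median Pearson
r ≥ 0.95); 20 seeds of the tail survival scenario (300 training / 300 test
subjects, ~30% censoring) for the concordance comparison; `1e-6` for the
tensor-nesting and plot-area identities; `1e-8` for train-time consistency.
These sizes were chosen as the smallest that make the stochastic checks
stable across seeds.

## Known limitations

* One functional predictor (one marker) per model; scalar covariates can
  enter unpenalized but are off by default.
* No REML smoothing selection and no random-effect (subject/cluster)
  terms; between-cluster variability is handled by the aggregation step,
  not modelled.
* Exact numerical agreement with other scalar-on-function implementations
  is not a goal: smoother dimension, penalty and λ-selection criteria
  differ across packages. Cross-checks against an independent smoother
  (`mgcv`) and an independent Cox fitter (`survival`) assert agreement of
  fits where the models coincide.
* The HTML plot export is a static snapshot plus embedded numeric data,
  not an interactive widget.
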