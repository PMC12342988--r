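# quindex: quantile-index biomarkers from clustered single-cell intensities

Single-cell imaging platforms (multiplex immunofluorescence
immunohistochemistry, quantitative pathology pipelines) measure a protein's
signal intensity in every segmented cell of a tissue. Most analyses collapse
these thousands of per-cell values to one average per patient, discarding the
intra-tumoral heterogeneity that often carries prognostic information.
`quindex` implements a supervised framework that uses the **entire per-subject
intensity distribution** — represented by its empirical quantile function — to
derive a scalar biomarker optimized for an outcome of interest.

It is aimed at biostatisticians analyzing single-cell signal-intensity (CSI)
data with a subject-level outcome: continuous, binary, or right-censored
survival. The same machinery applies to any clustered single-cell measurement
with quantitative expression levels.

## The model

For subject *i*, let `Q_i(p)` be the empirical quantile function of the cell
intensities, evaluated on a grid of probabilities `p_1 < … < p_K` in (0, 1)
(default: `K = 100` midpoints `(k − 0.5)/K`). When subjects contain several
clusters (ROIs, TMA cores), cluster-level quantile functions are aggregated
point-wise (mean, median, min, or max) at the subject level — never by pooling
cells.

Two scalar-on-function predictors are fitted against the outcome:

* the **linear quantile index**, from a functional generalized linear model
  (or linear functional Cox model for survival):

  `QI_i = ∫₀¹ β(p) Q_i(p) dp`

* the **nonlinear quantile index**, from a functional generalized additive
  model (or additive functional Cox model):

  `nlQI_i = ∫₀¹ F(p, Q_i(p)) dp`

with `β(p)` an unknown coefficient function (penalized B-spline) and
`F(p, q)` an unknown smooth bivariate surface (penalized tensor-product
spline). Fitting maximizes a penalized likelihood (IRLS for
gaussian/binomial; Newton iterations on the Breslow partial likelihood for
Cox), with smoothing parameters chosen by GCV or cross-validated partial
likelihood.

The fitted model defines the **integrand surface**
`S(p, q) = β̂(p)·q` (linear) or `F̂(p, q)` (nonlinear), optionally
sign-adjusted by `ĉ = sign(corr(Q_i(p̃), index))` at a reference probability
`p̃` (default 0.5) so indices correlate positively with the median-level
quantile. Scoring any subject — training or independent test — integrates the
surface along that subject's quantile path:
`index_i = Σ_k w_k S*(p_k, Q_i(p_k))`. Geometrically, the index is the area
under the projection of the subject's integrand path onto the (p, s)-plane;
`plot_integrand_surface()` renders surface, paths, and projections.

## Worked example

Simulate a survival cohort whose log-hazard is driven by the *upper tail* of
the (log-scale) intensity distribution — the regime where a mean-based
biomarker is blind — then fit on a training cohort and score an independent
test cohort:

```r
library(quindex)

cfg   <- sim_scenario("tail", seed = 42)   # 300 subjects, ~30% censoring
train <- simulate_study(cfg, seed = 42)
test  <- simulate_study(cfg, seed = 43)

fit  <- fit_qi_model(train$Q, train$outcomes, kind = "linear")
surf <- sign_adjust(integrand_surface(fit), train$Q)
surf
#> Integrand surface (linear kind, cox family): sign +1 at p~ = 0.495,
#>   q-range [-8.68, 9.119]

qi_test <- compute_qi(surf, test$Q)
head(qi_test, 3)
#>   subject_id        qi extrapolated
#> 1      S0001 0.4973095            0
#> 2      S0002 0.9410816            0
#> 3      S0003 1.4995215            0

evaluate_predictor(qi_test, test$outcomes)
#> Quantile-index evaluation (survival outcome, n = 300)
#>   concordance = 0.7346
```

The test-set concordance of 0.73 says that for 73% of comparable subject
pairs the higher quantile index went with the shorter survival — here nearly
matching the concordance of the data-generating true index, while a
mean-intensity Cox model reaches only ~0.59 on the same data. Training-set
evaluations are labelled optimistically biased:

```r
evaluate_predictor(compute_qi(surf, train$Q), train$outcomes, training = TRUE)
#> Quantile-index evaluation (survival outcome, n = 300)
#>   concordance = 0.7145  [training data: optimistically biased]
```

`plot_integrand_surface(surf, train$Q, subjects = 1:8, file = "surface.html")`
writes a rendering of the surface with the eight subjects' integration paths
and their (p, q)- and (p, s)-projections, with all plotted series embedded as
JSON.

## Command-line interface

A thin Rscript wrapper covers the full pipeline
(`simulate`, `quantiles`, `fit`, `predict`, `evaluate`, `plot-surface`,
`run`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli/quindex.R", package = "quindex"))')
Rscript $CLI simulate  --scenario tail --seed 3 --out-cells cells.csv \
                       --out-outcomes outcomes.csv --out-truth truth.csv
Rscript $CLI quantiles --cells cells.csv --log --k 100 --out q.csv
Rscript $CLI fit       --quantiles q.csv --outcomes outcomes.csv \
                       --outcome-kind survival --out model.json
Rscript $CLI predict   --model model.json --quantiles q.csv --out qi.csv
```

`run` executes Steps 1–3 from a YAML config and writes quantiles, model,
indices, an evaluation report, and a provenance record; train/test splitting
is always the caller's responsibility.

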