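---
title: "Small-area estimation of unintended births and pregnancies: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area estimation of unintended births and pregnancies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The estimation problem

Surveys that measure pregnancy intendedness (state surveys of recent
mothers; the national pregnancy-history survey) are too small to support
estimates below the state level, while the administrative file that has
full spatial coverage — the birth-record file — does not ask about
intendedness. The method implemented here bridges the two: it learns the
association between intendedness and covariates where intendedness is
observed, transfers that association to the birth-record file where the
covariates (but not the outcome) are observed, and then corrects for the
fact that births are a selected subset of pregnancies.

Formally, with $Y_i \in \{0,1\}$ unintendedness, $X_i$ the covariates
shared between survey and birth records, $L_j$ a live-birth indicator and
$Z_j$ the covariates shared between the pregnancy history and birth
records:

* **f-model**: $\Pr(Y=1 \mid X) = f(X)$, fit with survey weights on women
  with a recent live birth;
* **g-model**: $\Pr(L=1 \mid Z, Y) = g(Z, Y)$, fit with survey weights on
  all pregnancies;
* **per-birth quantities**: $\hat Y_b = \hat f(X_b)$,
  $\hat U_b = \hat f(X_b) / \hat g(Z_b, 1)$,
  $\hat P_b = \hat f(X_b)/\hat g(Z_b,1) + (1-\hat f(X_b))/\hat g(Z_b,0)$.

$\hat U_b$ is an inverse-probability count: if unintended pregnancies end
in live birth with probability $\hat g(Z,1)$, each observed unintended
birth stands for $1/\hat g(Z,1)$ unintended pregnancies. Summing
$\hat Y_b$, $\hat U_b$, $\hat P_b$ within areas and dividing by the years
of data and the female population 15–45 gives the seven area-level
outcomes (births and pregnancies: per-year counts, unintended percentages,
incidence per 1,000 women).

Two reading notes on the aggregation formulas. First, the percentage of
pregnancies unintended is computed as $100 \cdot \sum_b \hat U_b / \sum_b
\hat P_b$; the ratio the other way up is not a percentage, and only this
orientation reproduces the arithmetic linking roughly 40,000 unintended
out of 100,700 annual pregnancies to 39.7%. Second, all "per year"
outcomes divide the multi-year sums by the configured `years_span`
(default 3), so totals over areas and the statewide row agree exactly.

## Outcome coding

The five survey responses to "how did you feel about becoming pregnant?"
are coded: *wanted later* and *didn't want then or ever* → unintended;
*wanted sooner*, *wanted then*, *wasn't sure* → not unintended. Treating
"unsure" as not-unintended is the literature's convention and the package
default. Because that choice is consequential, `code_intendedness()` also
supports `unsure_as_unintended` and `drop_unsure`, and
`coding_sensitivity()` re-runs the fit-and-predict stage under all three.
The statewide share is, by construction, lowest under the default,
intermediate when unsure rows are dropped, and highest when unsure codes
as unintended; the suite asserts this ordering.

## Missing data

Missing binary covariates are imputed as 0 and missing continuous
covariates with the median — with one indicator column per imputed field,
so the models can learn from missingness itself. One deliberate
sharpening: the medians are computed on the *fitting* table and frozen
into the model (`fit_imputer()`), then reused when the model is applied to
the birth-record file. Recomputing medians on the application file would
let the application data shift the feature definition and leak
distributional drift into predictions. Imputation is idempotent, which
the suite checks.

## Model families and selection

Five candidate families are supported, each honouring observation weights
in its fitting criterion and each deterministic under a fixed seed:

| family | engine | default hyperparameters |
|---|---|---|
| logistic | `stats::glm` (quasibinomial link) | — |
| random_forest | `ranger`, impurity importance | 300 trees, min node 10 |
| gradient_boosting | `xgboost`, single thread | 100 rounds, depth 3, eta 0.1 |
| neural_net | `nnet`, one hidden layer, standardised inputs | 8 units, decay 0.01 |
| linear_sgd | `glmnet`, ridge logistic | $\alpha=0$, $\lambda=10^{-3}$ |

The quasibinomial link lets `glm` accept non-integer survey weights
without complaint while producing the same point estimates as binomial
logistic regression. The "linear_sgd" family denotes a regularised linear
(logistic-link) classifier; it is fit by glmnet's coordinate descent,
which reaches the same estimator a stochastic-gradient trainer would
target, with better numerical behaviour at these sample sizes.

`select_model()` runs stratified-by-outcome K-fold cross-validation
(default K = 5; K is a convention choice, recorded in the config) and
scores candidates by the **survey-weighted c-statistic**: the weighted
probability that a random positive outscores a random negative, ties
counting one half, each pair weighted by the product of the two
observation weights. The implementation is a single sorted pass over
score groups and is tested for exact equality against brute-force pair
enumeration. Ties in mean CV score are broken by grid order — families in
a fixed precedence (logistic, random forest, gradient boosting, neural
net, regularised linear), simpler settings first — so selection is fully
reproducible. The winner is refit on all data and carries its CV table.

Interpretation tools mirror what practitioners report for such models:
`importance_report()` normalises impurity-based (Gini) importances to
shares summing to 1, so "the top five features account for X%" reads off
the cumulative share; `predictive_margins()` forces one covariate to a
level for every record, predicts, and summarises the prediction
distribution (mean, quartiles, and adjacent values — the 1.5·IQR fences
clipped to the observed extremes), the partial-dependence construction
behind box-plot margin panels.

## Births to pregnancies

`pregnancy_multipliers()` floors $\hat g(Z,1)$ and $\hat g(Z,0)$ at
`g_floor` (default 0.05) before dividing. Unfloored inverse-probability
weights explode when a fitted probability approaches zero; a floor of
0.05 caps any single birth's contribution at 20 pregnancies, far beyond
plausible pregnancy loss, so in practice it only guards against fitting
artifacts. The value is configurable and recorded in the run config. The
identities $\hat U_b \le \hat P_b$ and $\hat P_b \ge 1$ hold by
construction, and with $\hat g \equiv 1$ the pregnancy outcomes collapse
exactly onto the birth outcomes — both are asserted in the suite.

## Geography and aggregation

Births are assigned to areas by even-odd ray casting over the polygon
tiling. Boundary points touch two adjacent polygons; they resolve to the
lexicographically smallest area id, a documented deterministic tie-break.
Points in no polygon are counted and excluded, as are records with
missing coordinates — both counts surface in the statewide report,
because such exclusions are part of the method's accounting.

Age bins default to 15–17, 18–20, 21–24, 25–29, 30–34, 35–45 (closed at
both extremes): fine where incidence varies fastest (teens and early
twenties), coarser above 35, and expressive enough to show the
characteristic peak among women roughly 18–30. The population table's
counts are used as denominators as-is. Cells with births but no
population denominator get an undefined (NA) incidence and are logged
rather than silently dropped.

## Density surfaces

The heat-map stage uses a quartic (biweight) kernel truncated at its
bandwidth — the kernel used by the standard desktop-GIS density tool this
output is meant to be comparable with — normalised so the surface
integrates to the total event weight per year. Events are weighted by
their expected-event values ($\hat Y_b$ or $\hat U_b$) rather than
thresholded, which preserves totals.

The bandwidth follows the mean-area-per-event rule:
$r = \sqrt{2\,A/E}$ with $A$ the study-region area and $E$ the *annual*
event count. Annual (not multi-year) counts are the default because they
reproduce both reference radii at Missouri scale — 2.4 miles for ~24,500
unintended births/yr and 1.9 miles for ~40,000 unintended
pregnancies/yr — from $A = 69{,}707$ sq mi.

The default cell size is $r/20$: at that resolution the discretised
surface conserves mass within 1%, which the suite verifies, along with
exact agreement with the closed-form kernel
$K(d) = \tfrac{3}{\pi r^2}(1-(d/r)^2)^2$ at cell centres. Coordinates are
assumed planar miles; real coordinates must be projected first. Surfaces
are written as ESRI ASCII grids (plain text) for portability.

## The synthetic generator

`ground_truth()` holds the true logistic models $f^*$ and $g^*$ and every
population parameter; `simulate_vital_records()` derives all four tables
and the polygon tiling from it deterministically. Design points:

* **Calibrated baselines.** Intercepts are calibrated by root-finding on
  the realised covariates so the marginal unintended share among births
  is 0.34 and the live-birth share of pregnancies 0.71 — the touchstone
  rates for this population. The default $f^*$ places its signal on
  marriage, private insurance, maternal age, parity and prenatal-care
  month (the dominant predictors this method is expected to surface);
  $g^*$ includes a negative intendedness term, so unintended pregnancies
  are less likely to end in live birth and the pregnancy percentage
  exceeds the birth percentage downstream.
* **Covariate marginals** (41% married, 55% privately insured, ages
  truncated-normal around 27, etc.) live in one documented block,
  `synth_marginals()`, so recovery tests reference the same constants the
  generator drew from.
* **Five-category response.** The binary truth is expanded to the five
  responses with fixed splits (unintended → *later* 70% / *never* 30%;
  intended → *sooner* 30% / *then* 55% / *unsure* 15%). Only the binary
  coding matters downstream; the splits exist so the coding-scheme
  sensitivity has realistic raw material, and the intended-side unsure
  share is large enough that the three codings produce clearly ordered
  statewide shares.
* **Survey weights** are gamma perturbations around 1/sampling-rate
  (mean exactly 1/rate; dispersion 0 gives a self-weighting census).
  This exercises every weighted estimator without simulating a
  multi-stage sampling design; it is a stand-in, not a design-based
  weight model.
* **Geographic heterogeneity through composition.** When per-area target
  shares are requested, the generator tilts each area's covariate mix
  (marriage and insurance down, age down, parity up in higher-risk
  areas) along a risk axis derived from the target, with a small
  per-area intercept residual making the calibration exact. This mirrors
  how real sub-state variation arises — areas differ in who lives there —
  and it is what makes area rankings *recoverable*: a classifier sees
  only covariates, so heterogeneity carried purely by hidden intercepts
  would be invisible to any method.
* **Geometry.** Rectangular tilings of a 69,707-sq-mi planar box stand in
  for the state's ~47 public-use microdata areas; coordinates are planar
  miles because the density radius rule is stated in miles. Missingness
  is injected MCAR at per-field rates.

What the generator does **not** emulate: informative nonresponse,
design-based weight construction, spatially correlated covariates within
areas, interstate movement, or the real joint distribution of birth-record
covariates. Passing recovery tests therefore demonstrates that the
estimator chain is correct and unbiased under its stated assumptions, not
that real-world selection or reporting biases are handled.

## Problem sizes and numerical choices

The test suite and examples run at sizes chosen to make sampling noise
small relative to the tolerances being asserted: distributional recovery
at 50,000 births (3-SE binomial bounds), statewide percentage recovery at
50,000 births with a 10% survey (±2 points), area-rank recovery over 20
replicates of 4,000 births each, and oracle equivalences at a few hundred
to 10,000 cases where the checks are exact. Intercept calibration uses
`uniroot` on [−30, 30] at tolerance 1e−10; stratified folds guarantee
both classes per fold whenever each class has at least K members; all
stochastic fits are seeded, xgboost runs single-threaded, and every
generator restores the caller's RNG state.

## Known limitations

* No confidence intervals: uncertainty from two stacked fitted models and
  derived ratios is not quantified here.
* Associations are held constant across the state; true area-varying
  coefficients would be attributed to composition.
* The live-birth correction inherits any underreporting of pregnancies
  not ending in birth in the underlying survey, biasing pregnancy counts
  downward.
* Planar geometry only; geodesic kernels and projections are out of
  scope.
* The intendedness outcome is the conventional binary coding; the
  sensitivity driver quantifies, but does not resolve, the "unsure"
  ambiguity.
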