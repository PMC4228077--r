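---
title: "Imputing mixed-type phenomic data: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imputing mixed-type phenomic data: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoimpute)
```

## The problem

Phenomic tables — hundreds of clinical and demographic variables on hundreds
of subjects — mix continuous measurements with ordinal scores, binary
indicators and multi-class nominal factors, and they are rarely complete.
Deleting incomplete rows wastes most of the data; imputing everything
blindly is risky because, unlike co-regulated omics features, many phenomic
variables associate with nothing else in the table. This package provides
(i) four K-nearest-neighbour imputers that handle all four variable types,
(ii) a per-cell *imputability measure* that quantifies whether a missing
value can be imputed at all, and (iii) a *self-training selection* scheme
that picks the best imputer for the data at hand without ground truth.

## Data model

A `phenomic_table` stores an N × P numeric code matrix plus per-variable
type metadata. Ordinal levels are coded 1..q in their declared order, binary
variables 0/1, nominal labels 1..L; the missingness mask is identically
`is.na()` of the codes, so values and mask cannot disagree. Coding maps are
bijections per variable, and `read_phenomic_csv()` → `write_imputed_csv()`
round-trips values, mask and spec exactly. A nominal variable declared with
two levels is normalized to binary so the correlation dispatch below is
unambiguous.

## Mixed-type correlation

Neighbour variables are ranked by the distance d = |1 − r|, where r comes
from a type-dispatched measure: Spearman (both continuous), polyserial
(continuous–ordinal), polychoric (both ordinal), point biserial = Pearson on
the 0/1 coding (continuous–binary) and its unsigned multi-class extension
(the correlation ratio under the normal-conditional model), the analogous
rank-biserial forms with midranks for ordinal inputs, phi (both binary) and
Cramér's V (nominal pairs). All reduce to, or generalize, the Pearson
correlation, which is what makes values comparable across type pairs when
selecting the K nearest neighbours.

Numerical choices:

* **Pairwise-complete estimation** with a minimum of `min_pairs = 10`
  complete pairs (configurable); pairs below the threshold get r = 0 and are
  ineligible as neighbours. Under general missingness pairwise deletion is
  the only workable option.
* **Midranks for ties** in every rank-based measure.
* **Phi is signed** by the Pearson correlation of the 0/1 codes, making phi
  literally equal to Pearson on 0/1 (its defining property); Cramér's V and
  the multi-class biserial extensions are unsigned in [0, 1].
* **Polyserial/polychoric by two-step ML**: thresholds from the marginal
  level frequencies through the inverse normal CDF, then a 1-D likelihood
  maximization over the latent correlation (`optimize`, tolerance 1e-6, rho
  restricted to (−0.999, 0.999)). Two-step estimation is markedly faster and
  more robust than full ML and is the standard practical choice; the tests
  verify parameter recovery against known generating correlations.
  Bivariate-normal cell probabilities use 32-node Gauss–Legendre quadrature
  of the conditional normal CDF over latent intervals clipped at ±8 sd. At
  |rho| near 1 with step-like integrands the quadrature loses accuracy, but
  the likelihood is then monotone toward the boundary, so estimates remain
  correctly pinned near ±1.
* **Degenerate inputs** (constant vectors, single observed level) return 0
  with a flag rather than failing, so a full P × P matrix can always be
  assembled; flagged pairs are excluded from neighbour selection.
* The distance d = |1 − r| makes strongly *negative* correlations distant,
  although their regressions would be informative. We implement the formula
  as defined; ranking by 1 − |r| is available as a non-default option
  (`variable_distance_matrix(..., rank_by_abs = TRUE)`).

## The four imputers

All four share the neighbour weight w_k = (r_k²/(1 − r_k² + ε))², ε = 1e−6,
which grows steeply as |r| → 1 so that near-perfect neighbours dominate.

**KNN-V.** For a missing cell (i, j), the K variables closest to j that are
observed at subject i (and share ≥ `min_pairs` observations with j) each
contribute a prediction from a single-predictor GLM fitted on available
cases: linear regression for continuous targets, cumulative-logit (ordinal
logistic) for ordinal, logistic for binary, multinomial logistic for
nominal. Aggregation is the w-weighted average (continuous), the rounded
weighted average clipped to [1, q] (ordinal), or the w-weighted majority
vote over predicted classes (nominal). Design details:

* A cumulative-logit model has no scalar inverse link, so the per-neighbour
  ordinal prediction is the *expected level* Σ m·P(level m); it feeds the
  rounded weighted average naturally.
* Nominal predictors enter the GLMs as factors (their codes carry no
  order); numeric predictors (continuous, ordinal, binary) enter linearly.
* With a discrete predictor the single-predictor multinomial logistic is
  saturated, so its argmax prediction *is* the conditional mode of the
  contingency table; we compute it directly.
* When a GLM fit fails — separation, sparse levels, degenerate predictors,
  all common in skewed clinical nominals — the neighbour falls back to the
  conditional mode (discrete targets) or conditional mean (continuous
  targets) given the neighbour's value, binning continuous neighbours into
  quintiles; ordinal fits try ordinal logistic → multinomial → contingency.
  Nominal targets with more than 10 levels or near-empty classes go straight
  to the contingency table for stability.
* A cell with no eligible neighbour at all falls back to the column
  marginal (mean / rounded mean / lowest-tie mode) and is flagged
  `marginal_fallback` in the provenance.
* Per-pair fits are cached within one imputation run: the fit depends only
  on the (target, neighbour) pair, not on the cell, so refitting per cell
  would change nothing but the runtime.

**KNN-S.** Subjects are compared by Gower distance: nominal variables
contribute 0/1 match/mismatch, continuous and ordinal variables the absolute
difference divided by the variable's total observed range (ordinal on its
integer codes), averaged over variables observed in both subjects. Subject
pairs sharing no observed variable get distance 1 and an `incomparable`
flag. The K nearest subjects observed at the target variable supply their
raw values, weighted through the same w(r) with similarity r = 1 − d and
aggregated by the same type rules. Two readings of "the same procedure as
KNN-V" were possible; we aggregate raw neighbour values without per-neighbour
GLMs because a single-predictor regression *across* a mixed-type subject
vector is not well defined, while the weighting/aggregation carries over
unchanged.

**KNN-H.** The convex combination p·KNN-S + (1 − p)·KNN-V per cell
(continuous: linear mix; ordinal: mix, round, clip; nominal: the two
candidate values vote with weights p and 1 − p, ties to the lower code). The
weight is estimated by hiding a second layer of 5% of the observed cells,
imputing it with both base methods, and minimizing the total squared mixture
error Σ(p·e_S + (1 − p)·e_V)² over the paired signed normalized errors,
giving

p̂ = clip[(Σe_V² − Σe_S·e_V) / (Σe_S² − 2Σe_S·e_V + Σe_V²), 0, 1],

averaged over 20 repetitions. Note the numerator: the minimizer of the
stated objective must give full weight to a method with zero error
(e_S ≡ 0 ⇒ p̂ = 1), which fixes the orientation of the closed form. Errors
pool across data types — each type's error is already normalized to a
comparable scale (continuous by the column sd, ordinal by q − 1, nominal a
0/1 indicator) — so one p serves the whole table. A vanishing denominator
(both methods identical on the layer) returns p̂ = 0.5, flagged.

**KNN-A.** The informativeness of variable neighbours varies with r_max,
the correlation between a variable and its closest neighbour: where r_max is
high KNN-V is nearly exact, where it is low only subjects can help. The
paired errors are therefore pooled across repetitions and p is re-estimated
within each sliding window (r_max − 0.1, r_max + 0.1) on a 0.01-step grid,
requiring at least 10 error pairs per window; sparser windows inherit the
global p̂, flagged. Each cell then uses the window weight at its variable's
r_max.

Defaults K = 5, second-layer rate 5%, 20 repetitions are the package-wide
conventions; K in the 5–15 range changes results little on block-correlated
data, and 5 is the cheapest of those.

## Evaluation metrics

e² = (ŷ − y)²/var(y_j) for continuous cells (variance of the truth column,
denominator n − 1), ((ŷ − y)/(q − 1))² for ordinal, and a misclassification
indicator for nominal; RMSE = √(mean e²) per type, PFC = mean(e). The
continuous normalization calibrates the scale: mean imputation under MCAR
has RMSE → 1, which the tests verify, so any method's RMSE reads as a
fraction of the baseline error. Zero-variance columns are excluded from the
continuous RMSE and flagged. `compare_methods()` uses a paired design —
every method sees the identical missing-data realization within a
repetition — so between-method differences are attributable to the methods.

## Imputability

For t repetitions (default 10) a second layer of 5% of the observed cells is
hidden and imputed with KNN-S and KNN-V. E_i is the mean over repetitions of
the per-repetition RMSE of subject i's hidden cells under KNN-S; E_j the
analogue for variable j under KNN-V; IMs_i = exp(−E_i), IMv_j = exp(−E_j),
and a missing cell's IM is max(IMs_i, IMv_j) — imputable from *either*
direction is enough. IM = 1 iff the average error is exactly zero, and IM
decreases monotonically in the error. Subjects or variables never hit by any
second layer inherit the pooled global error, flagged `unsampled`; we
average only over repetitions with at least one hit because an absent
repetition carries no information about that subject. IM is defined through
KNN-S/KNN-V regardless of which imputer is later selected (the subject and
variable directions are exactly what the two base methods probe); computing
IM from the selected method instead is exposed as
`compute_im(..., method = "selected")`.

`filter_by_im()` partitions missing cells by quantile (default: flag the
lowest 25%) or by an absolute threshold; ties break deterministically by
(i, j) order. The package only flags — it never deletes.

## Self-training selection and the guideline

`sts_select()` hides n second layers (default 20, all methods see identical
layers), scores each registered imputer per data type (RMSE for continuous
and ordinal, PFC for nominal), and selects the arg-min of the mean error per
type; methods within 5% of the minimum are reported as comparable, since
differences that small are within simulation noise. Methods failing on more
than half the repetitions are excluded. `sts_accuracy()` evaluates the
scheme itself on a complete table: the "true best" per realization is the
comparable-best set on the first-layer cells, and accuracy is the fraction
of realizations in which the STS pick lands in that set.

`run_guideline()` chains the pieces: STS per data type → IM → imputation of
each type with its winning method → either Option A (all cells imputed,
IMs reported alongside for downstream down-weighting) or Option B (only
cells passing the IM filter imputed; the rest stay missing, flagged). Stage
seeds derive from the master seed by fixed offsets (+1, +2, +3), so stages
are decoupled yet the run is reproducible; with one seed, Option B's imputed
cells are exactly Option A's output restricted to the passing cells.
External imputers (e.g. random-forest or chained-equation packages) can join
the roster through `register_imputer()`; re-implementing them is out of
scope here.

## The simulation scenarios

The generators produce complete 600 × 300 mixed-type tables (any `scale`
shrinks N, P, cluster-size means and discretization counts proportionally):

* **Scenario I**: 6 variable clusters (sizes Poisson(40)) built as linear
  transforms α + β·basis of a shared N(μ, 4) basis, μ ~ UNIF(−2, 2); we
  draw α ~ UNIF(−1, 1), β ~ UNIF(0.5, 2) — positive slopes keep
  within-cluster correlations positive, matching the intended structure.
  Six subject clusters (sizes Poisson(80)) each add a shared N(1, 2) row
  vector; unclustered subjects add independent N(0, 4) vectors (the additive
  reading preserves both structures simultaneously). Then 100 variables are
  cut into nominals and 60 into ordinals with 3–6 levels at random quantile
  points; nominal labels are shuffled so codes carry no order. Subject bases
  are added *before* discretization.
* **Scenario II**: 20 clusters of each kind, sizes Poisson(15)/Poisson(25).
* **Scenario III**: no variable clusters; 40 subject clusters
  (sizes Poisson(14)) share a base vector (entries N(0, 4), a choice the
  construction leaves open) plus N(0, 0.01) noise — near-duplicate subjects,
  essentially uncorrelated variables. 100 variables become sparse nominals:
  the 5%/95% extreme quantiles are always cut points plus up to 27 more from
  UNIF(0.01, 0.99), giving up to 30 levels, none ordinal (the scenario
  mirrors sparse clinical nominals).

Poisson cluster sizes are forced ≥ 1 and truncated in declaration order if
they overshoot N or P, the remainder staying unclustered. The generators
emulate *block correlation, mixed types and sparse levels*; they do not
emulate real phenomic features such as skewed or heavy-tailed continuous
marginals, MAR/MNAR missingness, logical dependencies between variables, or
longitudinal structure — so passing tests demonstrate correct behaviour
under MCAR with Gaussian-latent structure, not performance guarantees on
arbitrary clinical data.

## Problem sizes and caching

The test-bed runs use scale 1/3 (200 × 100) or 1/4 tables with 5%
missingness, 10 seeds for ordering claims and 10 reduced second-layer
repetitions for the hybrid weights — sizes at which every structural effect
of the full-scale scenarios is already stable while a full suite run stays
in the minutes. One deliberate economy: within second-layer procedures the
variable correlation matrix is computed once on the first-layer table and
reused across repetitions, and Gower distances are updated incrementally for
the hidden cells (the update is exact, as the tests verify). A second layer
removes only ~5% of cells, which perturbs P² latent-ML correlation estimates
negligibly, while recomputing them per repetition would dominate the entire
runtime. Externally registered imputers see only the two-layer table; no
caching crosses that interface.

## Known limitations

* MCAR second layers calibrate p̂, IM and STS; under MAR/MNAR missingness
  the second layer is not distributionally representative of the first, and
  all three inherit that bias.
* Single imputation only: no between-imputation variance, so downstream
  standard errors ignore imputation uncertainty (IMs can down-weight, not
  replace, proper multiple imputation).
* The |1 − r| neighbour ranking discards strongly negative correlates by
  design fidelity; flip `rank_by_abs` if your data contain informative
  negative relationships.
* Cells are imputed independently from observed data only — no chained
  updates — so imputed values never feed later fits within a run.
* Gower distance weights all shared variables equally; dominated by nominal
  mismatches when nominals outnumber numeric variables.
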