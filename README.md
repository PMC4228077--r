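# phenoimpute

Missing-value imputation, imputability assessment and data-driven method
selection for **mixed-type phenomic tables** — the subjects × variables
matrices of demographic and clinical covariates (continuous, ordinal, binary
and multi-class nominal) that accompany modern cohort studies. Unlike omics
matrices, many phenomic variables correlate with nothing else in the table,
so some missing cells simply *cannot* be imputed well; this package both
imputes and tells you which cells to trust.

## What it implements

**Four KNN imputers on a common weighting scheme.** The weight of the k-th
nearest neighbour with correlation (or similarity) r_k is

    w_k = ( r_k^2 / (1 − r_k^2 + ε) )^2 ,   ε = 1e−6

* **KNN-V** (nearest variables): variables are ranked by the distance
  d = |1 − r| under a mixed-type correlation suite — Spearman (Con–Con),
  polyserial (Con–Ord), polychoric (Ord–Ord), point/rank biserial and their
  multi-class extensions (Con/Ord–Bin/Cat), phi (Bin–Bin) and Cramér's V
  (Bin/Cat–Cat) — all Pearson-comparable so neighbours can be ranked across
  types. Each of the K neighbours observed at the target subject contributes
  a single-predictor GLM prediction (linear, ordinal-logistic, logistic or
  multinomial-logistic by target type, with a contingency-table fallback when
  a fit fails on sparse levels). Predictions are pooled by the weighted
  average (continuous), its rounded value clipped to [1, q] (ordinal), or a
  weighted majority vote (nominal).
* **KNN-S** (nearest subjects): neighbours under Gower distance (match /
  mismatch for nominal variables, range-scaled absolute difference for
  numeric and ordinal ones, averaged over variables observed in both
  subjects); the neighbours' observed values of the target variable are
  pooled with the same rules, with similarity r = 1 − d.
* **KNN-H**: the convex combination `p·KNN-S + (1 − p)·KNN-V`, with p chosen
  to minimise the total squared error of the mixture on a simulated "second
  layer" of missing values (5% of the observed cells, 20 repetitions):
  p̂ = clip[(Σe_V² − Σe_S e_V) / (Σe_S² − 2Σe_S e_V + Σe_V²), 0, 1].
* **KNN-A**: as KNN-H, but p varies with r_max (the correlation between a
  cell's variable and its closest neighbour variable), estimated in sliding
  windows (r_max ± 0.1) with at least 10 error pairs each.

**Imputability measure (IM).** Per subject, IMs_i = exp(−E_i) where E_i is
the average second-layer RMSE of subject i under KNN-S; per variable,
IMv_j = exp(−E_j) under KNN-V; a missing cell's IM is max(IMs_i, IMv_j) ∈
(0, 1]. Low-IM cells have no usable neighbours in either direction and
should be imputed with caution or not at all.

**Self-training selection (STS).** Without ground truth, every candidate
imputer is scored on identical second layers of missing values; the method
with the smallest average RMSE (continuous/ordinal) or PFC (nominal) per
data type wins, with methods within 5% of the minimum reported as
comparable.

**Evaluation metrics.** e² = (ŷ−y)²/var(y_j) for continuous cells,
((ŷ−y)/(q−1))² for ordinal, a 0/1 misclassification indicator for nominal;
RMSE = √(mean e²), PFC = mean(e).

**Simulation scenarios.** Three seeded generators of complete 600 × 300
mixed-type tables (scalable down) with Poisson-sized variable/subject
clusters: block-correlated variables and subjects (I), many small clusters
(II), and subject-only structure with sparse many-level nominals (III) —
the benchmark bed used throughout the tests.

## Worked example

```r
library(phenoimpute)

cd  <- simulate_phenomic("I", seed = 42, scale = 1/3)   # complete 200 x 100 table
md  <- generate_missing(cd, m = 0.05, seed = 1)         # hide 5% of the cells
md
#> phenomic_table: 200 subjects x 100 variables (1000 missing cells, 5.0%)
#>   types: continuous=47, ordinal=20, binary=0, categorical=33

res <- impute_phenomic(md, method = "knn-a", n_reps = 10, seed = 2)
res
#> phenomic_imputation: method 'knn-a' (K = 5), 1000 cells imputed
#>   hybrid weight p_global = 0.257 (adaptive)
#>   cells with fallback flags: 0 (0.0%)

evaluate_imputation(res, cd, missing_layer(md, cd))
#> imputation_eval:
#>   continuous RMSE: 0.4397  (n = 471)
#>   ordinal    RMSE: 0.1924  (n = 204)
#>   nominal    PFC : 0.3508  (n = 325)

compute_im(md, t = 5, seed = 3)
#> imputability_scores (t = 5, rate = 5%, knn-vs):
#>   IMs (subjects):  median 0.627, range [0.378, 0.872]
#>   IMv (variables): median 0.685, range [0.477, 0.884]
#>   1000 missing cells scored

sts_select(md, c("mean", "knn-v", "knn-s"), n_reps = 5, seed = 4)
#> sts_report (5 second-layer repetitions at 5% rate):
#>       continuous ordinal nominal
#> mean      1.0055  0.4020  0.5573
#> knn-v     0.4459  0.2229  0.3010
#> knn-s     0.5979  0.2678  0.3778
#>   continuous: selected 'knn-v' (comparable: knn-v)
#>   ordinal: selected 'knn-v' (comparable: knn-v)
#>   nominal: selected 'knn-v' (comparable: knn-v)
```

The normalized continuous RMSE reads directly against the mean-imputation
baseline, which sits at 1 by construction: 0.44 means the adaptive hybrid
removes more than half of the baseline error on this table. The IM medians
(~0.63–0.69 ≈ exp(−0.4)) say a typical cell imputes with roughly 0.4
normalized RMSE; cells near the low end of the range are the ones to flag.
STS picks KNN-V here because this scenario has strong variable clusters.

The full pipeline (STS → IM → impute with the per-type winners, Option A
"impute everything, report IMs" or Option B "impute only cells above an IM
threshold") is `run_guideline()`, also exposed as a command-line tool:

```sh
$(Rscript -e 'cat(system.file("exec", "phenoimpute", package = "phenoimpute"))') \
  run --table MD.csv --spec spec.json --option B --im-cutoff 0.25 --seed 17 --out-dir results/
```

Tables are read/written as CSV with a JSON type-spec sidecar
(`read_phenomic_csv()` / `write_imputed_csv()`); see `?phenomic_table`.

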