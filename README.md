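# clustall

Robust consensus-based stratification of patient cohorts described by
mixed-type clinical data, with missing values handled by multiple
imputation.

## The problem

Given a cohort table — one row per patient, columns mixing numeric
laboratory values, binary manifestations, ordinal grades and nominal
categories, with cells missing — find the subgroup structure that is
*actually there*, not the structure induced by one particular choice of
variables, distance metric, clustering algorithm or imputation. The
package targets clinical researchers stratifying observational cohorts
(the motivating use case is acute decompensation of cirrhosis at hospital
admission) where a published subgroup must survive a change of pipeline
settings to be credible.

## The method

1. **Complexity reduction.** Encoded features are grouped by a dendrogram
   under the dissimilarity `1 − |r|` (pairwise-complete Pearson, average
   linkage). Every non-trivial cut ("depth", `g ∈ {2, …, d−1}` groups)
   replaces each group by its first ≤ 3 principal components (standardized
   columns; singletons pass through), giving one embedding per depth —
   `d` columns with distinct merge heights yield `d − 2` depths.

2. **Stratification.** Each embedding is clustered under
   correlation distance `d(i,j) = 1 − r(i,j)` (k-means on row-standardized
   rows, average-linkage hierarchical) and Gower dissimilarity
   (PAM/k-medoids, hierarchical), for `k ∈ {2,…,6}`. The `k` per
   combination is the consensus of three internal validity indices —
   WB-ratio (↓), Dunn (↑), average silhouette (↑) — majority vote,
   silhouette as arbiter. One candidate stratification per
   `depth × metric × method`, i.e. `4 × #depths` candidates.

3. **Missing data.** The table is imputed `m` times by chained equations
   (predictive mean matching / logistic / multinomial / ordered logit by
   feature kind). Per combination, the modal `k` across imputations is
   kept and the `m` partitions are consolidated through the co-assignment
   matrix `freq[i,j]` = fraction of imputations co-clustering patients
   `i, j` (correlation distance on its rows, one hierarchical cut).

4. **Robustness.** Each candidate is re-clustered on `B` bootstrap
   resamples; per-cluster stability is the mean best Jaccard match to the
   original cluster, and candidates whose *minimum* cluster stability is
   below 0.85 are excluded. Survivors are compared by pair-counting
   Jaccard distance, grouped (average linkage, cut at `τ = 0.3`), and each
   group with ≥ 5 members contributes its centroid as a final
   representative. None, one, or several representatives are all valid
   outcomes.

5. **Signature & transfer.** Representatives are characterized by a
   minimal predictive signature (forward–backward selection with early
   dropping, multinomial-logistic likelihood-ratio tests) and reproduced
   in external cohorts by kNN on reference-standardized signature columns
   with majority voting across target imputations.

## Worked example

A 300-patient cohort with 30 mixed-type features in three correlated
blocks, three planted subgroups at effect size 4 SD on 40% of features,
and 20% of cells deleted completely at random:

```r
library(clustall)

sim <- generate_cohort(sim_config(
  n_patients = 300,
  feature_blocks = list(
    list(kinds = c(numeric = 8, binary = 2, nominal = 1, ordinal = 1), rho = 0.45),
    list(kinds = c(numeric = 6, binary = 3, nominal = 1, ordinal = 1), rho = 0.30),
    list(kinds = c(numeric = 4, binary = 2, nominal = 1), rho = 0.15)),
  n_clusters = 3, effect_size = 4, informative_frac = 0.4,
  missing_rate = 0.2, seed = 101))
print(sim$cohort)
#> cohort_table: 300 patients x 30 features (20.0% missing)
#>   kinds: binary=7, nominal=3, numeric=18, ordinal=2

ens <- run_pipeline(sim$cohort, run_config(m = 20, B = 100, seed = 101))
print(ens)
#> strat_ensemble: 136 candidates -> 74 robust -> 1 representatives
#> stratification depth1_correlation_hierarchical: k=3,
#>   sizes [100, 100, 100], min stability 0.959
```

The 30 features encode to 34 columns, hence 136 candidates
(34 depths × 4 combinations). 74 candidates pass the 0.85 bootstrap
stability filter; they fall into 3 groups, one of which has ≥ 5 members
and therefore yields a representative: a 3-cluster partition of 100/100/100
patients whose weakest cluster has bootstrap Jaccard stability 0.959. It
matches the planted subgroups exactly (adjusted Rand index 1.0 against
`sim$true_labels`). A minimal signature for it:

```r
enc <- encode_cohort(filter_features_by_missingness(sim$cohort))
imp <- impute_chained(enc, m = 20, seed = 101)
minimal_signature(imp$datasets[[1]], ens$representatives[[1]]$labels)
#> signature (3 features): num14, num6, num7
```

`write_outputs()` (or `run_pipeline(..., out_dir = )`) persists labels,
per-cluster stabilities, a JSON run summary and the log;
`select_K()`/`transfer_labels()` carry a fitted stratification to a new
cohort. A thin command-line front-end with `run`, `simulate`, `transfer`,
`report` and `config` subcommands is installed at `inst/cli/clustall.R`.

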