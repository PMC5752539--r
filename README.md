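# mirtarkey

Discovery of **prognosis-related key miRNA–target interactions** from paired
tumor/normal miRNA and mRNA expression with survival follow-up.

MicroRNAs repress their target mRNAs, and the loss or gain of a specific
miRNA–target regulation can drive tumor progression. `mirtarkey` treats the
*pair* — a disease-associated miRNA together with one predicted target — as
the unit of prognostic information and selects the pairs whose expression
ratio is stably associated with overall survival. It is aimed at
computational biologists analysing TCGA-like cohorts (expression matrices +
clinical tables) who want a reproducible, fully tested implementation of the
whole chain: screening, stability selection, network characterization,
hallmark impact scoring and signature evaluation.

## Method

For each candidate pair (m, g) from a predicted-target catalogue:

1. **Dysregulation screen.** m and g must be differentially expressed
   (Welch test on log2 RPM/RPKM, BH FDR < 0.05, fold change > 1.2) in
   *opposite* directions, and the reversed pattern (m high ∧ g low per
   median dichotomization, or the mirror image) must occur in > 20% of
   tumors.
2. **Resampled Cox stability selection.** Outcome-extreme patient groups
   are defined from the 95% CI of the Kaplan–Meier median survival
   (good: time above the upper bound; poor: death below the lower bound).
   Across 1,000 resamples of 80% of each group, a univariate Cox model of
   survival on the per-patient log ratio x = log2 m − log2 g is fitted
   (Newton–Raphson, Efron ties). The pair passes if the coefficient β keeps
   one sign in every resample and Wald p < 0.05 in > 60% of them.
3. **Log-rank confirmation.** Patients split by the reversed expression
   pattern must differ in survival (log-rank p < 0.05, full cohort). The
   survivors are the *key interactions*, labelled high-risk (β > 0) or
   low-risk (β < 0).

Downstream: bipartite-network degree statistics with a log–log least-squares
power-law fit and hub calling (top 10% of nodes by degree, ≥ 10 targets);
hallmark impact via random walk with restart (r = 0.7) on a PPI network
scored as the median steady-state probability over each hallmark's pathway
genes, tested against 1,000 degree-preserving edge rewirings; and signature
evaluation by k-means patient clustering on the interaction-ratio matrix
with log-rank and age/gender-adjusted Cox models.

A synthetic-cohort generator (`simulate_cohort()`) emulates the full input
suite — negative-binomial counts with planted negative regulations,
proportional-hazards survival on the planted ratios, a scale-free PPI
network, pathway sets with a planted "metastasis-like" hallmark, candidate
lists with decoys — and carries ground truth for recovery testing.

## Worked example

```r
library(mirtarkey)

cohort <- simulate_cohort(sim_config(seed = 1))         # synthetic TCGA-like cohort
res    <- run_pipeline(cohort, mtk_config(n_resamples = 200, seed = 1))
res$key_interactions
```

```
    mirna   target mirna_dir target_dir pattern_fraction median_beta beta_sign sig_freq logrank_p risk_group
1 miR-008 gene0638        up       down            0.405       0.155         1    0.965   0.01536  high-risk
2 miR-026 gene1863      down         up            0.400      -0.194        -1    1.000   0.00124   low-risk
3 miR-073 gene0891        up       down            0.380       0.142         1    0.900   0.01900  high-risk
4 miR-077 gene0017        up       down            0.380       0.118         1    0.725   0.01538  high-risk
5 miR-079 gene0965        up       down            0.385       0.168         1    1.000   0.00741  high-risk
6 miR-081 gene1657      down         up            0.390      -0.149        -1    0.825   0.02687   low-risk
```

Six pairs survive all three stages. Each row reads: the miRNA is
differentially expressed opposite to its target, the reversed high/low
pattern covers ~40% of tumors, the Cox coefficient on the log ratio kept
one sign across all 200 resamples and was significant in 72–100% of them
(`sig_freq`), and the pattern-split log-rank test confirms a survival
difference. `risk_group` says whether a *larger* miRNA:target ratio raises
(`high-risk`) or lowers (`low-risk`) the hazard.

```r
recovery_metrics(res$key_interactions, cohort$truth)
#> $sensitivity 0.6   $fdp 0   $n_selected 6   $n_true 10
```

All six selections are planted prognostic pairs (no false discoveries; 6 of
the 10 planted pairs recovered at this seed).

```r
hallmark_permutation_test(cohort$ppi, cohort$truth$target,
                          cohort$gene_sets, cohort$hallmark_map,
                          mtk_config(n_permutations = 200, seed = 1))
#>                         hallmark    score       p n_permutations significant
#> 1 tissue_invasion_and_metastasis 6.17e-04 0.00498            200        TRUE
#> 2                neutral_process 6.12e-05 0.20896            200       FALSE
```

The planted metastasis-like hallmark scores ten times the neutral one and
is the only one significant against the degree-preserving rewiring null.

See `vignettes/key-interaction-discovery.Rmd` for the model, parameter and
design discussion.

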