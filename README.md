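# sepsig

Gene-expression prognostic signatures for 30-day sepsis mortality, and the
multi-cohort machinery to evaluate them.

Sepsis outcomes are hard to predict from bedside severity scores alone.
Whole-blood transcriptomics offers a direct readout of the dysregulated
host response, and several groups have published small gene signatures
that stratify mortality risk. This package is for computational
researchers who want to score expression cohorts with such signatures,
retrain parametrized predictors, and evaluate prognostic performance
across many heterogeneous cohorts the way multi-cohort validation studies
do — without rebuilding ROC meta-analysis, reclassification statistics and
enrichment filters each time.

## What is implemented

**Signature scoring.** The parameter-free difference-of-geometric-means
score. For a sample with log2 expression *x* and a signature with up-gene
set *U* (higher in non-survivors) and down-gene set *D*,

    S = mean_{g in U} x_g  -  mean_{g in D} x_g

(the geometric mean in linear space is the arithmetic mean in log2 space).
Higher *S* means higher predicted mortality risk. The four published
predictors (Duke 5 up / 13 down; Sage LR 9/9; Sage RF 13/4; Stanford 8/4)
ship as a built-in fixture; their directional union is 58 genes (31 up,
27 down).

**Re-trainable models.** Cross-cohort feature selection (per-cohort Welch
t statistics combined by √n-weighted Stouffer z), elastic-net logistic
regression (glmnet, CV-selected penalty) and a class-weighted random
forest, plus a rank-average ensemble.

**Evaluation.** Trapezoidal AUROC (= pairwise concordance, ties ½) with
stratified-bootstrap CIs, trapezoidal AUPRC, Kester–Buntinx summary ROC
curves across cohorts (logit-linear D–S fit, inverse-variance point
weights), operating points at a target sensitivity, test characteristics,
joint severity + gene-score logistic models, continuous net
reclassification improvement (cNRI, range \[−2, 2\]), paired AUROC tests,
inter-model Spearman rank correlation, 3-of-4 consensus classification,
and a longitudinal slope/level comparison.

**Preprocessing.** Probe-to-gene collapse by probe means, between-arrays
quantile normalization, log2-CPM with voom precision weights, and the
first-48-hours / known-outcome sample filters.

**Enrichment.** GMT gene sets over a background universe, the ≥3-gene and
≥10% retention filter, one-sided Fisher's exact tests with BH correction,
and cell-type profile enrichment with permutation p-values.

**Synthetic cohorts.** `simulate_multicohort()` generates multi-cohort
log2 expression with the structure the analyses assume: a latent risk
drives both death and the clinical severity covariate, signature genes
shift in non-survivors, cohorts differ by batch shifts and mortality
rates (drawn around 23.2% ± 13.4%). Every stage of the pipeline is
testable without downloading any accession.

## Worked example

```r
library(sepsig)

sigs   <- sepsis_signatures()          # the four built-in predictors
pooled <- pooled_union(sigs)           # 58 genes, 31 up / 27 down

cfg <- sim_config(n_cohorts = 5, n_samples = 100, mortality_rate = 0.25,
                  delta = 0.4, signature = pooled, n_noise_genes = 200,
                  seed = 42)
sim <- simulate_multicohort(cfg)
rep <- run_validation_pipeline(sim, n_boot = 200, seed = 42)
print(rep)
```

```
Multi-cohort validation report: 5 evaluable cohort(s), 4 signatures
  summary AUROC Duke: 0.882
  summary AUROC SageLR: 0.855
  summary AUROC SageRF: 0.799
  summary AUROC Stanford: 0.829
  ensemble AUROC: 0.958, AUPRC: 0.9
```

Each summary AUROC is the cross-cohort Kester–Buntinx estimate for one
signature; the ensemble line pools the within-cohort rank-normalized
scores of all four. Per-cohort detail:

```r
print(rep$per_cohort$C01$Stanford)
#> AUROC 0.815 (95% CI 0.719-0.886), AUPRC 0.68 at prevalence 0.27
#> (27 died / 73 survived)
```

Comparison against the simulated clinical severity score in the same
cohort (severity-only, gene-only and joint logistic models, plus the cNRI
of the joint model over severity alone):

```r
rep$severity_comparison$C01$Stanford
#> severity AUROC 0.729, gene AUROC 0.815, joint AUROC 0.864,
#> cNRI 0.86 (p = 2.6e-05)
```

The joint model outperforms either covariate because severity and the
gene score are coupled to the same latent risk through different paths —
the property the evaluation machinery is designed to detect. Inter-model
agreement on this run spans Spearman rho 0.29–0.45, and at each model's
90%-sensitivity threshold 54% of patients are correctly classified by at
least 3 of 4 models.

The 21-cohort study registry is also bundled:

```r
summarize_mortality(load_cohort_registry(), roles = "discovery")
#> $total_survived 485 ; $total_died 157 ...
```

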