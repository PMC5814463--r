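---
title: "Methods: multi-cohort evaluation of sepsis-mortality gene signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-cohort evaluation of sepsis-mortality gene signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepsig)
```

This vignette documents the statistical content of the package: the
models and formulas, their assumptions, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate,
and the numerical and design choices that were genuinely open.

## The signature score

The core statistic is the parameter-free difference of geometric means.
For a signature with up-gene set $U$ (expected higher in non-survivors)
and down-gene set $D$, and a sample with log2 expression $x_g$,

$$ S \;=\; \frac{1}{|U|}\sum_{g \in U} x_g \;-\; \frac{1}{|D|}\sum_{g \in D} x_g. $$

On the linear scale this is the log2 ratio of the two geometric means;
we compute it in log2 space, where it is exact and numerically safe.
Three properties follow directly and are enforced by tests: adding a
constant to a sample's log2 values (equivalently, rescaling the linear
expression) leaves $S$ unchanged; swapping $U$ and $D$ negates $S$; and
$S$ is monotone in each member gene. Because the score has no fitted
weights, genes missing from a matrix are simply dropped and the means
renormalize over the genes present — with a warning, since a heavily
truncated signature is not the published one. Linear-scale input must be
log2-transformed first; values are floored at $2^{-10}$ so zeros do not
produce infinities. The floor only matters for background-subtracted
array values near zero and is far below biologically meaningful signal.

Four published predictors ship as a fixture (Duke 5 up / 13 down, Sage
LR 9/9, Sage RF 13/4, Stanford 8/4). Gene identity is the upper-cased
official symbol string, with no alias resolution: the source tables
operate on symbols, and resolving aliases would make results depend on
an external annotation snapshot. Legacy symbols (e.g. *EMR3*, *IL8*,
*SEPP1*) are preserved verbatim for the same reason. The fixture file is
checksum-guarded. Pooling the four lists gives 58 genes (31 up, 27
down); a gene assigned opposite directions by two signatures would be a
directional conflict and is an error — none occurs in the fixture.

## Preprocessing

*Probe collapse.* A gene's expression is the arithmetic mean of its
probes' rows. Probes mapping to multiple genes are rejected rather than
duplicated: duplication would double-count those measurements in any
downstream mean. Unmapped probes are dropped with a count.

*Quantile normalization* uses `limma::normalizeQuantiles(ties = TRUE)`,
so tied values receive the mean of the reference distribution over their
tied ranks — the dominant convention. The operation is idempotent and
equalizes column sums, both covered by tests.

*RNA-seq.* Counts are transformed to
$\log_2\!\big((c + 0.5)/(L + 1)\times 10^6\big)$ with per-observation
precision weights from the fitted mean–variance trend (`limma::voom`).
The final expression is, by default, the element-wise product of weight
and log2-CPM. Multiplying precision weights into the expression values
is an unusual use of weights — the conventional route carries them into a
weighted model fit — but it is the construction this pipeline
standardizes on for compatibility across cohorts, and
`weighted = FALSE` returns plain log2-CPM with weights alongside for
users who prefer the conventional route. Note the direction of the
weight–mean relation: for overdispersed counts the log-scale variance
behaves like $1/\mu + \phi$, so the *low*-count observations are the
noisiest and precision weights **increase** with the fitted mean. The
test suite checks this direction with a negative-binomial Monte-Carlo
oracle (dispersion 0.2).

*Sample filters.* The inclusion window keeps samples with sampling time
in $[0, 48]$ hours — the boundary is closed, a choice the window's prose
description leaves open — and missing times are kept (and logged) rather
than dropped, since many cohorts annotate admission sampling only
implicitly. Samples with unclear 30-day mortality can be excluded where
an outcome is required.

## Re-trainable predictors

*Feature selection.* Per cohort, each gene gets a Welch t statistic
(non-survivors minus survivors), mapped to a z score through the probit
transform of its one-sided p (clamped at $10^{-15}$ to keep the
transform finite). Cohort z scores are combined by Stouffer's method
with weights $\sqrt{n_c}$, and genes pass at $|z| \ge$ a configurable
threshold. Cohorts with one outcome class carry no contrast and are
excluded with a warning. Under the null the combined z is standard
normal, so the selected fraction at threshold 1.96 calibrates to 5% — a
property test. Genes are restricted to those shared by all usable
cohorts, matching the common-background convention of multi-cohort
analysis.

*Models.* The penalized logistic regression is an elastic net
($\alpha = 0.5$ by default, configurable) with penalty strength chosen
by 5-fold cross-validation maximizing AUROC; folds are stratified by
outcome class and cohort so that small cohorts and rare deaths are
spread across folds. On very small training sets the CV measure falls
back to deviance (AUROC per fold needs enough positives). The random
forest uses 1000 trees, $\sqrt{p}$ candidate features per split, and
inverse-frequency class weights; class weighting rather than resampling
keeps fitting deterministic given the seed. The exact architectures and
thresholds of the originally published parametrized models are not
printed in their main text, so these defaults are stated, configurable,
and recorded in `training_meta` — the package makes the two-phase design
re-trainable, not the published coefficients.

*Ensemble.* Different models emit incommensurate scales, so the
ensemble averages within-cohort rank-normalized scores,
$r/(n+1)$, making it invariant to monotone transformations of any
member. Two models with exactly opposite rankings cancel to a constant
½.

## Discrimination and reclassification statistics

*AUROC* is computed by mid-ranks, which equals both the trapezoidal area
over the tie-grouped empirical ROC and the pairwise concordance
probability with ties counted ½; the test suite proves the equivalence
against an exhaustive $O(n^2)$ oracle. CIs are stratified bootstrap
(2000 replicates by default) — the CI method behind published per-cohort
intervals is typically unstated, and the bootstrap is assumption-light.
*AUPRC* is the trapezoidal area over recall-ordered operating points at
distinct thresholds, prepended with a recall-zero point at the first
attainable precision.

*Summary ROC.* Each cohort's operating points are mapped to
$(S, D) = (\mathrm{logit\,TPR} + \mathrm{logit\,FPR},\;
\mathrm{logit\,TPR} - \mathrm{logit\,FPR})$ and pooled; the linear
relation $D = a + bS$ is fitted by weighted least squares and
back-transformed onto an FPR grid, whose trapezoidal integral is the
summary AUROC. Points with TPR or FPR at 0 or 1 are continuity-corrected
by half a count before the logit; the trivial endpoints are excluded.
Two fitting details were genuinely open. First, the point weights: we
weight each operating point by the inverse binomial variance of its $D$,
which both scales with cohort size and strongly downweights the
continuity-corrected tail points. Weighting by cohort size alone lets
the tail points — whose positions are artifacts of the correction — bend
the fit and biases the summary AUROC upward by several points; with
inverse-variance weights the estimator recovers a known binormal AUC of
0.8 without detectable bias (a Monte-Carlo acceptance check holds it
within ±0.03 from two cohorts of 500). Second, the proper-curve
constraint $|b| < 1$: fits outside it are clamped with a warning. The
family and the trapezoidal integration are fixed; the fit itself is an
ordinary weighted regression and straightforward to swap. CIs bootstrap
over cohorts, the natural resampling unit for a cross-cohort summary.

*Thresholds.* "Nearest sensitivity above target" is interpreted on the
discrete achievable set: the smallest achievable sensitivity strictly
greater than the target, ties broken towards higher specificity. With 3
positives and target 0.9 the only achievable choice is sensitivity 1.
Test characteristics use score ≥ threshold ⇒ predicted death, and report
undefined PPV/NPV as missing rather than 0.

*Severity comparison.* Three maximum-likelihood logistic fits
(severity-only, gene-only, joint additive) are compared on the AUROC of
their fitted probabilities; samples without a severity value are
dropped. (Quasi-)separated fits — detected by fitted probabilities
pinned at the boundary — are refit with a small ridge penalty via IRLS,
with a warning; the glm warning alone is not a reliable detector because
it triggers only within machine epsilon of the boundary. The *cNRI* is
the sum of the event component $P(\text{new} > \text{old}\mid\text{event})
- P(\text{new} < \text{old}\mid\text{event})$ and the analogous non-event
component with the inequalities reversed; ties contribute zero, each
component lies in $[-1, 1]$, and the total in $[-2, 2]$. Inference
defaults to the asymptotic normal form with component variances from the
up/down proportions; a stratified bootstrap is available behind a flag
for small cohorts, where the normal approximation is rough.

*Agreement.* Model correlation uses within-cohort mid-ranks normalized
by $r/(n+1)$ and pooled, so cohort batch shifts in score location cannot
masquerade as agreement; for a single cohort this reduces exactly to
Spearman's rho. Consensus classification at each model's 90%-sensitivity
threshold is pooled across cohorts by default (a per-cohort variant is a
trivial loop over the same function); patients correct in ≥3 of 4 models
count as consensus, 1–2 as no consensus, 0 as always misclassified.

*Longitudinal check.* Per-patient OLS slopes of score against time are
compared between outcome groups by Welch t-test, and score levels on
per-patient means; patients with a single distinct time point carry no
slope information and are excluded with a warning.

## Gene-set over-representation

The background universe defaults to the genes shared by all input
cohorts. Sets are intersected with the background; the retention filter
keeps sets overlapping the predictor genes by at least 3 genes *and* at
least 10% of the set's background-intersected size. Enrichment is a
one-sided Fisher's exact test — one-sided because the question is
over-representation — with BH adjustment. Test oracles: an explicit
hypergeometric tail-sum enumeration to $10^{-12}$, and edge-case tables
for the retention rules. Cell-type enrichment applies the signature
score to sorted-cell reference profiles, with significance from
permutations of same-size random up/down gene draws within the profile's
universe (two-sided, with the $+1$ correction so p is never 0).

## The synthetic-cohort generator

`simulate_multicohort()` draws, per patient, a latent risk
$r \sim N(0,1)$; death is Bernoulli with probability
$\mathrm{logit}^{-1}(q_c + r)$, where $q_c$ is calibrated by numerical
integration so the cohort's expected mortality equals its configured
rate. Gene baselines are $N(8, 1.5^2)$ log2 units shared across cohorts;
each cohort adds per-gene batch shifts $N(0, \tau^2)$; non-survivors
gain $+\delta$ on up genes and $-\delta$ on down genes; observation
noise is $N(0, \sigma^2)$. Severity is $\lambda r$ plus
$(1-\lambda)$-weighted independent noise, rescaled to an APACHE-II-like
0–40 range. Defaults: per-cohort mortality rates drawn from
$N(0.232, 0.134^2)$ truncated to $(0.02, 0.8)$ — the observed mean and
spread across the 21 registry cohorts — with $\delta = 1$, $\sigma = 1$,
$\tau = 0.5$ log2 units, 1000 noise genes, and $\lambda = 0.7$, which
places severity discrimination in the AUROC range clinical scores
actually achieve (~0.7–0.8). Coupling severity and death through the
same latent risk is deliberate: it makes the joint severity + gene model
genuinely better than either covariate, the qualitative claim the
evaluation machinery must be able to detect, and a property the test
suite checks in ≥90% of 100 simulations.

A Gaussian log2 model (rather than negative-binomial) is the default
because most cohorts in this setting are microarrays; a separate
negative-binomial count simulator (dispersion 0.2) exercises the voom
pathway. What the generator does **not** emulate: platform-specific
intensity distributions and probe effects, gene–gene correlation beyond
the shared outcome effect, informative missingness, non-Gaussian batch
structure, and case-mix differences between cohorts. Passing tests
therefore demonstrate that the statistical machinery is correct and
well-calibrated under the stated generative model — not that any fixed
AUROC level would be attained on real accession data.

For the sorted-cell reference fixture, per-gene baselines are kept near
a common location (SD 0.25): with microarray-scale baseline
heterogeneity the up/down baseline difference alone has SD ≈ 0.9 and a
zero-contrast profile would not score near zero; keeping genes
exchangeable at null makes the permutation test's premise true by
construction.

## Problem sizes and reproducibility

Every stochastic routine takes an explicit seed, and simulation outputs
are pure functions of their configuration. The shipped test suite runs
its Monte-Carlo checks at deliberate desk scale — e.g. 1000 random
instances for the concordance and counting oracles, two cohorts of 500
for the binormal summary-ROC recovery, five cohorts of 200 for feature
recovery, 10–20 replicates for trend checks — sizes at which each
property is sharp but the whole suite completes in well under a minute.
The headline external-validation figures of the motivating study (summary
AUROCs, Spearman ranges, Table-level results) depend on the original
accession data and are out of scope here; the package reproduces the
countable facts (signature bookkeeping, registry totals, cNRI extremes)
and the method properties instead.

## Known limitations

- The summary-ROC fit is a two-parameter logit-linear family; strongly
  asymmetric or improper empirical curves are represented only after
  clamping the slope.
- cNRI asymptotic inference is coarse for very small cohorts (use the
  bootstrap flag).
- The elastic-net at `lambda.min` admits some null genes at small
  training sizes; sparsity-oriented users should consider `lambda.1se`
  via the stored `cv.glmnet` object.
- No CEL/IDAT parsing, background correction, ComBat co-normalization,
  time-to-event modeling, DeLong tests, or calibration metrics — the
  package starts from summarized expression matrices and binary 30-day
  mortality.
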