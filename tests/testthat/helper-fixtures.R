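# small constructors and independent oracles shared across test files

toy_expr <- function(values, genes, samples = NULL, scale = "log2") {
  samples <- samples %||% paste0("s", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expr_matrix(values, scale = scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive pairwise-concordance AUROC, ties counted 1/2
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# direct counting cNRI
oracle_cnri <- function(old, new, labels) {
  d <- sign(new - old)
  ev <- d[labels == 1]; ne <- d[labels == 0]
  (mean(ev > 0) - mean(ev < 0)) + (mean(ne < 0) - mean(ne > 0))
}

# hypergeometric upper-tail p by explicit enumeration
oracle_fet_p <- function(k, set_size, n_pred, n_bg) {
  ks <- k:min(set_size, n_pred)
  sum(choose(set_size, ks) * choose(n_bg - set_size, n_pred - ks)) /
    choose(n_bg, n_pred)
}

# one-cohort simulation wrapper used by several score-level checks
sim_one_cohort <- function(n, delta, sigma = 1, signature, seed,
                           mortality_rate = 0.25, tau = 0) {
  cfg <- sim_config(n_cohorts = 1, n_samples = n,
                    mortality_rate = mortality_rate, delta = delta,
                    sigma = sigma, tau = tau, n_noise_genes = 50,
                    signature = signature, seed = seed)
  simulate_multicohort(cfg)[[1]]
}
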