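#' Configuration for the multi-cohort expression simulator
#'
#' Defines the generative model the downstream analyses assume: a latent
#' per-patient risk drives both 30-day mortality and the clinical severity
#' covariate; signature genes shift up or down in non-survivors; cohorts
#' differ by batch shifts and mortality rates. Defaults mirror the
#' structure of the multi-cohort sepsis compendium: per-cohort mortality
#' rates drawn around 23.2% with spread 13.4% (truncated to (0.02, 0.8)),
#' a 1 log2-unit signature effect, unit within-cohort gene noise and a
#' 0.5 log2-unit cohort batch-shift scale.
#'
#' @param n_cohorts Number of cohorts.
#' @param n_samples Per-cohort sample size (recycled).
#' @param mortality_rate Per-cohort mortality rate in (0, 1), recycled;
#'   `NULL` (default) draws rates from Normal(0.232, 0.134^2) truncated to
#'   (0.02, 0.8).
#' @param delta Signature effect size in log2 units: non-survivors gain
#'   `+delta` on up genes and `-delta` on down genes.
#' @param sigma Within-cohort per-gene observation noise SD (log2 units).
#' @param tau Cohort batch-shift SD (log2 units, per cohort per gene).
#' @param n_noise_genes Number of null genes beside the signature genes.
#' @param signature A [gene_signature()] whose genes carry the effect
#'   (default: the built-in Stanford predictor).
#' @param severity_coupling Lambda in \[0, 1\]: weight of the latent risk
#'   in the severity covariate (`severity = lambda * risk + (1 - lambda) *
#'   noise`, rescaled to an APACHE-II-like 0-40 range).
#' @param seed Mandatory integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_cohorts = 5L, n_samples = 100L,
                       mortality_rate = NULL, delta = 1, sigma = 1,
                       tau = 0.5, n_noise_genes = 1000L,
                       signature = NULL, severity_coupling = 0.7,
                       seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  signature <- signature %||% sepsis_signatures()[["Stanford"]]
  stopifnot(inherits(signature, "gene_signature"),
            n_cohorts >= 1L, all(n_samples >= 2L),
            delta >= 0, sigma >= 0, tau >= 0, n_noise_genes >= 0,
            severity_coupling >= 0, severity_coupling <= 1)
  if (!is.null(mortality_rate) &&
      (any(mortality_rate <= 0) || any(mortality_rate >= 1)))
    stop("mortality_rate must lie in (0, 1)", call. = FALSE)
  structure(list(n_cohorts = as.integer(n_cohorts),
                 n_samples = rep_len(as.integer(n_samples), n_cohorts),
                 mortality_rate = mortality_rate,
                 delta = delta, sigma = sigma, tau = tau,
                 n_noise_genes = as.integer(n_noise_genes),
                 signature = signature,
                 severity_coupling = severity_coupling,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# intercept q so that E_r[plogis(q + r)], r ~ N(0,1), equals the target rate
.calibrate_logit_intercept <- function(rate) {
  f <- function(q) {
    integrate(function(r) plogis(q + r) * dnorm(r), -8, 8,
              rel.tol = 1e-10)$value - rate
  }
  uniroot(f, c(-30, 30), tol = 1e-10)$root
}

#' Simulate a multi-cohort expression study
#'
#' Per sample, a latent risk `r ~ N(0, 1)` sets the death probability
#' `plogis(q_c + r)`, with the cohort intercept `q_c` calibrated so the
#' expected cohort mortality equals the configured rate. Gene baselines
#' (`N(8, 1.5^2)` log2 units) are shared across cohorts; each cohort adds
#' a per-gene batch shift `N(0, tau^2)`; non-survivors gain `+delta` on
#' the signature's up genes and `-delta` on its down genes; observation
#' noise is `N(0, sigma^2)`. Severity is `lambda * r` plus independent
#' noise, rescaled across the study to a 0-40 range. Sampling times are
#' uniform on 0-48 h. Fully reproducible from the config seed.
#'
#' @param cfg A [sim_config()].
#' @return List of cohorts; each is a list with `expr` (a `log2`-scale
#'   [expr_matrix()]), `samples` (a [sample_table()]) and `latent_risk`.
#' @export
simulate_multicohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  sig <- cfg$signature
  genes <- c(sig$up, sig$down)
  if (cfg$n_noise_genes > 0)
    genes <- c(genes, sprintf("NOISE%05d", seq_len(cfg$n_noise_genes)))
  if (anyDuplicated(genes))
    stop("signature genes collide with noise gene names", call. = FALSE)
  G <- length(genes)
  baseline <- rnorm(G, mean = 8, sd = 1.5)
  effect <- numeric(G)
  effect[match(sig$up, genes)] <- cfg$delta
  effect[match(sig$down, genes)] <- -cfg$delta
  rates <- cfg$mortality_rate
  if (is.null(rates)) {
    rates <- pmin(pmax(rnorm(cfg$n_cohorts, 0.232, 0.134), 0.02), 0.8)
  } else {
    rates <- rep_len(rates, cfg$n_cohorts)
  }
  lam <- cfg$severity_coupling
  cohorts <- vector("list", cfg$n_cohorts)
  for (c_i in seq_len(cfg$n_cohorts)) {
    n <- cfg$n_samples[c_i]
    q <- .calibrate_logit_intercept(rates[c_i])
    r <- rnorm(n)
    death <- rbinom(n, 1, plogis(q + r))
    batch <- rnorm(G, 0, cfg$tau)
    x <- baseline + batch + outer(effect, death) +
      matrix(rnorm(G * n, 0, cfg$sigma), G, n)
    ids <- sprintf("C%02dS%04d", c_i, seq_len(n))
    dimnames(x) <- list(genes, ids)
    sev_raw <- lam * r + (1 - lam) * rnorm(n)
    cohorts[[c_i]] <- list(
      expr = expr_matrix(x, scale = "log2", cohort_id = sprintf("C%02d", c_i)),
      samples = sample_table(
        sample_id = ids, cohort_id = sprintf("C%02d", c_i),
        mortality_30d = death,
        severity_value = sev_raw,  # rescaled below over the whole study
        severity_type = "APACHE II",
        time_from_admission_h = runif(n, 0, 48)),
      latent_risk = r)
  }
  all_sev <- unlist(lapply(cohorts, function(co) co$samples$severity_value))
  lo <- min(all_sev); hi <- max(all_sev)
  for (c_i in seq_along(cohorts)) {
    s <- cohorts[[c_i]]$samples$severity_value
    cohorts[[c_i]]$samples$severity_value <-
      if (hi > lo) (s - lo) / (hi - lo) * 40 else rep(20, length(s))
  }
  cohorts
}

#' Simulate sorted-cell reference profiles
#'
#' One log2 expression profile per cell type over a shared gene universe
#' (the signature genes plus noise genes). The designated cell type (the
#' first, by default) has the signature's up genes elevated by `contrast`
#' and its down genes depressed by `contrast`; all other types are null.
#' Per-gene baselines are kept near a common location (`baseline_sd`
#' small) so that, at zero contrast, genes are exchangeable and the
#' enrichment score is centered at zero.
#'
#' @param cell_types Character vector of cell-type names.
#' @param signature A [gene_signature()].
#' @param contrast Non-negative log2 shift applied in the designated type.
#' @param seed Integer seed.
#' @param designated Name of the enriched cell type (default first).
#' @param n_noise_genes Null genes added to the universe (default 200).
#' @param baseline_sd SD of the shared per-gene baseline (default 0.25).
#' @param profile_noise_sd Per-profile noise SD (default 0.25).
#' @return Named list of named numeric profiles.
#' @export
simulate_reference_profiles <- function(cell_types, signature, contrast,
                                        seed, designated = cell_types[1],
                                        n_noise_genes = 200L,
                                        baseline_sd = 0.25,
                                        profile_noise_sd = 0.25) {
  stopifnot(inherits(signature, "gene_signature"), contrast >= 0,
            designated %in% cell_types)
  set.seed(seed)
  genes <- c(signature$up, signature$down,
             sprintf("NOISE%05d", seq_len(n_noise_genes)))
  baseline <- setNames(rnorm(length(genes), 8, baseline_sd), genes)
  out <- lapply(cell_types, function(ct) {
    prof <- baseline + rnorm(length(genes), 0, profile_noise_sd)
    if (ct == designated) {
      prof[signature$up] <- prof[signature$up] + contrast
      prof[signature$down] <- prof[signature$down] - contrast
    }
    prof
  })
  setNames(out, cell_types)
}

#' Simulate a negative-binomial RNA-seq count matrix
#'
#' Gene means are log-normal; counts are negative binomial with the given
#' dispersion. Used to exercise the log2-CPM precision-weight pathway.
#'
#' @param n_genes,n_samples Matrix dimensions.
#' @param dispersion Negative-binomial dispersion (default 0.2).
#' @param seed Integer seed.
#' @return A `counts`-scale [expr_matrix()].
#' @export
simulate_counts <- function(n_genes = 500L, n_samples = 20L,
                            dispersion = 0.2, seed = 1L) {
  set.seed(seed)
  mu <- exp(rnorm(n_genes, log(100), 1.5))
  x <- matrix(rnbinom(n_genes * n_samples, mu = mu, size = 1 / dispersion),
              n_genes, n_samples)
  dimnames(x) <- list(sprintf("G%05d", seq_len(n_genes)),
                      sprintf("S%03d", seq_len(n_samples)))
  expr_matrix(x, scale = "counts")
}
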