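#' Empirical ROC curve
#'
#' Operating points at every distinct score threshold with the convention
#' score >= threshold => predicted death. The curve always contains the
#' trivial endpoints (FPR, TPR) = (0, 0) and (1, 1).
#'
#' @param scores Numeric risk scores (higher = higher mortality risk).
#' @param labels Binary outcome (1 = died).
#' @return Data frame of class `roc_curve` with columns `threshold`,
#'   `sensitivity`, `specificity`, and attributes `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- .check_labels(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(th, function(t) sum(scores >= t & labels == 1) / n_pos,
                 numeric(1))
  spec <- vapply(th, function(t) sum(scores < t & labels == 0) / n_neg,
                 numeric(1))
  out <- data.frame(threshold = th, sensitivity = sens, specificity = spec)
  structure(out, class = c("roc_curve", "data.frame"),
            n_pos = n_pos, n_neg = n_neg)
}

#' Trapezoidal AUROC with stratified-bootstrap confidence interval
#'
#' The area under the empirical ROC curve by the trapezoidal rule, with
#' ties handled so that the result equals the pairwise concordance
#' probability P(score of a random non-survivor > score of a random
#' survivor), ties counted one half. The 95% CI is a stratified bootstrap
#' (resampling survivors and non-survivors separately).
#'
#' @param scores Numeric risk scores.
#' @param labels Binary outcome (1 = died).
#' @param ci Compute the bootstrap CI (default `TRUE`).
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Seed for the bootstrap.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `auroc`, `ci` (lo, hi or `NULL`), `n_pos`, `n_neg`.
#' @export
auroc <- function(scores, labels, ci = TRUE, n_boot = 2000L, seed = 1L,
                  conf_level = 0.95) {
  labels <- .check_labels(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  est <- .auroc_rank(scores, labels)
  ci_out <- NULL
  if (ci) {
    set.seed(seed)
    pos <- which(labels == 1); neg <- which(labels == 0)
    reps <- vapply(seq_len(n_boot), function(b) {
      idx <- c(.resample(pos), .resample(neg))
      .auroc_rank(scores[idx], labels[idx])
    }, numeric(1))
    a <- (1 - conf_level) / 2
    ci_out <- unname(quantile(reps, c(a, 1 - a)))
  }
  list(auroc = est, ci = ci_out, n_pos = sum(labels == 1),
       n_neg = sum(labels == 0))
}

# mid-rank AUROC = concordance with ties counted 1/2
.auroc_rank <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Trapezoidal area under the precision-recall curve
#'
#' Precision-recall operating points are computed at every distinct score
#' threshold (descending), prepended with a recall-zero point at the first
#' attainable precision, and integrated by the trapezoidal rule over
#' recall.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary outcome (1 = died); at least one positive.
#' @return The AUPRC as a single number.
#' @export
auprc <- function(scores, labels) {
  labels <- .check_labels(labels, require_both = FALSE)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  if (sum(labels == 1) == 0) stop("no positive labels", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]; s <- scores[o]
  grp_end <- c(diff(s) != 0, TRUE)  # last index of each tie group
  tp <- cumsum(y)[grp_end]
  n_at <- seq_along(y)[grp_end]
  recall <- tp / sum(labels == 1)
  precision <- tp / n_at
  .trapezoid(c(0, recall), c(precision[1], precision))
}

#' Kester-Buntinx summary ROC across cohorts
#'
#' Pools the operating points of several per-cohort ROC curves, maps each
#' to `(S, D) = (logit TPR + logit FPR, logit TPR - logit FPR)`, fits the
#' linear relation `D = a + b S` with each point weighted by the inverse
#' binomial variance of its `D` (which grows with cohort size and
#' downweights near-degenerate tail points), and
#' back-transforms the fit onto an FPR grid to obtain a summary curve and
#' its trapezoidal AUROC. Degenerate points (TPR or FPR equal to 0 or 1)
#' are continuity-corrected by half a count before the logit; the trivial
#' all-positive/all-negative endpoints are excluded from the fit. The CI
#' is a bootstrap over cohorts.
#'
#' @param cohort_rocs List of [roc_curve()] objects (>= 1 cohort).
#' @param n_boot Bootstrap replicates over cohorts (default 500).
#' @param seed Seed for the bootstrap.
#' @param fpr_grid Grid of false-positive rates for the summary curve.
#' @return List of class `summary_roc` with `intercept`, `slope`, `curve`
#'   (data frame `fpr`, `tpr`), `auroc` and `ci`.
#' @export
summary_roc <- function(cohort_rocs, n_boot = 500L, seed = 1L,
                        fpr_grid = seq(0.005, 0.995, by = 0.005)) {
  if (inherits(cohort_rocs, "roc_curve")) cohort_rocs <- list(cohort_rocs)
  if (!length(cohort_rocs)) stop("no cohorts", call. = FALSE)
  pts <- lapply(cohort_rocs, .sroc_points)
  fit_auc <- function(point_list) {
    d <- do.call(rbind, point_list)
    fit <- .sroc_fit(d)
    .sroc_auc(fit$a, fit$b, fpr_grid)
  }
  d <- do.call(rbind, pts)
  fit <- .sroc_fit(d)
  curve <- data.frame(fpr = fpr_grid,
                      tpr = .sroc_tpr(fit$a, fit$b, fpr_grid))
  est <- .sroc_auc(fit$a, fit$b, fpr_grid)
  ci <- NULL
  if (length(pts) >= 2L && n_boot > 0) {
    set.seed(seed)
    reps <- vapply(seq_len(n_boot), function(b) {
      fit_auc(pts[sample(seq_along(pts), replace = TRUE)])
    }, numeric(1))
    ci <- unname(quantile(reps, c(0.025, 0.975), na.rm = TRUE))
  }
  structure(list(intercept = fit$a, slope = fit$b, curve = curve,
                 auroc = est, ci = ci, n_cohorts = length(pts)),
            class = "summary_roc")
}

# interior operating points of one cohort in (S, D, weight) form
.sroc_points <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  n_pos <- attr(roc, "n_pos"); n_neg <- attr(roc, "n_neg")
  tpr <- roc$sensitivity
  fpr <- 1 - roc$specificity
  keep <- !((tpr == 0 & fpr == 0) | (tpr == 1 & fpr == 1))
  tpr <- tpr[keep]; fpr <- fpr[keep]
  tpr <- pmin(pmax(tpr, 0.5 / n_pos), 1 - 0.5 / n_pos)
  fpr <- pmin(pmax(fpr, 0.5 / n_neg), 1 - 0.5 / n_neg)
  u <- qlogis(tpr); v <- qlogis(fpr)
  w <- 1 / (1 / (n_pos * tpr * (1 - tpr)) + 1 / (n_neg * fpr * (1 - fpr)))
  data.frame(S = u + v, D = u - v, w = w)
}

.sroc_fit <- function(d) {
  if (nrow(d) < 2L || var(d$S) == 0)
    return(list(a = mean(d$D), b = 0))
  fit <- lm(D ~ S, data = d, weights = d$w)
  a <- coef(fit)[[1]]; b <- coef(fit)[[2]]
  # the back-transform requires |b| < 1 (proper curve family)
  if (abs(b) >= 1) {
    warning("summary ROC slope clamped to the proper-curve range",
            call. = FALSE)
    b <- sign(b) * 0.99
  }
  list(a = a, b = b)
}

.sroc_tpr <- function(a, b, fpr) {
  v <- qlogis(fpr)
  plogis((a + (1 + b) * v) / (1 - b))
}

.sroc_auc <- function(a, b, fpr_grid) {
  fpr <- c(0, fpr_grid, 1)
  tpr <- c(0, .sroc_tpr(a, b, fpr_grid), 1)
  .trapezoid(fpr, tpr)
}

#' @export
print.summary_roc <- function(x, ...) {
  cat("Summary ROC over ", x$n_cohorts, " cohort(s): AUROC ",
      round(x$auroc, 3), sep = "")
  if (!is.null(x$ci))
    cat(" (95% CI ", round(x$ci[1], 3), "-", round(x$ci[2], 3), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Operating point at the nearest sensitivity above a target
#'
#' Among the achievable operating points with sensitivity strictly greater
#' than `target`, returns the one with the smallest sensitivity; ties are
#' broken towards higher specificity.
#'
#' @param roc A [roc_curve()].
#' @param target Target sensitivity in (0, 1), e.g. 0.9.
#' @return List with `threshold`, `sensitivity`, `specificity`.
#' @export
threshold_at_sensitivity <- function(roc, target) {
  stopifnot(inherits(roc, "roc_curve"))
  cand <- roc[roc$sensitivity > target, , drop = FALSE]
  if (!nrow(cand))
    stop("no achievable operating point with sensitivity > ", target,
         call. = FALSE)
  cand <- cand[order(cand$sensitivity, -cand$specificity), , drop = FALSE]
  list(threshold = cand$threshold[1],
       sensitivity = cand$sensitivity[1],
       specificity = cand$specificity[1])
}

#' Test characteristics at a fixed threshold
#'
#' Standard 2x2 quantities with the convention score >= threshold =>
#' predicted death. PPV and NPV with a zero denominator are reported as
#' `NA`, not 0.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary outcome (1 = died).
#' @param threshold Decision threshold.
#' @return Named list: `accuracy`, `sensitivity`, `specificity`, `ppv`,
#'   `npv`.
#' @export
test_characteristics <- function(scores, labels, threshold) {
  labels <- .check_labels(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  list(accuracy = (tp + tn) / length(labels),
       sensitivity = div(tp, tp + fn),
       specificity = div(tn, tn + fp),
       ppv = div(tp, tp + fp),
       npv = div(tn, tn + fn))
}

# ridge-penalized logistic regression by IRLS; numerical guard for
# separated fits only
.ridge_logistic <- function(X, y, lambda = 1e-2, maxit = 100L) {
  X <- cbind(1, as.matrix(X))
  beta <- rep(0, ncol(X))
  pen <- diag(c(0, rep(lambda, ncol(X) - 1L)))
  for (i in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    new <- solve(crossprod(X, w * X) + pen, crossprod(X, w * z))
    if (max(abs(new - beta)) < 1e-10) { beta <- new; break }
    beta <- new
  }
  as.vector(X %*% beta)
}

.logistic_scores <- function(X, y) {
  df <- data.frame(y = y, X)
  fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
  # (quasi-)separation: fitted probabilities pinned at the boundary
  sep <- any(fitted(fit) < 1e-8) || any(fitted(fit) > 1 - 1e-8)
  if (sep) {
    warning("perfect separation: ridge-penalized refit used", call. = FALSE)
    eta <- .ridge_logistic(as.matrix(X), y)
    list(scores = plogis(eta), loglik = sum(y * eta - log1p(exp(eta))))
  } else {
    list(scores = fitted(fit), loglik = as.numeric(logLik(fit)))
  }
}

#' Joint clinical-severity and gene-score logistic models
#'
#' Fits three logistic regressions for 30-day mortality -- severity only,
#' gene score only, and the joint model with both covariates and no
#' interaction -- and reports the AUROC of each model's fitted
#' probabilities. Samples without a severity value are dropped. Perfectly
#' separated fits are refit with a small ridge penalty, with a warning.
#'
#' @param t A [sample_table()] with `severity_value` and outcome.
#' @param gene_scores Named numeric vector of gene-model scores (names
#'   matching `t$sample_id`).
#' @return List with `auroc_severity`, `auroc_gene`, `auroc_joint`,
#'   matching log-likelihoods, fitted probabilities and `n`.
#' @export
joint_severity_model <- function(t, gene_scores) {
  idx <- match(t$sample_id, names(gene_scores))
  if (anyNA(idx)) stop("gene scores missing for some samples", call. = FALSE)
  g <- as.numeric(gene_scores[idx])
  keep <- !is.na(t$severity_value) & !is.na(t$mortality_30d)
  if (sum(!keep))
    message(sum(!keep), " sample(s) without severity or outcome dropped")
  y <- .check_labels(t$mortality_30d[keep])
  sev <- t$severity_value[keep]
  g <- g[keep]
  m_sev <- .logistic_scores(data.frame(severity = sev), y)
  m_gene <- .logistic_scores(data.frame(gene = g), y)
  m_joint <- .logistic_scores(data.frame(severity = sev, gene = g), y)
  list(auroc_severity = .auroc_rank(m_sev$scores, y),
       auroc_gene = .auroc_rank(m_gene$scores, y),
       auroc_joint = .auroc_rank(m_joint$scores, y),
       loglik_severity = m_sev$loglik,
       loglik_gene = m_gene$loglik,
       loglik_joint = m_joint$loglik,
       fitted = list(severity = m_sev$scores, gene = m_gene$scores,
                     joint = m_joint$scores),
       n = length(y))
}

#' Continuous net reclassification improvement
#'
#' Measures whether a new risk model moves predictions in the correct
#' direction relative to an old one. The event component is
#' P(new > old | event) - P(new < old | event); the non-event component is
#' P(new < old | non-event) - P(new > old | non-event); ties contribute
#' zero. The cNRI is their sum, with range \[-2, 2\]: 2 means every
#' prediction improved, -2 that every prediction worsened. Inference uses
#' the asymptotic normal form with component variances estimated from the
#' up/down proportions; a cohort bootstrap is available for small samples.
#'
#' @param old_risk,new_risk Per-sample risks under the old and new model.
#' @param labels Binary outcome (1 = event).
#' @param method `"asymptotic"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap replicates when `method = "bootstrap"`.
#' @param seed Seed for the bootstrap.
#' @param conf_level Confidence level (default 0.95).
#' @return List of class `nri_result` with `event_component`,
#'   `nonevent_component`, `cnri`, `ci_95`, `p_value`.
#' @export
cnri <- function(old_risk, new_risk, labels,
                 method = c("asymptotic", "bootstrap"),
                 n_boot = 2000L, seed = 1L, conf_level = 0.95) {
  method <- match.arg(method)
  labels <- .check_labels(labels)
  stopifnot(length(old_risk) == length(labels),
            length(new_risk) == length(labels))
  comp <- function(idx) {
    d <- sign(new_risk[idx] - old_risk[idx])
    p_up <- mean(d > 0); p_down <- mean(d < 0)
    est <- p_up - p_down
    v <- (p_up + p_down - est^2) / length(idx)
    c(est = est, var = v)
  }
  ev <- comp(which(labels == 1))
  ne <- comp(which(labels == 0))
  # non-events improve when the new risk moves DOWN
  ne["est"] <- -ne["est"]
  est <- unname(ev["est"] + ne["est"])
  if (method == "asymptotic") {
    se <- sqrt(ev[["var"]] + ne[["var"]])
    zq <- qnorm(1 - (1 - conf_level) / 2)
    if (se == 0) {
      p <- if (est == 0) 1 else 0
      ci <- c(est, est)
    } else {
      p <- 2 * pnorm(-abs(est / se))
      ci <- est + c(-1, 1) * zq * se
    }
  } else {
    set.seed(seed)
    pos <- which(labels == 1); neg <- which(labels == 0)
    reps <- vapply(seq_len(n_boot), function(b) {
      i1 <- .resample(pos); i0 <- .resample(neg)
      d1 <- sign(new_risk[i1] - old_risk[i1])
      d0 <- sign(new_risk[i0] - old_risk[i0])
      (mean(d1 > 0) - mean(d1 < 0)) + (mean(d0 < 0) - mean(d0 > 0))
    }, numeric(1))
    a <- (1 - conf_level) / 2
    ci <- unname(quantile(reps, c(a, 1 - a)))
    p <- min(1, 2 * min(mean(reps <= 0), mean(reps >= 0)))
  }
  structure(list(event_component = unname(ev["est"]),
                 nonevent_component = unname(ne["est"]),
                 cnri = est, ci_95 = ci, p_value = unname(p),
                 method = method),
            class = "nri_result")
}

#' @export
print.nri_result <- function(x, ...) {
  cat("cNRI ", round(x$cnri, 3), " (event ", round(x$event_component, 3),
      " + non-event ", round(x$nonevent_component, 3), "), 95% CI ",
      round(x$ci_95[1], 3), " to ", round(x$ci_95[2], 3), ", p = ",
      signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}

#' Paired t-test on per-dataset AUROCs
#'
#' @param aurocs_a,aurocs_b Per-dataset AUROCs of two models over the same
#'   datasets (>= 2).
#' @return List with `mean_difference`, `t`, `df`, `p_value` and a
#'   `degenerate` flag (all differences equal: zero variance).
#' @export
paired_auroc_test <- function(aurocs_a, aurocs_b) {
  stopifnot(length(aurocs_a) == length(aurocs_b), length(aurocs_a) >= 2L)
  d <- aurocs_a - aurocs_b
  if (sd(d) == 0) {
    if (all(d == 0))
      return(list(mean_difference = 0, t = 0, df = length(d) - 1,
                  p_value = 1, degenerate = TRUE))
    return(list(mean_difference = mean(d), t = sign(mean(d)) * Inf,
                df = length(d) - 1, p_value = 0, degenerate = TRUE))
  }
  tt <- t.test(aurocs_a, aurocs_b, paired = TRUE)
  list(mean_difference = unname(tt$estimate), t = unname(tt$statistic),
       df = unname(tt$parameter), p_value = tt$p.value, degenerate = FALSE)
}

#' Pairwise Spearman correlation of model scores
#'
#' Compares models on relative patient ranks rather than raw scores:
#' scores are converted to mid-ranks within cohort, normalized to
#' `rank / (n + 1)`, pooled, and correlated per model pair.
#'
#' @param scores_by_model Named list of >= 2 named numeric score vectors
#'   over the same samples.
#' @param cohort Optional cohort label per sample (default: one cohort).
#' @return Symmetric matrix of Spearman rho values.
#' @export
model_rank_correlation <- function(scores_by_model, cohort = NULL) {
  if (length(scores_by_model) < 2L) stop("need >= 2 models", call. = FALSE)
  ids <- names(scores_by_model[[1]])
  if (length(ids) < 3L) stop("need >= 3 shared samples", call. = FALSE)
  for (s in scores_by_model[-1])
    if (!identical(sort(names(s)), sort(ids)))
      stop("models were scored on different sample sets", call. = FALSE)
  cohort <- cohort %||% rep("all", length(ids))
  ranked <- vapply(scores_by_model, function(s) {
    s <- s[ids]
    r <- numeric(length(s))
    for (g in unique(cohort)) {
      idx <- cohort == g
      r[idx] <- rank(s[idx], ties.method = "average") / (sum(idx) + 1)
    }
    r
  }, numeric(length(ids)))
  rho <- cor(ranked, method = "pearson")
  nm <- names(scores_by_model) %||% paste0("model", seq_along(scores_by_model))
  dimnames(rho) <- list(nm, nm)
  rho
}

#' Consensus classification across four models
#'
#' Each patient carries four correctness flags (was the patient correctly
#' classified by each model at that model's 90%-sensitivity threshold).
#' Patients correct in 0 models are `always_misclassified`, in 1-2 models
#' `no_consensus`, in 3-4 models `consensus`.
#'
#' @param per_model_correct Matrix or data frame of exactly 4 binary
#'   columns (models), one row per patient.
#' @return List with `category` (factor per patient) and `fractions`
#'   (named proportions).
#' @export
consensus_classification <- function(per_model_correct) {
  m <- as.matrix(per_model_correct)
  if (ncol(m) != 4L) stop("exactly 4 model flags required", call. = FALSE)
  if (!all(m %in% c(0, 1))) stop("flags must be binary", call. = FALSE)
  k <- rowSums(m)
  category <- factor(ifelse(k == 0, "always_misclassified",
                     ifelse(k <= 2, "no_consensus", "consensus")),
                     levels = c("always_misclassified", "no_consensus",
                                "consensus"))
  list(category = category,
       fractions = prop.table(table(category)))
}

#' Longitudinal slope and level comparison between outcome groups
#'
#' For patients with repeated measurements, fits a per-patient ordinary
#' least-squares slope of score versus time and compares slopes between
#' survivors and non-survivors with a two-sided t-test; the score level is
#' compared on per-patient mean scores. Patients with fewer than two
#' distinct time points are excluded with a warning.
#'
#' @param scores Numeric score per measurement.
#' @param time_h Time of each measurement (hours).
#' @param patient_id Patient identifier per measurement.
#' @param labels Binary outcome per measurement (constant within patient).
#' @return List with `mean_slope` (per group), `slope_p`, `level_p`,
#'   `n_patients` (per group).
#' @export
longitudinal_slope_test <- function(scores, time_h, patient_id, labels) {
  labels <- .check_labels(labels, require_both = FALSE)
  stopifnot(length(scores) == length(time_h),
            length(scores) == length(patient_id),
            length(scores) == length(labels))
  per <- split(seq_along(scores), patient_id)
  slopes <- c(); means <- c(); grp <- c()
  n_excluded <- 0L
  for (idx in per) {
    tt <- time_h[idx]
    if (length(unique(tt)) < 2L) { n_excluded <- n_excluded + 1L; next }
    y <- scores[idx]
    slopes <- c(slopes, cov(tt, y) / var(tt))
    means <- c(means, mean(y))
    grp <- c(grp, labels[idx][1])
  }
  if (n_excluded)
    warning(n_excluded, " patient(s) with a single time point excluded",
            call. = FALSE)
  if (min(table(factor(grp, levels = c(0, 1)))) < 3L)
    stop("need >= 3 patients with repeated measures per group",
         call. = FALSE)
  safe_t <- function(a, b) {
    if (sd(a) == 0 && sd(b) == 0)
      return(if (mean(a) == mean(b)) 1 else 0)
    t.test(a, b)$p.value
  }
  list(mean_slope = c(survivor = mean(slopes[grp == 0]),
                      nonsurvivor = mean(slopes[grp == 1])),
       slope_p = safe_t(slopes[grp == 0], slopes[grp == 1]),
       level_p = safe_t(means[grp == 0], means[grp == 1]),
       n_patients = c(survivor = sum(grp == 0), nonsurvivor = sum(grp == 1)))
}

#' Per-cohort discrimination report
#'
#' Bundles the full single-cohort evaluation: trapezoidal AUROC with
#' bootstrap CI, AUPRC, the empirical ROC curve, and test characteristics
#' at named sensitivity-target thresholds.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary outcome (1 = died).
#' @param sens_targets Named vector of target sensitivities for threshold
#'   policies (default `c(high_sens = 0.9)`).
#' @param n_boot Bootstrap replicates for the AUROC CI.
#' @param seed Seed for the bootstrap.
#' @return List of class `eval_report`: `auroc`, `auroc_ci_95`, `auprc`,
#'   `roc`, `thresholds` (per policy: threshold + test characteristics),
#'   `prevalence`.
#' @export
eval_report <- function(scores, labels, sens_targets = c(high_sens = 0.9),
                        n_boot = 2000L, seed = 1L) {
  labels <- .check_labels(labels)
  a <- auroc(scores, labels, ci = n_boot > 0, n_boot = n_boot, seed = seed)
  roc <- roc_curve(scores, labels)
  thr <- lapply(sens_targets, function(tg) {
    op <- threshold_at_sensitivity(roc, tg)
    c(op, test_characteristics(scores, labels, op$threshold))
  })
  structure(list(auroc = a$auroc, auroc_ci_95 = a$ci,
                 auprc = auprc(scores, labels), roc = roc,
                 thresholds = thr,
                 prevalence = mean(labels),
                 n_pos = a$n_pos, n_neg = a$n_neg),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("AUROC ", round(x$auroc, 3), sep = "")
  if (!is.null(x$auroc_ci_95))
    cat(" (95% CI ", round(x$auroc_ci_95[1], 3), "-",
        round(x$auroc_ci_95[2], 3), ")", sep = "")
  cat(", AUPRC ", round(x$auprc, 3), " at prevalence ",
      round(x$prevalence, 3), " (", x$n_pos, " died / ", x$n_neg,
      " survived)\n", sep = "")
  invisible(x)
}
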