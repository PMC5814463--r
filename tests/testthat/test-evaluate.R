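test_that("auroc matches hand examples and degenerate cases", {
  expect_equal(auroc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0), ci = FALSE)$auroc,
               0.75)
  expect_equal(auroc(c(5, 6, 7, 1, 2), c(1, 1, 1, 0, 0), ci = FALSE)$auroc, 1)
  expect_equal(auroc(rep(3, 10), rep(c(0, 1), 5), ci = FALSE)$auroc, 0.5)
  expect_error(auroc(1:3, c(1, 1, 1)), "both outcome classes")
})

test_that("auroc is monotone-invariant and complements under negation", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    s <- sample(1:8, n, replace = TRUE) + rnorm(n, 0, 0.01)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    a <- auroc(s, y, ci = FALSE)$auroc
    expect_equal(auroc(exp(s / 2), y, ci = FALSE)$auroc, a)
    expect_equal(auroc(-s, y, ci = FALSE)$auroc, 1 - a)
  }
})

test_that("the bootstrap CI brackets the point estimate and shrinks with n", {
  set.seed(3)
  y <- rbinom(300, 1, 0.3)
  s <- y + rnorm(300)
  a <- auroc(s, y, n_boot = 500, seed = 9)
  expect_true(a$ci[1] <= a$auroc && a$auroc <= a$ci[2])
  small <- auroc(s[1:60], y[1:60], n_boot = 500, seed = 9)
  expect_gt(diff(small$ci), diff(a$ci))
})

test_that("auprc hits exact values and approaches prevalence under random scores", {
  expect_equal(auprc(c(5, 6, 7, 1, 2), c(1, 1, 1, 0, 0)), 1)
  expect_equal(auprc(c(9, 1, 2, 3), c(1, 0, 0, 0)), 1)
  expect_error(auprc(1:4, rep(0, 4)), "no positive")
  set.seed(20)
  y <- rbinom(2000, 1, 0.2)
  expect_equal(auprc(runif(2000), y), 0.2, tolerance = 0.03 / 0.2)
})

test_that("roc_curve carries both trivial endpoints with monotone sensitivity", {
  set.seed(2)
  s <- rnorm(50); y <- rbinom(50, 1, 0.4)
  r <- roc_curve(s, y)
  fpr <- 1 - r$specificity
  expect_true(any(r$sensitivity == 0 & fpr == 0))
  expect_true(any(r$sensitivity == 1 & fpr == 1))
  expect_true(all(diff(r$sensitivity) >= 0))
  expect_true(all(diff(fpr) >= 0))
  # trapezoid over the empirical curve equals the mid-rank AUROC
  expect_equal(-sum(diff(fpr) * (head(r$sensitivity, -1) +
                                 tail(r$sensitivity, -1)) / 2) * -1,
               auroc(s, y, ci = FALSE)$auroc)
})

test_that("summary ROC on copies of one cohort reproduces its AUROC", {
  set.seed(7)
  s <- c(rnorm(150, 1.2), rnorm(350))
  y <- rep(c(1, 0), c(150, 350))
  r <- roc_curve(s, y)
  sr <- summary_roc(list(r, r, r), n_boot = 50)
  expect_equal(sr$auroc, auroc(s, y, ci = FALSE)$auroc, tolerance = 0.02 / 0.8)
  single <- summary_roc(r, n_boot = 0)
  expect_equal(single$auroc, sr$auroc, tolerance = 1e-9)
})

test_that("a zero-slope summary curve is symmetric about the anti-diagonal", {
  fpr <- seq(0.05, 0.95, by = 0.05)
  a <- 2.2
  tpr <- plogis(a + qlogis(fpr))           # b = 0 member of the family
  # map (f, t) -> (1 - t, 1 - f): the curve must contain its own mirror
  mirror <- plogis(a + qlogis(1 - tpr))
  expect_equal(mirror, 1 - fpr, tolerance = 1e-12)
})

test_that("summary ROC recovers a binormal AUC from two cohorts", {
  set.seed(41)
  mu <- sqrt(2) * qnorm(0.8)
  rocs <- lapply(1:2, function(i) {
    y <- rep(c(1, 0), c(150, 350))
    s <- c(rnorm(150, mu), rnorm(350))
    roc_curve(s, y)
  })
  sr <- summary_roc(rocs, n_boot = 100, seed = 5)
  expect_equal(sr$auroc, 0.8, tolerance = 0.03 / 0.8)
  expect_true(sr$ci[1] <= sr$auroc && sr$auroc <= sr$ci[2])
})

test_that("threshold_at_sensitivity picks the minimal sensitivity above target", {
  s <- c(0.9, 0.6, 0.3, 0.8, 0.2, 0.1)
  y <- c(1, 1, 1, 0, 0, 0)
  r <- roc_curve(s, y)
  # achievable sensitivities are 1/3, 2/3, 1: target 0.9 forces 1.0
  op <- threshold_at_sensitivity(r, 0.9)
  expect_equal(op$sensitivity, 1)
  # target 0 gives the lowest achievable positive sensitivity
  op0 <- threshold_at_sensitivity(r, 0)
  expect_equal(op0$sensitivity, 1 / 3)
  set.seed(6)
  sc <- rnorm(1000); yc <- rbinom(1000, 1, 0.4)
  opc <- threshold_at_sensitivity(roc_curve(sc, yc), 0.95)
  expect_gt(opc$sensitivity, 0.95)
  expect_lte(opc$sensitivity, 0.96)
})

test_that("test characteristics match hand 2x2 counts and identities", {
  # TP=2 FP=1 TN=3 FN=0
  s <- c(0.9, 0.8, 0.7, 0.2, 0.1, 0.05)
  y <- c(1, 1, 0, 0, 0, 0)
  tc <- test_characteristics(s, y, threshold = 0.5)
  expect_equal(tc$sensitivity, 1)
  expect_equal(tc$specificity, 0.75)
  expect_equal(tc$ppv, 2 / 3)
  expect_equal(tc$npv, 1)
  expect_equal(tc$accuracy, 5 / 6)
  # accuracy = (sens*n_pos + spec*n_neg)/n
  expect_equal(tc$accuracy, (tc$sensitivity * 2 + tc$specificity * 4) / 6)
  # predict-all-positive
  tcp <- test_characteristics(s, y, threshold = -Inf)
  expect_equal(tcp$sensitivity, 1)
  expect_equal(tcp$specificity, 0)
  expect_equal(tcp$ppv, 1 / 3)
  expect_true(is.na(tcp$npv))
  # everything correct
  tca <- test_characteristics(s, y, threshold = 0.75)
  expect_true(all(unlist(tca) == 1))
})

test_that("joint severity model nests and degrades gracefully", {
  set.seed(10)
  n <- 150
  sev <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + sev))
  t <- sample_table(paste0("s", 1:n), "c", y, severity_value = sev)
  # a gene score identical to severity adds nothing
  g <- setNames(sev, t$sample_id)
  jm <- joint_severity_model(t, g)
  expect_equal(jm$auroc_joint, jm$auroc_severity, tolerance = 1e-9)
  # an independent gene score cannot reduce the joint likelihood
  g2 <- setNames(rnorm(n), t$sample_id)
  jm2 <- joint_severity_model(t, g2)
  expect_gte(jm2$loglik_joint, jm2$loglik_severity - 1e-8)
  # samples without severity are dropped
  t3 <- t; t3$severity_value[1:10] <- NA
  expect_message(jm3 <- joint_severity_model(t3, g2), "dropped")
  expect_equal(jm3$n, n - 10)
  # perfect separation falls back to a penalized refit
  t4 <- sample_table(paste0("q", 1:20), "c", rep(c(0, 1), each = 10),
                     severity_value = c(rnorm(10, 0), rnorm(10, 30)))
  g4 <- setNames(rnorm(20), t4$sample_id)
  w <- capture_warnings(jm4 <- joint_severity_model(t4, g4))
  expect_true(any(grepl("separation", w)))  # severity-only and joint both refit
  expect_true(is.finite(jm4$auroc_joint))
})

test_that("joint models beat either covariate when each carries half the risk", {
  set.seed(55)
  wins <- replicate(100, {
    n <- 400
    r1 <- rnorm(n); r2 <- rnorm(n)
    y <- rbinom(n, 1, plogis(-1.2 + r1 + r2))
    if (length(unique(y)) < 2) return(NA)
    t <- sample_table(paste0("s", 1:n), "c", y,
                      severity_value = r1 + rnorm(n, 0, 0.3))
    g <- setNames(r2 + rnorm(n, 0, 0.3), t$sample_id)
    jm <- joint_severity_model(t, g)
    jm$auroc_joint > max(jm$auroc_severity, jm$auroc_gene)
  })
  expect_gte(mean(wins, na.rm = TRUE), 0.9)
})

test_that("cnri matches hand counting and attains its extremes", {
  # events: (0.2 -> 0.6), (0.5 -> 0.4); nonevents: (0.7 -> 0.2), (0.3 -> 0.3)
  old <- c(0.2, 0.5, 0.7, 0.3)
  new <- c(0.6, 0.4, 0.2, 0.3)
  y <- c(1, 1, 0, 0)
  r <- cnri(old, new, y)
  expect_equal(r$event_component, 0)
  expect_equal(r$nonevent_component, 0.5)
  expect_equal(r$cnri, 0.5)
  # identity
  expect_equal(cnri(old, old, y)$cnri, 0)
  # perfect reclassification reaches the maximum of 2
  y2 <- rep(c(1, 0), each = 10)
  new2 <- c(seq(0.9, 0.99, length.out = 10), seq(0.01, 0.1, length.out = 10))
  old2 <- 1 - new2
  r2 <- cnri(old2, new2, y2)
  expect_equal(r2$cnri, 2)
  expect_equal(cnri(new2, old2, y2)$cnri, -2)
})

test_that("cnri is antisymmetric, bounded, and agrees with the counting oracle", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(6:30, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    old <- sample(1:5, n, replace = TRUE) / 5
    new <- sample(1:5, n, replace = TRUE) / 5
    r <- cnri(old, new, y)
    expect_equal(r$cnri, oracle_cnri(old, new, y))
    expect_equal(cnri(new, old, y)$cnri, -r$cnri)
    expect_true(r$cnri >= -2 && r$cnri <= 2)
  }
})

test_that("cnri bootstrap inference broadly agrees with the asymptotic form", {
  set.seed(8)
  n <- 120
  y <- rbinom(n, 1, 0.3)
  old <- rnorm(n)
  new <- old + 0.8 * y + rnorm(n, 0, 0.5)
  ra <- cnri(old, new, y)
  rb <- cnri(old, new, y, method = "bootstrap", n_boot = 1000, seed = 2)
  expect_equal(ra$cnri, rb$cnri)
  expect_equal(ra$ci_95, rb$ci_95, tolerance = 0.25)
})

test_that("paired AUROC comparisons handle typical and degenerate inputs", {
  d <- c(0.05, 0.1, 0.02, 0.08)
  res <- paired_auroc_test(0.7 + d, rep(0.7, 4))
  t_hand <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(res$t, t_hand)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), df = 3))
  expect_equal(paired_auroc_test(c(0.7, 0.8), c(0.7, 0.8))$p_value, 1)
  deg <- paired_auroc_test(c(0.8, 0.9, 0.7, 0.75, 0.85) + 0.1,
                           c(0.8, 0.9, 0.7, 0.75, 0.85))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 0)
  expect_equal(deg$mean_difference, 0.1)
})

test_that("model rank correlation reproduces hand-computed Spearman values", {
  ids <- paste0("s", 1:5)
  a <- setNames(c(10, 20, 30, 40, 50), ids)
  expect_equal(model_rank_correlation(list(m1 = a, m2 = a^3))["m1", "m2"], 1)
  expect_equal(model_rank_correlation(list(m1 = a,
                                           m2 = setNames(rev(a), ids)))[1, 2],
               -1)
  b <- setNames(c(1, 4, 2, 5, 3), ids)  # rank displacement sums to 10
  expect_equal(model_rank_correlation(list(a = a, b = b))["a", "b"], 0.5)
  expect_equal(cor(a, b, method = "spearman"), 0.5)
  expect_error(model_rank_correlation(list(a[1:2], b[1:2])), ">= 3")
})

test_that("consensus categories follow the 3-of-4 rule", {
  flags <- rbind(c(1, 1, 1, 0), c(1, 1, 0, 0), c(0, 0, 0, 0), c(1, 1, 1, 1),
                 c(1, 0, 0, 0))
  res <- consensus_classification(flags)
  expect_equal(as.character(res$category),
               c("consensus", "no_consensus", "always_misclassified",
                 "consensus", "no_consensus"))
  expect_equal(sum(res$fractions), 1)
  expect_error(consensus_classification(flags[, 1:3]), "exactly 4")
})

test_that("longitudinal slope test separates level shifts from slope shifts", {
  make_long <- function(offsets, slopes, sd, seed) {
    set.seed(seed)
    n <- length(offsets)
    times <- rep(c(0, 24, 48), n)
    pid <- rep(seq_len(n), each = 3)
    y <- offsets[pid] + slopes[pid] * times / 24 + rnorm(3 * n, 0, sd)
    list(scores = y, time = times, pid = pid)
  }
  # flat groups with equal offsets: nothing to find
  d0 <- make_long(rep(1, 12), rep(0, 12), sd = 0.3, seed = 1)
  lab0 <- rep(c(0, 1), each = 6)[d0$pid]
  r0 <- longitudinal_slope_test(d0$scores, d0$time, d0$pid, lab0)
  expect_gt(r0$slope_p, 0.05)
  expect_gt(r0$level_p, 0.05)
  # non-survivors offset +1, identical slopes: level signal only
  d1 <- make_long(rep(c(0, 1), each = 20), rep(0, 40), sd = 0.3, seed = 2)
  lab1 <- rep(c(0, 1), each = 20)[d1$pid]
  r1 <- longitudinal_slope_test(d1$scores, d1$time, d1$pid, lab1)
  expect_gt(r1$slope_p, 0.05)
  expect_lt(r1$level_p, 0.01)
  # constructed slope difference of 0.5/day is detected
  d2 <- make_long(rep(0, 20), rep(c(0, 0.5), each = 10), sd = 0.1, seed = 3)
  lab2 <- rep(c(0, 1), each = 10)[d2$pid]
  r2 <- longitudinal_slope_test(d2$scores, d2$time, d2$pid, lab2)
  expect_lt(r2$slope_p, 0.01)
  # single-time-point patients are excluded with a warning
  expect_warning(
    longitudinal_slope_test(c(d2$scores, 5), c(d2$time, 0),
                            c(d2$pid, 99), c(lab2, 0)),
    "single time point")
})

test_that("eval_report bundles discrimination statistics consistently", {
  set.seed(17)
  y <- rbinom(120, 1, 0.25)
  s <- y + rnorm(120)
  rep <- eval_report(s, y, n_boot = 200, seed = 4)
  expect_true(rep$auroc_ci_95[1] <= rep$auroc &&
              rep$auroc <= rep$auroc_ci_95[2])
  expect_equal(rep$prevalence, mean(y))
  expect_gt(rep$thresholds$high_sens$sensitivity, 0.9)
  tc <- rep$thresholds$high_sens
  expect_equal(tc$accuracy,
               (tc$sensitivity * rep$n_pos + tc$specificity * rep$n_neg) /
                 (rep$n_pos + rep$n_neg))
})
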