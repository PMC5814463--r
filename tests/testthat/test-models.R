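make_cohorts <- function(n_cohorts, n, delta, n_noise, seed,
                         signature = gene_signature("sig",
                                                    up = paste0("U", 1:6),
                                                    down = paste0("D", 1:6))) {
  cfg <- sim_config(n_cohorts = n_cohorts, n_samples = n,
                    mortality_rate = 0.3, delta = delta, sigma = 1,
                    tau = 0.3, n_noise_genes = n_noise,
                    signature = signature, seed = seed)
  simulate_multicohort(cfg)
}

test_that("select_features combines cohort evidence and screens nulls", {
  cohorts <- make_cohorts(5, 100, delta = 2, n_noise = 100, seed = 21)
  fs <- select_features(cohorts, z_threshold = 4)
  planted <- c(paste0("U", 1:6), paste0("D", 1:6))
  expect_true(all(planted %in% fs$selected))
  # null genes sit near z = 0
  nulls <- fs$statistics[grepl("^NOISE", fs$statistics$gene), "z"]
  expect_lt(mean(abs(nulls) >= 4), 0.02)
})

test_that("select_features type-I rate is calibrated on a pure null", {
  cohorts <- make_cohorts(3, 120, delta = 0, n_noise = 1000, seed = 8)
  fs <- select_features(cohorts, z_threshold = 1.96)
  frac <- length(fs$selected) / nrow(fs$statistics)
  expect_gt(frac, 0.05 - 3 * sqrt(0.05 * 0.95 / 1000))
  expect_lt(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("select_features is invariant to gene and cohort order and guards degenerate cohorts", {
  cohorts <- make_cohorts(3, 60, delta = 1, n_noise = 30, seed = 4)
  fs1 <- select_features(cohorts, 3)
  fs2 <- select_features(rev(cohorts), 3)
  expect_identical(fs1$selected, fs2$selected)
  shuf <- lapply(cohorts, function(co) {
    idx <- sample(nrow(co$expr))
    co$expr <- expr_matrix(unclass(co$expr)[idx, , drop = FALSE],
                           scale = "log2")
    co
  })
  expect_identical(select_features(shuf, 3)$selected, fs1$selected)
  # a single-class cohort is excluded with a warning, not fatal
  dead <- cohorts[[1]]
  dead$samples$mortality_30d <- 1L
  expect_warning(fs3 <- select_features(c(list(dead), cohorts[-1]), 3),
                 "single outcome class")
  expect_equal(fs3$n_cohorts_used, 2)
})

test_that("both model kinds separate a linearly separable toy problem", {
  n <- 60
  y <- rep(c(0L, 1L), each = n / 2)
  x <- rbind(G1 = 8 + 3 * y + rnorm(n, 0, 0.1),
             G2 = 8 - 3 * y + rnorm(n, 0, 0.1))
  colnames(x) <- paste0("s", 1:n)
  m <- expr_matrix(x, "log2")
  t <- sample_table(colnames(x), "c1", y)
  for (kind in c("penalized_lr", "random_forest")) {
    fit <- fit_model(kind, m, t, features = c("G1", "G2"), seed = 2)
    a <- auroc(fit$training_scores, y, ci = FALSE)$auroc
    expect_equal(a, 1.0)
    expect_true(all(fit$training_scores >= 0 & fit$training_scores <= 1))
  }
})

test_that("fitting and prediction are deterministic given the seed", {
  co <- make_cohorts(1, 80, delta = 1, n_noise = 20, seed = 14)[[1]]
  feats <- rownames(co$expr)[1:15]
  for (kind in c("penalized_lr", "random_forest")) {
    f1 <- fit_model(kind, co$expr, co$samples, feats, seed = 7)
    f2 <- fit_model(kind, co$expr, co$samples, feats, seed = 7)
    expect_identical(f1$training_scores, f2$training_scores)
    expect_identical(predict(f1, co$expr), f1$training_scores)
  }
})

test_that("predictions are sample-order equivariant and constant on constant input", {
  co <- make_cohorts(1, 80, delta = 1, n_noise = 20, seed = 15)[[1]]
  feats <- rownames(co$expr)[1:12]
  fit <- fit_model("penalized_lr", co$expr, co$samples, feats, seed = 3)
  perm <- sample(ncol(co$expr))
  mp <- expr_matrix(unclass(co$expr)[, perm, drop = FALSE], "log2")
  expect_equal(predict(fit, mp), fit$training_scores[perm])

  const <- matrix(8, nrow(co$expr), 5,
                  dimnames = list(rownames(co$expr), paste0("k", 1:5)))
  pk <- predict(fit, expr_matrix(const, "log2"))
  expect_equal(diff(range(pk)), 0)
  expect_error(predict(fit, expr_matrix(const[-1, , drop = FALSE], "log2")),
               "absent")
})

test_that("the elastic net concentrates coefficients on signal genes", {
  hits <- vapply(1:20, function(rep) {
    sim <- make_cohorts(3, 200, delta = 1, n_noise = 90, seed = 100 + rep,
                        signature = gene_signature("sg",
                                                   up = paste0("U", 1:5),
                                                   down = paste0("D", 1:5)))
    co <- list(expr = expr_matrix(do.call(cbind, lapply(sim, function(s)
                 unclass(s$expr))), "log2"),
               samples = do.call(rbind, lapply(sim, `[[`, "samples")))
    fit <- fit_model("penalized_lr", co$expr, co$samples,
                     rownames(co$expr), seed = rep)
    beta <- coef(fit$fit, s = "lambda.min")[-1, 1]
    nz <- names(beta)[beta != 0]
    if (!length(nz)) return(NA_real_)
    mean(grepl("^[UD]", nz))
  }, numeric(1))
  expect_gt(mean(hits, na.rm = TRUE), 0.7)
})

test_that("ensemble averaging of rank-normalized scores behaves as designed", {
  ids <- paste0("s", 1:40)
  base <- setNames(seq_len(40) + 0, ids)
  # identical rankings are preserved; monotone transforms are irrelevant
  ens <- ensemble_predict(list(base, exp(base / 10), rank(base)))
  expect_equal(order(ens), order(base))
  # exactly opposite rankings cancel to a constant 0.5
  opp <- ensemble_predict(list(base, setNames(-base, ids)))
  expect_equal(as.numeric(opp), rep(0.5, 40))
  expect_error(ensemble_predict(list(base)), "at least 2")
  expect_error(ensemble_predict(list(base, setNames(base, rev(ids))[1:39])),
               "different sample sets")
})

test_that("the ensemble is at least as discriminative as the average member", {
  set.seed(77)
  wins <- replicate(50, {
    n <- 200
    r <- rnorm(n)
    y <- rbinom(n, 1, plogis(-1 + 1.5 * r))
    ids <- paste0("s", 1:n)
    models <- lapply(1:4, function(i) setNames(r + rnorm(n, 0, 1.2), ids))
    ind <- vapply(models, function(s) auroc(s, y, ci = FALSE)$auroc,
                  numeric(1))
    ens <- auroc(ensemble_predict(models), y, ci = FALSE)$auroc
    ens >= mean(ind)
  })
  expect_gt(mean(wins), 0.9)
})
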