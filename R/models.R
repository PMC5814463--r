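# Welch t statistics per gene (rows), non-survivors minus survivors
.welch_t_rows <- function(x, y) {
  x1 <- x[, y == 1, drop = FALSE]
  x0 <- x[, y == 0, drop = FALSE]
  n1 <- ncol(x1); n0 <- ncol(x0)
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v0 <- rowSums((x0 - m0)^2) / (n0 - 1)
  se2 <- v1 / n1 + v0 / n0
  t <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  # zero-variance genes: no evidence if means equal, saturating otherwise
  zero <- se2 == 0
  t[zero] <- ifelse(m1[zero] == m0[zero], 0, sign(m1 - m0)[zero] * Inf)
  df[!is.finite(df)] <- 1
  list(t = t, df = df)
}

# probit transform of the one-sided p, sign-preserving and clamped
.t_to_z <- function(t, df) {
  p <- pt(t, df)
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  qnorm(p)
}

#' Cross-cohort differential-expression feature selection
#'
#' The discovery-phase screen: per cohort, each gene gets a Welch
#' t-statistic comparing non-survivors to survivors, converted to a
#' z-score; cohort z-scores are combined by Stouffer's method weighted by
#' the square root of cohort size; genes with `|combined z| >=
#' z_threshold` are selected. Cohorts with a single outcome class are
#' excluded with a warning. Genes are restricted to those shared by all
#' usable cohorts.
#'
#' @param cohorts List of cohorts, each a list with elements `expr`
#'   (a `log2`-scale [expr_matrix()]) and `samples` (a [sample_table()]
#'   aligned to its columns).
#' @param z_threshold Absolute combined-z selection threshold.
#' @return List of class `feature_selection` with `statistics` (data frame
#'   of `gene` and combined `z`), `selected` (character vector),
#'   `z_threshold` and `n_cohorts_used`.
#' @export
select_features <- function(cohorts, z_threshold) {
  if (length(cohorts) < 2L) stop("need at least 2 cohorts", call. = FALSE)
  usable <- list()
  for (i in seq_along(cohorts)) {
    co <- cohorts[[i]]
    y <- co$samples$mortality_30d
    keep <- !is.na(y)
    if (length(unique(y[keep])) < 2L) {
      warning("cohort ", i, " has a single outcome class; excluded",
              call. = FALSE)
      next
    }
    x <- .expr_values(co$expr)[, keep, drop = FALSE]
    usable[[length(usable) + 1L]] <- list(x = x, y = y[keep])
  }
  if (!length(usable))
    stop("no cohort with both outcome classes", call. = FALSE)
  genes <- Reduce(intersect, lapply(usable, function(u) rownames(u$x)))
  genes <- sort(genes)
  if (!length(genes)) stop("no genes shared across cohorts", call. = FALSE)
  zmat <- vapply(usable, function(u) {
    wt <- .welch_t_rows(u$x[genes, , drop = FALSE], u$y)
    .t_to_z(wt$t, wt$df)
  }, numeric(length(genes)))
  zmat <- matrix(zmat, nrow = length(genes))
  w <- sqrt(vapply(usable, function(u) length(u$y), numeric(1)))
  z <- as.vector(zmat %*% w) / sqrt(sum(w^2))
  stats <- data.frame(gene = genes, z = z, stringsAsFactors = FALSE)
  structure(list(statistics = stats,
                 selected = genes[abs(z) >= z_threshold],
                 z_threshold = z_threshold,
                 n_cohorts_used = length(usable)),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat("Feature selection: ", length(x$selected), "/",
      nrow(x$statistics), " genes at |z| >= ", x$z_threshold,
      " over ", x$n_cohorts_used, " cohorts\n", sep = "")
  invisible(x)
}

# stratified fold assignment; strata = interaction of class (and cohort)
.stratified_folds <- function(strata, k) {
  fold <- integer(length(strata))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Fit a re-trainable mortality predictor
#'
#' Two architectures are available. `penalized_lr` is an elastic-net
#' logistic regression (alpha defaults to 0.5) with penalty strength
#' chosen by stratified 5-fold cross-validation maximizing AUROC
#' ([glmnet::cv.glmnet()]); folds are stratified by outcome class and, if
#' present, cohort. `random_forest` is a [randomForest::randomForest()]
#' with 1000 trees, `sqrt(p)` candidate features per split and inverse-
#' frequency class weights. Both are fitted on log2 expression of the
#' requested feature genes and are fully reproducible given `seed`.
#'
#' @param kind `"penalized_lr"` or `"random_forest"`.
#' @param m A `log2`-scale [expr_matrix()].
#' @param t A [sample_table()] aligned to the columns of `m`.
#' @param features Gene list to use as predictors (must be present in `m`).
#' @param hyper Optional list of hyperparameters: `alpha`, `nfolds`
#'   (penalized LR); `ntree`, `mtry` (random forest).
#' @param seed Integer seed.
#' @return Object of class `sepsig_model` with elements `kind`,
#'   `feature_genes`, `fit`, `seed`, `training_meta` and
#'   `training_scores`.
#' @export
fit_model <- function(kind = c("penalized_lr", "random_forest"), m, t,
                      features, hyper = list(), seed = 1L) {
  kind <- match.arg(kind)
  x <- .expr_values(m)
  absent <- setdiff(features, rownames(x))
  if (length(absent))
    stop("feature gene(s) absent from matrix: ",
         paste(head(absent, 10), collapse = ", "), call. = FALSE)
  y <- .check_labels(t$mortality_30d)
  X <- base::t(x[features, , drop = FALSE])
  set.seed(seed)
  if (kind == "penalized_lr") {
    alpha <- hyper$alpha %||% 0.5
    nfolds <- hyper$nfolds %||% 5L
    strata <- interaction(y, t$cohort_id %||% "all", drop = TRUE)
    foldid <- .stratified_folds(as.integer(strata), nfolds)
    measure <- if (min(table(y, foldid)) >= 1 && length(y) >= 10 * nfolds)
      "auc" else "deviance"
    cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = alpha,
                            type.measure = measure, foldid = foldid)
    fit <- cv
    meta <- list(alpha = alpha, nfolds = nfolds, lambda = cv$lambda.min,
                 cv_measure = measure,
                 cohorts = unique(t$cohort_id))
  } else {
    ntree <- hyper$ntree %||% 1000L
    p <- ncol(X)
    mtry <- hyper$mtry %||% max(1L, floor(sqrt(p)))
    cw <- 1 / table(factor(y, levels = c(0, 1)))
    cw <- cw / sum(cw)
    fit <- randomForest::randomForest(X, factor(y, levels = c(0, 1)),
                                      ntree = ntree, mtry = mtry,
                                      classwt = as.numeric(cw))
    meta <- list(ntree = ntree, mtry = mtry,
                 class_weights = as.numeric(cw),
                 cohorts = unique(t$cohort_id))
  }
  model <- structure(list(kind = kind, feature_genes = features, fit = fit,
                          seed = seed, training_meta = meta),
                     class = "sepsig_model")
  model$training_scores <- predict(model, m)
  model
}

#' Predict mortality risk with a trained model
#'
#' Returns a per-sample risk score in \[0, 1\]: the predicted probability
#' for penalized logistic regression, the non-survivor vote fraction for
#' the random forest. All feature genes must be present; there is no
#' imputation.
#'
#' @param object A `sepsig_model`.
#' @param newdata A `log2`-scale [expr_matrix()].
#' @param ... Ignored.
#' @return Named numeric vector of risks, one per sample.
#' @export
predict.sepsig_model <- function(object, newdata, ...) {
  x <- .expr_values(newdata)
  absent <- setdiff(object$feature_genes, rownames(x))
  if (length(absent))
    stop("feature gene(s) absent from matrix: ",
         paste(head(absent, 10), collapse = ", "), call. = FALSE)
  X <- base::t(x[object$feature_genes, , drop = FALSE])
  if (object$kind == "penalized_lr") {
    p <- predict(object$fit, newx = X, s = "lambda.min", type = "response")
    setNames(as.numeric(p), rownames(X))
  } else {
    p <- predict(object$fit, X, type = "prob")[, "1"]
    setNames(as.numeric(p), rownames(X))
  }
}

#' @export
print.sepsig_model <- function(x, ...) {
  cat("sepsig model (", x$kind, "): ", length(x$feature_genes),
      " feature genes, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Ensemble of model scores by rank averaging
#'
#' Combines two or more per-sample score vectors over identical samples
#' into one ensemble score: each model's scores are rank-normalized to
#' `rank / (n + 1)` within cohort (mid-ranks for ties) and averaged across
#' models. The result is invariant to strictly monotone transformations of
#' any input model's scores.
#'
#' @param per_model_scores List of >= 2 named numeric vectors over the
#'   same sample set.
#' @param cohort Optional cohort label per sample (default: one cohort).
#' @return Named numeric vector of ensemble scores.
#' @export
ensemble_predict <- function(per_model_scores, cohort = NULL) {
  if (length(per_model_scores) < 2L)
    stop("need at least 2 models", call. = FALSE)
  ids <- names(per_model_scores[[1]])
  if (is.null(ids)) stop("score vectors must be named", call. = FALSE)
  for (s in per_model_scores[-1])
    if (!identical(sort(names(s)), sort(ids)))
      stop("models were scored on different sample sets", call. = FALSE)
  cohort <- cohort %||% rep("all", length(ids))
  ranked <- vapply(per_model_scores, function(s) {
    s <- s[ids]
    r <- numeric(length(s))
    for (g in unique(cohort)) {
      idx <- cohort == g
      r[idx] <- rank(s[idx], ties.method = "average") / (sum(idx) + 1)
    }
    r
  }, numeric(length(ids)))
  setNames(rowMeans(ranked), ids)
}
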