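#' End-to-end multi-cohort validation pipeline
#'
#' Scores every cohort with every signature, evaluates per-cohort
#' discrimination (AUROC with bootstrap CI, AUPRC, thresholds at the
#' high-sensitivity target), fits per-signature summary ROC curves across
#' cohorts, builds the rank-average ensemble, computes inter-model rank
#' correlations and (with exactly four signatures) the consensus
#' classification at each signature's high-sensitivity threshold, and --
#' where severity values are present -- compares each signature against
#' the clinical severity score via joint logistic models and the cNRI.
#' Cohorts with a single outcome class are skipped per-statistic with a
#' logged reason; the run continues.
#'
#' @param cohorts List of cohorts, each a list with `expr` (a `log2`-scale
#'   [expr_matrix()]) and `samples` (a [sample_table()]); e.g. the output
#'   of [simulate_multicohort()].
#' @param signatures A [signature_set()] (default: the four built-in
#'   predictors).
#' @param target_sensitivity Sensitivity target for threshold policies
#'   (default 0.9).
#' @param n_boot Bootstrap replicates for CIs (default 200, keeping full
#'   runs quick; raise for publication-grade CIs).
#' @param seed Integer seed for all bootstrap resampling.
#' @param output_dir If non-`NULL`, write `report.json` and per-signature
#'   ROC-point and score TSVs there.
#' @return List of class `sepsig_report` with elements `per_cohort`,
#'   `summary_roc`, `ensemble`, `rank_correlation`, `consensus`,
#'   `severity_comparison`, `skipped`, `config`.
#' @export
run_validation_pipeline <- function(cohorts, signatures = sepsis_signatures(),
                                    target_sensitivity = 0.9,
                                    n_boot = 200L, seed = 1L,
                                    output_dir = NULL) {
  stopifnot(length(cohorts) >= 1L)
  if (!inherits(signatures, "signature_set"))
    signatures <- signature_set(signatures)
  sig_names <- names(signatures)
  cohort_ids <- vapply(seq_along(cohorts), function(i) {
    cohorts[[i]]$samples$cohort_id[1] %||% paste0("cohort", i)
  }, character(1))
  skipped <- character(0)

  # per-cohort scoring and evaluation
  scores <- list()    # [[cohort]][[signature]] named numeric
  per_cohort <- list()
  for (i in seq_along(cohorts)) {
    co <- cohorts[[i]]
    cid <- cohort_ids[i]
    y <- co$samples$mortality_30d
    scores[[cid]] <- lapply(signatures, function(s)
      signature_score(co$expr, s))
    if (length(unique(y[!is.na(y)])) < 2L) {
      skipped <- c(skipped,
                   paste0(cid, ": single outcome class, discrimination ",
                          "statistics skipped"))
      next
    }
    keep <- !is.na(y)
    per_cohort[[cid]] <- lapply(sig_names, function(nm) {
      eval_report(scores[[cid]][[nm]][keep], y[keep],
                  sens_targets = setNames(target_sensitivity, "high_sens"),
                  n_boot = n_boot, seed = seed)
    })
    names(per_cohort[[cid]]) <- sig_names
  }
  if (!length(per_cohort))
    stop("no cohort with both outcome classes", call. = FALSE)
  eval_ids <- names(per_cohort)

  # cross-cohort summary ROC per signature
  sroc <- lapply(sig_names, function(nm) {
    summary_roc(lapply(per_cohort, function(pc) pc[[nm]]$roc),
                n_boot = n_boot, seed = seed)
  })
  names(sroc) <- sig_names

  # pooled data across evaluable cohorts
  pool <- function(nm) unlist(lapply(eval_ids, function(cid) {
    keep <- !is.na(cohorts[[match(cid, cohort_ids)]]$samples$mortality_30d)
    scores[[cid]][[nm]][keep]
  }))
  pooled_scores <- lapply(sig_names, pool)
  names(pooled_scores) <- sig_names
  pooled_y <- unlist(lapply(eval_ids, function(cid) {
    y <- cohorts[[match(cid, cohort_ids)]]$samples$mortality_30d
    y[!is.na(y)]
  }))
  pooled_cohort <- rep(eval_ids, times = vapply(eval_ids, function(cid) {
    sum(!is.na(cohorts[[match(cid, cohort_ids)]]$samples$mortality_30d))
  }, numeric(1)))

  ens_scores <- ensemble_predict(pooled_scores, cohort = pooled_cohort)
  ensemble <- list(scores = ens_scores,
                   auroc = auroc(ens_scores, pooled_y, ci = n_boot > 0,
                                 n_boot = max(n_boot, 1L), seed = seed),
                   auprc = auprc(ens_scores, pooled_y))

  rank_cor <- model_rank_correlation(pooled_scores, cohort = pooled_cohort)

  consensus <- NULL
  if (length(sig_names) == 4L) {
    correct <- vapply(sig_names, function(nm) {
      s <- pooled_scores[[nm]]
      thr <- threshold_at_sensitivity(roc_curve(s, pooled_y),
                                      target_sensitivity)$threshold
      pred <- as.integer(s >= thr)
      as.integer(pred == pooled_y)
    }, integer(length(pooled_y)))
    consensus <- consensus_classification(correct)
  }

  # severity comparison per cohort, where severity is available
  severity_comparison <- list()
  for (cid in eval_ids) {
    co <- cohorts[[match(cid, cohort_ids)]]
    ok <- !is.na(co$samples$severity_value) & !is.na(co$samples$mortality_30d)
    if (sum(ok) < 10L || length(unique(co$samples$mortality_30d[ok])) < 2L) {
      if (any(!is.na(co$samples$severity_value)))
        skipped <- c(skipped, paste0(cid, ": too few samples with severity ",
                                     "for the joint-model comparison"))
      next
    }
    severity_comparison[[cid]] <- lapply(sig_names, function(nm) {
      jm <- joint_severity_model(co$samples, scores[[cid]][[nm]])
      nri <- cnri(jm$fitted$severity, jm$fitted$joint,
                  co$samples$mortality_30d[ok])
      list(auroc_severity = jm$auroc_severity, auroc_gene = jm$auroc_gene,
           auroc_joint = jm$auroc_joint,
           cnri = nri$cnri, cnri_ci_95 = nri$ci_95, cnri_p = nri$p_value)
    })
    names(severity_comparison[[cid]]) <- sig_names
  }

  report <- structure(
    list(per_cohort = per_cohort, summary_roc = sroc, ensemble = ensemble,
         rank_correlation = rank_cor, consensus = consensus,
         severity_comparison = severity_comparison, skipped = skipped,
         config = list(signatures = sig_names,
                       target_sensitivity = target_sensitivity,
                       n_boot = n_boot, seed = seed)),
    class = "sepsig_report")
  if (!is.null(output_dir)) .write_report(report, scores, output_dir)
  report
}

.write_report <- function(report, scores, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  json <- list(
    per_cohort = lapply(report$per_cohort, function(pc) lapply(pc, function(r)
      list(auroc = r$auroc, auroc_ci_95 = r$auroc_ci_95, auprc = r$auprc,
           prevalence = r$prevalence, thresholds = r$thresholds))),
    summary_roc = lapply(report$summary_roc, function(s)
      list(auroc = s$auroc, ci = s$ci, intercept = s$intercept,
           slope = s$slope)),
    ensemble = list(auroc = report$ensemble$auroc$auroc,
                    ci = report$ensemble$auroc$ci,
                    auprc = report$ensemble$auprc),
    rank_correlation = report$rank_correlation,
    consensus = if (!is.null(report$consensus))
      as.list(report$consensus$fractions),
    severity_comparison = report$severity_comparison,
    skipped = report$skipped,
    config = report$config)
  jsonlite::write_json(json, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (cid in names(report$per_cohort)) {
    rocs <- do.call(rbind, lapply(names(report$per_cohort[[cid]]), function(nm) {
      r <- report$per_cohort[[cid]][[nm]]$roc
      data.frame(signature = nm, threshold = r$threshold,
                 sensitivity = r$sensitivity, specificity = r$specificity)
    }))
    write.table(rocs, file.path(output_dir, paste0("roc_", cid, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    sc <- do.call(rbind, lapply(names(scores[[cid]]), function(nm)
      data.frame(sample_id = names(scores[[cid]][[nm]]), cohort_id = cid,
                 signature = nm, score = as.numeric(scores[[cid]][[nm]]))))
    write.table(sc, file.path(output_dir, paste0("scores_", cid, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(output_dir)
}

#' @export
print.sepsig_report <- function(x, ...) {
  cat("Multi-cohort validation report:", length(x$per_cohort),
      "evaluable cohort(s),", length(x$config$signatures), "signatures\n")
  for (nm in names(x$summary_roc))
    cat("  summary AUROC ", nm, ": ", round(x$summary_roc[[nm]]$auroc, 3),
        "\n", sep = "")
  cat("  ensemble AUROC: ", round(x$ensemble$auroc$auroc, 3),
      ", AUPRC: ", round(x$ensemble$auprc, 3), "\n", sep = "")
  if (length(x$skipped))
    cat("  skipped:", paste(x$skipped, collapse = "; "), "\n")
  invisible(x)
}
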