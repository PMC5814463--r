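#' Construct an expression matrix
#'
#' A genes-by-samples numeric matrix carrying its measurement scale
#' (`log2`, `linear` or `counts`) and an optional cohort label. Row names
#' are gene identifiers, column names sample identifiers; both must be
#' unique and values finite. Count matrices must be integer-valued and
#' non-negative.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param scale One of `"log2"`, `"linear"`, `"counts"`.
#' @param cohort_id Optional cohort label.
#' @return The matrix with class `expr_matrix` and `scale`/`cohort_id`
#'   attributes.
#' @export
expr_matrix <- function(values, scale = c("log2", "linear", "counts"),
                        cohort_id = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have gene row names and sample column names",
         call. = FALSE)
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("gene and sample identifiers must be unique", call. = FALSE)
  if (any(!is.finite(values)))
    stop("expression values must be finite", call. = FALSE)
  if (scale == "counts" && (any(values < 0) || any(values != round(values))))
    stop("counts must be non-negative integers", call. = FALSE)
  structure(values, scale = scale, cohort_id = cohort_id,
            class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("Expression matrix: ", nrow(x), " genes x ", ncol(x), " samples (",
      attr(x, "scale"), " scale",
      if (!is.null(attr(x, "cohort_id")))
        paste0(", cohort ", attr(x, "cohort_id")), ")\n", sep = "")
  invisible(x)
}

#' Measurement scale of an expression matrix
#' @param m An [expr_matrix()] (a plain matrix is assumed `log2`).
#' @return `"log2"`, `"linear"` or `"counts"`.
#' @export
expr_scale <- function(m) attr(m, "scale") %||% "log2"

.expr_values <- function(m) {
  v <- unclass(m)
  attr(v, "scale") <- NULL
  attr(v, "cohort_id") <- NULL
  v
}

#' Construct a per-sample annotation table
#'
#' @param sample_id Unique sample identifiers.
#' @param cohort_id Cohort labels.
#' @param mortality_30d 30-day mortality: 0, 1 or `NA`.
#' @param severity_value Optional clinical severity score values.
#' @param severity_type Optional severity score type (e.g. `"APACHE II"`,
#'   `"SOFA"`, `"PRISM"`).
#' @param time_from_admission_h Optional sampling time in hours from
#'   admission (non-negative).
#' @return A `data.frame` of class `sample_table`.
#' @export
sample_table <- function(sample_id, cohort_id, mortality_30d,
                         severity_value = NA_real_,
                         severity_type = NA_character_,
                         time_from_admission_h = NA_real_) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("sample identifiers must be unique", call. = FALSE)
  m <- as.integer(mortality_30d)
  if (!all(m %in% c(0L, 1L, NA_integer_)))
    stop("mortality_30d must be 0, 1 or NA", call. = FALSE)
  tt <- as.numeric(time_from_admission_h)
  if (any(tt < 0, na.rm = TRUE))
    stop("time_from_admission_h must be non-negative", call. = FALSE)
  out <- data.frame(sample_id = sample_id,
                    cohort_id = as.character(cohort_id),
                    mortality_30d = m,
                    severity_value = as.numeric(severity_value),
                    severity_type = as.character(severity_type),
                    time_from_admission_h = tt,
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_table", "data.frame")
  out
}

#' Collapse probe-level rows to gene level by the mean of probes
#'
#' Each gene's expression is the arithmetic mean, per sample, of the rows
#' of its probes. Probes absent from the mapping are dropped (count
#' reported via a message). A probe mapped to more than one gene is an
#' error, to avoid double counting.
#'
#' @param probe_matrix An [expr_matrix()] on the `log2` or `linear` scale
#'   with probe identifiers as row names.
#' @param mapping Data frame with columns `probe_id` and `gene_symbol`.
#' @return A gene-level [expr_matrix()] on the same scale, genes sorted
#'   alphabetically.
#' @export
collapse_probes <- function(probe_matrix, mapping) {
  scale <- expr_scale(probe_matrix)
  if (!scale %in% c("log2", "linear"))
    stop("collapse_probes expects log2 or linear scale input", call. = FALSE)
  if (!all(c("probe_id", "gene_symbol") %in% names(mapping)))
    stop("mapping must have columns probe_id and gene_symbol", call. = FALSE)
  mapping <- mapping[!is.na(mapping$probe_id) & !is.na(mapping$gene_symbol), ]
  mapping <- unique(mapping[c("probe_id", "gene_symbol")])
  if (!nrow(mapping)) stop("empty probe-to-gene mapping", call. = FALSE)
  multi <- unique(mapping$probe_id[duplicated(mapping$probe_id)])
  if (length(multi))
    stop("probe(s) mapped to multiple genes: ",
         paste(head(multi, 5), collapse = ", "), call. = FALSE)
  probes <- rownames(probe_matrix)
  keep <- probes %in% mapping$probe_id
  n_drop <- sum(!keep)
  if (n_drop) message(n_drop, " unmapped probe(s) dropped")
  if (!any(keep)) stop("no probes map to any gene", call. = FALSE)
  x <- .expr_values(probe_matrix)[keep, , drop = FALSE]
  genes <- mapping$gene_symbol[match(rownames(x), mapping$probe_id)]
  sums <- rowsum(x, group = genes)
  counts <- as.vector(table(genes)[rownames(sums)])
  out <- sums / counts
  expr_matrix(out[order(rownames(out)), , drop = FALSE], scale = scale,
              cohort_id = attr(probe_matrix, "cohort_id"))
}

#' Between-arrays quantile normalization
#'
#' Forces every sample's value distribution onto the cross-sample mean of
#' sorted vectors. Tied values within a sample receive the mean of the
#' reference values at their tied ranks. Backed by
#' [limma::normalizeQuantiles()].
#'
#' @param m An [expr_matrix()] (`log2` or `linear`) with at least two
#'   samples.
#' @return A quantile-normalized [expr_matrix()] on the same scale.
#' @export
quantile_normalize <- function(m) {
  scale <- expr_scale(m)
  if (!scale %in% c("log2", "linear"))
    stop("quantile_normalize expects log2 or linear scale input",
         call. = FALSE)
  if (ncol(m) < 2L) stop("need at least 2 samples", call. = FALSE)
  x <- .expr_values(m)
  if (diff(range(x)) == 0) {
    warning("constant matrix: returned unchanged", call. = FALSE)
    return(m)
  }
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  expr_matrix(out, scale = scale, cohort_id = attr(m, "cohort_id"))
}

#' Log2-CPM transformation with precision weights
#'
#' Converts RNA-seq counts to `log2((count + 0.5) / (libsize + 1) * 1e6)`
#' and estimates per-observation precision weights from the fitted
#' mean-variance trend (the voom construction, via [limma::voom()]). The
#' returned expression is, by default, the element-wise product of the
#' precision weights with log2-CPM; set `weighted = FALSE` to obtain plain
#' log2-CPM with the weights carried separately.
#'
#' @param counts An [expr_matrix()] on the `counts` scale with at least 10
#'   genes and positive library sizes.
#' @param weighted Multiply weights into the log2-CPM values (default).
#' @return List with `expr` (a `log2`-scale [expr_matrix()]), `log2cpm`
#'   (unweighted matrix) and `weights` (per-observation precision weights).
#' @export
log2_cpm_weights <- function(counts, weighted = TRUE) {
  if (expr_scale(counts) != "counts")
    stop("input must be on the counts scale", call. = FALSE)
  x <- .expr_values(counts)
  if (any(x < 0)) stop("negative counts", call. = FALSE)
  if (nrow(x) < 10L)
    stop("need at least 10 genes to fit the mean-variance trend",
         call. = FALSE)
  if (any(colSums(x) <= 0)) stop("library sizes must be positive", call. = FALSE)
  v <- limma::voom(x)
  final <- if (weighted) v$E * v$weights else v$E
  list(expr = expr_matrix(final, scale = "log2",
                          cohort_id = attr(counts, "cohort_id")),
       log2cpm = v$E, weights = v$weights)
}

#' Apply the sample-inclusion filters
#'
#' Keeps samples drawn within the first `max_time_h` hours after admission
#' (closed interval; a missing sampling time keeps the sample and is
#' logged) and, if `require_outcome`, drops samples with an unclear
#' mortality outcome.
#'
#' @param t A [sample_table()].
#' @param max_time_h Inclusion window in hours (default 48).
#' @param require_outcome Drop samples with missing 30-day mortality.
#' @return List with `samples` (the filtered table) and `exclusions`
#'   (a data frame of `sample_id` and `reason`).
#' @export
filter_samples <- function(t, max_time_h = 48, require_outcome = FALSE) {
  stopifnot(is.data.frame(t))
  reasons <- character(0); ids <- character(0)
  late <- !is.na(t$time_from_admission_h) & t$time_from_admission_h > max_time_h
  if (any(late)) {
    ids <- c(ids, t$sample_id[late])
    reasons <- c(reasons, rep(sprintf("sampled after %g h", max_time_h),
                              sum(late)))
  }
  keep <- !late
  if (require_outcome) {
    no_out <- keep & is.na(t$mortality_30d)
    if (any(no_out)) {
      ids <- c(ids, t$sample_id[no_out])
      reasons <- c(reasons, rep("missing mortality outcome", sum(no_out)))
    }
    keep <- keep & !is.na(t$mortality_30d)
  }
  n_na_time <- sum(is.na(t$time_from_admission_h))
  if (n_na_time)
    message(n_na_time, " sample(s) with missing sampling time kept")
  list(samples = t[keep, , drop = FALSE],
       exclusions = data.frame(sample_id = ids, reason = reasons,
                               stringsAsFactors = FALSE))
}
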