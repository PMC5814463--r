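#' Difference-of-geometric-means signature score
#'
#' The parameter-free score behind the Duke and Stanford mortality
#' predictors: for each sample, the geometric mean of the up genes minus
#' the geometric mean of the down genes. On the log2 scale the geometric
#' mean is the arithmetic mean of log2 values, so the score is
#' `mean(log2 x, up genes) - mean(log2 x, down genes)`. Higher scores mean
#' higher predicted mortality risk. Signature genes absent from the matrix
#' are dropped with a warning; the means renormalize over the genes
#' present.
#'
#' @param m An [expr_matrix()] on the `log2` scale.
#' @param sig A [gene_signature()].
#' @return Named numeric vector of per-sample scores with attributes
#'   `signature`, `n_up_used` and `n_down_used`.
#' @examples
#' x <- matrix(rnorm(40, 8), 4, 10,
#'             dimnames = list(c("A", "B", "C", "D"), paste0("s", 1:10)))
#' m <- expr_matrix(x, "log2")
#' signature_score(m, gene_signature("toy", up = c("A", "B"), down = "C"))
#' @export
signature_score <- function(m, sig) {
  stopifnot(inherits(sig, "gene_signature"))
  scale <- expr_scale(m)
  if (scale == "linear")
    stop("linear-scale input: apply log2_transform() first", call. = FALSE)
  if (scale == "counts")
    stop("counts input: apply log2_cpm_weights() first", call. = FALSE)
  x <- .expr_values(m)
  up <- intersect(sig$up, rownames(x))
  down <- intersect(sig$down, rownames(x))
  missing <- setdiff(c(sig$up, sig$down), rownames(x))
  if (length(missing))
    warning(length(missing), " signature gene(s) absent from matrix for '",
            sig$name, "': ", paste(head(missing, 5), collapse = ", "),
            call. = FALSE)
  if (!length(up))
    stop("no up genes of '", sig$name, "' present in matrix", call. = FALSE)
  if (!length(down))
    stop("no down genes of '", sig$name, "' present in matrix", call. = FALSE)
  s <- colMeans(x[up, , drop = FALSE]) - colMeans(x[down, , drop = FALSE])
  structure(s, signature = sig$name,
            n_up_used = length(up), n_down_used = length(down))
}

#' Log2-transform a linear-scale expression matrix
#'
#' Values are floored at `2^-10` before taking log2 so that zeros and
#' negatives do not produce infinities.
#'
#' @param m An [expr_matrix()] on the `linear` scale.
#' @param floor Lower floor applied before the log (default `2^-10`).
#' @return A `log2`-scale [expr_matrix()].
#' @export
log2_transform <- function(m, floor = 2^-10) {
  if (expr_scale(m) != "linear")
    stop("log2_transform expects linear-scale input", call. = FALSE)
  expr_matrix(log2(pmax(.expr_values(m), floor)), scale = "log2",
              cohort_id = attr(m, "cohort_id"))
}

#' Cell-type enrichment of a signature in sorted-cell profiles
#'
#' For each reference cell-type profile (a named vector of log2 expression
#' over a shared gene universe), computes the same difference-of-geometric-
#' means score as [signature_score()]: mean log2 expression of the up genes
#' minus the down genes. A high score indicates the signature is enriched
#' for genes highly expressed in that cell type. Significance is a
#' two-sided permutation p-value from `n_perm` random draws of same-size,
#' disjoint up/down gene sets from the profile's gene universe.
#'
#' @param pooled A [gene_signature()] (typically [pooled_union()] of the
#'   four predictors).
#' @param profiles Named list of named numeric vectors (one per cell type),
#'   log2 scale.
#' @param n_perm Number of permutations (a value below 100 warns).
#' @param seed Integer seed for the permutation draws.
#' @return Data frame with one row per cell type: `cell_type`, `score`,
#'   `p_value`, `n_up_used`, `n_down_used`.
#' @export
enrichment_in_profiles <- function(pooled, profiles, n_perm = 1000L,
                                   seed = 1L) {
  stopifnot(inherits(pooled, "gene_signature"))
  if (!length(profiles)) stop("empty profile collection", call. = FALSE)
  if (is.null(names(profiles)) || any(!nzchar(names(profiles))))
    stop("profiles must be a named list", call. = FALSE)
  if (n_perm < 100L)
    warning("n_perm < 100 gives a coarse permutation p-value", call. = FALSE)
  set.seed(seed)
  rows <- lapply(names(profiles), function(ct) {
    prof <- profiles[[ct]]
    universe <- names(prof)
    if (is.null(universe) || anyDuplicated(universe))
      stop("profile '", ct, "' must have unique gene names", call. = FALSE)
    if (any(!is.finite(prof)))
      stop("profile '", ct, "' has non-finite values", call. = FALSE)
    up <- intersect(pooled$up, universe)
    down <- intersect(pooled$down, universe)
    if (!length(up) || !length(down))
      stop("profile '", ct, "' covers no ",
           if (!length(up)) "up" else "down", " genes", call. = FALSE)
    obs <- mean(prof[up]) - mean(prof[down])
    k_up <- length(up); k_down <- length(down)
    perm <- vapply(seq_len(n_perm), function(i) {
      draw <- sample(universe, k_up + k_down)
      mean(prof[draw[seq_len(k_up)]]) - mean(prof[draw[-seq_len(k_up)]])
    }, numeric(1))
    p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
    data.frame(cell_type = ct, score = obs, p_value = p,
               n_up_used = k_up, n_down_used = k_down,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write per-sample signature scores to TSV
#'
#' @param scores Named numeric vector from [signature_score()].
#' @param path Output path.
#' @param cohort_id Optional cohort label column.
#' @export
write_scores <- function(scores, path, cohort_id = NA_character_) {
  df <- data.frame(sample_id = names(scores),
                   cohort_id = cohort_id,
                   signature = attr(scores, "signature") %||% NA_character_,
                   score = as.numeric(scores), stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
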