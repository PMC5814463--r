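#' Read a GMT gene-set file
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (upper-cased, deduplicated),
#'   with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  recs <- .read_gmt_lines(path)
  sets <- lapply(recs, function(r) unique(toupper(r$genes)))
  names(sets) <- vapply(recs, `[[`, character(1), "name")
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set names in GMT", call. = FALSE)
  attr(sets, "descriptions") <-
    setNames(vapply(recs, `[[`, character(1), "description"), names(sets))
  sets
}

#' Write gene sets to GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional per-set description (default the set name).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a gene-set collection over a background universe
#'
#' Genes absent from the background are removed from each set; sets left
#' empty are dropped with a warning.
#'
#' @param sets Named list of character vectors of gene symbols.
#' @param background Character vector: the gene universe (e.g. the genes
#'   shared by all input cohorts).
#' @return List of class `gene_set_collection` with `sets` and
#'   `background`.
#' @export
gene_set_collection <- function(sets, background) {
  background <- unique(toupper(background))
  if (!length(background)) stop("empty background", call. = FALSE)
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must be uniquely named", call. = FALSE)
  sets <- lapply(sets, function(g) intersect(unique(toupper(g)), background))
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning(sum(empty), " set(s) empty after background intersection dropped",
            call. = FALSE)
    sets <- sets[!empty]
  }
  structure(list(sets = sets, background = background),
            class = "gene_set_collection")
}

#' Retention filter on gene sets by predictor overlap
#'
#' Keeps sets whose overlap with the predictor genes is at least 3 genes
#' AND at least 10% of the (background-intersected) set size; all others
#' are removed to reduce the multiple-testing burden.
#'
#' @param coll A [gene_set_collection()].
#' @param predictors Character vector of predictor gene symbols; genes
#'   outside the background are dropped with a warning.
#' @param min_genes Minimum overlap count (default 3).
#' @param min_fraction Minimum overlap fraction of set size (default 0.1).
#' @return A filtered [gene_set_collection()] (warning if nothing
#'   survives).
#' @export
filter_gene_sets <- function(coll, predictors, min_genes = 3L,
                             min_fraction = 0.1) {
  stopifnot(inherits(coll, "gene_set_collection"))
  predictors <- unique(toupper(predictors))
  out <- setdiff(predictors, coll$background)
  if (length(out)) {
    warning(length(out), " predictor gene(s) outside background dropped",
            call. = FALSE)
    predictors <- intersect(predictors, coll$background)
  }
  keep <- vapply(coll$sets, function(g) {
    ov <- length(intersect(g, predictors))
    ov >= min_genes && ov >= min_fraction * length(g)
  }, logical(1))
  if (!any(keep))
    warning("no gene set passes the retention filter", call. = FALSE)
  structure(list(sets = coll$sets[keep], background = coll$background),
            class = "gene_set_collection")
}

#' Over-representation by Fisher's exact test with BH correction
#'
#' For each set, a one-sided (enrichment) Fisher's exact test on the 2x2
#' table of in-set/out-of-set by predictor/background-only counts, with
#' Benjamini-Hochberg adjustment across sets.
#'
#' @param coll A (typically filtered) [gene_set_collection()].
#' @param predictors Character vector of predictor gene symbols (within
#'   the background).
#' @param fdr Significance threshold on the BH-adjusted q-value.
#' @return Data frame sorted by p-value: `set`, `set_size`, `overlap`,
#'   `odds_ratio`, `p_value`, `q_value`, `significant`, `overlap_genes`.
#' @export
overrepresentation_fet <- function(coll, predictors, fdr = 0.05) {
  stopifnot(inherits(coll, "gene_set_collection"))
  predictors <- intersect(unique(toupper(predictors)), coll$background)
  if (!length(predictors)) stop("no predictor genes in background", call. = FALSE)
  N <- length(coll$background)
  K <- length(predictors)
  rows <- lapply(names(coll$sets), function(nm) {
    g <- coll$sets[[nm]]
    if (length(g) > N) stop("set larger than background: ", nm, call. = FALSE)
    ov <- intersect(g, predictors)
    k <- length(ov); s <- length(g)
    tab <- matrix(c(k, K - k, s - k, N - K - s + k), nrow = 2)
    ft <- fisher.test(tab, alternative = "greater")
    data.frame(set = nm, set_size = s, overlap = k,
               odds_ratio = unname(ft$estimate), p_value = ft$p.value,
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_value <- p.adjust(res$p_value, method = "BH")
  res$significant <- res$q_value < fdr
  res[order(res$p_value),
      c("set", "set_size", "overlap", "odds_ratio", "p_value", "q_value",
        "significant", "overlap_genes")]
}
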