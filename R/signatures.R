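#' Construct a gene signature
#'
#' A gene signature is a pair of disjoint gene-symbol sets: genes expected
#' higher in non-survivors (`up`) and genes expected lower (`down`). Symbols
#' are upper-cased; gene identity is by symbol string, with no alias
#' resolution. Duplicates within a list are removed with a warning.
#'
#' @param name Short identifier for the signature.
#' @param up Character vector of gene symbols higher in non-survivors.
#' @param down Character vector of gene symbols lower in non-survivors.
#' @return An object of class `gene_signature`: a list with elements
#'   `name`, `up` and `down`.
#' @examples
#' sig <- gene_signature("toy", up = c("DEFA4", "IL8"), down = "LY86")
#' @export
gene_signature <- function(name, up = character(), down = character()) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("signature name must be a non-empty string", call. = FALSE)
  up <- toupper(as.character(up))
  down <- toupper(as.character(down))
  if (any(!nzchar(c(up, down))))
    stop("gene symbols must be non-empty strings (signature '", name, "')",
         call. = FALSE)
  if (anyDuplicated(up) || anyDuplicated(down)) {
    warning("duplicate gene symbols removed in signature '", name, "'",
            call. = FALSE)
    up <- unique(up)
    down <- unique(down)
  }
  both <- intersect(up, down)
  if (length(both))
    stop("genes present in both up and down lists of '", name, "': ",
         paste(both, collapse = ", "), call. = FALSE)
  if (length(up) + length(down) == 0L)
    stop("signature '", name, "' has no genes", call. = FALSE)
  structure(list(name = name, up = up, down = down),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("Gene signature '", x$name, "': ", length(x$up), " up, ",
      length(x$down), " down\n", sep = "")
  invisible(x)
}

#' Construct a set of uniquely named signatures
#'
#' @param signatures List of [gene_signature()] objects.
#' @return An object of class `signature_set` (a named list of signatures).
#' @export
signature_set <- function(signatures) {
  if (!length(signatures)) stop("empty signature set", call. = FALSE)
  ok <- vapply(signatures, inherits, logical(1), "gene_signature")
  if (!all(ok)) stop("all elements must be gene_signature objects", call. = FALSE)
  nm <- vapply(signatures, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("signature names must be unique: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  structure(setNames(signatures, nm), class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat("Signature set with", length(x), "signatures:\n")
  for (s in x)
    cat("  ", s$name, ": ", length(s$up), " up / ", length(s$down),
        " down\n", sep = "")
  invisible(x)
}

# one GMT record per line: name <tab> description <tab> genes...
.read_gmt_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("malformed GMT record (need name, description, >=1 gene): '",
           substr(l, 1, 40), "'", call. = FALSE)
    list(name = f[1], description = f[2], genes = f[-(1:2)])
  })
}

#' Load gene signatures from a file
#'
#' Two formats are accepted. A GMT file pairs records named `<name>_up` and
#' `<name>_down` into one signature per `<name>` (a missing partner yields
#' an empty list on that side). A YAML file holds a sequence of records with
#' explicit `name`, `up` and `down` keys. The format is chosen by file
#' extension (`.gmt` vs `.yml`/`.yaml`).
#'
#' @param path Path to a signature file.
#' @return A [signature_set()].
#' @examples
#' path <- system.file("extdata", "sepsis_mortality_signatures.gmt",
#'                     package = "sepsig")
#' sigs <- load_signatures(path)
#' @export
load_signatures <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "gmt") {
    recs <- .read_gmt_lines(path)
    nm <- vapply(recs, `[[`, character(1), "name")
    bad <- !grepl("_(up|down)$", nm)
    if (any(bad))
      stop("GMT signature records must end in _up or _down; offending: ",
           paste(nm[bad], collapse = ", "), call. = FALSE)
    base <- sub("_(up|down)$", "", nm)
    side <- sub("^.*_(up|down)$", "\\1", nm)
    sigs <- lapply(unique(base), function(b) {
      up <- unlist(lapply(recs[base == b & side == "up"], `[[`, "genes"))
      down <- unlist(lapply(recs[base == b & side == "down"], `[[`, "genes"))
      gene_signature(b, up = up %||% character(), down = down %||% character())
    })
  } else if (ext %in% c("yml", "yaml")) {
    recs <- yaml::read_yaml(path)
    if (!is.list(recs) || !length(recs))
      stop("malformed YAML signature file: expected a sequence of records",
           call. = FALSE)
    sigs <- lapply(seq_along(recs), function(i) {
      r <- recs[[i]]
      if (is.null(r$name))
        stop("malformed signature record #", i, ": missing 'name'",
             call. = FALSE)
      gene_signature(r$name,
                     up = unlist(r$up) %||% character(),
                     down = unlist(r$down) %||% character())
    })
  } else {
    stop("unrecognized signature file extension: '", ext,
         "' (expected gmt, yml or yaml)", call. = FALSE)
  }
  signature_set(sigs)
}

#' The four published sepsis-mortality gene predictors
#'
#' Loads the built-in fixture with the Duke (5 up / 13 down), Sage LR
#' (9/9), Sage RF (13/4) and Stanford (8/4) mortality signatures. Higher
#' signature scores correspond to higher 30-day mortality risk.
#'
#' @return A [signature_set()] with signatures `Duke`, `SageLR`, `SageRF`
#'   and `Stanford`.
#' @export
sepsis_signatures <- function() {
  load_signatures(system.file("extdata", "sepsis_mortality_signatures.gmt",
                              package = "sepsig", mustWork = TRUE))
}

#' Pool the signatures of a set into one aggregate signature
#'
#' Takes the union of all up lists and of all down lists. A gene assigned
#' up in one signature and down in another is a directional conflict and an
#' error; the four built-in predictors have none, pooling to 58 genes
#' (31 up, 27 down).
#'
#' @param sigs A [signature_set()].
#' @param name Name for the pooled signature.
#' @return A [gene_signature()].
#' @export
pooled_union <- function(sigs, name = "pooled") {
  if (!inherits(sigs, "signature_set")) sigs <- signature_set(sigs)
  up <- sort(unique(unlist(lapply(sigs, `[[`, "up"))))
  down <- sort(unique(unlist(lapply(sigs, `[[`, "down"))))
  conflict <- intersect(up, down)
  if (length(conflict))
    stop("directional conflict between signatures for gene(s): ",
         paste(conflict, collapse = ", "), call. = FALSE)
  gene_signature(name, up = up, down = down)
}

#' Overlap report between two signatures
#'
#' @param a,b [gene_signature()] objects.
#' @return A list with `shared_up`, `shared_down`, `conflicting` (genes up
#'   in one signature and down in the other) and their counts. Symmetric
#'   in `a` and `b`.
#' @export
signature_overlap <- function(a, b) {
  stopifnot(inherits(a, "gene_signature"), inherits(b, "gene_signature"))
  shared_up <- sort(intersect(a$up, b$up))
  shared_down <- sort(intersect(a$down, b$down))
  conflicting <- sort(union(intersect(a$up, b$down), intersect(a$down, b$up)))
  list(shared_up = shared_up, shared_down = shared_down,
       conflicting = conflicting,
       n_shared_up = length(shared_up), n_shared_down = length(shared_down),
       n_conflicting = length(conflicting))
}
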