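# checksum of the shipped registry transcription; load_cohort_registry()
# refuses a silently edited fixture
.REGISTRY_MD5 <- "018281639e9a506ef2697f6e846103a2"

#' Load the 21-cohort study registry
#'
#' The registry records, per cohort: accession, role (12 discovery, 5
#' validation, 4 hospital-acquired-infection), survivor and non-survivor
#' counts, severity score type, country and sampling-time notes. When
#' loading the built-in fixture its checksum is verified; a mismatch is an
#' error.
#'
#' @param path Optional path to a registry TSV; default is the built-in
#'   fixture.
#' @param checksum Expected MD5 of the file; defaults to the fixture's
#'   checksum when loading the built-in registry, `NULL` (no check)
#'   otherwise.
#' @return Data frame of class `cohort_registry`, one row per cohort.
#' @export
load_cohort_registry <- function(path = NULL, checksum = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cohort_registry.tsv",
                        package = "sepsig", mustWork = TRUE)
    checksum <- checksum %||% .REGISTRY_MD5
  }
  if (!is.null(checksum) && unname(tools::md5sum(path)) != checksum)
    stop("cohort registry checksum mismatch", call. = FALSE)
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "role", "n_survived", "n_died")
  if (!all(need %in% names(d)))
    stop("registry must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(d$accession))
    stop("cohort accessions must be unique", call. = FALSE)
  if (!all(d$role %in% c("discovery", "validation", "hai")))
    stop("roles must be discovery, validation or hai", call. = FALSE)
  if (any(d$n_survived < 0) || any(d$n_died < 0) ||
      any(d$n_survived + d$n_died < 1))
    stop("each cohort needs non-negative counts summing to >= 1",
         call. = FALSE)
  class(d) <- c("cohort_registry", "data.frame")
  d
}

#' Mortality summary over the cohort registry
#'
#' Per-cohort mortality rate is deaths / (deaths + survivors). The mean
#' rate is unweighted over cohorts; the SD uses the population divisor N.
#'
#' @param records A [load_cohort_registry()] data frame.
#' @param roles Optional role filter (subset of `"discovery"`,
#'   `"validation"`, `"hai"`).
#' @return List with `total_survived`, `total_died`, `rates` (named
#'   per-cohort), `mean_rate`, `sd_rate`, `n_cohorts`.
#' @export
summarize_mortality <- function(records, roles = NULL) {
  stopifnot(is.data.frame(records))
  if (!is.null(roles)) records <- records[records$role %in% roles, ]
  if (!nrow(records)) stop("no cohorts after role filter", call. = FALSE)
  r <- records$n_died / (records$n_died + records$n_survived)
  list(total_survived = sum(records$n_survived),
       total_died = sum(records$n_died),
       rates = setNames(r, records$accession),
       mean_rate = mean(r),
       sd_rate = sqrt(mean((r - mean(r))^2)),
       n_cohorts = nrow(records))
}
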