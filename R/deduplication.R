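#' FDA-recommended case-level deduplication
#'
#' A FAERS case (CASEID) accumulates report versions (PRIMARYID) over time.
#' Following the FDA recommendation, for reports sharing a CASEID the version
#' with the highest FDA_DT is retained; among versions tied on FDA_DT the
#' highest PRIMARYID wins. Equivalently the retained version is the argmax
#' over (FDA_DT, PRIMARYID) in lexicographic order. A missing FDA_DT compares
#' lower than any present date, so a dated version always beats an undated
#' one.
#'
#' @param demo a DEMO data frame with at least `primaryid`, `caseid`,
#'   `fda_dt` (packed partial dates, `NA` allowed).
#' @return an object of class `"dedup_result"`: a list with
#'   `retained` (the retained DEMO rows, one per CASEID),
#'   `removed_as_duplicate`, `removed_as_deleted` (0 until
#'   [apply_deletions()]), and `n_input`.
#' @seealso [apply_deletions()], [retained_primaryids()]
#' @export
deduplicate_reports <- function(demo) {
  stopifnot(all(c("primaryid", "caseid", "fda_dt") %in% names(demo)))
  if (anyDuplicated(demo$primaryid))
    stop("integrity error: duplicate PRIMARYID values in input DEMO table")
  key_dt <- ifelse(is.na(demo$fda_dt), -1, as.numeric(demo$fda_dt))
  o <- order(demo$caseid, key_dt, demo$primaryid)
  last <- !duplicated(demo$caseid[o], fromLast = TRUE)
  retained <- demo[o[last], , drop = FALSE]
  rownames(retained) <- NULL
  structure(list(retained = retained,
                 removed_as_duplicate = nrow(demo) - nrow(retained),
                 removed_as_deleted = 0L,
                 n_input = nrow(demo)),
            class = "dedup_result")
}

#' Remove FDA-deleted cases from a deduplicated set
#'
#' FAERS publishes lists of CASEIDs deleted after initial dissemination;
#' retained reports whose CASEID appears on the list are removed and counted
#' separately.
#'
#' @param dedup a `"dedup_result"` from [deduplicate_reports()].
#' @param deleted_caseids numeric vector of case ids (may be empty).
#' @return the updated `"dedup_result"`.
#' @export
apply_deletions <- function(dedup, deleted_caseids) {
  stopifnot(inherits(dedup, "dedup_result"))
  if (length(deleted_caseids) == 0L) return(dedup)
  drop <- dedup$retained$caseid %in% deleted_caseids
  dedup$retained <- dedup$retained[!drop, , drop = FALSE]
  rownames(dedup$retained) <- NULL
  dedup$removed_as_deleted <- dedup$removed_as_deleted + sum(drop)
  dedup
}

#' Primaryids retained after deduplication
#' @param dedup a `"dedup_result"`.
#' @return numeric vector of retained PRIMARYID values.
#' @export
retained_primaryids <- function(dedup) dedup$retained$primaryid

#' @export
print.dedup_result <- function(x, ...) {
  cat("FAERS case-level deduplication\n")
  cat(sprintf("  input report versions : %d\n", x$n_input))
  cat(sprintf("  retained cases        : %d\n", nrow(x$retained)))
  cat(sprintf("  removed as duplicates : %d\n", x$removed_as_duplicate))
  cat(sprintf("  removed as deleted    : %d\n", x$removed_as_deleted))
  invisible(x)
}
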