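#' Clinical characterisation of the target cohort
#'
#' Builds the descriptive blocks of a pharmacovigilance report: sex, age
#' bins, serious outcomes, top reporting countries, top indications, reporter
#' occupations and reports per year, each as counts plus percentages of the
#' cohort size. Ties in the top-k blocks break alphabetically for
#' determinism.
#'
#' @param cases case table from [build_report_cases()], already filtered to
#'   the cohort of interest (e.g. `cases[cases$is_target, ]`).
#' @param top_k how many countries/indications to keep (default 5).
#' @return object of class `"cohort_summary"`: a list of data frames
#'   (`sex`, `age`, `outcomes`, `countries`, `indications`, `reporters`,
#'   `years`), each with `category`, `n` and `pct` columns, plus `n_cohort`.
#' @export
describe_cohort <- function(cases, top_k = 5L) {
  n <- nrow(cases)
  pct <- function(k) if (n > 0) round_half_up(100 * k / n, 1) else NA_real_
  block <- function(x, levels = NULL, top = NULL) {
    x <- ifelse(is.na(x) | x == "", "Missing", as.character(x))
    tb <- table(x)
    # deterministic order: by count desc then name
    tb <- tb[order(-as.integer(tb), names(tb))]
    if (!is.null(levels)) tb <- stats::setNames(as.integer(table(factor(x, levels = levels))), levels)
    if (!is.null(top)) tb <- utils::head(tb, top)
    data.frame(category = names(tb), n = as.integer(tb), pct = pct(as.integer(tb)),
               stringsAsFactors = FALSE)
  }

  outcomes <- NULL
  if (!is.null(cases$outcomes)) {
    oc <- unlist(cases$outcomes, use.names = FALSE)
    lev <- c(DE = "Death", HO = "Hospitalization", DS = "Disability",
             LT = "Life-threatening", CA = "Congenital anomaly",
             RI = "Required intervention", OT = "Other serious")
    tb <- table(factor(oc, levels = names(lev)))
    outcomes <- data.frame(category = unname(lev), n = as.integer(tb),
                           pct = pct(as.integer(tb)), stringsAsFactors = FALSE)
  }
  indications <- NULL
  if (!is.null(cases$indications)) {
    first_ind <- vapply(cases$indications, function(v)
      if (length(v) == 0L) "Missing" else v[[1L]], character(1))
    indications <- block(first_ind, top = top_k)
  }

  years <- block(cases$report_year)
  years <- years[order(years$category), , drop = FALSE]
  rownames(years) <- NULL

  structure(list(
    n_cohort = n,
    sex = block(cases$sex, levels = c("F", "M", "UNK")),
    age = block(as.character(cases$age_bin),
                levels = c("<18", "18-64", "65-84", ">=85", "Unknown")),
    outcomes = outcomes,
    countries = block(cases$country, top = top_k),
    indications = indications,
    reporters = block(cases$reporter_occupation),
    years = years
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d deduplicated reports\n", x$n_cohort))
  for (nm in c("sex", "age", "outcomes", "countries", "indications", "reporters")) {
    if (is.null(x[[nm]])) next
    cat(sprintf("\n%s:\n", toupper(nm)))
    print(x[[nm]], row.names = FALSE)
  }
  invisible(x)
}

#' Yearly reporting trend, by country group and scaled total
#'
#' Counts reports per calendar year for each named country group, plus the
#' overall total multiplied by `scale_factor` — the convention of shrinking
#' the all-countries series (e.g. to one quarter) so it can share an axis
#' with single-country series.
#'
#' @param cases case table (filtered to the cohort of interest).
#' @param groups named list of country-code character vectors, e.g.
#'   `list(USA = "US", GBR = "GB")`.
#' @param scale_factor positive multiplier for the total series (default
#'   0.25).
#' @return data frame with `year`, one count column per group, `total` and
#'   `scaled_total`.
#' @export
yearly_trend <- function(cases, groups = list(), scale_factor = 0.25) {
  stopifnot(scale_factor > 0)
  yrs <- sort(unique(cases$report_year[!is.na(cases$report_year)]))
  out <- data.frame(year = yrs)
  for (g in names(groups)) {
    sel <- cases$country %in% groups[[g]]
    out[[g]] <- as.integer(table(factor(cases$report_year[sel], levels = yrs)))
  }
  out$total <- as.integer(table(factor(cases$report_year, levels = yrs)))
  out$scaled_total <- out$total * scale_factor
  out
}

#' Sex-stratified disproportionality signals
#'
#' Runs the full four-algorithm battery within one sex stratum (target drug
#' vs all other drugs, restricted to reports of that sex). Unknown-sex
#' reports are excluded from strata but remain in pooled analyses. Rows come
#' back sorted by `a` descending; optionally only the top-k most frequent
#' terms and/or only terms meeting all four criteria are kept.
#'
#' @param events event table from [build_event_table()].
#' @param cases case table from [build_report_cases()] (all reports, both
#'   target and comparator).
#' @param sex `"F"` or `"M"`.
#' @param level `"pt"` or `"soc"`.
#' @param top_k keep only the k most frequent terms (by stratum `a`);
#'   `Inf` keeps all. Default 30.
#' @param all_four_only keep only rows meeting all four criteria (default
#'   `FALSE`).
#' @return a data frame like `as.data.frame()` of a [disprop()] fit with a
#'   `stratum` column prepended; zero rows if the stratum is empty.
#' @export
stratified_signals <- function(events, cases, sex = c("F", "M"),
                               level = c("pt", "soc"), top_k = 30L,
                               all_four_only = FALSE) {
  sex <- match.arg(sex)
  level <- match.arg(level)
  ids <- cases$primaryid[cases$sex == sex]
  ev <- events[events$primaryid %in% ids, , drop = FALSE]
  if (nrow(ev) == 0L || !any(ev$is_target) || !any(!ev$is_target)) {
    out <- data.frame(stratum = character(), term = character(), a = integer())
    return(out)
  }
  fit <- as.data.frame(disprop(ev, level = level))
  if (all_four_only) fit <- fit[fit$all_four, , drop = FALSE]
  if (is.finite(top_k)) fit <- utils::head(fit, top_k)
  cbind(data.frame(stratum = rep(sex, nrow(fit)), stringsAsFactors = FALSE), fit)
}
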