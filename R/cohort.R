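#' Keyword match on drug name and active ingredient
#'
#' A drug row matches if any keyword is a case-insensitive substring of the
#' verbatim drug name or of the active-ingredient (`PROD_AI`) field after
#' whitespace normalisation, so `"donepezil"` matches both
#' `"DONEPEZIL HYDROCHLORIDE"` and `"Donepezil."` but brand names
#' (`"ARICEPT"`) only match through their `PROD_AI`.
#'
#' @param drugname character vector of drug names.
#' @param prod_ai character vector of active ingredients (`NA` allowed).
#' @param keywords non-empty character vector of keywords.
#' @return logical vector.
#' @export
match_drug <- function(drugname, prod_ai, keywords) {
  stopifnot(length(keywords) > 0L)
  norm <- function(x) tolower(gsub("[[:space:]]+", " ", trimws(ifelse(is.na(x), "", x))))
  dn <- norm(drugname)
  ai <- norm(prod_ai)
  hit <- rep(FALSE, length(dn))
  for (kw in tolower(trimws(keywords)))
    hit <- hit | grepl(kw, dn, fixed = TRUE) | grepl(kw, ai, fixed = TRUE)
  hit
}

#' Select reports with the target drug as primary suspect
#'
#' Implements the cohort rule: a retained report enters the target cohort iff
#' it has at least one DRUG row matching the keywords with role code `PS`
#' ("primary suspect"). Reports where the drug appears only as secondary
#' suspect, concomitant or interacting are excluded.
#'
#' @param drug DRUG data frame (`primaryid`, `role_cod`, `drugname`,
#'   `prod_ai`).
#' @param retained_ids primaryids retained after deduplication.
#' @param keywords drug keywords, as in [match_drug()].
#' @param role required role code (default `"PS"`).
#' @return numeric vector of target primaryids (subset of `retained_ids`).
#' @export
select_target_reports <- function(drug, retained_ids, keywords, role = "PS") {
  if (nrow(drug) == 0L) return(numeric())
  hit <- drug$role_cod %in% role &
    match_drug(drug$drugname, drug$prod_ai, keywords) &
    drug$primaryid %in% retained_ids
  unique(drug$primaryid[hit])
}

#' Convert FAERS age value/unit pairs to years
#'
#' Unit codes: `DEC` decades (x10), `YR` years, `MON` months (/12), `WK`
#' weeks (/52.1775), `DY` days (/365.25), `HR` hours (/8766). A missing unit
#' with a value present is taken as years. Negative ages become missing.
#'
#' @param age_value numeric vector.
#' @param age_cod character vector of unit codes (`NA` allowed).
#' @return numeric vector of ages in years (`NA` where missing/invalid),
#'   with attribute `n_negative` counting negatives mapped to missing.
#' @export
age_to_years <- function(age_value, age_cod) {
  factors <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.1775,
               DY = 1 / 365.25, HR = 1 / 8766)
  f <- unname(factors[as.character(age_cod)])
  f[is.na(f)] <- 1 # missing unit, value present: years
  out <- age_value * f
  n_neg <- sum(!is.na(out) & out < 0)
  out[!is.na(out) & out < 0] <- NA_real_
  attr(out, "n_negative") <- n_neg
  out
}

#' Age bins used in the descriptive tables
#' @param years numeric age in years.
#' @return factor with levels `<18`, `18-64`, `65-84`, `>=85`, `Unknown`.
#' @export
age_bin <- function(years) {
  lev <- c("<18", "18-64", "65-84", ">=85", "Unknown")
  out <- rep("Unknown", length(years))
  out[!is.na(years) & years < 18] <- "<18"
  out[!is.na(years) & years >= 18 & years < 65] <- "18-64"
  out[!is.na(years) & years >= 65 & years < 85] <- "65-84"
  out[!is.na(years) & years >= 85] <- ">=85"
  factor(out, levels = lev)
}

#' Assemble one case row per retained report
#'
#' Joins demographics with target-cohort membership and (optionally) serious
#' outcomes and indications, producing the per-report case table the
#' descriptive and stratified analyses run on.
#'
#' @param demo_retained retained DEMO rows (from [deduplicate_reports()]).
#' @param target_ids primaryids of the target cohort.
#' @param outc optional OUTC data frame.
#' @param indi optional INDI data frame.
#' @return data frame with one row per retained report: identifiers,
#'   `is_target`, `sex`, `age_years`, `age_bin`, `country`,
#'   `reporter_occupation`, `report_year`, `event_dt`, plus list columns
#'   `outcomes` and `indications` when the side tables are supplied.
#' @export
build_report_cases <- function(demo_retained, target_ids, outc = NULL, indi = NULL) {
  cases <- data.frame(
    primaryid = demo_retained$primaryid,
    caseid = demo_retained$caseid,
    is_target = demo_retained$primaryid %in% target_ids,
    sex = demo_retained$sex,
    age_years = as.numeric(age_to_years(demo_retained$age, demo_retained$age_cod)),
    country = demo_retained$country,
    reporter_occupation = demo_retained$reporter_occupation,
    report_year = demo_retained$report_year,
    event_dt = demo_retained$event_dt,
    stringsAsFactors = FALSE
  )
  cases$age_bin <- age_bin(cases$age_years)
  if (!is.null(outc)) {
    keep <- outc$primaryid %in% cases$primaryid
    cases$outcomes <- unname(split(outc$outc_cod[keep], factor(outc$primaryid[keep], levels = cases$primaryid)))
  }
  if (!is.null(indi)) {
    keep <- indi$primaryid %in% cases$primaryid & !is.na(indi$indi_pt)
    cases$indications <- unname(split(indi$indi_pt[keep], factor(indi$primaryid[keep], levels = cases$primaryid)))
  }
  cases
}

#' Build the drug-event record table
#'
#' The counting unit of the whole analysis: one record per distinct
#' (retained report, normalised PT) pair, flagged target vs non-target and
#' annotated with its SOC from the vocabulary. Repeated PTs within a report
#' collapse to one record; the first verbatim casing seen for each normalised
#' PT is kept for display.
#'
#' @param reac REAC data frame.
#' @param retained_ids primaryids retained after deduplication.
#' @param target_ids primaryids of the target cohort.
#' @param vocab named character vector from [read_vocabulary()].
#' @param unmapped policy for PTs absent from the vocabulary: `"label"`
#'   (default) assigns SOC `"UNMAPPED"`, `"error"` stops.
#' @return data frame with columns `primaryid`, `pt` (display casing),
#'   `soc`, `is_target`.
#' @export
build_event_table <- function(reac, retained_ids, target_ids, vocab,
                              unmapped = c("label", "error")) {
  unmapped <- match.arg(unmapped)
  keep <- reac$primaryid %in% retained_ids
  pid <- reac$primaryid[keep]
  pt_raw <- trimws(reac$pt[keep])
  pt_norm <- normalize_pt(pt_raw)
  dup <- duplicated(paste(pid, pt_norm, sep = "\r"))
  pid <- pid[dup == FALSE]
  pt_raw <- pt_raw[!dup]
  pt_norm <- pt_norm[!dup]

  # canonical display casing: most frequent verbatim form per normalised PT,
  # ties broken by first occurrence
  pair <- paste(pt_norm, pt_raw, sep = "\r")
  up <- !duplicated(pair)
  cnt <- table(pair)
  pu <- pair[up]
  o <- order(pt_norm[up], -as.integer(cnt[pu]), match(pu, pair))
  nu <- pt_norm[up][o]
  ru <- pt_raw[up][o]
  keep_first <- !duplicated(nu)
  display <- stats::setNames(ru[keep_first], nu[keep_first])

  soc <- unname(vocab[pt_norm])
  if (anyNA(soc)) {
    if (unmapped == "error")
      stop("PT(s) absent from vocabulary: ",
           paste(utils::head(unique(pt_norm[is.na(soc)]), 5L), collapse = ", "))
    soc[is.na(soc)] <- "UNMAPPED"
  }
  out <- data.frame(primaryid = pid,
                    pt = unname(display[pt_norm]),
                    soc = soc,
                    is_target = pid %in% target_ids,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
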