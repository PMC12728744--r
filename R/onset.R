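#' Time to onset for one or more reports
#'
#' Onset is the calendar-day interval from therapy initiation to adverse
#' event occurrence. Only full-precision dates on both sides are used:
#' month- or year-precision values are excluded rather than imputed, so no
#' onset is ever fabricated from a partial date. Events dated before therapy
#' start are excluded as `pre_treatment`.
#'
#' @param event_dt packed partial-date integers (event occurrence).
#' @param start_dt packed partial-date integers (therapy start).
#' @return data frame with columns `onset_days` (integer, `NA` when
#'   excluded), `included` (logical) and `reason` (factor:
#'   `ok`, `pre_treatment`, `partial_date`, `missing_date`).
#' @export
compute_onset <- function(event_dt, start_dt) {
  n <- max(length(event_dt), length(start_dt))
  event_dt <- rep_len(as.integer(event_dt), n)
  start_dt <- rep_len(as.integer(start_dt), n)
  reason <- rep("ok", n)
  missing_any <- is.na(event_dt) | is.na(start_dt)
  partial <- !missing_any & (event_dt %% 100L == 0L | start_dt %% 100L == 0L)
  reason[partial] <- "partial_date"
  reason[missing_any] <- "missing_date"

  days <- rep(NA_integer_, n)
  full <- !missing_any & !partial
  if (any(full)) {
    days[full] <- as.integer(partial_date_to_date(event_dt[full]) -
                             partial_date_to_date(start_dt[full]))
  }
  pre <- full & days < 0L
  reason[pre] <- "pre_treatment"
  days[pre] <- NA_integer_
  data.frame(onset_days = days,
             included = reason == "ok",
             reason = factor(reason, levels = c("ok", "pre_treatment",
                                                "partial_date", "missing_date")))
}

#' Onset records for the target cohort
#'
#' Links each target report to the therapy row of its matched primary-suspect
#' drug (via `DSG_DRUG_SEQ`), takes the earliest full-precision start date
#' when several therapy rows exist, and computes onset against the report's
#' event date.
#'
#' @param ther THER data frame.
#' @param drug DRUG data frame.
#' @param cases case table from [build_report_cases()] (supplies `event_dt`).
#' @param keywords target-drug keywords.
#' @param role role code identifying the suspect rows (default `"PS"`).
#' @return data frame: `primaryid`, `onset_days`, `included`, `reason`, for
#'   every target case.
#' @export
onset_for_cohort <- function(ther, drug, cases, keywords, role = "PS") {
  targets <- cases[cases$is_target, , drop = FALSE]
  hit <- drug$role_cod %in% role & match_drug(drug$drugname, drug$prod_ai, keywords)
  dseq <- drug[hit & drug$primaryid %in% targets$primaryid,
               c("primaryid", "drug_seq"), drop = FALSE]

  th <- merge(dseq, ther, by.x = c("primaryid", "drug_seq"),
              by.y = c("primaryid", "dsg_drug_seq"))
  full <- !is.na(th$start_dt) & th$start_dt %% 100L > 0L
  th_full <- th[full, , drop = FALSE]
  # earliest full start date per report
  if (nrow(th_full) > 0L) {
    o <- order(th_full$primaryid, th_full$start_dt)
    th_full <- th_full[o, , drop = FALSE]
    th_full <- th_full[!duplicated(th_full$primaryid), , drop = FALSE]
  }
  start <- th_full$start_dt[match(targets$primaryid, th_full$primaryid)]
  # reports with only partial-precision therapy dates stay partial, not missing
  partial_start <- th$start_dt[match(targets$primaryid, th$primaryid)]
  use_partial <- is.na(start) & !is.na(partial_start)
  start[use_partial] <- partial_start[use_partial]
  onset <- compute_onset(targets$event_dt, start)
  cbind(data.frame(primaryid = targets$primaryid), onset)
}

#' Summarise a time-to-onset distribution
#'
#' Median and quartiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7, the convention that yields fractional
#' quartiles). Counts are binned in 30-day intervals up to 360 days plus a
#' `>360` bin; `fraction_first_month` is the share with onset at most 30
#' days and `fraction_over_one_year` the share beyond 365 days.
#'
#' @param onset either the data frame from [compute_onset()] /
#'   [onset_for_cohort()] or a bare numeric vector of included onset days.
#' @return object of class `"onset_summary"`: list with `n_included`,
#'   `n_excluded` (named by reason), `mean_days`, `median_days`, `q1`, `q3`,
#'   `bin_counts`, `fraction_first_month`, `fraction_over_one_year`. All
#'   summary fields are `NA` (and `bin_counts` zero) when nothing is
#'   included.
#' @export
summarize_onset <- function(onset) {
  if (is.data.frame(onset)) {
    days <- onset$onset_days[onset$included]
    excl <- table(onset$reason[!onset$included])
    n_excluded <- stats::setNames(as.integer(excl), names(excl))
  } else {
    days <- onset[!is.na(onset)]
    n_excluded <- c(pre_treatment = 0L, partial_date = 0L, missing_date = 0L)
  }
  breaks <- seq(0, 360, by = 30)
  labels <- c(paste0(breaks[-length(breaks)] + c(0, rep(1, length(breaks) - 2)),
                     "-", breaks[-1]), ">360")
  bins <- stats::setNames(integer(length(labels)), labels)
  if (length(days) > 0L) {
    idx <- pmin(pmax(ceiling(days / 30), 1L), length(labels)) # day 0 joins bin 1
    tb <- table(factor(labels[idx], levels = labels))
    bins <- stats::setNames(as.integer(tb), labels)
  }
  q <- if (length(days) > 0L) unname(stats::quantile(days, c(.25, .5, .75), type = 7)) else rep(NA_real_, 3)
  structure(list(
    n_included = length(days),
    n_excluded = n_excluded,
    mean_days = if (length(days)) mean(days) else NA_real_,
    median_days = q[2], q1 = q[1], q3 = q[3],
    bin_counts = bins,
    fraction_first_month = if (length(days)) mean(days <= 30) else NA_real_,
    fraction_over_one_year = if (length(days)) mean(days > 365) else NA_real_
  ), class = "onset_summary")
}

#' @export
print.onset_summary <- function(x, ...) {
  cat("Time-to-onset summary\n")
  cat(sprintf("  included reports : %d (excluded: %s)\n", x$n_included,
              if (sum(x$n_excluded) > 0)
                paste(names(x$n_excluded), x$n_excluded, sep = "=", collapse = ", ")
              else "none"))
  if (x$n_included > 0) {
    cat(sprintf("  mean %.1f d, median %.1f d, IQR %.2f-%.2f d\n",
                x$mean_days, x$median_days, x$q1, x$q3))
    cat(sprintf("  within first month (<=30 d): %.1f%%; beyond one year (>365 d): %.1f%%\n",
                100 * x$fraction_first_month, 100 * x$fraction_over_one_year))
  }
  invisible(x)
}

#' Onset summary as a plot-ready bin table
#' @param x an `"onset_summary"`.
#' @return data frame with `bin` and `count` columns.
#' @export
onset_bin_table <- function(x) {
  stopifnot(inherits(x, "onset_summary"))
  data.frame(bin = names(x$bin_counts), count = unname(x$bin_counts),
             stringsAsFactors = FALSE)
}
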