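#' Parse FAERS partial dates
#'
#' FAERS date fields (`FDA_DT`, `EVENT_DT`, `START_DT`, ...) carry dates at
#' day, month or year precision as 8-, 6- or 4-digit integers. Anything else
#' (including impossible calendar dates such as month 13 or February 30) is
#' treated as missing. The parser is total: it never errors, and it is
#' idempotent on its own rendered output (see [format_partial_date()]).
#'
#' Parsed dates are returned in a packed integer encoding `YYYYMMDD` where an
#' absent month or day is stored as `00`, so `202003` parses to `20200300`.
#' The packing sorts chronologically at equal precision and keeps lower
#' precision sorting below the same period's full dates, which is what the
#' case-level deduplication tie-break needs.
#'
#' @param x character or numeric vector of raw date fields.
#' @return integer vector of packed partial dates, `NA` where missing or
#'   unparseable, with attribute `n_invalid` counting non-empty inputs that
#'   failed to parse.
#' @seealso [format_partial_date()], [partial_date_precision()]
#' @export
#' @examples
#' parse_partial_date(c("20200315", "202003", "2020", "20201332", ""))
parse_partial_date <- function(x) {
  s <- trimws(as.character(x))
  s[is.na(s) | s == "" | toupper(s) == "NA"] <- NA_character_
  digits <- !is.na(s) & grepl("^[0-9]{4}([0-9]{2})?([0-9]{2})?$", s)
  out <- rep(NA_integer_, length(s))

  yr <- mo <- dy <- rep(NA_integer_, length(s))
  n8 <- digits & nchar(s) == 8L
  n6 <- digits & nchar(s) == 6L
  n4 <- digits & nchar(s) == 4L
  yr[digits] <- as.integer(substr(s[digits], 1L, 4L))
  mo[n6 | n8] <- as.integer(substr(s[n6 | n8], 5L, 6L))
  dy[n8] <- as.integer(substr(s[n8], 7L, 8L))

  ok <- digits & yr >= 1000L
  bad_mo <- !is.na(mo) & (mo < 1L | mo > 12L)
  ok <- ok & !bad_mo
  # day validity against the actual month length (leap years included)
  chk <- ok & !is.na(dy)
  if (any(chk)) {
    dlen <- .days_in_month(yr[chk], mo[chk])
    bad_dy <- dy[chk] < 1L | dy[chk] > dlen
    ok[chk][bad_dy] <- FALSE
  }

  out[ok] <- yr[ok] * 10000L +
    ifelse(is.na(mo[ok]), 0L, mo[ok]) * 100L +
    ifelse(is.na(dy[ok]), 0L, dy[ok])
  attr(out, "n_invalid") <- sum(!is.na(s) & is.na(out))
  out
}

.days_in_month <- function(year, month) {
  base <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  d <- base[month]
  leap <- (year %% 4L == 0L & year %% 100L != 0L) | year %% 400L == 0L
  d[month == 2L & leap] <- 29L
  d
}

#' Render a packed partial date back to its FAERS digit string
#'
#' @param pd packed partial-date integer vector from [parse_partial_date()].
#' @return character vector (`"YYYYMMDD"`, `"YYYYMM"` or `"YYYY"`), `NA` for
#'   missing.
#' @export
format_partial_date <- function(pd) {
  pd <- as.integer(pd)
  out <- rep(NA_character_, length(pd))
  i <- !is.na(pd)
  yr <- pd[i] %/% 10000L
  mo <- (pd[i] %/% 100L) %% 100L
  dy <- pd[i] %% 100L
  out[i] <- ifelse(dy > 0L, sprintf("%04d%02d%02d", yr, mo, dy),
            ifelse(mo > 0L, sprintf("%04d%02d", yr, mo),
                   sprintf("%04d", yr)))
  out
}

#' Precision of a packed partial date
#'
#' @param pd packed partial-date integer vector.
#' @return character vector in `{"day","month","year"}`, `NA` for missing.
#' @export
partial_date_precision <- function(pd) {
  pd <- as.integer(pd)
  out <- rep(NA_character_, length(pd))
  i <- !is.na(pd)
  mo <- (pd[i] %/% 100L) %% 100L
  dy <- pd[i] %% 100L
  out[i] <- ifelse(dy > 0L, "day", ifelse(mo > 0L, "month", "year"))
  out
}

#' Year component of a packed partial date
#' @param pd packed partial-date integer vector.
#' @return integer year, `NA` for missing.
#' @export
partial_date_year <- function(pd) {
  pd <- as.integer(pd)
  ifelse(is.na(pd), NA_integer_, pd %/% 10000L)
}

#' Convert full-precision packed dates to [Date]
#'
#' Only day-precision values convert; month- or year-precision values yield
#' `NA` (the package never imputes a day-of-month).
#'
#' @param pd packed partial-date integer vector.
#' @return a `Date` vector.
#' @export
partial_date_to_date <- function(pd) {
  pd <- as.integer(pd)
  full <- !is.na(pd) & pd %% 100L > 0L
  out <- rep(as.Date(NA), length(pd))
  out[full] <- as.Date(sprintf("%08d", pd[full]), format = "%Y%m%d")
  out
}

#' Pack a calendar date into the partial-date encoding
#' @param dates a `Date` vector.
#' @return packed partial-date integers at day precision.
#' @export
date_to_partial_date <- function(dates) {
  as.integer(format(dates, "%Y%m%d"))
}
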