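#' @keywords internal
#' Required and recognised columns per FAERS table kind. Column names are
#' matched case-insensitively; the aliases cover the common post-2004
#' quarterly header variants.
.faers_table_spec <- list(
  DEMO = list(required = c("primaryid", "caseid", "fda_dt"),
              aliases = c(sex = "gndr_cod", country = "occr_country",
                          country2 = "reporter_country",
                          reporter_occupation = "occp_cod")),
  DRUG = list(required = c("primaryid", "caseid", "drug_seq", "role_cod", "drugname"),
              aliases = c(role_cod = "role_code")),
  REAC = list(required = c("primaryid", "caseid", "pt"),
              aliases = character()),
  THER = list(required = c("primaryid", "caseid", "dsg_drug_seq", "start_dt"),
              aliases = character()),
  INDI = list(required = c("primaryid", "caseid", "indi_drug_seq", "indi_pt"),
              aliases = character()),
  OUTC = list(required = c("primaryid", "caseid", "outc_cod"),
              aliases = c(outc_cod = "outc_code"))
)

.occp_map <- c(MD = "physician", PH = "pharmacist",
               OT = "other health professional", HP = "other health professional",
               CN = "consumer/other", LW = "consumer/other")
.occp_unmap <- c("physician" = "MD", "pharmacist" = "PH",
                 "other health professional" = "OT", "consumer/other" = "CN")
.outcome_codes <- c("DE", "HO", "DS", "LT", "CA", "RI", "OT")

#' Read a FAERS-style quarterly ASCII table
#'
#' FAERS quarterly extracts distribute each table as `$`-delimited text with a
#' header row and no quoting. `read_faers_table()` parses one such file into a
#' typed data frame, tolerating missing and partial fields. Lines whose field
#' count does not match the header, or that fail a required-field rule (empty
#' drug name, empty PT, non-numeric identifier, unknown role or outcome code)
#' are skipped and counted, never silently dropped; a load report is attached
#' as the `"load_report"` attribute and retrievable with [load_report()].
#'
#' @param path path to the ASCII table file.
#' @param kind one of `"DEMO"`, `"DRUG"`, `"REAC"`, `"THER"`, `"INDI"`,
#'   `"OUTC"`.
#' @return a data frame with canonical lower-case columns for `kind`
#'   (dates packed as partial-date integers, see [parse_partial_date()]),
#'   and attribute `load_report`: a list with `lines_read`, `records_kept`,
#'   `records_skipped` and a named `reasons` count vector satisfying
#'   `lines_read == records_kept + records_skipped`.
#' @export
read_faers_table <- function(path, kind = c("DEMO", "DRUG", "REAC", "THER", "INDI", "OUTC")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file does not exist: ", path)
  spec <- .faers_table_spec[[kind]]

  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty file (no header row): ", path)
  header <- tolower(trimws(strsplit(lines[[1L]], "$", fixed = TRUE)[[1L]]))
  # fold aliases onto canonical names
  for (canon in names(spec$aliases)) {
    canon_name <- sub("[0-9]+$", "", canon)
    header[header == spec$aliases[[canon]]] <- canon_name
  }
  missing_cols <- setdiff(spec$required, header)
  if (length(missing_cols) > 0L)
    stop(sprintf("FAERS %s table %s is missing required column(s): %s",
                 kind, path, paste(missing_cols, collapse = ", ")))

  body <- lines[-1L]
  ncol_expected <- length(header)
  reasons <- integer()
  add_reason <- function(reasons, name, n) {
    if (n > 0L) reasons[name] <- (if (name %in% names(reasons)) reasons[[name]] else 0L) + n
    reasons
  }

  fields <- strsplit(body, "$", fixed = TRUE)
  # strsplit drops a trailing empty field; pad
  nf <- lengths(fields)
  trailing <- nf == ncol_expected - 1L & endsWith(body, "$")
  fields[trailing] <- lapply(fields[trailing], function(f) c(f, ""))
  nf[trailing] <- ncol_expected
  bad <- nf != ncol_expected
  reasons <- add_reason(reasons, "bad_field_count", sum(bad))
  fields <- fields[!bad]

  if (length(fields) > 0L) {
    mat <- matrix(trimws(unlist(fields, use.names = FALSE)),
                  ncol = ncol_expected, byrow = TRUE)
  } else {
    mat <- matrix(character(), ncol = ncol_expected)
  }
  colnames(mat) <- header
  col <- function(name) if (name %in% header) mat[, name] else rep(NA_character_, nrow(mat))
  blank_na <- function(x) { x[x == ""] <- NA_character_; x }

  primaryid <- suppressWarnings(as.numeric(col("primaryid")))
  caseid <- suppressWarnings(as.numeric(col("caseid")))
  keep <- !is.na(primaryid) & !is.na(caseid)
  reasons <- add_reason(reasons, "bad_identifier", sum(!keep))

  df <- switch(kind,
    DEMO = {
      fda_dt <- parse_partial_date(col("fda_dt"))
      event_dt <- parse_partial_date(col("event_dt"))
      sex <- toupper(col("sex"))
      sex[!(sex %in% c("F", "M"))] <- "UNK"
      age <- suppressWarnings(as.numeric(col("age")))
      age_cod <- toupper(blank_na(col("age_cod")))
      age_cod[!is.na(age_cod) & !(age_cod %in% c("DEC", "YR", "MON", "WK", "DY", "HR"))] <- NA_character_
      occ_raw <- toupper(blank_na(col("reporter_occupation")))
      occ <- unname(.occp_map[occ_raw])
      # accept already-mapped labels on re-read
      lab <- tolower(blank_na(col("reporter_occupation")))
      occ[is.na(occ) & lab %in% names(.occp_unmap)] <- lab[is.na(occ) & lab %in% names(.occp_unmap)]
      data.frame(primaryid = primaryid, caseid = caseid, fda_dt = as.integer(fda_dt),
                 event_dt = as.integer(event_dt), sex = sex, age = age,
                 age_cod = age_cod, reporter_occupation = occ,
                 country = toupper(blank_na(col("country"))),
                 report_year = partial_date_year(fda_dt),
                 stringsAsFactors = FALSE)
    },
    DRUG = {
      role <- toupper(blank_na(col("role_cod")))
      drugname <- blank_na(col("drugname"))
      ok <- !is.na(drugname) & role %in% c("PS", "SS", "C", "I")
      keep2 <- keep & ok
      reasons <- add_reason(reasons, "empty_drugname", sum(keep & is.na(drugname)))
      reasons <- add_reason(reasons, "bad_role_code",
                            sum(keep & !is.na(drugname) & !(role %in% c("PS", "SS", "C", "I"))))
      keep <- keep2
      data.frame(primaryid = primaryid, caseid = caseid,
                 drug_seq = suppressWarnings(as.integer(col("drug_seq"))),
                 role_cod = role, drugname = drugname,
                 prod_ai = blank_na(col("prod_ai")), stringsAsFactors = FALSE)
    },
    REAC = {
      pt <- blank_na(col("pt"))
      reasons <- add_reason(reasons, "empty_pt", sum(keep & is.na(pt)))
      keep <- keep & !is.na(pt)
      data.frame(primaryid = primaryid, caseid = caseid, pt = pt,
                 stringsAsFactors = FALSE)
    },
    THER = {
      start_dt <- parse_partial_date(col("start_dt"))
      end_dt <- parse_partial_date(col("end_dt"))
      full <- function(pd) !is.na(pd) & pd %% 100L > 0L
      inconsistent <- full(start_dt) & full(end_dt) & end_dt < start_dt
      data.frame(primaryid = primaryid, caseid = caseid,
                 dsg_drug_seq = suppressWarnings(as.integer(col("dsg_drug_seq"))),
                 start_dt = as.integer(start_dt), end_dt = as.integer(end_dt),
                 inconsistent = inconsistent, stringsAsFactors = FALSE)
    },
    INDI = {
      data.frame(primaryid = primaryid, caseid = caseid,
                 indi_drug_seq = suppressWarnings(as.integer(col("indi_drug_seq"))),
                 indi_pt = blank_na(col("indi_pt")), stringsAsFactors = FALSE)
    },
    OUTC = {
      outc <- toupper(blank_na(col("outc_cod")))
      reasons <- add_reason(reasons, "bad_outcome_code",
                            sum(keep & !(outc %in% .outcome_codes)))
      keep <- keep & outc %in% .outcome_codes
      data.frame(primaryid = primaryid, caseid = caseid, outc_cod = outc,
                 stringsAsFactors = FALSE)
    }
  )

  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "load_report") <- list(
    table = kind,
    lines_read = length(body),
    records_kept = nrow(df),
    records_skipped = length(body) - nrow(df),
    reasons = reasons
  )
  df
}

#' Retrieve the load report attached by [read_faers_table()]
#' @param x a data frame returned by [read_faers_table()].
#' @return the load-report list, or `NULL`.
#' @export
load_report <- function(x) attr(x, "load_report")

#' Write a canonical table back to the FAERS `$`-delimited dialect
#'
#' Inverse of [read_faers_table()]: packed partial dates are rendered back to
#' digit strings, reporter occupations back to FAERS `OCCP_COD` codes, and
#' missing values to empty fields, so that `read_faers_table()` on the output
#' reproduces the input values. Embedded `$` in free text is not supported by
#' the dialect; offending rows are dropped with a warning.
#'
#' @param df a canonical data frame (as returned by [read_faers_table()] or
#'   built by [generate_faers()]).
#' @param path output file path.
#' @param kind table kind, as in [read_faers_table()].
#' @return `path`, invisibly.
#' @export
write_faers_table <- function(df, path, kind = c("DEMO", "DRUG", "REAC", "THER", "INDI", "OUTC")) {
  kind <- match.arg(kind)
  out <- df
  for (dcol in intersect(c("fda_dt", "event_dt", "start_dt", "end_dt"), names(out)))
    out[[dcol]] <- format_partial_date(out[[dcol]])
  if (kind == "DEMO") {
    out$sex[out$sex == "UNK"] <- ""
    out$reporter_occupation <- unname(.occp_unmap[out$reporter_occupation])
    out$report_year <- NULL
  }
  if (kind == "THER") out$inconsistent <- NULL
  if ("primaryid" %in% names(out)) out$primaryid <- format(out$primaryid, scientific = FALSE, trim = TRUE)
  if ("caseid" %in% names(out)) out$caseid <- format(out$caseid, scientific = FALSE, trim = TRUE)
  header_names <- names(out)
  header_names[header_names == "reporter_occupation"] <- "occp_cod"
  header_names[header_names == "country"] <- "occr_country"

  cells <- vapply(out, function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    x
  }, character(nrow(out)))
  if (nrow(out) == 1L) cells <- matrix(cells, nrow = 1L)
  if (nrow(out) == 0L) cells <- matrix(character(), ncol = length(out))
  has_dollar <- if (nrow(out)) apply(cells, 1L, function(r) any(grepl("$", r, fixed = TRUE))) else logical()
  if (any(has_dollar)) {
    warning(sum(has_dollar), " row(s) with embedded '$' dropped from ", kind)
    cells <- cells[!has_dollar, , drop = FALSE]
  }
  lines <- c(paste(header_names, collapse = "$"),
             if (nrow(cells)) apply(cells, 1L, paste, collapse = "$"))
  writeLines(lines, path)
  invisible(path)
}

#' Normalise a MedDRA preferred-term string for joining
#'
#' Trims, collapses internal whitespace and case-folds. FAERS PT casing is
#' inconsistent across quarters, so all joins (vocabulary lookup, event-table
#' grouping, expected-PT comparison) go through this normal form while the
#' verbatim casing is kept for display.
#'
#' @param pt character vector of PT strings.
#' @return normalised character vector.
#' @export
normalize_pt <- function(pt) {
  tolower(gsub("[[:space:]]+", " ", trimws(pt)))
}

#' Read a PT to SOC vocabulary map
#'
#' The MedDRA dictionary is licensed and never bundled; the pipeline consumes
#' a user-supplied (or synthetic) two-column delimited map `pt<TAB>soc`.
#' Lookup is case-insensitive after whitespace normalisation.
#'
#' @param path path to the two-column tab-delimited file (a header row
#'   `pt<TAB>soc` is accepted and skipped).
#' @return named character vector: SOC strings named by normalised PT.
#' @export
read_vocabulary <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                          col.names = c("pt", "soc"), stringsAsFactors = FALSE)
  if (nrow(df) > 0L && normalize_pt(df$pt[1L]) == "pt") df <- df[-1L, , drop = FALSE]
  stats::setNames(df$soc, normalize_pt(df$pt))
}

#' Write a PT to SOC vocabulary map
#' @param vocab named character vector (SOC named by PT).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  writeLines(c("pt\tsoc", paste(names(vocab), vocab, sep = "\t")), path)
  invisible(path)
}

#' Read an FDA deleted-case list
#' @param path plain-text file, one CASEID per line (blank lines ignored).
#' @return numeric vector of case ids.
#' @export
read_deletion_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  as.numeric(x[x != ""])
}

#' Round half-up at a given number of decimals
#'
#' Display rounding convention of published signal tables (base R's `round()`
#' rounds half to even).
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

.signal_table_cols <- c("soc", "pt", "a", "b", "c", "d", "ror", "ror_low", "ror_high",
                        "prr", "chi2", "ic", "ic025", "ebgm", "ebgm05",
                        "ror_sig", "prr_sig", "bcpnn_sig", "mgps_sig", "all_four")

#' Write a signal table as delimited text
#'
#' Fixed column order (SOC, PT, fourfold counts, the four algorithms' point
#' estimates and interval bounds, per-algorithm flags), numbers at full
#' precision, plus a 2-decimal half-up `ror_display` column in the
#' `"estimate (low-high)"` style of published tables. Round-trips through
#' [read_signal_table()].
#'
#' @param df a signal data frame (e.g. `as.data.frame()` of a [disprop()]
#'   fit); extra columns such as `unintended` are kept after the fixed block.
#' @param path output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_signal_table <- function(df, path) {
  df <- as.data.frame(df)
  if (!"soc" %in% names(df)) df$soc <- NA_character_
  if (!"pt" %in% names(df) && "term" %in% names(df)) df$pt <- df$term
  missing_cols <- setdiff(.signal_table_cols, names(df))
  for (mc in missing_cols) df[[mc]] <- NA
  extra <- setdiff(names(df), c(.signal_table_cols, "term", "level", "n"))
  df$ror_display <- ifelse(is.na(df$ror), "",
    sprintf("%.2f (%.2f-%.2f)", round_half_up(df$ror), round_half_up(df$ror_low),
            round_half_up(df$ror_high)))
  out <- df[, c(.signal_table_cols, extra, "ror_display")]
  con <- tryCatch(file(path, "w"), error = function(e) stop("cannot write: ", path))
  on.exit(close(con))
  utils::write.table(format(out, digits = 15, scientific = FALSE, trim = TRUE, na.encode = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a signal table written by [write_signal_table()]
#' @param path path to the tab-delimited signal table.
#' @return a data frame.
#' @export
read_signal_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                          na.strings = "")
  for (lcol in intersect(c("ror_sig", "prr_sig", "bcpnn_sig", "mgps_sig", "all_four",
                           "unintended"), names(df)))
    df[[lcol]] <- as.logical(df[[lcol]])
  df
}
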