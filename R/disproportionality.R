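#' Signal statistics on fourfold tables
#'
#' Given the cells of one or more fourfold tables
#' \preformatted{
#'               target AE   other AE
#'  target drug      a           b
#'  other drugs      c           d
#' }
#' computes the four disproportionality algorithms in their simplified
#' (non-shrinkage) forms:
#' \itemize{
#'  \item ROR = ad/bc with 95% CI
#'    \eqn{\exp(\ln ROR \pm 1.96\sqrt{1/a+1/b+1/c+1/d})};
#'  \item PRR = a(c+d)/(c(a+b)) with the Pearson chi-squared
#'    \eqn{(ad-bc)^2 N / ((a+b)(c+d)(a+c)(b+d))}, no continuity correction;
#'  \item the BCPNN information component
#'    \eqn{IC = \log_2 (aN/((a+c)(a+b)))}; its lower bound IC025 is the
#'    log-normal lower bound of the base (observed/expected) quantity on the
#'    \eqn{\log_2} scale, so \eqn{IC025 > 0 \iff EBGM05 > 1};
#'  \item the MGPS \eqn{EBGM = aN/((a+c)(a+b))} with
#'    \eqn{EBGM05 = \exp(\ln EBGM - 1.96\sqrt{1/a+1/b+1/c+1/d})}.
#' }
#' IC and EBGM are the same base quantity on different scales, so
#' `ebgm == 2^ic` exactly wherever both are defined.
#'
#' A statistic whose formula divides by an empty cell or margin is undefined
#' and returned as `NA` (never silently coerced); the exception is `a = 0`
#' with non-empty margins, where IC is \eqn{-\infty} by convention. With
#' `zero_correction = TRUE` a Haldane-Anscombe +0.5 is added to every cell of
#' tables containing a zero before estimation.
#'
#' @param a,b,c,d non-negative integer vectors (recycled to common length).
#' @param zero_correction logical; apply +0.5 to all cells of zero-containing
#'   tables (default `FALSE`).
#' @return data frame with columns `a`, `b`, `c`, `d`, `n`, `ror`,
#'   `ror_low`, `ror_high`, `prr`, `chi2`, `ic`, `ic025`, `ebgm`, `ebgm05`.
#' @export
#' @examples
#' signal_metrics(10, 90, 100, 9900) # ror 11, prr 10, ebgm ~9.18
signal_metrics <- function(a, b, c, d, zero_correction = FALSE) {
  m <- cbind(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
             d = as.numeric(d)) # doubles: margin products overflow int range
  if (any(m < 0, na.rm = TRUE)) stop("negative cell count")
  a <- m[, "a"]; b <- m[, "b"]; c <- m[, "c"]; d <- m[, "d"]
  n_int <- a + b + c + d
  if (zero_correction) {
    z <- a == 0 | b == 0 | c == 0 | d == 0
    a <- a + 0.5 * z; b <- b + 0.5 * z; c <- c + 0.5 * z; d <- d + 0.5 * z
  }
  n <- a + b + c + d

  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d) # Inf when any cell 0
  all_pos <- a > 0 & b > 0 & c > 0 & d > 0

  ror <- ifelse(all_pos, (a * d) / (b * c), NA_real_)
  ror_low <- exp(log(ror) - 1.96 * se)
  ror_high <- exp(log(ror) + 1.96 * se)

  prr <- ifelse(c > 0 & (a + b) > 0, a * (c + d) / (c * (a + b)), NA_real_)
  margins_pos <- (a + b) > 0 & (c + d) > 0 & (a + c) > 0 & (b + d) > 0
  chi2 <- ifelse(margins_pos,
                 (a * d - b * c)^2 * n / ((a + b) * (c + d) * (a + c) * (b + d)),
                 NA_real_)

  oe_margins <- (a + b) > 0 & (a + c) > 0
  ebgm <- ifelse(oe_margins, a * n / ((a + c) * (a + b)), NA_real_)
  ic <- log2(ebgm) # -Inf at a = 0 with margins present
  ebgm05 <- ifelse(all_pos, exp(log(ebgm) - 1.96 * se), NA_real_)
  ic025 <- log2(ebgm05)

  data.frame(a = m[, "a"], b = m[, "b"], c = m[, "c"], d = m[, "d"], n = n_int,
             ror = ror, ror_low = ror_low, ror_high = ror_high,
             prr = prr, chi2 = chi2, ic = ic, ic025 = ic025,
             ebgm = ebgm, ebgm05 = ebgm05)
}

#' Apply the four algorithms' signal criteria
#'
#' Criteria: ROR lower 95% bound > 1 with a >= 3; PRR > 2 with chi-squared
#' > 4 and a > 3; IC025 > 0; EBGM05 > 2 with table total N > 0. `all_four`
#' is their conjunction. An undefined (`NA`) statistic never signals.
#'
#' @param metrics data frame from [signal_metrics()].
#' @return `metrics` with logical columns `ror_sig`, `prr_sig`, `bcpnn_sig`,
#'   `mgps_sig`, `all_four` appended.
#' @export
classify_signals <- function(metrics) {
  yes <- function(x) !is.na(x) & x
  metrics$ror_sig <- yes(metrics$ror_low > 1 & metrics$a >= 3)
  metrics$prr_sig <- yes(metrics$prr > 2 & metrics$chi2 > 4 & metrics$a > 3)
  metrics$bcpnn_sig <- yes(metrics$ic025 > 0)
  metrics$mgps_sig <- yes(metrics$ebgm05 > 2 & metrics$n > 0)
  metrics$all_four <- metrics$ror_sig & metrics$prr_sig & metrics$bcpnn_sig & metrics$mgps_sig
  metrics
}

#' Fourfold table for one term
#'
#' Counts distinct (report, PT) records into the fourfold table for one PT or
#' SOC: `a` target-drug records with the event, `b` target-drug records with
#' other events, `c`/`d` likewise for all other drugs.
#'
#' @param events event table from [build_event_table()].
#' @param term the PT or SOC value to tabulate.
#' @param level `"pt"` or `"soc"`.
#' @return named integer vector `c(a=, b=, c=, d=)`.
#' @export
build_contingency <- function(events, term, level = c("pt", "soc")) {
  level <- match.arg(level)
  val <- if (level == "pt") normalize_pt(events$pt) == normalize_pt(term)
         else events$soc == term
  a <- sum(events$is_target & val)
  b <- sum(events$is_target & !val)
  c <- sum(!events$is_target & val)
  d <- sum(!events$is_target & !val)
  c(a = a, b = b, c = c, d = d)
}

#' Fit the disproportionality battery over all terms
#'
#' The central estimator: batch-evaluates the four algorithms over every PT
#' (or SOC) in a drug-event record table, target drug against all other
#' drugs, and applies the signal criteria.
#'
#' @param events event table from [build_event_table()] (or a synthetic one):
#'   columns `primaryid`, `pt`, `soc`, `is_target`, one row per distinct
#'   (report, PT) record.
#' @param level aggregate at `"pt"` (default) or `"soc"` level.
#' @param min_count drop terms with `a + c` below this (default 1).
#' @param zero_correction passed to [signal_metrics()].
#' @return an object of class `"disprop"`: a data frame with one row per
#'   term, sorted by `a` descending (ties by term name), columns `term`,
#'   `soc` (PT level only), the fourfold counts, all statistics and flags;
#'   attributes `level`, `n_target`, `n_other`, `n_records`, `n_tests`.
#' @seealso [signal_metrics()], [classify_signals()], [stratified_signals()]
#' @export
disprop <- function(events, level = c("pt", "soc"), min_count = 1L,
                    zero_correction = FALSE) {
  level <- match.arg(level)
  stopifnot(nrow(events) > 0L)
  term <- if (level == "pt") events$pt else events$soc
  n_target <- sum(events$is_target)
  n_other <- sum(!events$is_target)

  tab <- table(term, factor(events$is_target, levels = c(FALSE, TRUE)))
  a <- as.integer(tab[, "TRUE"])
  c_ <- as.integer(tab[, "FALSE"])
  terms <- rownames(tab)
  keep <- (a + c_) >= min_count
  a <- a[keep]; c_ <- c_[keep]; terms <- terms[keep]

  met <- signal_metrics(a, n_target - a, c_, n_other - c_,
                        zero_correction = zero_correction)
  met <- classify_signals(met)
  out <- cbind(data.frame(term = terms, stringsAsFactors = FALSE), met)
  if (level == "pt") {
    soc_of <- events$soc[match(terms, events$pt)]
    out <- cbind(out[, "term", drop = FALSE], soc = soc_of,
                 out[, setdiff(names(out), "term")])
  }
  out <- out[order(-out$a, out$term), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("disprop", "data.frame"),
            level = level, n_target = n_target, n_other = n_other,
            n_records = nrow(events), n_tests = length(terms))
}

#' @export
print.disprop <- function(x, n = 10L, ...) {
  lv <- attr(x, "level")
  cat(sprintf("Disproportionality analysis at %s level\n", toupper(lv)))
  cat(sprintf("  records: %d target, %d other; %d terms tested (no multiplicity adjustment)\n",
              attr(x, "n_target"), attr(x, "n_other"), attr(x, "n_tests")))
  cat(sprintf("  signals meeting all four criteria: %d\n\n", sum(x$all_four)))
  top <- utils::head(as.data.frame(x), n)
  disp <- data.frame(
    term = top$term,
    a = top$a,
    `ROR (95% CI)` = ifelse(is.na(top$ror), "-",
      sprintf("%.2f (%.2f-%.2f)", round_half_up(top$ror),
              round_half_up(top$ror_low), round_half_up(top$ror_high))),
    `PRR (chi2)` = ifelse(is.na(top$prr), "-",
      sprintf("%.2f (%.2f)", round_half_up(top$prr), round_half_up(top$chi2))),
    `IC (IC025)` = ifelse(is.na(top$ic), "-",
      sprintf("%.2f (%.2f)", round_half_up(top$ic), round_half_up(top$ic025))),
    `EBGM (EBGM05)` = ifelse(is.na(top$ebgm), "-",
      sprintf("%.2f (%.2f)", round_half_up(top$ebgm), round_half_up(top$ebgm05))),
    all_four = top$all_four,
    check.names = FALSE)
  print(disp, row.names = FALSE)
  if (nrow(x) > n) cat(sprintf("  ... and %d more terms\n", nrow(x) - n))
  invisible(x)
}

#' @export
summary.disprop <- function(object, ...) {
  s <- list(level = attr(object, "level"),
            n_terms = nrow(object),
            n_records = attr(object, "n_records"),
            n_target = attr(object, "n_target"),
            n_other = attr(object, "n_other"),
            n_sig = c(ror = sum(object$ror_sig), prr = sum(object$prr_sig),
                      bcpnn = sum(object$bcpnn_sig), mgps = sum(object$mgps_sig),
                      all_four = sum(object$all_four)))
  class(s) <- "summary.disprop"
  s
}

#' @export
print.summary.disprop <- function(x, ...) {
  cat(sprintf("Disproportionality fit (%s level): %d terms on %d records\n",
              toupper(x$level), x$n_terms, x$n_records))
  cat(sprintf("  target records %d, comparator records %d\n", x$n_target, x$n_other))
  cat("  signals per algorithm:\n")
  cat(sprintf("    ROR %d | PRR %d | BCPNN %d | MGPS %d | all four %d\n",
              x$n_sig["ror"], x$n_sig["prr"], x$n_sig["bcpnn"], x$n_sig["mgps"],
              x$n_sig["all_four"]))
  invisible(x)
}

#' @export
as.data.frame.disprop <- function(x, ...) {
  class(x) <- "data.frame"
  attr(x, "level") <- attr(x, "n_target") <- attr(x, "n_other") <- NULL
  attr(x, "n_records") <- attr(x, "n_tests") <- NULL
  x
}

#' Forest-style plot of the strongest signals
#'
#' Draws ROR point estimates and 95% confidence intervals on a log axis for
#' the `n` most frequent terms with a defined ROR.
#'
#' @param x a `"disprop"` fit.
#' @param n number of terms to draw.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.disprop <- function(x, n = 20L, ...) {
  df <- as.data.frame(x)
  df <- df[!is.na(df$ror), , drop = FALSE]
  df <- utils::head(df, n)
  if (nrow(df) == 0L) {
    warning("no terms with a defined ROR to plot")
    return(invisible(x))
  }
  df <- df[rev(seq_len(nrow(df))), ]
  y <- seq_len(nrow(df))
  old <- graphics::par(mar = c(4, 12, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(df$ror, y, log = "x", pch = 16, yaxt = "n",
                 xlim = range(c(df$ror_low, df$ror_high, 1), finite = TRUE),
                 xlab = "ROR (log scale, 95% CI)", ylab = "",
                 main = sprintf("Top signals (%s level)", toupper(attr(x, "level"))), ...)
  graphics::segments(df$ror_low, y, df$ror_high, y)
  graphics::abline(v = 1, lty = 2, col = "grey50")
  graphics::axis(2, at = y, labels = df$term, las = 2, cex.axis = 0.7)
  invisible(x)
}
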