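test_that("onset is the calendar-day difference with the stated exclusions", {
  o <- compute_onset(
    event_dt = parse_partial_date(c("20200219", "20200201", "20200401", NA, "20200315")),
    start_dt = parse_partial_date(c("20200101", "20200301", "202003", "20200101", "20200315")))
  expect_equal(o$onset_days[1], 49L)
  expect_true(o$included[1])
  expect_equal(as.character(o$reason[2]), "pre_treatment")
  expect_equal(as.character(o$reason[3]), "partial_date")
  expect_equal(as.character(o$reason[4]), "missing_date")
  expect_equal(o$onset_days[5], 0L) # same-day onset included at 0 days
  # exclusion conservation
  expect_equal(sum(o$included) + sum(!o$included), nrow(o))
})

test_that("shifting both dates by k days leaves onset unchanged", {
  set.seed(8)
  start <- as.Date("2015-06-01") + sample(0:2000, 50, replace = TRUE)
  event <- start + sample(0:500, 50, replace = TRUE)
  for (k in c(-400, 17, 365)) {
    o1 <- compute_onset(date_to_partial_date(event), date_to_partial_date(start))
    o2 <- compute_onset(date_to_partial_date(event + k), date_to_partial_date(start + k))
    expect_equal(o1$onset_days, o2$onset_days)
  }
})

test_that("the onset summary reproduces the interpolated quartile fixture", {
  s <- summarize_onset(c(10, 49, 300))
  expect_equal(s$median_days, 49)
  expect_equal(s$q1, 29.5)
  expect_equal(s$q3, 174.5)
  expect_equal(s$n_included, 3L)
})

test_that("quantiles match an independent sorted-array oracle", {
  set.seed(99)
  for (n in c(4, 37, 1000)) {
    x <- sample(0:2000, n, replace = TRUE)
    s <- summarize_onset(x)
    expect_equal(s$q1, quantile_oracle(x, 0.25))
    expect_equal(s$median_days, quantile_oracle(x, 0.5))
    expect_equal(s$q3, quantile_oracle(x, 0.75))
    # order invariance
    s2 <- summarize_onset(rev(sort(x)))
    expect_equal(s2$median_days, s$median_days)
  }
})

test_that("bins and fractions partition the included records", {
  days <- c(0, 15, 30, 31, 60, 360, 361, 365, 366, 1000)
  s <- summarize_onset(days)
  expect_equal(sum(s$bin_counts), length(days))
  expect_equal(unname(s$bin_counts["0-30"]), 3L)
  expect_equal(unname(s$bin_counts["31-60"]), 2L)
  expect_equal(unname(s$bin_counts[">360"]), 4L) # 361, 365, 366, 1000
  expect_equal(s$fraction_first_month, 0.3)
  expect_equal(s$fraction_over_one_year, 0.2)   # 366 and 1000 only

  all_early <- summarize_onset(c(1, 5, 30))
  expect_equal(all_early$fraction_first_month, 1.0)
})

test_that("an empty record set yields an empty summary, not an error", {
  o <- compute_onset(integer(), integer())
  s <- summarize_onset(o)
  expect_equal(s$n_included, 0L)
  expect_true(is.na(s$median_days))
  expect_equal(sum(s$bin_counts), 0L)
})

test_that("cohort onset links therapy start through the suspect drug sequence", {
  cases <- data.frame(primaryid = c(1, 2, 3), caseid = c(1, 2, 3),
                      is_target = c(TRUE, TRUE, FALSE),
                      event_dt = c(20200219L, 20200510L, 20200101L),
                      sex = "F", stringsAsFactors = FALSE)
  drug <- data.frame(primaryid = c(1, 2, 3), caseid = c(1, 2, 3),
                     drug_seq = c(1L, 2L, 1L), role_cod = "PS",
                     drugname = c("DONEPEZIL", "DONEPEZIL", "OTHER"),
                     prod_ai = NA_character_, stringsAsFactors = FALSE)
  ther <- data.frame(primaryid = c(1, 1, 2), caseid = c(1, 1, 2),
                     dsg_drug_seq = c(1L, 1L, 2L),
                     # two therapy rows for report 1: the earliest full date wins
                     start_dt = c(20200101L, 20190601L, 20200501L),
                     end_dt = NA_integer_, stringsAsFactors = FALSE)
  o <- onset_for_cohort(ther, drug, cases, "donepezil")
  expect_equal(nrow(o), 2L) # target reports only
  expect_equal(o$onset_days[o$primaryid == 1], 263L) # from 2019-06-01
  expect_equal(o$onset_days[o$primaryid == 2], 9L)
})

test_that("a lognormal onset generator recovers its configured median", {
  # distribution check at the study's included-onset scale
  for (seed in 1:5) {
    set.seed(seed)
    x <- round(rlnorm(2782, meanlog = log(49), sdlog = 1.4))
    s <- summarize_onset(x)
    expect_true(abs(s$median_days - 49) / 49 < 0.10)
  }
})
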