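make_cases <- function(n, sex = "F", age = 70, country = "US", year = 2019,
                       reporter = "physician") {
  df <- data.frame(primaryid = seq_len(n), caseid = seq_len(n),
                   is_target = TRUE, sex = sex, age_years = age,
                   country = country, reporter_occupation = reporter,
                   report_year = year, event_dt = NA_integer_,
                   stringsAsFactors = FALSE)
  df$age_bin <- age_bin(df$age_years)
  df
}

test_that("sex and age blocks report counts and percentages of the cohort", {
  cases <- rbind(make_cases(2, sex = "F"), make_cases(2, sex = "M"))
  cs <- describe_cohort(cases)
  expect_equal(cs$n_cohort, 4L)
  expect_equal(cs$sex$n[cs$sex$category == "F"], 2L)
  expect_equal(cs$sex$pct[cs$sex$category == "F"], 50.0)

  cases2 <- make_cases(3, age = c(70, 80, 90))
  cs2 <- describe_cohort(cases2)
  expect_equal(cs2$age$n[cs2$age$category == "65-84"], 2L)
  expect_equal(cs2$age$n[cs2$age$category == ">=85"], 1L)
})

test_that("percentages are scale-invariant under cohort duplication", {
  set.seed(4)
  cases <- make_cases(40, sex = sample(c("F", "M", "UNK"), 40, replace = TRUE),
                      age = sample(c(30, 70, 90, NA), 40, replace = TRUE),
                      country = sample(c("US", "GB", "JP"), 40, replace = TRUE))
  doubled <- rbind(cases, transform(cases, primaryid = primaryid + 1000))
  c1 <- describe_cohort(cases)
  c2 <- describe_cohort(doubled)
  expect_equal(c1$sex$pct, c2$sex$pct)
  expect_equal(c1$age$pct, c2$age$pct)
  expect_equal(c2$sex$n, 2L * c1$sex$n)
})

test_that("yearly trend counts per group and scales the total", {
  cases <- rbind(make_cases(848, year = 2019, country = "US"),
                 make_cases(100, year = 2020, country = "GB"))
  tr <- yearly_trend(cases, groups = list(USA = "US", GBR = "GB"),
                     scale_factor = 0.25)
  expect_equal(tr$total[tr$year == 2019], 848L)
  expect_equal(tr$scaled_total[tr$year == 2019], 212.0)
  expect_equal(tr$USA[tr$year == 2019], 848L)
  expect_equal(tr$GBR[tr$year == 2019], 0L)

  single <- yearly_trend(make_cases(1, year = 2019), scale_factor = 1)
  expect_equal(single$total, 1L)
  # empty group gives an all-zero series
  tr0 <- yearly_trend(cases, groups = list(JPN = "JP"))
  expect_true(all(tr0$JPN == 0L))
})

test_that("stratified fourfold margins add up to the pooled table", {
  set.seed(17)
  n <- 400
  cases <- make_cases(n, sex = sample(c("F", "M", "UNK"), n, replace = TRUE,
                                      prob = c(.45, .45, .1)))
  cases$is_target <- rep(c(TRUE, FALSE), length.out = n)
  ev <- make_events(pid = rep(cases$primaryid, each = 2),
                    is_target = rep(cases$is_target, each = 2),
                    pt = sample(paste0("E", 1:6), 2 * n, replace = TRUE))
  ev <- ev[!duplicated(ev[c("primaryid", "pt")]), ]

  pooled <- disprop(ev)
  fem <- stratified_signals(ev, cases, "F", top_k = Inf)
  mal <- stratified_signals(ev, cases, "M", top_k = Inf)
  for (term in pooled$term) {
    a_f <- fem$a[fem$term == term]
    a_m <- mal$a[mal$term == term]
    a_u <- pooled$a[pooled$term == term] -
      (if (length(a_f)) a_f else 0L) - (if (length(a_m)) a_m else 0L)
    expect_gte(a_u, 0L) # unknown-sex remainder is never negative
  }
  # a PT present only in female reports has no male-stratum row
  ev_f <- ev[ev$primaryid %in% cases$primaryid[cases$sex == "F"], ]
  only_f <- setdiff(unique(ev_f$pt), ev$pt[ev$primaryid %in%
                                             cases$primaryid[cases$sex == "M"]])
  if (length(only_f) > 0) {
    expect_false(any(mal$term %in% only_f))
  }
  # empty stratum gives an empty result
  none <- stratified_signals(ev[0, ], cases, "F")
  expect_equal(nrow(none), 0L)
})
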