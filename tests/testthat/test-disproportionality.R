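test_that("point estimates match hand-evaluated values on the worked table", {
  m <- signal_metrics(10, 90, 100, 9900)
  expect_equal(m$ror, 11)                      # ad/bc = 99000/9000
  expect_equal(m$prr, 10)                      # a(c+d)/(c(a+b)) = 10*10000/(100*100)
  expect_equal(m$ebgm, 101000 / 11000)         # aN/((a+c)(a+b)) = 9.1818...
  expect_equal(m$ic, log2(101000 / 11000))     # 3.1989...
  se <- sqrt(1 / 10 + 1 / 90 + 1 / 100 + 1 / 9900)
  expect_equal(m$ror_low, 11 * exp(-1.96 * se))
  expect_equal(m$ror_high, 11 * exp(1.96 * se))
  expect_equal(m$ebgm05, m$ebgm * exp(-1.96 * se))
  # chi-squared agrees with the independent textbook implementation
  oracle <- suppressWarnings(
    stats::chisq.test(matrix(c(10, 90, 100, 9900), 2, byrow = TRUE),
                      correct = FALSE))
  expect_equal(m$chi2, unname(oracle$statistic))
})

test_that("independence tables give the null value for every statistic", {
  tb <- independence_tables(1000)
  m <- signal_metrics(tb$a, tb$b, tb$c, tb$d)
  expect_true(all(abs(m$ror - 1) < 1e-9))
  expect_true(all(abs(m$prr - 1) < 1e-9))
  expect_true(all(abs(m$ebgm - 1) < 1e-9))
  expect_true(all(abs(m$ic) < 1e-9))
  expect_true(all(abs(m$chi2) < 1e-9))
  # CIs straddle the null
  expect_true(all(m$ror_low < 1 & m$ror_high > 1))
  f <- classify_signals(m)
  expect_false(any(f$ror_sig | f$prr_sig | f$bcpnn_sig | f$mgps_sig | f$all_four))
})

test_that("EBGM is exactly 2^IC on every defined table", {
  tb <- random_tables(2000, seed = 5)
  m <- signal_metrics(tb$a, tb$b, tb$c, tb$d)
  expect_equal(m$ebgm, 2^m$ic, tolerance = 1e-12)
  expect_equal(m$ebgm05, 2^m$ic025, tolerance = 1e-12)
})

test_that("sign(ror - prr) equals sign(ror - 1) on random nondegenerate tables", {
  tb <- random_tables(10000, seed = 99)
  m <- signal_metrics(tb$a, tb$b, tb$c, tb$d)
  agree <- sign(m$ror - m$prr) == sign(m$ror - 1) |
    (abs(m$ror - m$prr) < 1e-12 & abs(m$ror - 1) < 1e-12)
  expect_true(all(agree))
})

test_that("chi-squared equals an independent Pearson implementation", {
  tb <- random_tables(10000, seed = 123)
  m <- signal_metrics(tb$a, tb$b, tb$c, tb$d)
  # independent route: expected counts under independence
  n <- tb$a + tb$b + tb$c + tb$d
  e_a <- (tb$a + tb$b) * (tb$a + tb$c) / n
  e_b <- (tb$a + tb$b) * (tb$b + tb$d) / n
  e_c <- (tb$c + tb$d) * (tb$a + tb$c) / n
  e_d <- (tb$c + tb$d) * (tb$b + tb$d) / n
  chi_oracle <- (tb$a - e_a)^2 / e_a + (tb$b - e_b)^2 / e_b +
    (tb$c - e_c)^2 / e_c + (tb$d - e_d)^2 / e_d
  expect_equal(m$chi2, chi_oracle, tolerance = 1e-9)
  # spot-check a few against stats::chisq.test as a second oracle
  for (i in c(1, 500, 10000)) {
    oracle_i <- suppressWarnings(
      stats::chisq.test(matrix(as.numeric(tb[i, ]), 2, byrow = TRUE),
                        correct = FALSE))
    expect_equal(m$chi2[i], unname(oracle_i$statistic), tolerance = 1e-9)
  }
})

test_that("all four statistics are strictly increasing in a at fixed b, c, d", {
  a <- 1:60
  m <- signal_metrics(a, 500, 300, 20000)
  expect_true(all(diff(m$ror) > 0))
  expect_true(all(diff(m$prr) > 0))
  expect_true(all(diff(m$ic) > 0))
  expect_true(all(diff(m$ebgm) > 0))
})

test_that("zero cells yield undefined markers, never silent numbers", {
  m <- signal_metrics(5, 0, 10, 100) # b = 0
  expect_true(is.na(m$ror))
  expect_true(is.na(m$ror_low))
  f <- classify_signals(m)
  expect_false(f$ror_sig)

  m0 <- signal_metrics(0, 50, 10, 100) # a = 0: IC -Inf convention
  expect_true(is.infinite(m0$ic) && m0$ic < 0)
  expect_false(classify_signals(m0)$bcpnn_sig)

  # Haldane-Anscombe correction makes the estimate finite
  mh <- signal_metrics(5, 0, 10, 100, zero_correction = TRUE)
  expect_false(is.na(mh$ror))
  expect_equal(mh$ror, (5.5 * 100.5) / (0.5 * 10.5))
})

test_that("signal criteria enforce the case-count thresholds", {
  # huge ror but a = 2: not a ROR signal
  f <- classify_signals(signal_metrics(2, 10, 1, 5000))
  expect_false(f$ror_sig)
  # prr criterion needs a > 3: a = 3 fails even with prr >> 2
  f3 <- classify_signals(signal_metrics(3, 10, 1, 5000))
  expect_false(f3$prr_sig)
  # a bradycardia-like table clears every bound
  f739 <- classify_signals(signal_metrics(739, 25381, 1200, 1400000))
  expect_true(f739$ror_sig && f739$prr_sig && f739$bcpnn_sig && f739$mgps_sig)
  expect_true(f739$all_four)
})

test_that("batch evaluation equals per-table scalar evaluation", {
  set.seed(21)
  ev <- make_events(pid = rep(1:40, each = 3),
                    is_target = rep(rep(c(TRUE, FALSE), 20), each = 3),
                    pt = sample(c("X", "Y", "Z"), 120, replace = TRUE))
  ev <- ev[!duplicated(ev[c("primaryid", "pt")]), ]
  fit <- disprop(ev)
  for (term in fit$term) {
    tb <- build_contingency(ev, term, "pt")
    ms <- signal_metrics(tb["a"], tb["b"], tb["c"], tb["d"])
    row <- fit[fit$term == term, ]
    expect_equal(row$a, unname(tb["a"]))
    expect_equal(row$ror, ms$ror)
    expect_equal(row$chi2, ms$chi2)
    expect_equal(row$ic, ms$ic)
  }
  # margins: every row's fourfold total is the record count
  expect_true(all(fit$n == nrow(ev)))
})

test_that("SOC-level aggregation counts records whose SOC matches", {
  ev <- make_events(pid = c(1, 1, 2, 3, 4),
                    is_target = c(TRUE, TRUE, TRUE, FALSE, FALSE),
                    pt = c("P1", "P2", "P3", "P1", "P4"),
                    soc = c("S1", "S2", "S1", "S1", "S2"))
  fit <- disprop(ev, level = "soc")
  s1 <- fit[fit$term == "S1", ]
  expect_equal(s1$a, 2) # target records in S1: (1,P1), (2,P3)
  expect_equal(s1$c, 1)
  tb <- build_contingency(ev, "S1", "soc")
  expect_equal(unname(tb), c(2, 1, 1, 1))
})

test_that("degenerate one-sided event tables are flagged, not crashed", {
  ev <- make_events(pid = 1:3, is_target = rep(TRUE, 3), pt = rep("X", 3))
  fit <- disprop(ev)
  expect_true(is.na(fit$ror))
  expect_false(fit$all_four)
})
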