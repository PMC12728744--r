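test_that("identical seed and config produce byte-identical extracts", {
  cfg <- faers_preset("minimal")
  d1 <- tempfile(); d2 <- tempfile()
  write_faers_bundle(generate_faers(cfg), d1)
  write_faers_bundle(generate_faers(cfg), d2)
  for (f in list.files(d1)) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  # a different seed changes the data
  cfg2 <- faers_preset("minimal"); cfg2$seed <- 2L
  b2 <- generate_faers(cfg2)
  expect_false(identical(generate_faers(cfg)$tables$demo, b2$tables$demo))
})

test_that("without duplicates or deletions, deduplication is the identity", {
  b <- generate_faers(faers_preset("minimal"))
  dd <- deduplicate_reports(b$tables$demo)
  expect_equal(dd$removed_as_duplicate, 0L)
  expect_equal(sort(retained_primaryids(dd)), sort(b$tables$demo$primaryid))
})

test_that("duplicate versions carry later dates and the max-rule survivor wins", {
  cfg <- generator_config(seed = 3L, n_reports = 400L, duplicate_rate = 0.3,
                          dup_tie_frac = 0.3, deletion_rate = 0)
  b <- generate_faers(cfg)
  demo <- b$tables$demo
  expect_gt(nrow(demo), 400L)
  expect_false(anyDuplicated(demo$primaryid) > 0)

  dd <- deduplicate_reports(demo)
  surv <- b$truth$duplicate_survivors
  got <- dd$retained$primaryid[match(surv$caseid, dd$retained$caseid)]
  expect_equal(got, surv$retained_primaryid)
  # non-surviving versions are exactly the removed ones
  expect_equal(dd$removed_as_duplicate, length(b$truth$duplicate_primaryids))
  # duplicated cases re-emit their reaction rows under every version
  dup_pid <- b$truth$duplicate_primaryids[1]
  case_of <- demo$caseid[demo$primaryid == dup_pid]
  versions <- demo$primaryid[demo$caseid == case_of]
  pts_by_ver <- lapply(versions, function(p) sort(b$tables$reac$pt[b$tables$reac$primaryid == p]))
  expect_true(all(vapply(pts_by_ver, identical, logical(1), pts_by_ver[[1]])))
})

test_that("the deletion list removes whole cases from the retained set", {
  cfg <- generator_config(seed = 5L, n_reports = 500L, deletion_rate = 0.1,
                          duplicate_rate = 0)
  b <- generate_faers(cfg)
  expect_gt(length(b$deleted_caseids), 0L)
  dd <- apply_deletions(deduplicate_reports(b$tables$demo), b$deleted_caseids)
  expect_false(any(dd$retained$caseid %in% b$deleted_caseids))
  expect_equal(dd$removed_as_deleted, length(b$deleted_caseids))
})

test_that("config validation rejects inconsistent lexicons and bad values", {
  expect_error(generator_config(signals = data.frame(pt = "Nonexistent",
                                                     odds_multiplier = 2,
                                                     sex = NA_character_)),
               "unknown PT")
  expect_error(generator_config(p_target = 1.5), "\\[0, 1\\]")
  pts <- data.frame(pt = c("A", "B"), soc = "S", weight = c(1, 1))
  expect_error(generator_config(pts = pts,
                                signals = data.frame(pt = "A", odds_multiplier = -1,
                                                     sex = NA_character_)),
               "> 0")
  expect_error(faers_preset("bogus"), "minimal")
})

test_that("the synthetic vocabulary is total over every emitted PT", {
  b <- generate_faers(faers_preset("minimal"))
  expect_true(all(normalize_pt(b$tables$reac$pt) %in% names(b$vocab)))
})

test_that("an injected reporting-odds signal is recovered near its multiplier", {
  fit <- fit_bundle(generate_faers(recovery_config(401L)))
  row <- fit[fit$term == "Target event", ]
  truth <- generate_faers(recovery_config(401L))$truth$signals
  expect_gt(row$a, 25) # expected target-side count is ~47
  expect_true(abs(truth$expected_a - 47) < 8)
  # the CI is wide at this scale; the point estimate should land within it
  expect_true(row$ror_low < 11 && 11 < row$ror_high)
  expect_true(row$all_four)
})

test_that("the sex-specific preset injects in the female stratum only", {
  cfg <- faers_preset("sex_specific_signal")
  expect_equal(cfg$signals$sex, "F")
  b <- generate_faers(cfg)
  dd <- deduplicate_reports(b$tables$demo)
  retained <- retained_primaryids(dd)
  targets <- select_target_reports(b$tables$drug, retained, "donepezil")
  events <- build_event_table(b$tables$reac, retained, targets, b$vocab)
  cases <- build_report_cases(dd$retained, targets)
  fem <- stratified_signals(events, cases, "F", top_k = Inf)
  mal <- stratified_signals(events, cases, "M", top_k = Inf)
  a_f <- fem$a[fem$term == "Torsade de pointes"]
  a_m <- mal$a[mal$term == "Torsade de pointes"]
  expect_gt(a_f, 3 * max(a_m, 1))
})

test_that("paper_like marginals approximate the configured study population", {
  cfg <- faers_preset("paper_like")
  cfg$n_reports <- 12000L # scaled-down draw of the same population
  b <- generate_faers(cfg)
  demo1 <- b$tables$demo[!duplicated(b$tables$demo$caseid), ]
  expect_true(abs(mean(demo1$sex == "F") - 0.513) < 0.02)
  yrs <- age_to_years(demo1$age, demo1$age_cod)
  bins <- table(age_bin(as.numeric(yrs)))
  expect_true(abs(bins[["65-84"]] / nrow(demo1) - 0.506) < 0.02)
  expect_true(abs(mean(demo1$country == "US", na.rm = TRUE) - 0.274 / 0.923) < 0.03)
})
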