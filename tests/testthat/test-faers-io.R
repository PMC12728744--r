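test_that("DEMO parsing maps fields and missing sentinels", {
  demo <- read_faers_table(tiny_demo_file(), "DEMO")
  expect_equal(nrow(demo), 2L)
  expect_equal(demo$sex, c("F", "M"))
  expect_equal(demo$fda_dt, c(20200315L, 20200316L))
  expect_equal(demo$reporter_occupation, c("physician", NA))
  expect_true(is.na(demo$age[2]))
  expect_equal(demo$report_year, c(2020L, 2020L))

  # empty sex field maps to the UNK sentinel
  f <- write_dollar_file(tempfile(), "primaryid$caseid$fda_dt$sex",
                         "1$10$20200101$")
  expect_equal(read_faers_table(f, "DEMO")$sex, "UNK")
})

test_that("DRUG parsing keeps the role enum and drops empty drug names", {
  f <- write_dollar_file(tempfile(),
    "primaryid$caseid$drug_seq$role_cod$drugname$prod_ai",
    c("1$10$1$PS$DONEPEZIL HYDROCHLORIDE$DONEPEZIL HYDROCHLORIDE",
      "2$11$1$SS$MEMANTINE$MEMANTINE HCL",
      "3$12$1$PS$$",              # empty drugname: dropped, counted
      "4$13$1$XX$ASPIRIN$ASPIRIN" # unknown role: dropped, counted
    ))
  drug <- read_faers_table(f, "DRUG")
  expect_equal(drug$role_cod, c("PS", "SS"))
  rep <- load_report(drug)
  expect_equal(rep$records_skipped, 2L)
  expect_equal(unname(rep$reasons["empty_drugname"]), 1L)
})

test_that("malformed lines are skipped and counted, never silently dropped", {
  f <- write_dollar_file(tempfile(), "primaryid$caseid$pt",
    c("1$10$Nausea",
      "2$11$Fall$extra$fields",   # wrong field count
      "3$12$",                    # empty PT
      "4$13$Vomiting"))
  reac <- read_faers_table(f, "REAC")
  rep <- load_report(reac)
  expect_equal(rep$lines_read, 4L)
  expect_equal(rep$records_kept, 2L)
  expect_equal(rep$records_kept + rep$records_skipped, rep$lines_read)
})

test_that("a missing required key column is a fatal, named format error", {
  f <- write_dollar_file(tempfile(), "primaryid$pt", "1$Nausea")
  expect_error(read_faers_table(f, "REAC"), "caseid")
})

test_that("write/read round-trips every synthetic table", {
  b <- generate_faers(faers_preset("minimal"))
  dir <- tempfile(); dir.create(dir)
  write_faers_bundle(b, dir)
  back <- read_faers_bundle(dir)
  for (nm in names(b$tables)) {
    got <- back$tables[[nm]]
    attr(got, "load_report") <- NULL
    want <- b$tables[[nm]]
    rownames(want) <- rownames(got) <- NULL
    expect_equal(got, want, ignore_attr = TRUE, info = nm)
  }
  expect_equal(back$vocab, b$vocab)
})

test_that("THER rows with end before start are kept but flagged", {
  f <- write_dollar_file(tempfile(),
    "primaryid$caseid$dsg_drug_seq$start_dt$end_dt",
    c("1$10$1$20200301$20200101", "2$11$1$20200101$20200301"))
  ther <- read_faers_table(f, "THER")
  expect_equal(nrow(ther), 2L)
  expect_equal(ther$inconsistent, c(TRUE, FALSE))
})

test_that("signal table writing is round-trippable with a 2-decimal display", {
  rows <- data.frame(term = c("Pleurothotonus", "Fall"),
                     soc = c("Nervous system disorders", "Injury"),
                     a = c(118, 491), b = c(1, 2), c = c(3, 4), d = c(5, 6),
                     ror = c(332.558, 3.444), ror_low = c(273.726, 3.151),
                     ror_high = c(404.017, 3.762),
                     prr = c(331.06, 3.39), chi2 = c(33489.62, 832.38),
                     ic = c(8.16, 1.76), ic025 = c(7.88, 1.63),
                     ebgm = c(285.67, 3.39), ebgm05 = c(242.73, 3.15),
                     ror_sig = c(TRUE, TRUE), prr_sig = c(TRUE, TRUE),
                     bcpnn_sig = c(TRUE, TRUE), mgps_sig = c(TRUE, TRUE),
                     all_four = c(TRUE, TRUE), stringsAsFactors = FALSE)
  rows$pt <- rows$term
  p <- tempfile(fileext = ".tsv")
  write_signal_table(rows, p)
  back <- read_signal_table(p)
  expect_equal(back$ror, rows$ror, tolerance = 1e-12)
  expect_equal(back$ror_display[1], "332.56 (273.73-404.02)")
  expect_equal(back$all_four, rows$all_four)

  # empty input gives a header-only file
  p2 <- tempfile(fileext = ".tsv")
  write_signal_table(rows[0, ], p2)
  expect_equal(length(readLines(p2)), 1L)
})

test_that("vocabulary lookup is case-insensitive after whitespace squeeze", {
  p <- tempfile()
  writeLines(c("pt\tsoc", "Nausea\tGastrointestinal disorders",
               "Torsade  de Pointes\tCardiac disorders"), p)
  v <- read_vocabulary(p)
  expect_equal(unname(v[normalize_pt("NAUSEA ")]), "Gastrointestinal disorders")
  expect_equal(unname(v[normalize_pt("torsade de pointes")]), "Cardiac disorders")
})

test_that("display rounding is half-up, not banker's", {
  expect_equal(round_half_up(332.555, 2), 332.56)
  expect_equal(round_half_up(2.265, 2), 2.27)
  expect_equal(round_half_up(-1.005, 2), -1.01)
})
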