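# Shared fixtures: everything is built in code at test time.

# Write a `$`-delimited table file from a header and row vectors.
write_dollar_file <- function(path, header, rows) {
  writeLines(c(header, rows), path)
  path
}

# A tiny two-report DEMO file.
tiny_demo_file <- function(path = tempfile(fileext = ".txt")) {
  write_dollar_file(path,
    "primaryid$caseid$fda_dt$event_dt$sex$age$age_cod$occp_cod$occr_country",
    c("1001$500$20200315$20200301$F$70$YR$MD$US",
      "1002$501$20200316$$M$$$$"))
}

# Random fourfold tables with all cells >= 1 (nondegenerate).
random_tables <- function(n, max_cell = 500L, seed = 42L) {
  set.seed(seed)
  data.frame(a = sample.int(max_cell, n, replace = TRUE),
             b = sample.int(max_cell, n, replace = TRUE),
             c = sample.int(max_cell, n, replace = TRUE),
             d = sample.int(max_cell, n, replace = TRUE))
}

# Tables satisfying exact row-proportion independence a/(a+b) = c/(c+d):
# (a, b) scaled by an integer factor t gives (c, d).
independence_tables <- function(n, seed = 7L) {
  set.seed(seed)
  a <- sample.int(200L, n, replace = TRUE)
  b <- sample.int(200L, n, replace = TRUE)
  t <- sample.int(20L, n, replace = TRUE)
  data.frame(a = a, b = b, c = a * t, d = b * t)
}

# Brute-force deduplication oracle: per caseid, scan for the max under
# (fda_dt, primaryid) lexicographic order, missing dates lowest.
dedup_oracle <- function(demo) {
  pick <- function(df) {
    key <- ifelse(is.na(df$fda_dt), -1, as.numeric(df$fda_dt))
    best <- 1L
    for (i in seq_len(nrow(df))[-1]) {
      if (key[i] > key[best] ||
          (key[i] == key[best] && df$primaryid[i] > df$primaryid[best]))
        best <- i
    }
    df$primaryid[best]
  }
  vapply(split(demo, demo$caseid), pick, numeric(1), USE.NAMES = FALSE)
}

# Independent quantile oracle: linear interpolation between order statistics
# at h = (n-1)p + 1, written directly from the definition.
quantile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# An event table from explicit (report, target?, pt) triples.
make_events <- function(pid, is_target, pt, soc = NULL) {
  if (is.null(soc)) soc <- paste0("SOC_", toupper(substr(pt, 1, 1)))
  data.frame(primaryid = pid, pt = pt, soc = soc, is_target = is_target,
             stringsAsFactors = FALSE)
}

# Generator config used for signal-recovery checks: one injected signal at
# odds x11 with expected target-side count near 50.
recovery_config <- function(seed) {
  pts <- data.frame(
    pt = c("Target event", paste0("Background event ", sprintf("%02d", 1:99))),
    soc = rep(paste("Synthetic SOC", LETTERS[1:5]), each = 20),
    weight = c(0.003, rep(0.997 / 99, 99)),
    stringsAsFactors = FALSE)
  generator_config(
    seed = seed, n_reports = 5000L, p_target = 0.1,
    pts = pts,
    signals = data.frame(pt = "Target event", odds_multiplier = 11,
                         sex = NA_character_, stringsAsFactors = FALSE),
    pts_per_report = c(mean = 3, dispersion = 2),
    duplicate_rate = 0, deletion_rate = 0,
    p_event_missing = 0, p_event_partial = 0,
    p_start_missing = 0, p_start_partial = 0, p_pre_treatment = 0)
}

# Null config (no injected signals) for calibration checks.
null_config <- function(seed, n_reports = 2000L, n_pts = 50L) {
  pts <- data.frame(
    pt = paste0("Background event ", sprintf("%02d", seq_len(n_pts))),
    soc = rep(paste("Synthetic SOC", LETTERS[1:5]), length.out = n_pts),
    weight = 1 / seq_len(n_pts),
    stringsAsFactors = FALSE)
  generator_config(
    seed = seed, n_reports = n_reports, p_target = 0.1, pts = pts,
    pts_per_report = c(mean = 3, dispersion = 2),
    duplicate_rate = 0, deletion_rate = 0,
    p_event_missing = 0, p_event_partial = 0,
    p_start_missing = 0, p_start_partial = 0, p_pre_treatment = 0)
}

# Run the analysis chain on an in-memory bundle and return the PT-level fit.
fit_bundle <- function(bundle, keywords = "donepezil") {
  dd <- deduplicate_reports(bundle$tables$demo)
  dd <- apply_deletions(dd, bundle$deleted_caseids)
  retained <- retained_primaryids(dd)
  targets <- select_target_reports(bundle$tables$drug, retained, keywords)
  events <- build_event_table(bundle$tables$reac, retained, targets, bundle$vocab)
  disprop(events, level = "pt")
}
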