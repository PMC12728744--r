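#' Pipeline configuration
#'
#' A single declarative configuration naming the input files and the
#' analysis choices. Can be built in R or loaded from a YAML file with
#' [read_pipeline_config()]; it round-trips losslessly through YAML.
#'
#' @param input_dir directory holding `DEMO.txt` ... `OUTC.txt` and
#'   `vocab.tsv` (e.g. written by [write_faers_bundle()]).
#' @param output_dir where result tables are written.
#' @param keywords target-drug keywords for [match_drug()].
#' @param role suspect-role filter (default `"PS"`).
#' @param deletion_list optional path to a deleted-case list; `NULL` skips
#'   the deletion step with a logged notice.
#' @param expected_pts optional character vector (or path to a one-PT-per-line
#'   file) of PTs listed in the drug's prescribing information; when given,
#'   signal tables gain an `unintended` column.
#' @param zero_correction Haldane-Anscombe +0.5 on zero cells (default
#'   `FALSE`).
#' @param top_k top-k for descriptive blocks and stratified tables.
#' @param trend_groups named list of country-code groups for [yearly_trend()].
#' @param trend_scale scale factor for the total trend series.
#' @param log_level `"info"` or `"quiet"`.
#' @return object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input_dir, output_dir,
                            keywords = "donepezil", role = "PS",
                            deletion_list = NULL, expected_pts = NULL,
                            zero_correction = FALSE, top_k = 30L,
                            trend_groups = list(USA = "US", GBR = "GB"),
                            trend_scale = 0.25, log_level = "info") {
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 keywords = keywords, role = role,
                 deletion_list = deletion_list, expected_pts = expected_pts,
                 zero_correction = zero_correction, top_k = as.integer(top_k),
                 trend_groups = trend_groups, trend_scale = trend_scale,
                 log_level = log_level),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @return a `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x)
}

#' @rdname read_pipeline_config
#' @param config a `"pipeline_config"`.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Flag unintended (off-label-information) adverse events
#'
#' A PT is unintended when it does not appear in the expected-PT list from
#' the drug's prescribing information (normalised comparison). With an empty
#' expected list every PT is unintended.
#'
#' @param signal_rows data frame with a `pt` (or `term`) column.
#' @param expected_pts character vector of expected PT strings.
#' @return `signal_rows` with a logical `unintended` column.
#' @export
flag_unintended <- function(signal_rows, expected_pts) {
  pt <- if ("pt" %in% names(signal_rows)) signal_rows$pt else signal_rows$term
  signal_rows$unintended <- !(normalize_pt(pt) %in% normalize_pt(expected_pts))
  signal_rows
}

#' Run the full signal-detection pipeline
#'
#' Executes read, deduplication, target-cohort extraction, event-table
#' construction, SOC- and PT-level disproportionality with signal
#' classification, time-to-onset, descriptive characterisation, yearly
#' trend and sex-stratified signals, writing every output table plus a run
#' manifest with the case-funnel counts. Any fatal stage error removes
#' partial outputs before rethrowing.
#'
#' @param config a `"pipeline_config"`.
#' @return (invisibly) a list with the in-memory results: `dedup`, `cases`,
#'   `events`, `fit_pt`, `fit_soc`, `onset`, `cohort`, `trend`, `strata`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (config$log_level != "quiet") message(sprintf(...))
  outdir <- config$output_dir
  fresh <- !dir.exists(outdir)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  ok <- FALSE
  on.exit(if (!ok) unlink(written))

  res <- tryCatch({
    stage <- "read"
    bundle <- read_faers_bundle(config$input_dir)
    tb <- bundle$tables
    n_raw <- nrow(tb$demo)
    say("read: %d report versions, %d drug rows, %d reaction rows",
        n_raw, nrow(tb$drug), nrow(tb$reac))

    stage <- "deduplicate"
    dd <- deduplicate_reports(tb$demo)
    if (!is.null(config$deletion_list) && file.exists(config$deletion_list)) {
      dd <- apply_deletions(dd, read_deletion_list(config$deletion_list))
    } else if (length(bundle$deleted_caseids) > 0L) {
      dd <- apply_deletions(dd, bundle$deleted_caseids)
    } else {
      say("deduplicate: no deletion list supplied; deletion step skipped")
    }
    retained <- retained_primaryids(dd)
    say("deduplicate: %d retained, %d duplicates removed, %d deleted",
        length(retained), dd$removed_as_duplicate, dd$removed_as_deleted)

    stage <- "cohort"
    targets <- select_target_reports(tb$drug, retained, config$keywords, config$role)
    cases <- build_report_cases(dd$retained, targets, outc = tb$outc, indi = tb$indi)
    say("cohort: %d target reports (keywords: %s, role %s)",
        length(targets), paste(config$keywords, collapse = ", "), config$role)

    stage <- "events"
    events <- build_event_table(tb$reac, retained, targets, bundle$vocab)
    say("events: %d distinct (report, PT) records (%d target)",
        nrow(events), sum(events$is_target))

    stage <- "signals"
    fit_pt <- disprop(events, level = "pt", zero_correction = config$zero_correction)
    fit_soc <- disprop(events, level = "soc", zero_correction = config$zero_correction)
    pt_df <- as.data.frame(fit_pt)
    if (!is.null(config$expected_pts)) {
      expected <- config$expected_pts
      if (length(expected) == 1L && file.exists(expected))
        expected <- readLines(expected, warn = FALSE)
      pt_df <- flag_unintended(pt_df, expected)
    }
    pt_df$pt <- pt_df$term
    soc_df <- as.data.frame(fit_soc)
    soc_df$soc <- soc_df$term

    stage <- "onset"
    onset <- onset_for_cohort(tb$ther, tb$drug, cases, config$keywords, config$role)
    osum <- summarize_onset(onset)

    stage <- "descriptive"
    cohort <- describe_cohort(cases[cases$is_target, , drop = FALSE],
                              top_k = min(config$top_k, 5L))
    trend <- yearly_trend(cases[cases$is_target, , drop = FALSE],
                          groups = config$trend_groups,
                          scale_factor = config$trend_scale)

    stage <- "subgroup"
    strata <- rbind(
      stratified_signals(events, cases, "F", top_k = config$top_k),
      stratified_signals(events, cases, "M", top_k = config$top_k))

    stage <- "write"
    wfile <- function(fn) { p <- file.path(outdir, fn); written <<- c(written, p); p }
    write_signal_table(pt_df, wfile("signals_pt.tsv"))
    write_signal_table(soc_df, wfile("signals_soc.tsv"))
    if (nrow(strata) > 0L) {
      strata_out <- strata; strata_out$pt <- strata_out$term
      write_signal_table(strata_out, wfile("signals_by_sex.tsv"))
    }
    utils::write.table(onset_bin_table(osum), wfile("onset_bins.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(unclass(osum), wfile("onset_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(unclass(cohort), wfile("cohort_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.table(trend, wfile("yearly_trend.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    manifest <- list(
      config = unclass(config),
      inputs = as.list(tools::md5sum(list.files(config$input_dir,
                                                full.names = TRUE))),
      funnel = list(report_versions = n_raw,
                    retained_cases = length(retained),
                    removed_as_duplicate = dd$removed_as_duplicate,
                    removed_as_deleted = dd$removed_as_deleted,
                    target_reports = length(targets),
                    event_records = nrow(events),
                    target_event_records = sum(events$is_target),
                    onset_included = osum$n_included,
                    onset_excluded = as.list(osum$n_excluded)),
      n_tests = list(pt = attr(fit_pt, "n_tests"), soc = attr(fit_soc, "n_tests")),
      r_version = as.character(getRversion()))
    jsonlite::write_json(manifest, wfile("manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    say("signals: %d PT terms (%d all-four), %d SOC terms (%d all-four)",
        nrow(pt_df), sum(pt_df$all_four), nrow(soc_df), sum(soc_df$all_four))
    ok <- TRUE
    list(dedup = dd, cases = cases, events = events, fit_pt = fit_pt,
         fit_soc = fit_soc, onset = onset, onset_summary = osum,
         cohort = cohort, trend = trend, strata = strata, manifest = manifest)
  }, error = function(e) {
    unlink(written)
    if (fresh) unlink(outdir, recursive = TRUE)
    stop(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(res)
}
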