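#' Configuration for the synthetic FAERS generator
#'
#' Full specification of a synthetic quarterly extract: cohort size and
#' target-drug share, drug and PT lexicons with a PT-to-SOC vocabulary,
#' the per-report PT-count distribution, injected drug-event signals as
#' reporting-odds multipliers, demographics, dates, the onset model,
#' duplicate/deletion mechanics and per-field missingness. Identical
#' `(seed, config)` pairs generate byte-identical extracts.
#'
#' Signal injection acts on the per-record reporting odds: for an injected
#' PT `s` with multiplier `m`, the target group's per-record probability
#' `q_s` solves `q_s/(1-q_s) = m * w_s/(1-w_s)` where `w_s` is the baseline
#' share, so the population record-level reporting odds ratio equals `m`
#' exactly by construction; non-injected PTs absorb the residual probability
#' mass (slightly deflating their odds, the usual masking effect of
#' disproportionality data).
#'
#' @param seed master seed; every table draws from its own stream derived
#'   from it, so adding a field to one table does not perturb the others.
#' @param n_reports number of cases before duplication.
#' @param p_target probability a report's primary suspect is the target drug.
#' @param target_drug list with `name`, `brand`, `prod_ai` strings.
#' @param other_drugs character vector of comparator drug names.
#' @param pts data frame with columns `pt`, `soc`, `weight` (baseline
#'   record-share weights; normalised internally).
#' @param signals data frame with columns `pt`, `odds_multiplier` and
#'   optionally `sex` (`NA` = both sexes, `"F"`/`"M"` = that stratum only);
#'   zero rows for a null extract.
#' @param pts_per_report numeric `c(mean=, dispersion=)`: mean PTs per
#'   report and the shape of the Gamma(mean 1) report-level reporting
#'   intensity that overdisperses the per-report PT count
#'   (negative-binomial-like; smaller shape = more dispersion).
#' @param sex_probs named probabilities over `F`, `M`, `UNK`.
#' @param age_bin_probs named probabilities over the age bins
#'   `<18`, `18-64`, `65-84`, `>=85`, `Unknown`.
#' @param country_probs named probabilities (name `Missing` allowed).
#' @param reporter_probs named probabilities over FAERS `OCCP_COD` codes
#'   `MD`, `PH`, `OT`, `CN` and `Missing`.
#' @param indication_probs named probabilities (name `Missing` allowed).
#' @param outcome_probs named per-report Bernoulli probabilities over outcome
#'   codes `DE`, `HO`, `DS`, `LT`, `CA`, `RI`, `OT` (not mutually exclusive).
#' @param year_range integer `c(first, last)` calendar years.
#' @param year_weights optional weights over the years (uniform if `NULL`).
#' @param onset onset model: `list(family = "lognormal", meanlog=, sdlog=)`
#'   or `list(family = "piecewise_loguniform", knots = <5 increasing days>)`
#'   with equal quartile mass between consecutive knots.
#' @param p_event_missing,p_event_partial,p_start_missing,p_start_partial
#'   missingness/partial-precision rates for the event and therapy-start
#'   dates.
#' @param p_pre_treatment fraction of reports whose recorded event date
#'   precedes therapy start (exercising the onset exclusion rule).
#' @param duplicate_rate fraction of cases re-emitted as later report
#'   versions.
#' @param dup_versions_max maximum extra versions per duplicated case (1-3).
#' @param dup_tie_frac fraction of duplicated cases whose last two versions
#'   share an FDA_DT (exercising the PRIMARYID tie-break).
#' @param deletion_rate fraction of caseids placed on the deletion list.
#' @param p_extra_drug probability of one extra non-suspect drug row.
#' @param p_target_nonps probability a comparator report also lists the
#'   target drug in a non-PS role (exercising the role filter).
#' @return object of class `"faers_generator_config"` (a validated list).
#' @seealso [faers_preset()], [generate_faers()]
#' @export
generator_config <- function(seed = 1L,
                             n_reports = 1000L,
                             p_target = 0.1,
                             target_drug = list(name = "DONEPEZIL", brand = "ARICEPT",
                                                prod_ai = "DONEPEZIL HYDROCHLORIDE"),
                             other_drugs = c("MEMANTINE", "RIVASTIGMINE", "GALANTAMINE",
                                             "METFORMIN", "ATORVASTATIN", "LISINOPRIL"),
                             pts = NULL,
                             signals = data.frame(pt = character(),
                                                  odds_multiplier = numeric(),
                                                  sex = character()),
                             pts_per_report = c(mean = 2.9, dispersion = 2),
                             sex_probs = c(F = 0.48, M = 0.42, UNK = 0.10),
                             age_bin_probs = c("<18" = 0.02, "18-64" = 0.18,
                                               "65-84" = 0.45, ">=85" = 0.15,
                                               "Unknown" = 0.20),
                             country_probs = c(US = 0.4, GB = 0.2, JP = 0.1,
                                               DE = 0.1, FR = 0.1, Missing = 0.1),
                             reporter_probs = c(MD = 0.3, PH = 0.2, OT = 0.2,
                                                CN = 0.2, Missing = 0.1),
                             indication_probs = c("Dementia Alzheimer's type" = 0.5,
                                                  "Dementia" = 0.3, Missing = 0.2),
                             outcome_probs = c(DE = 0.05, HO = 0.3, DS = 0.03,
                                               LT = 0.05, OT = 0.2),
                             year_range = c(2004L, 2024L),
                             year_weights = NULL,
                             onset = list(family = "lognormal",
                                          meanlog = log(49), sdlog = 1.4),
                             p_event_missing = 0.05, p_event_partial = 0.05,
                             p_start_missing = 0.3, p_start_partial = 0.1,
                             p_pre_treatment = 0.02,
                             duplicate_rate = 0.05, dup_versions_max = 3L,
                             dup_tie_frac = 0.2,
                             deletion_rate = 0.01,
                             p_extra_drug = 0.3, p_target_nonps = 0.01) {
  if (is.null(pts)) {
    pts <- data.frame(
      pt = paste0("Event ", sprintf("%03d", 1:20)),
      soc = rep(paste("Synthetic SOC", LETTERS[1:5]), each = 4),
      weight = 1 / (1:20),
      stringsAsFactors = FALSE)
  }
  if (is.null(signals$sex)) signals$sex <- rep(NA_character_, nrow(signals))
  cfg <- list(seed = as.integer(seed), n_reports = as.integer(n_reports),
              p_target = p_target, target_drug = target_drug,
              other_drugs = other_drugs, pts = pts, signals = signals,
              pts_per_report = pts_per_report, sex_probs = sex_probs,
              age_bin_probs = age_bin_probs, country_probs = country_probs,
              reporter_probs = reporter_probs, indication_probs = indication_probs,
              outcome_probs = outcome_probs, year_range = year_range,
              year_weights = year_weights, onset = onset,
              p_event_missing = p_event_missing, p_event_partial = p_event_partial,
              p_start_missing = p_start_missing, p_start_partial = p_start_partial,
              p_pre_treatment = p_pre_treatment,
              duplicate_rate = duplicate_rate,
              dup_versions_max = as.integer(dup_versions_max),
              dup_tie_frac = dup_tie_frac, deletion_rate = deletion_rate,
              p_extra_drug = p_extra_drug, p_target_nonps = p_target_nonps)

  probs <- c(p_target, duplicate_rate, dup_tie_frac, deletion_rate,
             p_event_missing, p_event_partial, p_start_missing, p_start_partial,
             p_pre_treatment, p_extra_drug, p_target_nonps,
             sex_probs, age_bin_probs, country_probs, reporter_probs,
             indication_probs, outcome_probs)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (duplicate_rate >= 1) stop("duplicate_rate must be < 1")
  if (nrow(signals) > 0) {
    if (any(signals$odds_multiplier <= 0)) stop("odds multipliers must be > 0")
    unknown <- setdiff(signals$pt, pts$pt)
    if (length(unknown) > 0)
      stop("signal references unknown PT(s): ", paste(unknown, collapse = ", "))
    if (!all(is.na(signals$sex) | signals$sex %in% c("F", "M")))
      stop("signal sex must be NA, 'F' or 'M'")
  }
  if (any(pts$weight <= 0)) stop("PT weights must be positive")
  if (anyDuplicated(pts$pt)) stop("duplicate PT in lexicon")
  structure(cfg, class = "faers_generator_config")
}

#' Frozen generator presets
#'
#' * `minimal`: 100 reports, 3 comparator drugs, 5 equally weighted PTs, no
#'   injected signals, no duplicates or deletions or missing dates - the
#'   smallest end-to-end exercise.
#' * `paper_like`: a donepezil-style study population: about 9,000
#'   target-drug reports out of 60,000 (roughly 2.9 PTs per report), sex
#'   split 51.3/35.6/13.1 F/M/UNK, age mass centred on 65-84, US/GB-dominated
#'   countries, 2004-2024 reporting years peaking in 2019, about a third of
#'   target reports with computable onsets drawn from a piecewise
#'   log-uniform distribution with quartile knots 11/49/265.75 days, and a
#'   panel of injected reporting-odds signals spanning weak (hypotension-like
#'   x2.4) to extreme (pleurothotonus-like x332.6) alongside protective
#'   (sub-unity) terms.
#' * `sex_specific_signal`: one PT (`Torsade de pointes`) injected at odds
#'   x20 in female reports only, on an otherwise null background.
#'
#' @param name preset name.
#' @return a `"faers_generator_config"`.
#' @export
faers_preset <- function(name = c("minimal", "paper_like", "sex_specific_signal")) {
  name <- tryCatch(match.arg(name),
                   error = function(e) stop("unknown preset; available: ",
                                            "minimal, paper_like, sex_specific_signal"))
  switch(name,
    minimal = generator_config(
      seed = 1L, n_reports = 100L, p_target = 0.3,
      other_drugs = c("MEMANTINE", "RIVASTIGMINE", "GALANTAMINE"),
      pts = data.frame(pt = c("Nausea", "Vomiting", "Dizziness", "Fall", "Headache"),
                       soc = c("Gastrointestinal disorders", "Gastrointestinal disorders",
                               "Nervous system disorders",
                               "Injury, poisoning and procedural complications",
                               "Nervous system disorders"),
                       weight = rep(0.2, 5), stringsAsFactors = FALSE),
      pts_per_report = c(mean = 2, dispersion = 2),
      duplicate_rate = 0, deletion_rate = 0,
      p_event_missing = 0, p_event_partial = 0,
      p_start_missing = 0, p_start_partial = 0, p_pre_treatment = 0),
    paper_like = {
      sig <- .paper_like_signals()
      generator_config(
        seed = 1L, n_reports = 60000L, p_target = 0.15,
        pts = .paper_like_lexicon(sig),
        signals = sig[, c("pt", "odds_multiplier", "sex")],
        pts_per_report = c(mean = 2.92, dispersion = 1.5),
        sex_probs = c(F = 0.513, M = 0.356, UNK = 0.131),
        age_bin_probs = c("<18" = 0.007, "18-64" = 0.068, "65-84" = 0.506,
                          ">=85" = 0.171, "Unknown" = 0.248),
        country_probs = c(US = 0.274, GB = 0.264, JP = 0.141, IT = 0.053,
                          DE = 0.036, FR = 0.045, CA = 0.035, AU = 0.030,
                          ES = 0.025, KR = 0.020, Missing = 0.077),
        reporter_probs = c(PH = 0.317, CN = 0.246, MD = 0.171, OT = 0.119,
                           Missing = 0.147),
        indication_probs = c("Dementia Alzheimer's type" = 0.338,
                             "Product used for unknown indication" = 0.232,
                             "Dementia" = 0.168, Missing = 0.082,
                             "Cognitive disorder" = 0.033, "Other" = 0.147),
        outcome_probs = c(DE = 0.084, HO = 0.387, DS = 0.038, LT = 0.066, OT = 0.275),
        year_range = c(2004L, 2024L),
        year_weights = c(seq(0.5, 1.5, length.out = 15), 2.1, 1.8, 1.7, 1.8, 1.7, 1.6),
        onset = list(family = "piecewise_loguniform",
                     knots = c(1, 11, 49, 265.75, 1700)),
        p_event_missing = 0.08, p_event_partial = 0.02,
        p_start_missing = 0.55, p_start_partial = 0.10,
        p_pre_treatment = 0.02,
        duplicate_rate = 0.05, dup_tie_frac = 0.2, deletion_rate = 0.01)
    },
    sex_specific_signal = generator_config(
      seed = 1L, n_reports = 4000L, p_target = 0.1,
      pts = data.frame(
        pt = c("Torsade de pointes", paste0("Background event ", sprintf("%02d", 1:29))),
        soc = c("Cardiac disorders", rep(paste("Synthetic SOC", LETTERS[1:5]), length.out = 29)),
        weight = c(0.004, rep(0.996 / 29, 29)), stringsAsFactors = FALSE),
      signals = data.frame(pt = "Torsade de pointes", odds_multiplier = 20,
                           sex = "F", stringsAsFactors = FALSE),
      pts_per_report = c(mean = 3, dispersion = 2),
      sex_probs = c(F = 0.5, M = 0.45, UNK = 0.05),
      duplicate_rate = 0, deletion_rate = 0,
      p_event_missing = 0, p_event_partial = 0,
      p_start_missing = 0, p_start_partial = 0, p_pre_treatment = 0)
  )
}

# Injected signal panel of the paper_like preset. Baseline weights are the
# study's target-side record shares divided by the multiplier, so the
# expected target-side frequencies and the reporting odds ratios of a
# donepezil-style extract are reproduced together.
.paper_like_signals <- function() {
  s <- rbind(
    c("Bradycardia",                      "Cardiac disorders",        739, 32.65),
    c("Vomiting",                         "Gastrointestinal disorders", 514, 2.59),
    c("Syncope",                          "Nervous system disorders", 511, 11.89),
    c("Fall",                             "Injury, poisoning and procedural complications", 491, 3.44),
    c("Diarrhoea",                        "Gastrointestinal disorders", 483, 1.77),
    c("Confusional state",                "Psychiatric disorders",    434, 6.22),
    c("Dizziness",                        "Nervous system disorders", 427, 1.99),
    c("Nausea",                           "Gastrointestinal disorders", 426, 1.26),
    c("Decreased appetite",               "Metabolism and nutrition disorders", 325, 3.32),
    c("Electrocardiogram QT prolonged",   "Investigations",           264, 17.38),
    c("Somnolence",                       "Nervous system disorders", 235, 2.70),
    c("Delirium",                         "Psychiatric disorders",    219, 15.07),
    c("Sinus bradycardia",                "Cardiac disorders",        219, 52.95),
    c("Drug ineffective",                 "General disorders and administration site conditions", 210, 0.36),
    c("Hypotension",                      "Vascular disorders",       210, 2.42),
    c("Loss of consciousness",            "Nervous system disorders", 198, 3.56),
    c("Fatigue",                          "General disorders and administration site conditions", 194, 0.57),
    c("Insomnia",                         "Psychiatric disorders",    189, 1.62),
    c("Headache",                         "Nervous system disorders", 185, 0.68),
    c("Tremor",                           "Nervous system disorders", 184, 2.53),
    c("Cognitive disorder",               "Nervous system disorders", 162, 8.14),
    c("Mania",                            "Psychiatric disorders",    143, 20.04),
    c("Hyperhidrosis",                    "Skin and subcutaneous tissue disorders", 133, 2.34),
    c("Pleurothotonus",                   "Nervous system disorders", 118, 332.56),
    c("Torsade de pointes",               "Cardiac disorders",        113, 33.65),
    c("Disorientation",                   "Psychiatric disorders",    109, 6.20))
  df <- data.frame(pt = s[, 1], soc = s[, 2],
                   target_count = as.numeric(s[, 3]),
                   odds_multiplier = as.numeric(s[, 4]),
                   stringsAsFactors = FALSE)
  # target-side record share at the study scale (26,120 target records)
  df$weight <- (df$target_count / 26120) / df$odds_multiplier
  df$sex <- NA_character_
  df
}

.paper_like_lexicon <- function(sig) {
  socs <- c("Nervous system disorders", "Psychiatric disorders",
            "Gastrointestinal disorders", "Cardiac disorders",
            "General disorders and administration site conditions",
            "Injury, poisoning and procedural complications",
            "Investigations", "Metabolism and nutrition disorders",
            "Musculoskeletal and connective tissue disorders",
            "Skin and subcutaneous tissue disorders", "Vascular disorders",
            "Respiratory, thoracic and mediastinal disorders",
            "Renal and urinary disorders", "Infections and infestations",
            "Eye disorders", "Blood and lymphatic system disorders",
            "Hepatobiliary disorders", "Social circumstances",
            "Ear and labyrinth disorders", "Endocrine disorders")
  n_fill <- 74
  fill <- data.frame(
    pt = paste0("Background event ", sprintf("%03d", seq_len(n_fill))),
    soc = rep(socs, length.out = n_fill),
    weight = 1 / seq_len(n_fill),
    stringsAsFactors = FALSE)
  fill$weight <- fill$weight / sum(fill$weight) * (1 - sum(sig$weight))
  rbind(sig[, c("pt", "soc", "weight")], fill)
}

.stage_seed <- function(seed, stage) {
  (as.numeric(seed) * 1009 + stage * 101) %% 2147483647
}

.rand_full_date <- function(n, years, weights = NULL) {
  yr <- if (length(years) == 1L) rep(years, n)
        else sample(years, n, replace = TRUE, prob = weights)
  mo <- sample.int(12L, n, replace = TRUE)
  dy <- sample.int(28L, n, replace = TRUE)
  yr * 10000L + mo * 100L + dy
}

.draw_onset <- function(n, onset) {
  if (onset$family == "lognormal") {
    pmax(0L, as.integer(round(stats::rlnorm(n, onset$meanlog, onset$sdlog))))
  } else if (onset$family == "piecewise_loguniform") {
    k <- onset$knots
    stopifnot(length(k) == 5L, all(diff(k) > 0))
    bin <- sample.int(4L, n, replace = TRUE)
    lo <- k[bin]; hi <- k[bin + 1L]
    as.integer(round(lo * (hi / lo)^stats::runif(n)))
  } else stop("unknown onset family: ", onset$family)
}

#' Generate a synthetic FAERS extract with known ground truth
#'
#' Emits the six canonical tables (in-memory, in the same canonical form
#' [read_faers_table()] produces), a deletion list, the synthetic PT-to-SOC
#' vocabulary, and a ground-truth record: the injected odds multipliers with
#' their expected target-side counts, which PRIMARYIDs are duplicate
#' versions (and which version survives deduplication), the deleted CASEIDs
#' and every report's true onset days. Write the files with
#' [write_faers_bundle()].
#'
#' @param config a `"faers_generator_config"` from [generator_config()] or
#'   [faers_preset()].
#' @return object of class `"faers_bundle"`: list with `tables` (named list
#'   `demo`, `drug`, `reac`, `ther`, `indi`, `outc`), `deleted_caseids`,
#'   `vocab` (named character vector) and `truth`.
#' @export
generate_faers <- function(config) {
  stopifnot(inherits(config, "faers_generator_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })

  n <- config$n_reports
  caseid <- 10000000 + seq_len(n)
  primaryid <- caseid * 10 + 1

  ## --- demographics stream ---------------------------------------------
  set.seed(.stage_seed(config$seed, 1L))
  sexp <- config$sex_probs / sum(config$sex_probs)
  sex <- sample(names(sexp), n, replace = TRUE, prob = sexp)
  agep <- config$age_bin_probs / sum(config$age_bin_probs)
  bin <- sample(names(agep), n, replace = TRUE, prob = agep)
  age <- rep(NA_real_, n)
  age[bin == "<18"] <- stats::runif(sum(bin == "<18"), 1, 17.9)
  age[bin == "18-64"] <- stats::runif(sum(bin == "18-64"), 18, 64.9)
  age[bin == "65-84"] <- stats::runif(sum(bin == "65-84"), 65, 84.9)
  age[bin == ">=85"] <- stats::runif(sum(bin == ">=85"), 85, 100)
  age <- floor(age)
  age_cod <- ifelse(is.na(age), NA_character_, "YR")
  dec <- !is.na(age) & stats::runif(n) < 0.05
  age[dec] <- age[dec] / 10
  age_cod[dec] <- "DEC"

  cp <- config$country_probs / sum(config$country_probs)
  country <- sample(names(cp), n, replace = TRUE, prob = cp)
  country[country == "Missing"] <- NA_character_
  rp <- config$reporter_probs / sum(config$reporter_probs)
  occp <- sample(names(rp), n, replace = TRUE, prob = rp)
  occp[occp == "Missing"] <- NA_character_

  years <- seq(config$year_range[1], config$year_range[2])
  fda_dt <- .rand_full_date(n, years, config$year_weights)
  is_target <- stats::runif(n) < config$p_target

  ## dates and true onset
  onset_true <- .draw_onset(n, config$onset)
  start_date <- partial_date_to_date(fda_dt) - onset_true -
    sample.int(60L, n, replace = TRUE)
  event_date <- start_date + onset_true
  pre <- stats::runif(n) < config$p_pre_treatment
  event_date[pre] <- start_date[pre] - sample.int(60L, sum(pre), replace = TRUE)
  start_dt <- date_to_partial_date(start_date)
  event_dt <- date_to_partial_date(event_date)
  u <- stats::runif(n)
  event_dt[u < config$p_event_missing] <- NA_integer_
  part <- u >= config$p_event_missing &
    u < config$p_event_missing + config$p_event_partial
  event_dt[part] <- event_dt[part] %/% 100L * 100L
  u <- stats::runif(n)
  start_missing <- u < config$p_start_missing
  start_dt[start_missing] <- NA_integer_
  part <- u >= config$p_start_missing &
    u < config$p_start_missing + config$p_start_partial
  start_dt[part] <- start_dt[part] %/% 100L * 100L

  demo <- data.frame(primaryid = primaryid, caseid = caseid,
                     fda_dt = fda_dt, event_dt = event_dt, sex = sex,
                     age = age, age_cod = age_cod,
                     reporter_occupation = unname(.occp_map[occp]),
                     country = country,
                     report_year = partial_date_year(fda_dt),
                     stringsAsFactors = FALSE)

  ## --- drug stream ------------------------------------------------------
  set.seed(.stage_seed(config$seed, 2L))
  td <- config$target_drug
  tname <- ifelse(stats::runif(n) < 0.5, td$name, td$brand)
  drugname <- ifelse(is_target, tname,
                     sample(config$other_drugs, n, replace = TRUE))
  prod_ai <- ifelse(is_target, td$prod_ai, drugname)
  drug <- data.frame(primaryid = primaryid, caseid = caseid, drug_seq = 1L,
                     role_cod = "PS", drugname = drugname, prod_ai = prod_ai,
                     stringsAsFactors = FALSE)
  extra <- stats::runif(n) < config$p_extra_drug
  if (any(extra)) {
    en <- sum(extra)
    drug <- rbind(drug, data.frame(
      primaryid = primaryid[extra], caseid = caseid[extra], drug_seq = 2L,
      role_cod = sample(c("SS", "C", "I"), en, replace = TRUE),
      drugname = sample(config$other_drugs, en, replace = TRUE),
      prod_ai = NA_character_, stringsAsFactors = FALSE))
  }
  nonps <- !is_target & stats::runif(n) < config$p_target_nonps
  if (any(nonps)) {
    drug <- rbind(drug, data.frame(
      primaryid = primaryid[nonps], caseid = caseid[nonps], drug_seq = 3L,
      role_cod = "SS", drugname = td$name, prod_ai = td$prod_ai,
      stringsAsFactors = FALSE))
  }

  ## --- reaction stream --------------------------------------------------
  ## Event model: PT j is present on report i with probability
  ## min(0.95, g_i * p_j), independently across PTs, where p_j = mu * w_j
  ## (mu = mean PTs per report) and g_i ~ Gamma(shape = dispersion,
  ## rate = dispersion) is a report-level reporting intensity giving
  ## negative-binomial-like overdispersion of the per-report PT count.
  ## For an injected PT the target group's presence probability solves
  ## p'/(mu - p') = m * p/(mu - p), and background PTs are scaled so the
  ## total expected record count stays mu; the population record-level
  ## reporting odds ratio then equals m exactly (the intensity g cancels
  ## from the within-report odds).
  set.seed(.stage_seed(config$seed, 3L))
  ppr <- config$pts_per_report
  mu <- ppr[["mean"]]
  w <- config$pts$weight / sum(config$pts$weight)
  names(w) <- config$pts$pt
  npts <- nrow(config$pts)
  p_base <- mu * w

  group_presence <- function(target, sx) {
    if (!target || nrow(config$signals) == 0L) return(p_base)
    sig <- config$signals[is.na(config$signals$sex) | config$signals$sex == sx, , drop = FALSE]
    if (nrow(sig) == 0L) return(p_base)
    p <- p_base
    i <- match(sig$pt, names(w))
    ps <- p_base[i]
    m <- sig$odds_multiplier
    p[i] <- mu * m * ps / (mu - ps + m * ps)
    if (any(p[i] >= 0.95))
      stop("injected signal presence probability reaches the 0.95 cap; ",
           "lower the multiplier or the baseline weight")
    if (sum(p[i]) >= mu)
      stop("injected signals leave no probability mass for background PTs")
    rest <- setdiff(seq_len(npts), i)
    p[rest] <- p_base[rest] * (mu - sum(p[i])) / (mu - sum(ps))
    p
  }

  g <- stats::rgamma(n, shape = ppr[["dispersion"]], rate = ppr[["dispersion"]])
  rec_pid_list <- rec_pt_list <- list()
  for (tg in c(FALSE, TRUE)) for (sx in c("F", "M", "UNK")) {
    sel <- which(is_target == tg & sex == sx)
    if (length(sel) == 0L) next
    pg <- group_presence(tg, sx)
    prob <- outer(g[sel], pg) # reports x PTs
    prob[prob > 0.95] <- 0.95
    hit <- which(matrix(stats::runif(length(prob)), nrow = nrow(prob)) < prob,
                 arr.ind = TRUE)
    rec_pid_list[[length(rec_pid_list) + 1L]] <- sel[hit[, 1L]]
    rec_pt_list[[length(rec_pt_list) + 1L]] <- hit[, 2L]
  }
  rec_i <- unlist(rec_pid_list, use.names = FALSE)
  rec_pt_idx <- unlist(rec_pt_list, use.names = FALSE)
  o <- order(rec_i, rec_pt_idx)
  rec_i <- rec_i[o]; rec_pt_idx <- rec_pt_idx[o]
  # a few literal duplicate rows, as real quarters contain
  dup_rows <- which(stats::runif(length(rec_i)) < 0.02)
  rec_i <- c(rec_i, rec_i[dup_rows])
  rec_pt_idx <- c(rec_pt_idx, rec_pt_idx[dup_rows])
  pt_out <- config$pts$pt[rec_pt_idx]
  upper <- stats::runif(length(pt_out)) < 0.1 # casing noise across quarters
  pt_out[upper] <- toupper(pt_out[upper])
  reac <- data.frame(primaryid = primaryid[rec_i], caseid = caseid[rec_i],
                     pt = pt_out, stringsAsFactors = FALSE)

  ## --- therapy stream ---------------------------------------------------
  set.seed(.stage_seed(config$seed, 4L))
  has_ther <- !is.na(start_dt)
  end_dt <- rep(NA_integer_, n)
  with_end <- has_ther & start_dt %% 100L > 0L & stats::runif(n) < 0.4
  dur <- sample.int(400L, n, replace = TRUE)
  end_dt[with_end] <- date_to_partial_date(
    partial_date_to_date(start_dt[with_end]) + dur[with_end])
  ther <- data.frame(primaryid = primaryid[has_ther], caseid = caseid[has_ther],
                     dsg_drug_seq = 1L, start_dt = start_dt[has_ther],
                     end_dt = end_dt[has_ther],
                     inconsistent = FALSE, stringsAsFactors = FALSE)

  ## --- indication stream ------------------------------------------------
  set.seed(.stage_seed(config$seed, 5L))
  ip <- config$indication_probs / sum(config$indication_probs)
  ind <- sample(names(ip), n, replace = TRUE, prob = ip)
  has_ind <- ind != "Missing"
  indi <- data.frame(primaryid = primaryid[has_ind], caseid = caseid[has_ind],
                     indi_drug_seq = 1L, indi_pt = ind[has_ind],
                     stringsAsFactors = FALSE)

  ## --- outcome stream ---------------------------------------------------
  set.seed(.stage_seed(config$seed, 6L))
  outc_list <- lapply(names(config$outcome_probs), function(code) {
    hit <- stats::runif(n) < config$outcome_probs[[code]]
    data.frame(primaryid = primaryid[hit], caseid = caseid[hit],
               outc_cod = code, stringsAsFactors = FALSE)
  })
  outc <- do.call(rbind, outc_list)
  outc <- outc[order(outc$primaryid), , drop = FALSE]
  rownames(outc) <- NULL

  ## --- duplicate versions ----------------------------------------------
  set.seed(.stage_seed(config$seed, 7L))
  tables <- list(demo = demo, drug = drug, reac = reac, ther = ther,
                 indi = indi, outc = outc)
  dup_truth <- data.frame(caseid = numeric(), retained_primaryid = numeric())
  duplicate_pids <- numeric()
  if (config$duplicate_rate > 0) {
    dup_idx <- which(stats::runif(n) < config$duplicate_rate)
    if (length(dup_idx) > 0L) {
      n_extra <- sample.int(config$dup_versions_max, length(dup_idx), replace = TRUE)
      tie <- stats::runif(length(dup_idx)) < config$dup_tie_frac
      ver_case <- rep(dup_idx, n_extra)
      ver_no <- sequence(n_extra) # 1..n_extra within case
      new_pid <- caseid[ver_case] * 10 + 1 + ver_no
      base_date <- partial_date_to_date(fda_dt[ver_case])
      lag <- sample.int(300L, length(ver_case), replace = TRUE) + 30L
      new_fda <- date_to_partial_date(base_date + cumsumish(ver_no, lag))
      # tie cases: the last extra version repeats the previous version's
      # FDA_DT (the original's, when there is a single extra version), so the
      # PRIMARYID tie-break decides the survivor
      last_of_case <- c(ver_case[-1] != ver_case[-length(ver_case)], TRUE)
      is_tie <- last_of_case & tie[match(ver_case, dup_idx)]
      prev_fda <- c(NA_integer_, new_fda[-length(new_fda)])
      new_fda[is_tie & ver_no > 1L] <- prev_fda[is_tie & ver_no > 1L]
      new_fda[is_tie & ver_no == 1L] <- fda_dt[ver_case[is_tie & ver_no == 1L]]

      extra_demo <- demo[ver_case, , drop = FALSE]
      extra_demo$primaryid <- new_pid
      extra_demo$fda_dt <- new_fda
      extra_demo$report_year <- partial_date_year(new_fda)
      tables$demo <- rbind(tables$demo, extra_demo)

      reemit <- function(tb) {
        sel <- tb$primaryid %in% primaryid[dup_idx]
        if (!any(sel)) return(tb)
        src <- tb[sel, , drop = FALSE]
        src$..rep <- match(src$primaryid, primaryid)
        map <- data.frame(..rep = ver_case, ..new_pid = new_pid)
        merged <- merge(src, map, by = "..rep")
        merged$primaryid <- merged$..new_pid
        rbind(tb, merged[, names(tb), drop = FALSE])
      }
      for (nm in c("drug", "reac", "ther", "indi", "outc"))
        tables[[nm]] <- reemit(tables[[nm]])

      # the survivor under the (FDA_DT, PRIMARYID) max-rule
      all_ver <- tables$demo[tables$demo$caseid %in% caseid[dup_idx], , drop = FALSE]
      o <- order(all_ver$caseid, all_ver$fda_dt, all_ver$primaryid)
      all_ver <- all_ver[o, , drop = FALSE]
      keep_last <- !duplicated(all_ver$caseid, fromLast = TRUE)
      dup_truth <- data.frame(caseid = all_ver$caseid[keep_last],
                              retained_primaryid = all_ver$primaryid[keep_last])
      duplicate_pids <- setdiff(all_ver$primaryid, dup_truth$retained_primaryid)
    }
  }
  rownames(tables$demo) <- NULL

  ## --- deletions --------------------------------------------------------
  set.seed(.stage_seed(config$seed, 8L))
  deleted_caseids <- caseid[stats::runif(n) < config$deletion_rate]

  ## --- ground truth -----------------------------------------------------
  truth_sig <- NULL
  if (nrow(config$signals) > 0L) {
    truth_sig <- config$signals
    exp_a <- vapply(seq_len(nrow(truth_sig)), function(i) {
      sx <- truth_sig$sex[i]
      sel_sex <- if (is.na(sx)) rep(TRUE, n) else sex == sx
      pg <- group_presence(TRUE, if (is.na(sx)) "UNK" else sx)
      sum(pmin(0.95, g[is_target & sel_sex] * pg[[truth_sig$pt[i]]]))
    }, numeric(1))
    truth_sig$expected_a <- exp_a
    truth_sig$true_ror <- truth_sig$odds_multiplier
  }
  truth <- list(
    n_reports = n,
    n_target_reports = sum(is_target),
    target_primaryids = primaryid[is_target],
    signals = truth_sig,
    duplicate_primaryids = duplicate_pids,
    duplicate_survivors = dup_truth,
    deleted_caseids = deleted_caseids,
    onset_days_true = data.frame(primaryid = primaryid, onset_days = onset_true,
                                 pre_treatment = pre)
  )
  vocab <- stats::setNames(config$pts$soc, normalize_pt(config$pts$pt))
  structure(list(tables = tables, deleted_caseids = deleted_caseids,
                 vocab = vocab, truth = truth, config = config),
            class = "faers_bundle")
}

# within-case cumulative lag: ver_no restarts at 1 for each case
cumsumish <- function(ver_no, lag) {
  out <- lag
  for (j in seq_along(lag)) if (ver_no[j] > 1L) out[j] <- out[j - 1L] + lag[j]
  out
}

#' @export
print.faers_bundle <- function(x, ...) {
  cat("Synthetic FAERS extract\n")
  cat(sprintf("  reports: %d (%d target), report versions in DEMO: %d\n",
              x$truth$n_reports, x$truth$n_target_reports, nrow(x$tables$demo)))
  cat(sprintf("  reaction rows: %d; injected signals: %d; deleted cases: %d\n",
              nrow(x$tables$reac),
              if (is.null(x$truth$signals)) 0L else nrow(x$truth$signals),
              length(x$deleted_caseids)))
  invisible(x)
}

#' Write a synthetic bundle as FAERS-dialect files
#'
#' Emits `DEMO.txt`, `DRUG.txt`, `REAC.txt`, `THER.txt`, `INDI.txt`,
#' `OUTC.txt` in the `$`-delimited dialect, `deleted_cases.txt` (one CASEID
#' per line), `vocab.tsv` and `truth.json`.
#'
#' @param bundle a `"faers_bundle"`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_faers_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "faers_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  kinds <- c(demo = "DEMO", drug = "DRUG", reac = "REAC", ther = "THER",
             indi = "INDI", outc = "OUTC")
  for (nm in names(kinds))
    write_faers_table(bundle$tables[[nm]], file.path(dir, paste0(kinds[[nm]], ".txt")),
                      kind = kinds[[nm]])
  writeLines(format(bundle$deleted_caseids, scientific = FALSE, trim = TRUE),
             file.path(dir, "deleted_cases.txt"))
  write_vocabulary(bundle$vocab, file.path(dir, "vocab.tsv"))
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a bundle directory back into canonical tables
#' @param dir directory written by [write_faers_bundle()].
#' @return list with `tables`, `deleted_caseids`, `vocab`.
#' @export
read_faers_bundle <- function(dir) {
  kinds <- c(demo = "DEMO", drug = "DRUG", reac = "REAC", ther = "THER",
             indi = "INDI", outc = "OUTC")
  tables <- lapply(names(kinds), function(nm)
    read_faers_table(file.path(dir, paste0(kinds[[nm]], ".txt")), kind = kinds[[nm]]))
  names(tables) <- names(kinds)
  del_path <- file.path(dir, "deleted_cases.txt")
  list(tables = tables,
       deleted_caseids = if (file.exists(del_path)) read_deletion_list(del_path) else numeric(),
       vocab = read_vocabulary(file.path(dir, "vocab.tsv")))
}
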