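Package: faersignal
Title: Disproportionality Signal Detection for FAERS-Style Spontaneous Report Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for pharmacovigilance signal detection on
    FDA Adverse Event Reporting System (FAERS) style quarterly extracts:
    reading the '$'-delimited DEMO/DRUG/REAC/THER/INDI/OUTC ASCII tables,
    FDA-recommended case-level deduplication, primary-suspect cohort
    extraction by drug-name keyword, four disproportionality algorithms on
    the fourfold table (reporting odds ratio, proportional reporting ratio
    with Pearson chi-squared, the Bayesian confidence propagation neural
    network information component, and the multi-item gamma Poisson
    shrinker EBGM in their simplified non-shrinkage forms) with the usual
    signal criteria, time-to-onset summaries, descriptive cohort tables,
    sex-stratified signals, and a synthetic FAERS generator with injectable
    ground-truth reporting-odds signals for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
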