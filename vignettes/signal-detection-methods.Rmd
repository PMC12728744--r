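---
title: "Disproportionality signal detection on spontaneous report data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection on spontaneous report data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous reporting systems such as the FDA Adverse Event Reporting System
(FAERS) collect individual case safety reports (ICSRs): a patient, one or
more drugs with role codes (primary suspect, secondary suspect, concomitant,
interacting), and one or more adverse events coded as MedDRA preferred terms
(PTs). There is no denominator of exposed patients, so absolute risks cannot
be estimated. Disproportionality analysis instead asks whether a drug-event
pair is reported *more often than expected* given the rest of the database,
via the fourfold table

|              | target AE | other AEs |
|--------------|-----------|-----------|
| target drug  | a         | b         |
| other drugs  | c         | d         |

`faersignal` implements the complete desk workflow around that table for a
cholinesterase-inhibitor-style pharmacovigilance study: reading the
`$`-delimited quarterly ASCII tables, case-level deduplication,
primary-suspect cohort extraction by drug-name keyword, batch evaluation of
four disproportionality algorithms with their conventional signal criteria,
time-to-onset summaries, descriptive cohort tables, sex-stratified signals,
and a synthetic FAERS generator with known ground truth so every stage is
testable without access to the real database.

## The four algorithms

All four statistics are functions of one fourfold table and are computed in
their simplified, non-shrinkage forms:

* **ROR** (reporting odds ratio): $ROR = ad/bc$, with the log-normal 95%
  interval $\exp(\ln ROR \pm 1.96\sqrt{1/a + 1/b + 1/c + 1/d})$.
  Criterion: lower bound $> 1$ and $a \ge 3$.
* **PRR** (proportional reporting ratio): $PRR = \frac{a(c+d)}{c(a+b)}$
  with the Pearson chi-squared
  $\chi^2 = \frac{(ad-bc)^2 N}{(a+b)(c+d)(a+c)(b+d)}$, no continuity
  correction. Criterion: $PRR > 2$, $\chi^2 > 4$, $a > 3$.
* **BCPNN information component**:
  $IC = \log_2 \frac{aN}{(a+c)(a+b)}$, the log2 observed-to-expected
  ratio. Criterion: $IC_{025} > 0$.
* **MGPS**: $EBGM = \frac{aN}{(a+c)(a+b)}$ with
  $EBGM_{05} = \exp(\ln EBGM - 1.96\sqrt{1/a+1/b+1/c+1/d})$.
  Criterion: $EBGM_{05} > 2$, $N > 0$.

Note that in these simplified forms IC and EBGM are *one quantity on two
scales*: $EBGM = 2^{IC}$ identically. The implementation computes the IC
interval bound by transforming the log-normal lower bound of the base
observed-to-expected quantity onto the $\log_2$ scale
($IC_{025} = \log_2 EBGM_{05}^{(1)}$-style bound), which keeps the
equivalence $IC_{025} > 0 \iff$ lower O/E bound $> 1$ and is well defined
for negative IC, unlike a literal "exp(ln IC)" recipe. No gamma-Poisson
mixture fitting and no BCPNN posterior sampling is performed: the full
empirical-Bayes shrinkage estimators are deliberately out of scope, and the
`ebgm == 2^ic` identity is asserted in the test suite as the documented
behaviour of the simplified forms.

A statistic whose formula divides by an empty cell or margin is *undefined*
and reported as `NA`, and an undefined statistic never signals. The only
convention is $IC = -\infty$ when $a = 0$ with non-empty margins. An
optional Haldane-Anscombe correction (+0.5 on every cell of a
zero-containing table, `zero_correction = TRUE`) is available but off by
default, since the standard formula set prescribes none. No
multiple-testing adjustment is applied — conventional practice in
disproportionality screening — but every fit records the number of terms
tested (`attr(fit, "n_tests")`), so the reader can judge the multiplicity.

The counting unit throughout is the **distinct (report, PT) record**: a
report contributes once per unique normalised PT, and $N = a+b+c+d$ is the
total record count. Record-level counting is what makes "26,120 adverse
events from 8,943 reports" style bookkeeping coherent; the pipeline also
reports case-level counts in its manifest so either convention can be
inspected.

## Deduplication and cohort rules

FAERS distributes successive versions of the same case under one CASEID with
different PRIMARYIDs. Following the FDA-recommended rule, the version with
the highest FDA_DT is retained, ties broken by the highest PRIMARYID; the
retained element is the lexicographic argmax and is therefore independent of
sort direction. A missing FDA_DT compares below every real date, so a dated
version always beats an undated one — the conservative completion of a rule
stated for comparable dates. Deleted-case lists, when supplied, remove whole
cases after deduplication and are counted separately.

The target cohort is defined by case-insensitive substring match of the
configured keywords against both the drug name and the active-ingredient
field, restricted to rows with role code PS. A report whose target drug
appears only as secondary suspect or concomitant is a comparator report, and
all PTs of a target report count as target records (no per-PT attribution —
the standard, and only workable, convention for spontaneous reports).

## Time to onset

Onset is the calendar-day difference between therapy start (THER table,
linked through the suspect drug's sequence number; earliest full date when
several rows exist) and the adverse-event date (EVENT_DT; the choice of
date field is config-overridable). Three exclusion rules apply, each
counted: events dated before therapy start (`pre_treatment`), month- or
year-precision dates on either side (`partial_date` — no day-of-month is
ever imputed, so no onset is fabricated), and missing dates. Quantiles use
linear interpolation between order statistics (`stats::quantile` type 7),
the convention that produces fractional quartiles such as 265.75 from
integer day counts. "Within the first month" means ≤ 30 days; "beyond one
year" means > 365 days; the histogram bins are 30-day intervals up to 360
days plus a `>360` bin.

## Sex-stratified signals

The stratified analysis runs the *full four-algorithm battery within each
sex stratum* (target drug vs all other drugs, restricted to reports of that
sex). This is the reading under which "PTs meeting all four algorithmic
criteria" per stratum parses; the alternative contrast (female vs male
within the target drug) is a different question and is not the default.
Unknown-sex reports are excluded from strata but retained in pooled
analyses, so per-PT stratum counts satisfy
$a_F + a_M + a_{UNK} = a_{pooled}$. The default reporting filter keeps the
30 most frequent terms per stratum (configurable).

## What the synthetic generator emulates

`generator_config()` / `generate_faers()` produce a multi-table extract in
the exact file dialect the reader consumes, with ground truth recorded for
every mechanism:

* **Event model.** PT $j$ appears on report $i$ with probability
  $\min(0.95,\; g_i \mu w_j)$, independently across PTs, where $\mu$ is the
  mean PT count per report, $w_j$ the baseline PT weights, and
  $g_i \sim \Gamma(\phi, \phi)$ a report-level reporting intensity giving
  negative-binomial-like overdispersion of the per-report PT count.
* **Signal injection.** For an injected PT with multiplier $m$ the target
  group's presence probability solves
  $p'/(\mu - p') = m\, p/(\mu - p)$, and background PTs are rescaled so the
  expected records per report stay $\mu$. The within-report odds of "this
  record is the signal PT" are then exactly $m$ times the comparator odds,
  and the intensity $g_i$ cancels from those odds — so the population
  record-level ROR equals the multiplier by construction. This makes ROR
  recovery a closed-form target: the acceptance suite verifies 95% CI
  coverage of an injected ×11 signal in 92–98 of 100 replicates with
  unbiased mean log-ROR. Injections can be restricted to one sex, which
  grounds the stratified analysis in known truth. Non-injected PTs absorb
  the rescaling and sit slightly below ROR 1 — the familiar masking effect
  of real disproportionality data.
* **Duplicates and deletions.** A configurable fraction of cases is
  re-emitted (all six tables) under later FDA_DTs and higher PRIMARYIDs,
  with a sub-fraction tying on FDA_DT to exercise the PRIMARYID tie-break;
  the generator records which version must survive. A deletion list removes
  whole cases.
* **Demographics, dates, onset.** Sex, age (with unit-code mix), country,
  reporter occupation, indications, outcomes and reporting years are drawn
  from configurable categorical distributions; therapy start and event
  dates are derived from a true onset draw and then corrupted by
  configurable missing/partial-precision rates, so the onset exclusions
  operate on known truth.

The `paper_like` preset freezes a donepezil-style study population: about
9,000 target reports out of 60,000 (≈2.9 PTs per report), sex split
51.3/35.6/13.1% F/M/UNK, age mass centred on the 65–84 bin, US/GB-dominated
reporting, years 2004–2024 peaking around 2019, and a panel of 26 injected
signals spanning protective (×0.36) to extreme (×332.6) odds with baseline
weights chosen so the expected target-side frequencies match the injected
odds panel. Its onset model is a piecewise log-uniform distribution with
quartile knots at 1, 11, 49, 265.75 and 1700 days: this reproduces a median
of 49 days, IQR 11–265.75, mean ≈232 days, ≈42% of onsets within 30 days
and ≈20% beyond one year *simultaneously*, which no single lognormal can do
(a lognormal matching the median and first-month share puts far too little
mass beyond one year). About 31% of target reports end up with computable
onsets, via the missing/partial date rates.

What the generator does **not** emulate: drug co-prescription structure
(comparator reports carry independent random drugs), PT co-occurrence
beyond the shared report intensity, a realistic MedDRA lexicon (the
vocabulary is synthetic and total by construction), secular trends in
reporting quality, and country- or reporter-correlated missingness.
Passing tests on synthetic data therefore demonstrate the correctness of
the *pipeline mechanics and estimators under the stated model*, not
robustness to every pathology of real FAERS extracts.

## Numerical and interface choices

* Identifiers are treated as opaque numbers (stored as doubles; real
  PRIMARYIDs exceed 32-bit integer range) and only ever compared or
  matched, never parsed.
* Partial dates are packed as `YYYYMMDD` integers with `00` for absent
  components: chronological order within a precision level, lower precision
  sorting below the same period's full dates, and a total, idempotent
  parser (impossible calendar dates, including leap-day violations, become
  missing and are counted).
* The `$` dialect has no quoting; lines with embedded `$`, wrong field
  counts, empty drug names or PTs, or invalid role/outcome codes are
  skipped and counted per reason, and every load report satisfies
  `lines_read = kept + skipped`.
* PT joins are case-insensitive after whitespace collapsing; the most
  frequent verbatim casing (ties: first seen) is kept for display.
* Display rounding is half-up at 2 decimals (`round_half_up()`), matching
  published signal tables; machine outputs always carry full precision.
* Ties in top-k descriptive blocks break alphabetically, and every output
  is deterministic given the inputs: re-running the pipeline on identical
  files is byte-identical (asserted in the tests).

## Problem sizes

The test suite exercises: 1,000 exact-independence tables and 10,000 random
tables for the algebraic laws and the Pearson oracle; 200-case engineered
fixtures for the deduplication oracle; 100 generator replicates (5,000
reports each) for ROR recovery; 500 replicates (2,000 reports each) for the
null calibration of the four-criteria conjunction, whose observed
false-signal rate is printed, not assumed; and 20 replicates (4,000 reports
each) for the sex-specific injection. The acceptance script runs the full
file-based pipeline once at the `paper_like` scale (60,000 reports). These
sizes were chosen to give stable Monte-Carlo margins for each property
while keeping a complete run in the minutes range.

## Limitations

Disproportionality statistics are measures of reporting, not of risk; the
package computes them faithfully but none of its outputs are incidence
estimates. The simplified IC/EBGM forms coincide and omit shrinkage, so
small-count terms are noisier than under a true BCPNN/MGPS posterior — the
conservative case-count criteria (`a >= 3`, `a > 3`) are the guard rails.
The synthetic calibration results quantify behaviour under the generator's
model only. Pre-2004 ISR-keyed legacy extracts and the FAERS XML dialect
are out of scope.
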