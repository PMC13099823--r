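---
title: "Methods: disproportionality signal detection and onset-time modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signal detection and onset-time modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous adverse-event reporting systems such as the FDA Adverse Event
Reporting System (FAERS) collect unsolicited reports of suspected drug
reactions. They have no denominator — nobody knows how many patients took a
drug without filing a report — so absolute risks cannot be estimated. What
can be estimated is *disproportionality*: whether a particular drug–event
pair is reported more often than one would expect if drug and event were
independent across the database. `faersignal` implements the full working
chain for such an analysis: report cleaning, four disproportionality
statistics with a consensus rule, time-to-onset modelling, subgroup screens,
and descriptive tables, plus a synthetic report generator used to validate
every stage against known ground truth.

## Cleaning spontaneous reports

FAERS ships quarterly `$`-delimited ASCII tables (DEMO, DRUG, REAC, OUTC,
THER, INDI, RPSR). Three cleaning rules matter:

1. **Deduplication.** Amended reports reappear under the same CASEID. Per
   the archive's own rule, rows are ordered by CASEID, FDA receipt date and
   PRIMARYID; the latest receipt date wins, ties go to the largest
   PRIMARYID. Rows whose receipt date cannot be parsed are quarantined to a
   rejects list rather than silently dropped, so every input row is
   accounted for.
2. **Deleted cases.** Quarters since 2019 list case identifiers whose
   reports were withdrawn; these are removed after deduplication.
3. **Standardization.** Preferred terms (PTs) map to a single primary
   system organ class (SOC) through a dictionary table; drug spellings map
   to generic names through a synonym table. Both lookups are
   case-insensitive after whitespace normalization. Real MedDRA is
   license-gated, so the package works against any user-supplied mapping;
   the synthetic generator emits a small mock dictionary covering its own
   vocabulary.

The target population is defined by the *primary suspect* (PS) drug only: a
report whose PS drug is the target forms the target population, everything
else — including reports carrying the target as secondary suspect or
concomitant — is background. Age units (decades, months, weeks, days,
hours) convert to years; a report is *serious* when any outcome code in
death / life-threatening / hospitalization / disability / congenital
anomaly / required-intervention is present, the usual regulatory
convention.

## The four statistics

For each PT, the report-level 2×2 table against the background is

|              | PT      | other PTs |
|--------------|---------|-----------|
| target drug  | a       | b         |
| other drugs  | c       | d         |

A report contributes at most once per cell for a given PT, so the margins
`a + b` and `c + d` are constant across PTs.

**Reporting odds ratio.** `ROR = ad / bc` with the Wald interval
`exp(ln ROR ± 1.96 √(1/a + 1/b + 1/c + 1/d))`; flagged when `a ≥ 3` and the
lower bound exceeds 1. When any cell is zero, 0.5 is added to every cell
(Haldane–Anscombe) for ROR, PRR and the chi-square — the Bayesian methods
handle zeros natively, so they are left uncorrected.

**Proportional reporting ratio.** `PRR = [a/(a+b)] / [c/(c+d)]` with the
Yates-corrected chi-square of the table; flagged under the MHRA-style rule
`a ≥ 3`, `PRR ≥ 2`, `χ² ≥ 4`, boundaries inclusive. The Yates correction
can be switched off.

**Information component (BCPNN).** `IC = log2 p(x,y) / (p(x) p(y))` under
the original unit-information beta priors: both margins get `Beta(1, 1)`,
and the joint cell gets `Beta(1, 1/(E[p_x] E[p_y]) − 1)` so the prior IC is
centred at zero. The normative computation is Monte-Carlo: 100,000
independent posterior draws of the three probabilities (seeded, so
deterministic), with `IC` the posterior expectation (or median, by option)
and `IC025` the 2.5th percentile; flagged when `IC025 > 0`. A closed-form
alternative uses the exact cumulants of the log-beta posteriors — polygamma
differences, which add across the three independent terms — with a
second-order Cornish–Fisher quantile to absorb the left skew at small
counts. On tables with `a ≥ 3` (the smallest count the detection rule ever
evaluates) the closed form tracks the Monte-Carlo quantile within 0.05; at
`a < 3` the posterior is too skewed for a two-term expansion, which is why
the Monte-Carlo version is normative.

**Empirical-Bayes gamma-Poisson shrinker (MGPS).** With baseline
expectation `E = (a+b)(a+c)/N`, the observed count is modelled as
`a ~ Poisson(λE)` with a two-component gamma mixture prior on λ. The prior
is conjugate: the posterior is again a gamma mixture whose component
weights come from the negative-binomial marginals. `EBGM = 2^{E[log2 λ|a]}`
via the digamma identity, and `EB05` — flagged when above 2 — is found by
monotone root-finding on the mixture CDF (bracketed above by doubling,
`uniroot` tolerance 1e-10). The default hyperparameters
`(α₁, β₁, α₂, β₂, w) = (0.2, 0.1, 2.0, 4.0, 1/3)` are the published fit to
FDA spontaneous-report data that FAERS studies conventionally reuse;
`fit_mgps_prior()` optionally re-estimates all five by direct maximization
of the marginal negative-binomial likelihood over the full table set
(`nlminb` on log/logit-transformed parameters — the same estimand an EM
pass would target, but more robust for a five-parameter mixture).

**Consensus.** A PT is a consensus signal only when all four flags hold
simultaneously; the rule can therefore never be less conservative than its
most conservative member. Results are ranked by descending ROR, ties broken
by larger `a`, then PT alphabetically, so exports are deterministic.

## Time to onset

Time to onset (TTO) is the interval from therapy initiation (the earliest
complete start date among the report's PS-drug therapy rows) to the
report's event date, one value per report. Reports with a missing date, a
partially known date (year or year–month precision), or an event preceding
therapy are excluded and tallied per reason — exclusions are data, not
errors.

The included onsets are fitted by maximum likelihood to the two-parameter
Weibull density `f(t) = (β/α)(t/α)^{β−1} e^{−(t/α)^β}`. The fit is obtained
with `fitdistrplus::fitdist` and then polished to the exact MLE through the
profile score equation in the shape (the scale follows in closed form),
which makes the scale-equivariance property `fit(k·t) = (k·α, β)` hold to
numerical precision. 95% Wald intervals are computed on the log parameters
from the observed information and back-transformed — the log scale respects
positivity; a natural-scale Wald interval would differ slightly for small
`n` and is the main sensitivity in this choice. Zero-day onsets (event on
the start date) are shifted to 0.5 days *in the likelihood only* to guard
`log 0`; the empirical median and IQR always use the raw values.

The failure type reads the shape CI against 1: *early* (decreasing hazard)
when the upper bound is below 1, *wear-out* when the lower bound exceeds 1,
otherwise *random*. Onset counts are also bucketed into the conventional
0–30 / 31–60 / … / 181–360 / >360-day histogram, right-inclusive.

## Subgroups and sex differences

Subgroup screens restrict both populations to a stratum — sex, age group
(the three-bin scheme and the binary <65 / ≥65 split are both first-class),
or serious vs non-serious report type — rebuild the tables, and screen with
the ROR criterion alone, ranked by frequency for top-k listings. Reports
with unknown sex or age are excluded from the respective axes rather than
imputed.

The sex-difference analysis compares, within target-drug reports, females
against males per PT: ROR > 1 with CI lower bound > 1 is *female-biased*,
ROR < 1 with upper bound < 1 *male-biased*. P-values come from the
chi-square test, falling back to Fisher's exact test when any expected cell
is below 5; Benjamini–Hochberg adjustment across tested PTs supplies the
FDR q-values, and `log2_ror` / `−log10 p` columns make the result
volcano-ready.

## The synthetic corpus

`generate_corpus()` emits the exact dialect the ingest functions read, so
every pipeline stage is testable without the multi-gigabyte FAERS download.
Each report draws its PT set as independent Bernoulli trials: a planted
association `(PT, rr, baseline)` appears in target reports with probability
`min(1, rr · baseline)` and in background reports with `baseline`; a report
with no sampled event receives one draw from the background pool, since
real reports always carry at least one reaction. Contamination is injected
deliberately: a fraction of cases is re-emitted as a superseded earlier
version (same CASEID, smaller PRIMARYID, earlier receipt date), extra cases
are emitted and placed on the deleted list, and a fraction of reports loses
one onset date. Onset intervals are Weibull draws rounded to whole days;
day-0 onsets are left in, since their handling is the fitting stage's
decision. Ground truth is written as a sidecar record that the analysis
path never reads.

Defaults are the validated study conditions: 563 target reports, onset
Weibull scale 45.74 days and shape 0.63, 44% unusable onset dates, and the
sex/age/country/reporter/outcome mix of the study's characteristics table
(outcome codes are multi-valued per report, so they are per-code
probabilities rather than a simplex). Where no study value exists a
realistic one was fixed once: 20,000 background reports (a desk-scale
background; real FAERS has millions, which only narrows the background
margins), 5% duplicate cases, 1% deleted cases, four quarters, and six
planted antifolate-class toxicities with relative rates 6–20 against a 1%
baseline.

What the generator does **not** model: correlation between PTs within a
report, drug–drug interactions, secular reporting trends, country-specific
reporting cultures, or notoriety effects. Passing tests therefore
demonstrate that the statistical machinery recovers known structure from
realistically contaminated input — not that real FAERS data are free of the
biases (under-reporting, confounding by indication) inherent to spontaneous
reports.

## Validation design and problem sizes

Every statistic is checked two ways: against hand-frozen arithmetic on
fixed tables, and against an independent oracle — brute-force nested-loop
counting for contingency tables, `chisq.test` for the chi-square, a
100,000-draw posterior simulation for the information component, a
million-sample posterior for EB05 (agreement within 0.01), and a 200×200
grid search of the Weibull likelihood. Stochastic recovery checks use the
study's own scale: 200 replicates of n = 316 onsets from Weibull(45.74,
0.63) recover the mean shape within ±0.05 and the mean scale within ±3
days; generator calibration uses 200 seeds of a 400/1,500-report corpus
with a null planted rate; null-consensus conservativeness uses ten
corpora of 300/3,000 reports with 30 null PTs. These sizes were chosen so
the whole suite runs in a few minutes on a laptop while leaving the
Monte-Carlo resolution well below the tolerances being asserted.

## Known limitations

* Disproportionality is hypothesis generation: a consensus signal is a
  reporting imbalance, not an incidence estimate or a causal claim.
* The Weibull fit uses observed onsets only; there is no censoring model
  for patients still on therapy.
* The closed-form information component is an approximation with a
  validity domain (`a ≥ 3`); the Monte-Carlo path is the definition.
* The deduplication rule trusts CASEID; cross-CASEID duplicates (the same
  patient reported by two senders) are out of scope, as is any
  record-linkage heuristic.
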