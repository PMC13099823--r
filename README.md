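# faersignal

Pharmacovigilance signal detection for FAERS-style spontaneous
adverse-event report archives, built for drug-safety analysts who want the
complete working chain — cleaning, disproportionality analysis, onset-time
modelling, subgroup screens — as reusable, tested R functions rather than
one-off scripts.

Spontaneous reporting databases have no denominator, so the package
estimates *disproportionality*: for each preferred term (PT) it forms the
report-level 2×2 table

|              | PT  | other PTs |
|--------------|-----|-----------|
| target drug  | a   | b         |
| other drugs  | c   | d         |

and computes four statistics with their conventional thresholds —

* **ROR** = ad/bc, flagged when a ≥ 3 and the 95% Wald CI lower bound > 1;
* **PRR** = [a/(a+b)]/[c/(c+d)], flagged when a ≥ 3, PRR ≥ 2 and the Yates
  χ² ≥ 4;
* **IC** (BCPNN information component) = log₂ p(x,y)/(p(x)p(y)) under
  unit-information beta priors, computed by seeded posterior simulation,
  flagged when IC025 > 0;
* **EBGM/EB05** (multi-item gamma-Poisson shrinker) with the standard
  two-gamma mixture prior, flagged when EB05 > 2 —

and declares a **consensus signal** only when all four flags hold. Around
that core it provides FAERS ASCII ingestion with case-level deduplication
and deleted-report removal, report-level time-to-onset analysis with a
Weibull maximum-likelihood fit and failure-type classification (shape CI
against 1), sex/age/report-type stratified screens with an FDR-adjusted
sex-difference test, descriptive characteristics and SOC tables, and a
synthetic FAERS-shaped corpus generator with planted signals for
end-to-end validation.

## Worked example

Generate a synthetic corpus under the package's default study conditions
(563 target reports, 20,000 background reports, six planted
antifolate-class toxicities, Weibull onset times with scale 45.74 days and
shape 0.63, plus duplicate/deleted/missing-date contamination) and run the
whole pipeline:

```r
library(faersignal)
spec <- planted_signal_spec(n_target = 563, n_background = 20000, seed = 42)
run <- run_pipeline(pipeline_config(synthetic = spec, n_draws = 1e4))
run
#> <pipeline_run>
#>   reports after cleaning: 20563 (1028 duplicates, 206 deleted removed)
#>   target / background:    563 / 20000
#>   consensus signals:      6 of 36 PTs evaluated
#>   onset records:          302

sig <- run$signals
head(sig[sig$consensus, c("pt", "a", "ror", "ror_lo", "prr", "ic025", "eb05")], 6)
#>                           pt   a   ror ror_lo   prr ic025 eb05
#> 1                 stomatitis 116 17.89  14.14 14.41  2.96 8.92
#> 2       mucosal inflammation  80 14.96  11.40 12.98  2.74 7.97
#> 3           thrombocytopenia  81 12.23   9.39 10.62  2.57 6.88
#> 4 neutrophil count decreased  58  8.27   6.15  7.52  2.11 5.03
#> 5 toxic epidermal necrolysis  35  5.07   3.53  4.82  1.43 3.20
#> 6                    anaemia  35  4.88   3.40  4.64  1.40 3.09

run$tto$fit
#> Weibull time-to-onset fit (n = 302)
#>   median (IQR): 24.00 (5.25, 71.50) days
#>   scale alpha : 45.43  [37.90, 54.46]
#>   shape beta  : 0.658 [0.603, 0.717]
#>   failure type: early
```

The cleaning stage removed exactly the 1,028 injected duplicate versions
and 206 deleted cases; all six planted associations — and only they — come
out as consensus signals, ranked by descending ROR with their contingency
counts and all four statistics; and the onset fit recovers the generating
Weibull parameters, with a shape CI entirely below 1 classifying the drug
as an early-failure (decreasing-hazard) profile.

Real archives are analysed the same way: point `pipeline_config(input_dir
= ...)` at a directory of quarterly `$`-delimited tables (one subdirectory
per quarter) with a deleted-case list and PT→SOC / drug-synonym mapping
files, or call the stage functions (`read_faers_table`,
`deduplicate_reports`, `assemble_cases`, `build_contingency_tables`,
`detect_signals`, `compute_tto`, `fit_weibull`, `stratified_signals`,
`sex_difference`, …) directly.

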