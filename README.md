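# faersignal

Pharmacovigilance signal detection and time-to-onset analysis for
FAERS-style spontaneous adverse-event reports, built around the
post-marketing safety profile of pentosan polysulfate sodium (PPS) — the
only FDA-approved oral therapy for interstitial cystitis / bladder pain
syndrome, whose long-latency pigmentary maculopathy made it a canonical
signal-detection case.

The package is for pharmacoepidemiologists and biostatisticians who need a
tested, reproducible R pipeline for spontaneous-report data: it ingests the
FAERS quarterly ASCII tables (DEMO, DRUG, REAC, OUTC, THER), applies the
FDA-recommended key-based deduplication (per CASEID keep the highest
FDA_DT, then the highest PRIMARYID), matches the suspect drug by synonym
list, and computes:

* **Disproportionality signals** per preferred term (PT) on the case-level
  2×2 table — ROR = ad/bc with a 95% Wald CI on the log scale,
  PRR = [a/(a+b)]/[c/(c+d)], Pearson χ², Haldane–Anscombe correction for
  zero cells — flagged by the joint criteria *a* ≥ 3, CI low > 1, PRR ≥ 2
  and χ² ≥ 4, with top-k rankings overall and per system organ class.
* **Sex-differential signals** on the female-vs-male 2×2 table within the
  drug's reports, with Wald p-values, Benjamini–Hochberg FDR control, and
  volcano-plot coordinates (log2 ROR vs −log10 adjusted p).
* **Outcome seriousness** (death > life-threatening > disability >
  hospitalization > congenital anomaly > other serious) and a
  clinical-characteristics table (sex, age bands, reporter, country, year,
  outcomes) with family-sum percentages.
* **Time-to-onset (TTO)** from therapy start to event with explicit
  exclusion accounting, Kaplan–Meier estimation, maximum-likelihood
  Weibull / log-normal / log-logistic fits, AIC/BIC model selection with
  Anderson–Darling statistics, and hazard-regime classification from the
  Weibull shape β (β < 1 with CI below 1 ⇒ decreasing hazard, the
  early-failure pattern).

A built-in synthetic FAERS-like generator (`simulate_faers()`) with known
ground truth — injected drug–event multipliers, a ~12:1 female-skewed
cohort, duplicate case versions, partial/missing dates, Weibull onset times
— makes every stage testable without downloading the database. See the
methods vignette (`vignettes/faers-pharmacovigilance.Rmd`) for the models,
assumptions and design decisions.

## Worked example

```r
library(faersignal)

cfg <- sim_config(n_reports = 5000, seed = 42)   # emulated study conditions
pl  <- run_pipeline(cfg)
pl
#> faersignal pipeline run
#>   raw demo rows: 5745; deduplicated cases: 5000; target cases: 2478
#>   positive signals: 8 PTs
#>   TTO-eligible records: 676; best family: weibull; hazard: decreasing/early-failure
```

5,745 raw report versions collapse to 5,000 unique cases; 2,478 have PPS as
primary suspect. The strongest disproportionality signals are the injected
eye-disorder terms:

```r
rank_top_pts(pl$signals, k = 2)[, c("pt", "a", "ror", "ror_low", "prr", "is_signal")]
#>   pt                         a    ror ror_low    prr is_signal
#> 1 MACULOPATHY              793 131.     67.9   89.7  TRUE
#> 2 PIGMENTARY MACULOPATHY   560 368.     91.7  285.   TRUE
```

so maculopathy is reported with PPS at 131 times the odds of the
all-other-drugs comparator, and the 95% CI lower bound (67.9) is far above
1. The sex screen recovers the built-in pattern — maculopathy terms
female-predominant after FDR:

```r
pl$gender[1:2, c("pt", "ror", "p_adj", "direction")]
#>   pt                      ror     p_adj direction
#> 1 MACULOPATHY            5.52  6.51e-10 female
#> 2 PIGMENTARY MACULOPATHY 5.28  1.07e-06 female
```

The onset profile is long-latency: a median of about 5 years, with
three-quarters of events after the first year, and the Weibull model
selected by AIC with shape well below 1:

```r
pl$tto_summary[, c("n", "median_days", "q1_days", "q3_days", "pct_over_year")]
#>     n median_days q1_days q3_days pct_over_year
#> 1 676       1816.    406.   5343.            76

pl$model_comparison[, c("family", "aic", "bic", "rank")]
#>   family         aic    bic  rank
#> 1 weibull     12442. 12451.    1
#> 2 loglogistic 12531. 12540.    2
#> 3 lognormal   12549. 12558.    3

tidy(pl$fits$weibull)
#>   term  estimate conf.low conf.high
#> 1 alpha 3212.      NA        NA
#> 2 beta     0.607    0.573     0.644

pl$hazard_class
#> [1] "decreasing/early-failure"
```

A shape of 0.61 with the whole CI below 1 classifies the hazard as
decreasing over time: the per-day chance of a *new* report is highest early
in therapy, even though individual events (the maculopathy terms
especially) arrive years in. `autoplot(pl$km)` draws the Kaplan–Meier
curve and `plot_volcano(pl$gender)` the sex-difference volcano.

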