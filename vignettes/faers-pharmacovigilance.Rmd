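---
title: "Methods: disproportionality and time-to-onset analysis of FAERS-style spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality and time-to-onset analysis of FAERS-style spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
library(dplyr)
```

`faersignal` implements a complete pharmacovigilance workflow for
spontaneous adverse-event reports in the FAERS quarterly ASCII format, with
pentosan polysulfate sodium (PPS) as the reference suspect drug. This
vignette is the package's account of the statistics it computes, the
assumptions behind them, and the design decisions taken where the
methodology was genuinely open.

## Ingestion and deduplication

FAERS distributes `$`-delimited tables (DEMO, DRUG, REAC, OUTC, THER) with
no quoting mechanism. Parsing is forgiving by design: unknown columns are
preserved as character, and any date that is not a complete, valid
`YYYYMMDD` string parses to `NA`. Partial dates (`YYYYMM`) are treated as
missing *everywhere*, not only in the time-to-onset stage where their
exclusion is mandatory; a uniform rule is simpler and strictly more
conservative than guessing a day of month.

Duplicate report versions are resolved by the FDA-recommended key rule: per
CASEID keep the version with the highest FDA_DT, breaking ties by the
highest PRIMARYID. PRIMARYIDs are compared with a numeric-aware total order
(digit-only identifiers numerically, mixed identifiers lexicographically):
real identifiers are numeric, but the comparison must be total to be a
well-defined sort key. Deduplication is idempotent and never increases the
record count — both properties are tested.

Suspect-drug matching uses whole-field equality after trimming,
case-folding, and collapsing internal whitespace, against a synonym list
(`pps_synonyms()` carries the twelve ELMIRON/PPS name variants). Only rows
with role code `PS` (primary suspect) match; concomitant and interacting
roles are excluded. Reports are deliberately *not* filtered by indication,
so off-label use is retained. Ages are normalised to years from the
`AGE_COD` unit (`YR`, `DEC`, `MON`, `WK`, `DY`, `HR`); an unknown unit or
an implausible result (outside 0–130 years) becomes missing.

## Disproportionality statistics

Signal detection counts unique deduplicated *cases* in a 2×2 table per
preferred term (PT): `a` target drug with the event, `b` target drug
without, `c` all other drugs with, `d` all other drugs without. The
comparator is the full set of deduplicated cases whose primary-suspect set
does not contain the target drug. The two measures are

$$\mathrm{ROR} = \frac{a d}{b c}, \qquad
  \mathrm{PRR} = \frac{a/(a+b)}{c/(c+d)},$$

with a Wald interval on the log ROR,
$\exp\{\ln \mathrm{ROR} \pm z\,\sqrt{1/a + 1/b + 1/c + 1/d}\}$ at
$z = 1.96$. The CI construction is a package choice (the criterion the
method prescribes only involves the interval's lower bound, not its
derivation); the Rothman Wald form is the standard in disproportionality
work. When any cell is zero, the Haldane–Anscombe correction adds 0.5 to
all four cells and the result is flagged `corrected`; with the correction
disabled a zero-cell estimate is `NA`, never an error. The chi-square is
the Pearson statistic without continuity correction (a `yates` switch is
provided); it is computed from the closed form
$n(ad-bc)^2/[(a+b)(c+d)(a+c)(b+d)]$ and tested against a brute-force
$\sum (O-E)^2/E$ on 1,000 random tables.

A PT is a *positive signal* when all three criteria hold: at least 3
reports ($a \ge 3$), ROR 95% CI lower bound above 1, and PRR $\ge 2$ with
$\chi^2 \ge 4$. Whether a joint or either-or combination is intended is
ambiguous in the source methodology; the package computes per-criterion
flags and defaults to the conservative joint AND (`rule = "either"` is
available). Reporting percentages use the number of target-drug cases as
denominator. Per-SOC summaries keep the top `k` signals by ROR within each
system organ class; PTs absent from the user-supplied PT→SOC map are
grouped under `UNMAPPED` (the licensed MedDRA dictionary cannot be shipped,
so the map is an input).

## Sex-differential signals

The gender screen contrasts females and males *within* the target-drug
cohort: `a` females with the PT, `b` females without, `c`/`d` the male
analogues; unknown-sex cases are excluded from this analysis only. The ROR
and CI are as above; the p-value is the two-sided normal probability of
$z = \ln(\mathrm{ROR})/\mathrm{SE}(\ln \mathrm{ROR})$ — the test is a
package choice since none is prescribed. The
family for Benjamini–Hochberg FDR adjustment is every PT with
$a + c \ge 3$ among target-drug reports, mirroring the 3-report floor of
the main analysis. A PT is female-predominant when the adjusted p-value is
below $\alpha$ and the CI lower bound exceeds 1, male-predominant in the
mirrored case. Volcano coordinates are $x = \log_2 \mathrm{ROR}$ and
$y = -\log_{10} p_{\mathrm{adj}}$ with the adjusted p floored at $10^{-300}$
so coordinates stay finite.

## Outcomes and characteristics

Each case receives exactly one seriousness category, the
highest-precedence outcome code present:
death (`DE`) > life-threatening (`LT`) > disability (`DS`) >
hospitalization (`HO`) > congenital anomaly (`CA`) > other serious
(`OT`). The mutually exclusive published counts do not state a precedence;
this order makes the most severe outcome dominate. The `RI` (required
intervention) code is treated as the "other serious" tier. A case with no
OUTC record is "unknown/non-serious". Characteristics tables use completed
years for the age bands (`<18`, `18–64`, `>=65`, unknown), the calendar
year of the retained version's FDA_DT, and family-sum denominators: within
each stratum family the counts sum to the case total and percentages to
100 ± rounding. Percentages are rounded half-away-from-zero at one decimal,
matching regulatory-table conventions.

## Time-to-onset analysis

TTO is the whole-day interval from the earliest parseable therapy start of
the suspect drug (THER `START_DT`) to the event date (DEMO `EVENT_DT`).
Records with missing event dates, missing start dates, or events preceding
the start are excluded and tallied. A same-day onset (0 days) is remapped
to 0.5 days so that log-time models remain defined — only events *before*
the start are invalid — with `zero_onset = "exclude"` available.

Quartiles use linear interpolation (R's type-7 default; the quantile rule
is unstated in the source methodology). The Kaplan–Meier curve is computed
by `survival::survfit` with every included record an event: spontaneous
reports carry no follow-up, so there is no censoring in the base analysis,
and the KM estimate then equals one minus the empirical CDF exactly (an
identity the tests assert); a status vector is accepted for generality.

Three parametric families are fitted by maximum likelihood:

* **Weibull**, density $f(t) = (\beta/\alpha)(t/\alpha)^{\beta-1}
  e^{-(t/\alpha)^\beta}$ with scale $\alpha$ (days) and shape $\beta$;
* **log-normal**, parameters $(\mu, \sigma)$ on $\ln t$ (closed-form MLE);
* **log-logistic**, survival $S(t) = 1/(1+(t/\alpha)^\beta)$.

The Weibull and log-logistic likelihoods are maximised over
$(\ln\alpha, \ln\beta)$ by BFGS with relative tolerance $10^{-10}$ and an
iteration cap of 500; initial values come from log-time moments
($\mathrm{sd}(\ln T) = (\pi/\sqrt6)/\beta$ for the Weibull,
$(\pi/\sqrt3)/\beta$ for the log-logistic). Standard errors are taken from
the observed information at the optimum and the shape CI is Wald on
$\ln\beta$ — the CI construction is unstated in the source methodology and
is the package's choice. The fits are cross-checked against the
accelerated-failure-time parameterization of `survival::survreg` in the
test suite (the independent route, never the implementation).

Model comparison uses $\mathrm{AIC} = 2k - 2\ell$ and
$\mathrm{BIC} = k\ln n - 2\ell$ with $k = 2$, ranked ascending by AIC with
alphabetical tie-break, and reports the Anderson–Darling statistic
$A^2 = -n - \tfrac1n \sum_i (2i-1)\,[\ln F(t_{(i)}) +
\ln(1 - F(t_{(n+1-i)}))]$ at the fitted parameters (statistic only, no
p-value). The hazard regime is read off the Weibull shape:
$\beta < 1$ with CI entirely below 1 is a decreasing hazard (early-failure
pattern), $\beta > 1$ with CI above 1 increasing (wear-out), anything else
consistent with constant (random failure).

PT-level comparisons (Kruskal–Wallis with tie correction via
`stats::kruskal.test`, and per-PT means) assign each record to *each* of
its PTs, since a multi-PT case has no canonical single event; this
de-overlap choice is documented and the expansion is a separate, tested
helper. Groups with fewer than 3 records are flagged, not dropped.

## The synthetic generator

Real FAERS extracts cannot be redistributed, so the package ships a
generator (`sim_config()` / `simulate_faers()`) whose defaults encode the
reporting profile the package is designed around:

| parameter | default | rationale |
|---|---|---|
| sex mix | 87.3% F / 7.1% M / 5.6% unknown | the reference cohort's mix (≈12.3:1 female:male) |
| TTO | Weibull, scale 3097 d, shape 0.62 | median $\alpha(\ln 2)^{1/\beta} \approx 1715$ d, decreasing hazard |
| outcome codes | OT 68.1%, none 28.4%, HO 2.1%, DS 0.9%, DE 0.3%, LT 0.2% | the reference outcome distribution |
| signal multipliers | eye-disorder PTs 40–400×, alopecia/psychiatric 2.5–4× | qualitative signal hierarchy of the reference profile |
| sex multipliers | maculopathy PTs 3× in females; GI/bladder PTs 3–4× in males | the reference sex-specific pattern |
| `duplicate_rate` | 0.15 | a realistic share of multi-version cases |
| `missing_event_date_rate` / `partial_date_rate` | 0.55 / 0.15 | event dates are missing for most spontaneous reports |
| `target_fraction` | 0.5 | far above any real database share, so signal-detection power is reached at $n \sim 10^4$ instead of $10^7$ |

Each report draws each PT independently (Bernoulli at
`base_rate × drug multiplier × sex multiplier`, capped at 1), which allows
multi-PT reports; a report drawing nothing receives one PT sampled by
baseline rate so every report has a reaction. Duplicate versions share the
CASEID with distinct PRIMARYIDs and FDA_DTs arranged so that all three
dedup branches (later date, tied date/higher id, later date with *lower*
id) occur. Ground truth travels as an attribute, giving the tests an
oracle for dedup, matching, cell counts and TTO eligibility.

What the generator does **not** emulate: calendar-time reporting dynamics
(the notoriety-bias spike of stimulated reporting), reporter-type
correlations with events, country structure beyond a constant mix, and
drug-specific background profiles. Passing tests therefore demonstrate
correctness of the statistical machinery under a known model — not that
real-FAERS magnitudes (e.g. six-figure RORs driven by litigation-era
reporting) would be reproduced, which would require the full database.

## Problem sizes and numerical conventions

The test suite exercises generator cohorts of 100–50,000 reports; the
acceptance script runs the full pipeline at 20,000 reports, where the
Weibull shape is recovered to about ±0.02 and the sex ratio to within
ordinary binomial error. Simulation-based checks use fixed seeds;
stochastic bounds (CI coverage 93–97%, FDR below 5% plus three Monte-Carlo
standard errors, shape recovery within ±0.05 over 20 cohorts of 297) are
stated with their sampling tolerances. Degenerate inputs are contracts,
not crashes: empty tables parse to empty collections, a PT absent from all
cases yields a zero-cell table, zero-cell estimates are `NA` markers when
the correction is off, and single-group Kruskal–Wallis or single-sex
gender screens raise classed errors.

## Limitations

Spontaneous reports carry no exposure denominator, so RORs and PRRs are
reporting associations, not risks; nothing here supports causal or
incidence statements. The dedup rule is key-based only — true duplicates
submitted under different CASEIDs are not detected. Bayesian
disproportionality (BCPNN, MGPS/EBGM), covariate-adjusted or
interval-censored models are out of scope.
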