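---
title: "Disproportionality signal detection and time-to-onset modelling with faersignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection and time-to-onset modelling with faersignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
library(dplyr)
```

## The problem

Spontaneous reporting systems such as FAERS collect voluntary post-marketing
reports of suspected adverse drug events. Each case lists demographics, the
drugs involved (with a role code separating the primary suspect from
concomitant medication), the events coded as MedDRA preferred terms (PTs)
grouped into system organ classes (SOCs), outcomes, and therapy/event dates.
Because reporting is voluntary there is no denominator of exposed patients;
the only question such data can answer is *disproportionality*: is event Y
reported relatively more often with drug X than with everything else in the
database?

`faersignal` implements the standard pharmacovigilance workflow around that
question for a set of target drugs — here, by default, the three proteasome
inhibitors used in multiple myeloma (bortezomib, carfilzomib, ixazomib) and
their neurological adverse events — but every piece is generic: the lexicon,
PT→SOC mapping, SOC of interest and thresholds are all data.

The pipeline is: ingest quarterly `$`-delimited (or CSV) tables →
deduplicate case versions → tag primary-suspect reports via a synonym
lexicon → map PTs to SOCs → score every (drug, PT) pair with four
disproportionality statistics → apply the four-algorithm signal criterion →
rank by frequency and strength → sex-stratified subgroup volcano →
time-to-onset Weibull/KM/log-rank → thalidomide-exclusion sensitivity
re-analysis.

## The fourfold table and the four algorithms

For one drug–event pair the universe of deduplicated report–PT pairs is
collapsed to the 2×2 table

|              | event Y | other events |
|--------------|---------|--------------|
| drug X       | a       | b            |
| other drugs  | c       | d            |

with `N = a+b+c+d` and expected count `E = (a+b)(a+c)/N` under independence.
Counting is at the report–PT *pair* level: a PT repeated inside one report
counts once, and `a+b` equals the drug's total pair count. (Whether b/c/d
should instead count whole reports is genuinely ambiguous in routine
practice; pair-level is the default here and the contingency builder is the
single place where that choice lives.)

The four statistics are the canonical published forms:

* **ROR** `= ad/bc`, with the Woolf interval
  `exp(log ROR ± 1.96·√(1/a+1/b+1/c+1/d))`. A zero cell triggers the
  Haldane–Anscombe correction (0.5 on all four cells) and a flag column;
  the Bayesian statistics need no correction and never receive one.
* **PRR** `= [a/(a+b)]/[c/(c+d)]` with the Yates-corrected Pearson χ²
  (`yates = FALSE` switches it off).
* **IC** (BCPNN information component)
  `= log2((a+½)/(E+½))`, with `IC025` the base-2 log of the 2.5th
  percentile of the `Gamma(a+½, E+½)` posterior of the reporting-rate
  ratio. This is the modern closed-form shrinkage version: it tends to the
  naive `log2(aN/((a+b)(a+c)))` as counts grow, equals 0 at independence,
  and pulls small-count cells toward the null. We chose it over the older
  Dirichlet-prior closed form because the latter over-shrinks moderate
  counts (a table with `a = 10`, `E ≈ 1.09` lands 0.8 bits under the naive
  component; the Gamma-posterior form stays within half a bit).
* **EBGM/EB05** (Gamma-Poisson Shrinker): `a ~ Poisson(λE)` with a
  two-component gamma mixture prior on λ. The five hyperparameters are
  fitted by marginal maximum likelihood over *all* cells of the universe
  (the marginal is a negative-binomial mixture), by Nelder–Mead from five
  documented starts on the log/logit scale, restarting until the
  improvement falls below 1e-8 relative, followed by a BFGS polish. The
  transformed parameters are box-bounded to ±8 and carry a negligible
  quadratic ridge (1e-3), so the mixture cannot collapse onto a point mass
  over a single extreme cell — with only a handful of true signals in a
  universe that degenerate solution is otherwise the likelihood's
  favourite. A fit pinned to the bound is reported as a converged boundary
  maximum (`at_bound = TRUE`): on data whose rate ratios are genuinely
  concentrated at one value, the tightest allowed component *is* the
  maximum-likelihood answer. EBGM is
  the posterior geometric mean `exp(E[log λ | a])`; EB05 is the 5th
  posterior percentile, root-solved from the mixture CDF and verified
  against numerical quadrature in the tests.

**Signal criterion.** A pair is a signal when all four agree:
`a ≥ 3` and ROR lower bound `> 1`; `PRR ≥ 2` and `χ² ≥ 4`; `IC025 > 0`;
`EB05 > 2`. These are the field's conventional thresholds; they are
config-overridable (`signal_criteria()`) because programmes differ.
Conjunction makes the concordant signal set a subset of every single
algorithm's set, which the null-calibration tests confirm empirically.

## Sex subgroup and volcano coordinates

Within one drug's sex-known reports, each PT gets the 2×2 of
(male vs female) × (PT vs other PTs); the ROR (male over female odds, so
`> 1` means male-dominant), a χ² p-value on the same table, and volcano
coordinates `(log2 ROR, −log10 p)`. Reports with missing sex are excluded
and counted. The alternative orientation (drug vs other drugs within each
sex) is a different question; the male-vs-female form matches "higher risk
of occurrence in males" phrasing and is the default. Raw p-values are the
default (the convention in this literature); Benjamini–Hochberg adjustment
is available (`p_adjust = "BH"`), and the significance flag is strict
(`p < α`).

## Time to onset

Latency is event date minus the *earliest* full-precision therapy start of
the tagged drug, in whole days; non-positive or incomplete latencies are
dropped and counted. Year- or month-precision dates are read as missing at
ingestion — fabricating a day would bias latency — but such reports still
count for disproportionality.

Per drug, pooled over the analysed SOC's PTs, a Weibull law is fitted by
maximum likelihood (Nelder–Mead on `(log β, log α)` from a
method-of-moments start; the optimum is checked against that start). 95%
CIs come from the observed information on the log-parameters (delta
method), matching the symmetric intervals conventional in WSP tables. The
hazard class follows the shape interval: **early failure** when `β < 1`
with the interval entirely below 1 (risk falls with time on therapy),
**random** when the interval contains 1, **wear-out** when entirely above
1. An endpoint exactly at 1 classifies as random: the boundary is treated
as compatible with constant hazard.

Spontaneous reports contain only realised onsets, so there is no censoring
model: the Kaplan–Meier cumulative incidence reduces to the empirical CDF
(the curve is still computed through `survival::survfit` for fidelity to
survival practice), and the k-sample log-rank test (`survival::survdiff`)
compares drugs, χ²(k−1) under the null.

## The synthetic-report generator

Every downstream stage is validated against `synth_generate()`, which
emulates the statistical skeleton of a spontaneous reporting system with
known ground truth:

* one primary-suspect drug per case, categorical over 3 targets + 10
  background drugs;
* events drawn from a 40-PT multinomial (20 PTs under "Nervous system
  disorders", the shipped miniature MedDRA-like mapping), tilted
  multiplicatively by planted (drug, PT, rrr) associations and by male-odds
  multipliers;
* per-drug Weibull onset laws; onset days are `ceiling`-ed to whole days
  ≥ 1, matching the integer-day ranges of onset tables;
* sex Bernoulli(0.5) before missingness; configurable missingness for sex
  and age; country/reporter as independent categoricals (their joint
  structure is deliberately not modelled);
* a fraction of cases duplicated as an extra earlier-dated, lower-version
  case copy that differs *only* in version id and receipt date, so
  deduplication correctness is isolable;
* thalidomide-style concomitant co-mentions on a fraction of bortezomib
  cases, for the sensitivity stage.

The defaults are the study conditions the package validates itself under:
20,000 cases; target shares 0.10/0.045/0.055 (the relative report volumes
of the three drugs against a large background universe); planted
(bortezomib, "Neuropathy peripheral", rrr 20); sex effect (bortezomib,
"Polyneuropathy", ×3 male); onset laws β/α = 0.70/68.8, 0.61/81.9,
0.65/153.5 days for bortezomib/carfilzomib/ixazomib and β = 1, α = 90 for
background drugs; 5% duplicates; 10% co-mentions; 15% missing sex, 30%
missing age. One seed drives everything (stage seeds are derived from it),
so a config + seed pair reproduces the bundle byte-for-byte.

What passing on this generator does *not* show: real FAERS data have
misspelled drug names, correlated demographics, duplicated cases that
differ in content, partial dates in bulk, and PT vocabularies four orders
of magnitude larger. The generator validates the statistical machinery and
the plumbing contracts, not robustness to real-world dirt.

## Numerical choices and degenerate inputs

* Empty margins in a fourfold table raise a degenerate-table error rather
  than returning NaN; a zero *cell* only triggers the flagged ROR
  correction.
* GPS: five documented starts, ±8 box bounds (transformed scale),
  restart-until-stall convergence at 1e-8 relative; non-convergence warns
  and returns the last iterate with `converged = FALSE`.
* Weibull MLE refuses all-equal samples (shape unidentifiable) and samples
  below `n_min = 10`.
* Quantiles are type-7 throughout (R's default linear interpolation).
* Percentages in descriptive tables are rounded half-up to one decimal, the
  convention of clinical baseline tables; `round_half_up()` is exported
  because R's `round()` rounds half to even.
* Ranking ties break by the other key (frequency↔ROR), then PT
  alphabetically, so output order is total and stable.
* Deduplication keeps the latest receipt date per case id, ties broken by
  the greatest version id — the FAERS case drill-down convention.

## Validation scale

The test-suite simulations use the full 20,000-case study conditions with
100 seeds for the calibration, power, Weibull-recovery and log-rank suites
(200 for the null uniformity of log-rank p-values); smaller universes
(5,000–8,000 cases) back the unit-level property checks. The acceptance
script (`scripts/acceptance.R`) re-runs the same analyses at 50 replicates
per quantity. These sizes give Monte-Carlo error comfortably below the
asserted margins (binomial standard error ≤ 2.2 points at 100 seeds for a
95% rate).

## Known limitations

* No indication-based filtering, no MedDRA hierarchy beyond PT→SOC, no
  regression-adjusted disproportionality, no IC temporal scan.
* The sensitivity stage models exclusion of one named concomitant drug;
  multi-drug adjustment is out of scope.
* Report-level vs pair-level b/c/d counting changes denominators slightly;
  only pair-level is wired into `signal_stats()` (the builder is isolated
  so the alternative is a local change).
* With no censoring, KM adds nothing beyond the ECDF — it is kept for
  interface fidelity with survival tooling.
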