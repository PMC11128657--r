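---
title: "Methods: disproportionality screening and onset kinetics in faersignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality screening and onset kinetics in faersignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

# The problem

A spontaneous-report database such as FAERS collects suspected
adverse-event reports, each naming one or more drugs (with role codes —
primary suspect, secondary suspect, concomitant, interacting) and one or
more MedDRA-coded reaction terms. There is no exposure denominator, so
incidence is undefined; the only quantity available is *reporting
disproportionality*: is the fraction of reports mentioning event Y
larger among reports of drug X than in the rest of the database? A pair
that clears several disproportionality thresholds at once is a *signal
of disproportionate reporting* — a hypothesis for pharmacovigilance
follow-up, emphatically not a causal claim.

`faersignal` implements that workflow for one target drug at a time,
plus the onset-kinetics analysis that usually accompanies it (how soon
after therapy start do the events occur, and does the hazard fall or
rise with time on drug?).

# Case assembly and deduplication

FAERS quarterly extracts are five `$`-delimited ASCII tables keyed by
`primaryid`. The same underlying case (`caseid`) reappears whenever a
report is revised, as a new `primaryid` with an incremented
`caseversion` — possibly in a later quarter. We therefore concatenate
all quarters *before* deduplicating, and keep, per `caseid`, the row
with the highest `caseversion`, breaking ties by the largest
`primaryid`. This is the FDA-documented convention; the package exposes
the counts removed at every step (repeated `primaryid` rows, reports
with no reaction term, superseded versions) so the filter funnel in the
run report always reconciles: retained + removed = input.

Ages arrive as a value plus a unit code; we convert
`DEC/YR/MON/WK/DY/HR` to years and treat anything unparseable or
outside [0, 130] years as missing. Dates are digit strings classified
as `full` (valid `YYYYMMDD`), `year_month`, `year_only`, or `invalid`;
`parse_date()` never raises, because downstream rules (below) depend on
the completeness class, not on parse success.

# Cohort extraction and the descriptive table

Drug names in spontaneous reports are free text. Names are normalized
(upper-case, whitespace collapsed, `HYDROCHLORIDE`/`HCL` salt tokens
stripped) and matched against a synonym dictionary. The default
matching mode is *substring containment of a normalized synonym*:
against a synonym list of brand and generic names this captures the
dose/form suffixes that dominate real variation ("BENDEKA 100MG")
while producing far fewer false positives than edit-distance matching
across an entire drug vocabulary. An edit-similarity mode
(`1 - distance/max(nchar)` against each synonym, default threshold
0.9) is available for dirtier sources. A report counts once no matter
how many of its drug rows match.

The descriptive table follows case-series convention: per category
(age bands <18 / 18–64 / ≥65, gender, severe-outcome levels, reporter
occupation, top-k countries, reporting year), counts and percentages
with the category's *available* (non-missing) count as denominator,
plus a percentage of the whole cohort. Percentages are rounded half-up
to two decimals, since that is how such tables are printed and checked
by hand. A report with several outcome codes is classified once by
severity priority (death > life-threatening > hospitalization >
disability > other); reporter codes map `MD`→physician,
`PH`→pharmacist, `CN` and `LW`→consumer, `HP`→health professional,
`OT`→other health professional.

# The four disproportionality statistics

All statistics are computed on per-term 2×2 tables whose counting unit
is the unique deduplicated report; `a ≥ 1` is required (a term never
reported with the drug is not a candidate signal).

* **ROR** = ad/bc, CI = exp(ln ROR ± z·√(1/a+1/b+1/c+1/d)). Any zero
  cell triggers the Haldane–Anscombe +0.5 on *all four* cells, and the
  row is flagged `corrected`.
* **PRR** = [a/(a+b)]/[c/(c+d)], same zero-cell treatment. The
  accompanying χ² is the Yates-continuity-corrected Pearson statistic
  on the uncorrected table — the convention under which the
  PRR ≥ 2 ∧ χ² ≥ 4 ∧ n ≥ 3 rule was calibrated; a flag switches to the
  plain Pearson statistic.
* **IC** (BCPNN information component) = log2((a+½)/(E+½)) with
  E = (a+b)(a+c)/N. The signal gate uses its lower credibility bound.
  The default is the closed-form approximation
  IC − 3.3(a+½)^−1/2 − 2(a+½)^−3/2, which approximates the 2.5th
  percentile of the gamma posterior λ ~ Gamma(a+½, E+½) on the log2
  scale; the exact quantile at 2.5% or 5% is available
  (`method = "quantile"`), since the literature's "IC05" is ambiguous
  between the two conventions. Across realistic tables the closed form
  and the exact 2.5% quantile agree within 0.05 log2 units (verified in
  the test suite), so the choice rarely flips a signal.
* **EBGM/EB05** — the empirical-Bayes gamma-Poisson shrinker, described
  next.

The combined criterion is the conjunction PRR ≥ 2, χ² ≥ 4, a ≥ 3,
IC lower bound > 0, EBGM > 2 ("at least" thresholds are ≥, the others
strict). No multiplicity adjustment is applied: the criterion is a
fixed operating rule, not an inference procedure, and we follow that
practice while noting that the false-positive rate over thousands of
terms is governed by the conjunction, not by any per-term error rate.
Rankings are emitted twice — by case count and by ROR CI lower
bound — each with the other statistic as tie-break, because the two
orderings answer different questions (burden vs. strength of evidence).

## The gamma-Poisson shrinker

Small-count pairs make raw ratios explode; the multi-item gamma-Poisson
shrinker stabilizes them. The relative reporting rate λ of a pair is
modelled as a draw from a two-component gamma mixture (shape/rate
parameterization), and `a | λ ~ Poisson(λE)`. Marginally `a` is a
mixture of negative binomials; `fit_gps_prior()` maximizes that
marginal likelihood over all drug–event pairs of the corpus (not just
the target drug's — the prior describes the whole database). The
posterior is again a gamma mixture with component j updated to
Gamma(α_j + a, β_j + E) and weights ∝ w_j·NB_j(a); EBGM is the
posterior geometric mean exp(E[ln λ]), and EB05 the 5th posterior
percentile found by root-finding on the mixture CDF (tolerance 1e-6
relative to the bracket).

Numerical choices: parameters are optimized on the log scale (logit
for the weight) so the search is unconstrained; five fixed starting
points (including the classic α₁=0.2, β₁=0.1, α₂=2, β₂=4, w=⅓) are
each run through Nelder–Mead then polished with BFGS, and the best
optimum wins — the procedure is fully deterministic. Components are
relabelled so component 1 has the smaller prior mean. By default the
likelihood is untruncated and fitted on the observed pairs (a ≥ 1);
a zero-truncation flag is provided for compatibility with variants
that model the a ≥ 1 restriction explicitly. Inputs with (nearly)
constant counts are rejected as unidentifiable rather than fitted
silently.

# Time to onset and the Weibull shape test

Onset is the day count from the *earliest complete* therapy-start date
of a target-drug row to the event date. Records are excluded — with an
explicit reason, in the priority order incomplete start, incomplete
event, negative onset — when either date is not a full calendar date or
the event precedes the start (a data-entry error in spontaneous
reports). The monthly histogram uses 30-day bins (month 1 = days 0–30
inclusive, month m = days (30(m−1), 30m], month 12 extended to day
365) with ">1 year" strictly beyond 365 days; quartiles are type-7
(linear interpolation), the R default, as the convention is rarely
stated in published tables.

Per SOC, included onsets are fitted with a two-parameter Weibull by
maximum likelihood (log-parameter BFGS after a Nelder–Mead pass; a
moment-style start from the log-time spread). Day-resolution data
contain zeros, which are incompatible with a continuous Weibull
likelihood when β < 1, so the pipeline adds 0.5 day before fitting —
the interval-midpoint treatment of interval-censored day counts
(configurable; `weibull_mle()` itself defaults to no shift for
continuous data). The shape CI is the observed-information normal
approximation on log β, hence always positive. The hazard class is
CI-based: `early_failure` when the CI upper bound is below 1 (hazard
demonstrably decreasing), `late_failure` when the lower bound exceeds
1, `constant` otherwise — a point estimate of 0.95 on 30 records is
not evidence of early failure, and the CI rule encodes that. The
three-parameter (location-shifted) Weibull sometimes quoted for onset
data is deliberately out of scope of the default path: with a shift
parameter the likelihood is unbounded as the shift approaches the
minimum observation, and published fits rarely document how that was
handled.

A note on published scale parameters: onset tables in the literature
sometimes print Weibull "scale" values in the single digits next to
medians of tens of days, which is inconsistent with the two-parameter
Weibull median α(ln 2)^{1/β}; such values likely reflect a transformed
parameterization of the originating software. `faersignal` reports α
in days, always. The acceptance script therefore treats published
(n, α, β) triples as *simulation truths* — draw n onsets from that
Weibull, refit, recover β — which is meaningful under any
parameterization of the source, rather than attempting to reproduce a
parameterization the source does not document.

# The synthetic generator

`synth_generate()` emulates the structural features the pipeline must
survive: multi-table cases keyed by report ID; revised case versions
(default 10% of cases, written twice); drug role codes with exactly one
primary suspect per report; Zipf-skewed drug and event frequencies over
the bundled ~78-PT hierarchy; demographic fields with realistic
missingness (18% of ages, 27% of countries); therapy-start dates
uniform over 2017-01 to 2023-06 with onset added on top; 15% of start
and event dates independently blanked or truncated to year-month; 1%
of reports with the event dated before therapy start; and onset times
drawn per primary SOC from a Weibull (default scale 45 days, shape
0.8 — an early-failure profile typical of oncology-drug case series).
Injected disproportionality multiplies the conditional PT probability
by ρ for reports where the target is primary suspect, then
renormalizes; because of the renormalization no finite ρ can push a
probability past 1, so "infeasibility" reduces to validation (ρ ≥ 1,
PT known), and the manifest records the exact realized rate ratio
(slightly below ρ) that tests should expect. All draws come from one
seeded Mersenne-Twister stream in a fixed order, so a (config, seed)
pair is bit-reproducible and `synth_manifest()` regenerates the ground
truth without touching the disk.

What the generator does *not* emulate — and what passing tests
therefore do not establish about real data: drug co-prescription
correlation (real background drugs are not independent), free-text
reaction verbatims needing LLT coding, reporting-rate drift over
calendar time, country- or reporter-specific reporting styles, and
true duplicate reports with *different* identifiers (the kind that
fuzzy record-linkage, out of scope here, is meant to catch).

# Problem sizes and test design

The test suite exercises every statistic against an independent oracle:
closed-form ROR/PRR/IC against direct arithmetic on 1,000 random
tables, χ² against `stats::chisq.test`, EB05 against 10⁶-draw
Monte-Carlo posterior quantiles (1% tolerance), the Weibull MLE against
a dense grid search and against `fitdistrplus`, and the whole pipeline
against the generator manifest. Shared fixtures use a 2,500-report
corpus; the end-to-end injected-signal check uses 50,000 reports with
three ρ = 5 pairs and requires every injected pair to pass the
combined criterion while ≥95% of null terms with a ≥ 3 fail it.
Weibull recovery is checked at n = 665 and n = 621 (shapes 0.76 and
0.84), sizes at which the asymptotic shape SE is ≈ 0.023–0.027, and
across 200 replicates at n = 300 for shapes 0.6–1.3 (mean bias below
0.03). These sizes were chosen so each property is tested at the scale
where its asymptotics are informative while the whole suite stays
interactive.

# Known limitations

* Disproportionality is confounded by co-medication, indication and
  secular reporting trends; no stratified or regression-adjusted
  variant is provided.
* The dedup key collapses revised versions of the same case but cannot
  detect true duplicates submitted under different case IDs.
* PT matching is exact after case-folding; verbatim reaction text and
  LLT-level coding are out of scope.
* The descriptive table reproduces the computation conventions of
  published case-series tables; published tables occasionally contain
  internal inconsistencies (percentages not tracking counts), which
  this package will not reproduce.
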