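# faersignal

Post-marketing safety-signal screening for spontaneous adverse-event
report databases in the FAERS quarterly format.

Spontaneous-report databases have no denominator: you cannot compute an
incidence, only ask whether a drug–event pair is reported *more often
than the database background would predict*. `faersignal` implements
that case/non-case disproportionality workflow end to end for a single
target drug (the bundled defaults target bendamustine, an alkylating
agent used in chronic lymphocytic leukemia and indolent B-cell
non-Hodgkin lymphoma, but any drug dictionary works):

1. **Ingestion** — read the quarterly `$`-delimited DEMO/DRUG/REAC/
   THER/OUTC ASCII tables, assemble multi-table rows into report cases,
   and deduplicate by FAERS case semantics (keep the highest
   `caseversion` per `caseid`, ties broken by largest `primaryid`).
2. **Cohort extraction** — find reports naming the target drug as
   primary suspect via a synonym dictionary (substring, exact, or
   edit-distance fuzzy matching on normalized names), and tabulate the
   cohort demographics with available-case denominators.
3. **MedDRA aggregation** — map Preferred Terms to their primary System
   Organ Class and resolve Standardised MedDRA Query membership (a
   small synthetic hierarchy ships with the package; supply your
   licensed MedDRA export as a TSV for real analyses).
4. **Disproportionality** — for each event term, build the 2×2 table

   |              | event | other events |
   |--------------|-------|--------------|
   | target drug  | a     | b            |
   | other drugs  | c     | d            |

   and compute four statistics: the reporting odds ratio
   ROR = ad/bc with log-normal 95% CI; the proportional reporting ratio
   PRR = [a/(a+b)]/[c/(c+d)] with Yates-corrected χ²; the BCPNN
   information component IC = log2((a+½)/(E+½)), E = (a+b)(a+c)/N, with
   its closed-form lower credibility bound; and the empirical-Bayes
   geometric mean EBGM with 5th posterior percentile EB05 under a
   two-component gamma-mixture prior fitted by maximum marginal
   likelihood across all drug–event pairs of the corpus.
   A term is flagged as a signal when **PRR ≥ 2 ∧ χ² ≥ 4 ∧ a ≥ 3 ∧
   IC lower bound > 0 ∧ EBGM > 2**, and signals are ranked both by case
   count and by the ROR CI lower bound.
5. **Time to onset** — days from the earliest fully dated therapy start
   to the event date (partial dates and event-before-start records are
   flagged, never silently dropped), summarised as median/IQR, monthly
   bins and an empirical CDF, then fitted per SOC with a two-parameter
   Weibull; the shape parameter β classifies the hazard (β CI below 1:
   early failure / decreasing risk; above 1: late failure).
6. **Synthetic data** — a deterministic generator
   ([`synth_generate()`]) emits corpora in the exact on-disk dialect
   together with a ground-truth manifest (true counts, injected
   disproportionality ratios, true onset days), so every stage above is
   testable without downloading a single FAERS archive.

## Worked example

```r
library(faersignal)

dir <- tempfile("faers-demo")
cfg <- synth_config(
  n_reports = 20000, seed = 2024,
  injected_pairs = data.frame(pt = c("Neutropenia", "Stevens-Johnson syndrome"),
                              rho = 5))
manifest <- synth_generate(cfg, dir)

corpus <- deduplicate(read_quarter(manifest$files))
#> <faers_corpus> 20000 reports | 51057 drug rows | 40274 reaction rows
#>   dedup: 21981 in -> 20000 retained ( 1981 duplicate versions removed )

cases <- extract_cases(corpus, drug_dictionary(), role = "PS")
#> <case_set> 822 reports with BENDAMUSTINE in role PS

hier <- read_hierarchy()
sig <- compute_signals(cases, corpus, level = "pt", hierarchy = hier)
rank_top(sig, k = 5)$by_count[, .(term, a, ror, ror_l, prr, chi2, ic_lower, ebgm, is_signal)]
#>                        term     a      ror    ror_l      prr     chi2 ic_lower     ebgm is_signal
#> 1:              NEUTROPENIA   140 4.907491 4.035530 4.241982 304.5163 1.610657 3.383515      TRUE
#> 2: STEVENS-JOHNSON SYNDROME    79 4.414992 3.438269 4.086787 158.1975 1.462080 3.383514      TRUE
```

The two event terms whose conditional reporting rate the generator
inflated fivefold are exactly the ones that pass the combined
criterion: both show an observed-to-expected ratio near 5 (ROR ≈ 4.4–4.9
after margin effects), χ² far above 4, a positive IC lower bound, and an
EBGM shrunk toward — but well above — the null. No other term is
flagged.

```r
rec <- compute_tto(cases)
summarize_tto(rec)
#> <tto_summary> n=602 | median 32 (IQR 11-65) | range 0-813 days
#> (48.5% of onsets in treatment month 1, 24.8% in month 2, ...)

fit_tto_weibull(compute_tto(cases, hier))[1:2, .(soc, n, alpha, beta, beta_l, beta_u, hazard_class)]
#>                                     soc     n    alpha      beta    beta_l   beta_u hazard_class
#> 1:          Infections and infestations   273 47.31715 0.9158061 0.8343480 1.005217     constant
#> 2: Blood and lymphatic system disorders   187 42.90171 0.9247130 0.8282290 1.032437     constant
```

The generator drew onsets from a Weibull with scale 45 days and shape
0.8; the per-SOC fits recover a scale near 45 and shapes near 0.8–0.9
(at a few hundred records per SOC the CI may straddle 1, hence
`constant` rather than `early_failure` — the classification is
deliberately CI-based, not point-estimate-based).

A one-call orchestration (`run_report()`, YAML-configurable, with a
thin CLI wrapper in `inst/cli/faersignal.R`) writes the descriptive
table, PT- and SOC-level signal CSVs, top-k rankings, SMQ breakdowns,
TTO records and fits, and a markdown run report with the full filter
funnel.

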