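---
title: "Methods: descriptive and disproportionality analysis of GLP-1 receptor agonist safety reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: descriptive and disproportionality analysis of GLP-1 receptor agonist safety reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glp1signal)
```

## Scientific setting

Semaglutide's popularity as a weight-loss drug — amplified by social media —
raised concern about dosing errors and off-label use showing up in
spontaneous adverse-event reporting. This package implements the analysis
pipeline for that question on Individual Case Safety Reports (ICSRs) of the
seven GLP-1 receptor agonists (semaglutide SEM, liraglutide LIR, dulaglutide
DUL, exenatide EXE, lixisenatide LIX, albiglutide ALB, tirzepatide TIR):

1. a MedDRA-style vocabulary grouping 35 preferred terms (PTs) into four
   analysis high level terms (HLTs): modified dose, overdose, underdose and
   off-label use;
2. an ICSR line-listing data model with the study's case-level filters;
3. descriptive summaries (report shares, ADR-per-report ratios, stratified
   characteristics, SOC and HLT frequencies, outcome distributions);
4. reporting odds ratio (ROR) disproportionality with Woolf confidence
   intervals and a signal-classification rule;
5. a seeded synthetic report generator that emulates the study conditions,
   including plantable true odds ratios;
6. relative-search-volume utilities for the search-interest side of the
   question.

The source database extract is not publicly deposited, so the package ships
two substitutes: the published per-drug summary counts (packaged as plain
CSV fixtures) for everything that can be recomputed exactly, and the
synthetic generator for everything that requires record-level data.

## Counting units

Spontaneous-report analyses mix two units, and the package keeps them
strictly separate:

* **cases (ICSRs)** are the unit for the characteristics tables (age, sex,
  geographic origin, reporter type, seriousness). "Not specified" strata are
  retained in every denominator — this is the only convention that
  reproduces the published stratified percentages.
* **ADR records** (one reported reaction within a case) are the unit for SOC
  distributions, HLT frequencies, outcome distributions and the 2×2
  contingency tables. The signal rule's "at least 5" threshold counts ADRs.

A case suspecting two study drugs contributes to both drugs' strata,
mirroring drug-centric database queries; the generator defaults to
single-suspect cases, under which target and comparator subsets are
disjoint.

## Rounding

All displayed percentages and ratios use half-up (commercial) rounding at
the conventional precision: 1 decimal for percentages, 2 for ADR-per-ICSR
ratios, 4 for RORs and their CI bounds. Base R's `round()` rounds half to
even and disagrees on exact ties; `round_half_up()` is used throughout.
With this convention, 319 of the 320 published stratified percentage cells
recompute exactly from their own published counts. The single exception is
the tirzepatide age-12–17 cell, printed as "2 (0.0)" although 2/2,333 =
0.086% rounds to 0.1 under the rule that reproduces every other cell
(truncation is ruled out by cells such as 64/18,149 = 0.353% printed as
0.4). The packaged fixture keeps the printed value verbatim; tests flag the
cell as a typographical inconsistency and assert the count-implied value
0.1 instead of forcing agreement with the misprint.

## The vocabulary

The bundled registry holds the 35 analysis PTs partitioned 11 (modified
dose) + 5 (overdose) + 10 (underdose) + 9 (off-label use); 8 of them carry
`observed = FALSE`, marking terms with no reports in the study window. The
group called "modified dose" in the registry is displayed elsewhere as
"improper dose"; the two labels name the same group and the package treats
them as display aliases of one HLT.

PT matching is case-insensitive after trimming and collapsing whitespace,
because spontaneous-report exports vary in casing and there is no published
matching rule. A PT outside the four groups maps to `NA` and counts as an
"other ADR", never as an error.

Only SOC *labels* ship (the standard 27), not the licensed dictionary
content. The SOC attached to each study PT is a mock assignment: dose-error
terms under "Injury, poisoning and procedural complications" and
off-label-use terms under "Surgical and medical procedures", consistent
with where such reactions are coded. The HLGT level exists in the real
hierarchy but is used by no computation here and is not modelled.

## Outcomes

Case outcomes use seven categories: fatal; not recovered/not resolved;
recovered/resolved with sequelae; recovering/resolving; recovered/resolved;
not specified; unknown. (Regulatory guidance describes "6 categories" but
enumerates seven; the package uses the seven-item enumeration.) The
"unfavorable" share of an HLT is the fatal plus not-recovered fraction of
its ADRs. The published off-label outcome figures are internally
inconsistent (356 not-recovered cases cannot be reconciled with the printed
7.2% under any reconstructible denominator); `outcome_distribution()`
reports raw counts and percentages side by side and makes no attempt to
force agreement.

## The disproportionality model

For target drug vs comparator and one HLT, the ADR-level 2×2 table is

|            | HLT ADRs | other ADRs |
|------------|----------|------------|
| target     | a        | b          |
| comparator | c        | d          |

with ROR = (a·d)/(b·c) and the Woolf (log-normal approximation) interval

ROR × exp(±z·√(1/a + 1/b + 1/c + 1/d)),  z = 1.959964.

The full-precision z (rather than 1.96) keeps 4-decimal CI bounds stable
and follows standard pharmacovigilance practice. The two-sided Wald
p-value (log(ROR)/SE against the normal) is reported with the star tiers
used in disproportionality forest plots (`*` p < 0.05, `***` p ≤ 0.001,
`****` p ≤ 0.0001; there is no `**` tier).

**Signal rule.** `insufficient` when a < 5; `higher` when a ≥ 5 and the CI
lower bound exceeds 1; `lower` when a ≥ 5 and the CI upper bound is below 1
(the symmetric reading); `none` otherwise. Fed the published ROR/CI pairs,
the rule reproduces every published direction (14/14).

**Zero cells.** A zero cell is a degenerate-table error by default; the
Haldane–Anscombe +0.5 correction is strictly opt-in and flagged in the
result, because silent correction changes estimates. The sweep driver
enables it at 1/10 simulation scale, where the smallest comparators (ALB,
LIX: a few hundred ADRs) can legitimately produce empty HLT cells.

No multiplicity adjustment is applied across the sweep, and no other
disproportionality estimator (PRR, IC, EBGM) is implemented — both are
deliberate scope choices.

## The synthetic generator

`default_config()` encodes the study conditions:

* **Case volumes**: the published per-drug totals (SEM 21,012; ALB 384;
  DUL 17,332; EXE 12,926; LIR 18,149; LIX 412; TIR 2,333) times a scale
  factor, default 1/10 so full-pipeline tests run in seconds; tests state
  their sizes explicitly where they differ.
* **ADR multiplicity**: zero-truncated Poisson per case, with the rate
  solved numerically (`uniroot`) so the truncated mean equals the published
  ADR-per-ICSR ratio (SEM 1.99, ALB 2.85, DUL 1.90, EXE 2.72, LIR 1.81,
  LIX 2.08, TIR 1.98). The zero-truncated Poisson is the simplest
  non-degenerate count model matching a printed mean.
* **HLT membership**: independent draw per ADR (matching the ADR-level
  counting unit). Semaglutide uses the published frequencies (0.79%,
  0.59%, 0.33%, 6.16%). Comparator probabilities use published
  frequencies where printed (e.g. DUL modified dose 0.68%, EXE 1.90%,
  TIR off-label 6.08%) and are otherwise derived by odds inversion from
  the published RORs against the semaglutide values — e.g. LIR off-label
  = odds⁻¹(odds(0.0616)/2.8377) ≈ 2.26%. Cells with neither a printed
  frequency nor a printed ROR (ALB/LIX dose groups, non-LIR underdose)
  are set once to plausible values of the same order and documented as
  uncalibrated. A consequence of this calibration is that the pooled
  off-label ROR implied by the defaults (~3.3) matches the published
  value without being planted directly.
* **Demographics**: exact published per-drug stratum proportions.
* **Outcomes**: per-(drug, HLT) multinomials anchored at the published
  unfavorable-outcome points (SEM overdose fatal 1.6%, not-recovered
  3.7%; modified dose 7.0%; underdose 6.6%; off-label 7.2%; LIR overdose
  fatal 2.7%; the EXE not-recovered points), with the remaining mass
  spread over the favorable/unspecified categories in fixed proportions.
* **Combination marker**: a liraglutide case carries the insulin-degludec
  fixed-combination marker with probability 0.05 (no published rate
  exists; the value only exercises the exclusion filter).
* **Report dates**: uniform on 2019-01-01 to 2024-03-31. Calendar dynamics
  are deliberately not modelled; dates exist to exercise the inclusive
  cutoff.
* **Randomness**: one root seed; each drug draws on a substream derived by
  stable hashing of its code, so adding or resizing one drug never
  perturbs another's draws, and an identical configuration yields a
  byte-identical listing.

**Planting odds ratios.** `plant_odds_ratio()` sets the target drug's HLT
probability by odds inversion against the (fixed) ADR-weighted comparator
probability: p_t = OR·o_c/(1 + OR·o_c), o_c = p_c/(1 − p_c). Requests that
would push the target's HLT mass above 1 raise an infeasible-parameter
error.

**What the generator does not emulate.** Duplicate and follow-up reports,
reporting-rate dynamics over time, multi-drug suspicion (off by default),
correlation between demographics and reactions, real MedDRA coding noise,
and per-drug SOC composition beyond the semaglutide-calibrated non-study
term weights (non-SEM SOC profiles share those weights and are
uncalibrated). Passing calibration tests therefore shows that the pipeline
recovers the parameters the generator encodes — not that real reporting
data behave this way.

## Search-interest utilities

Relative search volume (RSV) rescales a series so its maximum is 100 and a
value of 50 means half the peak popularity; regional popularity gives the
top region 100 and scales the rest proportionally. Displayed values are
integers (the convention of trend tools); internal computation is at full
precision, normalization is idempotent, and any positive rescaling of the
raw input leaves the output unchanged. That last invariance is also the
key caveat: single-term exports carry no shared scale, so cross-term
ratios require jointly normalized input and cannot be recovered from
per-term series. Related queries are classified by case-insensitive
substring against per-bucket keyword lists, weight-loss before
side-effects, so a dual-match lands deterministically in the first bucket.

## Problem sizes and numerical checks

The test suite regenerates every fixture-independent input in code, at
sizes chosen to keep the default run under a minute while leaving the
statistical checks well-powered: calibration of the semaglutide HLT
frequencies at ~50,000 ADRs against 3 binomial standard errors; Woolf CI
coverage over 2,000 simulated tables with a planted odds ratio of 2
(expected 0.95 ± 0.02); planted-OR recovery through the full
generate→count→estimate pipeline over 200 seeded replicates (mean log-ROR
within 3 Monte-Carlo standard errors of log 3, CI coverage ≥ 93%); and a
type-I check that the one-sided "higher" rate under the null stays at the
nominal 2.5% over 500 replicates. The published full-scale ROR table is
not reproducible at desk scale — the underlying extract is not deposited
and the cell counts were never printed — which is why those
property-based substitutes, plus exact reproduction of every printed
count-derived percentage and direction, define the package's evidence.

## Known limitations

* The packaged counts inherit any errors of the published tables (one
  known percentage misprint, documented above).
* Comparator HLT probabilities derived from published RORs treat the
  published point estimates as exact.
* The generator's independence assumptions understate the clustering of
  reactions within real cases; ADR-level contingency counts in real data
  are not independent draws.
* `apply_study_filters()` models only the three published filters
  (drug class, combination exclusion, cutoff); no de-duplication logic
  exists because the dialect has no duplicate semantics.
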