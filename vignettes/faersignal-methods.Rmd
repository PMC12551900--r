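---
title: "Disproportionality analysis of FAERS reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality analysis of FAERS reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous-report databases such as FAERS collect suspected drug adverse
events (AEs) from consumers, clinicians and manufacturers. They have no
denominator of exposed patients, so absolute risks cannot be estimated;
what can be asked is whether a specific AE is reported *disproportionately*
often for a drug relative to the rest of the database. This package applies
that logic to the four androgen receptor pathway inhibitors (ARPIs) used in
prostate cancer, comparing five treatment groups: enzalutamide (G1),
apalutamide (G2), darolutamide (G3), abiraterone (G4), each as the only
ARPI on the case, and the abiraterone + enzalutamide combination (G5).

## The estimator

For a group with `m` reports of a specific AE out of `n` AE reports in
total, against `M` and `N` database-wide, the proportional reporting ratio
is

$$\mathrm{PRR} = \frac{m/n}{(M-m)/(N-n)}.$$

The group's own reports are removed from the comparator, so the ratio
compares the group against *all other* reports. Counting is event-level:
a case reporting three AEs contributes three entries, and more than one AE
per patient is allowed throughout (the summary tables use the same
convention).

**Confidence interval.** We use the standard log-scale Wald interval,
$\exp(\log \mathrm{PRR} \pm z_{1-\alpha/2}\,s)$ with
$s = \sqrt{1/m - 1/n + 1/(M-m) - 1/(N-n)}$ and $\alpha = 0.05$ by default.
This is the conventional interval for the PRR; published analyses rarely
state their CI method, so it is documented here as an explicit assumption
of this package.

**Zero cells.** When $m = 0$ or $M - m = 0$ the estimate or its variance is
undefined; we then add the Haldane–Anscombe 0.5 to all four cells of the
derived 2×2 table. Nonzero configurations are never perturbed, so the
estimator is exactly the fraction arithmetic above whenever that is
defined. A cell with $m = 0$ *and* $M - m = 0$ (the AE was reported
nowhere) stays undefined: `prr()` raises an error and `prr_panel()` records
a noted `NA` instead of aborting the panel.

**Signal rule.** A cell is flagged when PRR ≥ 2, the conventional
threshold; the threshold is a parameter. The composite rule
(PRR ≥ 2 ∧ χ² ≥ 4 ∧ m ≥ 3) common elsewhere is deliberately not the
default, matching the analysis this package reproduces; it can be applied
downstream from the panel's columns. No multiplicity adjustment is applied
(two-tailed α = 0.05 throughout); with 65 panel cells this inflates the
family-wise error rate, which is the accepted practice in screening-stage
disproportionality work — signals are hypotheses, not confirmed risks.

## Association tests

Stratified count tables (characteristics by group; events by age band or
group) are tested with Pearson's chi-squared test without continuity
correction when all expected cells are ≥ 5, and Fisher's exact test for
2×2 tables otherwise; larger sparse tables stay chi-squared with a
small-cell flag. Both call the standard `stats` implementations — the
selection rule, not the tests, is the package's logic.

## Cohort construction choices

Several details are underdetermined by convention and fixed here as design
choices:

- **Deduplication** keeps, per case id, the maximal `caseversion`, breaking
  ties by latest receipt date and then by lexicographically largest
  `primaryid`. FAERS ships every resubmission; max-version is the
  conventional "current record" rule.
- **Date window** is closed on both ends (a case received exactly on the
  end date is retained).
- **Age** is converted to years from the FAERS unit code (decades, months,
  weeks, days, hours) before the range check `[0, 130]`; the five analysis
  bands `<50, 50–59, 60–69, 70–79, ≥80` own their lower boundaries (age 50
  falls in 50–59, age 80 in ≥80).
- **Country** uses the occurrence-country field, falling back to reporter
  country when absent; occurrence country is the closer proxy for "US
  residents".
- **Prostate-cancer indication** is matched case-insensitively against a
  configurable substring list (default: "prostate cancer", "prostatic",
  "castration-resistant") on the indication PT of an ARPI drug entry. The
  underlying dictionary ships no authoritative PT list for this, so the
  pattern list is data, not code.
- **ARPI detection inspects all drug roles** (suspect, concomitant,
  interacting) by default: the group definitions read "with other
  medications", implying the whole drug list. Restricting to suspect-only
  is available via the `arpi_roles` argument.
- **Seriousness** is derived from the outcome (OUTC) file — any outcome row
  marks the case serious — since the post-2012 demographic file carries no
  seriousness field.
- **The comparator database** for PRR denominators is the
  window/US/age-filtered database *without* the indication requirement
  (`require_indication = FALSE`), so "all other reports" means everything
  else observed, not only the treated cohort.

Malformed input rows are quarantined to a diagnostics report (one line per
row with a reason) rather than raising: real FAERS quarters contain
malformed rows, and one bad row must not abort a quarter.

## Event grouping

Reaction PTs are aggregated into 12 disease categories — Lack of efficacy,
General complications, Infection, CNS, OPH/ENT, Respiratory,
Musculoskeletal, Vascular, Endocrine, Gastro intestinal, Kidney/Urology,
Skin — plus an "Others" catch-all for unmapped terms. Published tables in
this analysis style list 13 rows while describing "12 disease groups"; the
package resolves this by treating "Others" as an explicit 13th catch-all
category. The MedDRA dictionary is licensed and cannot be bundled, so the
mapping is user-supplied data (a two-column TSV with byte-exact category
labels); the package ships a starter map of ~100 common
oncology-pharmacovigilance PTs, which is also what the synthetic generator
draws from. The conventional ">100 reports" floor for individually mapping
a PT is supported as a reporting-side screen (`pt_frequency()`), not a
hard-coded list.

## The synthetic generator

`synthetic_config()` describes a database as a background stratum plus up
to five ARPI group strata. Its defaults are fixed from the published
aggregate tables of the ARPI cohort this package reproduces:

- group case counts = the published group sizes scaled down tenfold
  (G1 2581, G2 333, G3 73, G4 1429, G5 69), with 20,000 background cases;
- category probabilities = the published events-by-group category totals
  (107,582 events);
- age-band mixture, seriousness (0.676), reporter-type and case-priority
  marginals = the published characteristics-table marginals;
- reactions per case ∈ {1..5} with probabilities (0.35, 0.25, 0.18, 0.12,
  0.10), mean ≈ 2.4 — the published events-per-case ratio;
- duplicate-version rate 0.10 and missing-age rate 0.25: not stated in the
  source tables; chosen once as realistic spontaneous-reporting values (the
  published flow loses a large fraction of cases to missing age) and not
  revisited.

Group *g* draws categories with probabilities proportional to
`background_probs × multipliers[g, ]`. Because each stratum's category
distribution is an explicit mixture, the infinite-sample PRR of every cell
follows analytically (`asymptotic_prr()`): the group's category probability
over the event-weighted average of all other strata. With a single
multiplier ρ on one cell, the truth is ρ / Z where Z = 1 + (ρ − 1)p₀ is the
group's renormalisation constant — e.g. ρ = 3.5 on Skin (p₀ ≈ 0.049) gives
an asymptotic PRR of 3.12, not 3.5. Storing this ground truth means
recovery tests need no second simulator.

The generator also injects the artefacts the upstream stages exist to
handle: superseded version-1 records, missing ages, brand-name drug
spellings (XTANDI, ERLEADA, NUBEQA, ZYTIGA), a small non-US fraction, and
background suspect drugs with non-prostate indications.

**What it does not emulate:** reporting-behaviour confounding (stimulated
reporting, the Weber effect), drug–drug interaction structure, duplicate
cases with *different* ids, narrative text, within-case correlation of
reaction terms, or secular trends. Passing recovery tests therefore shows
the estimator and pipeline are correct under clean mixture sampling — not
that PRRs on real FAERS data are unbiased, which no estimator can promise
from spontaneous reports.

## Validation experiments and problem sizes

Two seeded experiments back the estimator (both in `R/validate.R`, run by
the test suite and the acceptance script):

- **CI coverage**: 100 replicates with multiplier 3.5 on (G2, Skin), 5,000
  expected group events against 50,000 background events; the 95% CI covers
  the asymptotic PRR in ≥ 90 replicates (binomially, ~95% expected).
- **Null panel**: one database with all multipliers at 1, five equal groups
  of ~10,000 events each plus ~28,000 background events (~78,000 total, so
  the rarest cell still holds hundreds of events); every one of the 65
  panel estimates must lie in [0.8, 1.25].

These sizes are the package's chosen compromise between Monte-Carlo error
and run time; they complete in well under a minute each on one CPU.
Published headline PRRs from the real database (e.g. the apalutamide skin
signal, PRR 3.558) require the full ten-year FAERS archive and are
reproduced in *format* (the panel and its TSV/forest-plot outputs), not in
value; the shipped aggregate count tables do allow exact reproduction of
the printed percentages and totals.

## Numerical conventions

- Percentages round half-up (12.45 → 12.5), matching printed-table
  convention; base R's round-half-to-even is not used for display values.
  Table precision defaults to 1 decimal for characteristics and 2 for event
  tables, as the published tables mix both.
- The PRR is reported unrounded; TSV outputs carry full precision.
- All pipeline stages are deterministic; only the generator consumes
  randomness, seeded from its config, so identical config ⇒ byte-identical
  files.

## Limitations

PRRs from spontaneous reports are reporting-rate ratios, not risks:
signals are hypothesis-generating. The pipeline inherits FAERS's
limitations — no exposure denominator, missing demographics,
indication-channelling — and mitigates only what bookkeeping can: explicit
flow counts for every exclusion, diagnostics for every dropped row, and a
comparator that removes the group's own reports.
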