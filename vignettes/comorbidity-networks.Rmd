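---
title: "Building comorbidity networks from ICD-10 claims: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building comorbidity networks from ICD-10 claims: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Legg–Calvé–Perthes disease (LCPD) is an idiopathic avascular necrosis of the
femoral head in children, typically diagnosed before age 12, with a marked
(roughly 3:1) male excess. Its etiology is unclear, which makes the diseases
recorded *before* the LCPD diagnosis — its comorbidity profile — an
informative object of study. `comorbnet` implements a data-driven
case-control design over longitudinal ICD-10-coded claims records: identify
incident cases, match population controls, screen every three-character
diagnosis category for association with case status, regroup the significant
categories clinically, and assemble an odds-ratio-weighted comorbidity
network. Nothing in the machinery is specific to LCPD; the index disease,
washout, age limit and grouping are all configuration.

```{r, eval = FALSE}
library(comorbnet)
cs <- generate_claims(demo_config(seed = 1))
```

## Cohort definition

**Incident cases.** A patient is an incident case iff they have at least one
index-coded visit, the first such visit falls after the washout window, no
index-coded visit falls inside the washout window, and their age at that
first visit is at most `max_age_years` (default 12). The washout (default
the calendar years 2002–2004 of a 2002-onward database) exists to separate
genuinely new diagnoses from readmissions and follow-up care of prevalent
patients; anyone index-coded during it is excluded outright. Patients
missing sex or birth year, or with no visit at all, are removed first
(`filter_complete()`): their records cannot support either matching or
ascertainment.

**Age** is computed as diagnosis year minus birth year. The data model
deliberately carries only a birth year — administrative claims extracts
often do — and whole-year ages are what clinical baseline tables report.

**Period before diagnosis.** For each case we record the time from their
first observed record to the diagnosis date, in years. This variable is
central: it measures how much ascertainment opportunity a patient had, and
matching on it equalizes the comorbidity lookback window between cases and
controls.

**Pre-diagnosis records.** Comorbidity ascertainment uses records strictly
*before* the diagnosis date. We read "prior to" as a strict inequality:
codes recorded on the diagnosis day itself are part of the diagnostic
workup, and counting them would let the index event contaminate its own
exposure history. The source design leaves this unstated; the strict
reading is the conservative one.

## Incidence

Annual incidence per 100,000 by sex uses a one-year washout (the first
database year is never a reporting year). A patient is a new case in year
*Y* iff their first index-coded visit falls in *Y* and they are age-eligible
that year. The at-risk denominator is not standardized in claims studies;
we use the count of age-eligible, demographically complete patients of that
sex not yet index-diagnosed before *Y*, and record that choice in the output
metadata. The male-vs-female comparison is an exact conditional binomial
test: given the total case count, the male share is binomial with success
probability equal to the male share of person-years under the null of equal
rates. No specific test is canonical here; the exact conditional test is
assumption-free at these case counts.

## Matching

Controls are drawn 1:3 per case by propensity-score matching. The score is
a logistic regression of case status on age, sex and period before
diagnosis. Candidates (complete, never index-coded patients) have no
diagnosis date, so each is assigned a seeded reference date uniform over
their record span, at which their age and available period are evaluated —
the same covariate definitions as cases.

Design choices the greedy matcher makes explicit, since "greedy
nearest-neighbor" underdetermines them:

* **Exact on sex, nearest-neighbor on the score.** Score distance alone
  cannot reliably reproduce identical sex proportions in a 3:1-male cohort;
  exact sex strata guarantee it, which is what matched baseline tables in
  this literature show.
* **Processing order**: cases are matched in descending score order
  (hardest-to-match first), ties broken by a seeded draw.
* **No caliper by default**; configurable.
* **Without replacement**: a control serves one case only.
* **Pseudo-index dates.** A matched control's ascertainment cutoff is its
  first record date plus the case's period before diagnosis, so both arms
  contribute windows of identical length by construction; candidates whose
  observation cannot accommodate the window are skipped during matching.

Balance is reported as standardized mean differences; below 0.1 is the
conventional adequacy threshold, and the suite checks it on synthetic
cohorts of 20,000 candidates.

## Association statistics

All analyses work on **presence**: a patient either has or does not have at
least one pre-index record in a three-character ICD-10 category ("cluster");
repeat visits count once. Codes are truncated to three characters because
fourth/fifth-digit subdivisions are noisy in administrative data and would
fragment counts.

For each cluster the 2×2 table (exposed/unexposed × case/control) yields:

* the **Haldane–Anscombe-corrected odds ratio**
  $\widehat{OR} = \dfrac{(a+\tfrac12)(d+\tfrac12)}{(b+\tfrac12)(c+\tfrac12)}$,
  with the ½ added to *every* cell *unconditionally* — not only when a zero
  cell occurs. The unconditional form is what the published tables this
  package reproduces used: a no-zero-cell row like other anaemias
  (8/167 vs 7/501) prints 3.51, the corrected value, where the uncorrected
  cross-product gives 3.55.
* the **two-sided exact Fisher p-value** under the point-probability rule
  (sum of hypergeometric probabilities of tables at most as probable as the
  observed one) — the convention of the major statistical packages, and the
  one `stats::fisher.test()` implements; the test suite cross-checks it
  against an independent enumeration oracle.

Clusters with p < α (default 0.05) are significant. **No multiple-testing
correction is applied by default** — the design screens at raw p < 0.05, as
the source analysis did; a Benjamini–Hochberg option exists but is off.

**Regrouping.** Significant clusters can be collapsed into clinical disease
groups (e.g. muscle/synovium codes M62, M65, M67). Group exposure is the
union of member exposures, counted once per patient, and the odds ratio and
p-value are recomputed on the union table. Ungrouped clusters pass through
as singletons.

**Pairwise links** between clusters/groups use the same statistics on joint
presence. They are computed over the pooled matched cohort by default: the
source description is ambiguous between "cases only" and "whole cohort",
and the pooled cohort gives every table 668 observations rather than 167;
`population = "cases"` is available.

**Reporting**: odds ratios are rounded half-up to 2 decimals and p-values
to 3, printing `"<0.001"` below that, matching clinical-table conventions
(`format_results()`; note base R's `round()` rounds half to even, hence
`round_half_up()`).

## The network

Nodes are the index disease plus every significant cluster/group; edges are
the mandatory index–cluster links (weighted by the case-control odds ratio)
plus the significant pairwise links (weighted by the pairwise odds ratio).
Degree is computed from the final edge set and is the node-size attribute;
node color classes come from the first letter of the (anchor) ICD-10 code.
A group node's chapter is anchored by its first listed member — groups in
practice span a single chapter, but the rule must be total. Exports:
GraphML and GEXF 1.2 with `degree`/`chapter` node attributes and
`weight`/`p` edge attributes, plus plain node and edge CSVs.

## The synthetic generator

No national claims database is redistributable, so validation rests on a
seeded generator (`sim_config()`, `generate_claims()`) that emulates the
*structure* the pipeline assumes: per-patient visit streams over a fixed
study window, a pediatric age mix (including children born mid-study, whose
observation starts at birth), demographic missingness, a rare index disease
with configurable sex-specific incidence emitted at a first-diagnosis date
with Poisson follow-up visits (so washout logic is exercised), and a
catalog of conditions with configurable prevalences.

Two structural choices matter:

* **Presence carries the effects.** Each patient carries latent condition
  indicators; a planted case-control odds ratio *OR* tilts the carriage
  probability among index cases to $p_1 = OR\,o/(1+OR\,o)$ with
  $o = p_0/(1-p_0)$, which hits the target odds ratio exactly in
  expectation. Pairwise co-occurrence uses the Plackett joint distribution
  with the requested odds ratio.
* **Per-condition visit streams.** Each carried condition emits its own
  Poisson visit stream (default 1.5 coded visits per condition-year) rather
  than competing for a shared visit budget. With a shared budget, the
  chance that a given condition is ever coded inside the pre-index window
  would depend on how many other conditions the patient carries, biasing
  observed odds ratios unevenly; with per-condition streams a carried
  condition is coded in a multi-year window with near-certainty, so the
  downstream estimate recovers the planted value. Background
  general-examination visits (code `Z00`) add presence-neutral noise.

What the generator does **not** emulate: multi-diagnosis visit records,
in/outpatient structure, billing incentives, coding error, enrollment gaps,
secular coding trends, and the 2% sampling design of national sample
cohorts (the generated population *is* the frame). Passing tests therefore
show that the pipeline recovers known structure from data obeying its
assumptions — not that real claims data obey them.

`demo_config()` packages the validation scale: 20,000 patients over
2002–2009, five null pediatric codes plus three planted comorbidities with
odds ratios 2, 5 and 10, and index incidence calibrated analytically (from
this design's washout/age retention fraction) so the expected incident case
count is about 167 — the published cohort's size, i.e. a 1:12 scale of its
~241,000-patient source frame — with the published 9.3:3.4 male:female
rate ratio. Validation sizes were chosen so each property is measured at
the scale it is stated for: single 20,000-patient cohorts for balance
checks, 200 seeded replicates for planted-effect recovery and type-I
calibration (the latter on directly simulated 167/501 presence matrices via
`simulate_presence()`, which is the association stage's input contract),
and 50 seeded replicates for end-to-end network recovery.

## Numerical and degenerate-input behavior

* The Haldane–Anscombe correction makes every odds ratio finite and
  positive; no zero-cell special-casing exists anywhere.
* Ties in matching (equal score distance) are broken by a pre-drawn seeded
  uniform per candidate, so results are reproducible across platforms.
* All randomness is seeded; the pipeline forks one stage seed per named
  stage from the run seed, so changing one stage's internals cannot perturb
  another stage's draws.
* Empty record lists yield all-zero presence rows; clusters present in no
  case are dropped from screening; a run with no significant cluster yields
  a single isolated index node rather than an error.
* Claims files round-trip exactly, including visitless patients (kept as a
  row with empty visit fields) and missing demographics (empty tokens).

## Known limitations

* Age in whole calendar years ignores birth month (±1 year).
* The incidence denominator is a design choice; absolute rates shift with
  other at-risk definitions, though sex contrasts are robust.
* Greedy matching is order-dependent by nature; the seeded deterministic
  order makes runs reproducible but not optimal (optimal matching is out of
  scope).
* Screening at raw p < 0.05 across hundreds of clusters trades false
  positives for sensitivity by design; treat single-cluster findings as
  hypothesis-generating.
* Published degree columns cannot be re-derived from printed tables alone
  (they need patient-level data); the network stage is validated on
  synthetic data and on degree sequences realized from the printed values.
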