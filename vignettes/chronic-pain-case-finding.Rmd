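---
title: "Chronic-pain case finding: the algorithm, its conventions, and how it is tested"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chronic-pain case finding: the algorithm, its conventions, and how it is tested}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painfinder)
```

## The problem

Chronic pain — persistent or recurrent pain lasting three months or longer —
is poorly captured by any single field in primary-care records. Searches
confined to analgesic prescribing miss everyone managed without drugs, and a
bare "chronic pain" diagnosis code is inconsistently recorded. A
case-finding definition therefore has to combine diagnosis codes and
prescribing histories, with timeframes, into explicit logic rules that can be
run as queries against coded records.

`painfinder` implements such a definition: four clinical criteria compiled
into eight per-patient logic rules evaluated at a snapshot date, with the
cohort defined as the union of the rules (the criteria are deliberately not
mutually exclusive).

## The rules

The denominator is every patient aged 18 or over at the snapshot date who is
currently registered with a general practice and has no informed-dissent
opt-out code. Within that population:

| Rule | Criterion | Fires when |
|------|-----------|------------|
| R1 | C1 | any *tier-1* condition code (a diagnosis that almost always entails chronic pain: fibromyalgia, rheumatoid arthritis, chronic low back pain, ...) at any time up to the snapshot |
| R2 | C2 | any *tier-2* condition code (conditions that can cause chronic pain: osteoarthritis, migraine, sciatica, ...) **and** ≥ 3 qualifying analgesic issues in the last 12 months |
| R3 | C3 | any trigeminal neuralgia code |
| R4 | C3 | any post-herpetic neuralgia code, or a neuropathy/neuropathic-pain code 3–6 months after an acute herpes zoster episode |
| R5 | C3 | any phantom-limb-pain code, or a neuropathy/neuropathic-pain code 3–24 months after an amputation |
| R6 | C3 | a diabetic neuropathy code plus at least one neuropathic-pain treatment issue at any time up to the snapshot |
| R7 | C3 | diabetes and neuropathic pain, coded separately |
| R8 | C4 | ≥ 4 qualifying analgesic issues in the last 12 months |

A *qualifying analgesic* issue is a prescription in one of: non-opioid
analgesics (excluding low-dose aspirin), opioid analgesics, neuropathic-pain
analgesics, tricyclic antidepressants restricted to amitriptyline and
nortriptyline, and antiepileptic drugs — the last counting only for patients
with no epilepsy diagnosis, because for them the prescription is presumed to
treat the epilepsy. A *neuropathic-pain treatment* (rule R6 only) is broader:
any analgesic except low-dose aspirin, an oral or intravenous anaesthetic, an
antiepileptic absent epilepsy, or an antidepressant of any class.

SSRIs, duloxetine and other non-TCA antidepressants sit in the
`ANTIDEPRESSANT_OTHER` category: they satisfy R6's treatment test but never
count towards the R2/R8 prescription thresholds, since their primary
indication (depression vs pain) cannot be resolved from coded data. This is a
known source of under-ascertainment, as is the exclusion of patients with
epilepsy whose only route into the cohort would be antiepileptic prescribing.

## Day conventions and numerical choices

The source phrasing is month-based ("in the last 12 months", "3–6 months",
"3–24 months") without a day convention. For determinism the package fixes,
in `window_config()`:

* **12-month prescription window** — the half-open interval
  `(snapshot − 365 d, snapshot]`. An issue dated on the snapshot counts; one
  dated exactly 365 days before does not.
* **Post-herpetic window** — the closed interval `[90, 183]` days between the
  zoster episode and the neuropathy/neuropathic-pain code.
* **Phantom-limb window** — the closed interval `[90, 730]` days after
  amputation.
* **Diagnosis lookback** — unlimited: any code on or before the snapshot.
  The definition intentionally captures people who have *ever* met it, i.e.
  people at risk of chronic pain, not only those currently in pain. A
  current-pain refinement is possible by shrinking windows via
  `window_config()`, but is not a separate mode.
* **Prescription counting unit** — deduplicated `(patient, drug, date)`
  issue records; two different drugs issued the same day count twice, the
  same drug recorded twice that day counts once.
* **Ages** — completed years by the birthday-anniversary convention; a 29
  February birthday increments on 1 March in common years. A patient whose
  18th birthday falls on the snapshot is eligible.
* **Epilepsy exclusion** — any epilepsy code on or before the snapshot
  disqualifies antiepileptics, regardless of whether the code predates the
  prescription; the source gives no timing, and the simpler convention keeps
  the rule monotone in diagnoses.
* **R6 treatment timing** — any treatment issue on or before the snapshot
  (no 12-month restriction); the treatment definition carries no window.

Where tier-2's "3 or more" window could anchor to the snapshot or to the
diagnosis date, the snapshot is used, consistent with the regular-analgesia
criterion's phrasing.

## Code lists

Eleven named roles fill the rules' code-set slots (`codelist_roles()`):
tier-1 conditions, tier-2 conditions, trigeminal neuralgia, acute herpes
zoster, post-herpetic neuralgia, phantom limb pain, neuropathy/neuropathic
pain, amputation, diabetic neuropathy, diabetes, and epilepsy. Phantom limb
pain is kept as its own role (rather than folded into the neuropathic-pain
list) so R5's direct-code branch needs no sub-tagging. Tier-1 and tier-2
lists must be disjoint — enforced as a registry invariant so that rule
attribution is deterministic.

The real clinical lists behind the published definition (1,932 SNOMED CT
codes) are not redistributable; the package ships schema-conformant **demo**
lists with one synthetic code per named tier-1 condition (12) and tier-2
condition group (20), in a clearly-fake `999…` numeric namespace. Users drop
in real lists by pointing `load_registry()` at their own manifest. Drug
classification is carried as a category column on prescription records
rather than by code lookup, because drug groups are defined at the level of
formulary chapters, not individual product codes.

## Prevalence reporting

`prevalence_overall()` and `prevalence_by()` report crude (unstandardised)
snapshot prevalence — included over eligible — overall and stratified by
decadal age band (18–24 … 85+), 18–64 vs 65+, gender, five-category census
ethnicity, IMD quintile (1 = most deprived nationally) and most- vs
least-deprived quintile. Unknown demographic values form explicit `unknown`
strata, so numerators and denominators always sum to the overall counts;
full precision is kept in files, with half-even rounding to one decimal for
display. Confidence intervals and age standardisation are out of scope.

## What the synthetic generator emulates — and what it does not

`generate_population()` is archetype-based: each patient is *constructed* to
satisfy exactly one intended rule set (one of R1…R8, a tier-1 + analgesia
"multi" archetype, or "none"), plus decoy diagnosis codes absent from every
list and never-qualifying prescription noise. Defaults emulate the study
conditions the algorithm was developed against: a registered adult
population, coded history spanning 1 April 2005 to 31 March 2021 with the
snapshot at the span end, a 4.6% informed-dissent fraction, and archetype
fractions summing to ≈ 16.5% so the synthetic prevalence lands in the band
reported for an inner-city registered adult population. Demographics (gender
≈ 50.5/49/0.5, a plural-White five-category ethnicity mix, a
deprivation-skewed IMD distribution, ages 18–95 with an exponential tilt
towards younger adults) are sampled independently of the rule labels.

Archetype construction rather than distributional simulation is deliberate:
the algorithm is deterministic, so the meaningful acceptance surface is
*exact* recovery of known labels, not statistical fit. Consequently passing
tests show that the engine implements the stated logic exactly; they say
nothing about how well the logic identifies chronic pain in real records,
where codes co-occur, histories are censored by registration churn, and
code-list quality dominates. Real co-occurrence structure, demographic-rule
correlation, and realistic coding noise are intentionally not modelled.

`generate_boundary_suite()` complements the random populations with a fixed,
handcrafted set of patients pinning every boundary: exactly 3 vs 4
prescriptions, issues dated on the snapshot and exactly 365 days before it,
zoster-to-pain gaps of 89/90/183/184 days, amputation gaps of 89/90/730/731
days, epilepsy + antiepileptics, aspirin-only and other-TCA-only
prescribing, tier-2 with 2 vs 3 issues, ages 17 vs 18 at the snapshot,
dissent and deregistration, and a post-snapshot diagnosis.

## How the implementation is verified

Two independent code paths are compared. The engine (`build_cohort()`)
evaluates rules vectorised across the population; the test suite carries a
naive reference classifier written as per-patient nested loops directly from
the clinical definitions, sharing no code with the engine. The acceptance
tests require rule-for-rule agreement between the two on 100 random
populations (seeds 0–99, 60–300 patients each — sizes chosen to keep the
loop-based oracle fast while varying composition), exact ground-truth
recovery (sensitivity = specificity = 1 per rule and criterion) on generated
populations of 600 and the boundary suite, the threshold/window boundary
flips above, the medication exclusions, the structural counts (8 rules, 5 of
them criterion 3; 12 tier-1 and 20 tier-2 demo entries), conservation of
stratified totals, and monotonicity of inclusion under adding/removing
qualifying prescriptions.

`scripts/acceptance.R` re-runs the pipeline end to end on a fresh
2,000-patient population for any seed and reports the computed prevalence,
pooled recovery sensitivity/specificity, boundary-suite accuracy and the
structural counts.

## Known limitations

* The demo code lists are placeholders; results on real data are entirely
  determined by the quality of the real lists substituted in.
* Identification is of people *at risk of* chronic pain (ever met the
  definition), not people currently in pain.
* Patients managing pain with over-the-counter medication, on SSRIs or
  duloxetine only, or with epilepsy plus antiepileptic-only analgesia are
  systematically missed — inherent to the definition, not the
  implementation.
* Prevalence is crude; no standardisation or uncertainty quantification.
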