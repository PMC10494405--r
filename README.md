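# painfinder

Rule-based identification of people living with chronic pain from coded
primary-care records, with stratified prevalence reporting and a
ground-truth-labelled synthetic data generator.

## The problem

Chronic pain — pain persisting three months or longer — is underestimated by
record searches confined to analgesic prescribing, because many patients are
managed without drugs and "chronic pain" itself is inconsistently coded.
`painfinder` implements a case-finding definition that combines diagnosis
codes with prescribing histories: four clinical criteria compiled into eight
per-patient logic rules, evaluated at a snapshot date over three flat tables
(patients, coded events, prescription issues).

The cohort is the union of the rules, within an eligible denominator of all
registered adults (≥ 18 at the snapshot) without an informed-dissent opt-out:

* **R1 (criterion 1)** — any *tier-1* condition code: one of 12 diagnoses
  that almost always entail chronic pain (fibromyalgia, rheumatoid
  arthritis, chronic low back pain, ...).
* **R2 (criterion 2)** — any of 20 *tier-2* condition groups (osteoarthritis,
  migraine, sciatica, ...) **and** ≥ 3 qualifying prescription-only analgesic
  issues in the last 12 months.
* **R3–R7 (criterion 3, chronic neuropathic pain)** — trigeminal neuralgia;
  post-herpetic neuralgia (direct code, or neuropathy/neuropathic pain 3–6
  months after acute herpes zoster); phantom limb pain (direct code, or
  neuropathy 3–24 months after amputation); diabetic neuropathy with a
  neuropathic-pain treatment; diabetes and neuropathic pain coded separately.
* **R8 (criterion 4)** — ≥ 4 qualifying prescription-only analgesic issues in
  the last 12 months.

Qualifying analgesics are non-opioids (excluding low-dose aspirin), opioids,
neuropathic-pain analgesics, amitriptyline/nortriptyline TCAs, and
antiepileptics for patients with no epilepsy diagnosis. Timeframes use
documented day conventions (half-open `(snapshot − 365 d, snapshot]` window;
closed `[90, 183]` and `[90, 730]` day intervals), all configurable via
`window_config()`. See the vignette
(`vignettes/chronic-pain-case-finding.Rmd`) for the full conventions and
design rationale.

The package ships **demo** code lists in a clearly-fake `999…` namespace (the
real clinical lists are not redistributable); real lists drop in via a
manifest mapping the eleven registry roles to CSV files.

## Worked example

```r
library(painfinder)

registry <- demo_registry()   # or load_registry("path/to/manifest.json")
pop <- generate_population(generator_config(n_patients = 1000, seed = 42),
                           registry)
cohort <- build_cohort(pop$dataset, registry)
cohort
#> <cohort_snapshot> snapshot 2021-03-31
#>   eligible: 954  included: 153
#>   per-rule counts: R1=56 R2=30 R3=5 R4=5 R5=4 R6=8 R7=8 R8=46
```

Of 1,000 generated patients, 954 are eligible (the rest carry the 4.6%
informed-dissent flag); 153 fire at least one rule, and the per-rule counts
show the attribution (not mutually exclusive — a patient may fire several).

```r
prevalence_overall(cohort)
#> $numerator   153
#> $denominator 954
#> $percent     16
prevalence_by(cohort, pop$dataset, "age_18_64_vs_65_plus")
#>   stratifier           stratum numerator denominator prevalence_percent
#> 1 age_18_64_vs_65_plus 18-64         141         851               16.6
#> 2 age_18_64_vs_65_plus 65+            12         103               11.7
```

Overall prevalence is 16.0% of the eligible population. The stratified table
gives numerator/denominator/percent per stratum; numerators and denominators
always sum to the overall counts (unknown demographics form explicit
`unknown` strata). Because this generator samples demographics independently
of the rule labels, strata differ only by sampling noise — real data, and the
study population this definition was developed on, show strong age, gender,
ethnicity and deprivation gradients.

The generator's labels let you verify the engine end to end:

```r
truth <- pop$truth                      # per-patient intended rules
all(cohort$results$fired_rules[match(truth$patient_id[truth$eligible],
    cohort$results$patient_id)] == truth$rules[truth$eligible])
#> TRUE
```

A command-line dispatcher is installed at
`system.file("cli", "painfinder.R", package = "painfinder")`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/painfinder.R", package="painfinder"))')" \
  generate --out demo_data
Rscript ... identify --data demo_data --codelists demo_data/codelists --out demo_out
Rscript ... prevalence --cohort demo_out/cohort.csv --patients demo_data/patients.csv \
  --out prevalence.csv
```

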