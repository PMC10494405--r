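# Independent naive reference classifier: per-patient nested loops written
# directly from the clinical definitions, sharing no code with the engine.
# Deliberately slow and explicit.

naive_anniversary <- function(birth, year) {
  b <- as.POSIXlt(birth)
  d <- as.Date(sprintf("%04d-%02d-%02d", year, b$mon + 1L, b$mday),
               format = "%Y-%m-%d")
  if (is.na(d)) d <- as.Date(sprintf("%04d-03-01", year))  # 29 Feb birthdays
  d
}

naive_age <- function(birth, snapshot) {
  sy <- as.POSIXlt(snapshot)$year + 1900L
  by <- as.POSIXlt(birth)$year + 1900L
  age <- sy - by
  if (naive_anniversary(birth, sy) > snapshot) age <- age - 1L
  age
}

naive_count_analgesics <- function(prx, has_epilepsy, snapshot, lookback = 365L) {
  counting <- c("NON_OPIOID_ANALGESIC", "OPIOID_ANALGESIC",
                "NEUROPATHIC_ANALGESIC", "TCA_AMITRIPTYLINE_NORTRIPTYLINE")
  seen <- character()
  count <- 0L
  for (j in seq_len(nrow(prx))) {
    d <- prx$issue_date[j]
    if (d <= snapshot - lookback || d > snapshot) next
    key <- paste(prx$drug_code[j], d)
    if (key %in% seen) next
    seen <- c(seen, key)
    cat_j <- prx$category[j]
    if (cat_j %in% counting ||
        (cat_j == "ANTIEPILEPTIC" && !has_epilepsy)) {
      count <- count + 1L
    }
  }
  count
}

# returns a data frame: patient_id, eligible, R1..R8 per patient
naive_classify <- function(dataset, registry, config = window_config()) {
  snapshot <- dataset$snapshot_date
  out <- list()
  for (i in seq_len(nrow(dataset$patients))) {
    p <- dataset$patients[i, ]
    id <- p$patient_id
    eligible <- !is.na(p$birth_date) &&
      naive_age(p$birth_date, snapshot) >= 18L &&
      p$registered_at_snapshot && !p$informed_dissent
    pev <- dataset$events[dataset$events$patient_id == id, ]
    prx <- dataset$prescriptions[dataset$prescriptions$patient_id == id, ]

    dates_of <- function(role) {
      ds <- as.Date(character())
      for (j in seq_len(nrow(pev))) {
        if (pev$code[j] %in% registry[[role]]$codes &&
            pev$event_date[j] <= snapshot) {
          ds <- c(ds, pev$event_date[j])
        }
      }
      ds
    }
    has <- function(role) length(dates_of(role)) > 0L

    has_epilepsy <- has("EPILEPSY")
    n_qual <- naive_count_analgesics(prx, has_epilepsy, snapshot,
                                     config$analgesic_lookback_days)

    r1 <- has("TIER1_CONDITIONS")
    r2 <- has("TIER2_CONDITIONS") && n_qual >= config$tier2_threshold
    r3 <- has("TRIGEMINAL_NEURALGIA")

    pair_in <- function(anchors, pains, lo, hi) {
      for (a in anchors) for (nn in pains) {
        gap <- as.integer(nn) - as.integer(a)
        if (gap >= lo && gap <= hi) return(TRUE)
      }
      FALSE
    }
    pains <- dates_of("NEUROPATHIC_PAIN")
    r4 <- has("POSTHERPETIC_NEURALGIA") ||
      pair_in(dates_of("HERPES_ZOSTER_ACUTE"), pains,
              config$postherpetic_window_days[1], config$postherpetic_window_days[2])
    r5 <- has("PHANTOM_LIMB_PAIN") ||
      pair_in(dates_of("AMPUTATION"), pains,
              config$phantom_window_days[1], config$phantom_window_days[2])

    r6 <- FALSE
    if (has("DIABETIC_NEUROPATHY")) {
      treatments <- c("NON_OPIOID_ANALGESIC", "OPIOID_ANALGESIC",
                      "NEUROPATHIC_ANALGESIC", "TCA_AMITRIPTYLINE_NORTRIPTYLINE",
                      "OTHER_TCA", "ANTIDEPRESSANT_OTHER", "ANAESTHETIC")
      for (j in seq_len(nrow(prx))) {
        if (prx$issue_date[j] > snapshot) next
        cat_j <- prx$category[j]
        if (cat_j %in% treatments ||
            (cat_j == "ANTIEPILEPTIC" && !has_epilepsy)) {
          r6 <- TRUE
        }
      }
    }
    r7 <- has("DIABETES") && has("NEUROPATHIC_PAIN")
    r8 <- n_qual >= config$criterion4_threshold

    out[[i]] <- data.frame(patient_id = id, eligible = eligible,
                           R1 = r1, R2 = r2, R3 = r3, R4 = r4, R5 = r5,
                           R6 = r6, R7 = r7, R8 = r8)
  }
  do.call(rbind, out)
}

# compare the engine with the naive oracle, rule for rule
expect_oracle_agreement <- function(dataset, registry, config = window_config()) {
  cohort <- build_cohort(dataset, registry, config)
  oracle <- naive_classify(dataset, registry, config)
  expect_setequal(cohort$results$patient_id,
                  oracle$patient_id[oracle$eligible])
  o <- oracle[oracle$eligible, ]
  o <- o[order(o$patient_id), ]
  r <- cohort$results[order(cohort$results$patient_id), ]
  for (rule in rule_ids()) {
    expect_identical(unname(r[[rule]]), unname(o[[rule]]),
                     label = paste("engine", rule),
                     expected.label = paste("oracle", rule))
  }
  invisible(TRUE)
}
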