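#' The eight logic rules and their criteria
#'
#' The four clinical criteria compile into eight logic rules: R1 (tier-1
#' condition), R2 (tier-2 condition corroborated by analgesic prescribing),
#' R3-R7 (the five chronic neuropathic pain rules) and R8 (regular
#' prescription-only analgesia). Criteria are not mutually exclusive; a
#' patient may fire any subset.
#'
#' @return \code{rule_ids()}: the eight rule identifiers.
#' @export
rule_ids <- function() {
  c("R1", "R2", "R3", "R4", "R5", "R6", "R7", "R8")
}

#' @rdname rule_ids
#' @return \code{rule_criterion_map()}: named character vector mapping each
#'   rule to its criterion (\code{R1} to \code{C1}, \code{R2} to \code{C2},
#'   \code{R3}-\code{R7} to \code{C3}, \code{R8} to \code{C4}).
#' @export
rule_criterion_map <- function() {
  c(R1 = "C1", R2 = "C2", R3 = "C3", R4 = "C3", R5 = "C3", R6 = "C3",
    R7 = "C3", R8 = "C4")
}

#' Window and threshold configuration
#'
#' Day-based conventions for the algorithm's timeframes. "In the last 12
#' months" is the half-open window \code{(snapshot - lookback, snapshot]};
#' "3-6 months" after acute herpes zoster is the closed day interval
#' \code{[90, 183]}; "3-24 months" after amputation is \code{[90, 730]}.
#' Diagnosis history is unlimited lookback (any code on or before the
#' snapshot).
#'
#' @param analgesic_lookback_days Prescription-counting window length (days).
#' @param postherpetic_window_days Closed interval (length 2) of days between
#'   an acute zoster episode and a qualifying neuropathy/neuropathic-pain code.
#' @param phantom_window_days Closed interval of days between an amputation
#'   and a qualifying neuropathy/neuropathic-pain code.
#' @param tier2_threshold Minimum qualifying analgesic issues for the tier-2
#'   rule ("3 or more").
#' @param criterion4_threshold Minimum qualifying analgesic issues for the
#'   regular-analgesia rule ("4 or more").
#' @return A \code{window_config} list.
#' @export
window_config <- function(analgesic_lookback_days = 365L,
                          postherpetic_window_days = c(90L, 183L),
                          phantom_window_days = c(90L, 730L),
                          tier2_threshold = 3L,
                          criterion4_threshold = 4L) {
  stopifnot(
    analgesic_lookback_days >= 1L,
    tier2_threshold >= 1L, criterion4_threshold >= 1L,
    length(postherpetic_window_days) == 2L,
    postherpetic_window_days[1] >= 0L,
    postherpetic_window_days[1] <= postherpetic_window_days[2],
    length(phantom_window_days) == 2L,
    phantom_window_days[1] >= 0L,
    phantom_window_days[1] <= phantom_window_days[2]
  )
  structure(
    list(
      analgesic_lookback_days = as.integer(analgesic_lookback_days),
      postherpetic_window_days = as.integer(postherpetic_window_days),
      phantom_window_days = as.integer(phantom_window_days),
      tier2_threshold = as.integer(tier2_threshold),
      criterion4_threshold = as.integer(criterion4_threshold)
    ),
    class = "window_config"
  )
}

#' Eligible denominator population
#'
#' All people aged 18 and over at the snapshot date who are currently
#' registered with a general practitioner and have no informed-dissent
#' opt-out. Patients with an unknown birth date cannot have their age
#' established and are excluded with a warning.
#'
#' @param dataset A \code{pain_dataset}.
#' @return Character vector of eligible patient ids.
#' @export
eligible_population <- function(dataset) {
  p <- dataset$patients
  unknown_bd <- is.na(p$birth_date)
  if (any(unknown_bd)) {
    warning(sum(unknown_bd), " patient(s) with unknown birth_date excluded",
            call. = FALSE)
  }
  age <- rep(NA_integer_, nrow(p))
  age[!unknown_bd] <- age_at(p$birth_date[!unknown_bd], dataset$snapshot_date)
  keep <- !unknown_bd & age >= 18L & p$registered_at_snapshot & !p$informed_dissent
  p$patient_id[keep]
}

#' Any matching coded event on or before the snapshot
#'
#' The diagnosis primitive shared by all rules: \code{TRUE} iff the patient
#' has at least one event whose code is in the list, dated on or before the
#' snapshot (inclusive boundary; unlimited lookback).
#'
#' @param dataset A \code{pain_dataset}.
#' @param patient_id Single patient id.
#' @param codelist A \code{codelist} (or bare character vector of codes).
#' @param snapshot_date Defaults to the dataset's snapshot.
#' @return Logical scalar.
#' @export
has_code <- function(dataset, patient_id, codelist,
                     snapshot_date = dataset$snapshot_date) {
  codes <- if (inherits(codelist, "codelist")) codelist$codes else codelist
  ev <- dataset$events
  any(ev$patient_id == patient_id & ev$code %in% codes &
        ev$event_date <= as.Date(snapshot_date))
}

# per-patient event/prescription slices, date-capped at the snapshot
patient_events <- function(dataset, patient_id) {
  dataset$events[dataset$events$patient_id == patient_id &
                   dataset$events$event_date <= dataset$snapshot_date, ]
}

patient_rx <- function(dataset, patient_id) {
  dataset$prescriptions[dataset$prescriptions$patient_id == patient_id &
                          dataset$prescriptions$issue_date <= dataset$snapshot_date, ]
}

#' Count qualifying prescription-only analgesic issues
#'
#' Counts deduplicated prescription issues (patient, drug, date) inside the
#' half-open window \code{(snapshot - lookback, snapshot]} whose category is a
#' prescription-only analgesic: non-opioid analgesics (never low-dose
#' aspirin), opioids, neuropathic-pain analgesics, amitriptyline/nortriptyline
#' TCAs, and antiepileptics only if the patient has no epilepsy diagnosis on
#' or before the snapshot. Other TCAs, other antidepressants, anaesthetics and
#' uncategorised drugs never count.
#'
#' @inheritParams has_code
#' @param registry A valid \code{codelist_registry} (for the epilepsy list).
#' @param config A [window_config()].
#' @return Integer count.
#' @export
count_qualifying_analgesics <- function(dataset, patient_id, registry,
                                        config = window_config()) {
  snapshot <- dataset$snapshot_date
  rx <- dataset$prescriptions
  rx <- rx[rx$patient_id == patient_id, ]
  rx <- rx[!duplicated(rx[c("patient_id", "drug_code", "issue_date")]), ]
  in_window <- rx$issue_date > snapshot - config$analgesic_lookback_days &
    rx$issue_date <= snapshot
  rx <- rx[in_window, ]
  cats <- qualifying_categories()
  if (!has_code(dataset, patient_id, registry$EPILEPSY)) {
    cats <- c(cats, "ANTIEPILEPTIC")
  }
  sum(rx$category %in% cats)
}

#' Rule R1: tier-1 condition
#'
#' Fires iff the patient has any tier-1 condition code — a diagnosis that
#' almost always results in chronic pain — on or before the snapshot.
#'
#' @inheritParams count_qualifying_analgesics
#' @return Logical scalar.
#' @export
evaluate_r1_tier1 <- function(dataset, patient_id, registry) {
  has_code(dataset, patient_id, registry$TIER1_CONDITIONS)
}

#' Rule R2: tier-2 condition with corroborating analgesia
#'
#' Fires iff the patient has any tier-2 condition code and at least
#' \code{tier2_threshold} (default 3) qualifying prescription-only analgesic
#' issues in the last 12 months — the same analgesic list and exclusions as
#' the regular-analgesia rule.
#'
#' @inheritParams count_qualifying_analgesics
#' @return Logical scalar.
#' @export
evaluate_r2_tier2 <- function(dataset, patient_id, registry,
                              config = window_config()) {
  has_code(dataset, patient_id, registry$TIER2_CONDITIONS) &&
    count_qualifying_analgesics(dataset, patient_id, registry, config) >=
      config$tier2_threshold
}

# any pair (a in anchor_dates, n in pain_dates) with n - a inside the closed
# day interval
any_gap_in <- function(anchor_dates, pain_dates, interval) {
  if (length(anchor_dates) == 0L || length(pain_dates) == 0L) return(FALSE)
  gaps <- outer(as.integer(pain_dates), as.integer(anchor_dates), `-`)
  any(gaps >= interval[1] & gaps <= interval[2])
}

#' Criterion 3: the five chronic neuropathic pain rules
#'
#' Evaluates R3-R7 for one patient:
#' \itemize{
#'   \item R3: any trigeminal neuralgia code.
#'   \item R4: any post-herpetic neuralgia code, or a neuropathy /
#'     neuropathic-pain code 3-6 months (90-183 days, closed) after an acute
#'     herpes zoster episode.
#'   \item R5: any phantom-limb-pain code, or a neuropathy / neuropathic-pain
#'     code 3-24 months (90-730 days, closed) after an amputation.
#'   \item R6: a diabetic neuropathy code plus at least one neuropathic-pain
#'     treatment issue — any analgesic except low-dose aspirin, an
#'     anaesthetic, an antiepileptic in patients with no history of epilepsy,
#'     or an antidepressant — on or before the snapshot.
#'   \item R7: diabetes and neuropathic pain, coded separately.
#' }
#' All event dates must be on or before the snapshot.
#'
#' @inheritParams count_qualifying_analgesics
#' @return Character vector: the subset of \code{c("R3","R4","R5","R6","R7")}
#'   that fired.
#' @export
evaluate_criterion3 <- function(dataset, patient_id, registry,
                                config = window_config()) {
  ev <- patient_events(dataset, patient_id)
  has_role <- function(role) any(ev$code %in% registry[[role]]$codes)
  dates_role <- function(role) ev$event_date[ev$code %in% registry[[role]]$codes]

  fired <- character()
  if (has_role("TRIGEMINAL_NEURALGIA")) fired <- c(fired, "R3")

  pain_dates <- dates_role("NEUROPATHIC_PAIN")
  if (has_role("POSTHERPETIC_NEURALGIA") ||
      any_gap_in(dates_role("HERPES_ZOSTER_ACUTE"), pain_dates,
                 config$postherpetic_window_days)) {
    fired <- c(fired, "R4")
  }
  if (has_role("PHANTOM_LIMB_PAIN") ||
      any_gap_in(dates_role("AMPUTATION"), pain_dates,
                 config$phantom_window_days)) {
    fired <- c(fired, "R5")
  }
  if (has_role("DIABETIC_NEUROPATHY")) {
    rx <- patient_rx(dataset, patient_id)
    cats <- treatment_categories()
    if (!has_role("EPILEPSY")) cats <- c(cats, "ANTIEPILEPTIC")
    if (any(rx$category %in% cats)) fired <- c(fired, "R6")
  }
  if (has_role("DIABETES") && has_role("NEUROPATHIC_PAIN")) {
    fired <- c(fired, "R7")
  }
  fired
}

#' Rule R8: regular prescription-only analgesia
#'
#' Fires iff the patient has \code{criterion4_threshold} (default 4) or more
#' qualifying prescription-only analgesic issues in the last 12 months.
#'
#' @inheritParams count_qualifying_analgesics
#' @return Logical scalar.
#' @export
evaluate_r8_analgesia <- function(dataset, patient_id, registry,
                                  config = window_config()) {
  count_qualifying_analgesics(dataset, patient_id, registry, config) >=
    config$criterion4_threshold
}

#' Classify one patient against all eight rules
#'
#' Evaluates every rule and derives the fired criteria through the
#' rule-to-criterion map. Inclusion in the chronic-pain cohort is the union:
#' any fired rule includes the patient.
#'
#' @inheritParams count_qualifying_analgesics
#' @return A list: \code{patient_id}, \code{fired_rules} (character vector),
#'   \code{fired_criteria}, \code{qualifying_analgesic_count}.
#' @export
classify_patient <- function(dataset, patient_id, registry,
                             config = window_config()) {
  if (!patient_id %in% dataset$patients$patient_id) {
    stop("unknown patient_id: ", patient_id, call. = FALSE)
  }
  n_qual <- count_qualifying_analgesics(dataset, patient_id, registry, config)
  fired <- character()
  if (evaluate_r1_tier1(dataset, patient_id, registry)) fired <- c(fired, "R1")
  if (has_code(dataset, patient_id, registry$TIER2_CONDITIONS) &&
      n_qual >= config$tier2_threshold) {
    fired <- c(fired, "R2")
  }
  fired <- c(fired, evaluate_criterion3(dataset, patient_id, registry, config))
  if (n_qual >= config$criterion4_threshold) fired <- c(fired, "R8")
  fired <- intersect(rule_ids(), fired)  # canonical order
  list(
    patient_id = patient_id,
    fired_rules = fired,
    fired_criteria = sort(unique(unname(rule_criterion_map()[fired]))),
    qualifying_analgesic_count = n_qual
  )
}

# ---- vectorised population-level engine ------------------------------------

# ids of eligible patients with >=1 event whose code is in the role list,
# dated <= snapshot
ids_with_role <- function(events, registry, role) {
  unique(events$patient_id[events$code %in% registry[[role]]$codes])
}

# ids with any (anchor, pain) event pair whose day gap lies in the closed
# interval; pairs are enumerated per patient via a join
ids_with_gap <- function(events, registry, anchor_role, interval) {
  a <- events[events$code %in% registry[[anchor_role]]$codes,
              c("patient_id", "event_date")]
  n <- events[events$code %in% registry$NEUROPATHIC_PAIN$codes,
              c("patient_id", "event_date")]
  if (nrow(a) == 0L || nrow(n) == 0L) return(character())
  names(a)[2] <- "anchor_date"
  names(n)[2] <- "pain_date"
  pairs <- dplyr::inner_join(a, n, by = "patient_id", relationship = "many-to-many")
  gap <- as.integer(pairs$pain_date) - as.integer(pairs$anchor_date)
  unique(pairs$patient_id[gap >= interval[1] & gap <= interval[2]])
}

#' Build the chronic-pain cohort at the snapshot date
#'
#' Determines the eligible denominator, evaluates all eight rules for every
#' eligible patient, and assembles the cohort as the union of fired rules.
#' Refuses to run against an invalid registry.
#'
#' @param dataset A \code{pain_dataset}.
#' @param registry A valid \code{codelist_registry}.
#' @param config A [window_config()].
#' @return A \code{cohort_snapshot}: \code{snapshot_date},
#'   \code{eligible_patient_ids}, \code{included_patient_ids}, and a
#'   \code{results} tibble (one row per eligible patient) with logical columns
#'   \code{R1}..\code{R8} and \code{C1}..\code{C4},
#'   \code{qualifying_analgesic_count}, semicolon-joined \code{fired_rules} /
#'   \code{fired_criteria}, and \code{included}.
#' @export
build_cohort <- function(dataset, registry, config = window_config()) {
  report <- validate_registry(registry)
  if (nrow(report) > 0L) {
    stop("invalid code-list registry: ",
         paste(report$role, report$violation, sep = ": ", collapse = "; "),
         call. = FALSE)
  }
  snapshot <- dataset$snapshot_date
  eligible <- eligible_population(dataset)

  ev <- dataset$events
  ev <- ev[ev$patient_id %in% eligible & ev$event_date <= snapshot, ]

  rx <- dataset$prescriptions
  rx <- rx[rx$patient_id %in% eligible & rx$issue_date <= snapshot, ]
  rx <- rx[!duplicated(rx[c("patient_id", "drug_code", "issue_date")]), ]

  epilepsy_ids <- ids_with_role(ev, registry, "EPILEPSY")

  # qualifying analgesic counts in the half-open 12-month window
  win <- rx[rx$issue_date > snapshot - config$analgesic_lookback_days, ]
  qual <- win$category %in% qualifying_categories() |
    (win$category == "ANTIEPILEPTIC" & !(win$patient_id %in% epilepsy_ids))
  counts_tab <- table(win$patient_id[qual])
  n_qual <- stats::setNames(rep(0L, length(eligible)), eligible)
  n_qual[names(counts_tab)] <- as.integer(counts_tab)
  n_qual <- unname(n_qual)

  r1_ids <- ids_with_role(ev, registry, "TIER1_CONDITIONS")
  tier2_ids <- ids_with_role(ev, registry, "TIER2_CONDITIONS")
  r3_ids <- ids_with_role(ev, registry, "TRIGEMINAL_NEURALGIA")
  r4_ids <- union(
    ids_with_role(ev, registry, "POSTHERPETIC_NEURALGIA"),
    ids_with_gap(ev, registry, "HERPES_ZOSTER_ACUTE",
                 config$postherpetic_window_days)
  )
  r5_ids <- union(
    ids_with_role(ev, registry, "PHANTOM_LIMB_PAIN"),
    ids_with_gap(ev, registry, "AMPUTATION", config$phantom_window_days)
  )
  # neuropathic-pain treatment: any qualifying treatment issue <= snapshot
  treat <- rx$category %in% treatment_categories() |
    (rx$category == "ANTIEPILEPTIC" & !(rx$patient_id %in% epilepsy_ids))
  treated_ids <- unique(rx$patient_id[treat])
  r6_ids <- intersect(ids_with_role(ev, registry, "DIABETIC_NEUROPATHY"),
                      treated_ids)
  r7_ids <- intersect(ids_with_role(ev, registry, "DIABETES"),
                      ids_with_role(ev, registry, "NEUROPATHIC_PAIN"))

  res <- tibble::tibble(
    patient_id = eligible,
    R1 = eligible %in% r1_ids,
    R2 = eligible %in% tier2_ids & n_qual >= config$tier2_threshold,
    R3 = eligible %in% r3_ids,
    R4 = eligible %in% r4_ids,
    R5 = eligible %in% r5_ids,
    R6 = eligible %in% r6_ids,
    R7 = eligible %in% r7_ids,
    R8 = n_qual >= config$criterion4_threshold,
    qualifying_analgesic_count = n_qual
  )
  res$C1 <- res$R1
  res$C2 <- res$R2
  res$C3 <- res$R3 | res$R4 | res$R5 | res$R6 | res$R7
  res$C4 <- res$R8
  rule_mat <- as.matrix(res[, rule_ids()])
  crit_mat <- as.matrix(res[, c("C1", "C2", "C3", "C4")])
  join_fired <- function(mat, labels) {
    vapply(seq_len(nrow(mat)),
           function(i) paste(labels[mat[i, ]], collapse = ";"),
           character(1))
  }
  res$fired_rules <- join_fired(rule_mat, rule_ids())
  res$fired_criteria <- join_fired(crit_mat, c("C1", "C2", "C3", "C4"))
  res$included <- rowSums(rule_mat) > 0L
  res <- res[order(res$patient_id), ]

  structure(
    list(
      snapshot_date = snapshot,
      eligible_patient_ids = sort(eligible),
      included_patient_ids = sort(res$patient_id[res$included]),
      results = res,
      rule_counts = colSums(rule_mat)
    ),
    class = "cohort_snapshot"
  )
}

#' @export
print.cohort_snapshot <- function(x, ...) {
  cat("<cohort_snapshot> snapshot", format(x$snapshot_date), "\n")
  cat("  eligible:", length(x$eligible_patient_ids),
      " included:", length(x$included_patient_ids), "\n")
  cat("  per-rule counts:",
      paste(names(x$rule_counts), x$rule_counts, sep = "=", collapse = " "), "\n")
  invisible(x)
}
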