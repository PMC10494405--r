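# Demo code lists live in a clearly-fake 999xxxyyy numeric namespace so they
# cannot be mistaken for real clinical code lists (the study's real lists are
# unpublished). One synthetic code per named tier-1 condition and tier-2
# condition group; a handful per neuropathic/exclusion role.

tier1_condition_names <- function() {
  c("Ankylosing spondylitis", "Chronic low back pain", "Chronic osteomyelitis",
    "Chronic pain", "Complex regional pain syndrome", "Fibromyalgia",
    "Fibrositis", "Periostitis", "Rheumatic pain", "Rheumatism",
    "Rheumatoid arthritis", "Still's disease")
}

tier2_condition_names <- function() {
  c("Arthrosis/arthritis/arthralgia/arthropathy (excl. reactive/transient)",
    "Cervicocranial/cervicobrachial syndrome",
    "Coccygodynia",
    "Connective tissue disorders",
    "Dysmenorrhoea",
    "Endometriosis",
    "Familial chondrocalcinosis",
    "Migraine",
    "Myositis (excl. infective causes)",
    "Osteoarthritis",
    "Osteochondritis",
    "Osteoporosis (incl. fragility fracture and collapsed vertebra)",
    "Pain/ache of different body parts/general aches and pains",
    "Pathological fracture",
    "Polymyalgia rheumatica/PMR/GCA",
    "Radiculopathy (incl. cauda equina compression)/radiculitis",
    "Sciatica",
    "Spinal stenosis",
    "Spondylopathy/spondylosis/spondylolisthesis",
    "Systemic lupus erythematosus")
}

demo_codes <- function() {
  fake <- function(block, n) sprintf("999%03d%03d", block, seq_len(n))
  list(
    TIER1_CONDITIONS = data.frame(
      code = fake(1L, 12L), description = tier1_condition_names()),
    TIER2_CONDITIONS = data.frame(
      code = fake(2L, 20L), description = tier2_condition_names()),
    TRIGEMINAL_NEURALGIA = data.frame(
      code = fake(3L, 2L),
      description = c("Trigeminal neuralgia", "Atypical trigeminal neuralgia")),
    HERPES_ZOSTER_ACUTE = data.frame(
      code = fake(4L, 2L),
      description = c("Acute herpes zoster", "Herpes zoster ophthalmicus")),
    POSTHERPETIC_NEURALGIA = data.frame(
      code = fake(5L, 2L),
      description = c("Post-herpetic neuralgia", "Post-zoster neuropathy")),
    PHANTOM_LIMB_PAIN = data.frame(
      code = fake(6L, 2L),
      description = c("Phantom limb pain", "Phantom limb syndrome with pain")),
    NEUROPATHIC_PAIN = data.frame(
      code = fake(7L, 3L),
      description = c("Neuropathic pain", "Neuropathy", "Peripheral neuropathy")),
    AMPUTATION = data.frame(
      code = fake(8L, 2L),
      description = c("Amputation of lower limb", "Amputation of upper limb")),
    DIABETIC_NEUROPATHY = data.frame(
      code = fake(9L, 2L),
      description = c("Diabetic neuropathy", "Diabetic polyneuropathy")),
    DIABETES = data.frame(
      code = fake(10L, 2L),
      description = c("Type 1 diabetes mellitus", "Type 2 diabetes mellitus")),
    EPILEPSY = data.frame(
      code = fake(11L, 2L),
      description = c("Epilepsy", "Focal epilepsy"))
  )
}

#' Write demonstration code lists and manifest
#'
#' Emits one CSV per registry role — one synthetic code per named tier-1
#' condition (12) and tier-2 condition group (20), plus small lists for the
#' neuropathic-pain and exclusion roles — and a \code{manifest.json} mapping
#' roles to files. Codes sit in a reserved, clearly-fake numeric namespace
#' (\code{999...}): they are demonstration plumbing, never clinical content.
#'
#' @param output_dir Directory to write into (created if absent).
#' @return Path of the written manifest, invisibly.
#' @export
generate_demo_codelists <- function(output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  lists <- demo_codes()
  manifest <- list()
  for (role in names(lists)) {
    fname <- paste0(tolower(role), ".csv")
    utils::write.csv(lists[[role]], file.path(output_dir, fname),
                     row.names = FALSE)
    manifest[[role]] <- fname
  }
  manifest_path <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest_path)
}

#' In-memory demonstration registry
#'
#' The same synthetic code lists as [generate_demo_codelists()], constructed
#' directly as a \code{codelist_registry} without touching disk.
#'
#' @return A valid \code{codelist_registry}.
#' @export
demo_registry <- function() {
  lists <- demo_codes()
  registry <- lapply(names(lists), function(role) {
    new_codelist(role, lists[[role]]$code, source = "builtin-demo")
  })
  names(registry) <- names(lists)
  structure(registry, class = "codelist_registry")
}

#' Synthetic-population generator configuration
#'
#' Defaults emulate the study conditions: a registered adult population over
#' the extract span 1 April 2005 to 31 March 2021 (snapshot at the span end),
#' a 4.6\% informed-dissent fraction, and archetype fractions summing to
#' roughly the 16-17\% chronic-pain prevalence band reported for an inner-city
#' registered adult population. Archetype counts are allocated
#' deterministically (largest remainder), so realised counts are within one
#' patient of \code{n * fraction}.
#'
#' @param n_patients Number of patients to generate.
#' @param seed RNG seed; identical seeds give identical populations.
#' @param target_fractions Named fractions for archetypes \code{R1}..\code{R8}
#'   and \code{multi} (tier-1 plus regular analgesia); the remainder are
#'   \code{none} patients built from decoys only.
#' @param dissent_fraction Fraction flagged with informed dissent (excluded
#'   from the eligible denominator).
#' @param date_span Two dates bounding the coded history.
#' @param decoy_codes_per_patient,noise_rx_per_patient Mean counts (Poisson)
#'   of irrelevant decoy diagnosis codes and never-qualifying prescription
#'   issues added per patient.
#' @return A \code{generator_config} list.
#' @export
generator_config <- function(n_patients = 500L,
                             seed = 1L,
                             target_fractions = c(
                               R1 = 0.05, R2 = 0.03, R3 = 0.005, R4 = 0.005,
                               R5 = 0.005, R6 = 0.01, R7 = 0.01, R8 = 0.04,
                               multi = 0.01),
                             dissent_fraction = 0.046,
                             date_span = as.Date(c("2005-04-01", "2021-03-31")),
                             decoy_codes_per_patient = 2,
                             noise_rx_per_patient = 1) {
  stopifnot(n_patients >= 1L, all(target_fractions >= 0),
            dissent_fraction >= 0, dissent_fraction < 1,
            length(date_span) == 2L)
  if (sum(target_fractions) > 1) {
    stop("archetype fractions sum to ", round(sum(target_fractions), 3),
         " (> 1)", call. = FALSE)
  }
  allowed <- c(rule_ids(), "multi")
  if (!all(names(target_fractions) %in% allowed)) {
    stop("unknown archetype(s): ",
         paste(setdiff(names(target_fractions), allowed), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(n_patients = as.integer(n_patients), seed = as.integer(seed),
         target_fractions = target_fractions,
         dissent_fraction = dissent_fraction,
         date_span = as.Date(date_span),
         decoy_codes_per_patient = decoy_codes_per_patient,
         noise_rx_per_patient = noise_rx_per_patient),
    class = "generator_config"
  )
}

# largest-remainder allocation of n patients to archetype counts; realised
# counts are within one patient of n * fraction
allocate_archetypes <- function(n, fractions) {
  exact <- n * fractions
  counts <- as.integer(floor(exact))
  extra <- as.integer(round(sum(exact))) - sum(counts)
  if (extra > 0L) {
    ord <- order(exact - counts, decreasing = TRUE)
    counts[ord[seq_len(extra)]] <- counts[ord[seq_len(extra)]] + 1L
  }
  counts
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Generate a labelled synthetic population
#'
#' Archetype-based construction: each patient is built to satisfy exactly the
#' rules of their assigned archetype under the default [window_config()] —
#' e.g. an \code{R8} patient gets four or more qualifying issues inside the
#' 12-month window and no diagnosis codes; a \code{none} patient gets only
#' decoy codes and never-qualifying prescriptions. Demographics (gender,
#' five-category ethnicity, IMD quintile, age 18-95) are sampled independently
#' of the rule labels. Deterministic for a fixed seed.
#'
#' @param config A [generator_config()].
#' @param registry A valid \code{codelist_registry} (codes are drawn from it).
#' @return A list: \code{dataset} (a \code{pain_dataset}) and \code{truth}, a
#'   tibble with \code{patient_id}, \code{eligible} (by construction),
#'   \code{archetype}, and semicolon-joined \code{rules} / \code{criteria}.
#' @export
generate_population <- function(config, registry) {
  report <- validate_registry(registry)
  if (nrow(report) > 0L) stop("invalid registry", call. = FALSE)
  with_seed(config$seed, {
    n <- config$n_patients
    snapshot <- config$date_span[2]
    span_start <- config$date_span[1]
    ids <- sprintf("P%06d", seq_len(n))

    fr <- config$target_fractions
    counts <- allocate_archetypes(n, fr)
    archetype <- c(rep(names(fr), counts), rep("none", n - sum(counts)))
    archetype <- archetype[sample.int(n)]

    age <- sample(18:95, n, replace = TRUE, prob = exp(-(18:95 - 18) / 22))
    birth_date <- snapshot - (round(age * 365.25) + sample(0:300, n, replace = TRUE))
    gender <- sample(c("female", "male", "other_unknown"), n, replace = TRUE,
                     prob = c(0.505, 0.49, 0.005))
    ethnicity <- sample(c("White", "Black", "Asian", "Mixed", "Other", "unknown"),
                        n, replace = TRUE,
                        prob = c(0.50, 0.22, 0.12, 0.07, 0.05, 0.04))
    imd <- sample(c(1:5, NA_integer_), n, replace = TRUE,
                  prob = c(0.30, 0.28, 0.20, 0.13, 0.07, 0.02))
    dissent <- rep(FALSE, n)
    n_dissent <- round(n * config$dissent_fraction)
    if (n_dissent > 0) dissent[sample.int(n, n_dissent)] <- TRUE

    patients <- tibble::tibble(
      patient_id = ids, birth_date = birth_date, gender = gender,
      ethnicity = ethnicity, imd_quintile = imd,
      registered_at_snapshot = TRUE, informed_dissent = dissent
    )

    ev <- list(); rx <- list()
    add_ev <- function(id, code, date) {
      ev[[length(ev) + 1L]] <<- data.frame(
        patient_id = id, code = code, event_date = as.Date(date, origin = "1970-01-01"))
    }
    add_rx <- function(id, category, dates, stem) {
      k <- length(dates)
      rx[[length(rx) + 1L]] <<- data.frame(
        patient_id = id, drug_code = sprintf("%s-%02d", stem, seq_len(k)),
        category = category,
        issue_date = as.Date(dates, origin = "1970-01-01"))
    }
    pick <- function(role) sample(registry[[role]]$codes, 1L)
    hist_date <- function() span_start + sample.int(as.integer(snapshot - span_start), 1L)
    # distinct in-window issue dates: offsets 0..364 back from the snapshot
    window_dates <- function(k) snapshot - sample(0:364, k)
    qual_cats <- function(k) sample(qualifying_categories(), k, replace = TRUE)

    for (i in seq_len(n)) {
      id <- ids[i]
      switch(archetype[i],
        R1 = add_ev(id, pick("TIER1_CONDITIONS"), hist_date()),
        R2 = {
          add_ev(id, pick("TIER2_CONDITIONS"), hist_date())
          add_rx(id, qual_cats(3L), window_dates(3L), "SYNQ")
        },
        R3 = add_ev(id, pick("TRIGEMINAL_NEURALGIA"), hist_date()),
        R4 = {
          gap <- sample(90:183, 1L)
          z <- span_start + sample.int(as.integer(snapshot - span_start) - gap, 1L)
          add_ev(id, pick("HERPES_ZOSTER_ACUTE"), z)
          add_ev(id, pick("NEUROPATHIC_PAIN"), z + gap)
        },
        R5 = {
          if (i %% 2L == 0L) {
            add_ev(id, pick("PHANTOM_LIMB_PAIN"), hist_date())
          } else {
            gap <- sample(90:730, 1L)
            a <- span_start + sample.int(as.integer(snapshot - span_start) - gap, 1L)
            add_ev(id, pick("AMPUTATION"), a)
            add_ev(id, pick("NEUROPATHIC_PAIN"), a + gap)
          }
        },
        R6 = {
          add_ev(id, pick("DIABETIC_NEUROPATHY"), hist_date())
          add_rx(id, "ANTIDEPRESSANT_OTHER", hist_date(), "SYNT")
        },
        R7 = {
          add_ev(id, pick("DIABETES"), hist_date())
          add_ev(id, pick("NEUROPATHIC_PAIN"), hist_date())
        },
        R8 = {
          k <- sample(4:6, 1L)
          add_rx(id, qual_cats(k), window_dates(k), "SYNQ")
        },
        multi = {
          add_ev(id, pick("TIER1_CONDITIONS"), hist_date())
          add_rx(id, qual_cats(4L), window_dates(4L), "SYNQ")
        },
        none = NULL
      )
      # decoy diagnosis codes: outside every registry list, never match a rule
      n_decoy <- stats::rpois(1L, config$decoy_codes_per_patient)
      if (n_decoy > 0L) {
        for (d in seq_len(n_decoy)) {
          add_ev(id, sprintf("DECOY%04d", sample.int(500L, 1L)), hist_date())
        }
      }
      # never-qualifying prescription noise (aspirin / uncategorised)
      n_noise <- stats::rpois(1L, config$noise_rx_per_patient)
      if (n_noise > 0L) {
        add_rx(id, sample(c("LOW_DOSE_ASPIRIN", "OTHER"), n_noise, replace = TRUE),
               snapshot - sample(0:5000, n_noise), "SYNN")
      }
    }

    events <- if (length(ev)) tibble::as_tibble(do.call(rbind, ev)) else
      tibble::tibble(patient_id = character(), code = character(),
                     event_date = as.Date(character()))
    prescriptions <- if (length(rx)) tibble::as_tibble(do.call(rbind, rx)) else
      tibble::tibble(patient_id = character(), drug_code = character(),
                     category = character(), issue_date = as.Date(character()))

    map <- rule_criterion_map()
    truth_rules <- ifelse(archetype %in% rule_ids(), archetype,
                   ifelse(archetype == "multi", "R1;R8", ""))
    truth_criteria <- vapply(strsplit(truth_rules, ";"), function(rs) {
      paste(sort(unique(unname(map[rs[nzchar(rs)]]))), collapse = ";")
    }, character(1))

    list(
      dataset = new_dataset(patients, events, prescriptions, snapshot),
      truth = tibble::tibble(
        patient_id = ids, eligible = !dissent, archetype = archetype,
        rules = truth_rules, criteria = truth_criteria
      )
    )
  })
}

#' Handcrafted boundary-case suite
#'
#' A fixed (unseeded) labelled dataset pinning every threshold and window
#' boundary of the algorithm: exactly-3 vs exactly-4 qualifying issues; issues
#' dated on the snapshot and exactly 365 days before it; zoster-to-pain gaps
#' of 89/90/183/184 days; amputation-to-pain gaps of 89/90/730/731 days;
#' epilepsy with antiepileptics; low-dose-aspirin-only and other-TCA-only
#' prescribing; tier-2 with two vs three issues; ages 17 vs 18 at snapshot;
#' informed dissent; and one direct-code patient per neuropathic rule.
#'
#' @param registry A valid \code{codelist_registry}.
#' @param snapshot_date Snapshot date for the suite.
#' @return Same shape as [generate_population()]: \code{dataset} plus
#'   \code{truth} labels (with \code{eligible} flags).
#' @export
generate_boundary_suite <- function(registry,
                                    snapshot_date = as.Date("2021-03-31")) {
  snapshot <- as.Date(snapshot_date)
  code1 <- function(role) registry[[role]]$codes[1]

  patients <- list(); events <- list(); rxs <- list(); truth <- list()
  add_patient <- function(id, rules, birth = as.Date("1980-06-15"),
                          registered = TRUE, dissent = FALSE,
                          eligible = registered && !dissent &&
                            age_at(birth, snapshot) >= 18L) {
    patients[[length(patients) + 1L]] <<- tibble::tibble(
      patient_id = id, birth_date = birth, gender = "female",
      ethnicity = "White", imd_quintile = 3L,
      registered_at_snapshot = registered, informed_dissent = dissent)
    map <- rule_criterion_map()
    truth[[length(truth) + 1L]] <<- tibble::tibble(
      patient_id = id, eligible = eligible, archetype = "boundary",
      rules = paste(rules, collapse = ";"),
      criteria = paste(sort(unique(unname(map[rules]))), collapse = ";"))
  }
  add_event <- function(id, role, date) {
    events[[length(events) + 1L]] <<- tibble::tibble(
      patient_id = id, code = code1(role), event_date = as.Date(date))
  }
  add_rx <- function(id, category, dates) {
    k <- length(dates)
    rxs[[length(rxs) + 1L]] <<- tibble::tibble(
      patient_id = id, drug_code = sprintf("BND-%s-%02d", id, seq_len(k)),
      category = rep_len(category, k), issue_date = as.Date(dates))
  }

  # prescription-count thresholds ("3 or more" / "4 or more")
  add_patient("B_RX3", character()); add_rx("B_RX3", "OPIOID_ANALGESIC", snapshot - c(10, 20, 30))
  add_patient("B_RX4", "R8"); add_rx("B_RX4", "OPIOID_ANALGESIC", snapshot - c(10, 20, 30, 40))
  # 12-month window boundaries: snapshot counts, snapshot - 365 does not
  add_patient("B_RX_SNAP", "R8"); add_rx("B_RX_SNAP", "OPIOID_ANALGESIC", rep(snapshot, 4))
  add_patient("B_RX_EDGE", character()); add_rx("B_RX_EDGE", "OPIOID_ANALGESIC", rep(snapshot - 365, 4))
  # post-herpetic gaps around [90, 183]
  z0 <- as.Date("2019-01-01")
  for (g in c(89, 90, 183, 184)) {
    id <- paste0("B_PHN_", g)
    add_patient(id, if (g >= 90 && g <= 183) "R4" else character())
    add_event(id, "HERPES_ZOSTER_ACUTE", z0)
    add_event(id, "NEUROPATHIC_PAIN", z0 + g)
  }
  # phantom-limb gaps around [90, 730]
  for (g in c(89, 90, 730, 731)) {
    id <- paste0("B_PLP_", g)
    add_patient(id, if (g >= 90 && g <= 730) "R5" else character())
    add_event(id, "AMPUTATION", z0)
    add_event(id, "NEUROPATHIC_PAIN", z0 + g)
  }
  # antiepileptics count only without an epilepsy diagnosis
  add_patient("B_EPI_AED", character())
  add_event("B_EPI_AED", "EPILEPSY", as.Date("2012-05-01"))
  add_rx("B_EPI_AED", "ANTIEPILEPTIC", snapshot - c(5, 15, 25, 35))
  add_patient("B_NOEPI_AED", "R8")
  add_rx("B_NOEPI_AED", "ANTIEPILEPTIC", snapshot - c(5, 15, 25, 35))
  # low-dose aspirin and non-amitriptyline TCAs never count
  add_patient("B_ASPIRIN", character())
  add_rx("B_ASPIRIN", "LOW_DOSE_ASPIRIN", snapshot - c(5, 15, 25, 35))
  add_patient("B_OTHER_TCA", character())
  add_rx("B_OTHER_TCA", "OTHER_TCA", snapshot - c(5, 15, 25, 35))
  add_patient("B_AMI_TCA", "R8")
  add_rx("B_AMI_TCA", "TCA_AMITRIPTYLINE_NORTRIPTYLINE", snapshot - c(5, 15, 25, 35))
  # tier-2 corroboration threshold
  add_patient("B_T2_RX2", character())
  add_event("B_T2_RX2", "TIER2_CONDITIONS", as.Date("2015-06-01"))
  add_rx("B_T2_RX2", "OPIOID_ANALGESIC", snapshot - c(10, 20))
  add_patient("B_T2_RX3", "R2")
  add_event("B_T2_RX3", "TIER2_CONDITIONS", as.Date("2015-06-01"))
  add_rx("B_T2_RX3", "OPIOID_ANALGESIC", snapshot - c(10, 20, 30))
  # eligibility boundaries: 18th birthday on the snapshot counts; 17 does not
  add_patient("B_AGE17", character(), birth = as.Date("2003-04-01"))
  add_event("B_AGE17", "TIER1_CONDITIONS", as.Date("2020-01-01"))
  add_patient("B_AGE18", "R1", birth = as.Date("2003-03-31"))
  add_event("B_AGE18", "TIER1_CONDITIONS", as.Date("2020-01-01"))
  add_patient("B_DISSENT", character(), dissent = TRUE)
  add_event("B_DISSENT", "TIER1_CONDITIONS", as.Date("2020-01-01"))
  add_patient("B_UNREG", character(), registered = FALSE)
  add_event("B_UNREG", "TIER1_CONDITIONS", as.Date("2020-01-01"))
  # diagnosis codes dated after the snapshot never count
  add_patient("B_FUTURE", character())
  add_event("B_FUTURE", "TIER1_CONDITIONS", snapshot + 1)
  # one direct-code patient per neuropathic rule, plus their negatives
  add_patient("B_TRIGEMINAL", "R3"); add_event("B_TRIGEMINAL", "TRIGEMINAL_NEURALGIA", as.Date("2018-02-01"))
  add_patient("B_PHN_CODE", "R4"); add_event("B_PHN_CODE", "POSTHERPETIC_NEURALGIA", as.Date("2018-02-01"))
  add_patient("B_PLP_CODE", "R5"); add_event("B_PLP_CODE", "PHANTOM_LIMB_PAIN", as.Date("2018-02-01"))
  add_patient("B_DN_TREATED", "R6")
  add_event("B_DN_TREATED", "DIABETIC_NEUROPATHY", as.Date("2016-09-01"))
  add_rx("B_DN_TREATED", "ANTIDEPRESSANT_OTHER", as.Date("2017-01-15"))
  add_patient("B_DN_UNTREATED", character())
  add_event("B_DN_UNTREATED", "DIABETIC_NEUROPATHY", as.Date("2016-09-01"))
  add_patient("B_DN_ASPIRIN", character())
  add_event("B_DN_ASPIRIN", "DIABETIC_NEUROPATHY", as.Date("2016-09-01"))
  add_rx("B_DN_ASPIRIN", "LOW_DOSE_ASPIRIN", as.Date("2017-01-15"))
  add_patient("B_DN_EPI_AED", character())
  add_event("B_DN_EPI_AED", "DIABETIC_NEUROPATHY", as.Date("2016-09-01"))
  add_event("B_DN_EPI_AED", "EPILEPSY", as.Date("2010-03-01"))
  add_rx("B_DN_EPI_AED", "ANTIEPILEPTIC", as.Date("2017-01-15"))
  add_patient("B_DM_NP", "R7")
  add_event("B_DM_NP", "DIABETES", as.Date("2014-01-01"))
  add_event("B_DM_NP", "NEUROPATHIC_PAIN", as.Date("2019-01-01"))
  add_patient("B_DM_ONLY", character())
  add_event("B_DM_ONLY", "DIABETES", as.Date("2014-01-01"))

  list(
    dataset = new_dataset(dplyr::bind_rows(patients), dplyr::bind_rows(events),
                          dplyr::bind_rows(rxs), snapshot),
    truth = dplyr::bind_rows(truth)
  )
}
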