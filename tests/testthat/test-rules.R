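reg <- demo_registry()

test_that("eligibility applies age, registration and dissent filters", {
  ds <- mk_dataset(dplyr::bind_rows(
    mk_patients("ADULT18", birth = "2003-03-31"),
    mk_patients("MINOR17", birth = "2003-04-01"),
    mk_patients("DISSENT", dissent = TRUE),
    mk_patients("UNREG", registered = FALSE),
    mk_patients("OK")
  ))
  expect_setequal(eligible_population(ds), c("ADULT18", "OK"))

  # unknown birth date excluded with a warning
  p <- mk_patients(c("A", "B"))
  p$birth_date[2] <- NA
  expect_warning(out <- eligible_population(mk_dataset(p)), "birth_date")
  expect_identical(out, "A")
})

test_that("has_code honours the snapshot boundary inclusively", {
  mk <- function(date) mk_dataset(
    mk_patients("A"),
    mk_events("A", rcode("TIER1_CONDITIONS"), date))
  expect_false(has_code(mk_dataset(mk_patients("A")), "A", reg$TIER1_CONDITIONS))
  expect_true(has_code(mk(as.character(SNAP)), "A", reg$TIER1_CONDITIONS))
  expect_false(has_code(mk(as.character(SNAP + 1)), "A", reg$TIER1_CONDITIONS))
})

test_that("qualifying analgesic counting: window, categories, exclusions, dedup", {
  # 5 opioid issues, 2 before the window start
  ds <- mk_dataset(
    mk_patients("A"),
    rx = mk_rx(rep("A", 5), "OPIOID_ANALGESIC",
               as.character(c(SNAP - c(1, 100, 364), SNAP - c(365, 400)))))
  expect_identical(count_qualifying_analgesics(ds, "A", reg), 3L)

  # low-dose aspirin never counts
  ds <- mk_dataset(mk_patients("A"),
                   rx = mk_rx(rep("A", 4), "LOW_DOSE_ASPIRIN",
                              as.character(SNAP - 1:4)))
  expect_identical(count_qualifying_analgesics(ds, "A", reg), 0L)

  # antiepileptics count only without an epilepsy code; other drugs unaffected
  rx <- mk_rx(rep("A", 5), c(rep("ANTIEPILEPTIC", 4), "OPIOID_ANALGESIC"),
              as.character(SNAP - 1:5))
  no_epi <- mk_dataset(mk_patients("A"), rx = rx)
  expect_identical(count_qualifying_analgesics(no_epi, "A", reg), 5L)
  with_epi <- mk_dataset(mk_patients("A"),
                         mk_events("A", rcode("EPILEPSY"), "2010-01-01"), rx)
  expect_identical(count_qualifying_analgesics(with_epi, "A", reg), 1L)

  # repeat issues of the same drug on the same date collapse to one
  dup <- mk_rx(rep("A", 3), "OPIOID_ANALGESIC",
               as.character(rep(SNAP - 1, 3)), drugs = "SAMEDRUG")
  expect_identical(
    count_qualifying_analgesics(mk_dataset(mk_patients("A"), rx = dup), "A", reg),
    1L)
})

test_that("R2 needs both the tier-2 code and the analgesic threshold", {
  t2 <- mk_events("A", rcode("TIER2_CONDITIONS"), "2018-01-01")
  rx3 <- mk_rx(rep("A", 3), "OPIOID_ANALGESIC", as.character(SNAP - 1:3))
  rx2 <- rx3[1:2, ]
  rx10 <- mk_rx(rep("A", 10), "OPIOID_ANALGESIC", as.character(SNAP - 1:10))
  expect_true(evaluate_r2_tier2(mk_dataset(mk_patients("A"), t2, rx3), "A", reg))
  expect_false(evaluate_r2_tier2(mk_dataset(mk_patients("A"), t2, rx2), "A", reg))
  # analgesia without the diagnosis is R8 territory, not R2
  expect_false(evaluate_r2_tier2(mk_dataset(mk_patients("A"), rx = rx10), "A", reg))
  expect_true(evaluate_r8_analgesia(mk_dataset(mk_patients("A"), rx = rx10), "A", reg))
})

test_that("criterion-3 temporal windows pair anchor and pain events", {
  gap_case <- function(anchor_role, gap) {
    z <- as.Date("2019-01-01")
    mk_dataset(mk_patients("A"),
               mk_events(c("A", "A"), c(rcode(anchor_role), rcode("NEUROPATHIC_PAIN")),
                         as.character(c(z, z + gap))))
  }
  expect_identical(evaluate_criterion3(gap_case("HERPES_ZOSTER_ACUTE", 120), "A", reg), "R4")
  expect_identical(evaluate_criterion3(gap_case("HERPES_ZOSTER_ACUTE", 60), "A", reg), character())
  expect_identical(evaluate_criterion3(gap_case("AMPUTATION", 800), "A", reg), character())
  expect_identical(evaluate_criterion3(gap_case("AMPUTATION", 700), "A", reg), "R5")

  # any qualifying pair suffices even with non-qualifying pairs present
  z <- as.Date("2019-01-01")
  multi <- mk_dataset(
    mk_patients("A"),
    mk_events(rep("A", 3),
              c(rcode("HERPES_ZOSTER_ACUTE"), rcode("NEUROPATHIC_PAIN"),
                rcode("NEUROPATHIC_PAIN")),
              as.character(c(z, z + 30, z + 100))))
  expect_identical(evaluate_criterion3(multi, "A", reg), "R4")
})

test_that("diabetic neuropathy needs a qualifying treatment; diabetes needs pain", {
  dn <- mk_events("A", rcode("DIABETIC_NEUROPATHY"), "2016-01-01")
  treat <- mk_rx("A", "ANTIDEPRESSANT_OTHER", "2017-06-01")
  expect_identical(
    evaluate_criterion3(mk_dataset(mk_patients("A"), dn, treat), "A", reg), "R6")
  expect_identical(
    evaluate_criterion3(mk_dataset(mk_patients("A"), dn), "A", reg), character())
  # diabetes alone fires nothing; with a separately coded neuropathic pain it fires R7
  dm <- mk_events("A", rcode("DIABETES"), "2014-01-01")
  expect_identical(evaluate_criterion3(mk_dataset(mk_patients("A"), dm), "A", reg),
                   character())
  both <- dplyr::bind_rows(dm, mk_events("A", rcode("NEUROPATHIC_PAIN"), "2019-01-01"))
  expect_identical(evaluate_criterion3(mk_dataset(mk_patients("A"), both), "A", reg),
                   "R7")
})

test_that("classify_patient unions rules and maps them to criteria", {
  ds <- mk_dataset(
    mk_patients("A"),
    mk_events("A", rcode("TIER1_CONDITIONS"), "2012-07-01"),
    mk_rx(rep("A", 4), "OPIOID_ANALGESIC", as.character(SNAP - 1:4)))
  res <- classify_patient(ds, "A", reg)
  expect_identical(res$fired_rules, c("R1", "R8"))
  expect_identical(res$fired_criteria, c("C1", "C4"))
  expect_identical(res$qualifying_analgesic_count, 4L)

  none <- classify_patient(mk_dataset(mk_patients("A")), "A", reg)
  expect_identical(none$fired_rules, character())
  expect_identical(none$fired_criteria, character())
  expect_error(classify_patient(ds, "NOBODY", reg), "unknown patient_id")
})

test_that("build_cohort agrees with classify_patient and refuses bad registries", {
  pop <- generate_population(generator_config(n_patients = 60, seed = 5), reg)
  cohort <- build_cohort(pop$dataset, reg)
  for (id in sample(cohort$results$patient_id, 10)) {
    single <- classify_patient(pop$dataset, id, reg)
    row <- cohort$results[cohort$results$patient_id == id, ]
    expect_identical(row$fired_rules,
                     paste(single$fired_rules, collapse = ";"))
    expect_identical(row$qualifying_analgesic_count,
                     single$qualifying_analgesic_count)
  }
  broken <- reg
  broken$TIER1_CONDITIONS$codes <- character()
  expect_error(build_cohort(pop$dataset, broken), "invalid code-list registry")

  empty <- build_cohort(mk_dataset(mk_patients(character())), reg)
  expect_length(empty$eligible_patient_ids, 0L)
  expect_length(empty$included_patient_ids, 0L)
})

test_that("cohort construction is invariant to input row order", {
  pop <- generate_population(generator_config(n_patients = 80, seed = 13), reg)
  ds <- pop$dataset
  set.seed(42)
  shuffled <- painfinder:::new_dataset(
    ds$patients[sample(nrow(ds$patients)), ],
    ds$events[sample(nrow(ds$events)), ],
    ds$prescriptions[sample(nrow(ds$prescriptions)), ],
    ds$snapshot_date)
  expect_identical(build_cohort(ds, reg)$results,
                   build_cohort(shuffled, reg)$results)
})

test_that("epilepsy codes only ever affect antiepileptic counting", {
  # a patient firing R1, R3 and R7 with an antiepileptic-driven R8
  ds <- mk_dataset(
    mk_patients("A"),
    mk_events(rep("A", 4),
              c(rcode("TIER1_CONDITIONS"), rcode("TRIGEMINAL_NEURALGIA"),
                rcode("DIABETES"), rcode("NEUROPATHIC_PAIN")),
              c("2010-01-01", "2011-01-01", "2012-01-01", "2013-01-01")),
    mk_rx(rep("A", 4), "ANTIEPILEPTIC", as.character(SNAP - 1:4)))
  before <- classify_patient(ds, "A", reg)
  expect_identical(before$fired_rules, c("R1", "R3", "R7", "R8"))

  with_epi <- mk_dataset(
    ds$patients,
    dplyr::bind_rows(ds$events, mk_events("A", rcode("EPILEPSY"), "2009-01-01")),
    ds$prescriptions)
  after <- classify_patient(with_epi, "A", reg)
  expect_identical(after$fired_rules, c("R1", "R3", "R7"))
  expect_identical(after$qualifying_analgesic_count, 0L)
})
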