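test_that("read_dataset round-trips a generated population through CSV", {
  pop <- generate_population(generator_config(n_patients = 40, seed = 3),
                             demo_registry())
  dir <- withr::local_tempdir()
  write_dataset(pop$dataset, dir)
  ds <- read_dataset(file.path(dir, "patients.csv"), file.path(dir, "events.csv"),
                     file.path(dir, "prescriptions.csv"), SNAP)
  expect_identical(nrow(ds$patients), nrow(pop$dataset$patients))
  expect_identical(nrow(ds$events), nrow(pop$dataset$events))
  expect_identical(nrow(ds$prescriptions), nrow(pop$dataset$prescriptions))
  # same cohort either way
  c1 <- build_cohort(pop$dataset, demo_registry())
  c2 <- build_cohort(ds, demo_registry())
  expect_identical(c1$results, c2$results)
})

test_that("reading is order-insensitive and collapses exact duplicates", {
  pop <- generate_population(generator_config(n_patients = 30, seed = 11),
                             demo_registry())
  dir <- withr::local_tempdir()
  write_dataset(pop$dataset, dir)
  # permute and duplicate the event rows
  ev <- utils::read.csv(file.path(dir, "events.csv"), colClasses = "character")
  set.seed(1)
  ev2 <- rbind(ev[sample(nrow(ev)), ], ev[1, ])
  utils::write.csv(ev2, file.path(dir, "events.csv"), row.names = FALSE,
                   quote = FALSE)
  expect_message(
    ds <- read_dataset(file.path(dir, "patients.csv"), file.path(dir, "events.csv"),
                       file.path(dir, "prescriptions.csv"), SNAP),
    "duplicate")
  c1 <- build_cohort(pop$dataset, demo_registry())
  c2 <- build_cohort(ds, demo_registry())
  expect_identical(c1$results, c2$results)
})

test_that("malformed rows, orphans and odd demographics are handled", {
  dir <- withr::local_tempdir()
  writeLines(c("patient_id,birth_date,gender,ethnicity,imd_quintile,registered_at_snapshot,informed_dissent",
               "P1,1980-01-01,female,White,2,true,false",
               "P2,1990-05-05,wibble,Martian,9,true,false"),
             file.path(dir, "patients.csv"))
  writeLines(c("patient_id,code,event_date", "P1,1001,2019-05-01",
               "GHOST,1001,2019-05-01"),
             file.path(dir, "events.csv"))
  writeLines(c("patient_id,drug_code,category,issue_date",
               "P1,D1,OPIOID_ANALGESIC,2021-02-30"),
             file.path(dir, "prescriptions.csv"))
  expect_error(
    suppressWarnings(read_dataset(file.path(dir, "patients.csv"),
                                  file.path(dir, "events.csv"),
                                  file.path(dir, "prescriptions.csv"), SNAP)),
    "malformed issue date")

  writeLines(c("patient_id,drug_code,category,issue_date",
               "P1,D1,OPIOID_ANALGESIC,2021-02-28"),
             file.path(dir, "prescriptions.csv"))
  warns <- capture_warnings(
    ds <- read_dataset(file.path(dir, "patients.csv"),
                       file.path(dir, "events.csv"),
                       file.path(dir, "prescriptions.csv"), SNAP))
  expect_match(warns, "gender", all = FALSE)
  expect_match(warns, "ethnicity", all = FALSE)
  expect_match(warns, "imd_quintile", all = FALSE)
  expect_match(warns, "unknown patient_id", all = FALSE)
  expect_identical(nrow(ds$events), 1L)  # orphan rejected
  expect_identical(ds$patients$gender[2], "other_unknown")
  expect_identical(ds$patients$ethnicity[2], "unknown")
  expect_true(is.na(ds$patients$imd_quintile[2]))
  expect_error(
    suppressWarnings(read_dataset(file.path(dir, "patients.csv"),
                                  file.path(dir, "events.csv"),
                                  file.path(dir, "prescriptions.csv"), SNAP,
                                  on_orphans = "error")),
    "unknown patient_id")
})

test_that("cohort files round-trip, including the empty cohort", {
  reg <- demo_registry()
  ds <- mk_dataset(
    mk_patients(c("A", "B")),
    mk_events(c("A", "A"), c(rcode("TIER1_CONDITIONS"), rcode("PHANTOM_LIMB_PAIN")),
              c("2015-01-01", "2016-01-01")),
    mk_rx(rep("A", 4), "OPIOID_ANALGESIC",
          as.character(SNAP - c(1, 2, 3, 4))))
  cohort <- build_cohort(ds, reg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_identical(back$patient_id, "A")
  expect_identical(back$rules, "R1;R5;R8")
  expect_identical(back$criteria, "C1;C3;C4")

  empty <- build_cohort(mk_dataset(mk_patients("Z")), reg)
  write_cohort(empty, path)
  expect_identical(nrow(read_cohort(path)), 0L)
})

test_that("prevalence files round-trip with full precision", {
  tab <- tibble::tibble(
    stratifier = "gender", stratum = c("female", "male"),
    numerator = c(1L, 2L), denominator = c(3L, 7L),
    prevalence_percent = 100 * c(1, 2) / c(3, 7))
  path <- withr::local_tempfile(fileext = ".csv")
  write_prevalence(tab, path)
  back <- read_prevalence(path)
  expect_equal(back, tab)

  write_prevalence(tab[0, ], path)
  expect_identical(nrow(read_prevalence(path)), 0L)
})
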