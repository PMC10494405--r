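# Fixture builders: everything constructed in code, no files needed.

SNAP <- as.Date("2021-03-31")

test_registry <- function() demo_registry()

mk_patients <- function(ids, birth = "1980-01-01", gender = "female",
                        ethnicity = "White", imd = 3L, registered = TRUE,
                        dissent = FALSE) {
  n <- length(ids)
  tibble::tibble(
    patient_id = ids,
    birth_date = as.Date(rep_len(birth, n)),
    gender = rep_len(gender, n),
    ethnicity = rep_len(ethnicity, n),
    imd_quintile = rep_len(as.integer(imd), n),
    registered_at_snapshot = rep_len(registered, n),
    informed_dissent = rep_len(dissent, n)
  )
}

mk_events <- function(ids = character(), codes = character(), dates = character()) {
  tibble::tibble(patient_id = ids, code = codes, event_date = as.Date(dates))
}

mk_rx <- function(ids = character(), cats = character(), dates = character(),
                  drugs = NULL) {
  n <- length(ids)
  if (is.null(drugs)) drugs <- sprintf("DRUG-%03d", seq_len(max(n, 0)))
  tibble::tibble(patient_id = ids, drug_code = rep_len(drugs, n),
                 category = rep_len(cats, n), issue_date = as.Date(dates))
}

mk_dataset <- function(patients, events = mk_events(), rx = mk_rx(),
                       snapshot = SNAP) {
  painfinder:::new_dataset(patients, events, rx, snapshot)
}

# first code of a role in the demo registry
rcode <- function(role, i = 1L) demo_registry()[[role]]$codes[i]
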