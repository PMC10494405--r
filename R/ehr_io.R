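#' @importFrom dplyr %>%
NULL

parse_iso_date <- function(x, what, file = what) {
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(x) & nzchar(x))
  if (length(bad) > 0L) {
    stop("malformed ", what, " date(s) in ", file, " at row(s): ",
         paste(utils::head(bad, 20L), collapse = ", "),
         if (length(bad) > 20L) " ..." else "",
         call. = FALSE)
  }
  d[is.na(x) | !nzchar(x)] <- NA
  d
}

normalise_gender <- function(x) {
  g <- tolower(trimws(x))
  out <- ifelse(g %in% c("female", "f"), "female",
         ifelse(g %in% c("male", "m"), "male", "other_unknown"))
  unknown_raw <- !(g %in% c("female", "f", "male", "m", "other", "unknown",
                            "other_unknown", "", NA))
  if (any(unknown_raw, na.rm = TRUE)) {
    warning(sum(unknown_raw, na.rm = TRUE),
            " unrecognised gender value(s) mapped to other_unknown", call. = FALSE)
  }
  out[is.na(x)] <- "other_unknown"
  out
}

normalise_ethnicity <- function(x) {
  known <- c("White", "Black", "Asian", "Mixed", "Other")
  e <- trimws(x)
  matched <- known[match(tolower(e), tolower(known))]
  out <- ifelse(is.na(matched), "unknown", matched)
  unrecognised <- !is.na(e) & nzchar(e) & is.na(matched) &
    !(tolower(e) %in% "unknown")
  if (any(unrecognised)) {
    warning(sum(unrecognised),
            " unrecognised ethnicity value(s) mapped to unknown", call. = FALSE)
  }
  out
}

parse_logical_col <- function(x, what) {
  v <- tolower(trimws(as.character(x)))
  out <- ifelse(v %in% c("true", "t", "1", "yes"), TRUE,
         ifelse(v %in% c("false", "f", "0", "no"), FALSE, NA))
  if (anyNA(out)) {
    stop("unparseable logical value(s) in column ", what, " at row(s): ",
         paste(utils::head(which(is.na(out)), 20L), collapse = ", "), call. = FALSE)
  }
  out
}

#' Read a flat-table primary-care dataset
#'
#' Loads the three CSV tables the algorithm consumes and bundles them with a
#' snapshot date. Dates are ISO-8601 (\code{YYYY-MM-DD}); malformed dates
#' raise a row-level error. Exact duplicate rows are collapsed by default
#' (common in EHR extracts) with a message reporting the count. Events and
#' prescriptions for unknown patients are dropped with a warning (or raise an
#' error with \code{on_orphans = "error"}). Events dated after the snapshot
#' are retained — filtering is the rules engine's job — so one dataset can
#' serve several snapshot dates.
#'
#' @param patients_path CSV: \code{patient_id,birth_date,gender,ethnicity,imd_quintile,registered_at_snapshot,informed_dissent}.
#' @param events_path CSV: \code{patient_id,code,event_date}.
#' @param prescriptions_path CSV: \code{patient_id,drug_code,category,issue_date}.
#' @param snapshot_date The census date (\code{Date} or ISO string).
#' @param keep_duplicates Keep exact duplicate event/prescription rows.
#' @param on_orphans \code{"drop"} (default, with warning) or \code{"error"}.
#' @return A \code{pain_dataset}: list of \code{patients}, \code{events},
#'   \code{prescriptions} tibbles plus \code{snapshot_date}.
#' @export
read_dataset <- function(patients_path, events_path, prescriptions_path,
                         snapshot_date, keep_duplicates = FALSE,
                         on_orphans = c("drop", "error")) {
  on_orphans <- match.arg(on_orphans)
  for (p in c(patients_path, events_path, prescriptions_path)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  snapshot_date <- as.Date(snapshot_date)
  if (is.na(snapshot_date)) stop("invalid snapshot_date", call. = FALSE)

  pt <- utils::read.csv(patients_path, colClasses = "character", strip.white = TRUE)
  patients <- tibble::tibble(
    patient_id = pt$patient_id,
    birth_date = parse_iso_date(pt$birth_date, "birth", patients_path),
    gender = normalise_gender(pt$gender),
    ethnicity = normalise_ethnicity(pt$ethnicity),
    imd_quintile = suppressWarnings(as.integer(pt$imd_quintile)),
    registered_at_snapshot = parse_logical_col(pt$registered_at_snapshot,
                                               "registered_at_snapshot"),
    informed_dissent = parse_logical_col(pt$informed_dissent, "informed_dissent")
  )
  if (anyDuplicated(patients$patient_id)) {
    stop("duplicate patient_id(s) in ", patients_path, call. = FALSE)
  }
  bad_imd <- !is.na(patients$imd_quintile) &
    (patients$imd_quintile < 1L | patients$imd_quintile > 5L)
  if (any(bad_imd)) {
    warning(sum(bad_imd), " imd_quintile value(s) outside 1-5 set to unknown",
            call. = FALSE)
    patients$imd_quintile[bad_imd] <- NA_integer_
  }
  future_birth <- !is.na(patients$birth_date) & patients$birth_date > snapshot_date
  if (any(future_birth)) {
    stop("birth_date after snapshot for patient(s): ",
         paste(utils::head(patients$patient_id[future_birth], 10L), collapse = ", "),
         call. = FALSE)
  }

  ev <- utils::read.csv(events_path, colClasses = "character", strip.white = TRUE)
  events <- tibble::tibble(
    patient_id = ev$patient_id,
    code = trimws(ev$code),
    event_date = parse_iso_date(ev$event_date, "event", events_path)
  )
  if (anyNA(events$event_date)) {
    stop("missing event_date in ", events_path, " at row(s): ",
         paste(utils::head(which(is.na(events$event_date)), 20L), collapse = ", "),
         call. = FALSE)
  }

  rx <- utils::read.csv(prescriptions_path, colClasses = "character",
                        strip.white = TRUE)
  prescriptions <- tibble::tibble(
    patient_id = rx$patient_id,
    drug_code = trimws(rx$drug_code),
    category = trimws(rx$category),
    issue_date = parse_iso_date(rx$issue_date, "issue", prescriptions_path)
  )
  unknown_cat <- !(prescriptions$category %in% drug_categories())
  if (any(unknown_cat)) {
    stop("unknown prescription category value(s): ",
         paste(unique(prescriptions$category[unknown_cat]), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(prescriptions$issue_date)) {
    stop("missing issue_date in ", prescriptions_path, call. = FALSE)
  }

  if (!keep_duplicates) {
    n0 <- nrow(events)
    events <- dplyr::distinct(events)
    n1 <- nrow(prescriptions)
    prescriptions <- dplyr::distinct(prescriptions)
    dropped <- (n0 - nrow(events)) + (n1 - nrow(prescriptions))
    if (dropped > 0L) {
      message("read_dataset: collapsed ", dropped, " exact duplicate row(s)")
    }
  }

  orphan_ev <- !(events$patient_id %in% patients$patient_id)
  orphan_rx <- !(prescriptions$patient_id %in% patients$patient_id)
  if (any(orphan_ev) || any(orphan_rx)) {
    msg <- paste0(sum(orphan_ev), " event row(s) and ", sum(orphan_rx),
                  " prescription row(s) reference unknown patient_id")
    if (on_orphans == "error") stop(msg, call. = FALSE)
    warning(msg, "; rejected", call. = FALSE)
    events <- events[!orphan_ev, ]
    prescriptions <- prescriptions[!orphan_rx, ]
  }

  new_dataset(patients, events, prescriptions, snapshot_date)
}

new_dataset <- function(patients, events, prescriptions, snapshot_date) {
  structure(
    list(patients = patients, events = events, prescriptions = prescriptions,
         snapshot_date = as.Date(snapshot_date)),
    class = "pain_dataset"
  )
}

#' @export
print.pain_dataset <- function(x, ...) {
  cat("<pain_dataset> snapshot", format(x$snapshot_date), "-",
      nrow(x$patients), "patients,", nrow(x$events), "events,",
      nrow(x$prescriptions), "prescription issues\n")
  invisible(x)
}

# write atomically: temp file in the target directory, then rename
write_csv_atomic <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv")
  utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE, na = "")
  if (!file.rename(tmp, path)) {
    file.remove(tmp)
    stop("could not write ", path, call. = FALSE)
  }
  invisible(path)
}

#' Write a cohort snapshot to CSV
#'
#' One row per included patient with the fired rule ids (\code{R1}..\code{R8})
#' and criteria (\code{C1}..\code{C4}) as semicolon-joined lists. Round-trips
#' losslessly through [read_cohort()].
#'
#' @param cohort A \code{cohort_snapshot} from [build_cohort()].
#' @param path Output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  rows <- cohort$results[cohort$results$included, , drop = FALSE]
  out <- tibble::tibble(
    patient_id = rows$patient_id,
    rules = rows$fired_rules,
    criteria = rows$fired_criteria
  )
  write_csv_atomic(out, path)
}

#' Read a cohort CSV written by [write_cohort()]
#'
#' @param path CSV path.
#' @return Tibble with \code{patient_id}, \code{rules}, \code{criteria}.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  tibble::as_tibble(df)
}

#' Write a prevalence table to CSV
#'
#' Columns \code{stratifier,stratum,numerator,denominator,prevalence_percent};
#' the percent column keeps full precision (display rounding is a
#' presentation concern).
#'
#' @param table A prevalence tibble from [prevalence_by()].
#' @param path Output CSV path.
#' @export
write_prevalence <- function(table, path) {
  stopifnot(all(c("stratifier", "stratum", "numerator", "denominator",
                  "prevalence_percent") %in% names(table)))
  write_csv_atomic(table, path)
}

#' Read a prevalence CSV written by [write_prevalence()]
#'
#' @param path CSV path.
#' @return Tibble with the prevalence-table columns.
#' @export
read_prevalence <- function(path) {
  if (!file.exists(path)) stop("prevalence file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = c(
    stratifier = "character", stratum = "character", numerator = "integer",
    denominator = "integer", prevalence_percent = "numeric"))
  tibble::as_tibble(df)
}

#' Write a dataset back to the three flat CSV tables
#'
#' Inverse of [read_dataset()]; used by the synthetic-data generator CLI.
#'
#' @param dataset A \code{pain_dataset}.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- dataset$patients
  p$birth_date <- format(p$birth_date)
  p$gender <- ifelse(p$gender == "other_unknown", "other", p$gender)
  p$registered_at_snapshot <- tolower(as.character(p$registered_at_snapshot))
  p$informed_dissent <- tolower(as.character(p$informed_dissent))
  e <- dataset$events
  e$event_date <- format(e$event_date)
  r <- dataset$prescriptions
  r$issue_date <- format(r$issue_date)
  paths <- file.path(dir, c("patients.csv", "events.csv", "prescriptions.csv"))
  write_csv_atomic(p, paths[1])
  write_csv_atomic(e, paths[2])
  write_csv_atomic(r, paths[3])
  invisible(paths)
}
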