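#' Age in completed years at a date
#'
#' Birthday-anniversary convention: the age increments on the anniversary of
#' the birth date (a 29 February birthday increments on 1 March in common
#' years). Vectorised over \code{birth_date}.
#'
#' @param birth_date \code{Date} vector.
#' @param snapshot_date Single \code{Date} (or ISO string).
#' @return Integer vector of completed years.
#' @export
age_at <- function(birth_date, snapshot_date) {
  birth_date <- as.Date(birth_date)
  snapshot_date <- as.Date(snapshot_date)
  if (any(birth_date > snapshot_date, na.rm = TRUE)) {
    stop("birth_date after snapshot_date", call. = FALSE)
  }
  b <- as.POSIXlt(birth_date)
  s <- as.POSIXlt(snapshot_date)
  years <- s$year - b$year
  before_anniversary <- (s$mon < b$mon) | (s$mon == b$mon & s$mday < b$mday)
  as.integer(years - before_anniversary)
}

#' Available stratifiers for prevalence reporting
#'
#' Each stratifier maps every eligible patient to exactly one stratum, with
#' \code{"unknown"} as the catch-all, so numerators and denominators always
#' sum to the overall cohort counts.
#'
#' @return Character vector of stratifier names.
#' @export
stratifiers <- function() {
  c("age_band", "age_18_64_vs_65_plus", "gender", "ethnicity5",
    "imd_quintile", "imd_most_vs_least")
}

age_band_labels <- function() {
  c("18-24", "25-34", "35-44", "45-54", "55-64", "65-74", "75-84", "85+")
}

# stratum label per patient for a given stratifier; 'unknown' catch-all
stratum_of <- function(patients, stratifier, snapshot_date) {
  switch(stratifier,
    age_band = {
      age <- age_at(patients$birth_date, snapshot_date)
      idx <- findInterval(age, c(18, 25, 35, 45, 55, 65, 75, 85))
      out <- ifelse(is.na(age) | idx == 0L, "unknown", age_band_labels()[idx])
      out
    },
    age_18_64_vs_65_plus = {
      age <- age_at(patients$birth_date, snapshot_date)
      ifelse(is.na(age), "unknown", ifelse(age >= 65L, "65+", "18-64"))
    },
    gender = ifelse(is.na(patients$gender), "other_unknown", patients$gender),
    ethnicity5 = ifelse(is.na(patients$ethnicity), "unknown", patients$ethnicity),
    imd_quintile = ifelse(is.na(patients$imd_quintile), "unknown",
                          as.character(patients$imd_quintile)),
    imd_most_vs_least = ifelse(is.na(patients$imd_quintile), "unknown",
      ifelse(patients$imd_quintile == 1L, "most_deprived_q1",
      ifelse(patients$imd_quintile == 5L, "least_deprived_q5", "q2_q4"))),
    stop("unknown stratifier: ", stratifier, "; valid options: ",
         paste(stratifiers(), collapse = ", "), call. = FALSE)
  )
}

#' Overall snapshot prevalence
#'
#' Crude prevalence of the identified cohort against the eligible denominator:
#' \code{100 * included / eligible}, reported to one decimal place (half-even).
#'
#' @param cohort A \code{cohort_snapshot}.
#' @return List with \code{numerator}, \code{denominator}, \code{percent}.
#' @export
prevalence_overall <- function(cohort) {
  den <- length(cohort$eligible_patient_ids)
  if (den == 0L) {
    stop("empty eligible denominator: prevalence undefined", call. = FALSE)
  }
  num <- length(cohort$included_patient_ids)
  list(numerator = num, denominator = den, percent = round(100 * num / den, 1))
}

#' Stratified snapshot prevalence
#'
#' Per-stratum numerator (included patients), denominator (eligible patients)
#' and crude prevalence, reproducing the stratified reporting structure: age
#' bands, 18-64 vs 65+, gender, five-category census ethnicity, IMD quintile
#' (1 = most deprived nationally) and most- vs least-deprived quintile.
#' Unknown demographic values form explicit \code{"unknown"} strata so sums
#' are conserved; strata with a zero denominator are omitted.
#'
#' @param cohort A \code{cohort_snapshot}.
#' @param patients The patients tibble (or a \code{pain_dataset}).
#' @param stratifier One of [stratifiers()].
#' @return Tibble with columns \code{stratifier}, \code{stratum},
#'   \code{numerator}, \code{denominator}, \code{prevalence_percent}
#'   (full precision).
#' @export
prevalence_by <- function(cohort, patients, stratifier) {
  if (inherits(patients, "pain_dataset")) patients <- patients$patients
  if (!stratifier %in% stratifiers()) {
    stop("unknown stratifier: ", stratifier, "; valid options: ",
         paste(stratifiers(), collapse = ", "), call. = FALSE)
  }
  p <- patients[patients$patient_id %in% cohort$eligible_patient_ids, ]
  stratum <- stratum_of(p, stratifier, cohort$snapshot_date)
  included <- p$patient_id %in% cohort$included_patient_ids
  den <- table(stratum)
  num <- table(factor(stratum[included], levels = names(den)))
  out <- tibble::tibble(
    stratifier = stratifier,
    stratum = names(den),
    numerator = as.integer(num),
    denominator = as.integer(den)
  )
  out$prevalence_percent <- 100 * out$numerator / out$denominator
  # stable, readable ordering
  lev <- switch(stratifier,
    age_band = c(age_band_labels(), "unknown"),
    age_18_64_vs_65_plus = c("18-64", "65+", "unknown"),
    gender = c("female", "male", "other_unknown"),
    ethnicity5 = c("White", "Black", "Asian", "Mixed", "Other", "unknown"),
    imd_quintile = c(as.character(1:5), "unknown"),
    imd_most_vs_least = c("most_deprived_q1", "q2_q4", "least_deprived_q5", "unknown")
  )
  out[order(match(out$stratum, lev)), ]
}
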