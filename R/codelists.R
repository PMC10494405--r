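#' Code-list roles used by the logic rules
#'
#' The case-finding logic references eleven named code sets: the tier-1 and
#' tier-2 condition lists, the neuropathic-pain rule lists (trigeminal
#' neuralgia, acute herpes zoster, post-herpetic neuralgia, phantom limb pain,
#' neuropathy/neuropathic pain, amputation, diabetic neuropathy, diabetes) and
#' the epilepsy exclusion list.
#'
#' @return Character vector of the eleven role names.
#' @export
codelist_roles <- function() {
  c(
    "TIER1_CONDITIONS",
    "TIER2_CONDITIONS",
    "TRIGEMINAL_NEURALGIA",
    "HERPES_ZOSTER_ACUTE",
    "POSTHERPETIC_NEURALGIA",
    "PHANTOM_LIMB_PAIN",
    "NEUROPATHIC_PAIN",
    "AMPUTATION",
    "DIABETIC_NEUROPATHY",
    "DIABETES",
    "EPILEPSY"
  )
}

#' Prescription drug categories
#'
#' Prescription issues carry a category, the analogue of a BNF chapter
#' grouping. \code{NON_OPIOID_ANALGESIC}, \code{OPIOID_ANALGESIC},
#' \code{NEUROPATHIC_ANALGESIC}, \code{TCA_AMITRIPTYLINE_NORTRIPTYLINE} and
#' (absent an epilepsy diagnosis) \code{ANTIEPILEPTIC} count towards the
#' prescription-only-analgesia thresholds; \code{LOW_DOSE_ASPIRIN} and
#' \code{OTHER_TCA} never do. \code{ANTIDEPRESSANT_OTHER} and
#' \code{ANAESTHETIC} only qualify as neuropathic-pain treatments for the
#' painful-diabetic-neuropathy rule.
#'
#' @return Character vector of the ten category names.
#' @export
drug_categories <- function() {
  c(
    "NON_OPIOID_ANALGESIC",
    "LOW_DOSE_ASPIRIN",
    "OPIOID_ANALGESIC",
    "NEUROPATHIC_ANALGESIC",
    "TCA_AMITRIPTYLINE_NORTRIPTYLINE",
    "OTHER_TCA",
    "ANTIEPILEPTIC",
    "ANTIDEPRESSANT_OTHER",
    "ANAESTHETIC",
    "OTHER"
  )
}

# categories counting towards the tier-2 / regular-analgesia thresholds
# (antiepileptics conditional on no epilepsy diagnosis)
qualifying_categories <- function() {
  c("NON_OPIOID_ANALGESIC", "OPIOID_ANALGESIC", "NEUROPATHIC_ANALGESIC",
    "TCA_AMITRIPTYLINE_NORTRIPTYLINE")
}

# categories qualifying as a neuropathic-pain treatment (painful diabetic
# neuropathy rule): any analgesic except low-dose aspirin, any TCA or other
# antidepressant, anaesthetics, plus antiepileptics absent epilepsy
treatment_categories <- function() {
  c("NON_OPIOID_ANALGESIC", "OPIOID_ANALGESIC", "NEUROPATHIC_ANALGESIC",
    "TCA_AMITRIPTYLINE_NORTRIPTYLINE", "OTHER_TCA", "ANTIDEPRESSANT_OTHER",
    "ANAESTHETIC")
}

new_codelist <- function(role, codes, description = "", source = "builtin-demo") {
  structure(
    list(role = role, codes = codes, description = description, source = source),
    class = "codelist"
  )
}

#' @export
print.codelist <- function(x, ...) {
  cat("<codelist> role:", x$role, "-", length(x$codes), "codes\n")
  invisible(x)
}

#' Load a single code list
#'
#' Reads a CSV with a \code{code} column (and optional \code{description}),
#' trims whitespace and deduplicates. Duplicate codes are collapsed with a
#' message reporting the count.
#'
#' @param path Path to a CSV file with header \code{code,description}.
#' @param role One of [codelist_roles()].
#' @return A \code{codelist} object.
#' @export
load_codelist <- function(path, role) {
  role <- match.arg(role, codelist_roles())
  if (!file.exists(path)) {
    stop("code-list file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  if (!"code" %in% names(df)) {
    stop("code-list file for role ", role, " lacks a 'code' column: ", path,
         call. = FALSE)
  }
  codes <- trimws(df$code)
  codes <- codes[nzchar(codes)]
  if (length(codes) == 0L) {
    stop("validation error: code list for role ", role, " is empty (", path, ")",
         call. = FALSE)
  }
  n_dup <- length(codes) - length(unique(codes))
  if (n_dup > 0L) {
    message("load_codelist: ", n_dup, " duplicate code(s) collapsed for role ", role)
  }
  new_codelist(role, unique(codes), source = path)
}

#' Load a full code-list registry from a manifest
#'
#' The manifest (JSON or YAML) maps each of the eleven roles to a code-list
#' CSV; relative paths resolve against the manifest's directory. A directory
#' containing \code{manifest.json} may be given instead of the file.
#'
#' @param path Manifest file (\code{.json}/\code{.yaml}/\code{.yml}) or a
#'   directory containing \code{manifest.json}.
#' @return A \code{codelist_registry}: a named list of \code{codelist}
#'   objects, one per role.
#' @export
load_registry <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  if (!file.exists(path)) {
    stop("registry manifest not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  manifest <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("unsupported manifest format: ", ext, call. = FALSE)
  )
  missing <- setdiff(codelist_roles(), names(manifest))
  if (length(missing) > 0L) {
    stop("registry manifest missing role(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  base <- dirname(path)
  lists <- lapply(codelist_roles(), function(role) {
    p <- manifest[[role]]
    if (!file.exists(p)) p <- file.path(base, manifest[[role]])
    load_codelist(p, role)
  })
  names(lists) <- codelist_roles()
  registry <- structure(lists, class = "codelist_registry")
  overlap <- intersect(registry$TIER1_CONDITIONS$codes, registry$TIER2_CONDITIONS$codes)
  if (length(overlap) > 0L) {
    stop("tier-1/tier-2 code lists overlap: ", paste(overlap, collapse = ", "),
         call. = FALSE)
  }
  registry
}

#' @export
print.codelist_registry <- function(x, ...) {
  cat("<codelist_registry> with", length(x), "roles\n")
  for (role in names(x)) {
    cat(sprintf("  %-26s %d codes\n", role, length(x[[role]]$codes)))
  }
  invisible(x)
}

#' Validate a code-list registry
#'
#' Checks the structural invariants the rules engine relies on: all eleven
#' roles present and non-empty, codes whitespace-clean, and the tier-1 and
#' tier-2 lists disjoint (so rule attribution is deterministic).
#' Violations are returned as data rather than raised.
#'
#' @param registry A \code{codelist_registry}.
#' @return A tibble with columns \code{role} and \code{violation};
#'   zero rows means the registry is valid.
#' @export
validate_registry <- function(registry) {
  violations <- list()
  add <- function(role, msg) {
    violations[[length(violations) + 1L]] <<- tibble::tibble(role = role, violation = msg)
  }
  for (role in codelist_roles()) {
    cl <- registry[[role]]
    if (is.null(cl)) {
      add(role, "role missing from registry")
      next
    }
    if (length(cl$codes) == 0L) add(role, "code list is empty")
    bad <- cl$codes[!nzchar(trimws(cl$codes)) | cl$codes != trimws(cl$codes)]
    if (length(bad) > 0L) add(role, "codes with surrounding whitespace or empty codes")
    if (anyDuplicated(cl$codes)) add(role, "duplicate codes present")
  }
  t1 <- registry$TIER1_CONDITIONS
  t2 <- registry$TIER2_CONDITIONS
  if (!is.null(t1) && !is.null(t2)) {
    overlap <- intersect(t1$codes, t2$codes)
    if (length(overlap) > 0L) {
      add("TIER1_CONDITIONS", paste0("codes shared with TIER2_CONDITIONS: ",
                                     paste(overlap, collapse = ", ")))
    }
  }
  if (length(violations) == 0L) {
    tibble::tibble(role = character(), violation = character())
  } else {
    dplyr::bind_rows(violations)
  }
}
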