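#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

## Controlled vocabularies used across all modules -------------------------

#' Line-level treatment classes
#'
#' The four classes that define treatment lines: topical therapy,
#' phototherapy, non-biologic systemic drugs and biologics. Finer-grained
#' prescription categories (retinoids, systemic steroids, long antibiotic
#' courses) reduce onto `systemic_nonbio`; category `other` is excluded from
#' line construction entirely.
#' @export
LINE_CLASSES <- c("topical", "phototherapy", "systemic_nonbio", "biologic")

#' Prescription-level treatment categories
#' @export
TREATMENT_CATEGORIES <- c(
  "topical", "phototherapy", "systemic_nonbio", "biologic",
  "antibiotic", "retinoid", "steroid_systemic", "other"
)

#' Recognised procedure-claim kinds
#' @export
PROCEDURE_KINDS <- c(
  "phototherapy", "tonsillectomy", "gma", "xray", "mri", "ct",
  "bone_scintigraphy", "outpatient_visit", "hospital_admission"
)

#' Terminating-event labels for treatment lines
#' @export
EVENT_TYPES <- c("discontinuation", "switch", "add_on", "reduction", "no_change")

#' Exclusion reasons, in the precedence order they are applied
#' @export
EXCLUSION_REASONS <- c(
  "single_diagnosis", "under_18", "pre_enrollment", "post_enrollment",
  "special_condition"
)

#' Map a prescription category onto its line-level class
#'
#' Antibiotics map to `systemic_nonbio` but are additionally subject to the
#' cumulative more-than-one-month rule during line construction (see
#' [reconstruct_lines()]); `other` maps to `NA` and never defines a line.
#'
#' @param category character vector of values from [TREATMENT_CATEGORIES].
#' @return character vector of [LINE_CLASSES] values (or `NA`).
#' @export
#' @examples
#' line_class_of(c("retinoid", "other", "biologic"))
line_class_of <- function(category) {
  map <- c(
    topical = "topical", phototherapy = "phototherapy",
    systemic_nonbio = "systemic_nonbio", retinoid = "systemic_nonbio",
    steroid_systemic = "systemic_nonbio", antibiotic = "systemic_nonbio",
    biologic = "biologic", other = NA_character_
  )
  unname(map[category])
}

## Study configuration ------------------------------------------------------

#' Study configuration
#'
#' Bundles every numeric assumption of the analysis: the study window, the
#' 6-month (183-day) pre- and post-index continuous-enrollment requirements,
#' the assumed exposure windows (14 days per topical fill, 28 days per
#' phototherapy session, DDD days for systemics with a 30-day fallback), the
#' 61-day grace period (maximum allowed gap duration), the 14-day
#' phototherapy/systemic combination-overlap threshold, and the 31-day
#' cumulative antibiotic threshold ("more than 1 month").
#'
#' Dates are handled half-open internally: an exposure `[start, end)`
#' excludes `end`, and every printed duration is `end - start` in days.
#'
#' @param study_start,study_end study window (Date or ISO-8601 string).
#' @param pre_index_days,post_index_days continuous-enrollment requirement
#'   before/after the index date, in days (183 = 6 months).
#' @param topical_duration_days assumed exposure per topical fill.
#' @param phototherapy_duration_days assumed exposure per phototherapy session.
#' @param systemic_default_days fallback days supplied when `ddd_days` is
#'   absent on a systemic or biologic claim.
#' @param grace_period_days maximum allowed gap duration between renewals.
#' @param combination_overlap_days phototherapy/systemic overlap longer than
#'   this is combination therapy.
#' @param antibiotic_min_days antibiotics count as systemic therapy only when
#'   cumulative merged exposure reaches this many days.
#' @param month_length_days days per month used for all per-month rates
#'   (default 365.25 / 12).
#' @param min_age minimum age at index for inclusion.
#' @param ppp_icd10 diagnosis code identifying the disease (dots ignored).
#' @param require_distinct_dates if `TRUE`, the two-claim confirmation rule
#'   requires claims on distinct dates; by default two same-day claim records
#'   satisfy it.
#' @param exclusion_icd10 character vector of ICD-10 prefixes whose presence
#'   excludes a patient (conditions requiring special management); empty by
#'   default.
#' @param seed integer seed from which all synthetic-data randomness flows.
#' @param category_map drug-to-category map, see [default_category_map()].
#' @param cci_map Charlson prefix/weight map, see [default_cci_map()].
#' @return object of class `ppp_config` (a named list).
#' @export
#' @examples
#' cfg <- ppp_config()
#' cfg$grace_period_days
ppp_config <- function(study_start = "2011-01-01",
                       study_end = "2017-03-30",
                       pre_index_days = 183L,
                       post_index_days = 183L,
                       topical_duration_days = 14L,
                       phototherapy_duration_days = 28L,
                       systemic_default_days = 30L,
                       grace_period_days = 61L,
                       combination_overlap_days = 14L,
                       antibiotic_min_days = 31L,
                       month_length_days = 365.25 / 12,
                       min_age = 18L,
                       ppp_icd10 = "L40.3",
                       require_distinct_dates = FALSE,
                       exclusion_icd10 = character(),
                       seed = 1L,
                       category_map = default_category_map(),
                       cci_map = default_cci_map()) {
  cfg <- list(
    study_start = as.Date(study_start),
    study_end = as.Date(study_end),
    pre_index_days = as.integer(pre_index_days),
    post_index_days = as.integer(post_index_days),
    topical_duration_days = as.integer(topical_duration_days),
    phototherapy_duration_days = as.integer(phototherapy_duration_days),
    systemic_default_days = as.integer(systemic_default_days),
    grace_period_days = as.integer(grace_period_days),
    combination_overlap_days = as.integer(combination_overlap_days),
    antibiotic_min_days = as.integer(antibiotic_min_days),
    month_length_days = as.numeric(month_length_days),
    min_age = as.integer(min_age),
    ppp_icd10 = as.character(ppp_icd10),
    require_distinct_dates = isTRUE(require_distinct_dates),
    exclusion_icd10 = as.character(exclusion_icd10),
    seed = as.integer(seed),
    category_map = category_map,
    cci_map = cci_map
  )
  class(cfg) <- "ppp_config"
  validate_config(cfg)
  cfg
}

#' Validate a study configuration
#'
#' @param config a `ppp_config` object.
#' @return the config, invisibly; errors describe the offending field.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "ppp_config"))
  durs <- c(
    "pre_index_days", "post_index_days", "topical_duration_days",
    "phototherapy_duration_days", "systemic_default_days",
    "grace_period_days", "combination_overlap_days", "antibiotic_min_days",
    "month_length_days"
  )
  for (d in durs) {
    v <- config[[d]]
    if (length(v) != 1L || is.na(v) || v <= 0) {
      stop("config field `", d, "` must be a single positive number", call. = FALSE)
    }
  }
  if (is.na(config$study_start) || is.na(config$study_end) ||
      config$study_start >= config$study_end) {
    stop("config requires study_start < study_end", call. = FALSE)
  }
  if (config$min_age < 0) stop("config field `min_age` must be >= 0", call. = FALSE)
  cm <- config$category_map
  need <- c("drug_code", "atc", "category", "route", "steroid")
  if (!all(need %in% names(cm))) {
    stop("category_map must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(cm$category), TREATMENT_CATEGORIES)
  if (length(bad) > 0) {
    stop("category_map contains unknown categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(cm$drug_code)) {
    stop("category_map drug_code values must be unique", call. = FALSE)
  }
  if (!all(c("icd10_prefix", "group", "weight") %in% names(config$cci_map))) {
    stop("cci_map must have columns icd10_prefix, group, weight", call. = FALSE)
  }
  invisible(config)
}

#' Read / write a study configuration as YAML
#'
#' The scalar fields are stored as YAML; the category and Charlson maps are
#' stored inline as lists of records so that one file materializes the whole
#' configuration.
#'
#' @param path YAML file path.
#' @return `read_config()` returns a `ppp_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  maps <- list()
  if (!is.null(raw$category_map)) {
    maps$category_map <- dplyr::bind_rows(lapply(raw$category_map, tibble::as_tibble))
  }
  if (!is.null(raw$cci_map)) {
    maps$cci_map <- dplyr::bind_rows(lapply(raw$cci_map, tibble::as_tibble))
  }
  raw$category_map <- NULL
  raw$cci_map <- NULL
  do.call(ppp_config, c(raw, maps))
}

#' @rdname read_config
#' @param config a `ppp_config` object.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  as_records <- function(df) {
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
  }
  out <- unclass(config)
  out$study_start <- format(out$study_start)
  out$study_end <- format(out$study_end)
  out$category_map <- as_records(config$category_map)
  out$cci_map <- as_records(config$cci_map)
  yaml::write_yaml(out, path)
  invisible(path)
}

## Default maps --------------------------------------------------------------

#' Default drug-to-category map
#'
#' A config-driven stand-in for a proprietary national drug-code dictionary:
#' drug codes are generic names, with WHO ATC codes, the treatment category
#' used by the line algorithm, the administration route, and a flag marking
#' corticosteroids (exempt from first-line topical truncation because
#' stopping them may require dose tapering). Users studying real extracts
#' replace or extend this table via [ppp_config()].
#'
#' @return tibble with columns `drug_code`, `atc`, `category`, `route`,
#'   `steroid`.
#' @export
default_category_map <- function() {
  m <- tibble::tribble(
    ~drug_code,            ~atc,      ~category,          ~route,      ~steroid,
    # antibiotics considered disease-directed when given > 1 month
    "clarithromycin",      "J01FA09", "antibiotic",       "oral",      FALSE,
    "roxithromycin",       "J01FA06", "antibiotic",       "oral",      FALSE,
    "minocycline",         "J01AA08", "antibiotic",       "oral",      FALSE,
    "doxycycline",         "J01AA02", "antibiotic",       "oral",      FALSE,
    # retinoids
    "etretinate",          "D05BB01", "retinoid",         "oral",      FALSE,
    "adapalene",           "D10AD03", "retinoid",         "topical",   FALSE,
    "retinol",             "A11CA01", "retinoid",         "oral",      FALSE,
    # systemic corticosteroids (oral or injection)
    "betamethasone",       "H02AB01", "steroid_systemic", "oral",      TRUE,
    "dexamethasone",       "H02AB02", "steroid_systemic", "oral",      TRUE,
    "methylprednisolone",  "H02AB04", "steroid_systemic", "injection", TRUE,
    "prednisolone",        "H02AB06", "steroid_systemic", "oral",      TRUE,
    "triamcinolone",       "H02AB08", "steroid_systemic", "injection", TRUE,
    "hydrocortisone",      "H02AB09", "steroid_systemic", "oral",      TRUE,
    "fludrocortisone",     "H02AA02", "steroid_systemic", "oral",      TRUE,
    # topical therapy
    "betamethasone_top",   "D07AC01", "topical",          "topical",   TRUE,
    "clobetasol_top",      "D07AD01", "topical",          "topical",   TRUE,
    "calcipotriol",        "D05AX02", "topical",          "topical",   FALSE,
    "maxacalcitol",        "D05AX04", "topical",          "topical",   FALSE,
    "salicylic_ointment",  "D02AF00", "topical",          "topical",   FALSE,
    # non-biologic systemic therapies
    "ciclosporin",         "L04AD01", "systemic_nonbio",  "oral",      FALSE,
    "methotrexate",        "L04AX03", "systemic_nonbio",  "oral",      FALSE,
    "sulfasalazine",       "A07EC01", "systemic_nonbio",  "oral",      FALSE,
    "dapsone",             "J04BA02", "systemic_nonbio",  "oral",      FALSE,
    "alendronate",         "M05BA04", "systemic_nonbio",  "oral",      FALSE,
    "biotin_inj",          "A11HA05", "systemic_nonbio",  "injection", FALSE,
    # biologics (used for coexisting immune conditions)
    "adalimumab",          "L04AB04", "biologic",         "injection", FALSE,
    "infliximab",          "L04AB02", "biologic",         "injection", FALSE,
    "etanercept",          "L04AB01", "biologic",         "injection", FALSE,
    "golimumab",           "L04AB06", "biologic",         "injection", FALSE,
    "certolizumab",        "L04AB05", "biologic",         "injection", FALSE,
    "ustekinumab",         "L04AC05", "biologic",         "injection", FALSE,
    "secukinumab",         "L04AC10", "biologic",         "injection", FALSE,
    "tocilizumab",         "L04AC07", "biologic",         "injection", FALSE,
    "abatacept",           "L04AA24", "biologic",         "injection", FALSE,
    # common background medication, never part of line construction
    "omeprazole",          "A02BC01", "other",            "oral",      FALSE,
    "amlodipine",          "C08CA01", "other",            "oral",      FALSE,
    "metformin",           "A10BA02", "other",            "oral",      FALSE,
    "loratadine",          "R06AX13", "other",            "oral",      FALSE,
    "ibuprofen",           "M01AE01", "other",            "oral",      FALSE,
    "acetaminophen",       "N02BE01", "other",            "oral",      FALSE,
    "amoxicillin",         "J01CA04", "other",            "oral",      FALSE,
    "atorvastatin",        "C10AA05", "other",            "oral",      FALSE,
    "levothyroxine",       "H03AA01", "other",            "oral",      FALSE,
    "sertraline",          "N06AB06", "other",            "oral",      FALSE
  )
  m
}

#' Default Charlson comorbidity prefix map (Quan-style ICD-10)
#'
#' One row per ICD-10 prefix; a diagnosis code (dots removed) matches a
#' condition group when any of the group's prefixes is a prefix of the code.
#' Each matched group contributes its weight once, regardless of how many
#' codes matched. The table is plain data and can be edited or replaced via
#' [ppp_config()].
#'
#' @return tibble with columns `icd10_prefix`, `group`, `weight`.
#' @export
default_cci_map <- function() {
  grp <- function(prefixes, group, weight) {
    tibble::tibble(icd10_prefix = prefixes, group = group, weight = weight)
  }
  dplyr::bind_rows(
    grp(c("I21", "I22", "I252"), "myocardial_infarction", 1),
    grp(c("I50", "I110", "I130", "I132", "I420", "I43"), "congestive_heart_failure", 1),
    grp(c("I70", "I71", "I731", "I738", "I739", "I771"), "peripheral_vascular", 1),
    grp(c("G45", "G46", "I6"), "cerebrovascular", 1),
    grp(c("F00", "F01", "F02", "F03", "G30"), "dementia", 1),
    grp(c("J4", "J60", "J61", "J62", "J63", "J64", "J65", "J66", "J67"),
        "chronic_pulmonary", 1),
    grp(c("M05", "M06", "M32", "M33", "M34", "M315", "M351", "M353"),
        "rheumatologic", 1),
    grp(c("K25", "K26", "K27", "K28"), "peptic_ulcer", 1),
    grp(c("B18", "K70", "K713", "K714", "K715", "K73", "K74", "K760"),
        "mild_liver", 1),
    grp(c("E10", "E11", "E13", "E14"), "diabetes", 1),
    grp(c("G81", "G82", "G041", "G114", "G801", "G802"), "hemiplegia", 2),
    grp(c("N18", "N19", "N052", "N053", "N054", "N055", "N056", "N057",
          "I120", "I131"), "renal", 2),
    grp(c("C0", "C1", "C2", "C30", "C31", "C32", "C33", "C34", "C37", "C38",
          "C39", "C40", "C41", "C43", "C45", "C46", "C47", "C48", "C49",
          "C5", "C6", "C70", "C71", "C72", "C73", "C74", "C75", "C76",
          "C81", "C82", "C83", "C84", "C85", "C88", "C90", "C91", "C92",
          "C93", "C94", "C95", "C96", "C97"), "malignancy", 2),
    grp(c("I85", "I864", "I982", "K704", "K711", "K721", "K729", "K765",
          "K766", "K767"), "severe_liver", 3),
    grp(c("C77", "C78", "C79", "C80"), "metastatic_tumor", 6),
    grp(c("B20", "B21", "B22", "B24"), "aids", 6)
  )
}

## shared small helpers -------------------------------------------------------

# strip dots from ICD-10 codes for prefix matching ("L40.3" -> "L403")
norm_icd10 <- function(code) gsub(".", "", code, fixed = TRUE)

# canonical regimen string from a set of line classes
regimen_string <- function(classes) {
  paste(LINE_CLASSES[LINE_CLASSES %in% classes], collapse = "+")
}

# head class of a regimen: biologic > systemic_nonbio > phototherapy > topical
head_class <- function(regimen) {
  prec <- c("biologic", "systemic_nonbio", "phototherapy", "topical")
  vapply(strsplit(regimen, "+", fixed = TRUE), function(cl) {
    prec[prec %in% cl][1L]
  }, character(1L))
}
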