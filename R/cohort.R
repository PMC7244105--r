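## cohort selection: index date, inclusion/exclusion, baseline measures ------

#' Earliest disease diagnosis claim inside the study window
#'
#' @param diagnoses diagnosis tibble restricted or not to the disease code;
#'   only rows matching `config$ppp_icd10` are considered.
#' @param config a [ppp_config()].
#' @return tibble with `patient_id` and `index_date` (patients without a
#'   qualifying claim are absent).
#' @export
find_index_date <- function(diagnoses, config) {
  ppp <- diagnoses[norm_icd10(diagnoses$icd10) == norm_icd10(config$ppp_icd10) &
                     !is.na(diagnoses$claim_date) &
                     diagnoses$claim_date >= config$study_start &
                     diagnoses$claim_date <= config$study_end, , drop = FALSE]
  if (nrow(ppp) == 0L) {
    return(tibble::tibble(patient_id = character(),
                          index_date = as.Date(integer(), origin = "1970-01-01")))
  }
  dplyr::summarise(dplyr::group_by(ppp, .data$patient_id),
                   index_date = min(.data$claim_date), .groups = "drop")
}

#' Confirmed diagnosis: at least two disease claims
#'
#' Two same-day claim records satisfy the rule by default; set
#' `require_distinct_dates = TRUE` in the config to demand distinct dates.
#'
#' @param diagnoses diagnosis tibble for one patient or many.
#' @param config a [ppp_config()].
#' @return tibble with `patient_id` and logical `confirmed`.
#' @export
confirm_diagnosis <- function(diagnoses, config) {
  ppp <- diagnoses[norm_icd10(diagnoses$icd10) == norm_icd10(config$ppp_icd10) &
                     !is.na(diagnoses$claim_date) &
                     diagnoses$claim_date >= config$study_start &
                     diagnoses$claim_date <= config$study_end, , drop = FALSE]
  g <- dplyr::group_by(ppp, .data$patient_id)
  counts <- if (config$require_distinct_dates) {
    dplyr::summarise(g, n = dplyr::n_distinct(.data$claim_date), .groups = "drop")
  } else {
    dplyr::summarise(g, n = dplyr::n(), .groups = "drop")
  }
  counts$confirmed <- counts$n >= 2L
  counts[, c("patient_id", "confirmed")]
}

#' Continuous enrollment around the index date
#'
#' True when a single normalized enrollment period covers the half-open
#' window `[index - pre_days, index + post_days)`.
#'
#' @param periods normalized enrollment periods of one patient
#'   ([normalize_enrollment()]).
#' @param index index date.
#' @param pre_days,post_days required coverage before/after index.
#' @return logical scalar.
#' @export
check_continuous_enrollment <- function(periods, index, pre_days, post_days) {
  s <- as.integer(periods$start_date)
  e <- as.integer(periods$end_date) + 1L # half-open end of coverage
  i <- as.integer(index)
  any(s <= i - pre_days & e >= i + post_days)
}

#' Classify treatment experience relative to the wash-out window
#'
#' `naive`: no treatment-category claim (prescription of a disease-directed
#' category, or phototherapy) in the wash-out window `[index - pre_days,
#' index)` but at least one during the study; `experienced`: any treatment
#' claim in the wash-out window; `na`: no treatment claim at any time.
#'
#' @param prescriptions categorized prescriptions of one patient.
#' @param procedures procedures of one patient.
#' @param index index date.
#' @param config a [ppp_config()].
#' @return one of `"naive"`, `"experienced"`, `"na"`.
#' @export
classify_experience <- function(prescriptions, procedures, index, config) {
  rx_dates <- prescriptions$dispense_date[prescriptions$category != "other"]
  ph_dates <- procedures$date[procedures$kind == "phototherapy"]
  trt <- c(as.integer(rx_dates), as.integer(ph_dates))
  trt <- trt[!is.na(trt)]
  if (length(trt) == 0L) return("na")
  i <- as.integer(index)
  washout <- trt[trt >= i - config$pre_index_days & trt < i]
  if (length(washout) > 0L) "experienced" else "naive"
}

#' Severity proxy from observed line-level classes
#'
#' Mild when the classes observed during follow-up are a subset of
#' `{topical}` (including none at all); moderate-to-severe when any
#' phototherapy, systemic or biologic therapy was received.
#'
#' @param classes character vector of observed line-level classes.
#' @return `"mild"` or `"moderate_severe"`.
#' @export
classify_severity <- function(classes) {
  if (all(classes %in% "topical")) "mild" else "moderate_severe"
}

#' Charlson comorbidity index from ICD-10 codes
#'
#' Matches codes (dots removed) against the configured prefix map; each
#' matched condition group contributes its weight once.
#'
#' @param icd10 character vector of diagnosis codes.
#' @param cci_map prefix/weight tibble, see [default_cci_map()].
#' @return nonnegative integer score.
#' @export
charlson_index <- function(icd10, cci_map = default_cci_map()) {
  if (length(icd10) == 0L) return(0)
  codes <- unique(norm_icd10(icd10))
  hit <- vapply(seq_len(nrow(cci_map)), function(k) {
    any(startsWith(codes, cci_map$icd10_prefix[k]))
  }, logical(1L))
  if (!any(hit)) return(0)
  matched <- cci_map[hit, , drop = FALSE]
  sum(matched$weight[!duplicated(matched$group)])
}

#' Polypharmacy: distinct ATC classes at a given level
#'
#' @param atc character vector of full ATC codes for the prescriptions in
#'   the window of interest.
#' @param level ATC hierarchy level: 1 (anatomical main group, 1-character
#'   prefix) or 3 (pharmacological subgroup, 4-character prefix, e.g.
#'   `A01A` vs `A01B`).
#' @return count of distinct prefixes.
#' @export
polypharmacy <- function(atc, level = 3L) {
  stopifnot(level %in% c(1L, 3L))
  width <- if (level == 1L) 1L else 4L
  atc <- atc[!is.na(atc) & nzchar(atc)]
  length(unique(substr(atc, 1L, width)))
}

comorbidity_flags <- tibble::tibble(
  flag = c("rheumatoid_arthritis", "inflammatory_bowel",
           "ankylosing_spondylitis", "juvenile_arthritis", "psoriasis"),
  prefixes = list(
    c("M05", "M06"),
    c("K50", "K51"),
    "M45",
    "M08",
    # psoriasis other than the pustular palmoplantar code itself
    c("L400", "L401", "L402", "L404", "L405", "L408", "L409")
  )
)

match_any_prefix <- function(codes, prefixes) {
  any(vapply(prefixes, function(p) any(startsWith(codes, p)), logical(1L)))
}

#' Apply the selection algorithm and compute baseline characteristics
#'
#' Builds one record per patient with at least one disease claim in the
#' study window: index date, eligibility with a single exclusion reason
#' applied in fixed precedence (no confirmed diagnosis, under 18,
#' insufficient pre-index enrollment, insufficient post-index enrollment,
#' then any configured special-management condition), the follow-up span
#' (index to the earlier of disenrollment and study end), treatment
#' experience, severity proxy, Charlson index, polypharmacy counts at ATC
#' levels 1 and 3 in the pre-index window, comorbidity flags at baseline
#' and during the selection period, and tonsillectomy/apheresis flags.
#'
#' @param enrollment,diagnosis,prescription,procedure claims tibbles.
#' @param config a [ppp_config()].
#' @return list with `cohort` (tibble) and `attrition` (tibble with one row
#'   per selection step: `step`, `reason`, `n_excluded`, `n_remaining`).
#' @export
build_cohort <- function(enrollment, diagnosis, prescription, procedure,
                         config) {
  validate_config(config)
  enr <- normalize_enrollment(enrollment)
  rx <- impute_dispense_date(categorize_prescriptions(prescription, config))

  idx <- find_index_date(diagnosis, config)
  conf <- confirm_diagnosis(diagnosis, config)
  cohort <- dplyr::left_join(idx, conf, by = "patient_id")
  n0 <- nrow(cohort)

  demo <- enr[!duplicated(enr$patient_id),
              intersect(c("patient_id", "birth_date", "sex"), names(enr))]
  cohort <- dplyr::left_join(cohort, demo, by = "patient_id")
  if (!"birth_date" %in% names(cohort)) cohort$birth_date <- as.Date(NA)
  if (!"sex" %in% names(cohort)) cohort$sex <- NA_character_
  cohort$age_at_index <-
    floor(as.numeric(cohort$index_date - cohort$birth_date) / 365.25)

  # enrollment period containing the index date
  enr_i <- dplyr::inner_join(
    enr, cohort[, c("patient_id", "index_date")], by = "patient_id")
  enr_i <- enr_i[enr_i$start_date <= enr_i$index_date &
                   enr_i$end_date >= enr_i$index_date, , drop = FALSE]
  span <- tibble::tibble(patient_id = enr_i$patient_id,
                         period_start = enr_i$start_date,
                         period_end = enr_i$end_date)
  cohort <- dplyr::left_join(cohort, span, by = "patient_id")

  i <- as.integer(cohort$index_date)
  ps <- as.integer(cohort$period_start)
  pe <- as.integer(cohort$period_end) + 1L # half-open
  pre_ok <- !is.na(ps) & ps <= i - config$pre_index_days
  fu_end_int <- pmin(pe, as.integer(config$study_end) + 1L)
  post_ok <- !is.na(pe) & (fu_end_int - i) >= config$post_index_days

  # configured special-management conditions (ICD-10 prefixes), empty default
  special <- rep(FALSE, nrow(cohort))
  if (length(config$exclusion_icd10) > 0) {
    codes_by_pat <- split(norm_icd10(diagnosis$icd10), diagnosis$patient_id)
    special <- vapply(cohort$patient_id, function(p) {
      cd <- codes_by_pat[[p]]
      !is.null(cd) && match_any_prefix(cd, norm_icd10(config$exclusion_icd10))
    }, logical(1L))
  }

  reason <- rep(NA_character_, nrow(cohort))
  reason[!cohort$confirmed] <- "single_diagnosis"
  step2 <- is.na(reason) & (is.na(cohort$age_at_index) |
                              cohort$age_at_index < config$min_age)
  reason[step2] <- "under_18"
  step3 <- is.na(reason) & !pre_ok
  reason[step3] <- "pre_enrollment"
  step4 <- is.na(reason) & !post_ok
  reason[step4] <- "post_enrollment"
  step5 <- is.na(reason) & special
  reason[step5] <- "special_condition"

  cohort$eligible <- is.na(reason)
  cohort$exclusion_reason <- reason
  cohort$follow_up_start <- cohort$index_date
  cohort$follow_up_end <- as.Date(fu_end_int, origin = "1970-01-01")
  cohort$follow_up_end[!cohort$eligible] <- as.Date(NA)
  cohort$follow_up_days <- as.integer(cohort$follow_up_end - cohort$index_date)

  n_excl <- vapply(EXCLUSION_REASONS,
                   function(r) sum(reason == r, na.rm = TRUE), integer(1L))
  attr_steps <- tibble::tibble(
    step = seq_along(EXCLUSION_REASONS),
    reason = EXCLUSION_REASONS,
    n_excluded = unname(n_excl)
  )
  attr_steps$n_remaining <- n0 - cumsum(attr_steps$n_excluded)

  elig <- cohort[cohort$eligible, , drop = FALSE]

  ## per-patient baseline measures (eligible patients only)
  rx_by_pat <- split(rx, rx$patient_id)
  proc_by_pat <- split(procedure, procedure$patient_id)
  dx_by_pat <- split(diagnosis, diagnosis$patient_id)
  empty_rx <- rx[0L, , drop = FALSE]
  empty_proc <- procedure[0L, , drop = FALSE]
  empty_dx <- diagnosis[0L, , drop = FALSE]

  elig_classes <- observed_line_classes(elig, rx, procedure, config)

  meas <- lapply(seq_len(nrow(elig)), function(k) {
    pid <- elig$patient_id[k]
    index <- elig$index_date[k]
    fu_end <- elig$follow_up_end[k]
    p_rx <- rx_by_pat[[pid]]; if (is.null(p_rx)) p_rx <- empty_rx
    p_pr <- proc_by_pat[[pid]]; if (is.null(p_pr)) p_pr <- empty_proc
    p_dx <- dx_by_pat[[pid]]; if (is.null(p_dx)) p_dx <- empty_dx

    in_washout <- !is.na(p_rx$dispense_date) &
      p_rx$dispense_date >= index - config$pre_index_days &
      p_rx$dispense_date < index
    base_dx <- p_dx[!is.na(p_dx$claim_date) &
                      p_dx$claim_date >= index - config$pre_index_days &
                      p_dx$claim_date < index, , drop = FALSE]
    sel_dx <- p_dx[!is.na(p_dx$claim_date) & p_dx$claim_date >= index &
                     p_dx$claim_date < fu_end, , drop = FALSE]
    base_codes <- norm_icd10(base_dx$icd10)
    sel_codes <- norm_icd10(sel_dx$icd10)

    flags <- vapply(seq_len(nrow(comorbidity_flags)), function(j) {
      pf <- comorbidity_flags$prefixes[[j]]
      c(match_any_prefix(base_codes, pf), match_any_prefix(sel_codes, pf))
    }, logical(2L))

    proc_fu <- p_pr[!is.na(p_pr$date) & p_pr$date >= index &
                      p_pr$date < fu_end, , drop = FALSE]
    c(
      list(
        patient_id = pid,
        treatment_experience = classify_experience(p_rx, p_pr, index, config),
        cci = charlson_index(base_dx$icd10, config$cci_map),
        polypharmacy_l1 = polypharmacy(p_rx$atc[in_washout], 1L),
        polypharmacy_l3 = polypharmacy(p_rx$atc[in_washout], 3L),
        tonsillectomy = any(proc_fu$kind == "tonsillectomy"),
        gma = any(proc_fu$kind == "gma")
      ),
      stats::setNames(as.list(flags[1L, ]),
                      paste0(comorbidity_flags$flag, "_baseline")),
      stats::setNames(as.list(flags[2L, ]),
                      paste0(comorbidity_flags$flag, "_selection"))
    )
  })
  meas_tbl <- dplyr::bind_rows(lapply(meas, tibble::as_tibble))
  if (nrow(elig) == 0L) {
    meas_tbl <- tibble::tibble(
      patient_id = character(), treatment_experience = character(),
      cci = numeric(), polypharmacy_l1 = integer(),
      polypharmacy_l3 = integer(), tonsillectomy = logical(),
      gma = logical()
    )
    for (f in comorbidity_flags$flag) {
      meas_tbl[[paste0(f, "_baseline")]] <- logical()
      meas_tbl[[paste0(f, "_selection")]] <- logical()
    }
  }

  cohort <- dplyr::left_join(cohort, meas_tbl, by = "patient_id")
  cohort <- dplyr::left_join(cohort, elig_classes, by = "patient_id")
  cohort$severity <- NA_character_
  if (nrow(elig) > 0) {
    ei <- cohort$eligible
    cohort$severity[ei] <- vapply(
      strsplit(ifelse(is.na(cohort$observed_classes[ei]), "",
                      cohort$observed_classes[ei]), "+", fixed = TRUE),
      function(cl) classify_severity(cl[nzchar(cl)]), character(1L))
  }
  cohort$confirmed <- NULL
  cohort$period_start <- NULL
  cohort$period_end <- NULL

  list(cohort = tibble::as_tibble(cohort), attrition = attr_steps)
}

# line-level classes observed during follow-up per eligible patient,
# after the antibiotic cumulative rule (drives the severity proxy)
observed_line_classes <- function(elig, rx, procedures, config) {
  if (nrow(elig) == 0L) {
    return(tibble::tibble(patient_id = character(),
                          observed_classes = character()))
  }
  ep <- expand_episodes(rx, procedures, elig, config)
  ep_by_pat <- split(ep, ep$patient_id)
  cls <- vapply(elig$patient_id, function(pid) {
    p <- ep_by_pat[[pid]]
    if (is.null(p) || nrow(p) == 0L) return("")
    present <- unique(p$class)
    if ("antibiotic" %in% present) {
      abx <- p[p$class == "antibiotic", , drop = FALSE]
      m <- merge_intervals(as.integer(abx$start), as.integer(abx$end),
                           abx$steroid, config$grace_period_days)
      present <- setdiff(present, "antibiotic")
      if (sum(m$end - m$start) >= config$antibiotic_min_days) {
        present <- union(present, "systemic_nonbio")
      }
    }
    regimen_string(present)
  }, character(1L))
  tibble::tibble(patient_id = elig$patient_id, observed_classes = unname(cls))
}
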