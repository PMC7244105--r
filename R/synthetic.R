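## synthetic claims generator with planted ground truth ----------------------

# integer draw in [lo, hi], safe for degenerate ranges
rint <- function(n, lo, hi) lo + floor(stats::runif(n) * (hi - lo + 1L))

# default monthly Poisson rates per resource kind and lognormal cost params
DEFAULT_HCRU_RATES <- c(
  outpatient_visit = 3.0, hospital_admission = 0.05, xray = 0.10,
  mri = 0.06, ct = 0.16, bone_scintigraphy = 0.05
)
DEFAULT_COST_MEANLOG <- c(
  outpatient_visit = log(3000), hospital_admission = log(120000),
  xray = log(4000), mri = log(15000), ct = log(12000),
  bone_scintigraphy = log(20000), pharmacy = log(4000)
)
DEFAULT_COST_SDLOG <- 0.5

#' Built-in patient trajectory archetypes
#'
#' Each archetype plants an unambiguous treatment trajectory: exposure fills
#' that tile each line exactly, transition gaps well inside the grace period
#' (0-20 days), discontinuation gaps well outside it (100 days),
#' phototherapy/systemic overlaps that are either zero or span the whole
#' line, and an explicit planted truth (line intervals, regimens,
#' terminating events, severity, treatment experience). Between them the
#' archetypes cover every first-line class, every terminating event, a
#' within-line refill gap, a combination-therapy line, the first-line
#' topical truncation rule and a never-treated patient.
#'
#' Offsets below are days relative to the patient's first treatment day;
#' `margin` is the extra follow-up after the last planted exposure (30 days
#' when the last line is censored, i.e. within the grace period; >= 92 days
#' when a terminal discontinuation is planted).
#'
#' @param config a [ppp_config()] (fixes fill durations).
#' @return named list of archetype descriptions.
#' @export
ppp_archetypes <- function(config = ppp_config()) {
  td <- config$topical_duration_days        # 14
  pd <- config$phototherapy_duration_days   # 28
  fills <- function(class, offsets, ddd = NA_real_, steroid = FALSE) {
    list(class = class, offsets = offsets, ddd = ddd, steroid = steroid)
  }
  truth <- function(regimen, start, end, event) {
    list(regimen = regimen, start = start, end = end, event = event)
  }
  list(
    mild_stable = list(
      experience = "naive", severity = "mild", margin = 30,
      plan = list(fills("topical", seq(0, 154, td))),
      truth = list(truth("topical", 0, 168, "no_change"))
    ),
    mild_discontinue = list(
      experience = "naive", severity = "mild", margin = 30,
      plan = list(fills("topical", seq(0, 70, td)),
                  fills("topical", 184 + seq(0, 42, td))),
      truth = list(truth("topical", 0, 84, "discontinuation"),
                   truth("topical", 184, 240, "no_change"))
    ),
    topical_to_systemic = list(
      experience = "naive", severity = "moderate_severe", margin = 30,
      plan = list(fills("topical", seq(0, 42, td)),
                  fills("systemic_nonbio", 70 + seq(0, 84, pd), ddd = pd)),
      truth = list(truth("topical", 0, 56, "switch"),
                   truth("systemic_nonbio", 70, 182, "no_change"))
    ),
    photo_to_systemic = list(
      experience = "naive", severity = "moderate_severe", margin = 92,
      plan = list(fills("phototherapy", c(0, 28)),
                  fills("systemic_nonbio", 66 + c(0, 28, 56), ddd = pd)),
      truth = list(truth("phototherapy", 0, 56, "switch"),
                   truth("systemic_nonbio", 66, 150, "discontinuation"))
    ),
    systemic_then_photo_with_topical = list(
      experience = "naive", severity = "moderate_severe", margin = 30,
      plan = list(fills("systemic_nonbio", c(0, 28, 56), ddd = pd),
                  fills("topical", seq(0, 154, td)),
                  fills("phototherapy", 84 + c(0, 28, 56))),
      truth = list(truth("topical+systemic_nonbio", 0, 84, "switch"),
                   truth("topical+phototherapy", 84, 168, "no_change"))
    ),
    biologic_user = list(
      experience = "experienced", severity = "moderate_severe", margin = 30,
      washout = list(class = "topical", offset = -40),
      plan = list(fills("biologic", seq(0, 140, pd), ddd = pd)),
      truth = list(truth("biologic", 0, 168, "no_change"))
    ),
    systemic_refill_gap = list(
      experience = "experienced", severity = "moderate_severe", margin = 113,
      washout = list(class = "systemic_nonbio", offset = -50),
      plan = list(fills("systemic_nonbio", c(0, 49), ddd = pd)),
      truth = list(truth("systemic_nonbio", 0, 77, "discontinuation"))
    ),
    photo_systemic_combination = list(
      experience = "naive", severity = "moderate_severe", margin = 30,
      plan = list(fills("phototherapy", seq(0, 140, pd)),
                  fills("systemic_nonbio", seq(0, 140, pd), ddd = pd)),
      truth = list(truth("phototherapy+systemic_nonbio", 0, 168, "no_change"))
    ),
    topical_truncated_by_systemic = list(
      experience = "naive", severity = "moderate_severe", margin = 92,
      plan = list(fills("topical", seq(0, 42, td)),
                  fills("systemic_nonbio", 28 + c(0, 28, 56), ddd = pd)),
      truth = list(truth("topical", 0, 28, "switch"),
                   truth("systemic_nonbio", 28, 112, "discontinuation"))
    ),
    never_treated = list(
      experience = "na", severity = "mild", margin = NA, fu_days = 200,
      plan = list(),
      truth = list()
    )
  )
}

default_archetype_mix <- function() {
  c(mild_stable = 0.15, mild_discontinue = 0.10, topical_to_systemic = 0.16,
    photo_to_systemic = 0.09, systemic_then_photo_with_topical = 0.10,
    biologic_user = 0.04, systemic_refill_gap = 0.10,
    photo_systemic_combination = 0.08, topical_truncated_by_systemic = 0.13,
    never_treated = 0.05)
}

# drug pools per planted class (chosen to avoid the corticosteroid taper
# exemption unless an archetype plants it explicitly)
SYNTH_DRUG_POOLS <- list(
  topical = c("calcipotriol", "maxacalcitol", "salicylic_ointment"),
  systemic_nonbio = c("ciclosporin", "methotrexate", "etretinate"),
  biologic = c("adalimumab", "infliximab", "ustekinumab"),
  other = c("omeprazole", "amlodipine", "metformin", "loratadine",
            "ibuprofen", "acetaminophen", "amoxicillin", "atorvastatin",
            "levothyroxine", "sertraline")
)

#' Generate a synthetic claims cohort with planted ground truth
#'
#' Emulates the structure of an employer-based insurance claims extract:
#' per-patient enrollment spans with demographics, disease and background
#' diagnosis claims, category-labelled prescriptions with realistic refill
#' schedules, phototherapy and resource-utilization procedure events
#' (homogeneous Poisson per kind) with lognormal costs. Every patient's
#' true treatment lines, terminating events, severity class and treatment
#' experience are recorded in the returned truth tables. Deterministic
#' given `seed`.
#'
#' @param n_patients number of patients (>= 1).
#' @param config a [ppp_config()].
#' @param mix named weights over [ppp_archetypes()] names.
#' @param seed integer seed; defaults to `config$seed`.
#' @param hcru_rates named monthly Poisson rates per resource kind.
#' @return list of tibbles: `enrollment`, `diagnosis`, `prescription`,
#'   `procedure`, `truth_patients`, `truth_lines`.
#' @export
synth_claims <- function(n_patients, config = ppp_config(),
                         mix = default_archetype_mix(),
                         seed = config$seed,
                         hcru_rates = DEFAULT_HCRU_RATES) {
  stopifnot(n_patients >= 1)
  if (length(mix) == 0L || sum(mix) <= 0) {
    stop("archetype mix must be a nonempty set of positive weights",
         call. = FALSE)
  }
  arch <- ppp_archetypes(config)
  if (!all(names(mix) %in% names(arch))) {
    stop("unknown archetype in mix: ",
         paste(setdiff(names(mix), names(arch)), collapse = ", "),
         call. = FALSE)
  }
  set.seed(seed)
  ids <- sprintf("P%05d", seq_len(n_patients))
  kinds <- sample(names(mix), n_patients, replace = TRUE,
                  prob = mix / sum(mix))
  # index dates early in the study window so follow-up never hits study end
  index0 <- as.integer(config$study_start) + rint(n_patients, 0L, 1095L)

  enr <- vector("list", n_patients); dx <- vector("list", n_patients)
  rx <- vector("list", n_patients); pr <- vector("list", n_patients)
  tp <- vector("list", n_patients); tl <- vector("list", n_patients)

  for (k in seq_len(n_patients)) {
    pid <- ids[k]
    a <- arch[[kinds[k]]]
    index <- index0[k]
    delta <- rint(1L, 0L, 10L) # treatment starts shortly after diagnosis
    t0 <- index + delta

    last_end <- if (length(a$truth) > 0) {
      max(vapply(a$truth, function(x) x$end, numeric(1L)))
    } else 0
    fu_days <- if (length(a$truth) > 0) {
      as.integer(delta + last_end + a$margin)
    } else as.integer(a$fu_days)

    enr_start <- index - config$pre_index_days - rint(1L, 30L, 300L)
    enr_end <- index + fu_days - 1L
    age_years <- rint(1L, 20L, 70L)
    birth <- index - as.integer(round(age_years * 365.25 + rint(1L, 0L, 300L)))
    sex <- if (stats::runif(1) < 0.43) "male" else "female"
    enr[[k]] <- tibble::tibble(
      patient_id = pid, start_date = enr_start, end_date = enr_end,
      birth_date = birth, sex = sex
    )

    # disease diagnoses (two claims confirm) + background comorbidities
    dx_dates <- c(index, index + rint(1L, 10L, 60L))
    dx_codes <- c(config$ppp_icd10, config$ppp_icd10)
    dx_setting <- c("outpatient", "outpatient")
    if (stats::runif(1) < 0.05) { # rheumatoid arthritis at baseline
      dx_dates <- c(dx_dates, index - rint(1L, 30L, 150L))
      dx_codes <- c(dx_codes, "M05.9"); dx_setting <- c(dx_setting, "outpatient")
    }
    if (stats::runif(1) < 0.06) { # a Charlson condition at baseline
      dx_dates <- c(dx_dates, index - rint(1L, 30L, 150L))
      dx_codes <- c(dx_codes, sample(c("I21.0", "E11.9", "K50.9", "J44.9"), 1L))
      dx_setting <- c(dx_setting, "inpatient")
    }
    if (stats::runif(1) < 0.08) { # plaque psoriasis during selection period
      dx_dates <- c(dx_dates, index + rint(1L, 20L, min(100L, fu_days - 1L)))
      dx_codes <- c(dx_codes, "L40.0"); dx_setting <- c(dx_setting, "outpatient")
    }
    dx[[k]] <- tibble::tibble(patient_id = pid, claim_date = dx_dates,
                              icd10 = dx_codes, setting = dx_setting)

    ## prescriptions and phototherapy procedures realizing the planted lines
    rx_rows <- list(); pr_rows <- list()
    add_rx <- function(class, date, ddd, steroid) {
      pool <- SYNTH_DRUG_POOLS[[class]]
      drug <- pool[rint(1L, 1L, length(pool))]
      rx_rows[[length(rx_rows) + 1L]] <<- tibble::tibble(
        patient_id = pid, dispense_date = date, claim_record_date = date,
        drug_code = drug, ddd_days = ddd,
        cost_yen = round(stats::rlnorm(1L, DEFAULT_COST_MEANLOG[["pharmacy"]],
                                       DEFAULT_COST_SDLOG))
      )
    }
    for (f in a$plan) {
      for (off in f$offsets) {
        if (f$class == "phototherapy") {
          pr_rows[[length(pr_rows) + 1L]] <- tibble::tibble(
            patient_id = pid, date = t0 + off, kind = "phototherapy",
            cost_yen = round(stats::rlnorm(1L, log(6000), DEFAULT_COST_SDLOG))
          )
        } else {
          add_rx(f$class, t0 + off, f$ddd, f$steroid)
        }
      }
    }
    if (!is.null(a$washout)) {
      add_rx(a$washout$class, index + a$washout$offset,
             if (a$washout$class == "topical") NA_real_ else 28, FALSE)
    }
    # background medication in the wash-out window (polypharmacy; category
    # `other`, so it never affects treatment-naive status)
    n_bg <- rint(1L, 0L, 5L)
    if (n_bg > 0L) {
      drugs <- sample(SYNTH_DRUG_POOLS$other, n_bg)
      for (d in drugs) {
        rx_rows[[length(rx_rows) + 1L]] <- tibble::tibble(
          patient_id = pid,
          dispense_date = index - rint(1L, 10L, config$pre_index_days - 3L),
          claim_record_date = NA_integer_, drug_code = d, ddd_days = 30,
          cost_yen = round(stats::rlnorm(1L, DEFAULT_COST_MEANLOG[["pharmacy"]],
                                         DEFAULT_COST_SDLOG))
        )
      }
    }
    rx[[k]] <- dplyr::bind_rows(rx_rows)

    ## resource utilization: homogeneous Poisson per kind over follow-up
    months <- fu_days / config$month_length_days
    for (res_kind in names(hcru_rates)) {
      n_ev <- stats::rpois(1L, hcru_rates[[res_kind]] * months)
      if (n_ev > 0L) {
        costs_ev <- round(stats::rlnorm(n_ev, DEFAULT_COST_MEANLOG[[res_kind]],
                                        DEFAULT_COST_SDLOG))
        pr_rows[[length(pr_rows) + 1L]] <- tibble::tibble(
          patient_id = pid, date = index + rint(n_ev, 0L, fu_days - 1L),
          kind = res_kind, cost_yen = costs_ev
        )
      }
    }
    pr[[k]] <- dplyr::bind_rows(pr_rows)

    tp[[k]] <- tibble::tibble(
      patient_id = pid, archetype = kinds[k], eligible = TRUE,
      exclusion_reason = NA_character_, index_date = index,
      follow_up_days = fu_days, treatment_experience = a$experience,
      severity = a$severity, n_lines = length(a$truth)
    )
    if (length(a$truth) > 0) {
      tl[[k]] <- tibble::tibble(
        patient_id = pid,
        line_number = seq_along(a$truth),
        regimen = vapply(a$truth, `[[`, character(1L), "regimen"),
        start = t0 + vapply(a$truth, `[[`, numeric(1L), "start"),
        end = t0 + vapply(a$truth, `[[`, numeric(1L), "end"),
        event = vapply(a$truth, `[[`, character(1L), "event")
      )
    }
  }

  as_date_cols <- function(df, cols) {
    for (cl in intersect(cols, names(df))) {
      df[[cl]] <- as.Date(df[[cl]], origin = "1970-01-01")
    }
    df
  }
  prescription <- as_date_cols(dplyr::bind_rows(rx),
                               c("dispense_date", "claim_record_date"))
  truth_lines <- as_date_cols(dplyr::bind_rows(tl), c("start", "end"))
  list(
    enrollment = as_date_cols(dplyr::bind_rows(enr),
                              c("start_date", "end_date", "birth_date")),
    diagnosis = as_date_cols(dplyr::bind_rows(dx), "claim_date"),
    prescription = prescription,
    procedure = as_date_cols(dplyr::bind_rows(pr), "date"),
    truth_patients = as_date_cols(dplyr::bind_rows(tp), "index_date"),
    truth_lines = truth_lines
  )
}

#' Plant selection-rule violations into a synthetic cohort
#'
#' Modifies exactly `floor(fraction * n)` patients per exclusion reason so
#' that they fail the corresponding criterion (and only that one, under the
#' documented precedence): `single_diagnosis` keeps only the index claim,
#' `under_18` moves the birth date to age 15 at index, `pre_enrollment`
#' starts enrollment 100 days before index, `post_enrollment` ends it 100
#' days after. The reason sets are disjoint; the truth table is updated.
#'
#' @param data list returned by [synth_claims()].
#' @param fractions named fractions in `[0, 1]` for reasons among
#'   `single_diagnosis`, `under_18`, `pre_enrollment`, `post_enrollment`.
#' @param seed integer seed for the patient draw.
#' @param ppp_icd10 disease code used when stripping confirmation claims.
#' @return modified `data` list.
#' @export
plant_exclusions <- function(data, fractions, seed = 1L,
                             ppp_icd10 = "L40.3") {
  stopifnot(all(names(fractions) %in% setdiff(EXCLUSION_REASONS,
                                              "special_condition")))
  stopifnot(all(fractions >= 0 & fractions <= 1))
  set.seed(seed)
  tp <- data$truth_patients
  n <- nrow(tp)
  pool <- sample(tp$patient_id)
  taken <- character(0)
  for (r in names(fractions)) {
    m <- floor(fractions[[r]] * n)
    if (m == 0L) next
    pick <- setdiff(pool, taken)[seq_len(m)]
    taken <- c(taken, pick)
    sel_tp <- tp$patient_id %in% pick
    tp$eligible[sel_tp] <- FALSE
    tp$exclusion_reason[sel_tp] <- r
    if (r == "single_diagnosis") {
      # keep only the earliest disease claim per planted patient
      dxx <- data$diagnosis
      ord <- order(dxx$patient_id, dxx$claim_date)
      dxx <- dxx[ord, , drop = FALSE]
      is_ppp <- norm_icd10(dxx$icd10) == norm_icd10(ppp_icd10) &
        dxx$patient_id %in% pick
      first <- is_ppp & !duplicated(paste(dxx$patient_id, is_ppp))
      data$diagnosis <- dxx[!is_ppp | first, , drop = FALSE]
    } else if (r == "under_18") {
      i <- match(pick, data$enrollment$patient_id)
      idx_dates <- tp$index_date[match(pick, tp$patient_id)]
      data$enrollment$birth_date[i] <- idx_dates - as.integer(15 * 365.25)
    } else if (r == "pre_enrollment") {
      i <- match(pick, data$enrollment$patient_id)
      idx_dates <- tp$index_date[match(pick, tp$patient_id)]
      data$enrollment$start_date[i] <- idx_dates - 100L
    } else if (r == "post_enrollment") {
      i <- match(pick, data$enrollment$patient_id)
      idx_dates <- tp$index_date[match(pick, tp$patient_id)]
      data$enrollment$end_date[i] <- idx_dates + 100L
    }
  }
  data$truth_patients <- tp
  data$truth_lines <- data$truth_lines[
    data$truth_lines$patient_id %in% tp$patient_id[tp$eligible], , drop = FALSE]
  data
}

#' Write the synthetic tables (and truth) to a directory of CSVs
#'
#' @param data list from [synth_claims()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(data)) {
    write_claims(data[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  invisible(dir)
}
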