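## resource utilization, costs and time-to-event -----------------------------

#' Kaplan-Meier product-limit estimator
#'
#' Hand-rolled product-limit estimator: at each distinct event time `t`,
#' the survival drops by the factor `1 - d(t)/n(t)` where `d(t)` is the
#' number of events and `n(t)` the number still at risk. At tied times
#' events precede censorings (the usual convention). With no events the
#' curve is constant at 1; with no censoring it equals one minus the
#' empirical CDF.
#'
#' @param time nonnegative times to event or censoring.
#' @param event logical (or 0/1): `TRUE` = event, `FALSE` = censored.
#' @return tibble with `time` (distinct event times, increasing), `n_risk`,
#'   `n_event`, `n_censor` (censorings at exactly that time) and
#'   `survival`.
#' @export
#' @examples
#' km_estimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))$survival # 2/3, 1/3, 0
km_estimate <- function(time, event) {
  stopifnot(length(time) == length(event), all(time >= 0))
  event <- as.logical(event)
  et <- sort(unique(time[event]))
  if (length(et) == 0L) {
    return(tibble::tibble(time = numeric(), n_risk = integer(),
                          n_event = integer(), n_censor = integer(),
                          survival = numeric()))
  }
  n_risk <- vapply(et, function(t) sum(time >= t), integer(1L))
  n_event <- vapply(et, function(t) sum(time == t & event), integer(1L))
  n_censor <- vapply(et, function(t) sum(time == t & !event), integer(1L))
  # running product kept as a reduced integer fraction so that telescoping
  # factors cancel exactly (without censoring the curve is then bitwise
  # (n - k)/n, i.e. one minus the empirical CDF); the fraction is flushed
  # into a floating prefix before its terms could lose integer precision
  gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
  surv <- numeric(length(et))
  prefix <- 1; num <- 1; den <- 1
  for (i in seq_along(et)) {
    num <- num * (n_risk[i] - n_event[i])
    den <- den * n_risk[i]
    g <- gcd2(num, den)
    num <- num / g; den <- den / g
    if (num > 2^45 || den > 2^45) {
      prefix <- prefix * num / den
      num <- 1; den <- 1
    }
    surv[i] <- prefix * num / den
  }
  tibble::tibble(
    time = et, n_risk = n_risk, n_event = n_event, n_censor = n_censor,
    survival = surv
  )
}

#' Per-person-per-month event rates
#'
#' Each patient's rate is their event count divided by their follow-up time
#' in months (`follow_up_days / month_length_days`). Patients with zero
#' follow-up are excluded (with a warning).
#'
#' @param counts integer event counts per patient.
#' @param follow_up_days follow-up in days per patient.
#' @param month_length_days days per month (see [ppp_config()]).
#' @return tibble with `count`, `follow_up_days`, `months`, `rate_pppm`.
#' @export
#' @examples
#' rate_per_person_month(3, 3 * 365.25 / 12, 365.25 / 12)$rate_pppm # 1
rate_per_person_month <- function(counts, follow_up_days,
                                  month_length_days = 365.25 / 12) {
  stopifnot(length(counts) == length(follow_up_days))
  bad <- follow_up_days <= 0
  if (any(bad)) {
    warning(sum(bad), " patient(s) with zero follow-up excluded from rates")
    counts <- counts[!bad]; follow_up_days <- follow_up_days[!bad]
  }
  months <- follow_up_days / month_length_days
  tibble::tibble(count = counts, follow_up_days = follow_up_days,
                 months = months, rate_pppm = counts / months)
}

#' Direct medical cost per patient-month by category
#'
#' Sums each patient's costs in yen over follow-up by category (inpatient =
#' hospital admissions; outpatient = visits, imaging, phototherapy and other
#' procedures; pharmacy = prescription costs) and divides by the patient's
#' follow-up in months. Total is the per-patient sum of the three
#' categories.
#'
#' @param cohort eligible-patient cohort tibble with `patient_id`,
#'   `index_date`, `follow_up_end`, `follow_up_days`.
#' @param prescriptions prescription tibble with `cost_yen` (imputed
#'   dispense dates).
#' @param procedures procedure tibble with `cost_yen`.
#' @param config a [ppp_config()].
#' @return tibble per patient: `patient_id`, `months`, `inpatient_pppm`,
#'   `outpatient_pppm`, `pharmacy_pppm`, `total_pppm`.
#' @export
cost_per_patient_month <- function(cohort, prescriptions, procedures, config) {
  elig <- cohort[cohort$eligible, , drop = FALSE]
  months <- elig$follow_up_days / config$month_length_days

  sum_costs <- function(df, date_col) {
    if (!"cost_yen" %in% names(df) || nrow(df) == 0L) {
      return(stats::setNames(rep(0, nrow(elig)), elig$patient_id))
    }
    j <- dplyr::inner_join(
      df, elig[, c("patient_id", "index_date", "follow_up_end")],
      by = "patient_id")
    d <- j[[date_col]]
    j <- j[!is.na(d) & d >= j$index_date & d < j$follow_up_end, , drop = FALSE]
    agg <- dplyr::summarise(dplyr::group_by(j, .data$patient_id),
                            total = sum(.data$cost_yen, na.rm = TRUE),
                            .groups = "drop")
    out <- stats::setNames(rep(0, nrow(elig)), elig$patient_id)
    out[agg$patient_id] <- agg$total
    out
  }

  inp <- sum_costs(procedures[procedures$kind == "hospital_admission", ], "date")
  outp <- sum_costs(procedures[procedures$kind != "hospital_admission", ], "date")
  rx <- impute_dispense_date(prescriptions)
  pharm <- sum_costs(rx, "dispense_date")

  tibble::tibble(
    patient_id = elig$patient_id,
    months = months,
    inpatient_pppm = unname(inp) / months,
    outpatient_pppm = unname(outp) / months,
    pharmacy_pppm = unname(pharm) / months,
    total_pppm = unname(inp + outp + pharm) / months
  )
}

HCRU_KINDS <- c("hospital_admission", "outpatient_visit", "xray", "mri",
                "ct", "bone_scintigraphy")

#' Summarize healthcare resource utilization
#'
#' For each resource kind and severity group (overall, mild, moderate to
#' severe): the number and percentage of patients with at least one
#' occurrence during follow-up, the mean and SD of per-patient monthly
#' rates among patients with at least one occurrence (the convention of the
#' source tables), the same over all patients, and the pooled rate (total
#' occurrences over total patient-months).
#'
#' @param cohort cohort tibble ([build_cohort()]); only eligible patients
#'   contribute.
#' @param procedures procedure tibble.
#' @param config a [ppp_config()].
#' @return tibble with one row per kind x group.
#' @export
summarize_hcru <- function(cohort, procedures, config) {
  elig <- cohort[cohort$eligible, , drop = FALSE]
  j <- dplyr::inner_join(
    procedures, elig[, c("patient_id", "index_date", "follow_up_end")],
    by = "patient_id")
  j <- j[!is.na(j$date) & j$date >= j$index_date & j$date < j$follow_up_end, ,
         drop = FALSE]

  groups <- list(overall = rep(TRUE, nrow(elig)),
                 mild = elig$severity == "mild",
                 moderate_severe = elig$severity == "moderate_severe")

  rows <- list()
  for (kind in HCRU_KINDS) {
    ev <- j[j$kind == kind, , drop = FALSE]
    cnt_tbl <- dplyr::summarise(dplyr::group_by(ev, .data$patient_id),
                                n = dplyr::n(), .groups = "drop")
    counts <- stats::setNames(rep(0L, nrow(elig)), elig$patient_id)
    counts[cnt_tbl$patient_id] <- cnt_tbl$n
    rates <- rate_per_person_month(unname(counts), elig$follow_up_days,
                                   config$month_length_days)
    for (g in names(groups)) {
      sel <- groups[[g]]
      r <- rates$rate_pppm[sel]
      cn <- unname(counts)[sel]
      users <- cn > 0
      rows[[length(rows) + 1L]] <- tibble::tibble(
        kind = kind, group = g, n = sum(sel),
        n_with_event = sum(users),
        pct_with_event = if (sum(sel) > 0) 100 * sum(users) / sum(sel) else NA_real_,
        rate_mean_users = if (any(users)) mean(r[users]) else NA_real_,
        rate_sd_users = if (sum(users) > 1) stats::sd(r[users]) else NA_real_,
        rate_mean_all = if (sum(sel) > 0) mean(r) else NA_real_,
        rate_sd_all = if (sum(sel) > 1) stats::sd(r) else NA_real_,
        rate_pooled = if (sum(sel) > 0)
          sum(cn) / sum(rates$months[sel]) else NA_real_
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Time to first occurrence of a resource kind
#'
#' The first occurrence after the index date is the event; patients
#' reaching the end of follow-up without one are censored there.
#'
#' @param cohort cohort tibble (eligible patients used).
#' @param procedures procedure tibble.
#' @param kind one of the resource kinds.
#' @return tibble with `patient_id`, `time` (days), `event`.
#' @export
time_to_first_event <- function(cohort, procedures, kind) {
  elig <- cohort[cohort$eligible, , drop = FALSE]
  ev <- procedures[procedures$kind == kind, , drop = FALSE]
  j <- dplyr::inner_join(
    ev, elig[, c("patient_id", "index_date", "follow_up_end")],
    by = "patient_id")
  j <- j[!is.na(j$date) & j$date >= j$index_date & j$date < j$follow_up_end, ,
         drop = FALSE]
  first <- dplyr::summarise(dplyr::group_by(j, .data$patient_id),
                            first_date = min(.data$date), .groups = "drop")
  out <- dplyr::left_join(elig[, c("patient_id", "index_date",
                                   "follow_up_days")],
                          first, by = "patient_id")
  hit <- !is.na(out$first_date)
  tibble::tibble(
    patient_id = out$patient_id,
    time = ifelse(hit, as.numeric(out$first_date - out$index_date),
                  out$follow_up_days),
    event = hit
  )
}

#' Time to first treatment discontinuation
#'
#' The event is the end of the first treatment line labelled
#' `discontinuation`; patients without one are censored at the end of
#' follow-up.
#'
#' @param cohort cohort tibble (eligible patients used).
#' @param lines treatment-line tibble ([build_treatment_lines()]).
#' @return tibble with `patient_id`, `time` (days), `event`.
#' @export
time_to_discontinuation <- function(cohort, lines) {
  elig <- cohort[cohort$eligible, , drop = FALSE]
  disc <- lines[lines$event == "discontinuation", , drop = FALSE]
  first <- dplyr::summarise(dplyr::group_by(disc, .data$patient_id),
                            end = min(.data$end), .groups = "drop")
  out <- dplyr::left_join(elig[, c("patient_id", "index_date",
                                   "follow_up_days")],
                          first, by = "patient_id")
  hit <- !is.na(out$end)
  tibble::tibble(
    patient_id = out$patient_id,
    time = ifelse(hit, as.numeric(out$end - out$index_date),
                  out$follow_up_days),
    event = hit
  )
}
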