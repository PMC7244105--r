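## publication-style summary tables ------------------------------------------

AGE_BANDS <- c("18-34", "35-44", "45-54", "55-64", "65+")
POLY_BANDS <- c("0", "1-3", "4-5", "6-8", ">8")

age_band <- function(age) {
  cut(age, breaks = c(18, 35, 45, 55, 65, Inf), right = FALSE,
      labels = AGE_BANDS)
}
poly_band <- function(n) {
  cut(n, breaks = c(-0.5, 0.5, 3.5, 5.5, 8.5, Inf), labels = POLY_BANDS)
}

# one row per (item, stat); groups = named list of logical masks over df rows
summarise_groups <- function(section, groups, builder) {
  rows <- list()
  for (g in names(groups)) {
    built <- builder(groups[[g]])
    built$section <- section
    built$group <- g
    rows[[g]] <- built
  }
  dplyr::bind_rows(rows)
}

count_pct <- function(item, hits, denom) {
  tibble::tibble(item = item, stat = "n_pct", n = sum(hits, na.rm = TRUE),
                 denom = denom,
                 pct = if (denom > 0) 100 * sum(hits, na.rm = TRUE) / denom
                       else NA_real_)
}
mean_sd <- function(item, x) {
  tibble::tibble(item = item, stat = "mean_sd", n = NA_integer_,
                 denom = NA_integer_, value = mean(x, na.rm = TRUE),
                 sd = stats::sd(x, na.rm = TRUE))
}
median_row <- function(item, x) {
  tibble::tibble(item = item, stat = "median", n = NA_integer_,
                 denom = NA_integer_, value = stats::median(x, na.rm = TRUE))
}

# the six standard cohort columns: all/naive x total/mild/moderate-severe
severity_groups <- function(cohort) {
  naive <- cohort$treatment_experience == "naive"
  list(
    all_total = rep(TRUE, nrow(cohort)),
    all_mild = cohort$severity == "mild",
    all_moderate_severe = cohort$severity == "moderate_severe",
    naive_total = naive,
    naive_mild = naive & cohort$severity == "mild",
    naive_moderate_severe = naive & cohort$severity == "moderate_severe"
  )
}

build_table1 <- function(cohort) {
  elig <- cohort[cohort$eligible, , drop = FALSE]
  groups <- severity_groups(elig)
  summarise_groups("table1", groups, function(sel) {
    d <- elig[sel, , drop = FALSE]
    n <- nrow(d)
    ab <- age_band(d$age_at_index)
    p3 <- poly_band(d$polypharmacy_l3)
    p1 <- poly_band(d$polypharmacy_l1)
    dplyr::bind_rows(
      tibble::tibble(item = "n", stat = "n_pct", n = n, denom = n,
                     pct = if (n > 0) 100 else NA_real_),
      mean_sd("follow_up_days", d$follow_up_days),
      mean_sd("age_at_index", d$age_at_index),
      dplyr::bind_rows(lapply(AGE_BANDS, function(b) {
        count_pct(paste0("age_", b), ab == b, n)
      })),
      count_pct("male", d$sex == "male", n),
      mean_sd("polypharmacy_l3", d$polypharmacy_l3),
      median_row("polypharmacy_l3", d$polypharmacy_l3),
      dplyr::bind_rows(lapply(POLY_BANDS, function(b) {
        count_pct(paste0("polypharmacy_l3_", b), p3 == b, n)
      })),
      mean_sd("polypharmacy_l1", d$polypharmacy_l1),
      median_row("polypharmacy_l1", d$polypharmacy_l1),
      dplyr::bind_rows(lapply(POLY_BANDS, function(b) {
        count_pct(paste0("polypharmacy_l1_", b), p1 == b, n)
      })),
      mean_sd("cci", d$cci),
      median_row("cci", d$cci),
      dplyr::bind_rows(lapply(comorbidity_flags$flag, function(f) {
        dplyr::bind_rows(
          count_pct(paste0(f, "_baseline"), d[[paste0(f, "_baseline")]], n),
          count_pct(paste0(f, "_selection"), d[[paste0(f, "_selection")]], n)
        )
      })),
      count_pct("experience_naive", d$treatment_experience == "naive", n),
      count_pct("experience_experienced",
                d$treatment_experience == "experienced", n),
      count_pct("experience_na", d$treatment_experience == "na", n),
      count_pct("gma", d$gma, n),
      count_pct("tonsillectomy", d$tonsillectomy, n)
    )
  })
}

# mutually exclusive first-line assignment per eligible patient
first_line_assignment <- function(cohort, lines, procedures) {
  elig <- cohort[cohort$eligible, , drop = FALSE]
  l1 <- lines[lines$line_number == 1L, , drop = FALSE]
  assign <- stats::setNames(rep("no_treatment", nrow(elig)), elig$patient_id)
  assign[l1$patient_id] <- l1$head_class
  # a medical intervention strictly before any drug line is the first line
  iv <- procedures[procedures$kind %in% c("gma", "tonsillectomy"), ,
                   drop = FALSE]
  if (nrow(iv) > 0) {
    iv <- dplyr::inner_join(
      iv, elig[, c("patient_id", "index_date", "follow_up_end")],
      by = "patient_id")
    iv <- iv[!is.na(iv$date) & iv$date >= iv$index_date &
               iv$date < iv$follow_up_end, , drop = FALSE]
    first_iv <- dplyr::summarise(dplyr::group_by(iv, .data$patient_id),
                                 date = min(.data$date),
                                 kind = .data$kind[which.min(.data$date)],
                                 .groups = "drop")
    l1_start <- stats::setNames(as.integer(l1$start), l1$patient_id)
    for (k in seq_len(nrow(first_iv))) {
      pid <- first_iv$patient_id[k]
      s <- l1_start[pid]
      if (is.na(s) || as.integer(first_iv$date[k]) < s) {
        assign[pid] <- first_iv$kind[k]
      }
    }
  }
  tibble::tibble(patient_id = elig$patient_id, first_line = unname(assign))
}

FIRST_LINE_ITEMS <- c("no_treatment", "topical", "phototherapy",
                      "systemic_nonbio", "biologic", "gma", "tonsillectomy")

build_table2 <- function(cohort, lines, procedures) {
  elig <- cohort[cohort$eligible, , drop = FALSE]
  fl <- first_line_assignment(cohort, lines, procedures)
  elig <- dplyr::left_join(elig, fl, by = "patient_id")
  groups <- severity_groups(elig)
  summarise_groups("table2", groups, function(sel) {
    d <- elig[sel, , drop = FALSE]
    n <- nrow(d)
    dplyr::bind_rows(
      tibble::tibble(item = "n", stat = "n_pct", n = n, denom = n,
                     pct = if (n > 0) 100 else NA_real_),
      dplyr::bind_rows(lapply(FIRST_LINE_ITEMS, function(it) {
        count_pct(it, d$first_line == it, n)
      }))
    )
  })
}

REGIMEN_BREAKDOWN <- list(
  topical = c(only = "topical"),
  phototherapy = c(
    only = "phototherapy",
    with_topical = "topical+phototherapy"
  ),
  systemic_nonbio = c(
    only = "systemic_nonbio",
    with_topical = "topical+systemic_nonbio",
    with_phototherapy = "phototherapy+systemic_nonbio",
    with_topical_and_phototherapy = "topical+phototherapy+systemic_nonbio"
  ),
  biologic = c(
    only = "biologic",
    with_nonbio = "systemic_nonbio+biologic",
    with_phototherapy = "phototherapy+biologic",
    with_topical = "topical+biologic",
    with_topical_and_phototherapy = "topical+phototherapy+biologic",
    with_nonbio_and_phototherapy = "phototherapy+systemic_nonbio+biologic",
    with_topical_and_nonbio = "topical+systemic_nonbio+biologic",
    with_topical_nonbio_and_phototherapy =
      "topical+phototherapy+systemic_nonbio+biologic"
  )
)

build_table3 <- function(cohort, lines, procedures, max_line = 6L) {
  elig <- cohort[cohort$eligible &
                   cohort$treatment_experience == "naive", , drop = FALSE]
  ln <- lines[lines$patient_id %in% elig$patient_id &
                lines$line_number <= max_line, , drop = FALSE]
  iv <- procedures[procedures$kind %in% c("gma", "tonsillectomy"), ,
                   drop = FALSE]
  iv <- iv[iv$patient_id %in% elig$patient_id, , drop = FALSE]
  rows <- list()
  for (k in seq_len(max_line)) {
    lk <- ln[ln$line_number == k, , drop = FALSE]
    n_line <- nrow(lk)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      line_number = k, head_class = "all", item = "n",
      n = n_line, denom = n_line,
      pct = if (n_line > 0) 100 else NA_real_)
    for (cl in names(REGIMEN_BREAKDOWN)) {
      in_cl <- lk$head_class == cl
      n_cl <- sum(in_cl)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        line_number = k, head_class = cl, item = "total", n = n_cl,
        denom = n_line,
        pct = if (n_line > 0) 100 * n_cl / n_line else NA_real_)
      br <- REGIMEN_BREAKDOWN[[cl]]
      if (length(br) > 1L) {
        for (b in names(br)) {
          nb <- sum(in_cl & lk$regimen == br[[b]])
          rows[[length(rows) + 1L]] <- tibble::tibble(
            line_number = k, head_class = cl, item = b, n = nb, denom = n_cl,
            pct = if (n_cl > 0) 100 * nb / n_cl else NA_real_)
        }
      }
    }
    # medical interventions during the line interval (never lines themselves)
    for (kind in c("gma", "tonsillectomy")) {
      n_iv <- 0L
      if (nrow(iv) > 0 && n_line > 0) {
        jj <- dplyr::inner_join(iv[iv$kind == kind, , drop = FALSE],
                                lk[, c("patient_id", "start", "end")],
                                by = "patient_id")
        n_iv <- length(unique(
          jj$patient_id[!is.na(jj$date) & jj$date >= jj$start &
                          jj$date < jj$end]))
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        line_number = k, head_class = "intervention", item = kind, n = n_iv,
        denom = n_line,
        pct = if (n_line > 0) 100 * n_iv / n_line else NA_real_)
    }
  }
  out <- dplyr::bind_rows(rows)
  out$section <- "table3"
  out
}

build_table4 <- function(cohort, lines, max_line = 3L) {
  elig <- cohort[cohort$eligible &
                   cohort$treatment_experience == "naive", , drop = FALSE]
  ln <- lines[lines$patient_id %in% elig$patient_id, , drop = FALSE]
  out <- line_duration_stats(ln, max_line = max_line)
  out$section <- "table4"
  out
}

#' Assemble the full study report
#'
#' Produces the publication-style tables from the upstream artifacts:
#' demographics and comorbidity by severity and treatment experience
#' (table 1), first-line distribution (table 2), per-line regimen breakdown
#' for treatment-naive patients up to the sixth line (table 3), line
#' durations and terminating-event proportions up to the third line,
#' medical interventions excluded (table 4), resource utilization
#' (table 5), per-patient-month costs, and the attrition flow. Re-running
#' on identical inputs is byte-identical.
#'
#' @param cohort_result list from [build_cohort()].
#' @param lines tibble from [build_treatment_lines()].
#' @param prescriptions,procedures claims tibbles.
#' @param config a [ppp_config()].
#' @return named list of tibbles (class `ppp_report`).
#' @export
build_report <- function(cohort_result, lines, prescriptions, procedures,
                         config) {
  cohort <- cohort_result$cohort
  bad <- setdiff(lines$patient_id, cohort$patient_id)
  if (length(bad) > 0) {
    stop("lines reference patients missing from the cohort: ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  elig <- cohort[cohort$eligible, , drop = FALSE]

  hcru <- summarize_hcru(cohort, procedures, config)
  costs_pat <- cost_per_patient_month(cohort, prescriptions, procedures,
                                      config)
  sev <- stats::setNames(elig$severity, elig$patient_id)
  costs_pat$severity <- unname(sev[costs_pat$patient_id])
  cost_groups <- list(overall = rep(TRUE, nrow(costs_pat)),
                      mild = costs_pat$severity == "mild",
                      moderate_severe = costs_pat$severity == "moderate_severe")
  cost_rows <- list()
  for (g in names(cost_groups)) {
    d <- costs_pat[cost_groups[[g]], , drop = FALSE]
    for (cat in c("inpatient", "outpatient", "pharmacy", "total")) {
      v <- d[[paste0(cat, "_pppm")]]
      cost_rows[[length(cost_rows) + 1L]] <- tibble::tibble(
        group = g, category = cat, n = nrow(d),
        mean_pppm = if (nrow(d) > 0) mean(v) else NA_real_,
        sd_pppm = if (nrow(d) > 1) stats::sd(v) else NA_real_,
        mean_pppm_users = if (any(v > 0)) mean(v[v > 0]) else NA_real_
      )
    }
  }

  report <- list(
    attrition = cohort_result$attrition,
    table1 = build_table1(cohort),
    table2 = build_table2(cohort, lines, procedures),
    table3 = build_table3(cohort, lines, procedures),
    table4 = build_table4(cohort, lines),
    table5 = hcru,
    costs = dplyr::bind_rows(cost_rows)
  )
  class(report) <- c("ppp_report", class(report))
  report
}

#' Write a report to a directory of CSVs plus a small HTML index
#'
#' Percentages are formatted to one decimal in the CSVs' `pct` columns'
#' companion `pct_fmt` field; the raw values are kept. Output is
#' deterministic for identical inputs.
#'
#' @param report a `ppp_report` ([build_report()]).
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report)) {
    df <- as.data.frame(report[[nm]])
    if ("pct" %in% names(df)) df$pct_fmt <- sprintf("%.1f", df$pct)
    utils::write.csv(df, file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE, na = "")
  }
  html <- c("<!DOCTYPE html>", "<html><head><meta charset='utf-8'>",
            "<title>PPP claims study report</title></head><body>")
  for (nm in names(report)) {
    df <- as.data.frame(report[[nm]])
    num <- vapply(df, is.numeric, logical(1L))
    df[num] <- lapply(df[num], function(x) round(x, 2))
    html <- c(html, paste0("<h2>", nm, "</h2>"), "<table border='1'>",
              paste0("<tr>", paste0("<th>", names(df), "</th>",
                                    collapse = ""), "</tr>"),
              apply(df, 1L, function(r) {
                paste0("<tr>", paste0("<td>", r, "</td>", collapse = ""),
                       "</tr>")
              }), "</table>")
  }
  html <- c(html, "</body></html>")
  writeLines(html, file.path(dir, "report.html"))
  invisible(dir)
}
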