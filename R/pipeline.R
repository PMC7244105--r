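## end-to-end study runner ---------------------------------------------------

#' Run the full synthetic study end to end
#'
#' Chains generation, cohort selection, line reconstruction, resource-use
#' and cost summarization and report assembly with one shared configuration
#' and a single seed. When `out_dir` is given, every intermediate is written
#' as CSV (claims tables, planted truth, cohort, attrition, lines, resource
#' and cost summaries, report tables, Kaplan-Meier curves) along with a run
#' manifest (`manifest.json`) recording the seed, configuration hash and
#' per-stage row counts.
#'
#' @param config a [ppp_config()].
#' @param n_patients synthetic cohort size.
#' @param seed integer; defaults to `config$seed`. All randomness flows from
#'   it.
#' @param exclusion_fractions optional named fractions passed to
#'   [plant_exclusions()].
#' @param out_dir optional output directory.
#' @return list with `data`, `cohort`, `attrition`, `lines`, `hcru`,
#'   `costs`, `report`, `km_discontinuation`, `manifest` (invisible).
#' @export
run_study <- function(config = ppp_config(), n_patients = 500L,
                      seed = config$seed, exclusion_fractions = NULL,
                      out_dir = NULL) {
  validate_config(config)
  data <- synth_claims(n_patients, config, seed = seed)
  if (!is.null(exclusion_fractions)) {
    data <- plant_exclusions(data, exclusion_fractions, seed = seed + 1L,
                             ppp_icd10 = config$ppp_icd10)
  }
  cohort_result <- build_cohort(data$enrollment, data$diagnosis,
                                data$prescription, data$procedure, config)
  lines <- build_treatment_lines(cohort_result$cohort, data$prescription,
                                 data$procedure, config)
  hcru <- summarize_hcru(cohort_result$cohort, data$procedure, config)
  costs <- cost_per_patient_month(cohort_result$cohort, data$prescription,
                                  data$procedure, config)
  report <- build_report(cohort_result, lines, data$prescription,
                         data$procedure, config)
  ttd <- time_to_discontinuation(cohort_result$cohort, lines)
  km <- km_estimate(ttd$time, ttd$event)

  manifest <- list(
    package_version = as.character(utils::packageVersion("ppplines")),
    seed = seed,
    n_patients = n_patients,
    row_counts = lapply(data, nrow),
    n_eligible = sum(cohort_result$cohort$eligible),
    n_lines = nrow(lines)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_synth(data, file.path(out_dir, "claims"))
    write_claims(cohort_result$cohort, file.path(out_dir, "cohort.csv"))
    utils::write.csv(cohort_result$attrition,
                     file.path(out_dir, "attrition.csv"), row.names = FALSE)
    write_claims(lines, file.path(out_dir, "lines.csv"))
    utils::write.csv(hcru, file.path(out_dir, "hcru.csv"), row.names = FALSE)
    utils::write.csv(costs, file.path(out_dir, "costs.csv"),
                     row.names = FALSE)
    utils::write.csv(km, file.path(out_dir, "km_discontinuation.csv"),
                     row.names = FALSE)
    write_report(report, file.path(out_dir, "report"))
    cfg_path <- file.path(out_dir, "config.yaml")
    write_config(config, cfg_path)
    manifest$config_md5 <- unname(tools::md5sum(cfg_path))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  invisible(list(data = data, cohort = cohort_result$cohort,
                 attrition = cohort_result$attrition, lines = lines,
                 hcru = hcru, costs = costs, report = report,
                 km_discontinuation = km, manifest = manifest))
}
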