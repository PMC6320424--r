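#' Run the end-to-end EMR processing pipeline on synthetic data
#'
#' Executes the full cascade: synthetic-table generation, visit-level
#' aggregation, visit exclusions, orphan-diagnosis filtering, diagnosis
#' standardization (backward mapping with fallback modification),
#' phenotyping to disease categories, patient-level aggregation, patient
#' exclusions, derived measures (CCI, PPS, housing SES, subsidy status,
#' RSR), cohort profiling, and the statistical validation harness. Every
#' stage's row counts are recorded in a run manifest; dropped rows are
#' attributable to exactly one exclusion rule.
#'
#' @param config A [synth_config()].
#' @param out_dir Optional directory; when given, all stage artifacts are
#'   written there (CSV tables, `exclusion_log.json`, `mapping_stats.json`,
#'   `profile.json`, `validation_report.json`, `manifest.json`).
#' @param alpha Level for the correlation CIs.
#' @param min_age Minimum age at visit (years).
#' @return A list with elements `visits`, `patients`, `measures` (measured
#'   patient table), `exclusion_log`, `std_stats`, `ccs_stats`, `profile`,
#'   `validation`, `manifest`, `generated` (the generator output).
#' @export
run_pipeline <- function(config = synth_config(), out_dir = NULL,
                         alpha = 0.05, min_age = 21) {
  gen <- generate_emr(config)
  tables <- gen$tables

  visits <- build_visits(tables, index = gen$index)
  vexcl <- apply_visit_exclusions(
    visits, c(config$window_start, config$window_end), min_age = min_age
  )
  kept_visits <- vexcl$visits

  dx <- filter_orphan_diagnoses(tables$diagnosis, kept_visits$visit_id)
  std <- standardize_diagnoses(dx, gen$xwalks$icd10_icd9, cutover = config$cutover)
  std_dx <- std$diagnoses
  n_unmapped_std <- sum(std_dx$excluded)
  mapped_dx <- std_dx[!std_dx$excluded, , drop = FALSE]
  phen <- phenotype_codes(mapped_dx, gen$xwalks$icd9_ccs)
  phen_dx <- phen$codes
  n_unmapped_phen <- sum(phen_dx$excluded)

  patients <- build_patients(kept_visits, tables$demographic, phen_dx,
                             study_end = config$study_end)
  pexcl <- apply_patient_exclusions(patients)
  exclusion_log <- dplyr::bind_rows(vexcl$log, pexcl$log)

  measures <- attach_measures(pexcl$patients, default_comorbidity_map(), gen$housing)
  profile <- summarize_cohort(measures, age_threshold = 65)
  validation <- validation_report(measures, alpha = alpha)

  manifest <- list(
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    versions = list(emrforge = as.character(utils::packageVersion("emrforge")),
                    r = as.character(getRversion())),
    counts = list(
      records = vapply(tables, nrow, integer(1)),
      visits_built = nrow(visits),
      visits_kept = nrow(kept_visits),
      diagnoses_total = nrow(tables$diagnosis),
      diagnoses_on_kept_visits = nrow(dx),
      diagnoses_unmapped_standardization = n_unmapped_std,
      diagnoses_unmapped_phenotyping = n_unmapped_phen,
      patients_built = nrow(patients),
      patients_kept = nrow(pexcl$patients)
    ),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  result <- list(
    visits = kept_visits, patients = pexcl$patients, measures = measures,
    exclusion_log = exclusion_log,
    std_stats = std$stats, ccs_stats = phen$stats,
    profile = profile, validation = validation,
    manifest = manifest, generated = gen
  )
  if (!is.null(out_dir)) {
    write_run_artifacts(result, out_dir)
  }
  result
}

flatten_list_cols <- function(df) {
  is_list <- vapply(df, is.list, logical(1))
  df[is_list] <- lapply(df[is_list], function(col) {
    vapply(col, function(v) paste(v, collapse = ";"), character(1))
  })
  df
}

#' Write the artifacts of a pipeline run
#'
#' @param result Return value of [run_pipeline()].
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_run_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    utils::write.csv(flatten_list_cols(as.data.frame(df)),
                     file.path(out_dir, name), row.names = FALSE)
  }
  for (nm in names(result$generated$tables)) {
    w(result$generated$tables[[nm]], paste0(nm, ".csv"))
  }
  w(result$visits, "visits.csv")
  w(result$patients, "patients.csv")
  w(result$measures, "measures.csv")
  write_crosswalk(result$generated$xwalks$icd10_icd9,
                  file.path(out_dir, "icd10_to_icd9.csv"))
  write_crosswalk(result$generated$xwalks$icd9_ccs,
                  file.path(out_dir, "icd9_to_ccs.csv"))
  w(result$generated$index, "inflation_index.csv")
  j <- function(x, name) {
    jsonlite::write_json(x, file.path(out_dir, name),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  j(result$exclusion_log, "exclusion_log.json")
  j(list(standardization = result$std_stats, phenotyping = result$ccs_stats),
    "mapping_stats.json")
  j(result$profile, "profile.json")
  j(unclass(result$validation), "validation_report.json")
  j(result$manifest, "manifest.json")
  invisible(out_dir)
}
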