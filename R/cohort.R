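#' Validate the five record-level EMR tables
#'
#' The record substrate is five tables: `demographic` (one row per patient),
#' `movement`, `billing`, `pharmacy` (one row per record/transaction) and
#' `diagnosis`. Patient ID is common to all tables, Visit ID to all but
#' demographics; the two IDs drive the record -> visit -> patient cascade.
#'
#' @param tables Named list with elements `demographic`, `movement`,
#'   `billing`, `pharmacy`, `diagnosis`.
#' @return The list, invisibly, after schema validation.
#' @export
validate_record_tables <- function(tables) {
  need <- c("demographic", "movement", "billing", "pharmacy", "diagnosis")
  missing <- setdiff(need, names(tables))
  if (length(missing) > 0) {
    emr_abort(sprintf("missing record table(s): %s", paste(missing, collapse = ", ")),
              "emrforge_schema_error")
  }
  assert_columns(tables$demographic,
                 c("patient_id", "sex", "race", "singaporean", "birth_date", "postal_code"),
                 "demographic table")
  if (anyDuplicated(tables$demographic$patient_id)) {
    emr_abort("demographic table must have at most one row per patient_id",
              "emrforge_schema_error")
  }
  assert_columns(tables$movement,
                 c("patient_id", "visit_id", "visit_class", "admission_date", "discharge_date"),
                 "movement table")
  assert_columns(tables$billing,
                 c("patient_id", "visit_id", "charge", "subsidy_amount", "subsidy_flag", "year"),
                 "billing table")
  assert_columns(tables$pharmacy,
                 c("patient_id", "visit_id", "drug_code", "is_prescription", "is_device"),
                 "pharmacy table")
  assert_columns(tables$diagnosis,
                 c("patient_id", "visit_id", "code", "role"),
                 "diagnosis table")
  invisible(tables)
}

#' Aggregate record-level tables into visit-level views
#'
#' Records are first aggregated within each of movement / billing / pharmacy
#' by Visit ID (sums for amounts, any() for flags, count-distinct for
#' prescription drugs), then the three aggregates are full-joined on Visit
#' ID — a visit seen in any of the three tables exists — and finally linked
#' to demographics through Patient ID. Charges are inflation-adjusted per
#' billing year before summation when an index is supplied.
#'
#' @param tables Record tables, see [validate_record_tables()].
#' @param index Optional inflation index tibble (`year`, `multiplier`), see
#'   [adjust_inflation()].
#' @return A visit-level tibble: identifiers, visit class and dates,
#'   `length_of_stay` (inpatient only), `charge`, `adjusted_charge`,
#'   `subsidy_amount`, `subsidy_flag`, `pps_visit`, `inpatient_flag`,
#'   `ed_flag`, `age_at_visit`, demographics.
#' @export
build_visits <- function(tables, index = NULL) {
  validate_record_tables(tables)

  mv <- tibble::as_tibble(tables$movement)
  mv$admission_date <- as_date_strict(mv$admission_date)
  mv$discharge_date <- as_date_strict(mv$discharge_date)
  mv_agg <- mv |>
    dplyr::distinct() |>
    dplyr::group_by(.data$visit_id)
  conflicts <- dplyr::summarise(mv_agg, n = dplyr::n(), .groups = "drop")
  if (any(conflicts$n > 1)) {
    emr_abort(
      sprintf("conflicting movement rows for visit(s): %s",
              paste(head(conflicts$visit_id[conflicts$n > 1], 5), collapse = ", ")),
      "emrforge_integrity_error"
    )
  }
  mv_agg <- dplyr::ungroup(mv_agg)

  bl <- tibble::as_tibble(tables$billing)
  if (!is.null(index)) {
    bl$adjusted <- adjust_inflation(bl$charge, bl$year, index)
  } else {
    bl$adjusted <- bl$charge
  }
  bl_agg <- bl |>
    dplyr::group_by(.data$visit_id) |>
    dplyr::summarise(
      charge = sum(.data$charge),
      adjusted_charge = sum(.data$adjusted),
      subsidy_amount = sum(.data$subsidy_amount),
      subsidy_flag = any(.data$subsidy_flag),
      bill_patient_id = .data$patient_id[1],
      .groups = "drop"
    )

  ph_agg <- tibble::as_tibble(tables$pharmacy) |>
    dplyr::group_by(.data$visit_id) |>
    dplyr::summarise(
      pps_visit = dplyr::n_distinct(
        .data$drug_code[.data$is_prescription & !.data$is_device]
      ),
      pharm_patient_id = .data$patient_id[1],
      .groups = "drop"
    )

  visits <- mv_agg |>
    dplyr::full_join(bl_agg, by = "visit_id") |>
    dplyr::full_join(ph_agg, by = "visit_id") |>
    dplyr::mutate(
      patient_id = dplyr::coalesce(.data$patient_id, .data$bill_patient_id,
                                   .data$pharm_patient_id),
      charge = dplyr::coalesce(.data$charge, 0),
      adjusted_charge = dplyr::coalesce(.data$adjusted_charge, 0),
      subsidy_amount = dplyr::coalesce(.data$subsidy_amount, 0),
      subsidy_flag = dplyr::coalesce(.data$subsidy_flag, FALSE),
      pps_visit = dplyr::coalesce(.data$pps_visit, 0L)
    ) |>
    dplyr::select(-dplyr::any_of(c("bill_patient_id", "pharm_patient_id")))

  visits <- visits |>
    dplyr::mutate(
      inpatient_flag = !is.na(.data$visit_class) & .data$visit_class == "inpatient",
      ed_flag = !is.na(.data$visit_class) & .data$visit_class == "ED",
      length_of_stay = ifelse(
        .data$inpatient_flag,
        as.numeric(.data$discharge_date - .data$admission_date),
        0
      )
    )
  if (any(visits$length_of_stay < 0, na.rm = TRUE)) {
    emr_abort("negative length of stay: discharge precedes admission",
              "emrforge_integrity_error")
  }

  demo <- tibble::as_tibble(tables$demographic)
  demo$birth_date <- as_date_strict(demo$birth_date)
  visits <- dplyr::left_join(visits, demo, by = "patient_id")
  visits$age_at_visit <- ifelse(
    is.na(visits$admission_date) | is.na(visits$birth_date),
    NA_real_,
    years_between(visits$birth_date, visits$admission_date)
  )
  visits
}

empty_exclusion_log <- function() {
  tibble::tibble(rule = character(0), level = character(0),
                 n_before = integer(0), n_removed = integer(0),
                 n_after = integer(0))
}

log_rule <- function(log, rule, level, n_before, n_removed) {
  dplyr::bind_rows(log, tibble::tibble(
    rule = rule, level = level,
    n_before = as.integer(n_before),
    n_removed = as.integer(n_removed),
    n_after = as.integer(n_before - n_removed)
  ))
}

#' Apply visit-level exclusion criteria
#'
#' Rules, in order, each logged: (0) a data-quality rule routing visits with
#' unresolvable dates or ages; (1) the study-window rule — any inpatient
#' visit not fully inside the window (admission before its start or discharge
#' after its end) is dropped, so every retained inpatient episode is captured
#' in full; (2) the adult-age rule — visits when the patient was younger than
#' `min_age` at the visit date are dropped.
#'
#' @param visits Visit-level tibble from [build_visits()].
#' @param window Length-2 vector of dates `[start, end]`.
#' @param min_age Minimum age in completed years at the visit (default 21).
#' @return A list: `visits` (retained rows) and `log` (ordered exclusion-log
#'   tibble with `rule`, `level`, `n_before`, `n_removed`, `n_after`).
#' @export
apply_visit_exclusions <- function(visits, window, min_age = 21) {
  stopifnot(length(window) == 2)
  start <- as_date_strict(window[1]); end <- as_date_strict(window[2])
  log <- empty_exclusion_log()

  bad_dates <- (visits$inpatient_flag %in% TRUE &
                  (is.na(visits$admission_date) | is.na(visits$discharge_date))) |
    is.na(visits$age_at_visit)
  log <- log_rule(log, "data_quality_unresolvable", "visit", nrow(visits), sum(bad_dates))
  visits <- visits[!bad_dates, , drop = FALSE]

  out_of_window <- visits$inpatient_flag &
    (visits$admission_date < start | visits$discharge_date > end)
  log <- log_rule(log, "inpatient_outside_window", "visit", nrow(visits), sum(out_of_window))
  visits <- visits[!out_of_window, , drop = FALSE]

  underage <- visits$age_at_visit < min_age
  log <- log_rule(log, "age_below_minimum", "visit", nrow(visits), sum(underage))
  visits <- visits[!underage, , drop = FALSE]

  list(visits = visits, log = log)
}

#' Filter diagnoses to visits retained in the cohort
#'
#' The diagnosis table is filtered by Visit ID against the visit universe
#' defined by the other tables after visit-level exclusions, so diagnoses on
#' excluded or unknown visits never enter the cohort.
#'
#' @param diagnoses Diagnosis tibble with a `visit_id` column.
#' @param kept_visit_ids Visit IDs retained after exclusion.
#' @return The surviving diagnosis rows.
#' @export
filter_orphan_diagnoses <- function(diagnoses, kept_visit_ids) {
  assert_columns(diagnoses, "visit_id", "diagnosis table")
  diagnoses[diagnoses$visit_id %in% kept_visit_ids, , drop = FALSE]
}

#' Adjust charges for inflation
#'
#' Multiplies nominal amounts by a per-year index that restates them at
#' base-year price levels (multiplier of the base year is 1 by convention).
#'
#' @param amount Non-negative amounts (SGD).
#' @param year Calendar year of each amount.
#' @param index Tibble with columns `year` and `multiplier`.
#' @return `amount * multiplier[year]`.
#' @export
adjust_inflation <- function(amount, year, index) {
  assert_columns(index, c("year", "multiplier"), "inflation index")
  if (any(amount < 0, na.rm = TRUE)) {
    emr_abort("amounts must be non-negative", "emrforge_config_error")
  }
  m <- index$multiplier[match(year, index$year)]
  if (anyNA(m)) {
    emr_abort(
      sprintf("year(s) outside the inflation index: %s",
              paste(unique(year[is.na(m)]), collapse = ", ")),
      "emrforge_config_error"
    )
  }
  amount * m
}

#' Aggregate visit-level views into patient-level views
#'
#' Sums length of stay, charges (already inflation-adjusted at visit level)
#' and subsidy over the patient's included visits; counts visits by class;
#' takes the maximum visit-level Polypharmacy Score; ORs diagnosis-derived
#' flags. The observed period is the span from first to last included visit
#' (inclusive of both days), in years.
#'
#' @param visits Exclusion-filtered visit tibble.
#' @param demographics Demographic table (one row per patient).
#' @param diagnoses Optional standardized + phenotyped diagnosis tibble
#'   (columns `patient_id`, `visit_id`, `role`, `std_code`, `category`);
#'   supplies the primary-diagnosis flag, per-category disease flags and the
#'   patient's code set.
#' @param study_end Date at which attained age is computed.
#' @return A patient-level tibble; diagnosis categories become logical
#'   `cat_<category>` columns and the patient's ICD code set is kept in the
#'   list-column `dx_codes`.
#' @export
build_patients <- function(visits, demographics, diagnoses = NULL,
                           study_end = NULL) {
  demo <- tibble::as_tibble(demographics)
  demo$birth_date <- as_date_strict(demo$birth_date)
  orphan <- setdiff(unique(visits$patient_id), demo$patient_id)
  if (length(orphan) > 0) {
    emr_abort(
      sprintf("visit(s) reference patient(s) absent from demographics: %s",
              paste(head(orphan, 5), collapse = ", ")),
      "emrforge_integrity_error"
    )
  }

  visit_date <- dplyr::coalesce(visits$admission_date, visits$discharge_date)
  patients <- visits |>
    dplyr::mutate(.visit_date = visit_date) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_visits = dplyr::n(),
      n_inpatient = sum(.data$inpatient_flag, na.rm = TRUE),
      n_soc = sum(.data$visit_class %in% "SOC"),
      n_ed = sum(.data$ed_flag, na.rm = TRUE),
      n_outpatient = sum(.data$visit_class %in% c("SOC", "ED", "other outpatient")),
      total_los = sum(.data$length_of_stay, na.rm = TRUE),
      total_charge = sum(.data$charge),
      total_adjusted_charge = sum(.data$adjusted_charge),
      total_subsidy = sum(.data$subsidy_amount),
      pps = max(c(0L, .data$pps_visit), na.rm = TRUE),
      subsidy_flags = list(.data$subsidy_flag),
      first_visit = min(.data$.visit_date, na.rm = TRUE),
      last_visit = max(.data$.visit_date, na.rm = TRUE),
      .groups = "drop"
    )

  patients <- dplyr::left_join(patients, demo, by = "patient_id")
  patients$observed_period <-
    (as.numeric(patients$last_visit - patients$first_visit) + 1) / 365.25
  patients$birth_year <- as.integer(format(patients$birth_date, "%Y"))
  if (!is.null(study_end)) {
    patients$age_at_end <- years_between(patients$birth_date, as_date_strict(study_end))
  }

  if (!is.null(diagnoses) && nrow(diagnoses) > 0) {
    assert_columns(diagnoses, c("patient_id", "role", "std_code"), "diagnosis table")
    dx <- diagnoses[diagnoses$patient_id %in% patients$patient_id, , drop = FALSE]
    pd <- dx |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(
        has_pd = any(.data$role == "primary"),
        dx_codes = list(unique(stats::na.omit(.data$std_code))),
        .groups = "drop"
      )
    patients <- dplyr::left_join(patients, pd, by = "patient_id")
    patients$has_pd <- dplyr::coalesce(patients$has_pd, FALSE)
    no_dx <- vapply(patients$dx_codes, is.null, logical(1))
    patients$dx_codes[no_dx] <- list(character(0))
    if ("category" %in% names(diagnoses)) {
      cats <- dx[!is.na(dx$category), c("patient_id", "category")]
      if (nrow(cats) > 0) {
        flags <- cats |>
          dplyr::distinct() |>
          dplyr::mutate(value = TRUE) |>
          tidyr::pivot_wider(names_from = "category", values_from = "value",
                             values_fill = FALSE, names_prefix = "cat_")
        patients <- dplyr::left_join(patients, flags, by = "patient_id")
        catcols <- grep("^cat_", names(patients), value = TRUE)
        patients[catcols] <- lapply(patients[catcols], function(v) dplyr::coalesce(v, FALSE))
      }
    }
  } else {
    patients$has_pd <- FALSE
    patients$dx_codes <- rep(list(character(0)), nrow(patients))
  }
  patients
}

#' Default sex-specific invalid-diagnosis rules
#'
#' Editable rule table for biologically implausible diagnoses: pregnancy,
#' childbirth and female-infertility code ranges for male patients; prostate
#' and male-genital ranges for female patients. Prefixes are matched against
#' the start of each normalized ICD-9-CM code.
#'
#' @return Tibble with columns `sex` and `prefix`.
#' @export
default_invalid_dx_rules <- function() {
  read_invalid_dx_rules(
    system.file("extdata", "invalid_dx_rules.csv", package = "emrforge")
  )
}

#' @rdname default_invalid_dx_rules
#' @param path CSV file with header `sex,prefix`.
#' @export
read_invalid_dx_rules <- function(path) {
  df <- read.csv(path, colClasses = "character")
  assert_columns(df, c("sex", "prefix"), "invalid-diagnosis rule file")
  tibble::as_tibble(df)
}

#' Apply patient-level exclusion criteria
#'
#' Rules, in order, each logged: (1) patients with no primary diagnosis; (2)
#' patients with birth year 1900 or earlier (the EMR assigns 1900 when the
#' birth date is unknown); (3) patients carrying a sex-implausible diagnosis
#' per the rule table. Patients whose sex is missing while a sex-specific
#' rule would fire are routed to a data-quality rule rather than silently
#' kept.
#'
#' @param patients Patient-level tibble from [build_patients()].
#' @param invalid_dx_rules Rule tibble (`sex`, `prefix`); defaults to
#'   [default_invalid_dx_rules()].
#' @return A list: `patients` (retained rows) and `log` (exclusion-log
#'   tibble).
#' @export
apply_patient_exclusions <- function(patients, invalid_dx_rules = default_invalid_dx_rules()) {
  assert_columns(patients, c("patient_id", "has_pd", "birth_year", "sex", "dx_codes"),
                 "patient table")
  log <- empty_exclusion_log()

  no_pd <- !patients$has_pd
  log <- log_rule(log, "no_primary_diagnosis", "patient", nrow(patients), sum(no_pd))
  patients <- patients[!no_pd, , drop = FALSE]

  old <- !is.na(patients$birth_year) & patients$birth_year <= 1900
  log <- log_rule(log, "birth_year_1900_or_earlier", "patient", nrow(patients), sum(old))
  patients <- patients[!old, , drop = FALSE]

  hits_rules <- function(codes, rules) {
    if (length(codes) == 0 || nrow(rules) == 0) return(FALSE)
    any(vapply(rules$prefix, function(p) any(startsWith(codes, p)), logical(1)))
  }
  flagged <- logical(nrow(patients))
  unknown_sex <- logical(nrow(patients))
  for (i in seq_len(nrow(patients))) {
    sx <- patients$sex[i]
    codes <- patients$dx_codes[[i]]
    if (is.na(sx)) {
      # Can't evaluate a sex-specific rule without sex: data-quality route if
      # any rule prefix matches regardless of sex.
      unknown_sex[i] <- hits_rules(codes, invalid_dx_rules)
    } else {
      flagged[i] <- hits_rules(codes, invalid_dx_rules[invalid_dx_rules$sex == sx, ])
    }
  }
  log <- log_rule(log, "invalid_sex_specific_diagnosis", "patient", nrow(patients), sum(flagged))
  patients <- patients[!flagged, , drop = FALSE]
  unknown_sex <- unknown_sex[!flagged]
  log <- log_rule(log, "data_quality_missing_sex", "patient", nrow(patients), sum(unknown_sex))
  patients <- patients[!unknown_sex, , drop = FALSE]

  list(patients = patients, log = log)
}

#' Profile a patient cohort
#'
#' Counts and percentages by sex, age band, race, subsidy status and housing
#' group; disease-category prevalence; medians and interquartile ranges for
#' charges, visits, length of stay and complexity scores — optionally
#' stratified at an age threshold.
#'
#' @param patients Patient-level tibble (measure columns used when present:
#'   `subsidy_status`, `housing_group`, `cci`, `pps`, `age_at_end`,
#'   `cat_*`).
#' @param age_threshold Optional age cut for stratification (e.g. 65).
#' @return A nested list (JSON-serializable profile report).
#' @export
summarize_cohort <- function(patients, age_threshold = NULL) {
  if (nrow(patients) == 0) {
    emr_abort("cannot profile an empty cohort", "emrforge_config_error")
  }

  count_pct <- function(x) {
    tab <- table(x, useNA = "ifany")
    lapply(seq_along(tab), function(i) {
      list(level = if (is.na(names(tab)[i]) || names(tab)[i] == "") "missing" else names(tab)[i],
           n = as.integer(tab[[i]]),
           pct = round_half_up(100 * tab[[i]] / length(x), 2))
    })
  }
  med_iqr <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(NULL)
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    list(total = sum(x), median = q[2], q1 = q[1], q3 = q[3])
  }
  profile_one <- function(p) {
    out <- list(n_patients = nrow(p), sex = count_pct(p$sex), race = count_pct(p$race))
    if ("age_at_end" %in% names(p)) {
      bands <- cut(p$age_at_end, c(21, 30, 40, 50, 60, 70, 80, Inf), right = FALSE,
                   labels = c("21-29", "30-39", "40-49", "50-59", "60-69", "70-79", ">=80"))
      out$age_band <- count_pct(bands)
    }
    if ("subsidy_status" %in% names(p)) out$subsidy_status <- count_pct(p$subsidy_status)
    if ("housing_group" %in% names(p)) out$housing_group <- count_pct(p$housing_group)
    catcols <- grep("^cat_", names(p), value = TRUE)
    if (length(catcols) > 0) {
      out$disease_prevalence <- lapply(catcols, function(cc) {
        list(category = sub("^cat_", "", cc), n = sum(p[[cc]]),
             pct = round_half_up(100 * mean(p[[cc]]), 2))
      })
    }
    nums <- c(charges = "total_adjusted_charge", inpatient_visits = "n_inpatient",
              soc_visits = "n_soc", ed_visits = "n_ed", los = "total_los",
              cci = "cci", pps = "pps")
    out$numeric <- Filter(Negate(is.null), lapply(nums[nums %in% names(p)],
                                                  function(v) med_iqr(p[[v]])))
    out
  }

  report <- profile_one(patients)
  if (!is.null(age_threshold) && "age_at_end" %in% names(patients)) {
    young <- patients[patients$age_at_end <= age_threshold, , drop = FALSE]
    old <- patients[patients$age_at_end > age_threshold, , drop = FALSE]
    report$strata <- list()
    if (nrow(young) > 0) {
      report$strata[[sprintf("age_le_%d", age_threshold)]] <- profile_one(young)
    }
    if (nrow(old) > 0) {
      report$strata[[sprintf("age_gt_%d", age_threshold)]] <- profile_one(old)
    }
  }
  report
}
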