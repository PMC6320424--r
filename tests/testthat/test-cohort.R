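test_that("visit aggregation sums bills, counts distinct drugs, links demographics", {
  v <- build_visits(tiny_tables(), index = identity_index())
  va <- v[v$visit_id == "VA", ]
  expect_equal(va$charge, 350)
  expect_equal(va$subsidy_amount, 175)
  expect_identical(va$pps_visit, 2L) # D1 dispensed twice counts once
  expect_equal(va$length_of_stay, 5)
  expect_identical(va$sex, "male")
  expect_equal(va$age_at_visit, 45)
  vc <- v[v$visit_id == "VC", ]
  expect_identical(vc$pps_visit, 0L) # non-prescription + device rows only
  expect_equal(vc$length_of_stay, 0)
})

test_that("a visit present only in pharmacy survives the full join", {
  tabs <- tiny_tables()
  tabs$pharmacy <- dplyr::bind_rows(tabs$pharmacy, tibble::tibble(
    patient_id = "P2", visit_id = "VD", drug_code = "D9",
    is_prescription = TRUE, is_device = FALSE
  ))
  v <- build_visits(tabs, identity_index())
  vd <- v[v$visit_id == "VD", ]
  expect_identical(nrow(vd), 1L)
  expect_true(is.na(vd$visit_class))
  expect_identical(vd$pps_visit, 1L)
  expect_identical(vd$patient_id, "P2")
})

test_that("conflicting movement rows for one visit raise an integrity error", {
  tabs <- tiny_tables()
  tabs$movement <- dplyr::bind_rows(tabs$movement, tibble::tibble(
    patient_id = "P1", visit_id = "VA", visit_class = "SOC",
    admission_date = as.Date("2006-03-01"), discharge_date = as.Date("2006-03-06")
  ))
  expect_error(build_visits(tabs, identity_index()), class = "emrforge_integrity_error")
})

test_that("inflation adjustment multiplies by the year index and validates the domain", {
  idx <- tibble::tibble(year = c(2005, 2015), multiplier = c(1.30, 1))
  expect_equal(adjust_inflation(100, 2015, idx), 100)
  expect_equal(adjust_inflation(100, 2005, idx), 130)
  expect_error(adjust_inflation(100, 1999, idx), class = "emrforge_config_error")
  expect_error(adjust_inflation(-1, 2015, idx), class = "emrforge_config_error")
})

test_that("visit exclusions apply the window and age rules in logged order", {
  demo <- tibble::tibble(
    patient_id = c("P1", "P2"), sex = c("male", "female"),
    race = "Chinese", singaporean = TRUE,
    birth_date = as.Date(c("1950-01-01", "1984-02-15")),
    postal_code = "100011"
  )
  mk_visit <- function(id, pid, class, adm, dis) tibble::tibble(
    visit_id = id, patient_id = pid, visit_class = class,
    admission_date = as.Date(adm), discharge_date = as.Date(dis),
    inpatient_flag = class == "inpatient", ed_flag = class == "ED",
    length_of_stay = as.numeric(as.Date(dis) - as.Date(adm)) * (class == "inpatient")
  )
  visits <- dplyr::bind_rows(
    mk_visit("V1", "P1", "inpatient", "2004-12-30", "2005-01-05"), # straddles start
    mk_visit("V2", "P1", "inpatient", "2013-12-28", "2014-01-03"), # straddles end
    mk_visit("V3", "P1", "other outpatient", "2004-06-01", "2004-06-01"), # outpatient: window rule does not apply
    mk_visit("V4", "P2", "SOC", "2005-01-10", "2005-01-10"),       # aged 20y11m
    mk_visit("V5", "P2", "SOC", "2005-02-20", "2005-02-20"),       # aged 21y0m
    mk_visit("V6", "P1", "inpatient", "2005-01-01", "2005-01-04")  # fully inside
  )
  visits <- dplyr::left_join(visits, demo, by = "patient_id")
  visits$age_at_visit <- floor(as.numeric(
    visits$admission_date - visits$birth_date) / 365.25)

  out <- apply_visit_exclusions(visits, c("2005-01-01", "2013-12-31"), min_age = 21)
  expect_setequal(out$visits$visit_id, c("V3", "V5", "V6"))
  expect_identical(out$log$rule,
                   c("data_quality_unresolvable", "inpatient_outside_window",
                     "age_below_minimum"))
  expect_identical(out$log$n_removed, c(0L, 2L, 1L))
  # log chains exactly
  expect_identical(out$log$n_after, out$log$n_before - out$log$n_removed)
  expect_identical(out$log$n_before[-1], out$log$n_after[-nrow(out$log)])
  # idempotence: re-running removes nothing
  again <- apply_visit_exclusions(out$visits, c("2005-01-01", "2013-12-31"), 21)
  expect_identical(sum(again$log$n_removed), 0L)
})

test_that("orphan diagnoses are filtered by the kept visit universe", {
  dx <- tibble::tibble(visit_id = c("V1", "V1", "V2", "V3", "V4"), code = "X")
  expect_identical(nrow(filter_orphan_diagnoses(dx, c("V1", "V3"))), 3L)
  expect_identical(nrow(filter_orphan_diagnoses(dx, character(0))), 0L)
})

test_that("patient aggregation sums visit quantities and carries diagnosis flags", {
  tabs <- tiny_tables()
  v <- build_visits(tabs, identity_index())
  fix <- make_fixture_crosswalks()
  std <- standardize_diagnoses(tabs$diagnosis, fix$icd10_icd9)
  phen <- phenotype_codes(std$diagnoses[!std$diagnoses$excluded, ], fix$icd9_ccs)
  p <- build_patients(v, tabs$demographic, phen$codes, study_end = "2013-12-31")
  p1 <- p[p$patient_id == "P1", ]
  expect_equal(p1$total_charge, 430)
  expect_equal(p1$total_los, 5)
  expect_identical(p1$n_inpatient, 1L)
  expect_identical(p1$n_soc, 1L)
  expect_identical(p1$pps, 2L)
  expect_true(p1$has_pd)
  expect_true(p1[["cat_essential hypertension"]])
  expect_setequal(p1$dx_codes[[1]], c("4019", "25000"))
  # a visit referencing an unknown patient is an integrity error
  v_bad <- v; v_bad$patient_id[1] <- "P99"
  expect_error(build_patients(v_bad, tabs$demographic), class = "emrforge_integrity_error")
})

test_that("patient exclusions drop no-PD, 1900-birth and sex-implausible patients in order", {
  mk_patient <- function(id, sex, by, has_pd, codes) tibble::tibble(
    patient_id = id, sex = sex, birth_year = by, has_pd = has_pd,
    dx_codes = list(codes)
  )
  patients <- dplyr::bind_rows(
    mk_patient("P1", "male", 1960, TRUE, c("4019")),
    mk_patient("P2", "female", 1955, FALSE, c("25000")),  # no PD
    mk_patient("P3", "male", 1900, TRUE, c("4019")),      # boundary: excluded
    mk_patient("P4", "male", 1901, TRUE, c("4019")),      # boundary: retained
    mk_patient("P5", "male", 1970, TRUE, c("650")),       # pregnancy code on a male
    mk_patient("P6", "female", 1970, TRUE, c("650")),     # valid on a female
    mk_patient("P7", "female", 1980, TRUE, c("600"))      # prostate-range on a female
  )
  out <- apply_patient_exclusions(patients)
  expect_setequal(out$patients$patient_id, c("P1", "P4", "P6"))
  expect_identical(out$log$rule,
                   c("no_primary_diagnosis", "birth_year_1900_or_earlier",
                     "invalid_sex_specific_diagnosis", "data_quality_missing_sex"))
  expect_identical(out$log$n_removed, c(1L, 1L, 2L, 0L))
  expect_identical(out$log$n_before[-1], out$log$n_after[-nrow(out$log)])
})

test_that("cohort profiling reports counts, percentages and medians", {
  p <- tibble::tibble(
    patient_id = sprintf("P%d", 1:4),
    sex = c("male", "male", "female", "female"),
    race = c("Chinese", "Chinese", "Indian", "Malay"),
    total_adjusted_charge = c(1, 2, 3, 100),
    n_inpatient = c(0L, 1L, 0L, 3L), n_soc = 1L, n_ed = 0L,
    total_los = c(0, 2, 0, 10)
  )
  prof <- summarize_cohort(p)
  male <- Filter(function(x) x$level == "male", prof$sex)[[1]]
  expect_identical(male$n, 2L)
  expect_equal(male$pct, 50.0)
  expect_equal(prof$numeric$charges$median, 2.5)
  expect_error(summarize_cohort(p[0, ]), class = "emrforge_config_error")
})
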