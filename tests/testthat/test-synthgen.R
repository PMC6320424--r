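# The generator is first-class: its tables, route tables and ledger are the
# ground truth the pipeline is checked against, so the generator itself is
# tested for determinism, internal consistency and plant fidelity.

small_cfg <- function(seed = 7) synth_config(n_patients = 250, seed = seed)

test_that("generation is deterministic given the seed and differs across seeds", {
  a <- generate_emr(small_cfg())
  b <- generate_emr(small_cfg())
  expect_identical(a$tables, b$tables)
  expect_identical(a$ledger, b$ledger)
  c <- generate_emr(small_cfg(seed = 8))
  expect_false(identical(a$tables$diagnosis, c$tables$diagnosis))
})

test_that("fixture crosswalks contain every route, and recorded routes match the engine", {
  fix <- make_fixture_crosswalks()
  for (spec in list(list(routes = fix$icd10_routes, xw = fix$icd10_icd9, target = "target"),
                    list(routes = fix$ccs_routes, xw = fix$icd9_ccs, target = "category"))) {
    expect_setequal(unique(spec$routes$route),
                    c("direct", "zero_added_1", "zero_added_2", "truncated", "unmapped"))
    got <- convert_codes(spec$routes$code, spec$xw)
    expect_identical(got$method, spec$routes$route)
    expect_identical(got$target, spec$routes[[spec$target]])
    expect_identical(got$ambiguous, spec$routes$ambiguous)
    trunc <- spec$routes$route == "truncated"
    expect_identical(got$n_removed[trunc], spec$routes$n_removed[trunc])
  }
  # at least one ambiguous key, flagged exactly for it
  expect_identical(sum(fix$icd10_routes$ambiguous), 1L)
  # category map assigns exactly one category per key (mutual exclusivity)
  expect_true(all(lengths(fix$icd9_ccs$entries) == 1))
})

test_that("the housing fixture has mixed and tie blocks and disjoint lists", {
  lk <- make_housing_lookup()
  per_block <- table(lk$public$postal)
  expect_true(any(per_block > 1))                       # mixed blocks exist
  expect_identical(housing_type("100003", lk), "2-room") # documented tie-break
  expect_identical(housing_type("100033", lk), "5-room")
  expect_length(intersect(unique(lk$public$postal), lk$private), 0)
  expect_identical(housing_type("999001", lk), "missing")
})

test_that("planted mapping routes reproduce the ledger's per-method counts end-to-end", {
  gen <- generate_emr(small_cfg())
  kept <- gen$ledger$visits$visit_id[gen$ledger$visits$kept]
  dx <- filter_orphan_diagnoses(gen$tables$diagnosis, kept)
  std <- standardize_diagnoses(dx, gen$xwalks$icd10_icd9, cutover = gen$config$cutover)
  expect_identical(std$stats, gen$ledger$expected_std_stats)
  phen <- phenotype_codes(std$diagnoses[!std$diagnoses$excluded, ], gen$xwalks$icd9_ccs)
  expect_identical(phen$stats, gen$ledger$expected_ccs_stats)
})

test_that("planted rule violators are removed by exactly their rules", {
  gen <- generate_emr(small_cfg())
  visits <- build_visits(gen$tables, gen$index)
  vex <- apply_visit_exclusions(visits, c(gen$config$window_start, gen$config$window_end))
  want_v <- gen$ledger$expected_exclusions$visit
  got_v <- setNames(vex$log$n_removed, vex$log$rule)
  expect_identical(got_v[names(want_v)], setNames(as.integer(want_v), names(want_v)))

  dx <- filter_orphan_diagnoses(gen$tables$diagnosis, vex$visits$visit_id)
  std <- standardize_diagnoses(dx, gen$xwalks$icd10_icd9, cutover = gen$config$cutover)
  phen <- phenotype_codes(std$diagnoses[!std$diagnoses$excluded, ], gen$xwalks$icd9_ccs)
  patients <- build_patients(vex$visits, gen$tables$demographic, phen$codes,
                             study_end = gen$config$study_end)
  pex <- apply_patient_exclusions(patients)
  want_p <- gen$ledger$expected_exclusions$patient
  got_p <- setNames(pex$log$n_removed, pex$log$rule)
  expect_identical(got_p[names(want_p)], setNames(as.integer(want_p), names(want_p)))
})

test_that("per-visit and per-patient aggregates equal the generator's ledger", {
  gen <- generate_emr(small_cfg())
  visits <- build_visits(gen$tables, gen$index)
  truth <- gen$ledger$visits
  m <- match(truth$visit_id, visits$visit_id)
  expect_false(anyNA(m))
  expect_equal(visits$charge[m], truth$charge, tolerance = 1e-9)
  expect_equal(visits$adjusted_charge[m], truth$adjusted_charge, tolerance = 1e-9)
  expect_equal(visits$subsidy_amount[m], truth$subsidy_amount, tolerance = 1e-9)
  expect_identical(visits$pps_visit[m], as.integer(truth$pps))

  vex <- apply_visit_exclusions(visits, c(gen$config$window_start, gen$config$window_end))
  patients <- build_patients(vex$visits, gen$tables$demographic)
  agg <- gen$ledger$patient_aggregates
  pm <- match(agg$patient_id, patients$patient_id)
  expect_false(anyNA(pm))
  expect_equal(patients$total_adjusted_charge[pm], agg$total_adjusted_charge,
               tolerance = 1e-9)
  expect_equal(patients$total_los[pm], agg$total_los)
  expect_identical(patients$n_inpatient[pm], as.integer(agg$n_inpatient))
  expect_identical(patients$pps[pm], as.integer(agg$pps))
})

test_that("inconsistent configurations are rejected before generation", {
  expect_error(synth_config(n_patients = 0), class = "emrforge_config_error")
  expect_error(synth_config(tier_probs = c(0.5, 0.4)), class = "emrforge_config_error")
  expect_error(synth_config(unmappable_frac = 1.2), class = "emrforge_config_error")
  expect_error(synth_config(n_patients = 20), class = "emrforge_config_error") # violators exceed half
  expect_error(synth_config(nonsense = 1), class = "emrforge_config_error")
})
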