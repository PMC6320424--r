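# Fixture code universe ------------------------------------------------------
#
# A small, hand-constructed code universe with every conversion route
# represented by construction: directly mappable codes, codes mappable only
# after one or two zero additions, codes mappable only after truncation, an
# ambiguous multi-target key, and codes unmappable by any route. The route of
# every fixture code is recorded here, independently of the conversion
# engine, so the engine can be checked against planted ground truth.

icd10_direct_map <- function() {
  c(I10 = "4019", E119 = "25000", E1122 = "25040", I214 = "41001",
    I252 = "412", I500 = "4280", I639 = "43491", J441 = "49121",
    J45 = "49390", K703 = "5712", K7211 = "57220", N183 = "5853",
    C509 = "1749", C787 = "1970", B24 = "042", E785 = "2720",
    F329 = "311", J189 = "486", N390 = "5990", K219 = "53081",
    O80 = "650", M0590 = "7140", F0390 = "29010", N179 = "5849",
    D649 = "2859")
}

icd9_ccs_direct_map <- function() {
  c("4019" = "essential hypertension",
    "25000" = "diabetes mellitus without complication",
    "25040" = "diabetes mellitus with complications",
    "41001" = "acute myocardial infarction",
    "412" = "coronary atherosclerosis",
    "4280" = "congestive heart failure",
    "43491" = "acute cerebrovascular disease",
    "49121" = "copd and bronchiectasis",
    "49390" = "asthma",
    "5712" = "chronic liver disease",
    "57220" = "chronic liver disease",
    "5853" = "chronic kidney disease",
    "1749" = "cancer of breast",
    "1970" = "secondary malignancies",
    "042" = "hiv infection",
    "2720" = "disorders of lipid metabolism",
    "311" = "mood disorders",
    "486" = "pneumonia",
    "5990" = "urinary tract infections",
    "53081" = "esophageal disorders",
    "650" = "normal pregnancy and delivery",
    "7140" = "rheumatoid arthritis",
    "29010" = "dementia",
    "5849" = "acute renal failure",
    "2859" = "deficiency anemia",
    "78900" = "abdominal pain",
    "78703" = "nausea and vomiting",
    "42731" = "cardiac dysrhythmias",
    "34590" = "epilepsy",
    "6829" = "skin infections",
    "9980" = "complications of procedures",
    "7242" = "back problems",
    "5589" = "noninfectious gastroenteritis",
    "4660" = "acute bronchitis",
    "5740" = "gallstones",
    "30500" = "substance-related disorders",
    "82000" = "fracture of hip")
}

#' Build the fixture crosswalks with recorded conversion routes
#'
#' Constructs two small crosswalks (backward map into ICD-9-CM style codes
#' and a code-to-category map in the style of the AHRQ single-level CCS
#' file) together with route tables that record, per fixture code and by
#' construction, which conversion route (direct / zero addition / truncation
#' / unmapped) must rescue it. The route tables are written independently of
#' the conversion engine and serve as its oracle.
#'
#' @return A list: `icd10_icd9` and `icd9_ccs` ([crosswalk()] objects),
#'   `icd10_routes` and `ccs_routes` (tibbles `code`, `route`, `n_removed`,
#'   `target` / `category`, `ambiguous`).
#' @export
make_fixture_crosswalks <- function() {
  direct10 <- icd10_direct_map()
  z1_keys <- c(R1040 = "78900", R110 = "78703", I480 = "42731",
               G400 = "34590", L030 = "6829")
  z1_sources <- c(R1040 = "R104", R110 = "R11", I480 = "I48",
                  G400 = "G40", L030 = "L03")
  z2_keys <- c(T8100 = "9980", M5400 = "7242", K5200 = "5589", J2000 = "4660")
  z2_sources <- c(T8100 = "T81", M5400 = "M54", K5200 = "K52", J2000 = "J20")
  trunc_extra_keys <- c(E11 = "25000", I25 = "412", K80 = "5740", F10 = "30500")
  trunc_sources <- tibble::tibble(
    code = c("J459", "E1165", "I2510", "K8080", "F1010"),
    key = c("J45", "E11", "I25", "K80", "F10"),
    n_removed = c(1L, 2L, 2L, 2L, 2L)
  )
  ambiguous_key <- list(S7200 = c("82000", "82001"))
  unmapped10 <- c("Z991", "U071", "Q999", "Z888")

  entries10 <- c(
    as.list(direct10), as.list(z1_keys), as.list(z2_keys),
    as.list(trunc_extra_keys), ambiguous_key
  )
  xw10 <- crosswalk(entries10, "ICD-10-AM", "ICD-9-CM")

  icd10_routes <- dplyr::bind_rows(
    tibble::tibble(code = names(direct10), route = "direct",
                   n_removed = NA_integer_, target = unname(direct10),
                   ambiguous = FALSE),
    tibble::tibble(code = "S7200", route = "direct", n_removed = NA_integer_,
                   target = "82000", ambiguous = TRUE),
    tibble::tibble(code = unname(z1_sources), route = "zero_added_1",
                   n_removed = NA_integer_, target = unname(z1_keys),
                   ambiguous = FALSE),
    tibble::tibble(code = unname(z2_sources), route = "zero_added_2",
                   n_removed = NA_integer_, target = unname(z2_keys),
                   ambiguous = FALSE),
    tibble::tibble(code = trunc_sources$code, route = "truncated",
                   n_removed = trunc_sources$n_removed,
                   target = unname(c(direct10["J45"], trunc_extra_keys)[trunc_sources$key]),
                   ambiguous = FALSE),
    tibble::tibble(code = unmapped10, route = "unmapped",
                   n_removed = NA_integer_, target = NA_character_,
                   ambiguous = FALSE)
  )

  direct9 <- icd9_ccs_direct_map()
  z1_keys9 <- c("30510" = "substance-related disorders", "78620" = "chest pain")
  z1_sources9 <- c("30510" = "3051", "78620" = "7862")
  z2_keys9 <- c("78000" = "general symptoms", "71900" = "joint disorders")
  z2_sources9 <- c("78000" = "780", "71900" = "719")
  trunc_keys9 <- c("786" = "chest and respiratory symptoms")
  trunc_sources9 <- tibble::tibble(code = "78659", key = "786", n_removed = 2L)
  unmapped9 <- c("E9999", "E8889", "7999")

  xw9 <- crosswalk(
    c(as.list(direct9), as.list(z1_keys9), as.list(z2_keys9), as.list(trunc_keys9)),
    "ICD-9-CM", "CCS", normalize_targets = FALSE
  )
  ccs_routes <- dplyr::bind_rows(
    tibble::tibble(code = names(direct9), route = "direct",
                   n_removed = NA_integer_, category = unname(direct9),
                   ambiguous = FALSE),
    tibble::tibble(code = unname(z1_sources9), route = "zero_added_1",
                   n_removed = NA_integer_, category = unname(z1_keys9),
                   ambiguous = FALSE),
    tibble::tibble(code = unname(z2_sources9), route = "zero_added_2",
                   n_removed = NA_integer_, category = unname(z2_keys9),
                   ambiguous = FALSE),
    tibble::tibble(code = trunc_sources9$code, route = "truncated",
                   n_removed = trunc_sources9$n_removed,
                   category = unname(trunc_keys9[trunc_sources9$key]),
                   ambiguous = FALSE),
    tibble::tibble(code = unmapped9, route = "unmapped",
                   n_removed = NA_integer_, category = NA_character_,
                   ambiguous = FALSE)
  )

  list(icd10_icd9 = xw10, icd9_ccs = xw9,
       icd10_routes = icd10_routes, ccs_routes = ccs_routes)
}

# Charlson signal codes in both coding eras (ICD-9-CM code and the fixture
# ICD-10 code that backward-maps onto it).
charlson_code_pairs <- function() {
  tibble::tibble(
    icd9 = c("25000", "25040", "41001", "412", "4280", "43491", "49121",
             "49390", "5712", "57220", "5853", "1749", "1970", "042",
             "29010", "7140"),
    icd10 = c("E119", "E1122", "I214", "I252", "I500", "I639", "J441",
              "J45", "K703", "K7211", "N183", "C509", "C787", "B24",
              "F0390", "M0590")
  )
}

#' Synthetic-cohort generator configuration
#'
#' Defaults define the study conditions of the synthetic EMR: a 2005-2013
#' window with a 2010 coding cut-over, a 3-tier latent disease-complexity
#' structure that jointly drives comorbidity coding, drug dispensing and
#' visit rates (negative-binomial visit counts), a housing distribution over
#' six groups with subsidy propensity and subsidy depth decreasing with
#' housing size, a 10% unmappable fraction among new-era codes, and
#' ledger-recorded planted rule violators for every exclusion criterion.
#'
#' @param ... Named overrides of the default fields.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(...) {
  cfg <- list(
    n_patients = 5000,
    seed = 7L,
    window_start = "2005-01-01",
    window_end = "2013-12-31",
    cutover = "2010-01-01",
    study_end = "2013-12-31",
    base_year = 2015L,
    annual_inflation = 0.025,
    # latent complexity tiers: low / medium / high
    tier_probs = c(0.60, 0.30, 0.10),
    inpatient_mu = c(0.2, 0.8, 2.5),
    soc_mu = c(1.5, 4, 10),
    ed_mu = c(0.4, 0.9, 1.8),
    other_mu = c(1, 2, 4),
    visit_theta = 1.5,
    los_mean = 3,
    drug_mu = c(1, 3, 8),
    comorbidity_mu = c(0.2, 1.2, 3.5),
    secondary_dx_mu = 1.2,
    p_nonprescription_row = 0.15,
    p_device_row = 0.05,
    # housing: group probabilities and subsidy behaviour by group
    housing_probs = c("rental/studio/1-2-room" = 0.03, "3-room" = 0.17,
                      "4-room" = 0.26, "5-room/executive" = 0.22,
                      "private" = 0.12, "missing" = 0.20),
    subsidy_prob = c("rental/studio/1-2-room" = 0.85, "3-room" = 0.75,
                     "4-room" = 0.70, "5-room/executive" = 0.65,
                     "private" = 0.44, "missing" = 0.60),
    subsidy_rate = c("rental/studio/1-2-room" = 0.65, "3-room" = 0.55,
                     "4-room" = 0.50, "5-room/executive" = 0.45,
                     "private" = 0.30, "missing" = 0.50),
    charge_meanlog = c(inpatient = 8, SOC = 5.5, ED = 6, `other outpatient` = 5),
    charge_sdlog = 0.6,
    # code mix among new-era (converted) codes
    unmappable_frac = 0.10,
    modified_frac = 0.15,
    icd9_unmappable_frac = 0.03,
    # planted rule violators (ledger-recorded)
    n_minor_visits = 12,
    n_prewindow_inpatient = 8,
    n_postwindow_inpatient = 5,
    n_birth1900 = 7,
    n_male_pregnancy = 5,
    n_no_pd = 9
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) {
    emr_abort(sprintf("unknown config field(s): %s", paste(bad, collapse = ", ")),
              "emrforge_config_error")
  }
  cfg[names(over)] <- over
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  if (cfg$n_patients < 1) emr_abort("n_patients must be >= 1", "emrforge_config_error")
  if (abs(sum(cfg$tier_probs) - 1) > 1e-9 || any(cfg$tier_probs < 0)) {
    emr_abort("tier_probs must be a probability vector summing to 1", "emrforge_config_error")
  }
  if (abs(sum(cfg$housing_probs) - 1) > 1e-9 || any(cfg$housing_probs < 0)) {
    emr_abort("housing_probs must be a probability vector summing to 1", "emrforge_config_error")
  }
  probs <- c(cfg$subsidy_prob, cfg$subsidy_rate, cfg$unmappable_frac,
             cfg$modified_frac, cfg$icd9_unmappable_frac)
  if (any(probs < 0 | probs > 1)) {
    emr_abort("probabilities must lie in [0, 1]", "emrforge_config_error")
  }
  n_violator_patients <- cfg$n_minor_visits + cfg$n_birth1900 +
    cfg$n_male_pregnancy + cfg$n_no_pd
  if (n_violator_patients > cfg$n_patients / 2) {
    emr_abort("planted rule violators exceed half the cohort: inconsistent config",
              "emrforge_config_error")
  }
  structure(cfg, class = c("synth_config", "list"))
}

#' Year-to-multiplier inflation index
#'
#' Constant-rate index restating nominal amounts at base-year levels; the
#' base year's multiplier is 1 by convention.
#'
#' @param years Years to cover.
#' @param base_year Base year.
#' @param annual Annual inflation rate for health goods and services.
#' @return Tibble `year`, `multiplier`.
#' @export
make_inflation_index <- function(years = 2004:2015, base_year = 2015, annual = 0.025) {
  tibble::tibble(year = years, multiplier = (1 + annual)^(base_year - years))
}

housing_block_sets <- function() {
  list(
    "rental/studio/1-2-room" = c("100001", "100002", "100003"),
    "3-room" = c("100011", "100012"),
    "4-room" = c("100021", "100022"),
    "5-room/executive" = c("100031", "100032", "100033"),
    "private" = c("200001", "200002", "200003"),
    "missing" = c("999001", "999002")
  )
}

#' Build the fixture housing lookup
#'
#' Public blocks cover every housing group and include a mixed-flat-type
#' block and two exact-tie blocks (resolved toward the larger flat type);
#' the private postal list is disjoint; two postal codes are deliberately on
#' neither list so patients assigned to them resolve to `missing`.
#'
#' @param config A [synth_config()] (unused fields tolerated; present for
#'   interface symmetry).
#' @return A [housing_lookup()].
#' @export
make_housing_lookup <- function(config = synth_config()) {
  public <- tibble::tribble(
    ~postal, ~flat_type, ~proportion,
    "100001", "rental", 1.0,
    "100002", "studio", 0.5, "100002", "1-room", 0.3, "100002", "2-room", 0.2,
    "100003", "1-room", 0.5, "100003", "2-room", 0.5,          # tie -> 2-room
    "100011", "3-room", 1.0,
    "100012", "3-room", 0.6, "100012", "4-room", 0.4,
    "100021", "4-room", 1.0,
    "100022", "4-room", 0.7, "100022", "5-room", 0.3,
    "100031", "5-room", 1.0,
    "100032", "executive", 0.6, "100032", "5-room", 0.4,
    "100033", "4-room", 0.5, "100033", "5-room", 0.5           # tie -> 5-room
  )
  housing_lookup(public, housing_block_sets()$private)
}

rnb <- function(n, mu, theta) stats::rnbinom(n, size = theta, mu = mu)

random_dates <- function(n, from, to) {
  from <- as_date_strict(from); to <- as_date_strict(to)
  from + sample.int(as.integer(to - from) + 1L, n, replace = TRUE) - 1L
}

#' Generate the five record-level EMR tables with a ground-truth ledger
#'
#' Emulates a patient -> visit -> record EMR cascade: demographics,
#' movement, billing (with subsidy flags and amounts), pharmacy (with
#' non-prescription and device rows) and diagnosis records, with
#' mixed-era diagnosis coding decided by visit date against the cut-over
#' date. Disease complexity is a 3-tier latent variable driving comorbidity
#' codes, drug counts and visit rates jointly; subsidy propensity and depth
#' depend on the planted housing group. Rule violators for every exclusion
#' criterion are planted in ledger-recorded numbers. Deterministic given
#' `config$seed`.
#'
#' @param config A [synth_config()].
#' @return A list: `tables` (the five record tables), `ledger` (ground
#'   truth: per-patient plants, per-visit expectations with kept flags,
#'   expected exclusion counts, expected mapping statistics), `xwalks`
#'   (fixture crosswalks and route tables), `housing` (lookup), `index`
#'   (inflation index), `config`.
#' @export
generate_emr <- function(config = synth_config()) {
  config <- validate_synth_config(config)
  withr::local_seed(config$seed)

  xw <- make_fixture_crosswalks()
  lookup <- make_housing_lookup(config)
  index <- make_inflation_index(2004:2015, config$base_year, config$annual_inflation)
  blocks <- housing_block_sets()
  pairs <- charlson_code_pairs()
  cutover <- as_date_strict(config$cutover)

  n <- config$n_patients
  n_minor <- config$n_minor_visits
  n_b1900 <- config$n_birth1900
  n_preg <- config$n_male_pregnancy
  n_nopd <- config$n_no_pd

  # --- patients ---------------------------------------------------------
  patient_id <- sprintf("P%06d", seq_len(n))
  role <- rep("regular", n)
  i <- 1
  idx_minor <- seq.int(i, length.out = n_minor); i <- i + n_minor
  idx_b1900 <- seq.int(i, length.out = n_b1900); i <- i + n_b1900
  idx_preg <- seq.int(i, length.out = n_preg); i <- i + n_preg
  idx_nopd <- seq.int(i, length.out = n_nopd)
  role[idx_minor] <- "minor_visit"
  role[idx_b1900] <- "birth_1900"
  role[idx_preg] <- "male_pregnancy"
  role[idx_nopd] <- "no_primary_dx"

  tier <- sample.int(3, n, replace = TRUE, prob = config$tier_probs)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  sex[idx_preg] <- "male"
  race <- sample(c("Chinese", "Indian", "Malay", "Others"), n, replace = TRUE,
                 prob = c(0.60, 0.13, 0.12, 0.15))
  singaporean <- stats::runif(n) < 0.65
  # regular patients are at least 21 throughout the window by construction;
  # the only under-21 visits are the planted ones
  birth_date <- random_dates(n, "1925-01-01", "1983-12-31")
  birth_date[idx_minor] <- as.Date("1990-06-15")
  birth_date[idx_b1900] <- as.Date("1900-01-01")
  housing_group <- sample(names(config$housing_probs), n, replace = TRUE,
                          prob = config$housing_probs)
  postal_code <- vapply(housing_group, function(g) sample(blocks[[g]], 1), character(1))

  demographic <- tibble::tibble(
    patient_id = patient_id, sex = sex, race = race,
    singaporean = singaporean, birth_date = birth_date,
    postal_code = postal_code
  )

  # --- visits -----------------------------------------------------------
  classes <- c("inpatient", "SOC", "ED", "other outpatient")
  counts <- cbind(
    rnb(n, config$inpatient_mu[tier], config$visit_theta),
    rnb(n, config$soc_mu[tier], config$visit_theta),
    rnb(n, config$ed_mu[tier], config$visit_theta),
    rnb(n, config$other_mu[tier], config$visit_theta)
  )
  # every violator patient needs at least one regular (kept) visit
  force_visit <- which(role != "regular" & rowSums(counts) == 0)
  counts[force_visit, 2] <- 1L

  vis_patient <- rep(rep(patient_id, 4), times = as.vector(counts))
  vis_class <- rep(rep(classes, each = n), times = as.vector(counts))
  n_vis <- length(vis_patient)

  vis_date <- random_dates(n_vis, config$window_start, config$window_end)
  # minor-visit patients: regular visits late in the window (aged >= 21)
  is_minor_pat <- vis_patient %in% patient_id[idx_minor]
  vis_date[is_minor_pat] <- random_dates(sum(is_minor_pat), "2012-01-01", config$window_end)
  los <- ifelse(vis_class == "inpatient", stats::rpois(n_vis, config$los_mean), 0L)
  # keep inpatient episodes inside the window
  max_adm <- as_date_strict(config$window_end) - los
  shift <- as.numeric(vis_date - max_adm)
  vis_date <- vis_date - pmax(0, shift)
  discharge <- vis_date + los
  planted_excl <- rep(NA_character_, n_vis)

  # planted under-21 visits (one per minor patient, SOC, pre-2010)
  minor_extra <- tibble::tibble(
    patient_id = patient_id[idx_minor],
    visit_class = "SOC",
    admission_date = as.Date("2008-06-01"),
    los = 0L,
    planted_excl = "age_below_minimum"
  )
  # pre-/post-window inpatient stays attached to regular adult hosts
  hosts <- patient_id[role == "regular"][seq_len(config$n_prewindow_inpatient +
                                                   config$n_postwindow_inpatient)]
  pre_extra <- tibble::tibble(
    patient_id = hosts[seq_len(config$n_prewindow_inpatient)],
    visit_class = "inpatient",
    admission_date = as.Date("2004-12-15"),
    los = 20L,
    planted_excl = "inpatient_outside_window"
  )
  post_extra <- tibble::tibble(
    patient_id = hosts[config$n_prewindow_inpatient + seq_len(config$n_postwindow_inpatient)],
    visit_class = "inpatient",
    admission_date = as.Date("2013-12-20"),
    los = 20L,
    planted_excl = "inpatient_outside_window"
  )
  extra <- dplyr::bind_rows(minor_extra, pre_extra, post_extra)

  visits <- tibble::tibble(
    patient_id = c(vis_patient, extra$patient_id),
    visit_class = c(vis_class, extra$visit_class),
    admission_date = c(vis_date, extra$admission_date),
    discharge_date = c(discharge, extra$admission_date + extra$los),
    planted_excl = c(planted_excl, extra$planted_excl)
  )
  visits <- visits[order(visits$patient_id, visits$admission_date), ]
  visits$visit_id <- sprintf("V%08d", seq_len(nrow(visits)))
  visits$kept <- is.na(visits$planted_excl)
  visits$year <- as.integer(format(visits$admission_date, "%Y"))
  visits$icd10_era <- visits$admission_date >= cutover

  pat_group <- setNames(housing_group, patient_id)
  pat_tier <- setNames(tier, patient_id)
  vgroup <- pat_group[visits$patient_id]
  vtier <- pat_tier[visits$patient_id]

  movement <- tibble::tibble(
    patient_id = visits$patient_id, visit_id = visits$visit_id,
    visit_class = visits$visit_class,
    admission_date = visits$admission_date,
    discharge_date = visits$discharge_date
  )

  # --- billing ----------------------------------------------------------
  nv <- nrow(visits)
  charge <- round(unname(stats::rlnorm(nv, config$charge_meanlog[visits$visit_class],
                                       config$charge_sdlog)), 2)
  sub_flag <- unname(stats::runif(nv) < config$subsidy_prob[vgroup])
  sub_depth <- pmin(1, unname(config$subsidy_rate[vgroup]) * stats::runif(nv, 0.85, 1.15))
  sub_amount <- round(ifelse(sub_flag, charge * sub_depth, 0), 2)

  n_bills <- sample.int(3, nv, replace = TRUE)
  bill_visit <- rep(seq_len(nv), n_bills)
  share <- stats::runif(length(bill_visit))
  share <- share / rep(tapply(share, bill_visit, sum), n_bills)
  billing <- tibble::tibble(
    patient_id = visits$patient_id[bill_visit],
    visit_id = visits$visit_id[bill_visit],
    charge = charge[bill_visit] * share,
    subsidy_amount = sub_amount[bill_visit] * share,
    subsidy_flag = sub_flag[bill_visit],
    year = visits$year[bill_visit]
  )

  # --- pharmacy ---------------------------------------------------------
  n_rx <- stats::rpois(nv, unname(config$drug_mu[vtier]))
  rx_visit <- rep(seq_len(nv), n_rx)
  rx <- tibble::tibble(
    patient_id = visits$patient_id[rx_visit],
    visit_id = visits$visit_id[rx_visit],
    drug_code = sprintf("DRUG%03d", sample.int(400, length(rx_visit), replace = TRUE)),
    is_prescription = TRUE,
    is_device = FALSE
  )
  # drugs dispensed in a visit are unique by construction of the score, so
  # deduplicate planted collisions and add repeat-dispensing rows explicitly
  rx <- dplyr::distinct(rx)
  dup <- rx[stats::runif(nrow(rx)) < 0.10, , drop = FALSE]
  n_extra <- stats::rbinom(nv, 1, config$p_nonprescription_row) +
    stats::rbinom(nv, 1, config$p_device_row)
  ex_visit <- rep(seq_len(nv), n_extra)
  extras <- tibble::tibble(
    patient_id = visits$patient_id[ex_visit],
    visit_id = visits$visit_id[ex_visit],
    drug_code = sprintf("OTC%03d", sample.int(50, length(ex_visit), replace = TRUE)),
    is_prescription = FALSE,
    is_device = stats::runif(length(ex_visit)) < 0.4
  )
  pharmacy <- dplyr::bind_rows(rx, dup, extras)
  pps_truth <- tibble::tibble(visit_id = visits$visit_id) |>
    dplyr::left_join(
      rx |> dplyr::group_by(.data$visit_id) |>
        dplyr::summarise(pps = dplyr::n_distinct(.data$drug_code), .groups = "drop"),
      by = "visit_id"
    )
  pps_truth$pps[is.na(pps_truth$pps)] <- 0L

  # --- diagnoses --------------------------------------------------------
  routes10 <- xw$icd10_routes
  routes9 <- xw$ccs_routes
  pool9 <- c("4019", "2720", "311", "486", "5990", "53081", "5849", "2859",
             "42731", "78900", "7242", "3051", "7862", "780", "719", "78659")
  pool9_un <- c("E9999", "7999")
  pool10_direct <- setdiff(routes10$code[routes10$route == "direct"], "O80")
  pool10_mod <- routes10$code[routes10$route %in%
                                c("zero_added_1", "zero_added_2", "truncated")]
  pool10_un <- routes10$code[routes10$route == "unmapped"]

  draw_codes <- function(k, era10) {
    if (k == 0) return(character(0))
    if (era10) {
      u <- stats::runif(k)
      out <- character(k)
      un <- u < config$unmappable_frac
      mod <- !un & u < config$unmappable_frac + config$modified_frac
      out[un] <- sample(pool10_un, sum(un), replace = TRUE)
      out[mod] <- sample(pool10_mod, sum(mod), replace = TRUE)
      out[!un & !mod] <- sample(pool10_direct, sum(!un & !mod), replace = TRUE)
      out
    } else {
      u <- stats::runif(k)
      out <- character(k)
      un <- u < config$icd9_unmappable_frac
      out[un] <- sample(pool9_un, sum(un), replace = TRUE)
      out[!un] <- sample(pool9, sum(!un), replace = TRUE)
      out
    }
  }

  n_sd <- stats::rpois(nv, config$secondary_dx_mu)
  # comorbidity (Charlson) codes: per patient, spread over that patient's visits
  n_com_pat <- stats::rpois(n, config$comorbidity_mu[tier])
  vis_by_pat <- split(seq_len(nv), visits$patient_id)

  dx_rows <- vector("list", 3)
  # one primary per visit (secondary-only for planted no-PD patients)
  nopd_ids <- patient_id[idx_nopd]
  primary_code <- vapply(seq_len(nv), function(i) {
    draw_codes(1, visits$icd10_era[i])
  }, character(1))
  dx_rows[[1]] <- tibble::tibble(
    patient_id = visits$patient_id, visit_id = visits$visit_id,
    code = primary_code,
    role = ifelse(visits$patient_id %in% nopd_ids, "secondary", "primary"),
    nosology = ifelse(visits$icd10_era, "ICD-10-AM", "ICD-9-CM"),
    date = visits$admission_date
  )
  sd_visit <- rep(seq_len(nv), n_sd)
  sd_codes <- unlist(lapply(seq_len(nv), function(i) draw_codes(n_sd[i], visits$icd10_era[i])),
                     use.names = FALSE)
  dx_rows[[2]] <- tibble::tibble(
    patient_id = visits$patient_id[sd_visit], visit_id = visits$visit_id[sd_visit],
    code = sd_codes, role = "secondary",
    nosology = ifelse(visits$icd10_era[sd_visit], "ICD-10-AM", "ICD-9-CM"),
    date = visits$admission_date[sd_visit]
  )
  com_list <- lapply(seq_len(n), function(p) {
    k <- n_com_pat[p]
    vi <- vis_by_pat[[patient_id[p]]]
    if (k == 0 || length(vi) == 0) return(NULL)
    at <- sample(vi, k, replace = TRUE)
    pair_idx <- sample.int(nrow(pairs), k, replace = TRUE)
    tibble::tibble(
      patient_id = patient_id[p],
      visit_id = visits$visit_id[at],
      code = ifelse(visits$icd10_era[at], pairs$icd10[pair_idx], pairs$icd9[pair_idx]),
      role = "secondary",
      nosology = ifelse(visits$icd10_era[at], "ICD-10-AM", "ICD-9-CM"),
      date = visits$admission_date[at]
    )
  })
  dx_rows[[3]] <- dplyr::bind_rows(com_list)

  diagnosis <- dplyr::bind_rows(dx_rows)
  # planted sex-implausible diagnoses: a delivery code on one visit of each
  # male violator (coded in the old nosology regardless of visit date)
  preg_visits <- vapply(patient_id[idx_preg],
                        function(p) visits$visit_id[vis_by_pat[[p]][1]], character(1))
  diagnosis <- dplyr::bind_rows(diagnosis, tibble::tibble(
    patient_id = patient_id[idx_preg], visit_id = preg_visits,
    code = "650", role = "secondary", nosology = "ICD-9-CM",
    date = visits$admission_date[match(preg_visits, visits$visit_id)]
  ))
  diagnosis <- diagnosis[order(diagnosis$visit_id, diagnosis$role), ]

  # --- ledger -----------------------------------------------------------
  kept_ids <- visits$visit_id[visits$kept]
  dx_kept <- diagnosis[diagnosis$visit_id %in% kept_ids, , drop = FALSE]
  dx10 <- dx_kept[dx_kept$nosology == "ICD-10-AM", , drop = FALSE]
  r10 <- routes10$route[match(dx10$code, routes10$code)]
  t10 <- routes10$target[match(dx10$code, routes10$code)]
  stopifnot(!anyNA(r10))
  expected_std <- mapping_stats(tibble::tibble(
    source = dx10$code,
    method = ifelse(r10 == "zero_added_1", "zero_added_1",
                    ifelse(r10 == "zero_added_2", "zero_added_2", r10)),
    ambiguous = routes10$ambiguous[match(dx10$code, routes10$code)],
    role = dx10$role
  ))
  std_codes <- c(dx_kept$code[dx_kept$nosology == "ICD-9-CM"],
                 t10[!is.na(t10)])
  std_roles <- c(dx_kept$role[dx_kept$nosology == "ICD-9-CM"],
                 dx10$role[!is.na(t10)])
  r9 <- routes9$route[match(std_codes, routes9$code)]
  stopifnot(!anyNA(r9))
  expected_ccs <- mapping_stats(tibble::tibble(
    source = std_codes, method = r9,
    ambiguous = routes9$ambiguous[match(std_codes, routes9$code)],
    role = std_roles
  ))

  # patients that reach the patient-level table (>= 1 kept visit) but have no
  # standardization-mappable primary diagnosis fall to the no-PD rule; the
  # planted secondary-only patients are a subset of these by construction
  pat_with_visit <- unique(visits$patient_id[visits$kept])
  pd_rows <- dx_kept[dx_kept$role == "primary", , drop = FALSE]
  pd_mappable <- pd_rows$nosology == "ICD-9-CM" |
    routes10$route[match(pd_rows$code, routes10$code)] != "unmapped"
  n_no_pd_expected <- length(setdiff(pat_with_visit,
                                     unique(pd_rows$patient_id[pd_mappable])))

  visit_truth <- tibble::tibble(
    visit_id = visits$visit_id, patient_id = visits$patient_id,
    visit_class = visits$visit_class, kept = visits$kept,
    planted_excl = visits$planted_excl, year = visits$year,
    charge = charge, subsidy_amount = sub_amount,
    adjusted_charge = adjust_inflation(charge, visits$year, index),
    subsidy_flag = sub_flag,
    length_of_stay = as.numeric(visits$discharge_date - visits$admission_date) *
      (visits$visit_class == "inpatient"),
    pps = pps_truth$pps
  )
  patient_truth <- tibble::tibble(
    patient_id = patient_id, tier = tier, housing_group = housing_group,
    role = role, birth_date = birth_date, sex = sex
  )
  pat_agg <- visit_truth[visit_truth$kept, ] |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_visits = dplyr::n(),
      n_inpatient = sum(.data$visit_class == "inpatient"),
      n_soc = sum(.data$visit_class == "SOC"),
      n_ed = sum(.data$visit_class == "ED"),
      total_charge = sum(.data$charge),
      total_adjusted_charge = sum(.data$adjusted_charge),
      total_subsidy = sum(.data$subsidy_amount),
      total_los = sum(.data$length_of_stay),
      pps = max(.data$pps),
      .groups = "drop"
    )

  ledger <- list(
    patients = patient_truth,
    visits = visit_truth,
    patient_aggregates = pat_agg,
    expected_std_stats = expected_std,
    expected_ccs_stats = expected_ccs,
    expected_exclusions = list(
      visit = c(data_quality_unresolvable = 0L,
                inpatient_outside_window = config$n_prewindow_inpatient +
                  config$n_postwindow_inpatient,
                age_below_minimum = config$n_minor_visits),
      patient = c(no_primary_diagnosis = n_no_pd_expected,
                  birth_year_1900_or_earlier = n_b1900,
                  invalid_sex_specific_diagnosis = n_preg,
                  data_quality_missing_sex = 0L)
    ),
    n_dx_total = nrow(diagnosis),
    n_dx_kept = nrow(dx_kept)
  )

  list(
    tables = list(demographic = demographic, movement = movement,
                  billing = billing, pharmacy = pharmacy, diagnosis = diagnosis),
    ledger = ledger,
    xwalks = xw,
    housing = lookup,
    index = index,
    config = config
  )
}

#' Parameter-recovery simulators for the validation harness
#'
#' `simulate_count_exposure()` draws a count outcome from a log-linked
#' negative binomial model with a known multiplicative exposure effect;
#' `simulate_subsidy_exposure()` draws subsidy status from a multinomial
#' logit with known odds ratios per housing group (vs private) and RSR from
#' a linear model with known group offsets. Both are used to check that the
#' regression routines recover planted effects.
#'
#' @param n Sample size.
#' @param effect True multiplicative effect per unit exposure.
#' @param intercept Intercept on the log scale.
#' @param theta Negative binomial dispersion.
#' @return `simulate_count_exposure()`: tibble `y`, `x`;
#'   `simulate_subsidy_exposure()`: tibble `status`, `rsr`,
#'   `housing_group`.
#' @export
simulate_count_exposure <- function(n, effect = 1.5, intercept = 0, theta = 1.2) {
  x <- stats::rnorm(n)
  mu <- exp(intercept + log(effect) * x)
  tibble::tibble(y = stats::rnbinom(n, size = theta, mu = mu), x = x)
}

#' @rdname simulate_count_exposure
#' @param or_subsidized,or_mixed Named vectors of true odds ratios
#'   (vs the private group) for the subsidized-vs-nonsubsidized and
#'   mixed-vs-nonsubsidized contrasts.
#' @param rsr_beta Named vector of true RSR offsets (percentage points vs
#'   private).
#' @param rsr_intercept Mean RSR in the private group.
#' @param rsr_sd Residual standard deviation of RSR.
#' @export
simulate_subsidy_exposure <- function(n,
                                      or_subsidized = c("rental/studio/1-2-room" = 14,
                                                        "3-room" = 5, "4-room" = 4,
                                                        "5-room/executive" = 3),
                                      or_mixed = c("rental/studio/1-2-room" = 3.3,
                                                   "3-room" = 2, "4-room" = 1.8,
                                                   "5-room/executive" = 1.65),
                                      rsr_beta = c("rental/studio/1-2-room" = 19,
                                                   "3-room" = 14.4, "4-room" = 12.7,
                                                   "5-room/executive" = 9.8),
                                      rsr_intercept = 33.9, rsr_sd = 12) {
  groups <- setdiff(housing_group_levels(), "missing")
  hg <- sample(groups, n, replace = TRUE,
               prob = c(0.05, 0.21, 0.32, 0.27, 0.15))
  b_sub <- c(log(or_subsidized), private = 0)[hg] + log(2)
  b_mix <- c(log(or_mixed), private = 0)[hg] + log(1.2)
  denom <- 1 + exp(b_sub) + exp(b_mix)
  u <- stats::runif(n)
  p_non <- 1 / denom
  p_sub <- exp(b_sub) / denom
  status <- ifelse(u < p_non, "nonsubsidized",
                   ifelse(u < p_non + p_sub, "subsidized", "mixed"))
  rsr_mu <- rsr_intercept + c(rsr_beta, private = 0)[hg]
  rsr <- pmin(100, pmax(0, stats::rnorm(n, rsr_mu, rsr_sd)))
  tibble::tibble(status = status, rsr = rsr, housing_group = hg)
}
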