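# Shared fixtures and independent oracles for the suite. Everything is built
# in code; nothing is read from disk except the package's own extdata.

toy_xwalk <- function() {
  crosswalk(
    list(A09 = "0091", C610 = "185", K35 = "540", E01 = c("111", "222")),
    "ICD-10-AM", "ICD-9-CM"
  )
}

# Brute-force conversion oracle: enumerate the full candidate set
# {code, code+"0", code+"00", all prefixes of length >= 3} with an explicit
# priority, then take the best-priority candidate present in the key set.
# Written against the rule statement, independently of convert_codes().
oracle_convert <- function(code, keys, prefer = "zero_first") {
  code <- toupper(gsub(".", "", trimws(code), fixed = TRUE))
  cands <- data.frame(cand = code, kind = "direct", rank = 0,
                      stringsAsFactors = FALSE)
  zeros <- data.frame(cand = c(paste0(code, "0"), paste0(code, "00")),
                      kind = c("zero_added_1", "zero_added_2"), rank = 1:2)
  truncs <- NULL
  if (nchar(code) > 3) {
    lens <- (nchar(code) - 1):3
    truncs <- data.frame(cand = substring(code, 1, lens), kind = "truncated",
                         rank = seq_along(lens))
  }
  if (prefer == "zero_first") {
    if (!is.null(truncs)) truncs$rank <- truncs$rank + 10
    cands <- rbind(cands, zeros, truncs)
  } else {
    zeros$rank <- zeros$rank + 10
    cands <- rbind(cands, truncs, zeros)
  }
  hits <- cands[cands$cand %in% keys, , drop = FALSE]
  if (nrow(hits) == 0) {
    return(list(method = "unmapped", key = NA_character_))
  }
  best <- hits[order(hits$rank), ][1, ]
  list(method = best$kind, key = best$cand)
}

# Independent Charlson scorer working straight off the map file with regex
# matching and explicit hierarchy if-statements.
oracle_cci <- function(codes) {
  path <- system.file("extdata", "charlson_deyo.csv", package = "emrforge")
  map <- read.csv(path, stringsAsFactors = FALSE)
  hit <- setNames(logical(nrow(map)), map$category)
  for (i in seq_len(nrow(map))) {
    for (p in strsplit(map$prefixes[i], ";")[[1]]) {
      if (any(grepl(paste0("^", p), codes))) hit[i] <- TRUE
    }
  }
  if (hit[["diabetes_with_complications"]]) hit[["diabetes"]] <- FALSE
  if (hit[["moderate_severe_liver_disease"]]) hit[["mild_liver_disease"]] <- FALSE
  if (hit[["metastatic_solid_tumour"]]) hit[["malignancy"]] <- FALSE
  sum(map$weight[hit])
}

# A minimal five-table cascade: 2 patients, 3 visits, hand-checkable totals.
tiny_tables <- function() {
  list(
    demographic = tibble::tibble(
      patient_id = c("P1", "P2"),
      sex = c("male", "female"),
      race = c("Chinese", "Malay"),
      singaporean = c(TRUE, FALSE),
      birth_date = as.Date(c("1960-04-10", "1975-11-02")),
      postal_code = c("100011", "200001")
    ),
    movement = tibble::tibble(
      patient_id = c("P1", "P1", "P2"),
      visit_id = c("VA", "VB", "VC"),
      visit_class = c("inpatient", "SOC", "ED"),
      admission_date = as.Date(c("2006-03-01", "2007-05-20", "2010-08-15")),
      discharge_date = as.Date(c("2006-03-06", "2007-05-20", "2010-08-15"))
    ),
    billing = tibble::tibble(
      patient_id = c("P1", "P1", "P1", "P1", "P2"),
      visit_id = c("VA", "VA", "VA", "VB", "VC"),
      charge = c(100, 200, 50, 80, 40),
      subsidy_amount = c(50, 100, 25, 0, 20),
      subsidy_flag = c(TRUE, TRUE, TRUE, FALSE, TRUE),
      year = c(2006, 2006, 2006, 2007, 2010)
    ),
    pharmacy = tibble::tibble(
      patient_id = c("P1", "P1", "P1", "P2", "P2"),
      visit_id = c("VA", "VA", "VA", "VC", "VC"),
      drug_code = c("D1", "D1", "D2", "D3", "X1"),
      is_prescription = c(TRUE, TRUE, TRUE, FALSE, TRUE),
      is_device = c(FALSE, FALSE, FALSE, FALSE, TRUE)
    ),
    diagnosis = tibble::tibble(
      patient_id = c("P1", "P1", "P2"),
      visit_id = c("VA", "VB", "VC"),
      code = c("4019", "25000", "E119"),
      role = c("primary", "primary", "primary"),
      nosology = c("ICD-9-CM", "ICD-9-CM", "ICD-10-AM"),
      date = as.Date(c("2006-03-01", "2007-05-20", "2010-08-15"))
    )
  )
}

identity_index <- function() tibble::tibble(year = 2004:2015, multiplier = 1)
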