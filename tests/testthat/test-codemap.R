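test_that("code normalization strips periods and whitespace, folds case, is idempotent", {
  expect_identical(normalize_code("e11.9"), "E119")
  expect_identical(normalize_code("410.00"), "41000")
  expect_identical(normalize_code("A09"), "A09")
  expect_identical(normalize_code(" a09 "), "A09")
  expect_identical(normalize_code(normalize_code("e11.9")), "E119")
  expect_error(normalize_code("  "), class = "emrforge_invalid_code")
  expect_error(normalize_code("."), class = "emrforge_invalid_code")
})

test_that("conversion walks the fallback ladder in order and records the method", {
  xw <- toy_xwalk()
  direct <- convert_code("A09", xw)
  expect_identical(direct$target, "0091")
  expect_identical(direct$method, "direct")

  z1 <- convert_code("C61", xw)
  expect_identical(z1$target, "185")
  expect_identical(z1$method, "zero_added_1")

  tr <- convert_code("K3580", xw)
  expect_identical(tr$target, "540")
  expect_identical(tr$method, "truncated")
  expect_identical(tr$n_removed, 2L)

  un <- convert_code("Z999", xw)
  expect_true(is.na(un$target))
  expect_identical(un$method, "unmapped")

  amb <- convert_code("E01", xw)
  expect_identical(amb$target, "111") # first stored target wins
  expect_true(amb$ambiguous)
  expect_false(direct$ambiguous)

  expect_error(convert_code(" ", xw), class = "emrforge_invalid_code")
})

test_that("truncation never matches a key shorter than 3 characters", {
  xw <- crosswalk(list(AB = "1", ABC = "2"))
  res <- convert_code("ABCDE", xw)
  expect_identical(res$method, "truncated")
  expect_identical(res$target, "2")   # stops at ABC, never reaches AB
  res2 <- convert_code("ABX", xw)     # 3 chars: no truncation candidates
  expect_identical(res2$method, "unmapped")
})

test_that("conversion agrees with the brute-force candidate-enumeration oracle", {
  fix <- make_fixture_crosswalks()
  for (prefer in c("zero_first", "truncate_first")) {
    for (xw in list(fix$icd10_icd9, fix$icd9_ccs)) {
      keys <- names(xw$entries)
      probes <- unique(c(
        keys, paste0(keys, "9"), paste0(keys, "00"), substr(keys, 1, 3),
        "QQQ1", "ZZ", "A000001"
      ))
      got <- convert_codes(probes, xw, prefer = prefer)
      for (i in seq_along(probes)) {
        oracle <- oracle_convert(probes[i], keys, prefer)
        expect_identical(got$method[i], oracle$method,
                         info = sprintf("%s (%s)", probes[i], prefer))
        if (oracle$method != "unmapped") {
          expect_identical(got$target[i], xw$entries[[oracle$key]][1])
        }
      }
    }
  }
})

test_that("conversion is deterministic: identical inputs give identical streams", {
  fix <- make_fixture_crosswalks()
  codes <- rep(fix$icd10_routes$code, 3)
  expect_identical(convert_codes(codes, fix$icd10_icd9),
                   convert_codes(codes, fix$icd10_icd9))
})

test_that("mapping statistics conserve counts by method on instances and unique codes", {
  fix <- make_fixture_crosswalks()
  set.seed(42)
  codes <- sample(fix$icd10_routes$code, 500, replace = TRUE)
  conv <- convert_codes(codes, fix$icd10_icd9)
  conv$role <- sample(c("primary", "secondary"), 500, replace = TRUE)
  st <- mapping_stats(conv)
  for (r in seq_len(nrow(st))) {
    expect_identical(st$direct[r] + st$zero_added[r] + st$truncated[r] + st$unmapped[r],
                     st$total[r])
    expect_identical(st$unique_direct[r] + st$unique_zero_added[r] +
                       st$unique_truncated[r] + st$unique_unmapped[r],
                     st$unique_total[r])
  }
  expect_identical(st$total[st$role == "combined"],
                   sum(st$total[st$role != "combined"]))
  pcts <- unlist(st[grepl("^pct_|mapping_rate", names(st))])
  expect_true(all(pcts >= 0 & pcts <= 100, na.rm = TRUE))
})

test_that("standardization passes through native codes and tallies only conversions", {
  xw <- toy_xwalk()
  dx <- tibble::tibble(
    code = c("401.9", "25000", "5849", "2859",              # native, era ICD-9
             "A09", "C61", "K3580", "E01", "A09", "Z999"),  # ICD-10 era
    role = c("primary", "secondary", "secondary", "primary",
             "primary", "secondary", "secondary", "primary", "primary", "secondary"),
    nosology = rep(c("ICD-9-CM", "ICD-10-AM"), c(4, 6))
  )
  out <- standardize_diagnoses(dx, xw)
  expect_identical(sum(!out$diagnoses$excluded), 9L)
  comb <- out$stats[out$stats$role == "combined", ]
  expect_identical(comb$total, 6L)
  expect_identical(comb$direct, 3L)  # A09 twice + ambiguous E01
  expect_identical(comb$unmapped, 1L)
  # pass-through codes are normalized but never modified
  expect_identical(out$diagnoses$std_code[1], "4019")
  expect_identical(out$diagnoses$map_method[1], "passthrough")
  # unmapped record flagged excluded but retained
  expect_true(out$diagnoses$excluded[out$diagnoses$code == "Z999"])

  empty <- standardize_diagnoses(dx[0, ], xw)
  expect_identical(nrow(empty$diagnoses), 0L)
  expect_true(all(empty$stats$total == 0L))

  expect_error(standardize_diagnoses(dx[, "code"], xw), class = "emrforge_schema_error")
})

test_that("era rule prefers the nosology column and falls back to the cut-over date", {
  xw <- toy_xwalk()
  dx <- tibble::tibble(
    code = c("A09", "4019"), role = c("primary", "primary"),
    date = as.Date(c("2012-06-01", "2006-06-01"))
  )
  out <- standardize_diagnoses(dx, xw, cutover = "2010-01-01")
  expect_identical(out$diagnoses$map_method, c("direct", "passthrough"))
  expect_error(standardize_diagnoses(dx[, c("code", "role")], xw),
               class = "emrforge_config_error")
})

test_that("phenotyping applies the same fallback engine and assigns one category per code", {
  fix <- make_fixture_crosswalks()
  codes <- tibble::tibble(
    std_code = c("4019", "3051", "780", "78659", "E9999"),
    role = rep("primary", 5)
  )
  out <- phenotype_codes(codes, fix$icd9_ccs)
  expect_identical(out$codes$phen_method,
                   c("direct", "zero_added_1", "zero_added_2", "truncated", "unmapped"))
  expect_identical(out$codes$category[1], "essential hypertension")
  expect_true(out$codes$excluded[5])
  # mutual exclusivity: one category per code, always
  expect_identical(unname(vapply(out$codes$category[!out$codes$excluded],
                                 length, integer(1))),
                   rep(1L, 4))
})

test_that("mapping rate reproduces the printed arithmetic and rejects bad inputs", {
  expect_equal(round(mapping_rate(810459, 930248), 1), 87.1)
  expect_equal(round(mapping_rate(4598488, 4722916), 1), 97.4)
  expect_equal(mapping_rate(0, 5), 0)
  expect_error(mapping_rate(1, 0), class = "emrforge_rate_error")
  expect_error(mapping_rate(6, 5), class = "emrforge_rate_error")
})

test_that("validity summaries reproduce the physician-rating arithmetic", {
  r1 <- tibble::tibble(code = sprintf("C%03d", 1:151),
                       rating = rep(c("valid", "invalid"), c(137, 14)))
  s1 <- validity_summary(r1, n_modified_unique = 653)
  expect_equal(round(s1$validity_rate, 1), 90.7)
  expect_equal(round(s1$sampling_fraction, 1), 23.1)

  r2 <- tibble::tibble(code = sprintf("D%03d", 1:361),
                       rating = rep(c("valid", "invalid"), c(332, 29)))
  s2 <- validity_summary(r2, n_modified_unique = 1747)
  expect_equal(round(s2$validity_rate, 1), 92.0)
  expect_equal(round(s2$sampling_fraction, 1), 20.7)
  expect_identical(s2$n_valid + s2$n_invalid, s2$n_sampled)

  all_valid <- tibble::tibble(code = c("A", "B"), rating = "valid")
  expect_equal(validity_summary(all_valid, 10)$validity_rate, 100)
  expect_error(validity_summary(r1[0, ], 653), class = "emrforge_rate_error")
})

test_that("crosswalk round-trips through its delimited-text format", {
  xw <- toy_xwalk()
  path <- withr::local_tempfile(fileext = ".csv")
  write_crosswalk(xw, path)
  back <- read_crosswalk(path, "ICD-10-AM", "ICD-9-CM")
  expect_identical(back$entries, xw$entries)
  expect_error(crosswalk(list(A1 = character(0))), class = "emrforge_crosswalk_error")
})
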