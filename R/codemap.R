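#' Normalize a diagnosis code
#'
#' Diagnosis codes arrive in mixed dialects ("E11.9", "e119 ", "410.00").
#' All comparison inside the package happens on a single dot-free, upper-case
#' dialect; crosswalk files are stored in the same dialect.
#'
#' @param raw A single code string.
#' @return The normalized code: upper case, periods and surrounding
#'   whitespace removed. Idempotent.
#' @examples
#' normalize_code("e11.9")   # "E119"
#' normalize_code("410.00")  # "41000"
#' @export
normalize_code <- function(raw) {
  if (length(raw) != 1 || is.na(raw)) {
    emr_abort("`raw` must be a single non-missing code string", "emrforge_invalid_code")
  }
  out <- toupper(gsub(".", "", trimws(as.character(raw)), fixed = TRUE))
  if (!nzchar(out)) {
    emr_abort("code is empty after normalization", "emrforge_invalid_code")
  }
  out
}

# Vectorized normalization used on whole diagnosis tables.
normalize_codes <- function(raw) {
  if (length(raw) == 0) return(character(0))
  out <- toupper(gsub(".", "", trimws(as.character(raw)), fixed = TRUE))
  bad <- is.na(out) | !nzchar(out)
  if (any(bad)) {
    emr_abort(
      sprintf("%d code(s) are empty or missing after normalization", sum(bad)),
      "emrforge_invalid_code"
    )
  }
  out
}

#' Convert a diagnosis code through a crosswalk with fallback modification
#'
#' Attempts, in order: (1) direct lookup of the normalized code; (2) zero
#' addition — one then two trailing `"0"` characters; (3) truncation — one
#' trailing character removed at a time, re-testing the crosswalk at each
#' length, down to a minimum of 3 characters. The first hit wins and the
#' modification method is recorded. A code that survives every step without a
#' hit is `unmapped`. When the matched key carries several targets the first
#' target in stored order is returned and the conversion is flagged
#' ambiguous.
#'
#' Zero addition is attempted before truncation because it preserves more of
#' the source code's specificity; set `prefer = "truncate_first"` to test the
#' opposite precedence.
#'
#' @param code A code string (normalized on entry).
#' @param xwalk A [crosswalk()].
#' @param prefer Fallback precedence, `"zero_first"` (default) or
#'   `"truncate_first"`.
#' @return A one-row tibble: `source`, `target` (`NA` if unmapped), `method`
#'   (one of `direct`, `zero_added_1`, `zero_added_2`, `truncated`,
#'   `unmapped`), `n_removed` (characters removed by truncation, else `NA`),
#'   `ambiguous`.
#' @examples
#' xw <- crosswalk(list(A09 = "0091", C610 = "185", K35 = "540"))
#' convert_code("A09", xw)    # direct
#' convert_code("C61", xw)    # zero_added_1
#' convert_code("K3580", xw)  # truncated, 2 characters removed
#' convert_code("Z999", xw)   # unmapped
#' @export
convert_code <- function(code, xwalk, prefer = c("zero_first", "truncate_first")) {
  prefer <- match.arg(prefer)
  stopifnot(inherits(xwalk, "crosswalk"))
  if (length(xwalk) == 0) {
    emr_abort("crosswalk is empty", "emrforge_crosswalk_error")
  }
  res <- convert_codes(code, xwalk, prefer)
  res
}

# The conversion engine, vectorized over codes. Each unique code is resolved
# once against the key set; the per-code candidate ladder is tiny (<= code
# length + 2 probes) so resolution is O(unique codes).
#' @rdname convert_code
#' @param codes Character vector of code strings.
#' @export
convert_codes <- function(codes, xwalk, prefer = c("zero_first", "truncate_first")) {
  prefer <- match.arg(prefer)
  stopifnot(inherits(xwalk, "crosswalk"))
  codes <- normalize_codes(codes)
  uniq <- unique(codes)

  resolve_one <- function(code) {
    zero_cands <- c(paste0(code, "0"), paste0(code, "00"))
    trunc_cands <- character(0)
    if (nchar(code) > 3) {
      lens <- seq(nchar(code) - 1, 3)
      trunc_cands <- substring(code, 1, lens)
    }
    ladder <- if (prefer == "zero_first") {
      c(code, zero_cands, trunc_cands)
    } else {
      c(code, trunc_cands, zero_cands)
    }
    hit <- match(ladder, names(xwalk$entries))
    first <- which(!is.na(hit))[1]
    if (is.na(first)) {
      return(list(target = NA_character_, method = "unmapped",
                  n_removed = NA_integer_, ambiguous = FALSE))
    }
    key <- ladder[first]
    targets <- xwalk$entries[[hit[first]]]
    method <- if (key == code) {
      "direct"
    } else if (key == zero_cands[1]) {
      "zero_added_1"
    } else if (key == zero_cands[2]) {
      "zero_added_2"
    } else {
      "truncated"
    }
    list(
      target = targets[1],
      method = method,
      n_removed = if (method == "truncated") nchar(code) - nchar(key) else NA_integer_,
      ambiguous = length(targets) > 1
    )
  }

  resolved <- lapply(uniq, resolve_one)
  lut <- match(codes, uniq)
  tibble::tibble(
    source = codes,
    target = vapply(resolved, `[[`, character(1), "target")[lut],
    method = vapply(resolved, `[[`, character(1), "method")[lut],
    n_removed = vapply(resolved, `[[`, integer(1), "n_removed")[lut],
    ambiguous = vapply(resolved, `[[`, logical(1), "ambiguous")[lut]
  )
}

#' Per-role mapping statistics for a conversion run
#'
#' Tallies conversion outcomes by diagnosis role (primary / secondary /
#' combined), on code instances and on unique codes, with percentages on both
#' the total and the mapped denominator — the row structure of a code-mapping
#' rate table.
#'
#' @param conversions Tibble with columns `source`, `method`, `ambiguous` and
#'   a `role` column (`"primary"` / `"secondary"`), e.g. the conversion
#'   columns attached by [standardize_diagnoses()].
#' @return A tibble with one row per role (`primary`, `secondary`,
#'   `combined`) and columns `total`, `direct`, `zero_added`, `truncated`,
#'   `unmapped`, `mapped`, `ambiguous`, their `unique_*` variants, and
#'   percentages `pct_<method>_of_total`, `pct_<method>_of_mapped`,
#'   `mapping_rate`.
#' @export
mapping_stats <- function(conversions) {
  assert_columns(conversions, c("source", "method", "role"), "conversions")
  methods3 <- c(direct = "direct", zero_added_1 = "zero_added",
                zero_added_2 = "zero_added", truncated = "truncated",
                unmapped = "unmapped")
  bad <- setdiff(unique(conversions$method), names(methods3))
  if (length(bad) > 0) {
    emr_abort(sprintf("unknown conversion method(s): %s", paste(bad, collapse = ", ")),
              "emrforge_schema_error")
  }
  bad_role <- setdiff(unique(conversions$role), c("primary", "secondary"))
  if (length(bad_role) > 0) {
    emr_abort("`role` must be 'primary' or 'secondary'", "emrforge_schema_error")
  }

  tally_one <- function(df, role_label) {
    m <- methods3[df$method]
    udf <- df[!duplicated(df$source), ]
    um <- methods3[udf$method]
    count <- function(v, lab) sum(v == lab)
    total <- nrow(df)
    direct <- count(m, "direct"); zero <- count(m, "zero_added")
    trunc <- count(m, "truncated"); unmap <- count(m, "unmapped")
    mapped <- total - unmap
    pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
    tibble::tibble(
      role = role_label,
      total = total, direct = direct, zero_added = zero, truncated = trunc,
      unmapped = unmap, mapped = mapped,
      ambiguous = sum(df$ambiguous %||% FALSE),
      unique_total = nrow(udf),
      unique_direct = count(um, "direct"),
      unique_zero_added = count(um, "zero_added"),
      unique_truncated = count(um, "truncated"),
      unique_unmapped = count(um, "unmapped"),
      unique_mapped = nrow(udf) - count(um, "unmapped"),
      pct_direct_of_total = pct(direct, total),
      pct_zero_added_of_total = pct(zero, total),
      pct_truncated_of_total = pct(trunc, total),
      pct_unmapped_of_total = pct(unmap, total),
      pct_direct_of_mapped = pct(direct, mapped),
      pct_zero_added_of_mapped = pct(zero, mapped),
      pct_truncated_of_mapped = pct(trunc, mapped),
      mapping_rate = pct(mapped, total)
    )
  }

  dplyr::bind_rows(
    tally_one(conversions[conversions$role == "primary", , drop = FALSE], "primary"),
    tally_one(conversions[conversions$role == "secondary", , drop = FALSE], "secondary"),
    tally_one(conversions, "combined")
  )
}

#' Standardize a diagnosis table to the target nosology
#'
#' Codes already in the target nosology pass through untouched and are not
#' counted in the conversion statistics; all other codes run the fallback
#' conversion of [convert_code()]. Records left unmapped after modification
#' are flagged `excluded` (they are retained in the returned table so an
#' exclusion log can account for them downstream).
#'
#' @param diagnoses Tibble with a raw code column `code`, a `role` column
#'   (`"primary"` / `"secondary"`), and either a `nosology` column naming the
#'   coding system of each record or a `date` column to which the cut-over
#'   rule applies.
#' @param xwalk Backward-mapping [crosswalk()] into the target nosology.
#' @param era_rule Function `(diagnoses) -> logical`, `TRUE` where the record
#'   is already in the target nosology. Defaults to
#'   [era_rule_cutover()]`(cutover, target_nosology)`.
#' @param cutover Cut-over date for the default era rule: records dated
#'   before it are treated as already coded in the target nosology.
#' @param target_nosology Label of the target system (defaults to the
#'   crosswalk's).
#' @inheritParams convert_code
#' @return A list: `diagnoses` (input plus `std_code`, `map_method`,
#'   `map_ambiguous`, `converted`, `excluded`) and `stats` (a
#'   [mapping_stats()] tibble over the converted records only).
#' @export
standardize_diagnoses <- function(diagnoses, xwalk, era_rule = NULL,
                                  cutover = NULL,
                                  target_nosology = xwalk$target_nosology,
                                  prefer = c("zero_first", "truncate_first")) {
  prefer <- match.arg(prefer)
  assert_columns(diagnoses, c("code", "role"), "diagnosis table")
  if (any(is.na(diagnoses$role)) ||
      !all(diagnoses$role %in% c("primary", "secondary"))) {
    emr_abort("every diagnosis record needs a role of 'primary' or 'secondary'",
              "emrforge_schema_error")
  }
  if (is.null(era_rule)) {
    era_rule <- era_rule_cutover(cutover, target_nosology)
  }

  n <- nrow(diagnoses)
  out <- tibble::as_tibble(diagnoses)
  if (n == 0) {
    out$std_code <- character(0); out$map_method <- character(0)
    out$map_ambiguous <- logical(0); out$converted <- logical(0)
    out$excluded <- logical(0)
    empty <- tibble::tibble(source = character(0), method = character(0),
                            ambiguous = logical(0), role = character(0))
    return(list(diagnoses = out, stats = mapping_stats(empty)))
  }

  native <- era_rule(out)
  if (length(native) != n || anyNA(native)) {
    emr_abort("era rule must return a complete logical vector over the records",
              "emrforge_schema_error")
  }

  out$std_code <- NA_character_
  out$map_method <- ifelse(native, "passthrough", NA_character_)
  out$map_ambiguous <- FALSE
  out$converted <- !native
  out$std_code[native] <- normalize_codes(out$code[native])

  if (any(!native)) {
    conv <- convert_codes(out$code[!native], xwalk, prefer)
    out$std_code[!native] <- conv$target
    out$map_method[!native] <- conv$method
    out$map_ambiguous[!native] <- conv$ambiguous
    stats <- mapping_stats(tibble::tibble(
      source = conv$source, method = conv$method,
      ambiguous = conv$ambiguous, role = out$role[!native]
    ))
  } else {
    stats <- mapping_stats(tibble::tibble(
      source = character(0), method = character(0),
      ambiguous = logical(0), role = character(0)
    ))
  }
  out$excluded <- is.na(out$std_code)
  list(diagnoses = out, stats = stats)
}

#' Default coding-era rule
#'
#' Decides whether a diagnosis record is already in the target nosology: a
#' `nosology` column wins when present; otherwise the record's `date` is
#' compared against the cut-over date of the coding migration (records dated
#' before the cut-over are in the old, target-side system).
#'
#' @inheritParams standardize_diagnoses
#' @return A predicate function over a diagnosis tibble.
#' @export
era_rule_cutover <- function(cutover = NULL, target_nosology = "ICD-9-CM") {
  function(df) {
    if ("nosology" %in% names(df) && !all(is.na(df$nosology))) {
      return(df$nosology == target_nosology)
    }
    if (is.null(cutover)) {
      emr_abort("no `nosology` column and no cut-over date: cannot decide coding era",
                "emrforge_config_error")
    }
    d <- as_date_strict(df$date)
    if (anyNA(d)) {
      emr_abort("unparseable dates while applying the cut-over era rule",
                "emrforge_schema_error")
    }
    d < as_date_strict(cutover)
  }
}

#' Phenotype standardized codes to mutually exclusive disease categories
#'
#' Applies the same fallback conversion engine against a code-to-category
#' crosswalk (in the style of the AHRQ single-level CCS file). Every mapped
#' code receives exactly one category; unmapped codes are flagged excluded.
#'
#' @param codes Tibble with a normalized code column `std_code` and a `role`
#'   column.
#' @param ccs_xwalk Code-to-category [crosswalk()].
#' @inheritParams convert_code
#' @return A list: `codes` (input plus `category`, `phen_method`,
#'   `phen_ambiguous`, `excluded`) and `stats` (a [mapping_stats()] tibble).
#' @export
phenotype_codes <- function(codes, ccs_xwalk, prefer = c("zero_first", "truncate_first")) {
  prefer <- match.arg(prefer)
  assert_columns(codes, c("std_code", "role"), "standardized code table")
  out <- tibble::as_tibble(codes)
  if (nrow(out) == 0) {
    out$category <- character(0); out$phen_method <- character(0)
    out$phen_ambiguous <- logical(0); out$excluded <- logical(0)
    empty <- tibble::tibble(source = character(0), method = character(0),
                            ambiguous = logical(0), role = character(0))
    return(list(codes = out, stats = mapping_stats(empty)))
  }
  conv <- convert_codes(out$std_code, ccs_xwalk, prefer)
  out$category <- conv$target
  out$phen_method <- conv$method
  out$phen_ambiguous <- conv$ambiguous
  out$excluded <- is.na(out$category)
  stats <- mapping_stats(tibble::tibble(
    source = conv$source, method = conv$method,
    ambiguous = conv$ambiguous, role = out$role
  ))
  list(codes = out, stats = stats)
}

#' Mapping rate
#'
#' @param mapped,total Counts with `0 <= mapped <= total`, `total > 0`.
#' @return `100 * mapped / total` at full precision; summary tables report it
#'   to one decimal place.
#' @examples
#' mapping_rate(810459, 930248) # 87.1...
#' @export
mapping_rate <- function(mapped, total) {
  if (length(total) != 1 || length(mapped) != 1 || is.na(total) || is.na(mapped)) {
    emr_abort("`mapped` and `total` must be single counts", "emrforge_rate_error")
  }
  if (total == 0) {
    emr_abort("mapping rate is undefined for total = 0", "emrforge_rate_error")
  }
  if (mapped < 0 || mapped > total) {
    emr_abort("need 0 <= mapped <= total", "emrforge_rate_error")
  }
  100 * mapped / total
}

#' Summarize a physician validity-rating exercise
#'
#' Modified codes (truncated or zero-added) are sampled and rated valid or
#' invalid; the summary reports the validity rate among rated codes and the
#' sampling fraction relative to all unique modified codes.
#'
#' @param ratings Tibble with columns `code` and `rating`
#'   (`"valid"` / `"invalid"`).
#' @param n_modified_unique Number of unique modified codes the sample was
#'   drawn from.
#' @return A one-row tibble: `n_sampled`, `n_valid`, `n_invalid`,
#'   `validity_rate`, `sampling_fraction` (both percentages, full precision).
#' @examples
#' r <- tibble::tibble(code = sprintf("C%03d", 1:151),
#'                     rating = rep(c("valid", "invalid"), c(137, 14)))
#' validity_summary(r, n_modified_unique = 653)
#' @export
validity_summary <- function(ratings, n_modified_unique) {
  assert_columns(ratings, c("code", "rating"), "ratings")
  if (nrow(ratings) == 0) {
    emr_abort("ratings table is empty", "emrforge_rate_error")
  }
  if (!all(ratings$rating %in% c("valid", "invalid"))) {
    emr_abort("ratings must be 'valid' or 'invalid'", "emrforge_rate_error")
  }
  n_sampled <- nrow(ratings)
  if (n_modified_unique < n_sampled) {
    emr_abort("`n_modified_unique` cannot be smaller than the number of rated codes",
              "emrforge_rate_error")
  }
  n_valid <- sum(ratings$rating == "valid")
  tibble::tibble(
    n_sampled = n_sampled,
    n_valid = n_valid,
    n_invalid = n_sampled - n_valid,
    validity_rate = mapping_rate(n_valid, n_sampled),
    sampling_fraction = mapping_rate(n_sampled, n_modified_unique)
  )
}
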