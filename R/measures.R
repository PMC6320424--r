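#' Comorbidity definition map
#'
#' The Charlson comorbidities are identified from ICD-9-CM codes by prefix
#' match. The shipped default is the 17-category Deyo ICD-9-CM adaptation
#' with the original Charlson weights (1/2/3/6) and three hierarchy pairs:
#' complicated diabetes supersedes uncomplicated diabetes, moderate/severe
#' liver disease supersedes mild liver disease, and metastatic solid tumour
#' supersedes non-metastatic malignancy. The file is an editable CSV
#' (`category,prefixes,weight,supersedes`, prefixes `;`-separated) so an
#' updated weight scheme can be swapped in.
#'
#' @param path CSV file path.
#' @return Tibble with columns `category`, `prefixes` (list-column of
#'   character vectors), `weight` (integer), `supersedes` (`NA` or a category
#'   name).
#' @export
read_comorbidity_map <- function(path) {
  df <- read.csv(path, colClasses = "character")
  assert_columns(df, c("category", "prefixes", "weight", "supersedes"), "comorbidity map")
  out <- tibble::tibble(
    category = df$category,
    prefixes = strsplit(df$prefixes, ";", fixed = TRUE),
    weight = as.integer(df$weight),
    supersedes = ifelse(nzchar(df$supersedes), df$supersedes, NA_character_)
  )
  if (any(lengths(out$prefixes) == 0)) {
    emr_abort("every comorbidity category needs at least one prefix", "emrforge_config_error")
  }
  if (any(out$weight < 1)) {
    emr_abort("comorbidity weights must be >= 1", "emrforge_config_error")
  }
  sup <- stats::na.omit(out$supersedes)
  if (!all(sup %in% out$category)) {
    emr_abort("hierarchy partner references an unknown category", "emrforge_config_error")
  }
  out
}

#' @rdname read_comorbidity_map
#' @export
default_comorbidity_map <- function() {
  read_comorbidity_map(system.file("extdata", "charlson_deyo.csv", package = "emrforge"))
}

#' Flag Charlson comorbidity categories from a patient's code set
#'
#' A category flags true iff any of the patient's codes (primary and
#' secondary, over all included visits) starts with any of the category's
#' prefixes. The hierarchy is applied afterwards: when both members of a
#' hierarchy pair are present only the severe member remains.
#'
#' @param codes Character vector of normalized ICD-9-CM codes.
#' @param cmap Comorbidity map, see [read_comorbidity_map()].
#' @return Named logical vector, one element per category.
#' @export
charlson_flags <- function(codes, cmap = default_comorbidity_map()) {
  flags <- vapply(cmap$prefixes, function(pfx) {
    if (length(codes) == 0) return(FALSE)
    any(vapply(pfx, function(p) any(startsWith(codes, p)), logical(1)))
  }, logical(1))
  names(flags) <- cmap$category
  for (i in which(!is.na(cmap$supersedes))) {
    if (flags[[cmap$category[i]]]) {
      flags[[cmap$supersedes[i]]] <- FALSE
    }
  }
  flags
}

#' Charlson Comorbidity Index
#'
#' Weighted sum over flagged comorbidity categories.
#'
#' @param flags Named logical vector from [charlson_flags()].
#' @param cmap Comorbidity map the flags were produced from.
#' @return Non-negative integer score.
#' @examples
#' cmap <- default_comorbidity_map()
#' cci(charlson_flags(c("41001", "1970"), cmap), cmap) # MI (1) + metastasis (6)
#' @export
cci <- function(flags, cmap = default_comorbidity_map()) {
  stopifnot(all(names(flags) %in% cmap$category))
  w <- cmap$weight[match(names(flags), cmap$category)]
  as.integer(sum(w[flags]))
}

#' Polypharmacy Score
#'
#' `pps_visit()` is the number of unique drugs dispensed in one visit,
#' excluding non-prescription items and devices. `pps_patient()` is the
#' maximum visit-level score across the patient's included visits (0 when
#' there are none).
#'
#' @param pharmacy Pharmacy rows of one visit (columns `drug_code`,
#'   `is_prescription`, `is_device`).
#' @return Non-negative integer.
#' @export
pps_visit <- function(pharmacy) {
  if (is.null(pharmacy) || nrow(pharmacy) == 0) return(0L)
  assert_columns(pharmacy, c("drug_code", "is_prescription", "is_device"), "pharmacy rows")
  keep <- pharmacy$is_prescription & !pharmacy$is_device
  length(unique(pharmacy$drug_code[keep]))
}

#' @rdname pps_visit
#' @param visit_pps Integer vector of visit-level scores for one patient.
#' @export
pps_patient <- function(visit_pps) {
  if (length(visit_pps) == 0) return(0L)
  as.integer(max(visit_pps))
}

# Flat types ordered by size; ties between flat types in a block break
# toward the larger type.
FLAT_TYPE_ORDER <- c("rental", "studio", "1-room", "2-room", "3-room",
                     "4-room", "5-room", "executive")

#' Load the postal-code housing lookup
#'
#' Public housing blocks come as a `postal,flat_type,proportion` table (one
#' row per flat type present in the block, proportions summing to 1 per
#' block); private housing is a plain list of postal codes, one per line.
#' The two code sets must be disjoint.
#'
#' @param public_path CSV of public-housing block compositions.
#' @param private_path Text file of private-housing postal codes.
#' @return An object of class `housing_lookup`.
#' @export
read_housing_lookup <- function(public_path, private_path) {
  pub <- read.csv(public_path, colClasses = c("character", "character", "numeric"))
  assert_columns(pub, c("postal", "flat_type", "proportion"), "housing lookup")
  priv <- readLines(private_path, warn = FALSE)
  priv <- trimws(priv[nzchar(trimws(priv))])
  housing_lookup(tibble::as_tibble(pub), priv)
}

#' @rdname read_housing_lookup
#' @param public Tibble `postal,flat_type,proportion`.
#' @param private Character vector of private-housing postal codes.
#' @export
housing_lookup <- function(public, private) {
  assert_columns(public, c("postal", "flat_type", "proportion"), "housing lookup")
  bad_type <- setdiff(unique(public$flat_type), FLAT_TYPE_ORDER)
  if (length(bad_type) > 0) {
    emr_abort(sprintf("unknown flat type(s): %s", paste(bad_type, collapse = ", ")),
              "emrforge_config_error")
  }
  sums <- tapply(public$proportion, public$postal, sum)
  if (any(abs(sums - 1) > 1e-9)) {
    emr_abort("flat-type proportions must sum to 1 within each block",
              "emrforge_config_error")
  }
  if (length(intersect(unique(public$postal), private)) > 0) {
    emr_abort("public and private postal-code lists must be disjoint",
              "emrforge_config_error")
  }
  structure(list(public = public, private = unique(private)), class = "housing_lookup")
}

#' @export
print.housing_lookup <- function(x, ...) {
  cat(sprintf("<housing_lookup> %d public blocks, %d private postal codes\n",
              length(unique(x$public$postal)), length(x$private)))
  invisible(x)
}

#' Resolve a postal code to a housing type
#'
#' Private-list hits resolve to `"private"`. Public blocks resolve to the
#' flat type with the largest proportion in the block; a tie breaks toward
#' the larger flat type. Postal codes on neither list (non-residential or
#' invalid addresses) resolve to `"missing"`. Total and deterministic.
#'
#' @param postal Postal code string(s); `NA` allowed (resolves to missing).
#' @param lookup A [housing_lookup()].
#' @return Character vector: a flat type, `"private"`, or `"missing"`.
#' @export
housing_type <- function(postal, lookup) {
  stopifnot(inherits(lookup, "housing_lookup"))
  block_type <- function(p) {
    if (is.na(p)) return("missing")
    if (p %in% lookup$private) return("private")
    rows <- lookup$public[lookup$public$postal == p, , drop = FALSE]
    if (nrow(rows) == 0) return("missing")
    best <- max(rows$proportion)
    cands <- rows$flat_type[rows$proportion >= best - 1e-12]
    cands[which.max(match(cands, FLAT_TYPE_ORDER))]
  }
  vapply(as.character(postal), block_type, character(1), USE.NAMES = FALSE)
}

#' Group flat types by size
#'
#' Collapses the full flat-type list into the analysis groups: rental to
#' 2-room (incl. studios), 3-room, 4-room, 5-room to executive; `private`
#' and `missing` pass through.
#'
#' @param flat_type Flat type(s), `"private"`, or `"missing"`.
#' @return Housing group label(s).
#' @export
group_housing <- function(flat_type) {
  map <- c(rental = "rental/studio/1-2-room", studio = "rental/studio/1-2-room",
           "1-room" = "rental/studio/1-2-room", "2-room" = "rental/studio/1-2-room",
           "3-room" = "3-room", "4-room" = "4-room",
           "5-room" = "5-room/executive", executive = "5-room/executive",
           private = "private", missing = "missing")
  bad <- setdiff(unique(flat_type), names(map))
  if (length(bad) > 0) {
    emr_abort(sprintf("unknown flat type label(s): %s", paste(bad, collapse = ", ")),
              "emrforge_config_error")
  }
  unname(map[flat_type])
}

#' Housing groups ordered from smallest to private
#' @return Character vector of the five substantive groups plus `missing`.
#' @export
housing_group_levels <- function() {
  c("rental/studio/1-2-room", "3-room", "4-room", "5-room/executive",
    "private", "missing")
}

#' Patient subsidy status
#'
#' A patient whose visits were all government-subsidized is `subsidized`,
#' all non-subsidized is `nonsubsidized`, anything in between `mixed`.
#'
#' @param flags Logical vector of per-visit subsidy flags (>= 1 visit).
#' @return `"subsidized"`, `"mixed"` or `"nonsubsidized"`.
#' @export
subsidy_status <- function(flags) {
  if (length(flags) == 0 || anyNA(flags)) {
    emr_abort("subsidy status needs at least one non-missing visit flag",
              "emrforge_rate_error")
  }
  if (all(flags)) "subsidized" else if (!any(flags)) "nonsubsidized" else "mixed"
}

#' Relative subsidy received
#'
#' The percentage of a patient's cumulative hospital charges paid for by
#' government subsidies.
#'
#' @param total_subsidy,total_charges Cumulative amounts (SGD), with
#'   `0 <= total_subsidy <= total_charges`.
#' @return Percentage in `[0, 100]`; `NA` with a warning when charges are
#'   zero (undefined RSR, logged by callers).
#' @export
rsr <- function(total_subsidy, total_charges) {
  if (any(total_subsidy < 0 | total_subsidy > pmax(total_charges, 0), na.rm = TRUE)) {
    emr_abort("need 0 <= total_subsidy <= total_charges", "emrforge_rate_error")
  }
  undefined <- total_charges <= 0
  if (any(undefined, na.rm = TRUE)) {
    rlang::warn(sprintf("RSR undefined for %d patient(s) with zero charges; set to NA",
                        sum(undefined, na.rm = TRUE)))
  }
  ifelse(undefined, NA_real_, 100 * total_subsidy / total_charges)
}

#' Attach derived proxy measures to a patient-level table
#'
#' Computes, per patient: the Charlson Comorbidity Index from the patient's
#' code set (primary and secondary diagnoses over all included visits), the
#' housing group from the latest postal code, subsidy status from the
#' per-visit subsidy flags, and relative subsidy received from cumulative
#' adjusted charges. Visit-level consistency (positive subsidy amount with a
#' false flag) raises a warning upstream in [build_visits()] inputs.
#'
#' @param patients Patient tibble from [build_patients()] (needs `dx_codes`,
#'   `postal_code`, `subsidy_flags`, `total_subsidy`,
#'   `total_adjusted_charge`).
#' @param cmap Comorbidity map.
#' @param lookup Housing lookup.
#' @return The patient tibble with `cci`, `housing_group`, `subsidy_status`,
#'   `rsr` columns added (`pps` is already carried from the visit cascade).
#' @export
attach_measures <- function(patients, cmap = default_comorbidity_map(), lookup = NULL) {
  assert_columns(patients,
                 c("dx_codes", "subsidy_flags", "total_subsidy", "total_adjusted_charge"),
                 "patient table")
  patients$cci <- vapply(
    patients$dx_codes,
    function(codes) cci(charlson_flags(codes, cmap), cmap),
    integer(1)
  )
  if (!is.null(lookup)) {
    patients$housing_group <- group_housing(housing_type(patients$postal_code, lookup))
  }
  patients$subsidy_status <- vapply(patients$subsidy_flags, subsidy_status, character(1))
  patients$rsr <- rsr(patients$total_subsidy, patients$total_adjusted_charge)
  patients
}
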