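#' Construct a diagnosis-code crosswalk
#'
#' A crosswalk maps normalized source codes to an ordered list of normalized
#' target codes, in the style of the ACCD ICD-10-AM to ICD-9-CM backward
#' mapping tables and the AHRQ single-level CCS file. Keys with several
#' targets keep their stored order; lookups that hit such a key return the
#' first target and are flagged ambiguous.
#'
#' @param entries Named list: each name a source code, each element a
#'   character vector of one or more target codes. Codes are normalized on
#'   construction (upper case, periods and surrounding whitespace removed).
#' @param source_nosology,target_nosology Labels for the two coding systems.
#' @param normalize_targets Normalize target values as codes (default). Set
#'   to `FALSE` when targets are category labels rather than codes, as in a
#'   code-to-category map.
#' @return An object of class `crosswalk`.
#' @examples
#' xw <- crosswalk(list(A09 = "0091", E119 = c("25000", "25001")),
#'                 "ICD-10-AM", "ICD-9-CM")
#' xw
#' @export
crosswalk <- function(entries, source_nosology = "source", target_nosology = "target",
                      normalize_targets = TRUE) {
  if (!is.list(entries) || is.null(names(entries)) || any(names(entries) == "")) {
    emr_abort("`entries` must be a fully named list", "emrforge_crosswalk_error")
  }
  keys <- vapply(names(entries), normalize_code, character(1))
  vals <- if (normalize_targets) {
    lapply(entries, function(v) vapply(v, normalize_code, character(1), USE.NAMES = FALSE))
  } else {
    lapply(entries, function(v) trimws(as.character(v)))
  }
  if (any(lengths(vals) == 0)) {
    emr_abort("every crosswalk key needs at least one target", "emrforge_crosswalk_error")
  }
  if (anyDuplicated(keys)) {
    emr_abort(
      sprintf("duplicate crosswalk key(s) after normalization: %s",
              paste(unique(keys[duplicated(keys)]), collapse = ", ")),
      "emrforge_crosswalk_error"
    )
  }
  structure(
    list(
      entries = setNames(vals, keys),
      source_nosology = source_nosology,
      target_nosology = target_nosology
    ),
    class = "crosswalk"
  )
}

#' @export
print.crosswalk <- function(x, ...) {
  cat(sprintf(
    "<crosswalk> %s -> %s: %d keys (%d with multiple targets)\n",
    x$source_nosology, x$target_nosology,
    length(x$entries), sum(lengths(x$entries) > 1)
  ))
  invisible(x)
}

#' @export
length.crosswalk <- function(x) length(x$entries)

#' Read / write a crosswalk as delimited text
#'
#' The on-disk format is a two-column CSV with header `source,target`;
#' one-to-many keys are repeated rows and file order fixes target priority.
#'
#' @param path File path.
#' @param source_nosology,target_nosology Labels for the coding systems.
#' @return `read_crosswalk()` returns a [crosswalk()]; `write_crosswalk()`
#'   returns `path` invisibly.
#' @inheritParams crosswalk
#' @export
read_crosswalk <- function(path, source_nosology = "source", target_nosology = "target",
                           normalize_targets = TRUE) {
  df <- read.csv(path, colClasses = "character")
  assert_columns(df, c("source", "target"), sprintf("crosswalk file '%s'", path))
  if (nrow(df) == 0) {
    emr_abort(sprintf("crosswalk file '%s' has no rows", path), "emrforge_crosswalk_error")
  }
  src <- vapply(df$source, normalize_code, character(1), USE.NAMES = FALSE)
  entries <- split(df$target, factor(src, levels = unique(src)))
  crosswalk(as.list(entries), source_nosology, target_nosology,
            normalize_targets = normalize_targets)
}

#' @rdname read_crosswalk
#' @param xwalk A [crosswalk()].
#' @export
write_crosswalk <- function(xwalk, path) {
  stopifnot(inherits(xwalk, "crosswalk"))
  df <- data.frame(
    source = rep(names(xwalk$entries), lengths(xwalk$entries)),
    target = unlist(xwalk$entries, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
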