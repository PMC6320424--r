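#' @importFrom rlang %||% abort warn
#' @importFrom stats median quantile setNames coef vcov qnorm pnorm p.adjust
#' @importFrom utils read.csv write.csv head
NULL

# Internal condition helpers: every user-facing error carries a class so
# callers (and the pipeline driver) can distinguish schema problems from
# configuration problems from bad codes.
emr_abort <- function(message, class) {
  rlang::abort(message, class = c(class, "emrforge_error"))
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    emr_abort(
      sprintf(
        "%s is missing required column(s): %s",
        what, paste(missing, collapse = ", ")
      ),
      "emrforge_schema_error"
    )
  }
  invisible(df)
}

# round() half-up at `digits` decimals, the convention of printed clinical
# summary tables (base round() is banker's rounding).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

as_date_strict <- function(x, what = "date") {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(as.character(x), format = "%Y-%m-%d")
  out
}

# Whole completed years between two dates (birthday convention).
years_between <- function(from, to) {
  from_lt <- as.POSIXlt(from)
  to_lt <- as.POSIXlt(to)
  age <- to_lt$year - from_lt$year
  before_birthday <- (to_lt$mon < from_lt$mon) |
    (to_lt$mon == from_lt$mon & to_lt$mday < from_lt$mday)
  age - as.integer(before_birthday)
}
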