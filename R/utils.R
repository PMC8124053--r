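#' Round half away from zero
#'
#' Clinical tables round 0.5 up (so 44.45 -> 44.5), whereas [base::round()]
#' rounds to even. All percentages formatted by this package go through this
#' helper; raw proportions are always kept alongside.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 44.45), 0)
round_half_up <- function(x, digits = 1) {
  stopifnot(is.numeric(x), length(digits) == 1, digits >= 0)
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Format a proportion as a percent
#'
#' @param p Proportion in `[0, 1]` (NA allowed for undefined ratios).
#' @param digits Decimal places of the percentage.
#' @return Numeric percent, rounded half up.
#' @export
as_percent <- function(p, digits = 1) {
  round_half_up(100 * p, digits)
}

# Internal: stop with a consistent error class so callers/tests can catch
# validation failures distinctly from programming errors.
abort_validation <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "nepscore_validation_error")
}

# Internal: ratio that returns NA (the "undefined" marker) instead of NaN
# when the denominator is zero.
safe_ratio <- function(num, den) {
  ifelse(den == 0, NA_real_, num / den)
}

# Internal: normalize heterogeneous clinical booleans. Accepts
# yes/no, true/false, 1/0, t/f (case-insensitive) and logicals.
parse_clinical_logical <- function(x, field = "value") {
  if (is.logical(x)) return(x)
  key <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(key))
  out[key %in% c("yes", "true", "1", "t", "y")] <- TRUE
  out[key %in% c("no", "false", "0", "f", "n")] <- FALSE
  bad <- !is.na(key) & key != "" & is.na(out)
  if (any(bad)) {
    abort_validation(
      "%s: cannot interpret %s as yes/no", field,
      paste(unique(sQuote(x[bad])), collapse = ", ")
    )
  }
  out
}

# Internal: single place defining the vital-status encoding.
is_dead <- function(vital_status) {
  if (is.logical(vital_status)) return(vital_status)
  key <- tolower(trimws(as.character(vital_status)))
  out <- rep(NA, length(key))
  out[key %in% c("dead", "deceased")] <- TRUE
  out[key %in% c("alive", "living")] <- FALSE
  bad <- !is.na(key) & is.na(out)
  if (any(bad)) {
    abort_validation(
      "vital_status must be 'alive' or 'dead', got %s",
      paste(unique(sQuote(key[bad])), collapse = ", ")
    )
  }
  out
}
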