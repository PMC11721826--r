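# Shared helpers: ICD-10 code validation, reporting-style rounding.

# Three-character category, optionally subdivided by one or two digits
# after a dot (e.g. "M91", "M91.1", "S72.01").
ICD10_PATTERN <- "^[A-Z][0-9]{2}(\\.[0-9]{1,2})?$"

is_valid_icd10 <- function(code) {
  !is.na(code) & grepl(ICD10_PATTERN, code)
}

#' Round half away from zero
#'
#' Decimal rounding with the half-up tie rule used in clinical tables
#' (`round()` in R rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_up(2.675, 2)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Format p-values for reporting
#'
#' Rounds to three decimals and prints values below 0.001 as `"<0.001"`,
#' the convention of clinical association tables.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Character vector.
#' @export
#' @examples
#' format_p(c(0.2345, 0.0004))
format_p <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1, na.rm = TRUE))
  out <- sprintf("%.3f", round_half_up(p, 3))
  out[!is.na(p) & p < 0.001] <- "<0.001"
  out[is.na(p)] <- NA_character_
  out
}

# Deterministic per-stage seed derived from the run seed and a stage name,
# kept below 2^31 so it is a valid R integer.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# assertion helper: stops with the offending field named
check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) {
    stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
  }
  invisible(TRUE)
}
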