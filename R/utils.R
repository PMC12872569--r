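# shared small helpers

#' Parse a FAERS date string
#'
#' FAERS date fields are 8-digit `YYYYMMDD` strings, but real extracts contain
#' partial dates (`YYYY` or `YYYYMM`), empty strings, and impossible calendar
#' days.  Anything that is not a complete, valid calendar date parses to `NA`:
#' downstream stages treat partial dates as missing rather than guessing a day.
#'
#' @param x character vector of raw date fields.
#' @return a `Date` vector of the same length; `NA` where the field is not a
#'   valid 8-digit calendar date.
#' @examples
#' parse_faers_date(c("20200131", "202001", "20200230", ""))
#' @export
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(as.Date(NA), length(x))
  ok <- !is.na(x) & grepl("^[0-9]{8}$", x)
  if (any(ok)) {
    d <- as.Date(x[ok], format = "%Y%m%d")   # invalid days (e.g. Feb 30) -> NA
    out[ok] <- d
  }
  out
}

# Normalize a drug name / free-text field for matching: trim, case-fold,
# collapse internal whitespace.
normalize_name <- function(x) {
  x <- toupper(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

# Numeric-aware total order key for PRIMARYID-style identifiers: digit-only ids
# are zero-padded so lexicographic order coincides with numeric order; mixed
# ids fall back to plain lexicographic comparison.
pid_order_key <- function(x) {
  x <- as.character(x)
  digits <- grepl("^[0-9]+$", x) & !is.na(x)
  width <- max(nchar(x[digits]), 0L)
  key <- x
  key[digits] <- formatC(x[digits], width = width, flag = "0")
  key
}

# round like the tables in regulatory summaries: half away from zero at 1 dp
round_pct <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

assert_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1].", field),
          class = "faersignal_config_error")
  }
  invisible(x)
}

assert_pos <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", field),
          class = "faersignal_config_error")
  }
  invisible(x)
}
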