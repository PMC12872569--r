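# Fixtures built in code: no data files.

# Cohort whose stratum counts match the published clinical-characteristics
# table of the reference analysis (4,643 tabulated cases).  Families are
# independent columns, so each family's counts are laid out directly.
table2_cases <- function() {
  n <- 4643
  rep_levels <- function(levels, counts) rep(levels, counts)
  outcome_codes <- c(
    replicate(15, "DE", simplify = FALSE),
    replicate(43, "DS", simplify = FALSE),
    replicate(97, "HO", simplify = FALSE),
    replicate(10, "LT", simplify = FALSE),
    replicate(3160, "OT", simplify = FALSE),
    replicate(1318, character(0), simplify = FALSE))
  tibble::tibble(
    caseid = as.character(seq_len(n)),
    primaryid = as.character(seq_len(n)),
    sex = rep_levels(c("male", "female", "unknown"), c(329, 4052, 262)),
    age_years = rep_levels(c(10, 40, 70, NA), c(616, 1289, 476, 2262)),
    reporter = rep_levels(
      c("physician", "consumer", "health professional",
        "other health-professional", "pharmacist", "lawyer", "unknown"),
      c(206, 1398, 518, 98, 112, 2286, 25)),
    country = rep_levels(c("US", "CA", "OTHER"), c(4514, 68, 61)),
    fda_dt = as.Date("2023-06-15"),
    pts = replicate(n, "MACULOPATHY", simplify = FALSE),
    outcome_codes = outcome_codes)
}

pct_of <- function(summary, fam, lev) {
  summary$pct[summary$family == fam & summary$level == lev]
}

# Minimal tto_records builder for unit tests.
make_tto <- function(t, pts = NULL) {
  n <- length(t)
  if (is.null(pts)) pts <- replicate(n, "PT_A", simplify = FALSE)
  if (!is.list(pts)) pts <- as.list(pts)
  out <- tibble::tibble(
    caseid = as.character(seq_len(n)),
    pts = pts,
    event_dt = as.Date("2020-01-01") + t,
    start_dt = as.Date("2020-01-01"),
    tto_days = as.numeric(t),
    included = TRUE,
    exclusion_reason = "none")
  class(out) <- c("tto_records", class(out))
  out
}

# Tiny case tibble for contingency-table tests.
mini_cases <- function(target, pts) {
  tibble::tibble(
    caseid = as.character(seq_along(target)),
    target = target,
    sex = "female",
    pts = pts)
}

# Brute-force Pearson chi-square: expected counts from the margins, summed
# over all four cells.  Independent of the closed form used in the package.
chi2_brute <- function(a, b, c, d) {
  o <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  n <- sum(o)
  e <- outer(rowSums(o), colSums(o)) / n
  sum((o - e)^2 / e)
}
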