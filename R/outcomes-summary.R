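# FDA outcome seriousness classification and clinical-characteristics
# summary.

outcome_levels <- c("death", "life-threatening", "disability",
                    "hospitalization", "congenital anomaly", "other serious",
                    "unknown/non-serious")

#' Classify a case's outcome codes into a single seriousness category
#'
#' FAERS OUTC codes mark the seriousness outcomes of a report (`DE` death,
#' `LT` life-threatening, `HO` hospitalization, `DS` disability, `CA`
#' congenital anomaly, `RI` required intervention, `OT` other serious).  A
#' case may carry several codes; the single category reported is the
#' highest-precedence one present, with precedence
#' `DE > LT > DS > HO > CA > OT` (so death dominates).  `RI` is treated as
#' the "other serious" tier.  An empty code set maps to
#' `"unknown/non-serious"`; unrecognized codes are ignored with a warning.
#'
#' @param codes a list of character vectors (one per case), or a single
#'   character vector of codes for one case.
#' @return factor of categories, levels ordered by precedence.
#' @examples
#' classify_outcome(list(c("HO", "DE"), "OT", character(0)))
#' @export
classify_outcome <- function(codes) {
  if (!is.list(codes)) codes <- list(codes)
  known <- c("DE", "LT", "DS", "HO", "CA", "RI", "OT")
  all_codes <- toupper(unlist(codes))
  bad <- setdiff(unique(all_codes), known)
  if (length(bad)) {
    warn(sprintf("ignoring unrecognized outcome code(s): %s",
                 paste(bad, collapse = ", ")))
  }
  cat_of <- function(cs) {
    cs <- toupper(cs)
    if ("DE" %in% cs) return("death")
    if ("LT" %in% cs) return("life-threatening")
    if ("DS" %in% cs) return("disability")
    if ("HO" %in% cs) return("hospitalization")
    if ("CA" %in% cs) return("congenital anomaly")
    if (any(c("OT", "RI") %in% cs)) return("other serious")
    "unknown/non-serious"
  }
  factor(map_chr(codes, cat_of), levels = outcome_levels)
}

age_band <- function(age_years) {
  dplyr::case_when(
    is.na(age_years) ~ "unknown",
    age_years < 18 ~ "<18",
    age_years < 65 ~ "18-64",
    TRUE ~ ">=65")
}

#' Clinical-characteristics summary of a case cohort
#'
#' Tabulates the cohort by stratum family -- gender, age band (`<18`,
#' `18-64`, `>=65`, `unknown`, completed years), reporter type, country,
#' calendar year of the retained report version (FDA_DT), and outcome
#' seriousness category -- with counts and percentages.  Percentage
#' denominators are the family totals (the counts within each family sum to
#' the number of cases); percentages are rounded to one decimal.
#'
#' @param cases a `faers_cases` tibble.
#' @return tibble with columns `family`, `level`, `n`, `pct`.
#' @export
summarize_characteristics <- function(cases) {
  if (nrow(cases) == 0) {
    return(tibble(family = character(0), level = character(0),
                  n = integer(0), pct = numeric(0)))
  }
  strata <- list(
    gender = cases$sex,
    age = age_band(cases$age_years),
    reporter = cases$reporter,
    country = dplyr::coalesce(as.character(cases$country), "unknown"),
    year = ifelse(is.na(cases$fda_dt), "unknown",
                  format(cases$fda_dt, "%Y")),
    outcome = as.character(classify_outcome(cases$outcome_codes)))
  purrr::imap(strata, function(x, fam) {
    tibble(level = x) %>%
      count(.data$level, name = "n") %>%
      mutate(family = fam, pct = round_pct(100 * .data$n / sum(.data$n))) %>%
      arrange(desc(.data$n), .data$level)
  }) %>%
    bind_rows() %>%
    select("family", "level", "n", "pct")
}

#' Female-to-male reporting ratio
#'
#' @param cases a `faers_cases` tibble.
#' @param digits decimals for display rounding.
#' @return the ratio (female count / male count) rounded to `digits`; `NA`
#'   with a warning when there are no male cases.
#' @export
gender_ratio <- function(cases, digits = 2) {
  n_f <- sum(cases$sex == "female")
  n_m <- sum(cases$sex == "male")
  if (n_m == 0) {
    warn("no male cases: female-to-male ratio undefined")
    return(NA_real_)
  }
  round(n_f / n_m, digits)
}
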