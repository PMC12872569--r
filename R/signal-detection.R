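# Disproportionality signal detection.
#
# Every statistic lives on the 2x2 contingency table
#
#                     target AE   all other AE
#   target drug           a            b
#   all other drugs       c            d
#
# counted at the level of the unique deduplicated case: a case reporting the
# same PT several times contributes once.  The comparator is every case in
# the (deduplicated) database whose primary-suspect set does not include the
# target drug.

#' Build the 2x2 contingency table for one drug-event pair
#'
#' @param cases a `faers_cases` tibble containing *all* deduplicated cases
#'   with a logical `target` column (see [assemble_cases()] with
#'   `all_cases = TRUE`).
#' @param pt preferred term (matched exactly against each case's PT set).
#' @return one-row tibble with columns `a`, `b`, `c`, `d`.
#' @export
build_contingency <- function(cases, pt) {
  has_pt <- map_lgl(cases$pts, ~ pt %in% .x)
  a <- sum(cases$target & has_pt)
  b <- sum(cases$target & !has_pt)
  cc <- sum(!cases$target & has_pt)
  d <- sum(!cases$target & !has_pt)
  tibble(a = a, b = b, c = cc, d = d)
}

haldane <- function(a, b, c, d, correct = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  adj <- if (isTRUE(correct)) ifelse(zero, 0.5, 0) else 0
  list(a = a + adj, b = b + adj, c = c + adj, d = d + adj,
       corrected = isTRUE(correct) & zero)
}

#' Reporting odds ratio with Wald confidence interval
#'
#' `ROR = (a/c) / (b/d) = ad / bc`, with a normal-theory interval on the log
#' scale: `exp(ln ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.  When any cell
#' is zero the Haldane-Anscombe correction adds 0.5 to all four cells
#' (flagged in `corrected`); with `correct = FALSE` a zero cell yields `NA`.
#'
#' @param a,b,c,d cell counts (vectorised).
#' @param correct apply the Haldane-Anscombe +0.5 correction to zero-cell
#'   tables.
#' @param z normal quantile for the interval (1.96 for 95%).
#' @return tibble with `ror`, `ror_low`, `ror_high`, `corrected`.
#' @export
ror_ci <- function(a, b, c, d, correct = TRUE, z = 1.96) {
  h <- haldane(a, b, c, d, correct)
  ror <- (h$a * h$d) / (h$b * h$c)
  se <- sqrt(1 / h$a + 1 / h$b + 1 / h$c + 1 / h$d)
  low <- exp(log(ror) - z * se)
  high <- exp(log(ror) + z * se)
  bad <- !is.finite(ror)
  ror[bad] <- NA_real_; low[bad] <- NA_real_; high[bad] <- NA_real_
  tibble(ror = ror, ror_low = low, ror_high = high, corrected = h$corrected)
}

#' Proportional reporting ratio and Pearson chi-square
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`.  The chi-square statistic is the Pearson
#' statistic on the 2x2 table with fixed margins,
#' `n (ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)]`, without continuity correction by
#' default (`yates = TRUE` subtracts n/2 from |ad - bc|).  The chi-square is
#' computed on the raw (uncorrected) counts; the PRR uses Haldane-corrected
#' cells when a zero cell would make it undefined.
#'
#' @inheritParams ror_ci
#' @param yates apply the Yates continuity correction to the chi-square.
#' @return tibble with `prr`, `chi2`.
#' @export
prr_chi2 <- function(a, b, c, d, correct = TRUE, yates = FALSE) {
  h <- haldane(a, b, c, d, correct)
  prr <- (h$a / (h$a + h$b)) / (h$c / (h$c + h$d))
  prr[!is.finite(prr)] <- NA_real_
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  num <- abs(a * d - b * c)
  if (isTRUE(yates)) num <- pmax(num - n / 2, 0)
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- ifelse(denom > 0, n * num^2 / denom, NA_real_)
  tibble(prr = prr, chi2 = chi2)
}

#' Evaluate the joint signal criteria on computed statistics
#'
#' The positive-signal definition combines three criteria: (1) at least
#' `min_n` reports (`a >= 3`); (2) lower bound of the 95% CI of the ROR
#' above 1; (3) `PRR >= 2` and `chi2 >= 4`.  `rule = "both"` (default)
#' requires all three; `rule = "either"` requires the report floor plus
#' either the ROR or the PRR criterion.
#'
#' @param stats tibble containing columns `a`, `ror_low`, `prr`, `chi2`.
#' @param min_n report-count floor.
#' @param prr_min,chi2_min PRR criterion thresholds.
#' @param rule `"both"` or `"either"`.
#' @return `stats` with added logical columns `crit_n`, `crit_ror`,
#'   `crit_prr`, `is_signal`.
#' @export
evaluate_signal <- function(stats, min_n = 3, prr_min = 2, chi2_min = 4,
                            rule = c("both", "either")) {
  rule <- match.arg(rule)
  out <- stats %>%
    mutate(crit_n = .data$a >= min_n,
           crit_ror = !is.na(.data$ror_low) & .data$ror_low > 1,
           crit_prr = !is.na(.data$prr) & .data$prr >= prr_min &
             !is.na(.data$chi2) & .data$chi2 >= chi2_min)
  if (rule == "both") {
    mutate(out, is_signal = .data$crit_n & .data$crit_ror & .data$crit_prr)
  } else {
    mutate(out, is_signal = .data$crit_n & (.data$crit_ror | .data$crit_prr))
  }
}

#' Disproportionality analysis over all reported preferred terms
#'
#' For every PT reported at least once with the target drug, builds the 2x2
#' case-level contingency table against the all-other-drugs comparator and
#' computes ROR (with 95% Wald CI), PRR, Pearson chi-square, the per-PT
#' reporting percentage among target-drug cases, and the joint signal flags.
#'
#' @param cases all deduplicated cases with a logical `target` column.
#' @param pt_soc optional PT-to-SOC map (tibble with columns `pt`, `soc`);
#'   unmapped PTs are labelled `"UNMAPPED"`.
#' @inheritParams evaluate_signal
#' @inheritParams ror_ci
#' @inheritParams prr_chi2
#' @return tibble of class `faers_signals`, one row per PT, ordered by
#'   descending report count: `pt`, `soc`, `a`, `b`, `c`, `d`, `n_reports`,
#'   `reporting_pct`, `ror`, `ror_low`, `ror_high`, `corrected`, `prr`,
#'   `chi2`, criteria flags and `is_signal`.
#' @examples
#' tabs <- simulate_faers(sim_config(n_reports = 2000, seed = 42))
#' cases <- assemble_cases(tabs, all_cases = TRUE, quiet = TRUE)
#' detect_signals(cases, pt_soc = default_pt_catalog())
#' @export
detect_signals <- function(cases, pt_soc = NULL, min_n = 3, prr_min = 2,
                           chi2_min = 4, rule = c("both", "either"),
                           correct = TRUE, yates = FALSE, z = 1.96) {
  rule <- match.arg(rule)
  if (!"target" %in% names(cases)) {
    abort("`cases` must carry a logical `target` column (assemble_cases(all_cases = TRUE)).")
  }
  n_target <- sum(cases$target)
  n_other <- sum(!cases$target)
  if (n_target == 0) abort("no target-drug cases present.")

  long <- tibble(caseid = rep(cases$caseid, lengths(cases$pts)),
                 target = rep(cases$target, lengths(cases$pts)),
                 pt = unlist(cases$pts)) %>%
    distinct()
  counts <- long %>%
    count(.data$pt, .data$target) %>%
    pivot_wider(names_from = "target", values_from = "n", values_fill = 0)
  if (!"TRUE" %in% names(counts)) counts$`TRUE` <- 0L
  if (!"FALSE" %in% names(counts)) counts$`FALSE` <- 0L
  res <- counts %>%
    rename(a = "TRUE", c = "FALSE") %>%
    filter(.data$a > 0) %>%
    mutate(b = n_target - .data$a, d = n_other - .data$c,
           n_reports = .data$a,
           reporting_pct = 100 * .data$a / n_target)
  res <- bind_cols(res,
                   ror_ci(res$a, res$b, res$c, res$d, correct = correct, z = z),
                   prr_chi2(res$a, res$b, res$c, res$d, correct = correct,
                            yates = yates))
  res <- evaluate_signal(res, min_n = min_n, prr_min = prr_min,
                         chi2_min = chi2_min, rule = rule)
  if (!is.null(pt_soc)) {
    res <- res %>%
      left_join(distinct(as_tibble(pt_soc)[c("pt", "soc")]), by = "pt") %>%
      mutate(soc = dplyr::coalesce(.data$soc, "UNMAPPED"))
  } else {
    res$soc <- NA_character_
  }
  res <- res %>%
    select("pt", "soc", "a", "b", "c", "d", "n_reports", "reporting_pct",
           "ror", "ror_low", "ror_high", "corrected", "prr", "chi2",
           "crit_n", "crit_ror", "crit_prr", "is_signal") %>%
    arrange(desc(.data$n_reports), .data$pt)
  class(res) <- c("faers_signals", class(res))
  res
}

#' Top-k preferred terms by report count or signal strength
#'
#' @param signals a [detect_signals()] result.
#' @param k number of PTs to keep (`k <= 0` returns an empty tibble).
#' @param by ranking key: `"n_reports"` or `"ror"`.
#' @return tibble of the top `k` rows, descending by the key, ties broken
#'   alphabetically by PT.
#' @export
rank_top_pts <- function(signals, k = 20, by = c("n_reports", "ror")) {
  by <- match.arg(by)
  if (k <= 0) return(signals[0, ])
  signals %>%
    arrange(desc(.data[[by]]), .data$pt) %>%
    head(k)
}

#' Strongest signals within each system organ class
#'
#' Within each SOC, keeps the positive signals (`is_signal`) and returns the
#' top `k` by descending ROR.
#'
#' @param signals a [detect_signals()] result with a `soc` column.
#' @param k signals to keep per SOC.
#' @return tibble grouped rows per SOC, descending ROR within SOC.
#' @export
top_signals_per_soc <- function(signals, k = 3) {
  if (all(is.na(signals$soc)) ||
      all(signals$soc == "UNMAPPED", na.rm = TRUE)) {
    warn("no PT-to-SOC mapping available; all PTs grouped under UNMAPPED")
  }
  signals %>%
    mutate(soc = dplyr::coalesce(.data$soc, "UNMAPPED")) %>%
    filter(.data$is_signal) %>%
    arrange(.data$soc, desc(.data$ror), .data$pt) %>%
    group_by(.data$soc) %>%
    slice_head(n = k) %>%
    ungroup()
}
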