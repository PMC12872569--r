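# Sex-differential signal detection among target-drug reports.
#
# The 2x2 table contrasts females and males *within* the target-drug cohort:
#
#                target AE    all other AE
#   female          a             b
#   male            c             d
#
# ROR = (a/c)/(b/d); ROR > 1 with CI low > 1 marks a female-predominant
# event, ROR < 1 with CI high < 1 a male-predominant one.  Unknown-sex cases
# are excluded here (but kept in the main disproportionality analysis).

#' Build the female-vs-male 2x2 table for one preferred term
#'
#' @param cases target-drug cases (a `faers_cases` tibble); unknown-sex cases
#'   contribute to no cell.
#' @param pt preferred term.
#' @return one-row tibble with `a` (female with PT), `b` (female without),
#'   `c` (male with PT), `d` (male without).
#' @export
build_gender_table <- function(cases, pt) {
  f <- cases$sex == "female"
  m <- cases$sex == "male"
  if (!any(f) || !any(m)) {
    abort("both female and male cases are required for the gender analysis.",
          class = "faersignal_analysis_error")
  }
  has_pt <- map_lgl(cases$pts, ~ pt %in% .x)
  tibble(a = sum(f & has_pt), b = sum(f & !has_pt),
         c = sum(m & has_pt), d = sum(m & !has_pt))
}

#' Gender reporting odds ratio with CI and Wald p-value
#'
#' Point estimate and Wald CI as in [ror_ci()]; the two-sided p-value is the
#' normal tail probability of `z = ln(ROR) / SE(ln ROR)` on the (Haldane-
#' corrected, when needed) cells.
#'
#' @inheritParams ror_ci
#' @return tibble with `ror`, `ror_low`, `ror_high`, `corrected`, `p_raw`.
#' @export
gender_ror <- function(a, b, c, d, correct = TRUE, z = 1.96) {
  h <- haldane(a, b, c, d, correct)
  res <- ror_ci(a, b, c, d, correct = correct, z = z)
  se <- sqrt(1 / h$a + 1 / h$b + 1 / h$c + 1 / h$d)
  zstat <- log(res$ror) / se
  res$p_raw <- 2 * pnorm(-abs(zstat))
  res
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment `p_adj(i) = min_{j >= i} min(1, p(j) * m / j)` on the
#' sorted p-values, mapped back to input order (the standard BH procedure).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, elementwise `>=` the input.
#' @export
fdr_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Sex-differential signal screen over all preferred terms
#'
#' Restricts to female/male target-drug cases, forms the gender 2x2 table for
#' every PT with at least `min_n` reports across both sexes (`a + c >= min_n`,
#' the FDR family), computes the gender ROR, Wald p-value, BH-adjusted
#' p-value, direction label, and volcano-plot coordinates.
#'
#' @param cases target-drug cases.  If a `target` column is present only
#'   target rows are used.
#' @param min_n minimum `a + c` for a PT to enter the FDR family.
#' @param alpha significance level on the adjusted p-value.
#' @inheritParams ror_ci
#' @return tibble of class `gender_signals`: `pt`, `a`, `b`, `c`, `d`, `ror`,
#'   `ror_low`, `ror_high`, `corrected`, `p_raw`, `p_adj`, `direction`
#'   (`"female"`, `"male"`, `"none"`), `log2_ror`, `neglog10_padj`,
#'   `labeled`.
#' @examples
#' tabs <- simulate_faers(sim_config(n_reports = 5000, seed = 7))
#' cases <- assemble_cases(tabs, quiet = TRUE)
#' gender_signals(cases)
#' @export
gender_signals <- function(cases, min_n = 3, alpha = 0.05, correct = TRUE,
                           z = 1.96) {
  if ("target" %in% names(cases)) cases <- filter(cases, .data$target)
  cases <- filter(cases, .data$sex %in% c("female", "male"))
  if (!any(cases$sex == "female") || !any(cases$sex == "male")) {
    abort("both female and male cases are required for the gender analysis.",
          class = "faersignal_analysis_error")
  }
  n_f <- sum(cases$sex == "female")
  n_m <- sum(cases$sex == "male")
  long <- tibble(caseid = rep(cases$caseid, lengths(cases$pts)),
                 sex = rep(cases$sex, lengths(cases$pts)),
                 pt = unlist(cases$pts)) %>%
    distinct()
  counts <- long %>%
    count(.data$pt, .data$sex) %>%
    pivot_wider(names_from = "sex", values_from = "n", values_fill = 0)
  if (!"female" %in% names(counts)) counts$female <- 0L
  if (!"male" %in% names(counts)) counts$male <- 0L
  res <- counts %>%
    rename(a = "female", c = "male") %>%
    mutate(b = n_f - .data$a, d = n_m - .data$c) %>%
    filter(.data$a + .data$c >= min_n)
  if (nrow(res) == 0) {
    abort("no PT reaches the report floor for the gender analysis.",
          class = "faersignal_analysis_error")
  }
  res <- bind_cols(res, gender_ror(res$a, res$b, res$c, res$d,
                                   correct = correct, z = z)) %>%
    mutate(p_adj = fdr_adjust(.data$p_raw),
           direction = dplyr::case_when(
             .data$p_adj < alpha & .data$ror_low > 1 ~ "female",
             .data$p_adj < alpha & .data$ror_high < 1 ~ "male",
             TRUE ~ "none"),
           log2_ror = log2(.data$ror),
           neglog10_padj = -log10(pmax(.data$p_adj, 1e-300)),
           labeled = .data$p_adj < alpha) %>%
    select("pt", "a", "b", "c", "d", "ror", "ror_low", "ror_high",
           "corrected", "p_raw", "p_adj", "direction", "log2_ror",
           "neglog10_padj", "labeled") %>%
    arrange(.data$p_adj, .data$pt)
  class(res) <- c("gender_signals", class(res))
  res
}

#' Volcano-plot coordinates for a gender signal screen
#'
#' @param signals a [gender_signals()] result.
#' @return tibble with `pt`, `x` (log2 ROR), `y` (-log10 adjusted p, floored
#'   at 1e-300), `labeled`.
#' @export
volcano_coordinates <- function(signals) {
  tibble(pt = signals$pt,
         x = signals$log2_ror,
         y = signals$neglog10_padj,
         labeled = signals$labeled)
}
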