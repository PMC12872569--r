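# Time-to-onset (TTO) analysis: interval computation with exclusion
# accounting, descriptive summary, Kaplan-Meier estimation, parametric
# maximum-likelihood fits (Weibull / log-normal / log-logistic), AIC/BIC
# model selection with Anderson-Darling statistics, hazard-regime
# classification from the Weibull shape, and PT-level Kruskal-Wallis
# comparison.

#' Compute time-to-onset records from assembled cases
#'
#' TTO is the whole-day interval from the (earliest) suspect-drug therapy
#' start date to the adverse-event occurrence date.  Cases with a missing
#' event date, missing start date, or an event preceding the start are
#' excluded (tallied, not errors).  A same-day onset (0 days) is remapped to
#' 0.5 days so that log-time models remain defined; set
#' `zero_onset = "exclude"` to drop those cases instead.
#'
#' @param cases a `faers_cases` tibble with `event_dt` and `start_dt`.
#' @param zero_onset `"half_day"` (default) or `"exclude"`.
#' @return tibble of class `tto_records` with `caseid`, `pts` (list-column),
#'   `event_dt`, `start_dt`, `tto_days`, `included`, `exclusion_reason`;
#'   attribute `"tally"` holds the exclusion counts.
#' @export
compute_tto <- function(cases, zero_onset = c("half_day", "exclude")) {
  zero_onset <- match.arg(zero_onset)
  raw_days <- as.numeric(cases$event_dt - cases$start_dt)
  reason <- dplyr::case_when(
    is.na(cases$event_dt) ~ "missing_event_date",
    is.na(cases$start_dt) ~ "missing_start_date",
    raw_days < 0 ~ "negative_interval",
    raw_days == 0 & zero_onset == "exclude" ~ "zero_interval",
    TRUE ~ "none")
  tto <- ifelse(reason == "none",
                ifelse(raw_days == 0, 0.5, raw_days), NA_real_)
  out <- tibble(caseid = cases$caseid,
                pts = cases$pts,
                event_dt = cases$event_dt,
                start_dt = cases$start_dt,
                tto_days = tto,
                included = reason == "none",
                exclusion_reason = reason)
  attr(out, "tally") <- table(factor(reason,
    levels = c("none", "missing_event_date", "missing_start_date",
               "negative_interval", "zero_interval")))
  class(out) <- c("tto_records", class(out))
  out
}

tto_values <- function(x) {
  if (is.numeric(x)) return(x[!is.na(x)])
  stopifnot(is.data.frame(x), "tto_days" %in% names(x))
  if ("included" %in% names(x)) x <- x[x$included, ]
  x$tto_days[!is.na(x$tto_days)]
}

#' Descriptive summary of the TTO distribution
#'
#' Median and interquartile range (type-7 linear-interpolation quantiles) and
#' the onset-window split: within the first month (`<= 30` days), between one
#' month and one year (`31-365`), and beyond one year (`> 365`).
#'
#' @param x a `tto_records` tibble or a numeric vector of onset days.
#' @return one-row tibble: `n`, `median_days`, `q1_days`, `q3_days`,
#'   `n_first_month`, `pct_first_month`, `n_month_to_year`,
#'   `pct_month_to_year`, `n_over_year`, `pct_over_year`.
#' @examples
#' tto_summary(c(10, 100, 212, 1715, 4018, 5000))
#' @export
tto_summary <- function(x) {
  t <- tto_values(x)
  if (length(t) == 0) abort("no included TTO records to summarise.")
  q <- unname(quantile(t, c(0.25, 0.5, 0.75), type = 7))
  n1 <- sum(t <= 30)
  n2 <- sum(t > 30 & t <= 365)
  n3 <- sum(t > 365)
  tibble(n = length(t),
         median_days = q[2], q1_days = q[1], q3_days = q[3],
         n_first_month = n1,
         pct_first_month = round_pct(100 * n1 / length(t)),
         n_month_to_year = n2,
         pct_month_to_year = round_pct(100 * n2 / length(t)),
         n_over_year = n3,
         pct_over_year = round_pct(100 * n3 / length(t)))
}

#' Kaplan-Meier estimate of the event-free curve
#'
#' Every included record is an event (the spontaneous-report framing has no
#' censoring); an optional `status` vector of 0/1 enables right censoring for
#' generality.  The estimate is `S(t) = prod_{t_i <= t} (1 - d_i / n_i)`,
#' computed by [survival::survfit()].  Without censoring the curve equals
#' `1 -` the empirical CDF.
#'
#' @param x a `tto_records` tibble or numeric vector of onset days.
#' @param grid optional time points at which to report the number at risk
#'   (records with `tto_days >= grid`).
#' @param status optional event indicator (1 = event), recycled to length of
#'   the data.
#' @return list of class `faers_km` with `curve` (tibble `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`) and `risk_table` (tibble `time`,
#'   `n_at_risk`), plus `n`.
#' @export
km_estimate <- function(x, grid = NULL, status = NULL) {
  t <- tto_values(x)
  if (length(t) == 0) abort("no included TTO records for the KM estimate.")
  status <- status %||% rep(1, length(t))
  fit <- survival::survfit(survival::Surv(t, status) ~ 1)
  curve <- tibble(time = fit$time, n_risk = fit$n.risk,
                  n_event = fit$n.event, n_censor = fit$n.censor,
                  survival = fit$surv)
  risk_table <- NULL
  if (!is.null(grid)) {
    risk_table <- tibble(time = grid,
                         n_at_risk = map_dbl(grid, ~ sum(t >= .x)))
  }
  structure(list(curve = curve, risk_table = risk_table, n = length(t)),
            class = "faers_km")
}

## ---- parametric fits ------------------------------------------------------

loglik_fun <- function(family) {
  switch(family,
    weibull = function(t, alpha, beta) {
      sum(log(beta) - beta * log(alpha) + (beta - 1) * log(t) -
            (t / alpha)^beta)
    },
    lognormal = function(t, meanlog, sdlog) {
      sum(dlnorm(t, meanlog, sdlog, log = TRUE))
    },
    loglogistic = function(t, alpha, beta) {
      z <- beta * (log(t) - log(alpha))
      sum(log(beta) - log(t) + z - 2 * log1p(exp(z)))
    })
}

cdf_fun <- function(family, params) {
  switch(family,
    weibull = function(t) pweibull(t, shape = params[["beta"]],
                                   scale = params[["alpha"]]),
    lognormal = function(t) plnorm(t, params[["meanlog"]], params[["sdlog"]]),
    loglogistic = function(t) stats::plogis(
      params[["beta"]] * (log(t) - log(params[["alpha"]]))))
}

anderson_darling <- function(t, F) {
  n <- length(t)
  u <- F(sort(t))
  eps <- 1e-12
  u <- pmin(pmax(u, eps), 1 - eps)
  i <- seq_len(n)
  -n - mean((2 * i - 1) * (log(u) + log(1 - rev(u))))
}

#' Fit a parametric time-to-onset model by maximum likelihood
#'
#' Families: Weibull with density
#' `f(t) = (beta/alpha) (t/alpha)^(beta-1) exp(-(t/alpha)^beta)` (`alpha` =
#' scale in days, `beta` = shape); log-normal with parameters `(meanlog,
#' sdlog)` on log time (closed-form MLE); log-logistic with survival
#' `S(t) = 1 / (1 + (t/alpha)^beta)`.  The Weibull and log-logistic
#' likelihoods are maximised over `(log alpha, log beta)` by BFGS with
#' moment-based initialisation from the log-time mean and spread (relative
#' tolerance 1e-10, at most 500 iterations).  Standard errors come from the
#' observed information at the optimum; the Weibull shape CI is Wald on
#' `log beta`.
#'
#' @param x a `tto_records` tibble or numeric vector of positive onset days.
#' @param family `"weibull"`, `"lognormal"`, or `"loglogistic"`.
#' @param shape optional fixed shape (Weibull only): the scale is then the
#'   closed-form MLE `mean(t^shape)^(1/shape)` (with `shape = 1` this is the
#'   exponential mean).
#' @param conf_level confidence level for the shape interval.
#' @return object of class `tto_fit`: `family`, `params` (named), `se_log`
#'   (SEs on the log/parameter scale), `beta_ci` (Weibull), `loglik`, `n`,
#'   `aic`, `bic`, `ad`, `converged`.
#' @examples
#' t <- rweibull(200, shape = 0.7, scale = 1000)
#' fit <- fit_tto(t, "weibull")
#' glance(fit)
#' @export
fit_tto <- function(x, family = c("weibull", "lognormal", "loglogistic"),
                    shape = NULL, conf_level = 0.95) {
  family <- match.arg(family)
  t <- tto_values(x)
  if (any(t <= 0)) abort("all TTO values must be positive.")
  n <- length(t)
  if (n < 2) abort("at least two TTO values are required for a fit.")
  ll <- loglik_fun(family)
  z <- qnorm(1 - (1 - conf_level) / 2)
  lt <- log(t)
  converged <- TRUE
  se_log <- c(NA_real_, NA_real_)
  beta_ci <- c(NA_real_, NA_real_)

  if (family == "lognormal") {
    mu <- mean(lt)
    sigma <- sqrt(mean((lt - mu)^2))
    params <- c(meanlog = mu, sdlog = sigma)
    loglik <- ll(t, mu, sigma)
    se_log <- c(meanlog = sigma / sqrt(n), log_sdlog = sqrt(1 / (2 * n)))
  } else if (!is.null(shape)) {
    stopifnot(family == "weibull", shape > 0)
    alpha <- mean(t^shape)^(1 / shape)
    params <- c(alpha = alpha, beta = shape)
    loglik <- ll(t, alpha, shape)
  } else {
    # moment-type initialisation on log time: for the Weibull,
    # sd(log T) = (pi/sqrt(6)) / beta; for the log-logistic,
    # sd(log T) = (pi/sqrt(3)) / beta
    s <- max(sd(lt), 1e-6)
    beta0 <- if (family == "weibull") (pi / sqrt(6)) / s else
      (pi / sqrt(3)) / s
    alpha0 <- if (family == "weibull")
      exp(mean(lt) + 0.5772156649 / beta0) else exp(mean(lt))
    nll <- function(theta) -ll(t, exp(theta[1]), exp(theta[2]))
    opt <- optim(c(log(alpha0), log(beta0)), nll, method = "BFGS",
                 hessian = TRUE,
                 control = list(reltol = 1e-10, maxit = 500))
    converged <- opt$convergence == 0
    params <- c(alpha = exp(opt$par[1]), beta = exp(opt$par[2]))
    loglik <- -opt$value
    vc <- tryCatch(solve(opt$hessian), error = function(e) NULL)
    if (!is.null(vc) && all(diag(vc) > 0)) {
      se_log <- sqrt(diag(vc))
      names(se_log) <- c("log_alpha", "log_beta")
      beta_ci <- exp(log(params[["beta"]]) + c(-1, 1) * z * se_log[[2]])
    } else {
      converged <- FALSE
    }
  }

  k <- 2
  structure(list(
    family = family,
    params = params,
    se_log = se_log,
    beta_ci = unname(beta_ci),
    loglik = loglik,
    n = n,
    aic = 2 * k - 2 * loglik,
    bic = k * log(n) - 2 * loglik,
    ad = anderson_darling(t, cdf_fun(family, as.list(params))),
    converged = converged
  ), class = "tto_fit")
}

#' @export
print.tto_fit <- function(x, ...) {
  cat(sprintf("Parametric TTO fit (%s), n = %d\n", x$family, x$n))
  print(round(x$params, 4))
  if (x$family == "weibull" && all(is.finite(x$beta_ci))) {
    cat(sprintf("shape 95%% CI: (%.3f, %.3f)\n", x$beta_ci[1], x$beta_ci[2]))
  }
  cat(sprintf("logLik %.2f  AIC %.1f  BIC %.1f  AD %.2f\n",
              x$loglik, x$aic, x$bic, x$ad))
  invisible(x)
}

#' Tidy a parametric TTO fit
#'
#' @param x a `tto_fit` object.
#' @param ... unused.
#' @return tibble with `term`, `estimate`, `conf.low`, `conf.high` (shape CI
#'   for the Weibull fit; `NA` elsewhere).
#' @method tidy tto_fit
#' @export
tidy.tto_fit <- function(x, ...) {
  out <- tibble(term = names(x$params), estimate = unname(x$params),
                conf.low = NA_real_, conf.high = NA_real_)
  if (x$family == "weibull" && all(is.finite(x$beta_ci))) {
    out$conf.low[out$term == "beta"] <- x$beta_ci[1]
    out$conf.high[out$term == "beta"] <- x$beta_ci[2]
  }
  out
}

#' One-row goodness-of-fit summary of a parametric TTO fit
#'
#' @param x a `tto_fit` object.
#' @param ... unused.
#' @return tibble with `family`, `n`, `logLik`, `AIC`, `BIC`, `AD`,
#'   `converged`.
#' @method glance tto_fit
#' @export
glance.tto_fit <- function(x, ...) {
  tibble(family = x$family, n = x$n, logLik = x$loglik, AIC = x$aic,
         BIC = x$bic, AD = x$ad, converged = x$converged)
}

#' Information criteria from a log-likelihood
#'
#' `AIC = 2k - 2 logLik`; `BIC = k log(n) - 2 logLik`.
#'
#' @param loglik log-likelihood at the optimum.
#' @param k number of free parameters (2 for the families fitted here).
#' @param n number of observations.
#' @return one-row tibble with `aic`, `bic`.
#' @export
information_criteria <- function(loglik, k = 2, n) {
  tibble(aic = 2 * k - 2 * loglik, bic = k * log(n) - 2 * loglik)
}

#' Rank candidate parametric models by AIC
#'
#' Accepts either a list of [fit_tto()] objects (which must share the same
#' data size) or a data frame with columns `family` and `aic`.  Lower AIC is
#' better; ties are broken alphabetically by family name.
#'
#' @param fits list of `tto_fit` objects, or a data frame with `family` and
#'   `aic`.
#' @return tibble ordered by ascending AIC with a `rank` column; attribute
#'   `"best_family"` and element one's family give the selected model.
#' @examples
#' select_model(data.frame(family = c("weibull", "loglogistic", "lognormal"),
#'                         aic = c(5138.7, 5239.4, 5248.9)))
#' @export
select_model <- function(fits) {
  if (is.data.frame(fits)) {
    tab <- as_tibble(fits)
    stopifnot(all(c("family", "aic") %in% names(tab)))
  } else {
    stopifnot(length(fits) >= 2,
              all(map_lgl(fits, inherits, "tto_fit")))
    ns <- map_dbl(fits, "n")
    if (length(unique(ns)) != 1) {
      abort("all fits must be computed on the same records.")
    }
    tab <- bind_rows(lapply(fits, glance)) %>%
      rename(aic = "AIC", bic = "BIC", ad = "AD", loglik = "logLik")
  }
  tab <- tab %>% arrange(.data$aic, .data$family) %>%
    mutate(rank = dplyr::row_number())
  attr(tab, "best_family") <- tab$family[1]
  tab
}

#' Classify the hazard regime from a Weibull shape estimate
#'
#' With shape `beta` and its 95% CI: `beta < 1` with CI upper limit below 1
#' means a hazard decreasing over time (early-failure pattern); `beta > 1`
#' with CI lower limit above 1 an increasing hazard (wear-out); anything else
#' is consistent with a constant hazard (random failure).
#'
#' @param fit a Weibull `tto_fit`, or a numeric shape estimate.
#' @param ci_low,ci_high CI bounds when `fit` is numeric.
#' @return one of `"decreasing/early-failure"`, `"constant/random"`,
#'   `"increasing/wear-out"`.
#' @examples
#' classify_hazard(0.62, 0.56, 0.69)
#' @export
classify_hazard <- function(fit, ci_low = NULL, ci_high = NULL) {
  if (inherits(fit, "tto_fit")) {
    if (fit$family != "weibull") {
      abort("hazard classification requires a Weibull fit.")
    }
    beta <- fit$params[["beta"]]
    ci_low <- fit$beta_ci[1]
    ci_high <- fit$beta_ci[2]
  } else {
    beta <- fit
  }
  if (beta < 1 && ci_high < 1) return("decreasing/early-failure")
  if (beta > 1 && ci_low > 1) return("increasing/wear-out")
  "constant/random"
}

## ---- PT-level comparisons -------------------------------------------------

expand_tto_by_pt <- function(tto, pts = NULL) {
  stopifnot(is.data.frame(tto), all(c("pts", "tto_days") %in% names(tto)))
  x <- tto[tto$included & !is.na(tto$tto_days), ]
  long <- tibble(caseid = rep(x$caseid, lengths(x$pts)),
                 pt = unlist(x$pts),
                 tto_days = rep(x$tto_days, lengths(x$pts))) %>%
    distinct()
  if (!is.null(pts)) long <- filter(long, .data$pt %in% pts)
  long
}

#' Kruskal-Wallis comparison of TTO distributions across preferred terms
#'
#' Each included record contributes its onset time to each of its PTs (a
#' multi-PT case appears in several groups); restrict with `pts` to compare
#' within one organ class.  The statistic uses the standard tie correction
#' and the chi-square approximation for the p-value.
#'
#' @param tto a `tto_records` tibble.
#' @param pts optional character vector restricting the PT groups.
#' @param min_n minimum group size for a PT to enter the test.
#' @return one-row tibble: `n_groups`, `n_obs`, `statistic`, `df`, `p_value`.
#' @export
tto_kruskal <- function(tto, pts = NULL, min_n = 1) {
  long <- expand_tto_by_pt(tto, pts) %>%
    add_count(.data$pt) %>%
    filter(.data$n >= min_n)
  if (length(unique(long$pt)) < 2) {
    abort("at least two PT groups are required for the Kruskal-Wallis test.",
          class = "faersignal_analysis_error")
  }
  kt <- kruskal.test(long$tto_days, factor(long$pt))
  tibble(n_groups = length(unique(long$pt)), n_obs = nrow(long),
         statistic = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value)
}

#' Mean time-to-onset per preferred term
#'
#' @param tto a `tto_records` tibble.
#' @param pts optional character vector restricting the PTs.
#' @param min_n groups with fewer records are flagged (`small = TRUE`), not
#'   dropped.
#' @return tibble with `pt`, `n`, `mean_days`, `small`.
#' @export
mean_tto_by_pt <- function(tto, pts = NULL, min_n = 3) {
  expand_tto_by_pt(tto, pts) %>%
    summarise(n = dplyr::n(), mean_days = mean(.data$tto_days), .by = "pt") %>%
    mutate(small = .data$n < min_n) %>%
    arrange(desc(.data$mean_days))
}
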