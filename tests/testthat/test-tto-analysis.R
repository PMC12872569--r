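test_that("TTO intervals apply the exclusion and same-day rules", {
  cases <- tibble::tibble(
    caseid = as.character(1:5),
    pts = replicate(5, "PT", simplify = FALSE),
    event_dt = as.Date(c("2020-01-31", "2019-12-31", NA, "2020-06-01",
                         "2020-01-01")),
    start_dt = as.Date(c("2020-01-01", "2020-01-01", "2020-01-01", NA,
                         "2020-01-01")))
  tto <- compute_tto(cases)
  expect_equal(tto$tto_days[1], 30)
  expect_identical(tto$exclusion_reason[2], "negative_interval")
  expect_identical(tto$exclusion_reason[3], "missing_event_date")
  expect_identical(tto$exclusion_reason[4], "missing_start_date")
  expect_equal(tto$tto_days[5], 0.5)       # same-day onset remapped
  expect_identical(tto$included, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_identical(tto$included, tto$exclusion_reason == "none")
  # configurable exclusion of same-day onsets
  strict <- compute_tto(cases, zero_onset = "exclude")
  expect_identical(strict$exclusion_reason[5], "zero_interval")
  tally <- attr(tto, "tally")
  expect_identical(unname(as.integer(tally["none"])), 2L)
})

test_that("TTO summary gives interpolated quartiles and onset-window bins", {
  s <- tto_summary(c(100, 212, 1715, 4018, 5000))
  expect_equal(s$median_days, 1715)
  expect_equal(s$q1_days, unname(quantile(c(100, 212, 1715, 4018, 5000), .25)))
  same <- tto_summary(rep(50, 10))
  expect_equal(same$q3_days - same$q1_days, 0)
  bins <- tto_summary(c(10, 30, 31, 365, 366, 1000))
  expect_identical(bins$n_first_month, 2L)      # right-closed at 30
  expect_identical(bins$n_month_to_year, 2L)    # (30, 365]
  expect_identical(bins$n_over_year, 2L)
})

test_that("Kaplan-Meier matches the textbook estimate and 1 - ECDF", {
  km <- km_estimate(c(1, 2, 3))
  expect_equal(km$curve$survival, c(2 / 3, 1 / 3, 0))
  tied <- km_estimate(c(2, 2, 4))
  expect_equal(tied$curve$survival[tied$curve$time == 2], 1 / 3)
  # no censoring: KM coincides with the empirical survival function
  set.seed(4)
  t <- round(rweibull(400, 0.6, 1500)) + 0.5
  km <- km_estimate(t, grid = c(0, 500, 1000, 5000))
  emp <- 1 - stats::ecdf(t)(km$curve$time)
  expect_equal(km$curve$survival, emp, tolerance = 1e-12)
  expect_equal(km$risk_table$n_at_risk,
               sapply(c(0, 500, 1000, 5000), function(g) sum(t >= g)))
  expect_true(all(diff(km$curve$survival) <= 0))
  expect_equal(dplyr::last(km$curve$survival), 0)
})

test_that("fixed-shape Weibull reduces to the exponential closed form", {
  fit <- fit_tto(c(1, 2, 3, 4), "weibull", shape = 1)
  expect_equal(fit$params[["alpha"]], 2.5)     # exponential mean
  expect_equal(fit$params[["beta"]], 1)
})

test_that("information criteria identities hold exactly", {
  ic <- information_criteria(-2567.35, k = 2, n = 297)
  expect_equal(ic$aic, 5138.7)
  expect_equal(ic$bic, 2 * log(297) + 2 * 2567.35)
  set.seed(5)
  fit <- fit_tto(rweibull(100, 0.8, 1000), "weibull")
  expect_equal(fit$aic, 2 * 2 - 2 * fit$loglik)
  expect_equal(fit$bic - fit$aic, 2 * (log(fit$n) - 2))
})

test_that("Weibull ML recovers generating parameters at large n", {
  set.seed(6)
  t <- rweibull(10000, shape = 0.62, scale = 3097)
  fit <- fit_tto(t, "weibull")
  expect_lt(abs(fit$params[["beta"]] - 0.62), 0.02)
  expect_lt(abs(fit$params[["alpha"]] - 3097) / 3097, 0.05)
  expect_true(fit$beta_ci[1] <= fit$params[["beta"]],
              fit$params[["beta"]] <= fit$beta_ci[2])
})

test_that("the ML fits agree with an independent AFT parameterization", {
  set.seed(7)
  t <- rweibull(500, shape = 0.7, scale = 2000)
  fit <- fit_tto(t, "weibull")
  sr <- survival::survreg(survival::Surv(t, rep(1, 500)) ~ 1,
                          dist = "weibull")
  expect_equal(fit$params[["alpha"]], exp(unname(coef(sr))), tolerance = 1e-4)
  expect_equal(fit$params[["beta"]], 1 / sr$scale, tolerance = 1e-4)
  expect_equal(fit$loglik, sr$loglik[1], tolerance = 1e-6)

  ln <- fit_tto(t, "lognormal")
  srln <- survival::survreg(survival::Surv(t, rep(1, 500)) ~ 1,
                            dist = "lognormal")
  expect_equal(ln$params[["meanlog"]], unname(coef(srln)), tolerance = 1e-5)
  expect_equal(ln$loglik, srln$loglik[1], tolerance = 1e-6)

  llg <- fit_tto(t, "loglogistic")
  srllg <- survival::survreg(survival::Surv(t, rep(1, 500)) ~ 1,
                             dist = "loglogistic")
  expect_equal(llg$params[["alpha"]], exp(unname(coef(srllg))),
               tolerance = 1e-4)
  expect_equal(llg$loglik, srllg$loglik[1], tolerance = 1e-6)
})

test_that("the likelihood is a local maximum at the reported estimates", {
  set.seed(9)
  t <- rweibull(300, 0.6, 1500)
  fit <- fit_tto(t, "weibull")
  ll <- function(alpha, beta) {
    sum(log(beta) - beta * log(alpha) + (beta - 1) * log(t) -
          (t / alpha)^beta)
  }
  at_opt <- ll(fit$params[["alpha"]], fit$params[["beta"]])
  for (i in 1:100) {
    eps <- runif(2, -0.05, 0.05)
    perturbed <- ll(fit$params[["alpha"]] * exp(eps[1]),
                    fit$params[["beta"]] * exp(eps[2]))
    expect_lte(perturbed, at_opt + 1e-8)
  }
})

test_that("model ranking is by ascending AIC with a stable family tie-break", {
  printed <- data.frame(family = c("weibull", "loglogistic", "lognormal"),
                        aic = c(5138.7, 5239.4, 5248.9))
  ranked <- select_model(printed)
  expect_identical(attr(ranked, "best_family"), "weibull")
  expect_identical(ranked$family, c("weibull", "loglogistic", "lognormal"))
  tied <- data.frame(family = c("lognormal", "weibull"), aic = c(10, 10))
  expect_identical(select_model(tied)$family, c("lognormal", "weibull"))
  set.seed(10)
  t <- rweibull(200, 0.7, 900)
  fits <- lapply(c("weibull", "lognormal", "loglogistic"), fit_tto, x = t)
  expect_error(select_model(list(fits[[1]], fit_tto(t[1:100], "lognormal"))),
               "same records")
  ranked <- select_model(fits)
  expect_identical(ranked$rank, 1:3)
})

test_that("hazard classification reads the shape and its CI", {
  expect_identical(classify_hazard(0.62, 0.56, 0.69),
                   "decreasing/early-failure")
  expect_identical(classify_hazard(1.00, 0.9, 1.1), "constant/random")
  expect_identical(classify_hazard(1.5, 1.2, 1.8), "increasing/wear-out")
  # boundary: beta < 1 but CI crossing 1 stays "constant/random"
  expect_identical(classify_hazard(0.9, 0.7, 1.05), "constant/random")
})

test_that("Kruskal-Wallis matches the hand rank computation", {
  tto <- make_tto(c(1, 2, 3, 4, 5, 6),
                  pts = list("A", "A", "A", "B", "B", "B"))
  kw <- tto_kruskal(tto)
  expect_equal(kw$statistic, 27 / 7, tolerance = 1e-12)  # R1=6, R2=15
  expect_equal(kw$df, 1)
  ident <- make_tto(c(1, 2, 3, 1, 2, 3),
                    pts = list("A", "A", "A", "B", "B", "B"))
  expect_equal(tto_kruskal(ident)$statistic, 0)
  one_group <- make_tto(c(1, 2, 3))
  expect_error(tto_kruskal(one_group), class = "faersignal_analysis_error")
})

test_that("per-PT means expand multi-PT cases into each group", {
  tto <- make_tto(c(100, 300, 50),
                  pts = list("PT_A", c("PT_A", "PT_B"), "PT_B"))
  m <- mean_tto_by_pt(tto)
  expect_equal(m$mean_days[m$pt == "PT_A"], 200)
  expect_equal(m$mean_days[m$pt == "PT_B"], 175)
  expect_true(all(m$small))                 # n < 3 flagged
  expect_false("PT_C" %in% m$pt)            # empty group absent
})
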