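test_that("contingency cells count unique cases, not PT rows", {
  cases <- mini_cases(target = c(TRUE, TRUE, FALSE, FALSE),
                      pts = list("PT1", "PT2", "PT1", "PT2"))
  expect_identical(build_contingency(cases, "PT1"),
                   tibble::tibble(a = 1L, b = 1L, c = 1L, d = 1L))
  # a PT repeated within one case still counts once
  rep_case <- mini_cases(TRUE, list(c("PT1", "PT1")))
  expect_identical(build_contingency(rep_case, "PT1")$a, 1L)
  # PT absent from every case: a = 0, not an error
  expect_identical(build_contingency(cases, "PT9")$a, 0L)
})

test_that("ROR point estimate and Wald CI match hand computation", {
  res <- ror_ci(5, 5, 5, 5)
  expect_equal(res$ror, 1)
  expect_true(res$ror_low < 1 && res$ror_high > 1)

  res <- ror_ci(10, 90, 100, 9900)
  expect_equal(res$ror, 11)
  # SE(ln ROR) = sqrt(1/10 + 1/90 + 1/100 + 1/9900) = 0.34816
  expect_equal(res$ror_low, 5.56, tolerance = 1e-3)
  expect_equal(res$ror_high, 21.77, tolerance = 1e-3)
  expect_false(res$corrected)
})

test_that("zero cells trigger the Haldane correction or an NA marker", {
  res <- ror_ci(3, 10, 0, 100)
  expect_true(res$corrected)
  expect_true(is.finite(res$ror))
  # by definition of the corrected estimate
  expect_equal(res$ror, (3.5 * 100.5) / (10.5 * 0.5))
  off <- ror_ci(3, 10, 0, 100, correct = FALSE)
  expect_true(is.na(off$ror))
})

test_that("PRR and Pearson chi-square match brute-force oracles", {
  res <- prr_chi2(5, 5, 5, 5)
  expect_equal(res$prr, 1)
  expect_equal(res$chi2, 0)

  res <- prr_chi2(10, 90, 100, 9900)
  expect_equal(res$prr, 10)
  expect_equal(res$chi2, chi2_brute(10, 90, 100, 9900))
  expect_equal(res$chi2, 74.45, tolerance = 1e-3)

  # chi-square is invariant under a simultaneous row and column swap
  expect_equal(prr_chi2(10, 90, 100, 9900)$chi2,
               prr_chi2(9900, 100, 90, 10)$chi2)
})

test_that("statistics satisfy the algebraic identities on random tables", {
  set.seed(42)
  for (i in 1:200) {
    cells <- rpois(4, lambda = sample(c(2, 20, 200), 4, replace = TRUE)) + 1
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    r <- ror_ci(a, b, c, d)
    p <- prr_chi2(a, b, c, d)
    # ROR / PRR = d(a+b) / (b(c+d)) exactly
    expect_equal(r$ror / p$prr, d * (a + b) / (b * (c + d)),
                 tolerance = 1e-12)
    expect_equal(p$chi2, chi2_brute(a, b, c, d), tolerance = 1e-9)
    # CI brackets the point estimate
    expect_true(r$ror_low <= r$ror && r$ror <= r$ror_high)
  }
})

test_that("proportional tables give ROR = PRR = 1 and ROR increases in a", {
  # a/(a+b) = c/(c+d) => both measures 1
  r <- ror_ci(20, 80, 60, 240)
  expect_equal(r$ror, 1)
  expect_equal(prr_chi2(20, 80, 60, 240)$prr, 1)
  # monotonicity in a, holding b, c, d
  rors <- sapply(c(5, 10, 20, 40), function(a) ror_ci(a, 50, 30, 300)$ror)
  expect_true(all(diff(rors) > 0))
})

test_that("the joint signal criteria combine report floor, ROR CI and PRR", {
  stats <- tibble::tibble(
    a = c(2, 5, 428, 5, 5),
    ror = c(100, 3, 441736.81, 3, 3),
    ror_low = c(50, 1.2, 182887.86, 0.9, 1.2),
    prr = c(90, 2.5, 425254.99, 2.5, 1.5),
    chi2 = c(50, 5, 1e6, 5, 5))
  out <- evaluate_signal(stats)
  # a = 2 fails the report floor no matter how large the ROR
  expect_false(out$is_signal[1])
  expect_true(out$is_signal[2])
  # published pigmentary-maculopathy fixture: all three criteria met
  expect_true(out$is_signal[3])
  expect_false(out$is_signal[4])   # CI low <= 1
  expect_false(out$is_signal[5])   # PRR < 2
  expect_identical(out$is_signal,
                   out$crit_n & out$crit_ror & out$crit_prr)
  either <- evaluate_signal(stats, rule = "either")
  expect_true(either$is_signal[4])  # PRR criterion alone suffices
})

test_that("signal screen cells match a brute-force recount on synthetic data", {
  tabs <- simulate_faers(sim_config(n_reports = 1500, seed = 31))
  cases <- assemble_cases(tabs, all_cases = TRUE, quiet = TRUE)
  sig <- detect_signals(cases, pt_soc = default_pt_catalog())
  for (pt in sample(sig$pt, 5)) {
    expect_identical(
      unlist(sig[sig$pt == pt, c("a", "b", "c", "d")], use.names = FALSE),
      unlist(build_contingency(cases, pt), use.names = FALSE))
  }
  expect_equal(sig$reporting_pct, 100 * sig$a / sum(cases$target))
})

test_that("PT ranking is by key with alphabetical tie-break", {
  sig <- tibble::tibble(pt = c("C", "B", "A"), n_reports = c(5, 3, 9),
                        ror = c(2, 8, 4))
  expect_identical(rank_top_pts(sig, 2)$pt, c("A", "C"))
  ties <- tibble::tibble(pt = c("B", "A"), n_reports = c(3, 3), ror = c(1, 1))
  expect_identical(rank_top_pts(ties, 2)$pt, c("A", "B"))
  expect_identical(nrow(rank_top_pts(sig, 0)), 0L)
  expect_identical(rank_top_pts(sig, 2, by = "ror")$pt, c("B", "A"))
})

test_that("per-SOC ranking keeps only signals, top-k by ROR", {
  sig <- tibble::tibble(
    pt = LETTERS[1:6],
    soc = c("S1", "S1", "S1", "S2", "S2", NA),
    ror = c(9, 5, 7, 3, 4, 10),
    is_signal = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
  out <- top_signals_per_soc(sig, k = 2)
  expect_identical(out$pt[out$soc == "S1"], c("A", "C"))
  expect_identical(out$pt[out$soc == "S2"], "D")
  expect_identical(out$pt[out$soc == "UNMAPPED"], "F")
})

test_that("an injected strong association ranks first among signals by ROR", {
  cat_tbl <- default_pt_catalog()
  sm <- tibble::tibble(drug = "TARGET", pt = "COLON DYSPLASIA",
                       multiplier = 500)
  cfg <- sim_config(n_reports = 8000, signal_multipliers = sm,
                    gender_pt_multipliers = NULL, seed = 17)
  cases <- assemble_cases(simulate_faers(cfg), all_cases = TRUE, quiet = TRUE)
  sig <- detect_signals(cases, pt_soc = cat_tbl)
  hits <- sig[sig$is_signal, ]
  expect_identical(hits$pt[which.max(hits$ror)], "COLON DYSPLASIA")
})
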