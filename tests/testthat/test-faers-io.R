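test_that("date parsing accepts only complete valid calendar dates", {
  expect_identical(parse_faers_date("20200131"), as.Date("2020-01-31"))
  expect_identical(parse_faers_date("202001"), as.Date(NA))   # partial
  expect_identical(parse_faers_date("20200230"), as.Date(NA)) # invalid day
  expect_identical(parse_faers_date(c("", "2020", NA)), rep(as.Date(NA), 3))
  expect_identical(parse_faers_date("20200315"), as.Date("2020-03-15"))
})

test_that("table parsing maps fields and flags missing required columns", {
  txt <- "primaryid$caseid$fda_dt\n1$100$20200315\n2$101$202003\n"
  tab <- parse_faers_table(txt, "demo")
  expect_identical(nrow(tab), 2L)
  expect_identical(parse_faers_date(tab$fda_dt)[1], as.Date("2020-03-15"))
  expect_true(is.na(parse_faers_date(tab$fda_dt)[2]))  # partial retained as NA
  expect_error(parse_faers_table("primaryid$fda_dt\n1$20200101\n", "demo"),
               "caseid", class = "faersignal_schema_error")
  # empty stream -> empty collection
  expect_identical(nrow(parse_faers_table("primaryid$caseid$fda_dt\n", "demo")),
                   0L)
})

test_that("deduplication keeps the latest FDA_DT, then the highest PRIMARYID", {
  demo <- tibble::tibble(
    primaryid = c("A", "B"), caseid = c("1", "1"),
    fda_dt = c("20200101", "20200301"))
  expect_identical(deduplicate(demo)$primaryid, "B")

  tie <- tibble::tibble(
    primaryid = c("3", "10"), caseid = c("1", "1"),
    fda_dt = c("20200301", "20200301"))
  expect_identical(deduplicate(tie)$primaryid, "10")  # numeric, not "3" > "10"

  nas <- tibble::tibble(
    primaryid = c("5", "4"), caseid = c("1", "1"),
    fda_dt = c("", "20200301"))
  expect_identical(deduplicate(nas)$primaryid, "4")   # NA date sorts lowest
})

test_that("deduplication is idempotent and never grows on synthetic data", {
  tabs <- simulate_faers(sim_config(n_reports = 400, duplicate_rate = 0.5,
                                    seed = 21))
  demo <- tabs$demo
  names(demo) <- tolower(names(demo))
  d1 <- deduplicate(demo)
  expect_lte(nrow(d1), nrow(demo))
  expect_identical(deduplicate(d1), d1)
  # ground truth: the generator marks the intended surviving version
  truth <- attr(tabs, "truth")
  expect_setequal(d1$primaryid, truth$primaryid)
})

test_that("primary-suspect matching normalizes names and requires role PS", {
  drug <- tibble::tibble(
    primaryid = c("1", "2", "3", "4"),
    drugname = c(" elmiron  ", "ELMIRON", "PENTOSAN  POLYSULFATE SODIUM",
                 "ASPIRIN"),
    role_cod = c("PS", "C", "PS", "PS"))
  hit <- match_primary_suspect(drug, c("ELMIRON", "PENTOSAN POLYSULFATE SODIUM"))
  expect_setequal(hit, c("1", "3"))      # concomitant role excluded
  expect_error(match_primary_suspect(drug, character(0)),
               class = "faersignal_config_error")
})

test_that("matched set equals generator ground truth", {
  tabs <- simulate_faers(sim_config(n_reports = 500, seed = 2))
  truth <- attr(tabs, "truth")
  drug <- tabs$drug
  names(drug) <- tolower(names(drug))
  drug <- drug[drug$primaryid %in% truth$primaryid, ]  # latest versions
  hit <- match_primary_suspect(drug, pps_synonyms())
  expect_setequal(hit, truth$primaryid[truth$is_target])
})

test_that("case assembly resolves duplicates, PT sets and therapy starts", {
  cfg <- sim_config(n_reports = 200, duplicate_rate = 0.5, target_fraction = 1,
                    seed = 13)
  tabs <- simulate_faers(cfg)
  cases <- assemble_cases(tabs, quiet = TRUE)
  expect_identical(nrow(cases), 200L)           # one case per CASEID
  expect_identical(anyDuplicated(cases$caseid), 0L)
  truth <- attr(tabs, "truth")
  m <- match(cases$caseid, truth$caseid)
  expect_identical(cases$primaryid, truth$primaryid[m])
  # per-case PT sets equal generated ground truth
  expect_identical(cases$pts, lapply(truth$pts[m], sort))
  # sex and typed demographics
  expect_identical(cases$sex, truth$sex[m])
})

test_that("earliest parseable therapy start date is used", {
  tabs <- list(
    demo = tibble::tibble(primaryid = "1", caseid = "1", fda_dt = "20200601",
                          event_dt = "20200115", sex = "F", age = "40",
                          age_cod = "YR", rept_cod = "MD", occr_country = "US"),
    drug = tibble::tibble(primaryid = "1", drugname = "ELMIRON",
                          role_cod = "PS"),
    reac = tibble::tibble(primaryid = "1", pt = "MACULOPATHY"),
    outc = tibble::tibble(primaryid = character(0), outc_cod = character(0)),
    ther = tibble::tibble(primaryid = c("1", "1", "1"),
                          drugname = c("ELMIRON", "ELMIRON", "ELMIRON"),
                          start_dt = c("20190101", "20180601", "201301")))
  cases <- assemble_cases(tabs, quiet = TRUE)
  expect_identical(cases$start_dt, as.Date("2018-06-01"))
})

test_that("age units convert to years and sex codes map to labels", {
  tabs <- list(
    demo = tibble::tibble(primaryid = as.character(1:5),
                          caseid = as.character(1:5),
                          fda_dt = rep("20200601", 5),
                          event_dt = rep("", 5),
                          sex = c("F", "M", "", "F", "M"),
                          age = c("480", "5", "30", "abc", "200"),
                          age_cod = c("MON", "DEC", "YR", "YR", "YR"),
                          rept_cod = rep("CN", 5),
                          occr_country = rep("US", 5)),
    drug = tibble::tibble(primaryid = as.character(1:5),
                          drugname = rep("ELMIRON", 5),
                          role_cod = rep("PS", 5)),
    reac = tibble::tibble(primaryid = as.character(1:5),
                          pt = rep("NAUSEA", 5)),
    outc = tibble::tibble(primaryid = character(0), outc_cod = character(0)),
    ther = tibble::tibble(primaryid = character(0), drugname = character(0),
                          start_dt = character(0)))
  cases <- assemble_cases(tabs, quiet = TRUE)
  expect_equal(cases$age_years, c(40, 50, 30, NA, NA))  # 200 yr out of range
  expect_identical(cases$sex, c("female", "male", "unknown", "female", "male"))
})

test_that("age filtering keeps documented ages at or above the threshold", {
  cases <- tibble::tibble(caseid = c("1", "2", "3"),
                          age_years = c(15, 16, NA))
  kept <- filter_by_age(cases, 16)
  expect_identical(kept$caseid, "2")
  all_known <- tibble::tibble(caseid = c("1", "2"), age_years = c(20, 30))
  expect_identical(filter_by_age(all_known, 0), all_known)  # identity
})
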