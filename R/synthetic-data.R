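# Synthetic FAERS-like data generator.
#
# Emulates the multi-table quarterly ASCII structure of a spontaneous
# reporting system with known, configurable statistical structure: injected
# drug-event association multipliers, a heavily female-skewed reporting
# population, duplicate case versions, partial/missing dates, Weibull (or
# log-normal / log-logistic) time-to-onset, and FDA outcome codes.  Every
# downstream stage of the package can therefore be tested against ground
# truth carried alongside the generated tables.

#' Synonym list for the reference suspect drug
#'
#' The twelve trade/generic name variants under which pentosan polysulfate
#' sodium appears in spontaneous reports.  Used as the default suspect-drug
#' search list throughout the package.
#'
#' @return character vector of drug name variants.
#' @export
pps_synonyms <- function() {
  c("ELMIRON",
    "ELMIRON BLADDER",
    "ELMIRON CAP",
    "ELMIRON CAPSULE",
    "ELMIRON 100",
    "ELMIRON 100MG ORAL",
    "ELMIRON PENTOSAN POLYSULFATE SODIUM 100 MG",
    "ELMIRON PENTOSAN POLYSULFATE SODIUM",
    "PENTOSAN POLYSULFATE ELMIRON",
    "PENTOSAN POLYSULFATE SODIUM",
    "PENTOSAN POLYSULFATE SODIUM CAPSULE",
    "PENTOSAN POLYSULFATE SODIUM 100 MG")
}

#' Default preferred-term catalogue with SOC mapping and baseline rates
#'
#' A compact MedDRA-like catalogue covering the organ classes that dominate
#' the reference drug's safety profile (eye disorders, skin, psychiatric,
#' gastrointestinal, renal/urinary, nervous system, general).  `base_rate` is
#' the per-report Bernoulli probability of the PT in background reports.
#'
#' @return tibble with columns `pt`, `soc`, `base_rate`.
#' @export
default_pt_catalog <- function() {
  tibble::tribble(
    ~pt,                            ~soc,                                        ~base_rate,
    "MACULOPATHY",                  "Eye disorders",                             0.0004,
    "PIGMENTARY MACULOPATHY",       "Eye disorders",                             0.0002,
    "RETINAL PIGMENTATION",         "Eye disorders",                             0.0002,
    "RETINAL DYSTROPHY",            "Eye disorders",                             0.0002,
    "MACULAR DEGENERATION",         "Eye disorders",                             0.0010,
    "VISUAL IMPAIRMENT",            "Eye disorders",                             0.0050,
    "ALOPECIA",                     "Skin and subcutaneous tissue disorders",    0.0100,
    "DEPRESSION",                   "Psychiatric disorders",                     0.0150,
    "ANXIETY",                      "Psychiatric disorders",                     0.0150,
    "NAUSEA",                       "Gastrointestinal disorders",                0.0300,
    "DIARRHOEA",                    "Gastrointestinal disorders",                0.0250,
    "ABDOMINAL DISCOMFORT",         "Gastrointestinal disorders",                0.0120,
    "COLON DYSPLASIA",              "Gastrointestinal disorders",                0.0001,
    "BLADDER PAIN",                 "Renal and urinary disorders",               0.0005,
    "URINARY BLADDER HAEMORRHAGE",  "Renal and urinary disorders",               0.0004,
    "HEADACHE",                     "Nervous system disorders",                  0.0300,
    "PAIN",                         "General disorders",                         0.0250,
    "FATIGUE",                      "General disorders",                         0.0200)
}

default_signal_multipliers <- function() {
  tibble::tribble(
    ~drug,     ~pt,                       ~multiplier,
    "TARGET",  "MACULOPATHY",             300,
    "TARGET",  "PIGMENTARY MACULOPATHY",  400,
    "TARGET",  "RETINAL PIGMENTATION",    250,
    "TARGET",  "RETINAL DYSTROPHY",       150,
    "TARGET",  "MACULAR DEGENERATION",    40,
    "TARGET",  "VISUAL IMPAIRMENT",       8,
    "TARGET",  "ALOPECIA",                4,
    "TARGET",  "DEPRESSION",              2.5,
    "TARGET",  "ANXIETY",                 2.5,
    "TARGET",  "COLON DYSPLASIA",         80,
    "TARGET",  "BLADDER PAIN",            30)
}

default_gender_multipliers <- function() {
  tibble::tribble(
    ~sex,     ~pt,                           ~multiplier,
    "female", "MACULOPATHY",                 3,
    "female", "PIGMENTARY MACULOPATHY",      3,
    "male",   "DIARRHOEA",                   3,
    "male",   "ABDOMINAL DISCOMFORT",        3,
    "male",   "URINARY BLADDER HAEMORRHAGE", 4)
}

#' Build a simulation configuration
#'
#' Returns a validated configuration for [simulate_faers()].  The defaults
#' emulate the reporting profile of the reference pharmacovigilance cohort:
#' sex mix 87.3% female / 7.1% male / 5.6% unknown, Weibull time-to-onset
#' with scale 3097 days and shape 0.62 (median about 1715 days), FDA outcome
#' code frequencies dominated by "other serious", and strongly eye-disorder-
#' skewed signal multipliers for the target drug.
#'
#' @param n_reports number of distinct cases to generate.
#' @param target_synonyms character vector of name variants for the target
#'   drug (all are matched as the same drug identity `"TARGET"`).
#' @param background_drugs character vector of comparator drug names.
#' @param pt_catalog tibble with columns `pt`, `soc`, `base_rate`.
#' @param signal_multipliers tibble `(drug, pt, multiplier)`; `drug` may be
#'   `"TARGET"` (any target synonym) or a background drug name.  Reporting
#'   rate for that drug-PT pair is `base_rate * multiplier`.
#' @param female_fraction,male_fraction,unknown_sex_fraction sex mix; must
#'   sum to 1.
#' @param gender_pt_multipliers tibble `(sex, pt, multiplier)` applied on top
#'   of the drug multipliers; `sex` is `"female"` or `"male"`.
#' @param tto_family one of `"weibull"`, `"lognormal"`, `"loglogistic"`.
#' @param tto_params named numeric: for weibull and loglogistic
#'   `c(scale=, shape=)` (scale in days); for lognormal `c(meanlog=, sdlog=)`.
#' @param duplicate_rate fraction of cases emitted as two report versions
#'   sharing a CASEID with distinct PRIMARYID/FDA_DT.
#' @param missing_event_date_rate,partial_date_rate probability that a
#'   generated EVENT_DT string is blanked, or truncated to `YYYYMM`.
#' @param missing_start_date_rate probability that START_DT is blanked.
#' @param target_fraction fraction of reports whose suspect drug is the
#'   target; high relative to a real database so that signal-detection power
#'   is reached at simulation sizes of tens of thousands rather than tens of
#'   millions of reports.
#' @param outcome_code_probs named probabilities over FDA outcome codes
#'   `DE, LT, HO, DS, CA, OT` plus `none` (no OUTC record); must sum to 1.
#' @param age_unknown_rate probability that AGE is missing.
#' @param seed integer seed; fixed seed gives bit-identical tables.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_reports = 10000,
                       target_synonyms = pps_synonyms(),
                       background_drugs = c("ASPIRIN", "IBUPROFEN", "METFORMIN",
                                            "LISINOPRIL", "OMEPRAZOLE",
                                            "ATORVASTATIN", "SERTRALINE"),
                       pt_catalog = default_pt_catalog(),
                       signal_multipliers = default_signal_multipliers(),
                       female_fraction = 0.873,
                       male_fraction = 0.071,
                       unknown_sex_fraction = 0.056,
                       gender_pt_multipliers = default_gender_multipliers(),
                       tto_family = c("weibull", "lognormal", "loglogistic"),
                       tto_params = c(scale = 3097, shape = 0.62),
                       duplicate_rate = 0.15,
                       missing_event_date_rate = 0.55,
                       partial_date_rate = 0.15,
                       missing_start_date_rate = 0.10,
                       target_fraction = 0.5,
                       outcome_code_probs = c(DE = 0.003, LT = 0.002, HO = 0.021,
                                              DS = 0.009, CA = 0, OT = 0.681,
                                              none = 0.284),
                       age_unknown_rate = 0.487,
                       seed = NULL) {
  tto_family <- match.arg(tto_family)
  if (!is.numeric(n_reports) || length(n_reports) != 1 || is.na(n_reports) ||
      n_reports < 1) {
    abort("`n_reports` must be a single integer >= 1.",
          class = "faersignal_config_error")
  }
  n_reports <- as.integer(n_reports)
  if (length(target_synonyms) < 1) {
    abort("`target_synonyms` must contain at least one name.",
          class = "faersignal_config_error")
  }
  stopifnot(is.data.frame(pt_catalog),
            all(c("pt", "soc", "base_rate") %in% names(pt_catalog)))
  if (any(pt_catalog$base_rate < 0 | pt_catalog$base_rate > 1)) {
    abort("`pt_catalog$base_rate` must lie in [0, 1].",
          class = "faersignal_config_error")
  }
  for (f in c("female_fraction", "male_fraction", "unknown_sex_fraction",
              "duplicate_rate", "missing_event_date_rate", "partial_date_rate",
              "missing_start_date_rate", "target_fraction",
              "age_unknown_rate")) {
    assert_prob(get(f), f)
  }
  if (abs(female_fraction + male_fraction + unknown_sex_fraction - 1) > 1e-9) {
    abort("sex fractions (`female_fraction` + `male_fraction` + `unknown_sex_fraction`) must sum to 1.",
          class = "faersignal_config_error")
  }
  if (!is.null(signal_multipliers)) {
    stopifnot(is.data.frame(signal_multipliers),
              all(c("drug", "pt", "multiplier") %in% names(signal_multipliers)))
    if (any(signal_multipliers$multiplier < 0)) {
      abort("`signal_multipliers$multiplier` must be >= 0.",
            class = "faersignal_config_error")
    }
  }
  if (tto_family %in% c("weibull", "loglogistic")) {
    if (!all(c("scale", "shape") %in% names(tto_params))) {
      abort("`tto_params` must name `scale` and `shape` for this family.",
            class = "faersignal_config_error")
    }
    assert_pos(unname(tto_params["scale"]), "tto_params[scale]")
    assert_pos(unname(tto_params["shape"]), "tto_params[shape]")
  } else {
    if (!all(c("meanlog", "sdlog") %in% names(tto_params))) {
      abort("`tto_params` must name `meanlog` and `sdlog` for the lognormal family.",
            class = "faersignal_config_error")
    }
    assert_pos(unname(tto_params["sdlog"]), "tto_params[sdlog]")
  }
  if (abs(sum(outcome_code_probs) - 1) > 1e-9 || any(outcome_code_probs < 0)) {
    abort("`outcome_code_probs` must be non-negative and sum to 1.",
          class = "faersignal_config_error")
  }
  structure(list(
    n_reports = n_reports,
    target_synonyms = target_synonyms,
    background_drugs = background_drugs,
    pt_catalog = as_tibble(pt_catalog),
    signal_multipliers = signal_multipliers,
    female_fraction = female_fraction,
    male_fraction = male_fraction,
    unknown_sex_fraction = unknown_sex_fraction,
    gender_pt_multipliers = gender_pt_multipliers,
    tto_family = tto_family,
    tto_params = tto_params,
    duplicate_rate = duplicate_rate,
    missing_event_date_rate = missing_event_date_rate,
    partial_date_rate = partial_date_rate,
    missing_start_date_rate = missing_start_date_rate,
    target_fraction = target_fraction,
    outcome_code_probs = outcome_code_probs,
    age_unknown_rate = age_unknown_rate,
    seed = seed
  ), class = "sim_config")
}

rtto <- function(n, family, params) {
  switch(family,
    weibull = rweibull(n, shape = params[["shape"]], scale = params[["scale"]]),
    lognormal = rlnorm(n, meanlog = params[["meanlog"]], sdlog = params[["sdlog"]]),
    loglogistic = {
      u <- runif(n)
      params[["scale"]] * (u / (1 - u))^(1 / params[["shape"]])
    })
}

fmt_date <- function(d) {
  out <- rep("", length(d))
  ok <- !is.na(d)
  out[ok] <- format(d[ok], "%Y%m%d")
  out
}

#' Generate synthetic FAERS-style tables
#'
#' Draws a cohort of spontaneous reports under the generative model described
#' in [sim_config()] and returns the five quarterly-ASCII-shaped tables
#' (DEMO, DRUG, REAC, OUTC, THER) as all-character tibbles, together with a
#' per-case ground-truth table (attribute `"truth"`) used by oracle tests.
#'
#' Per report: a suspect drug identity is drawn (`TARGET` with probability
#' `target_fraction`, else a background drug); each PT in the catalogue is
#' drawn independently (Bernoulli with rate `base_rate` times the matching
#' drug and sex multipliers, capped at 1); reports that draw no PT receive
#' one PT sampled proportional to the baseline rates so every report has at
#' least one reaction.  Target-drug reports always carry `ROLE_COD = "PS"`;
#' background suspects draw a role from PS/SS/C.  A fraction
#' `duplicate_rate` of cases is emitted as two versions sharing the CASEID:
#' the later version (higher FDA_DT, ties broken by higher PRIMARYID) is the
#' deduplication ground truth.
#'
#' @param config a [sim_config()] object.
#' @return list of class `faers_tables` with elements `demo`, `drug`, `reac`,
#'   `outc`, `ther`; attributes `truth` (tibble) and `config`.
#' @examples
#' tabs <- simulate_faers(sim_config(n_reports = 50, seed = 1))
#' names(tabs)
#' head(tabs$demo)
#' @export
simulate_faers <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be created by sim_config().",
          class = "faersignal_config_error")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_reports
  cat_tbl <- config$pt_catalog
  P <- nrow(cat_tbl)

  caseid <- as.character(10000000 + seq_len(n))

  ## demographics ------------------------------------------------------------
  sex_raw <- sample(c("F", "M", "UNK"), n, replace = TRUE,
                    prob = c(config$female_fraction, config$male_fraction,
                             config$unknown_sex_fraction))
  age_known <- runif(n) >= config$age_unknown_rate
  # band mix follows the known-age distribution of the emulated cohort
  band <- sample(1:3, n, replace = TRUE, prob = c(0.259, 0.541, 0.200))
  age <- numeric(n)
  age[band == 1] <- floor(runif(sum(band == 1), 1, 18))
  age[band == 2] <- floor(runif(sum(band == 2), 18, 65))
  age[band == 3] <- floor(runif(sum(band == 3), 65, 95))
  age[!age_known] <- NA_real_
  # a slice of known ages is expressed in months or decades to exercise
  # AGE_COD unit conversion
  age_cod <- ifelse(is.na(age), "", "YR")
  u_cod <- runif(n)
  age_cod[!is.na(age) & u_cod < 0.05] <- "MON"
  age_cod[!is.na(age) & u_cod >= 0.05 & u_cod < 0.07] <- "DEC"
  age_str <- rep("", n)
  age_str[age_cod == "YR"] <- as.character(age[age_cod == "YR"])
  age_str[age_cod == "MON"] <- as.character(age[age_cod == "MON"] * 12)
  age_str[age_cod == "DEC"] <- as.character(age[age_cod == "DEC"] / 10)

  reporter <- sample(c("LW", "CN", "HP", "MD", "OT", "PH", ""), n,
                     replace = TRUE,
                     prob = c(0.492, 0.301, 0.112, 0.044, 0.021, 0.024, 0.006))
  country <- sample(c("US", "CA", "GB"), n, replace = TRUE,
                    prob = c(0.973, 0.014, 0.013))

  ## drugs -------------------------------------------------------------------
  is_target <- runif(n) < config$target_fraction
  identity <- ifelse(is_target, "TARGET",
                     sample(config$background_drugs, n, replace = TRUE))
  drugname <- ifelse(is_target,
                     sample(config$target_synonyms, n, replace = TRUE),
                     identity)
  role <- ifelse(is_target, "PS",
                 sample(c("PS", "SS", "C"), n, replace = TRUE,
                        prob = c(0.6, 0.2, 0.2)))
  has_concom <- runif(n) < 0.3
  concom <- sample(config$background_drugs, n, replace = TRUE)

  ## reactions: independent Bernoulli per PT ---------------------------------
  p <- matrix(rep(cat_tbl$base_rate, each = n), nrow = n, ncol = P)
  colnames(p) <- cat_tbl$pt
  if (!is.null(config$signal_multipliers) && nrow(config$signal_multipliers)) {
    sm <- config$signal_multipliers
    for (i in seq_len(nrow(sm))) {
      j <- match(sm$pt[i], cat_tbl$pt)
      if (is.na(j)) next
      rows <- identity == sm$drug[i] |
        (sm$drug[i] %in% c("TARGET", normalize_name(config$target_synonyms)) &
           is_target)
      p[rows, j] <- p[rows, j] * sm$multiplier[i]
    }
  }
  if (!is.null(config$gender_pt_multipliers) &&
      nrow(config$gender_pt_multipliers)) {
    gm <- config$gender_pt_multipliers
    sex_lab <- c(F = "female", M = "male", UNK = "unknown")[sex_raw]
    for (i in seq_len(nrow(gm))) {
      j <- match(gm$pt[i], cat_tbl$pt)
      if (is.na(j)) next
      rows <- sex_lab == gm$sex[i]
      p[rows, j] <- p[rows, j] * gm$multiplier[i]
    }
  }
  p <- pmin(p, 1)
  hit <- matrix(runif(n * P), n, P) < p
  none <- rowSums(hit) == 0
  if (any(none)) {
    forced <- sample.int(P, sum(none), replace = TRUE,
                         prob = cat_tbl$base_rate)
    hit[cbind(which(none), forced)] <- TRUE
  }
  pts_list <- apply(hit, 1, function(r) cat_tbl$pt[r], simplify = FALSE)

  ## outcome -----------------------------------------------------------------
  oc_probs <- config$outcome_code_probs
  outcome_code <- sample(names(oc_probs), n, replace = TRUE, prob = oc_probs)

  ## dates and time-to-onset -------------------------------------------------
  start_dt <- as.Date("2004-01-01") + floor(runif(n, 0, 7305))
  tto_true <- rtto(n, config$tto_family, config$tto_params)
  tto_int <- pmax(round(tto_true), 0)
  event_dt <- start_dt + tto_int
  fda_dt <- event_dt + floor(runif(n, 10, 400))

  event_str <- fmt_date(event_dt)
  u_ev <- runif(n)
  event_str[u_ev < config$missing_event_date_rate] <- ""
  part <- u_ev >= config$missing_event_date_rate &
    u_ev < config$missing_event_date_rate + config$partial_date_rate
  event_str[part] <- substr(event_str[part], 1, 6)
  start_str <- fmt_date(start_dt)
  start_str[runif(n) < config$missing_start_date_rate] <- ""

  ## duplicate versions ------------------------------------------------------
  dup <- runif(n) < config$duplicate_rate
  u_dup <- runif(n)
  # latest version id suffix 2; older duplicate gets suffix 1 usually, or
  # suffix 3 with an earlier FDA_DT (so the date, not the id, decides), or a
  # tied FDA_DT (so the higher id decides)
  pid_latest <- paste0(caseid, "2")
  old_suffix <- ifelse(u_dup < 0.1, "1", ifelse(u_dup < 0.2, "3", "1"))
  tie <- dup & u_dup < 0.1
  pid_old <- paste0(caseid, old_suffix)
  fda_old <- fda_dt - ifelse(tie, 0, floor(runif(n, 30, 400)))

  demo_row <- function(pid, fda) {
    tibble(PRIMARYID = pid, CASEID = caseid, FDA_DT = fmt_date(fda),
           EVENT_DT = event_str, SEX = sex_raw, AGE = age_str,
           AGE_COD = age_cod, REPT_COD = reporter, OCCR_COUNTRY = country)
  }
  demo <- bind_rows(demo_row(pid_latest, fda_dt),
                    demo_row(pid_old, fda_old)[dup, ]) %>%
    arrange(.data$CASEID, .data$PRIMARYID)

  child_ids <- function() {
    tibble(PRIMARYID = c(pid_latest, pid_old[dup]),
           CASEID = c(caseid, caseid[dup]),
           idx = c(seq_len(n), which(dup)))
  }
  ids <- child_ids()

  drug_one <- tibble(idx = seq_len(n), DRUGNAME = drugname, ROLE_COD = role)
  drug_con <- tibble(idx = which(has_concom), DRUGNAME = concom[has_concom],
                     ROLE_COD = "C")
  drug <- ids %>%
    inner_join(bind_rows(drug_one, drug_con), by = "idx",
               relationship = "many-to-many") %>%
    select("PRIMARYID", "CASEID", "DRUGNAME", "ROLE_COD") %>%
    arrange(.data$CASEID, .data$PRIMARYID, .data$DRUGNAME)

  reac_base <- tibble(idx = rep(seq_len(n), lengths(pts_list)),
                      PT = unlist(pts_list))
  # report-level PT multiplicity: a small share of reaction rows is repeated
  rep_rows <- runif(nrow(reac_base)) < 0.03
  reac_base <- bind_rows(reac_base, reac_base[rep_rows, ])
  reac <- ids %>%
    inner_join(reac_base, by = "idx", relationship = "many-to-many") %>%
    select("PRIMARYID", "CASEID", "PT") %>%
    arrange(.data$CASEID, .data$PRIMARYID, .data$PT)

  outc_base <- tibble(idx = which(outcome_code != "none"),
                      OUTC_COD = outcome_code[outcome_code != "none"])
  outc <- ids %>%
    inner_join(outc_base, by = "idx") %>%
    select("PRIMARYID", "CASEID", "OUTC_COD") %>%
    arrange(.data$CASEID, .data$PRIMARYID)

  ther_base <- tibble(idx = seq_len(n), DRUGNAME = drugname,
                      START_DT = start_str)
  ther <- ids %>%
    inner_join(ther_base, by = "idx") %>%
    select("PRIMARYID", "CASEID", "DRUGNAME", "START_DT") %>%
    arrange(.data$CASEID, .data$PRIMARYID)

  truth <- tibble(
    caseid = caseid,
    primaryid = pid_latest,
    is_target = is_target,
    drug_identity = identity,
    sex = unname(c(F = "female", M = "male", UNK = "unknown")[sex_raw]),
    age_years = age,
    reporter_code = reporter,
    country = country,
    fda_dt = fda_dt,
    pts = pts_list,
    outcome_code = outcome_code,
    start_dt = if_else(start_str == "", as.Date(NA), start_dt),
    event_dt = if_else(nchar(event_str) == 8, event_dt, as.Date(NA)),
    tto_days = as.numeric(tto_int),
    duplicated = dup
  )

  structure(list(demo = demo, drug = drug, reac = reac, outc = outc,
                 ther = ther),
            class = "faers_tables", truth = truth, config = config)
}

#' Write FAERS-style '$'-delimited ASCII files
#'
#' One file per table (`DEMO.txt`, `DRUG.txt`, `REAC.txt`, `OUTC.txt`,
#' `THER.txt`) with a header line.  The dialect matches the real quarterly
#' extracts: fields separated by `$` with no quoting mechanism, so any `$`
#' occurring inside a value is replaced by `/` before writing.
#'
#' @param tables a `faers_tables` list (or any named list of character
#'   tibbles).
#' @param dir output directory; created if absent.
#' @return invisibly, the paths written.
#' @export
write_faers_ascii <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    tab <- mutate(as_tibble(tab),
                  across(where(is.character), ~ gsub("$", "/", .x, fixed = TRUE)))
    path <- file.path(dir, paste0(toupper(nm), ".txt"))
    readr::write_delim(tab, path, delim = "$", na = "", quote = "none",
                       escape = "none")
    paths <- c(paths, path)
  }
  invisible(paths)
}
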