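# Parsing and assembly of FAERS quarterly ASCII tables.
#
# The quarterly extracts are '$'-delimited text with a header row and no
# quoting.  Parsing is deliberately forgiving: unknown columns ride along as
# character, malformed dates become NA, and only a missing *required* column
# is an error.

faers_required_cols <- list(
  demo = c("primaryid", "caseid", "fda_dt"),
  drug = c("primaryid", "drugname", "role_cod"),
  reac = c("primaryid", "pt"),
  outc = c("primaryid", "outc_cod"),
  ther = c("primaryid", "start_dt")
)

read_faers_raw <- function(file) {
  readr::read_delim(file, delim = "$",
                    col_types = readr::cols(.default = readr::col_character()),
                    quote = "", na = character(), trim_ws = FALSE,
                    progress = FALSE, show_col_types = FALSE)
}

#' Parse one FAERS ASCII table
#'
#' Reads a '$'-delimited table (file path, literal text, or an already-read
#' data frame) and checks that the columns required for `table` are present
#' (case-insensitively).  All fields stay character; typing of dates, sex and
#' age happens in [assemble_cases()].  Column names are lower-cased.
#'
#' @param x file path, a character scalar containing the raw text, or a data
#'   frame.
#' @param table one of `"demo"`, `"drug"`, `"reac"`, `"outc"`, `"ther"`.
#' @return tibble of character columns.
#' @export
parse_faers_table <- function(x, table = c("demo", "drug", "reac", "outc",
                                           "ther")) {
  table <- match.arg(table)
  if (is.data.frame(x)) {
    raw <- as_tibble(x)
  } else if (length(x) == 1 && (file.exists(x) || grepl("\n", x))) {
    raw <- if (file.exists(x)) read_faers_raw(x) else read_faers_raw(I(x))
  } else {
    abort("`x` must be a file path, raw table text, or a data frame.")
  }
  names(raw) <- tolower(names(raw))
  req <- faers_required_cols[[table]]
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols)) {
    abort(sprintf("%s table is missing required column(s): %s",
                  toupper(table), paste(missing_cols, collapse = ", ")),
          class = "faersignal_schema_error")
  }
  raw
}

#' Read a directory of FAERS ASCII tables
#'
#' Expects files `DEMO.txt`, `DRUG.txt`, `REAC.txt`, `OUTC.txt`, `THER.txt`
#' (case-insensitive) as produced by [write_faers_ascii()] or unpacked from a
#' quarterly extract.
#'
#' @param dir directory path.
#' @return list of class `faers_tables`.
#' @export
read_faers_tables <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  find1 <- function(stem) {
    hit <- files[toupper(basename(files)) == paste0(stem, ".TXT")]
    if (!length(hit)) {
      abort(sprintf("no %s.txt found in %s", stem, dir),
            class = "faersignal_schema_error")
    }
    hit[[1]]
  }
  out <- list(
    demo = parse_faers_table(find1("DEMO"), "demo"),
    drug = parse_faers_table(find1("DRUG"), "drug"),
    reac = parse_faers_table(find1("REAC"), "reac"),
    outc = parse_faers_table(find1("OUTC"), "outc"),
    ther = parse_faers_table(find1("THER"), "ther"))
  class(out) <- "faers_tables"
  out
}

# AGE + AGE_COD -> years; unknown unit code or non-numeric age -> NA
age_to_years <- function(age, age_cod) {
  a <- suppressWarnings(as.numeric(age))
  cod <- toupper(trimws(ifelse(is.na(age_cod), "YR", age_cod)))
  cod[cod == ""] <- "YR"
  factor_tbl <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 7 / 365.25,
                  DY = 1 / 365.25, HR = 1 / (24 * 365.25))
  mult <- unname(factor_tbl[cod])
  yrs <- a * mult
  yrs[is.na(mult)] <- NA_real_          # unknown unit code
  yrs[!is.na(yrs) & (yrs < 0 | yrs > 130)] <- NA_real_
  yrs
}

sex_label <- function(sex) {
  s <- toupper(trimws(ifelse(is.na(sex), "", sex)))
  dplyr::case_match(s, "F" ~ "female", "M" ~ "male", .default = "unknown")
}

reporter_label <- function(code) {
  s <- toupper(trimws(ifelse(is.na(code), "", code)))
  dplyr::case_match(s,
    "MD" ~ "physician",
    "CN" ~ "consumer",
    "HP" ~ "health professional",
    "OT" ~ "other health-professional",
    "PH" ~ "pharmacist",
    "LW" ~ "lawyer",
    .default = "unknown")
}

#' Deduplicate demographic records by case
#'
#' Applies the FDA-recommended key-based rule: among report versions sharing
#' a CASEID, keep the one with the highest FDA_DT; on ties, the highest
#' PRIMARYID.  A missing FDA_DT sorts lowest.  PRIMARYIDs are compared with a
#' numeric-aware order (digit-only ids numerically, otherwise
#' lexicographically).
#'
#' @param demo tibble with at least `primaryid`, `caseid`, `fda_dt` columns;
#'   `fda_dt` may be raw `YYYYMMDD` strings or `Date`.
#' @return tibble with one row per `caseid`, ordered by ascending `caseid`.
#' @export
deduplicate <- function(demo) {
  demo <- as_tibble(demo)
  fda <- if (inherits(demo$fda_dt, "Date")) demo$fda_dt else
    parse_faers_date(demo$fda_dt)
  key_fda <- as.numeric(fda)
  key_fda[is.na(key_fda)] <- -Inf
  demo %>%
    mutate(.fda_key = key_fda, .pid_key = pid_order_key(.data$primaryid)) %>%
    arrange(.data$caseid, desc(.data$.fda_key), desc(.data$.pid_key)) %>%
    distinct(.data$caseid, .keep_all = TRUE) %>%
    select(-".fda_key", -".pid_key") %>%
    arrange(.data$caseid)
}

#' Identify reports whose primary-suspect drug matches a synonym list
#'
#' A report matches when some DRUG row has role code `PS` and a DRUGNAME
#' equal to one of the synonyms after trimming, case-folding, and collapsing
#' internal whitespace (whole-field equality).
#'
#' @param drug DRUG table (character tibble with `primaryid`, `drugname`,
#'   `role_cod`).
#' @param synonyms non-empty character vector of drug name variants.
#' @return character vector of matching `primaryid`s (unique).
#' @export
match_primary_suspect <- function(drug, synonyms) {
  if (length(synonyms) < 1) {
    abort("`synonyms` must contain at least one drug name.",
          class = "faersignal_config_error")
  }
  syn <- normalize_name(synonyms)
  drug <- as_tibble(drug)
  hit <- toupper(trimws(drug$role_cod)) == "PS" &
    normalize_name(drug$drugname) %in% syn
  unique(drug$primaryid[hit & !is.na(hit)])
}

#' Assemble analysis-ready case reports
#'
#' Runs the full ingestion chain: deduplicate the DEMO table, drop child-table
#' rows whose PRIMARYID has no (retained) DEMO row, type the demographic
#' fields, collect the distinct PT set, outcome-code set, drug list and
#' earliest parseable therapy start date per drug for each case, and flag the
#' cases whose primary-suspect drug matches `synonyms`.
#'
#' @param tables a `faers_tables` list (from [read_faers_tables()] or
#'   [simulate_faers()]).
#' @param synonyms suspect-drug synonym list; default [pps_synonyms()].
#' @param all_cases if `FALSE` (default, mirroring a suspect-drug-focused
#'   extraction) only matched cases are returned; if `TRUE` every
#'   deduplicated case is returned with a logical `target` column, as needed
#'   for disproportionality against the full-database comparator.
#' @param quiet suppress informational messages about dropped orphans.
#' @return tibble of class `faers_cases`, one row per case: `primaryid`,
#'   `caseid`, `fda_dt`, `event_dt`, `sex`, `age_years`, `reporter`,
#'   `country`, `target`, list-columns `pts`, `outcome_codes`, `drugs`,
#'   `therapy_starts`, and `start_dt` (earliest therapy start among drugs
#'   matching `synonyms`).
#' @export
assemble_cases <- function(tables, synonyms = pps_synonyms(),
                           all_cases = FALSE, quiet = FALSE) {
  demo <- parse_faers_table(tables$demo, "demo")
  drug <- parse_faers_table(tables$drug, "drug")
  reac <- parse_faers_table(tables$reac, "reac")
  outc <- parse_faers_table(tables$outc, "outc")
  ther <- parse_faers_table(tables$ther, "ther")

  demo <- deduplicate(demo)
  keep_ids <- demo$primaryid

  n_orphan <- sum(!drug$primaryid %in% keep_ids) +
    sum(!reac$primaryid %in% keep_ids) +
    sum(!outc$primaryid %in% keep_ids) +
    sum(!ther$primaryid %in% keep_ids)
  if (n_orphan > 0 && !quiet) {
    inform(sprintf(
      "dropped %d child-table row(s) without a retained DEMO record", n_orphan))
  }
  drug <- filter(drug, .data$primaryid %in% keep_ids)
  reac <- filter(reac, .data$primaryid %in% keep_ids)
  outc <- filter(outc, .data$primaryid %in% keep_ids)
  ther <- filter(ther, .data$primaryid %in% keep_ids)

  target_ids <- match_primary_suspect(drug, synonyms)

  pts_by_id <- reac %>%
    mutate(pt = trimws(.data$pt)) %>%
    filter(.data$pt != "") %>%
    distinct(.data$primaryid, .data$pt) %>%
    summarise(pts = list(sort(.data$pt)), .by = "primaryid")
  outc_by_id <- outc %>%
    mutate(outc_cod = toupper(trimws(.data$outc_cod))) %>%
    filter(.data$outc_cod != "") %>%
    distinct(.data$primaryid, .data$outc_cod) %>%
    summarise(outcome_codes = list(sort(.data$outc_cod)), .by = "primaryid")
  drugs_by_id <- drug %>%
    mutate(drugname = normalize_name(.data$drugname),
           role = toupper(trimws(.data$role_cod))) %>%
    distinct(.data$primaryid, .data$drugname, .data$role) %>%
    summarise(drugs = list(tibble(drugname = drugname, role = role)),
              .by = "primaryid")
  min_date <- function(x) {
    x <- x[!is.na(x)]
    if (length(x)) min(x) else as.Date(NA)
  }
  ther_by_id <- ther %>%
    mutate(drugname = normalize_name(.data$drugname),
           start = parse_faers_date(.data$start_dt)) %>%
    filter(!is.na(.data$start)) %>%
    summarise(start = min_date(.data$start), .by = c("primaryid", "drugname"))
  starts_by_id <- ther_by_id %>%
    summarise(therapy_starts = list(tibble(drugname = drugname,
                                           start = start)),
              .by = "primaryid")
  syn <- normalize_name(synonyms)
  target_start <- ther_by_id %>%
    filter(.data$drugname %in% syn) %>%
    summarise(start_dt = min_date(.data$start), .by = "primaryid")

  cases <- demo %>%
    mutate(fda_dt = parse_faers_date(.data$fda_dt),
           event_dt = if ("event_dt" %in% names(demo))
             parse_faers_date(.data$event_dt) else as.Date(NA),
           sex = if ("sex" %in% names(demo)) sex_label(.data$sex) else
             "unknown",
           age_years = if (all(c("age") %in% names(demo)))
             age_to_years(.data$age,
                          if ("age_cod" %in% names(demo)) .data$age_cod else
                            "YR") else NA_real_,
           reporter = if ("rept_cod" %in% names(demo))
             reporter_label(.data$rept_cod) else "unknown",
           country = if ("occr_country" %in% names(demo))
             trimws(.data$occr_country) else NA_character_) %>%
    select("primaryid", "caseid", "fda_dt", "event_dt", "sex", "age_years",
           "reporter", "country") %>%
    left_join(pts_by_id, by = "primaryid") %>%
    left_join(outc_by_id, by = "primaryid") %>%
    left_join(drugs_by_id, by = "primaryid") %>%
    left_join(starts_by_id, by = "primaryid") %>%
    left_join(target_start, by = "primaryid") %>%
    mutate(pts = map(.data$pts, ~ .x %||% character(0)),
           outcome_codes = map(.data$outcome_codes, ~ .x %||% character(0)),
           target = .data$primaryid %in% target_ids)

  no_pt <- lengths(cases$pts) == 0
  if (any(no_pt) && !quiet) {
    inform(sprintf("dropped %d case(s) with no reaction record", sum(no_pt)))
  }
  cases <- cases[!no_pt, ]
  if (!all_cases) cases <- filter(cases, .data$target)
  class(cases) <- c("faers_cases", class(cases))
  cases
}

#' Restrict cases to a minimum documented age
#'
#' Keeps cases with a non-missing age of at least `min_age` completed years;
#' cases with unknown age are excluded (the sensitivity-analysis convention
#' for a drug indicated in patients aged 16 and over).
#'
#' @param cases a `faers_cases` tibble.
#' @param min_age minimum age in years (>= 0).
#' @return filtered tibble.
#' @export
filter_by_age <- function(cases, min_age = 16) {
  stopifnot(is.numeric(min_age), min_age >= 0)
  filter(cases, !is.na(.data$age_years), .data$age_years >= min_age)
}
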