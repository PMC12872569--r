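# End-to-end orchestration: simulate/ingest -> deduplicate & assemble ->
# disproportionality signals -> gender screen -> characteristics -> TTO.

stage_run <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)),
          class = "faersignal_stage_error")
  })
}

#' Run the full pharmacovigilance pipeline
#'
#' Orchestrates every stage on one input: ingestion (or simulation),
#' deduplication and case assembly, disproportionality signal detection,
#' sex-differential screen, clinical-characteristics summary, and
#' time-to-onset analysis (descriptives, Kaplan-Meier, the three parametric
#' fits, AIC selection and hazard classification).  A machine-readable
#' manifest records the record counts at every filtering step; identical
#' input and seed give identical outputs.
#'
#' @param source a [sim_config()] (data are simulated), a directory of FAERS
#'   ASCII files, or a `faers_tables` list.
#' @param synonyms suspect-drug synonym list.
#' @param pt_soc PT-to-SOC map (tibble `pt`, `soc`).
#' @param min_n,prr_min,chi2_min,alpha signal thresholds.
#' @param min_age optional minimum documented age (years); `NULL` disables
#'   the age filter.
#' @param km_grid time grid (days) for the number-at-risk table.
#' @param out_dir optional directory; when given, per-stage CSVs and
#'   `manifest.json` are written there.
#' @param seed optional integer; overrides the seed in a `sim_config`
#'   source.
#' @param quiet suppress stage messages.
#' @return list of class `faers_pipeline`: `cases`, `signals`, `gender`,
#'   `characteristics`, `gender_ratio`, `tto`, `tto_summary`, `km`, `fits`,
#'   `model_comparison`, `hazard_class`, `manifest`.
#' @export
run_pipeline <- function(source,
                         synonyms = pps_synonyms(),
                         pt_soc = default_pt_catalog(),
                         min_n = 3, prr_min = 2, chi2_min = 4, alpha = 0.05,
                         min_age = NULL,
                         km_grid = seq(0, 8000, by = 1000),
                         out_dir = NULL, seed = NULL, quiet = TRUE) {
  tables <- stage_run("ingest", {
    if (inherits(source, "sim_config")) {
      if (!is.null(seed)) source$seed <- seed
      simulate_faers(source)
    } else if (is.character(source) && length(source) == 1 &&
               dir.exists(source)) {
      read_faers_tables(source)
    } else if (inherits(source, "faers_tables") || is.list(source)) {
      source
    } else {
      abort("`source` must be a sim_config, a directory, or a faers_tables list.")
    }
  })

  n_raw <- nrow(tables$demo)
  cases <- stage_run("assemble",
                     assemble_cases(tables, synonyms, all_cases = TRUE,
                                    quiet = quiet))
  n_dedup <- nrow(cases)
  if (!is.null(min_age)) {
    cases <- stage_run("age_filter", filter_by_age(cases, min_age))
  }
  n_after_age <- nrow(cases)
  target_cases <- filter(cases, .data$target)
  n_target <- nrow(target_cases)

  signals <- stage_run("signals",
                       detect_signals(cases, pt_soc = pt_soc, min_n = min_n,
                                      prr_min = prr_min,
                                      chi2_min = chi2_min))
  gender <- stage_run("gender",
                      gender_signals(target_cases, min_n = min_n,
                                     alpha = alpha))
  characteristics <- stage_run("summarize",
                               summarize_characteristics(target_cases))
  ratio <- suppressWarnings(gender_ratio(target_cases))

  tto <- stage_run("tto", compute_tto(target_cases))
  tto_vals <- tto_values(tto)
  n_tto <- length(tto_vals)
  tto_sum <- km <- fits <- comparison <- NULL
  hazard <- NA_character_
  if (n_tto >= 10) {
    tto_sum <- stage_run("tto", tto_summary(tto))
    km <- stage_run("tto", km_estimate(tto, grid = km_grid))
    fits <- stage_run("tto_fit", lapply(
      c("weibull", "lognormal", "loglogistic"),
      function(f) fit_tto(tto, family = f)))
    names(fits) <- map_chr(fits, "family")
    comparison <- select_model(fits)
    hazard <- classify_hazard(fits$weibull)
  } else if (!quiet) {
    inform(sprintf("only %d TTO-eligible records; parametric TTO analysis skipped",
                   n_tto))
  }

  manifest <- list(
    package = "faersignal",
    version = as.character(utils::packageVersion("faersignal")),
    seed = seed %||% (if (inherits(source, "sim_config")) source$seed),
    thresholds = list(min_n = min_n, prr_min = prr_min, chi2_min = chi2_min,
                      alpha = alpha, min_age = min_age),
    counts = list(raw_demo_rows = n_raw,
                  deduplicated_cases = n_dedup,
                  after_age_filter = n_after_age,
                  target_cases = n_target,
                  tto_eligible = n_tto),
    n_signals = sum(signals$is_signal),
    best_tto_family = if (!is.null(comparison))
      attr(comparison, "best_family") else NA_character_,
    hazard_class = hazard)

  out <- structure(list(cases = cases, signals = signals, gender = gender,
                        characteristics = characteristics,
                        gender_ratio = ratio, tto = tto,
                        tto_summary = tto_sum, km = km, fits = fits,
                        model_comparison = comparison, hazard_class = hazard,
                        manifest = manifest),
                   class = "faers_pipeline")

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_csv(signals, file.path(out_dir, "signals.csv"))
    readr::write_csv(gender, file.path(out_dir, "gender_signals.csv"))
    readr::write_csv(characteristics,
                     file.path(out_dir, "characteristics.csv"))
    tto_flat <- tto %>%
      mutate(pts = map_chr(.data$pts, paste, collapse = ";"))
    readr::write_csv(tto_flat, file.path(out_dir, "tto_records.csv"))
    if (!is.null(km)) {
      readr::write_csv(km$curve, file.path(out_dir, "km_curve.csv"))
      if (!is.null(km$risk_table)) {
        readr::write_csv(km$risk_table, file.path(out_dir, "km_risk_table.csv"))
      }
    }
    if (!is.null(comparison)) {
      readr::write_csv(comparison, file.path(out_dir, "fits.csv"))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' @export
print.faers_pipeline <- function(x, ...) {
  cat("faersignal pipeline run\n")
  cnt <- x$manifest$counts
  cat(sprintf("  raw demo rows: %d; deduplicated cases: %d; target cases: %d\n",
              cnt$raw_demo_rows, cnt$deduplicated_cases, cnt$target_cases))
  cat(sprintf("  positive signals: %d PTs\n", x$manifest$n_signals))
  cat(sprintf("  TTO-eligible records: %d", cnt$tto_eligible))
  if (!is.null(x$model_comparison)) {
    cat(sprintf("; best family: %s; hazard: %s",
                attr(x$model_comparison, "best_family"), x$hazard_class))
  }
  cat("\n")
  invisible(x)
}
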