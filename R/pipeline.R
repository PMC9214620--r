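#' End-to-end run configuration
#'
#' Bundles the screening constants (exposure window 275-215 days before
#' delivery, 315-day diagnosis lookback, minimum 5 exposed patients,
#' alpha 0.05) with either a synthetic-cohort config or paths to input
#' tables. All defaults equal the screening constants above; every one is
#' overridable.
#'
#' @param sim A [simulation_config()] to generate the inputs, or `NULL`
#'   to read them from `paths`.
#' @param paths Named list with `deliveries`, `orders`, `diagnoses` CSV
#'   paths (and optionally `code_lists`, `annotations`, `gold`); required
#'   when `sim` is `NULL`.
#' @param window Exposure window in days before delivery, `c(start, end)`
#'   with `start > end`.
#' @param lookback_days Diagnosis lookback for ART/infertility (> 0).
#' @param min_patients Minimum distinct exposed patients per medication.
#' @param alpha Significance level in (0, 1).
#' @param models Model labels to screen (default all three).
#' @param tolerance_days "At delivery" tolerance for the MB outcome.
#' @param decoys Whether to append decoy records after simulating
#'   (exercises the builders' insensitivity; default `TRUE`).
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = simulation_config(), paths = NULL,
                       window = c(275L, 215L), lookback_days = 315L,
                       min_patients = 5L, alpha = 0.05,
                       models = c("model1", "model2", "model3"),
                       tolerance_days = 0L, decoys = TRUE) {
  stopifnot(length(window) == 2L, window[1] > window[2],
            lookback_days > 0, alpha > 0, alpha < 1, min_patients >= 1)
  models <- match.arg(models, c("model1", "model2", "model3"),
                      several.ok = TRUE)
  if (is.null(sim)) {
    need <- c("deliveries", "orders", "diagnoses")
    if (is.null(paths) || !all(need %in% names(paths))) {
      stop("run_config without a simulation needs paths$deliveries, ",
           "paths$orders, paths$diagnoses")
    }
  }
  structure(list(sim = sim, paths = paths, window = as.integer(window),
                 lookback_days = as.integer(lookback_days),
                 min_patients = as.integer(min_patients), alpha = alpha,
                 models = models, tolerance_days = as.integer(tolerance_days),
                 decoys = isTRUE(decoys)),
            class = "run_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full screening pipeline
#'
#' Executes simulate (optional) -> build-cohort -> build-exposure ->
#' screen (one pass per model) -> validate -> report inputs, writing every
#' stage's table plus a `manifest.json` recording the configuration, seed
#' and per-stage row counts. Re-running the same configuration yields
#' byte-identical outputs. A stage failure halts the run with the failing
#' stage named; earlier outputs are retained.
#'
#' @param config A [run_config()].
#' @param out_dir Artifact directory (created if missing).
#' @return `out_dir`, invisibly; see `manifest.json` there for contents.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  counts <- list()

  if (!is.null(config$sim)) {
    cohort_raw <- with_stage("simulate", {
      co <- generate_cohort(config$sim)
      if (config$decoys) co <- emit_decoys(co, config$sim)
      write_cohort_tables(co, out_dir)
      co
    })
    deliveries <- cohort_raw$deliveries
    orders <- cohort_raw$orders
    diagnoses <- cohort_raw$diagnoses
    annotations <- config$sim$annotations
    gold <- config$sim$gold_ids
    code_lists <- default_code_lists()
    seed <- config$sim$seed
  } else {
    deliveries <- with_stage("read-inputs",
                             read_deliveries(config$paths$deliveries))
    orders <- with_stage("read-inputs", read_orders(config$paths$orders))
    diagnoses <- with_stage("read-inputs",
                            read_diagnoses(config$paths$diagnoses))
    code_lists <- with_stage("read-inputs",
      if (is.null(config$paths$code_lists)) default_code_lists()
      else read_code_lists(config$paths$code_lists))
    annotations <- with_stage("read-inputs",
      if (is.null(config$paths$annotations)) default_annotations()
      else read_annotations(config$paths$annotations))
    gold <- with_stage("read-inputs",
      if (is.null(config$paths$gold)) gold_standard_ids(annotations)
      else read_csv_checked(config$paths$gold, "medication_id")$medication_id)
    seed <- NA_integer_
  }
  counts$deliveries <- nrow(deliveries)
  counts$orders <- nrow(orders)
  counts$diagnoses <- nrow(diagnoses)

  cohort <- with_stage("build-cohort", {
    co <- build_cohort(deliveries, diagnoses, code_lists,
                       config$tolerance_days, config$lookback_days)
    utils::write.csv(co, file.path(out_dir, "cohort.csv"), row.names = FALSE)
    co
  })
  counts$cohort <- nrow(cohort)

  exposure <- with_stage("build-exposure", {
    mapped <- map_orders(orders, annotations)
    ex <- window_exposure(cohort, mapped, config$window)
    ex <- filter_min_patients(ex, config$min_patients)
    write_exposure_matrix(ex, file.path(out_dir, "exposure_matrix.csv"))
    utils::write.csv(
      data.frame(medication_id = names(ex$n_patients),
                 n_patients = unname(ex$n_patients)),
      file.path(out_dir, "medication_counts.csv"), row.names = FALSE)
    ex
  })
  counts$medications_retained <- ncol(exposure$m)

  with_stage("summarize", {
    utils::write.csv(summarize_cohort(cohort, exposure, gold),
                     file.path(out_dir, "summary.csv"), row.names = FALSE)
  })

  screens <- list()
  for (lab in config$models) {
    screens[[lab]] <- with_stage(paste0("screen-", lab), {
      sc <- run_mwas(cohort, exposure, model_spec(lab, config$alpha))
      write_screen(sc, file.path(out_dir, paste0("results_", lab, ".csv")))
      sc
    })
    counts[[paste0("significant_nominal_", lab)]] <-
      sum(screens[[lab]]$results$sig_nominal)
  }

  with_stage("forest", {
    lab <- utils::tail(config$models, 1)
    utils::write.csv(export_forest(screens[[lab]]),
                     file.path(out_dir, "forest_data.csv"), row.names = FALSE)
  })

  with_stage("validate", {
    gold_scored <- intersect(gold, colnames(exposure$m))
    utils::write.csv(performance_table(screens, gold_scored),
                     file.path(out_dir, "performance.csv"), row.names = FALSE)
  })

  manifest <- list(
    config = list(window = config$window, lookback_days = config$lookback_days,
                  min_patients = config$min_patients, alpha = config$alpha,
                  models = config$models,
                  tolerance_days = config$tolerance_days,
                  simulated = !is.null(config$sim), seed = seed),
    counts = counts,
    files = sort(list.files(out_dir))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Render a human-readable report from a completed artifact directory
#'
#' Reads only the stage output files (no recomputation of screen
#' statistics) and renders the cohort summary block, the 6-row performance
#' table and the forest-plot data. Before rendering, it checks the
#' structural invariant that every Bonferroni-significant medication is
#' also nominally significant in each results file and aborts if a file
#' violates it (a tampered or corrupted artifact).
#'
#' @param dir Artifact directory written by [run_pipeline()].
#' @param file Optional path to also write the report text to.
#' @return Character vector of report lines, invisibly printed.
#' @export
make_report <- function(dir, file = file.path(dir, "report.txt")) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) stop("incomplete artifact: no manifest.json in ",
                                   dir)
  manifest <- jsonlite::read_json(man_path)
  need <- c("summary.csv", "performance.csv", "forest_data.csv")
  miss <- need[!file.exists(file.path(dir, need))]
  if (length(miss)) stop("incomplete artifact: missing ",
                         paste(miss, collapse = ", "))

  for (lab in unlist(manifest$config$models)) {
    res <- read_results(file.path(dir, paste0("results_", lab, ".csv")))
    bad <- res$sig_bonf == 1L & res$sig_nominal == 0L
    if (any(bad)) {
      stop("invariant violation in results_", lab, ".csv: ",
           "Bonferroni-significant but not nominally significant: ",
           paste(res$medication_id[bad], collapse = ", "))
    }
  }

  summary <- utils::read.csv(file.path(dir, "summary.csv"))
  perf <- utils::read.csv(file.path(dir, "performance.csv"))
  forest <- utils::read.csv(file.path(dir, "forest_data.csv"))

  fmt <- function(df) utils::capture.output(print(df, row.names = FALSE))
  lines <- c(
    "Medication-wide association screen - run report",
    strrep("=", 48),
    paste0("deliveries: ", manifest$counts$deliveries,
           " | medications retained: ",
           manifest$counts$medications_retained),
    "",
    "Cohort summary (per exposure stratum)",
    fmt(summary[, c("stratum", "n", "mb_n", "mb_pct", "art_n", "art_pct",
                    "infertility_n", "infertility_pct", "age_mean",
                    "age_sd")]),
    "",
    "Gold-standard validation (per model and calling mode)",
    fmt(perf),
    "",
    if (nrow(forest) == 0L) {
      "Forest-plot data: no significant medications in the final model."
    } else {
      c(paste0("Forest-plot data (final model; ",
               length(unique(forest$medication_id)),
               " significant medications)"),
        fmt(forest))
    }
  )
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
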