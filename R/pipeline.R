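#' Run configuration
#'
#' Validates and normalizes the configuration driving [run_all()].
#' Unknown keys are rejected so typos fail loudly; the fully resolved
#' configuration is serialized into every run manifest.
#'
#' @param n_subjects Cohort size (default 28).
#' @param preset Generator preset name (see [coupling_preset()]).
#' @param seed Master seed for every source of randomness in the run.
#' @param missing `NULL` for the default layout (one subject missing the
#'   3-Hz protocol when `n_subjects == 28`), or a list of
#'   `(subject, protocol)` pairs.
#' @param labels Indexes to benchmark.
#' @param models Classifier families to benchmark.
#' @param cv_folds,cv_seeds Cross-validation geometry.
#' @param write_signals Also write every raw recording as CSV (large).
#' @return Object of class `run_config`.
#' @export
run_config <- function(n_subjects = 28, preset = "strong", seed = 1L,
                       missing = NULL, labels = c("I_PV", "I_NM", "I_MS"),
                       models = ml_models(), cv_folds = 10, cv_seeds = 10,
                       write_signals = FALSE) {
  cfg <- as.list(environment())
  stopifnot(n_subjects >= 1, cv_folds >= 2, cv_seeds >= 1,
            preset %in% c("null", "weak", "strong"),
            all(labels %in% index_names()),
            all(models %in% ml_models()))
  structure(cfg, class = "run_config")
}

#' Validate a configuration read from a JSON/YAML-style list
#' @param x Named list of [run_config()] fields.
#' @return A validated `run_config`.
#' @export
as_run_config <- function(x) {
  if (inherits(x, "run_config")) return(x)
  unknown <- setdiff(names(x), names(formals(run_config)))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  do.call(run_config, x)
}

#' Run the full pipeline: simulate, extract, score, screen, benchmark
#'
#' Executes every stage against a synthetic cohort and writes the complete
#' artifact set into `out`: `features.csv`, `questionnaire.csv`,
#' `indexes.csv`, `marginals_symptoms.csv`, `marginals_indexes.csv`,
#' `cohort.csv`, `significance.csv`, `metrics.csv`, one
#' `importance_<index>.csv` per benchmarked index, the per-subject
#' change reports, and `manifest.json` (configuration, seed, package
#' version, dropped-row counts).  Rerunning with the same configuration
#' reproduces byte-identical CSVs.
#'
#' @param config A [run_config()] (or plain list accepted by
#'   [as_run_config()]).
#' @param out Output directory (created if needed).
#' @param progress Print stage announcements.
#' @return Invisibly, a list with the in-memory stage outputs
#'   (`cohort`, `index_set`, `significance`, `benchmark`, `changes`).
#' @export
run_all <- function(config = run_config(), out, progress = TRUE) {
  config <- as_run_config(config)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (progress) message("[", format(Sys.time(), "%H:%M:%S"),
                                             "] ", ...)
  cc <- coupling_preset(config$preset, seed = config$seed)
  missing <- if (is.null(config$missing)) default_missing(config$n_subjects)
             else config$missing

  say("simulate + extract: ", config$n_subjects, " subjects, preset '",
      config$preset, "'")
  sim <- simulate_cohort(config$n_subjects, missing, cc)
  if (config$write_signals) {
    say("writing raw signals")
    for (m in generate_cohort(config$n_subjects, missing, cc))
      write_measurement(m, file.path(out, "signals"))
  }
  write_table_csv(sim$features, file.path(out, "features.csv"))
  write_questionnaire(sim$questionnaire, file.path(out, "questionnaire.csv"))

  say("score questionnaires")
  iset <- compute_indexes(sim$questionnaire)
  write_table_csv(iset$indexes, file.path(out, "indexes.csv"))
  write_table_csv(iset$marginals$symptoms,
                  file.path(out, "marginals_symptoms.csv"))
  write_table_csv(iset$marginals$indexes,
                  file.path(out, "marginals_indexes.csv"))

  cohort <- build_cohort_table(sim$features, iset)
  write_table_csv(cohort, file.path(out, "cohort.csv"))

  say("univariate screening")
  sig <- significance_matrix(cohort)
  write_table_csv(as.data.frame(sig), file.path(out, "significance.csv"))

  say("classifier benchmark: ", paste(config$models, collapse = "/"),
      " on ", paste(config$labels, collapse = ","))
  bench <- benchmark_all(cohort, labels = config$labels,
                         models = config$models, k = config$cv_folds,
                         seeds = config$cv_seeds,
                         base_seed = config$seed * 1000L)
  write_table_csv(bench$metrics, file.path(out, "metrics.csv"))
  for (lab in config$labels)
    write_table_csv(as.data.frame(bench$importance[[lab]]),
                    file.path(out, paste0("importance_", lab, ".csv")))

  say("change reports")
  changes <- list(features = change_report(cohort, feature_names()),
                  symptoms = change_report(sim$questionnaire,
                                           symptom_names(), tolerance = 0))
  write_table_csv(changes$features, file.path(out, "changes_features.csv"))
  write_table_csv(changes$symptoms, file.path(out, "changes_symptoms.csv"))

  manifest <- list(config = unclass(config), seed = config$seed,
                   package_version = as.character(utils::packageVersion("mssignal")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   n_measurements = nrow(cohort),
                   excluded_rows = attr(cohort, "excluded"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done: ", out)
  invisible(list(cohort = cohort, index_set = iset, significance = sig,
                 benchmark = bench, changes = changes))
}

#' Per-subject direction-of-change report
#'
#' For every subject with a static (P0) measurement, the sign of the
#' change of each column between P0 and each wave protocol:
#' `"up"`, `"down"` or `"unchanged"` (absolute difference below
#' `tolerance`).  Subjects without a P0 row are skipped with a warning;
#' rows for a missing wave protocol are omitted.
#'
#' @param table Data frame with `subject_id`, `protocol` and the value
#'   columns.
#' @param columns Which columns to compare (default: the 19 features
#'   present in `table`).
#' @param tolerance Absolute difference below which a change counts as
#'   `"unchanged"` (use 0 for integer symptom scores).
#' @return Long data frame: `subject_id`, `protocol`, `variable`,
#'   `direction`.
#' @export
change_report <- function(table,
                          columns = intersect(feature_names(), names(table)),
                          tolerance = 1e-9) {
  table <- as.data.frame(table)
  stopifnot(all(c("subject_id", "protocol") %in% names(table)),
            length(columns) > 0)
  out <- list()
  for (s in unique(table$subject_id)) {
    sub <- table[table$subject_id == s, ]
    p0 <- sub[sub$protocol == "P0", ]
    if (nrow(p0) == 0) {
      warning("subject ", s, " has no P0 row; skipped")
      next
    }
    for (p in intersect(c("P1", "P3"), sub$protocol)) {
      delta <- as.numeric(sub[sub$protocol == p, columns][1, ]) -
        as.numeric(p0[1, columns])
      dir <- ifelse(is.na(delta), NA_character_,
                    ifelse(abs(delta) <= tolerance, "unchanged",
                           ifelse(delta > 0, "up", "down")))
      out[[length(out) + 1L]] <- data.frame(subject_id = s, protocol = p,
                                            variable = columns,
                                            direction = dir)
    }
  }
  do.call(rbind, out)
}
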