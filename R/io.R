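#' Write / read a recording as CSV with a JSON sidecar
#'
#' Signals are stored as plain CSV (one column per channel, one row per
#' sample) next to a `.json` sidecar holding the sampling rate, modality
#' and channel labels, so a measurement directory is self-describing and
#' fully round-trips through [read_recording()].
#'
#' @param rec A [recording()].
#' @param path CSV file path (sidecar written as `<path>.json`).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  df <- as.data.frame(t(rec$samples))
  names(df) <- rec$labels
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(rate = rec$rate, modality = rec$modality,
                            labels = rec$labels),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  recording(t(as.matrix(df)), meta$rate, meta$labels, meta$modality)
}

#' Write a measurement's recordings and questionnaire to a directory
#'
#' Layout: `subject<id>/<protocol>/{eeg.csv,emg.csv,hr.csv}` plus sidecars;
#' questionnaires are collected by the caller into a single cohort CSV.
#'
#' @param m A `measurement`.
#' @param dir Output root directory.
#' @return The measurement directory, invisibly.
#' @export
write_measurement <- function(m, dir) {
  d <- file.path(dir, sprintf("subject%02d", m$subject_id), m$protocol$name)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  write_recording(m$eeg, file.path(d, "eeg.csv"))
  write_recording(m$emg, file.path(d, "emg.csv"))
  write_recording(m$hr, file.path(d, "hr.csv"))
  invisible(d)
}

#' Read / write the cohort questionnaire table
#'
#' One row per measurement: `subject_id`, `protocol`, then the 13 symptom
#' columns in [symptom_names()] order.
#'
#' @param df Data frame in that layout.
#' @param path CSV path.
#' @export
write_questionnaire <- function(df, path) {
  stopifnot(all(c("subject_id", "protocol", symptom_names()) %in% names(df)))
  utils::write.csv(df[c("subject_id", "protocol", symptom_names())], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_questionnaire
#' @export
read_questionnaire <- function(path) {
  df <- utils::read.csv(path)
  miss <- setdiff(symptom_names(), names(df))
  if (length(miss)) stop("questionnaire lacks columns: ",
                         paste(miss, collapse = ", "))
  df
}

# generic CSV writers for tables whose reader is plain read.csv
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Join features and indexes into the cohort analysis table
#'
#' Merges the feature table with the computed index table on
#' `(subject_id, protocol)`.  The join is audited: the output row count
#' plus the number of logged exclusions always equals the input row
#' count.
#'
#' @param features Feature data frame from [simulate_cohort()] or
#'   [read_questionnaire()]-style CSV.
#' @param index_set An `index_set` from [compute_indexes()] (or its
#'   `indexes` data frame).
#' @return Data frame with id columns, 19 features, 8 indexes and
#'   `SumMS`; attribute `"excluded"` counts feature rows without a
#'   questionnaire match.
#' @export
build_cohort_table <- function(features, index_set) {
  idx <- if (inherits(index_set, "index_set")) index_set$indexes else index_set
  out <- merge(features, idx, by = c("subject_id", "protocol"), sort = FALSE)
  excluded <- nrow(features) - nrow(out)
  if (excluded > 0)
    warning(excluded, " feature row(s) had no questionnaire match")
  out <- out[order(out$subject_id, out$protocol), ]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
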