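#' Recording container
#'
#' One modality's multichannel time series: a channels x time numeric
#' matrix plus its sampling rate and channel labels.  EEG recordings carry
#' 64 channels at 500 Hz, EMG two channels (left/right gastrocnemius) at
#' 1600 Hz, and the heart-rate series is a single 1-Hz beats/min channel
#' (the chest sensor's native sampling only matters for beat detection,
#' which happens upstream of this representation).
#'
#' @param samples Numeric channels x time matrix (microvolts for EEG/EMG,
#'   beats/min for HR).
#' @param rate Sampling rate in Hz.
#' @param labels Unique channel names, one per row of `samples`.
#' @param modality One of `"EEG"`, `"EMG"`, `"HR"`.
#' @return An object of class `recording`.
#' @export
recording <- function(samples, rate, labels, modality = c("EEG", "EMG", "HR")) {
  modality <- match.arg(modality)
  samples <- as.matrix(samples)
  stopifnot(rate > 0, nrow(samples) == length(labels),
            !anyDuplicated(labels))
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("recording contains NA or non-finite samples")
  structure(list(samples = samples, rate = rate,
                 labels = as.character(labels), modality = modality),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s: %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              x$modality, nrow(x$samples), ncol(x$samples), x$rate,
              ncol(x$samples) / x$rate))
  invisible(x)
}

# canonical 64 EEG channel names: extended 10-10 selection
eeg_channel_names <- function() {
  layout <- eeg_layout()
  layout$label
}

# Idealized 10-10 electrode layout: labels with 2-D positions from the
# standard polar projection (azimuth/ring scheme).  Shipped as a plain-text
# fixture so bad-channel interpolation is deterministic.
eeg_layout <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "eeg_layout_64.csv", package = "mssignal")
      if (path == "")  # during in-source development
        path <- file.path("inst", "extdata", "eeg_layout_64.csv")
      cache <<- utils::read.csv(path, stringsAsFactors = FALSE)
    }
    cache
  }
})
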