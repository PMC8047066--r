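#' Names of the 19 biometric features
#'
#' Five EEG relative band powers, two EMG rectified-signal areas, five
#' relative spectral-band shares per leg, and the heart-rate mean and
#' standard deviation, in canonical table order.
#'
#' @return Character vector of length 19.
#' @export
feature_names <- function() {
  c("eeg_delta", "eeg_theta", "eeg_alpha", "eeg_beta", "eeg_lg",
    "emg_L_area", "emg_R_area",
    paste0("emg_L_", rownames(emg_bands())),
    paste0("emg_R_", rownames(emg_bands())),
    "hr_average", "hr_std")
}

#' Rectified-signal area of an EMG trace
#'
#' The integral of the rectified (absolute-value) signal divided by the
#' number of samples, i.e. the mean absolute amplitude in microvolts.
#'
#' @param x Numeric vector (one filtered EMG channel).
#' @return Non-negative scalar.
#' @examples
#' emg_area(c(3, -4, 0, 5))  # 3
#' @export
emg_area <- function(x) {
  if (length(x) == 0) stop("empty signal")
  mean(abs(x))
}

#' Heart-rate summary features
#'
#' @param hr A heart-rate [recording()] (or numeric beats/min vector).
#' @return Named vector: `hr_average` and `hr_std` (sample standard
#'   deviation; 0 for a length-1 series).
#' @export
hr_stats <- function(hr) {
  x <- if (inherits(hr, "recording")) as.numeric(hr$samples) else as.numeric(hr)
  if (length(x) == 0) stop("empty heart-rate series")
  s <- if (length(x) > 1) stats::sd(x) else 0
  c(hr_average = mean(x), hr_std = s)
}

#' EEG preprocessing: reference, filter, channel QC, epoching
#'
#' Implements the standard resting-EEG cleanup chain in a fixed order:
#' common average reference; zero-phase 0.1--40 Hz band-pass (the squared
#' magnitude of a 4th-order Butterworth — the forward-backward response —
#' applied spectrally); mark a channel bad when any
#' sample exceeds `reject_uv` microvolts; reject the whole trial when more
#' than `reject_frac` of channels are bad; otherwise interpolate bad
#' channels by inverse-distance weighting of their four nearest neighbours
#' on the idealized 10-10 layout; subtract each channel's DC offset
#' estimated from the static (0-Hz) baseline recording; cut consecutive
#' 30-s epochs; and drop any epoch in which a kept channel still exceeds
#' the amplitude threshold (the automated stand-in for manual artifact
#' review).
#'
#' @param eeg 64-channel EEG [recording()].
#' @param baseline The same subject's 0-Hz protocol EEG [recording()];
#'   used only to estimate per-channel offsets.
#' @param reject_uv Amplitude threshold in microvolts (default 300).
#' @param reject_frac Maximal tolerated fraction of bad channels (default
#'   0.20, strictly-greater rule).
#' @param epoch_sec Epoch length in seconds (default 30).
#' @return An object of class `epoch_set`: list with `epochs` (list of
#'   channels x samples matrices), `rate`, `kept_channels`,
#'   `rejected_channels`, `rejected_epochs`, `rejected` (logical: whole
#'   trial), `reason`.  A rejected trial is a value, not an error.
#' @export
eeg_preprocess <- function(eeg, baseline = eeg, reject_uv = 300,
                           reject_frac = 0.20, epoch_sec = 30) {
  stopifnot(inherits(eeg, "recording"))
  if (nrow(eeg$samples) != 64)
    stop("EEG recording must have 64 channels, got ", nrow(eeg$samples))
  if (abs(baseline$rate - eeg$rate) > 1e-9)
    stop("baseline must share the EEG sampling rate")
  x <- t(eeg$samples)                       # time x channels
  x <- x - rowMeans(x)                      # common average reference
  x <- butter_bandpass_zerophase(x, eeg$rate, 0.1, 40)
  off <- rowMeans(baseline$samples)
  eeg_qc_epoch(x, eeg$rate, eeg$labels, off, reject_uv, reject_frac,
               epoch_sec)
}

# QC + epoching back-end shared by eeg_preprocess and the fused
# spectrum-domain path: bad-channel marking, trial rejection,
# interpolation, baseline offset subtraction, epoch cutting, epoch QC.
eeg_qc_epoch <- function(x, rate, labels, baseline_offsets, reject_uv = 300,
                         reject_frac = 0.20, epoch_sec = 30) {
  peak <- pmax(apply(x, 2, max), -apply(x, 2, min))
  bad <- which(peak > reject_uv)
  empty <- function(reason) structure(
    list(epochs = list(), rate = rate, kept_channels = character(0),
         rejected_channels = labels[bad], rejected_epochs = integer(0),
         rejected = TRUE, reason = reason), class = "epoch_set")
  if (length(bad) / ncol(x) > reject_frac)
    return(empty(sprintf("trial rejected: %d of %d channels (> %.0f%%) over %g uV",
                         length(bad), ncol(x), 100 * reject_frac, reject_uv)))
  if (length(bad))
    x[, bad] <- interpolate_channels(x, bad, labels)
  # baseline DC-offset correction from the static recording (centred so it
  # is consistent with the average reference)
  off <- baseline_offsets - mean(baseline_offsets)
  x <- sweep(x, 2, off)
  ne <- floor(nrow(x) / (epoch_sec * rate))
  if (ne == 0) return(empty("recording shorter than one epoch"))
  len <- epoch_sec * rate
  tc <- lapply(seq_len(ne), function(i)
    x[((i - 1) * len + 1):(i * len), , drop = FALSE])   # time x channels
  bad_ep <- which(vapply(tc, function(e)
    max(e) > reject_uv || min(e) < -reject_uv, logical(1)))
  keep <- setdiff(seq_len(ne), bad_ep)
  if (!length(keep)) return(empty("all epochs rejected"))
  structure(list(epochs = lapply(tc[keep], t), rate = rate,
                 kept_channels = labels,
                 rejected_channels = labels[bad],
                 rejected_epochs = bad_ep, rejected = FALSE, reason = NULL,
                 epochs_tc = tc[keep]),
            class = "epoch_set")
}

# Fused preprocessing of a synthetic EEG given directly as its sparse
# spectrum: the common average reference and the zero-phase band-pass are
# both linear, so they are applied to the Fourier coefficients before a
# single inverse transform.  Numerically equivalent to
# generate_recording() |> eeg_preprocess() (the baseline offsets of the
# band-limited synthetic signals are exactly zero), at one FFT per trial.
eeg_preprocess_spectrum <- function(sp, reject_uv = 300, reject_frac = 0.20,
                                    epoch_sec = 30) {
  Z <- sp$Z - rowMeans(sp$Z)                # common average reference
  w <- 2 * pi * sp$freq
  w1 <- 2 * pi * 0.1; w2 <- 2 * pi * 40
  h2 <- 1 / (1 + ((w^2 - w1 * w2) / (w * (w2 - w1)))^8)
  x <- sparse_spectrum_signal(sp$n, sp$kpos, Z * h2)
  eeg_qc_epoch(x, sp$rate, sp$labels, numeric(length(sp$labels)),
               reject_uv, reject_frac, epoch_sec)
}

#' @export
print.epoch_set <- function(x, ...) {
  if (x$rejected) cat("<epoch_set> TRIAL REJECTED:", x$reason, "\n")
  else cat(sprintf("<epoch_set> %d epoch(s), %d channel(s), %d interpolated, %d epoch(s) dropped\n",
                   length(x$epochs), length(x$kept_channels),
                   length(x$rejected_channels), length(x$rejected_epochs)))
  invisible(x)
}

# Inverse-distance-weighted reconstruction of bad channels from their four
# nearest good neighbours on the idealized layout.
interpolate_channels <- function(x, bad, labels, k = 4) {
  layout <- eeg_layout()
  pos <- as.matrix(layout[match(labels, layout$label), c("x", "y")])
  good <- setdiff(seq_along(labels), bad)
  vapply(bad, function(b) {
    d <- sqrt(colSums((t(pos[good, , drop = FALSE]) - pos[b, ])^2))
    nb <- good[order(d)][seq_len(min(k, length(good)))]
    w <- 1 / pmax(d[order(d)][seq_len(length(nb))], 1e-6)
    as.numeric(x[, nb, drop = FALSE] %*% (w / sum(w)))
  }, numeric(nrow(x)))
}

#' EEG relative band powers from an epoch set
#'
#' For every epoch and channel, a Welch PSD (2-s Hann windows, 50 %
#' overlap) is reduced to relative shares of the five canonical bands —
#' delta 0.5--4, theta 4--8, alpha 8--13, beta 13--35, low gamma 35--40 Hz
#' — then shares are averaged across channels and finally across epochs.
#'
#' @param epochs An `epoch_set` from [eeg_preprocess()].
#' @return Named numeric vector of 5 shares summing to 1
#'   (`eeg_delta` ... `eeg_lg`).
#' @export
eeg_band_relpower <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (epochs$rejected || length(epochs$epochs) == 0)
    stop("no usable epochs: EEG features are missing for this trial")
  rate <- epochs$rate
  tc <- epochs$epochs_tc                     # time-major views, if cached
  if (is.null(tc)) tc <- lapply(epochs$epochs, t)
  nep <- length(tc); nch <- ncol(tc[[1]]); epl <- nrow(tc[[1]])
  nw <- round(2 * rate)                      # 2-s Hann windows, 50% overlap
  if (epl < nw) stop("epoch shorter than one Welch window")
  xall <- do.call(rbind, tc)
  within <- seq(1L, epl - nw + 1L, by = nw %/% 2L)
  nsw <- length(within)
  starts <- as.vector(outer(within, (seq_len(nep) - 1L) * epl, `+`))
  idx <- as.vector(outer(seq_len(nw) - 1L, starts, `+`))
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / (nw + 1))
  seg <- xall[idx, , drop = FALSE]
  dim(seg) <- c(nw, length(starts) * nch)
  seg <- seg * w
  nf <- nw %/% 2 + 1L
  pw <- packed_power(seg)[seq_len(nf), , drop = FALSE]
  freq <- (seq_len(nf) - 1L) * rate / nw
  b <- eeg_bands()
  sel <- vapply(seq_len(nrow(b)), function(i)
    as.numeric(freq >= b[i, 1] & freq < b[i, 2]), numeric(nf))
  bp <- crossprod(sel, pw)                   # bands x (seg, epoch, channel)
  dim(bp) <- c(nrow(b), nsw, nep * nch)
  bp <- apply(bp, c(1, 3), sum)              # Welch average per epoch/channel
  sh <- sweep(bp, 2, colSums(bp), "/")       # shares per (epoch, channel)
  stats::setNames(rowMeans(sh), paste0("eeg_", rownames(b)))
}

#' Extract the 19 biometric features of one measurement
#'
#' EMG chain per leg: 50th-order FIR band-pass 40--500 Hz, then the
#' rectified-signal area and the five relative PSD band shares (whole-trace
#' periodogram).  EEG chain: [eeg_preprocess()] then [eeg_band_relpower()];
#' if the trial is rejected the five EEG features are returned as `NA` and
#' downstream analyses drop or impute them per their own policy.  HR chain:
#' mean and sample standard deviation.
#'
#' @param measurement A `measurement` (see [generate_measurement()]), or
#'   any list with `eeg`, `emg`, `hr` recordings.
#' @param baseline Optional 0-Hz EEG [recording()] for offset correction;
#'   defaults to the measurement's own EEG.
#' @param fir_order EMG filter order.
#' @return Named numeric vector over [feature_names()] (length 19).
#' @export
extract_features <- function(measurement, baseline = NULL, fir_order = 50) {
  stopifnot(!is.null(measurement$eeg), !is.null(measurement$emg),
            !is.null(measurement$hr))
  eeg_feats <- stats::setNames(rep(NA_real_, 5),
                               paste0("eeg_", rownames(eeg_bands())))
  ep <- eeg_preprocess(measurement$eeg,
                       baseline = if (is.null(baseline)) measurement$eeg
                                  else baseline)
  if (!ep$rejected) eeg_feats <- eeg_band_relpower(ep)
  assemble_features(eeg_feats, measurement$emg, measurement$hr, fir_order)
}

# EMG + HR feature block and final ordering, shared with the streaming
# fast path.
assemble_features <- function(eeg_feats, emg, hr, fir_order = 50) {
  if (nrow(emg$samples) != 2) stop("EMG must carry exactly 2 channels (L, R)")
  legs <- lapply(1:2, function(i) {
    filt <- bandpass_fir(as.numeric(emg$samples[i, ]), emg$rate,
                         40, 500, fir_order)
    c(area = emg_area(filt),
      relative_band_power(filt, emg$rate, emg_bands(), "periodogram"))
  })
  out <- c(eeg_feats,
           emg_L_area = legs[[1]][["area"]], emg_R_area = legs[[2]][["area"]],
           stats::setNames(legs[[1]][-1], paste0("emg_L_", rownames(emg_bands()))),
           stats::setNames(legs[[2]][-1], paste0("emg_R_", rownames(emg_bands()))),
           hr_stats(hr))
  out[feature_names()]
}

#' Stream a cohort straight into its feature and questionnaire tables
#'
#' Generates each subject's three measurements one at a time, extracts the
#' 19 features, and discards the raw signals, so arbitrarily large cohorts
#' fit in memory.  The EEG leg runs through the fused spectrum-domain
#' preprocessing (numerically equivalent to generating the recording and
#' calling [eeg_preprocess()], at a third of the FFT work; the synthetic
#' recordings are exactly DC-free, so the static-baseline offset
#' correction is identically zero).
#'
#' @inheritParams generate_cohort
#' @param progress Print one line per subject.
#' @return List with `features` (data frame: subject_id, protocol, 19
#'   feature columns) and `questionnaire` (data frame: subject_id,
#'   protocol, 13 symptom columns).
#' @export
simulate_cohort <- function(n_subjects = 28,
                            missing = default_missing(n_subjects),
                            config = coupling_preset("strong"),
                            progress = FALSE) {
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop("n_subjects must be a positive count")
  n_subjects <- as.integer(n_subjects)
  skip <- check_missing(n_subjects, missing)
  feats <- list(); quest <- list()
  for (s in seq_len(n_subjects)) {
    if (progress) message("subject ", s, "/", n_subjects)
    latent <- generate_latent(s, config)
    for (p in c("P0", "P1", "P3")) {
      if (paste0(s, ":", p) %in% skip) next
      proto <- protocol_spec(p)
      # EEG via the fused spectrum path (one FFT per trial); seeded exactly
      # as generate_recording so the two routes draw identical signals
      set.seed(derive_seed(config$seed, "rec", s, p, "EEG"))
      sp <- sim_eeg_spectrum(latent, proto, config)
      ep <- eeg_preprocess_spectrum(sp)
      eeg_feats <- stats::setNames(rep(NA_real_, 5),
                                   paste0("eeg_", rownames(eeg_bands())))
      if (!ep$rejected) eeg_feats <- eeg_band_relpower(ep)
      emg <- generate_recording(latent, proto, "EMG", config, s)
      hr <- generate_recording(latent, proto, "HR", config, s)
      fv <- assemble_features(eeg_feats, emg, hr)
      q <- generate_questionnaire(latent, proto, config, s)
      feats[[length(feats) + 1L]] <-
        data.frame(subject_id = s, protocol = p, t(fv))
      quest[[length(quest) + 1L]] <-
        data.frame(subject_id = s, protocol = p, t(q))
    }
  }
  list(features = do.call(rbind, feats),
       questionnaire = do.call(rbind, quest))
}
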