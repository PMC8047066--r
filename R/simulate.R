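#' Draw a subject's latent physiological state
#'
#' Subjects differ in a scalar motion-sickness susceptibility (uniform on
#' \[0, 1\]), a resting heart rate, a baseline gastrocnemius activation
#' level, and an individual EEG beta-oscillator gain.  These four numbers
#' are the only subject-level quantities the generator conditions on; all
#' coupling between them and the observable data is governed by the
#' [coupling_config()].
#'
#' @param subject_id Integer subject identifier.
#' @param config A [coupling_config()]; its seed and the subject id fix the
#'   draw.
#' @return A list with `susceptibility`, `hr_baseline`, `emg_tone`,
#'   `eeg_beta_gain`.
#' @export
generate_latent <- function(subject_id, config) {
  set.seed(derive_seed(config$seed, "latent", subject_id))
  list(susceptibility = stats::runif(1),
       hr_baseline = stats::rnorm(1, 70, 6),
       emg_tone = exp(stats::rnorm(1, log(30), 0.2)),
       eeg_beta_gain = exp(stats::rnorm(1, 0, 0.2)))
}

#' Generate one synthetic recording
#'
#' The generative model, per modality:
#' \describe{
#'   \item{EEG}{Per channel, a 1/f background plus Gaussian spectral bumps
#'     for the delta/theta/alpha/beta/low-gamma oscillators, synthesized by
#'     spectrally shaping white noise.  The beta bump amplitude is scaled
#'     by `1 + eeg_beta_effect * susceptibility * intensity`, where
#'     intensity is the [protocol_intensity()].}
#'   \item{EMG}{Per 30-s protocol segment, Gaussian noise shaped to a
#'     40--500 Hz envelope.  Overall amplitude scales with
#'     `emg_tone * (0.3 + platform_amplitude * (1 + emg_amp_effect *
#'     susceptibility))` and the envelope concentrates toward the low
#'     (40--132 Hz) band as the same drive grows, so both the rectified
#'     area and the low-band share respond to platform amplitude and, when
#'     coupled, to susceptibility.}
#'   \item{HR}{A 1-Hz beats/min series: `hr_baseline + hr_effect *
#'     susceptibility * intensity` plus an AR(1) drift (coefficient 0.9).}
#' }
#'
#' @param latent Output of [generate_latent()].
#' @param protocol A [protocol_spec()].
#' @param modality `"EEG"`, `"EMG"` or `"HR"`.
#' @param config A [coupling_config()].
#' @param subject_id Used only for hierarchical seeding, so any single
#'   recording can be regenerated without replaying the whole cohort.
#' @return A [recording()].
#' @export
generate_recording <- function(latent, protocol,
                               modality = c("EEG", "EMG", "HR"),
                               config, subject_id = 0L) {
  modality <- match.arg(modality)
  stopifnot(inherits(protocol, "protocol_spec"),
            inherits(config, "coupling_config"))
  set.seed(derive_seed(config$seed, "rec", subject_id, protocol$name, modality))
  switch(modality,
         EEG = sim_eeg(latent, protocol, config),
         EMG = sim_emg(latent, protocol, config),
         HR  = sim_hr(latent, protocol, config))
}

# Band-limited random spectrum synthesis.  Rather than filtering white
# noise, the generator draws complex-Gaussian Fourier coefficients only at
# the in-band bins (positive half), with per-bin amplitudes given by the
# spectral profile: the exact stationary-Gaussian model, and far cheaper
# than shaping white noise with a forward transform.
draw_sparse_spectrum <- function(n, kpos, amp_rows) {
  m <- length(kpos); nch <- ncol(amp_rows)
  sdv <- sqrt(n / 2)
  (matrix(stats::rnorm(m * nch, 0, sdv), m, nch) +
     1i * matrix(stats::rnorm(m * nch, 0, sdv), m, nch)) * amp_rows
}

# Real signals (time x channels) from positive-half coefficients by the
# Hermitian inverse transform, two channels per complex FFT (channel pair
# packed as real/imaginary part).
sparse_spectrum_signal <- function(n, kpos, Z) {
  nch <- ncol(Z)
  padded <- nch %% 2L == 1L
  if (padded) Z <- cbind(Z, 0i)
  odd <- seq(1L, ncol(Z), 2L)
  S <- matrix(0i, n, length(odd))
  S[kpos, ] <- Z[, odd, drop = FALSE] + 1i * Z[, odd + 1L, drop = FALSE]
  S[n - kpos + 2L, ] <- Conj(Z[, odd, drop = FALSE]) +
    1i * Conj(Z[, odd + 1L, drop = FALSE])
  Y <- stats::mvfft(S, inverse = TRUE) / n
  x <- matrix(0, n, ncol(Z))
  x[, odd] <- Re(Y)
  x[, odd + 1L] <- Im(Y)
  if (padded) x[, seq_len(nch), drop = FALSE] else x
}

# positive-half bin indices (DC excluded) with frequency in [lo, hi]
band_bins <- function(n, rate, lo, hi) {
  k <- seq(2L, floor(n / 2) + 1L)
  f <- (k - 1L) * rate / n
  keep <- f >= lo & f <= hi
  list(k = k[keep], f = f[keep])
}

eeg_bump <- function(f, c0, w, a) a * exp(-(f - c0)^2 / (2 * w^2))

# Per-channel spectral amplitude profile: 1/f background plus
# delta/theta/alpha/beta/low-gamma oscillator bumps; the beta bump scales
# with susceptibility x intensity.  The draw order (channel gains, beta
# gains, then Fourier coefficients) is fixed -- it defines the generator's
# seed contract.
sim_eeg_spectrum <- function(latent, protocol, config) {
  rate <- MODALITY_RATES[["EEG"]]
  n <- round(protocol$duration * rate)
  labels <- eeg_channel_names()
  nch <- length(labels)
  inten <- protocol_intensity(protocol)
  beta_scale <- latent$eeg_beta_gain *
    (1 + config$eeg_beta_effect * latent$susceptibility * inten)
  bb <- band_bins(n, rate, 0.2, 45)
  base <- sqrt(60 / (bb$f + 0.6)) +
    eeg_bump(bb$f, 2, 1.2, 3) + eeg_bump(bb$f, 6, 1.5, 2.5) +
    eeg_bump(bb$f, 10, 1.5, 4) + eeg_bump(bb$f, 37.5, 1.5, 1)
  beta <- eeg_bump(bb$f, 22, 5, 2.5 * beta_scale)
  sd_ch <- config$noise_sd[["eeg"]]
  gain <- pmax(0.2, 1 + stats::rnorm(nch, 0, sd_ch))
  beta_g <- pmax(0.2, 1 + stats::rnorm(nch, 0, sd_ch))
  amp <- 8 * (outer(base, gain) + outer(beta, beta_g))   # ~10 uV RMS
  list(n = n, rate = rate, labels = labels, kpos = bb$k, freq = bb$f,
       Z = draw_sparse_spectrum(n, bb$k, amp))
}

sim_eeg <- function(latent, protocol, config) {
  sp <- sim_eeg_spectrum(latent, protocol, config)
  sig <- sparse_spectrum_signal(sp$n, sp$kpos, sp$Z)
  recording(t(sig), sp$rate, sp$labels, "EEG")
}

# EMG segments: the static protocol is one segment at zero platform
# amplitude; wave protocols use their four 25/50/75/25 % segments.
emg_segments <- function(protocol) {
  if (nrow(protocol$segments)) protocol$segments
  else data.frame(duration = protocol$duration, platform_amplitude = 0)
}

sim_emg <- function(latent, protocol, config) {
  rate <- MODALITY_RATES[["EMG"]]
  segs <- emg_segments(protocol)
  sd_amp <- config$noise_sd[["emg"]]
  chans <- lapply(seq_len(nrow(segs)), function(i) {
    amp_frac <- segs$platform_amplitude[i] / 100
    drive <- amp_frac * (1 + config$emg_amp_effect * latent$susceptibility)
    n <- round(segs$duration[i] * rate)
    # spectral envelope concentrates toward the low band as drive grows
    tau <- 220 / (1 + 1.2 * drive)
    bb <- band_bins(n, rate, 30, 520)
    env <- matrix(exp(-pmax(bb$f - 40, 0) / tau), ncol = 1)[, c(1, 1)]
    amp <- latent$emg_tone * (0.3 + drive) *
      pmax(0.2, 1 + stats::rnorm(2, 0, sd_amp))
    raw <- sparse_spectrum_signal(n, bb$k, draw_sparse_spectrum(n, bb$k, env))
    raw <- sweep(raw, 2, sqrt(colMeans(raw^2)), "/")  # unit RMS per channel
    t(t(raw) * amp)
  })
  samples <- t(do.call(rbind, chans))
  recording(samples, rate, c("EMG_L", "EMG_R"), "EMG")
}

sim_hr <- function(latent, protocol, config) {
  rate <- MODALITY_RATES[["HR"]]
  n <- round(protocol$duration * rate)
  inten <- protocol_intensity(protocol)
  level <- latent$hr_baseline +
    config$hr_effect * latent$susceptibility * inten
  drift <- as.numeric(stats::filter(stats::rnorm(n, 0, config$noise_sd[["hr"]]),
                                    0.9, method = "recursive"))
  recording(matrix(level + drift, 1), rate, "HR", "HR")
}

#' Generate a questionnaire response from the ordinal threshold model
#'
#' Each of the 13 symptoms is scored as the number of cut points lying
#' below `g + noise`, where the latent symptom drive is
#' `g = symptom_gain * susceptibility * intensity` and the noise is drawn
#' independently per symptom.  Scores are therefore integers in
#' \{0, 1, 2\} that increase stochastically with both susceptibility and
#' protocol intensity.
#'
#' @inheritParams generate_recording
#' @return Named integer vector over [symptom_names()], values in 0..2.
#' @export
generate_questionnaire <- function(latent, protocol, config, subject_id = 0L) {
  stopifnot(inherits(config, "coupling_config"))
  set.seed(derive_seed(config$seed, "mssq", subject_id, protocol$name))
  g <- config$symptom_gain * latent$susceptibility *
    protocol_intensity(protocol)
  noise <- stats::rnorm(length(symptom_names()), 0,
                        config$noise_sd[["symptom"]])
  cuts <- config$symptom_thresholds
  score <- vapply(g + noise, function(v) sum(v > cuts), numeric(1))
  stats::setNames(as.integer(score), symptom_names())
}

#' Generate one subject-by-protocol measurement
#'
#' @inheritParams generate_recording
#' @return A list of class `measurement` with `subject_id`, `protocol`,
#'   recordings `eeg`, `emg`, `hr`, and `questionnaire`.
#' @export
generate_measurement <- function(subject_id, protocol, latent, config) {
  structure(list(
    subject_id = subject_id,
    protocol = protocol,
    eeg = generate_recording(latent, protocol, "EEG", config, subject_id),
    emg = generate_recording(latent, protocol, "EMG", config, subject_id),
    hr  = generate_recording(latent, protocol, "HR",  config, subject_id),
    questionnaire = generate_questionnaire(latent, protocol, config,
                                           subject_id)),
    class = "measurement")
}

#' @export
print.measurement <- function(x, ...) {
  cat(sprintf("<measurement> subject %s, protocol %s\n", x$subject_id,
              x$protocol$name))
  invisible(x)
}

check_missing <- function(n_subjects, missing) {
  if (length(missing) == 0) return(character(0))
  keys <- vapply(missing, function(m) {
    s <- as.integer(m[[1]]); p <- as.character(m[[2]])
    if (is.na(s) || s < 1 || s > n_subjects)
      stop("missing pair refers to unknown subject: ", m[[1]])
    if (!p %in% c("P0", "P1", "P3"))
      stop("missing pair refers to unknown protocol: ", p)
    paste0(s, ":", p)
  }, character(1))
  if (anyDuplicated(keys)) stop("duplicate missing pair")
  keys
}

#' Generate a full synthetic cohort of measurements
#'
#' The default layout mirrors the study design: 28 subjects performing all
#' three protocols except one subject who skips the 3-Hz protocol, i.e.
#' `28 * 3 - 1 = 83` measurements.
#'
#' Note the memory cost: each EEG recording is a 64 x 60000 matrix, so a
#' materialized 83-measurement cohort holds roughly 2.5 GB of signal.  Use
#' [simulate_cohort()] to stream generation straight into feature
#' extraction when only the feature table is needed.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param missing List of `(subject, protocol)` pairs to omit, e.g.
#'   `list(c(28, "P3"))`.  Defaults to the last subject missing `P3` when
#'   `n_subjects` matches the 28-subject study layout, otherwise empty.
#' @param config A [coupling_config()].
#' @return List of `measurement` objects, ordered by subject then protocol.
#' @export
generate_cohort <- function(n_subjects = 28,
                            missing = default_missing(n_subjects),
                            config = coupling_preset("strong")) {
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop("n_subjects must be a positive count")
  n_subjects <- as.integer(n_subjects)
  skip <- check_missing(n_subjects, missing)
  out <- list()
  for (s in seq_len(n_subjects)) {
    latent <- generate_latent(s, config)
    for (p in c("P0", "P1", "P3")) {
      if (paste0(s, ":", p) %in% skip) next
      out[[length(out) + 1L]] <-
        generate_measurement(s, protocol_spec(p), latent, config)
    }
  }
  out
}

#' @rdname generate_cohort
#' @export
default_missing <- function(n_subjects) {
  if (n_subjects == 28) list(c(28, "P3")) else list()
}
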