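#' Measurement protocol descriptors
#'
#' Each subject performs three platform protocols: a static 60-s baseline
#' (`P0`, 0 Hz waves) and two 120-s wave protocols at 1 Hz (`P1`, wave
#' amplitude 0.6) and 3 Hz (`P3`, wave amplitude 0.5).  The wave protocols
#' are divided into four 30-s segments whose platform movement amplitude
#' follows the fixed 25/50/75/25 % schedule.
#'
#' @param name One of `"P0"`, `"P1"`, `"P3"`.
#' @return An object of class `protocol_spec` with fields `name`,
#'   `wave_frequency` (Hz), `wave_amplitude` (unitless), `duration` (s) and
#'   `segments` (data frame of segment durations and platform amplitudes in
#'   percent; empty for `P0`).
#' @examples
#' protocol_spec("P1")$segments
#' @export
protocol_spec <- function(name = c("P0", "P1", "P3")) {
  name <- match.arg(name)
  seg <- function(amps) data.frame(duration = rep(30, length(amps)),
                                   platform_amplitude = amps)
  spec <- switch(name,
    P0 = list(name = "P0", wave_frequency = 0, wave_amplitude = 0,
              duration = 60, segments = seg(numeric(0))),
    P1 = list(name = "P1", wave_frequency = 1, wave_amplitude = 0.6,
              duration = 120, segments = seg(c(25, 50, 75, 25))),
    P3 = list(name = "P3", wave_frequency = 3, wave_amplitude = 0.5,
              duration = 120, segments = seg(c(25, 50, 75, 25))))
  structure(spec, class = "protocol_spec")
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat(sprintf("Protocol %s: %g Hz waves, amplitude %g, %g s", x$name,
              x$wave_frequency, x$wave_amplitude, x$duration))
  if (nrow(x$segments))
    cat(sprintf(", segments %s%%",
                paste(x$segments$platform_amplitude, collapse = "/")))
  cat("\n")
  invisible(x)
}

#' All three protocols, in measurement order.
#' @return Named list of [protocol_spec()] objects (`P0`, `P1`, `P3`).
#' @export
protocol_set <- function() {
  p <- c("P0", "P1", "P3")
  stats::setNames(lapply(p, protocol_spec), p)
}

#' Stimulus intensity of a protocol
#'
#' A scalar summarizing how provocative a protocol is, defined as the wave
#' frequency times the mean platform movement amplitude (as a fraction),
#' so that the static baseline has intensity 0 and the 3-Hz protocol about
#' three times the intensity of the 1-Hz one.  The product form encodes the
#' design premise that faster waves at comparable amplitude are harder on
#' the subject.
#'
#' @param protocol A [protocol_spec()].
#' @return Non-negative scalar.
#' @export
protocol_intensity <- function(protocol) {
  stopifnot(inherits(protocol, "protocol_spec"))
  if (!nrow(protocol$segments)) return(0)
  protocol$wave_frequency * mean(protocol$segments$platform_amplitude) / 100
}

# sampling rates fixed by the acquisition hardware (Hz)
MODALITY_RATES <- c(EEG = 500, EMG = 1600, HR = 1)
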