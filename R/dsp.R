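#' Linear-phase FIR band-pass filtering
#'
#' Designs a Hamming-windowed sinc band-pass filter (the muscle-signal
#' conditioning step: order 50, pass band 40--500 Hz at 1600 Hz sampling)
#' and applies it with full delay compensation, so the output is aligned
#' with and the same length as the input.  The tap mean is subtracted after
#' the window design, which places an exact spectral null at DC; with a low
#' edge this close to DC relative to the filter length, the textbook design
#' alone leaves appreciable DC leakage.
#'
#' @param x Numeric vector (one channel) or matrix with one channel per
#'   column.
#' @param rate Sampling rate in Hz.
#' @param low,high Pass-band edges in Hz.
#' @param order Filter order (number of taps minus one); must be even so the
#'   group delay `order/2` is an integer.
#' @param clip_high If `TRUE` (default) a `high` at or above Nyquist is
#'   clipped to 0.99 of Nyquist so the design stays valid for arbitrary
#'   rates; if `FALSE` such an input is an error.
#' @return Filtered signal, same shape as `x`.  The designed taps are
#'   attached as attribute `"taps"`.
#' @examples
#' x <- sin(2 * pi * 250 * seq(0, 1, by = 1 / 1600))
#' y <- bandpass_fir(x, 1600, 40, 500)
#' @export
bandpass_fir <- function(x, rate, low = 40, high = 500, order = 50,
                         clip_high = TRUE) {
  stopifnot(rate > 0, low > 0, high > low, order %% 2 == 0, order > 0)
  nyq <- rate / 2
  if (high >= nyq) {
    if (!clip_high) stop("upper cutoff must be below Nyquist (", nyq, " Hz)")
    high <- 0.99 * nyq
    if (high <= low) stop("cannot clip upper cutoff above lower cutoff")
  }
  h <- signal::fir1(order, c(low, high) / nyq, type = "pass")
  h <- h - mean(h)                      # exact DC null
  y <- fir_apply(x, h)
  attr(y, "taps") <- as.numeric(h)
  y
}

# Zero-phase application of a symmetric FIR: causal convolution on a
# zero-padded copy, then shift back by the order/2 group delay.
fir_apply <- function(x, h) {
  d <- (length(h) - 1L) %/% 2L
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(as.numeric(x), ncol = 1) else as.matrix(x)
  n <- nrow(xm)
  pad <- matrix(0, 2L * d, ncol(xm))
  xp <- rbind(pad, xm, pad)
  z <- stats::filter(xp, h, method = "convolution", sides = 1)
  y <- z[(3L * d + 1L):(3L * d + n), , drop = FALSE]
  y <- unclass(y)
  if (vec) as.numeric(y) else y
}

# Zero-phase Butterworth band-pass applied spectrally: multiply the FFT by
# the squared magnitude response |H(f)|^2 of the analog band-pass
# prototype, i.e. the response a forward-backward time-domain pass would
# have, without its edge transients.  One FFT pair filters all channels.
butter_bandpass_zerophase <- function(x, rate, low, high, order = 4) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(as.numeric(x), ncol = 1) else as.matrix(x)
  n <- nrow(xm)
  f <- c(seq(0, floor(n / 2)), seq(ceiling(n / 2) - 1, 1)) * rate / n
  w <- 2 * pi * f; w1 <- 2 * pi * low; w2 <- 2 * pi * high
  arg <- ifelse(w > 0, (w^2 - w1 * w2) / (w * (w2 - w1)), Inf)
  h2 <- 1 / (1 + arg^(2 * order))         # |H|^2: order-n pass each way
  y <- Re(stats::mvfft(stats::mvfft(xm) * h2, inverse = TRUE)) / n
  if (vec) as.numeric(y) else y
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram with Hann windows and 50 % overlap.  The
#' 2-s default window gives 0.5-Hz resolution — fine enough for the 0.5-Hz
#' lower edge of the EEG delta band — while still averaging about 29
#' segments per 30-s epoch.
#'
#' @param x Numeric vector, or matrix with one channel per column.
#' @param rate Sampling rate (Hz).
#' @param window_sec Segment length in seconds.
#' @param overlap Fractional overlap between consecutive segments.
#' @return List with `freq` (Hz) and `psd` (one-sided density, a vector for
#'   vector input, else a frequencies x channels matrix).
#' @export
welch_psd <- function(x, rate, window_sec = 2, overlap = 0.5) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(as.numeric(x), ncol = 1) else as.matrix(x)
  nw <- round(window_sec * rate)
  if (nrow(xm) < nw)
    stop("signal shorter than one Welch window (", nw, " samples)")
  hop <- max(1L, round(nw * (1 - overlap)))
  starts <- seq(1L, nrow(xm) - nw + 1L, by = hop)
  nseg <- length(starts)
  nch <- ncol(xm)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / (nw + 1))   # Hann
  idx <- as.vector(outer(seq_len(nw) - 1L, starts, `+`))  # nw * nseg
  seg <- xm[idx, , drop = FALSE]                          # (nw*nseg) x nch
  dim(seg) <- c(nw, nseg * nch)
  seg <- seg * w
  sp <- packed_power(seg) / (rate * sum(w^2))
  nf <- nw %/% 2 + 1L
  sp <- sp[seq_len(nf), , drop = FALSE]
  # one-sided: double every bin except DC (and Nyquist when nw is even)
  dbl <- rep(2, nf); dbl[1] <- 1; if (nw %% 2 == 0) dbl[nf] <- 1
  sp <- sp * dbl
  psd <- vapply(seq_len(nch), function(ch)
    rowMeans(sp[, ((ch - 1L) * nseg + 1L):(ch * nseg), drop = FALSE]),
    numeric(nf))
  freq <- (seq_len(nf) - 1L) * rate / nw
  list(freq = freq, psd = if (vec) psd[, 1] else psd)
}

# |FFT|^2 of each real column, computed two columns per complex transform
# (pack columns 2j-1, 2j as real/imaginary part and split the transform by
# Hermitian symmetry).
packed_power <- function(seg) {
  n <- nrow(seg); m <- ncol(seg)
  padded <- m %% 2L == 1L
  if (padded) seg <- cbind(seg, 0)
  odd <- seq(1L, ncol(seg), 2L)
  Fp <- stats::mvfft(seg[, odd, drop = FALSE] +
                       1i * seg[, odd + 1L, drop = FALSE])
  Rp <- Re(Fp); Ip <- Im(Fp)
  mir <- c(1L, n:2L)
  Rm <- Rp[mir, , drop = FALSE]             # Re Conj(F(-f)) =  Re F(-f)
  Im_ <- -Ip[mir, , drop = FALSE]           # Im Conj(F(-f)) = -Im F(-f)
  out <- matrix(0, n, ncol(seg))
  out[, odd] <- ((Rp + Rm)^2 + (Ip + Im_)^2) / 4
  out[, odd + 1L] <- ((Rp - Rm)^2 + (Ip - Im_)^2) / 4
  if (padded) out[, seq_len(m), drop = FALSE] else out
}

# Plain one-sided FFT periodogram (density scaling as welch_psd).
periodogram_psd <- function(x, rate) {
  x <- as.numeric(x)
  n <- length(x)
  sp <- Mod(stats::fft(x))^2 / (rate * n)
  nf <- n %/% 2 + 1L
  sp <- sp[seq_len(nf)]
  dbl <- rep(2, nf); dbl[1] <- 1; if (n %% 2 == 0) dbl[nf] <- 1
  list(freq = (seq_len(nf) - 1L) * rate / n, psd = sp * dbl)
}

#' Relative power in named frequency bands
#'
#' Integrates a PSD estimate over a set of contiguous, non-overlapping
#' bands and normalizes by the total power over the union of the bands, so
#' the returned shares lie in `[0, 1]` and sum to one.  Bands are half-open
#' (`lo <= f < hi`) so a shared edge is counted once.
#'
#' @param x Numeric vector (a single channel).
#' @param rate Sampling rate (Hz).
#' @param bands Two-column matrix (or data frame) of band edges in Hz,
#'   columns `lo` and `hi`, ordered and non-overlapping.
#' @param method `"periodogram"` (single FFT of the whole trace, used for
#'   the EMG bands) or `"welch"` (averaged 2-s Hann windows, used for EEG).
#' @return Numeric vector of band shares (named when `bands` has row
#'   names), summing to 1.
#' @examples
#' fs <- 1600; t <- seq(0, 2, by = 1 / fs)
#' relative_band_power(sin(2 * pi * 80 * t), fs, emg_bands())
#' @export
relative_band_power <- function(x, rate,
                                bands = emg_bands(),
                                method = c("periodogram", "welch")) {
  method <- match.arg(method)
  bands <- as.matrix(bands)
  stopifnot(ncol(bands) == 2)
  lo <- bands[, 1]; hi <- bands[, 2]
  if (any(hi <= lo) || is.unsorted(lo) || any(lo[-1] < hi[-length(hi)]))
    stop("bands must be ordered and non-overlapping")
  if (any(lo < 0) || any(hi > rate / 2))
    stop("band outside [0, rate/2]")
  est <- switch(method,
    periodogram = periodogram_psd(x, rate),
    welch = welch_psd(x, rate))
  band_shares(est$freq, est$psd, lo, hi, rownames(bands))
}

band_shares <- function(freq, psd, lo, hi, names = NULL) {
  p <- vapply(seq_along(lo), function(i)
    sum(psd[freq >= lo[i] & freq < hi[i]]), numeric(1))
  tot <- sum(p)
  if (tot <= 0) stop("no power in the requested bands")
  stats::setNames(p / tot, names)
}

#' @rdname relative_band_power
#' @export
emg_bands <- function() {
  b <- cbind(lo = c(40, 132, 224, 316, 408), hi = c(132, 224, 316, 408, 500))
  rownames(b) <- c("40_132", "132_224", "224_316", "316_408", "408_500")
  b
}

#' @rdname relative_band_power
#' @export
eeg_bands <- function() {
  b <- cbind(lo = c(0.5, 4, 8, 13, 35), hi = c(4, 8, 13, 35, 40))
  rownames(b) <- c("delta", "theta", "alpha", "beta", "lg")
  b
}
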