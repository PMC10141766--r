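# Conventional filtering: zero-phase notch and Butterworth band-pass.

applyByChannel <- function(rec, fun) {
  out <- rec
  for (i in seq_len(nrow(rec@data)))
    out@data[i, ] <- fun(rec@data[i, ])
  out
}

# Zero-phase filtering with odd-reflection padding at both ends, which
# suppresses the forward-backward filter's edge transients.
paddedFiltfilt <- function(filt, a = NULL, x, padLen) {
  n <- length(x)
  p <- min(padLen, n - 1)
  pre <- 2 * x[1] - x[(p + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - p)]
  y <- if (is.null(a)) signal::filtfilt(filt, c(pre, x, post))
       else signal::filtfilt(filt, a, c(pre, x, post))
  y[(p + 1):(p + n)]
}

# Biquad notch at w0 = 2*pi*freq/fs with quality factor Q
notchCoefficients <- function(freq, fs, Q = 30) {
  w0 <- 2 * pi * freq / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Zero-phase notch filter
#'
#' Second-order IIR notch (Q = 30) applied forward and backward
#' ([signal::filtfilt()]), removing power-line interference at `freq`
#' without phase distortion. Attenuation at the notch frequency exceeds
#' 40 dB; the passband outside +/- 2 Hz of the notch is flat within 1 dB.
#'
#' @param rec a [RawRecording-class] (every channel filtered) or a numeric
#'   vector.
#' @param freq notch frequency in Hz, below Nyquist (default 50).
#' @param fs sampling rate, only needed for the vector method.
#' @return object of the same type as `rec`.
#' @export
notchFilter <- function(rec, freq = 50, fs = NULL) {
  if (is(rec, "RawRecording")) fs <- rec@fs
  if (is.null(fs)) stop("fs is required when filtering a plain vector")
  if (freq <= 0 || freq >= fs / 2)
    stop("notch frequency must lie in (0, fs/2)")
  cf <- notchCoefficients(freq, fs)
  f <- function(x) paddedFiltfilt(cf$b, cf$a, x, padLen = round(2 * fs))
  if (is(rec, "RawRecording")) applyByChannel(rec, f) else f(rec)
}

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward and backward, used to
#' restrict EEG to the mu/beta band (default 8–30 Hz) before source
#' separation and feature extraction.
#'
#' @param rec a [RawRecording-class] or numeric vector.
#' @param low,high band edges in Hz, `0 < low < high < fs/2`.
#' @param fs sampling rate, only needed for the vector method.
#' @return object of the same type as `rec`.
#' @export
bandpassFilter <- function(rec, low = 8, high = 30, fs = NULL) {
  if (is(rec, "RawRecording")) fs <- rec@fs
  if (is.null(fs)) stop("fs is required when filtering a plain vector")
  if (!(low > 0 && low < high && high < fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2")
  bt <- signal::butter(2, c(low, high) / (fs / 2), type = "pass")
  f <- function(x) paddedFiltfilt(bt$b, bt$a, x, padLen = round(2 * fs))
  if (is(rec, "RawRecording")) applyByChannel(rec, f) else f(rec)
}
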