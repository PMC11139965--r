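#' Digital filters for surface EMG conditioning
#'
#' The conditioning chain uses three zero-phase IIR filters: a 20--450 Hz
#' Butterworth band-pass (realized as a 4th-order high-pass at 20 Hz cascaded
#' with a 4th-order low-pass at 450 Hz), a narrow 60 Hz notch (Q = 30) for
#' power-line interference, and a 2nd-order 6 Hz Butterworth low-pass that
#' turns the rectified signal into a linear envelope. Each filter is applied
#' forward and backward, so timing features (peak latencies) are not skewed by
#' group delay; the effective order doubles.
#'
#' Biquad sections follow the standard audio-EQ cookbook parameterization; a
#' 4th-order Butterworth response is the cascade of two 2nd-order sections
#' with Q = 0.5412 and Q = 1.3066.
#'
#' @name emg-filters
NULL

# one biquad section; returns list(b = c(b0,b1,b2), a = c(1,a1,a2))
biquad <- function(type = c("lowpass", "highpass", "notch"), fc, fs, Q) {
  type <- match.arg(type)
  w0 <- 2 * pi * fc / fs
  cw <- cos(w0)
  alpha <- sin(w0) / (2 * Q)
  co <- switch(type,
    lowpass  = c((1 - cw) / 2, 1 - cw, (1 - cw) / 2),
    highpass = c((1 + cw) / 2, -(1 + cw), (1 + cw) / 2),
    notch    = c(1, -2 * cw, 1)
  )
  a0 <- 1 + alpha
  list(b = co / a0, a = c(1, -2 * cw / a0, (1 - alpha) / a0))
}

BUTTER4_Q <- c(0.54119610, 1.30656296)  # cascade Qs of a 4th-order Butterworth

apply_biquad <- function(x, bq) {
  # direct-form filtering via stats::filter: FIR part then recursive part
  v <- stats::filter(c(0, 0, x), bq$b, method = "convolution", sides = 1)
  v <- as.numeric(v)[-(1:2)]
  as.numeric(stats::filter(v, -bq$a[2:3], method = "recursive"))
}

# zero-phase pass over a biquad cascade with odd-reflection padding
filtfilt_biquads <- function(x, biquads, n_pad) {
  n <- length(x)
  n_pad <- min(n - 1L, as.integer(n_pad))
  if (n_pad > 0) {
    front <- 2 * x[1] - x[seq(n_pad + 1, 2)]
    back <- 2 * x[n] - x[seq(n - 1, n - n_pad)]
    y <- c(front, x, back)
  } else {
    y <- x
  }
  for (bq in biquads) y <- apply_biquad(y, bq)
  y <- rev(y)
  for (bq in biquads) y <- apply_biquad(y, bq)
  y <- rev(y)
  if (n_pad > 0) y <- y[seq(n_pad + 1, n_pad + n)]
  y
}

#' Band-pass raw EMG to the 20--450 Hz surface-EMG band
#'
#' Zero-phase Butterworth band-pass: 4th-order high-pass at 20 Hz cascaded
#' with a 4th-order low-pass at 450 Hz, each applied forward-backward.
#'
#' @param x numeric vector, one raw EMG channel.
#' @param fs sampling rate in Hz; must exceed 900 so the 450 Hz edge is below
#'   Nyquist.
#' @return filtered signal, same length as `x`.
#' @export
bandpass_20_450 <- function(x, fs) {
  if (fs <= 900) stop_field("fs", "must exceed 900 Hz (450 Hz band edge below Nyquist)")
  bqs <- c(
    lapply(BUTTER4_Q, function(q) biquad("highpass", 20, fs, q)),
    lapply(BUTTER4_Q, function(q) biquad("lowpass", 450, fs, q))
  )
  filtfilt_biquads(x, bqs, n_pad = round(3 * fs / 20))
}

#' Notch out 60 Hz power-line interference
#'
#' Zero-phase 2nd-order notch centred at 60 Hz with quality factor 30
#' (about 2 Hz bandwidth), leaving 50 and 70 Hz essentially untouched.
#'
#' @inheritParams bandpass_20_450
#' @return filtered signal, same length as `x`.
#' @export
notch_60 <- function(x, fs) {
  if (fs <= 120) stop_field("fs", "must exceed 120 Hz to notch 60 Hz")
  filtfilt_biquads(x, list(biquad("notch", 60, fs, Q = 30)), n_pad = round(fs / 4))
}

#' Linear envelope of rectified EMG
#'
#' Zero-phase 2nd-order Butterworth low-pass at 6 Hz applied to the rectified
#' signal; residual negative undershoot is clipped to zero so envelopes stay
#' nonnegative.
#'
#' @param x numeric vector, a rectified EMG channel.
#' @param fs sampling rate in Hz (> 12).
#' @param fc low-pass cutoff in Hz, default 6.
#' @return nonnegative envelope, same length as `x`.
#' @export
linear_envelope <- function(x, fs, fc = 6) {
  if (fs <= 2 * fc) stop_field("fs", "must exceed twice the envelope cutoff")
  y <- filtfilt_biquads(x, list(biquad("lowpass", fc, fs, Q = 1 / sqrt(2))),
                        n_pad = round(3 * fs / fc))
  pmax(y, 0)
}

#' Full-wave rectification
#'
#' @param x numeric vector.
#' @return elementwise absolute value.
#' @export
rectify <- function(x) abs(x)
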