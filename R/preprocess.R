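#' Signal-to-noise ratio of an EMG epoch in decibels
#'
#' `20 * log10(RMS(epoch) / RMS(noise_reference))`, the RMS-ratio SNR used to
#' gate gait-cycle epochs at 18 dB. The noise reference is a quiet-baseline
#' segment recorded away from muscle contraction (the synthetic generator
#' emits one per trial).
#'
#' @param epoch numeric vector, the conditioned EMG of one gait cycle.
#' @param noise_reference numeric vector, conditioned quiet-baseline EMG.
#' @return SNR in dB.
#' @export
snr_db <- function(epoch, noise_reference) {
  if (length(epoch) == 0 || length(noise_reference) == 0)
    stop("epoch and noise_reference must be nonempty", call. = FALSE)
  rms_ref <- sqrt(mean(noise_reference^2))
  if (rms_ref <= 0) stop("noise reference has zero RMS", call. = FALSE)
  20 * log10(sqrt(mean(epoch^2)) / rms_ref)
}

#' Gate EMG epochs by signal-to-noise ratio
#'
#' Epochs whose SNR against the noise reference falls below `threshold_db`
#' (default 18 dB) are excluded; an SNR exactly at the threshold is retained.
#' Exclusions are logged with epoch id and measured SNR. If nothing survives,
#' an error is raised rather than returning silently empty output.
#'
#' @param epochs named list of numeric vectors.
#' @param noise_reference quiet-baseline segment (same conditioning).
#' @param threshold_db exclusion threshold in dB.
#' @return list with `kept` (surviving epochs), `log` (data.frame: epoch,
#'   snr_db, kept).
#' @export
gate_epochs <- function(epochs, noise_reference, threshold_db = 18) {
  if (!is.finite(threshold_db) && threshold_db != -Inf)
    stop_field("threshold_db", "must be finite or -Inf")
  ids <- names(epochs) %||% as.character(seq_along(epochs))
  snr <- vapply(epochs, snr_db, numeric(1), noise_reference = noise_reference)
  keep <- snr >= threshold_db
  log <- data.frame(epoch = ids, snr_db = as.numeric(snr), kept = keep,
                    row.names = NULL)
  if (!any(keep)) stop("no usable cycles: every epoch fell below the SNR gate",
                       call. = FALSE)
  list(kept = epochs[keep], log = log)
}

#' Resample one gait cycle of an envelope to 101 points
#'
#' Linear interpolation onto 0--100% of the gait cycle (1% increments), with
#' the stance/swing boundary at
#' `round(100 * (toe_off - heel_strike) / (next_heel_strike - heel_strike))`,
#' clipped to [1, 99].
#'
#' @param envelope numeric vector, a full-trial linear envelope.
#' @param heel_strike,toe_off,next_heel_strike event times in seconds;
#'   must satisfy `heel_strike < toe_off < next_heel_strike` and lie within
#'   the signal.
#' @param fs sampling rate in Hz.
#' @param muscle optional muscle label carried along.
#' @return object of class `normalized_envelope`: `values` (101 reals),
#'   `stance_boundary`, `muscle`, `amplitude_scale` (1 until amplitude
#'   normalization).
#' @export
time_normalize <- function(envelope, heel_strike, toe_off, next_heel_strike,
                           fs, muscle = NA_character_) {
  n <- length(envelope)
  t_end <- (n - 1) / fs
  if (!(heel_strike < toe_off && toe_off < next_heel_strike))
    stop("events must satisfy heel_strike < toe_off < next_heel_strike", call. = FALSE)
  if (heel_strike < 0 || next_heel_strike > t_end)
    stop("events outside signal", call. = FALSE)
  tt <- seq(heel_strike, next_heel_strike, length.out = 101)
  vals <- approx(x = (seq_len(n) - 1) / fs, y = envelope, xout = tt)$y
  sb <- round(100 * (toe_off - heel_strike) / (next_heel_strike - heel_strike))
  sb <- min(99L, max(1L, as.integer(sb)))
  structure(list(values = vals, stance_boundary = sb, muscle = muscle,
                 amplitude_scale = 1), class = "normalized_envelope")
}

#' Average gait cycles and normalize to each muscle's maximum
#'
#' Pointwise mean of the surviving 101-point cycles of one muscle across
#' trials, then division by the maximum of the averaged waveform (peak
#' normalization; maximum-voluntary-contraction data are assumed
#' unavailable). The result's maximum is exactly 1. The stance boundary of
#' the averaged envelope is the rounded mean of the per-cycle boundaries.
#'
#' @param cycles nonempty list of `normalized_envelope` objects, one muscle.
#' @return a `normalized_envelope` with `amplitude_scale` = the divisor used.
#' @export
average_and_normalize <- function(cycles) {
  if (length(cycles) == 0) stop("no cycles to average", call. = FALSE)
  vals <- vapply(cycles, function(cy) cy$values, numeric(101))
  avg <- rowMeans(vals)
  scale <- max(avg)
  if (scale <= 0) stop("averaged envelope is identically zero", call. = FALSE)
  sb <- as.integer(round(mean(vapply(cycles, function(cy) cy$stance_boundary, numeric(1)))))
  structure(list(values = avg / scale, stance_boundary = min(99L, max(1L, sb)),
                 muscle = cycles[[1]]$muscle, amplitude_scale = scale),
            class = "normalized_envelope")
}

#' Preprocess one raw trial into per-cycle normalized envelopes
#'
#' Per muscle: band-pass 20--450 Hz, notch 60 Hz, per-cycle SNR gating
#' against the trial's conditioned rest segment (threshold 18 dB), full-wave
#' rectification, 6 Hz linear envelope, and time normalization of each
#' surviving cycle to 101 points. SNR is computed on the conditioned
#' (band-passed, notched) signal.
#'
#' @param trial a `raw_emg_trial`.
#' @param events a `gait_events` for the trial.
#' @param threshold_db SNR gate in dB (default 18).
#' @return list with `cycles` (per muscle: list of `normalized_envelope`)
#'   and `exclusion_log` (data.frame: muscle, cycle, snr_db, kept).
#' @export
preprocess_trial <- function(trial, events, threshold_db = 18) {
  fs <- trial$fs
  hs <- events$heel_strikes
  to <- events$toe_offs
  n_cycles <- length(to)
  stopifnot(length(hs) == n_cycles + 1)
  rest_idx <- seq(max(1, floor(trial$rest_window[1] * fs) + 1),
                  floor(trial$rest_window[2] * fs))
  cycles <- stats::setNames(vector("list", length(trial$muscles)), trial$muscles)
  logs <- list()
  for (m in trial$muscles) {
    cond <- notch_60(bandpass_20_450(trial$signals[, m], fs), fs)
    ref <- cond[rest_idx]
    idx_of <- function(s) min(length(cond), max(1, floor(s * fs) + 1))
    epochs <- lapply(seq_len(n_cycles), function(k)
      cond[idx_of(hs[k]):idx_of(hs[k + 1])])
    names(epochs) <- as.character(seq_len(n_cycles))
    snr <- vapply(epochs, snr_db, numeric(1), noise_reference = ref)
    keep <- snr >= threshold_db
    logs[[m]] <- data.frame(muscle = m, cycle = seq_len(n_cycles),
                            snr_db = as.numeric(snr), kept = keep)
    env <- linear_envelope(rectify(cond), fs)
    kept_cycles <- lapply(which(keep), function(k)
      time_normalize(env, hs[k], to[k], hs[k + 1], fs, muscle = m))
    cycles[[m]] <- kept_cycles
  }
  list(cycles = cycles, exclusion_log = do.call(rbind, c(logs, list(make.row.names = FALSE))))
}

#' Preprocess all trials of one limb into averaged envelopes
#'
#' Runs [preprocess_trial()] over every trial, pools the surviving cycles per
#' muscle, and averages + peak-normalizes them. Errors with "no usable
#' cycles" if any muscle loses every cycle to the SNR gate.
#'
#' @param trials list of `raw_emg_trial`.
#' @param events list of `gait_events`, parallel to `trials`.
#' @param threshold_db SNR gate in dB.
#' @return list with `envelopes` (per muscle `normalized_envelope`) and
#'   `exclusion_log`.
#' @export
preprocess_limb <- function(trials, events, threshold_db = 18) {
  pooled <- stats::setNames(vector("list", length(MUSCLES)), MUSCLES)
  logs <- list()
  for (i in seq_along(trials)) {
    res <- preprocess_trial(trials[[i]], events[[i]], threshold_db)
    res$exclusion_log$trial <- i
    logs[[i]] <- res$exclusion_log
    for (m in names(res$cycles)) pooled[[m]] <- c(pooled[[m]], res$cycles[[m]])
  }
  empty <- vapply(pooled, function(x) length(x) == 0, logical(1))
  if (any(empty))
    stop(sprintf("no usable cycles for muscle(s): %s",
                 paste(names(pooled)[empty], collapse = ", ")), call. = FALSE)
  list(envelopes = lapply(pooled, average_and_normalize),
       exclusion_log = do.call(rbind, c(logs, list(make.row.names = FALSE))))
}
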