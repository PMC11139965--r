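#' Rudolph co-contraction index time series
#'
#' For two amplitude-normalized envelopes of a muscle pair,
#' `CCI(t) = (EMG_L(t) / EMG_H(t)) * (EMG_L(t) + EMG_H(t))`, where at each
#' time point `EMG_L` is the lower and `EMG_H` the higher of the two
#' activities (per-sample assignment, so the index is symmetric in its
#' arguments and the ratio never exceeds 1). Where both envelopes are zero
#' the index is defined as 0.
#'
#' @param envA,envB `normalized_envelope` objects (101 points, same limb).
#' @param pair optional pair label, e.g. `"TA-G"`.
#' @return object of class `cci_series`: `pair`, `values` (101 reals),
#'   `stance_boundary`.
#' @export
cci_timeseries <- function(envA, envB, pair = NULL) {
  a <- if (inherits(envA, "normalized_envelope")) envA$values else envA
  b <- if (inherits(envB, "normalized_envelope")) envB$values else envB
  if (length(a) != length(b)) stop("envelope length mismatch", call. = FALSE)
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  cci <- ifelse(hi == 0, 0, (lo / hi) * (lo + hi))
  sb <- if (inherits(envA, "normalized_envelope")) envA$stance_boundary else NA_integer_
  if (is.null(pair) && inherits(envA, "normalized_envelope"))
    pair <- paste(envA$muscle, envB$muscle, sep = "-")
  structure(list(pair = pair, values = cci, stance_boundary = sb),
            class = "cci_series")
}

#' Window summary of a co-contraction time series
#'
#' The co-contraction over a window is the sum of `CCI(t)` for `t` from `t1`
#' to `t2` divided by the number of samples -- i.e. the arithmetic mean over
#' the inclusive index range. The printed-formula variant that divides by
#' `(t2 - t1)` (one fewer than the sample count) is available via
#' `divisor = "printed"`.
#'
#' @param series a `cci_series` or numeric vector of 101 values.
#' @param t1,t2 window bounds as percent-of-cycle indices, `0 <= t1 < t2 <= 100`.
#' @param divisor `"count"` (mean over t2 - t1 + 1 samples, default) or
#'   `"printed"` (divide by t2 - t1).
#' @return a single co-contraction value.
#' @export
cci_window <- function(series, t1 = 0, t2 = 100, divisor = c("count", "printed")) {
  divisor <- match.arg(divisor)
  v <- if (inherits(series, "cci_series")) series$values else series
  if (!(t1 >= 0 && t1 < t2 && t2 <= 100)) stop("require 0 <= t1 < t2 <= 100", call. = FALSE)
  s <- sum(v[(t1 + 1):(t2 + 1)])
  if (divisor == "count") s / (t2 - t1 + 1) else s / (t2 - t1)
}

window_indices <- function(window, stance_boundary) {
  switch(window,
    full = c(0L, 100L),
    stance = c(0L, as.integer(stance_boundary)),
    swing = c(as.integer(stance_boundary), 100L),
    stop_field("window", sprintf("unknown window '%s'", window))
  )
}

#' Fiducial features of a normalized envelope
#'
#' Over the full cycle, stance, or swing window: mean amplitude (`A`),
#' extrema (`MAX`, `MIN`), latency of the extrema in percent of the full
#' gait cycle (`T_MAX`, `T_MIN`; first index attaining the extremum), and
#' trapezoidal area under the curve (`AUC`, amplitude x %cycle units).
#' Stance is `[0, stance_boundary]`, swing `[stance_boundary, 100]` (shared
#' boundary point).
#'
#' @param env a `normalized_envelope`.
#' @param window `"full"`, `"stance"` or `"swing"`.
#' @return named numeric vector `A, MAX, MIN, T_MAX, T_MIN, AUC`.
#' @export
fiducial_features <- function(env, window = c("full", "stance", "swing")) {
  window <- match.arg(window)
  b <- window_indices(window, env$stance_boundary)
  if (b[2] - b[1] < 1) stop("degenerate window (fewer than 2 points)", call. = FALSE)
  idx <- (b[1] + 1):(b[2] + 1)
  v <- env$values[idx]
  pct <- b[1]:b[2]
  i_max <- which.max(v)
  i_min <- which.min(v)
  c(A = mean(v), MAX = max(v), MIN = min(v),
    T_MAX = pct[i_max], T_MIN = pct[i_min],
    AUC = sum((v[-1] + v[-length(v)]) / 2))
}

#' Temporospatial gait variables from events
#'
#' Cadence is `120 / mean cycle duration` (steps per minute, two steps per
#' cycle); speed is stride length over mean cycle duration. Stride and step
#' length are passed through from the motion-capture record (their
#' computation from marker data is out of scope).
#'
#' @param events a `gait_events` with at least two heel strikes.
#' @param stride_length_m,step_length_m lengths in meters.
#' @return named numeric vector `speed, step_length, stride_length, cadence`.
#' @export
temporospatial_features <- function(events, stride_length_m, step_length_m) {
  hs <- events$heel_strikes
  if (length(hs) < 2) stop("need at least two heel strikes", call. = FALSE)
  dur <- mean(diff(hs))
  c(speed = stride_length_m / dur, step_length = step_length_m,
    stride_length = stride_length_m, cadence = 120 / dur)
}

feature_names_for <- function() {
  stats <- c("A", "MAX", "MIN", "T_MAX", "T_MIN", "AUC")
  wtok <- c(full = "", stance = "ST", swing = "SW")
  nm <- character(0)
  for (m in MUSCLES) for (w in names(wtok)) for (s in stats) {
    nm <- c(nm, if (wtok[[w]] == "") paste(m, s, sep = "_")
                else paste(m, wtok[[w]], s, sep = "_"))
  }
  for (p in CCI_PAIRS) for (w in names(wtok)) for (s in c("A", "MAX", "MIN")) {
    base <- paste0("CCI_", p)
    nm <- c(nm, if (wtok[[w]] == "") paste(base, s, sep = "_")
                else paste(base, wtok[[w]], s, sep = "_"))
  }
  c(nm, "speed", "step_length", "stride_length", "cadence")
}

limb_feature_vector <- function(envelopes, events, stride_length_m, step_length_m,
                                divisor = "count") {
  wtok <- c(full = "", stance = "ST", swing = "SW")
  out <- numeric(0)
  for (m in MUSCLES) {
    env <- envelopes[[m]]
    for (w in names(wtok)) {
      f <- fiducial_features(env, w)
      names(f) <- if (wtok[[w]] == "") paste(m, names(f), sep = "_")
                  else paste(m, wtok[[w]], names(f), sep = "_")
      out <- c(out, f)
    }
  }
  # consensus stance boundary across muscles (per-muscle gating can leave
  # slightly different per-muscle boundaries); invariant to input order
  sb <- round(mean(vapply(MUSCLES, function(m)
    envelopes[[m]]$stance_boundary, numeric(1))))
  sb <- min(99L, max(1L, as.integer(sb)))
  for (p in CCI_PAIRS) {
    mm <- strsplit(p, "-", fixed = TRUE)[[1]]
    ser <- cci_timeseries(envelopes[[mm[1]]], envelopes[[mm[2]]], pair = p)
    for (w in names(wtok)) {
      b <- window_indices(w, sb)
      vals <- ser$values[(b[1] + 1):(b[2] + 1)]
      f <- c(A = cci_window(ser, b[1], b[2], divisor = divisor),
             MAX = max(vals), MIN = min(vals))
      names(f) <- if (wtok[[w]] == "") paste0("CCI_", p, "_", names(f))
                  else paste0("CCI_", p, "_", wtok[[w]], "_", names(f))
      out <- c(out, f)
    }
  }
  c(out, temporospatial_features(events, stride_length_m, step_length_m))
}

#' Assemble the limb-level feature table
#'
#' One row per limb: 4 muscles x 3 windows x 6 fiducial stats, 4
#' co-contraction pairs x 3 windows x (A, MAX, MIN), 4 temporospatial
#' variables, then the PROM targets (`womac_total`, `pain`, `stiffness`,
#' `physical_function`, `vas`) and identifiers (`subject_id`, `limb`,
#' `latent_severity` when known). Column order is deterministic. Limbs
#' missing a muscle are skipped with a warning.
#'
#' @param limb_records list; each element has `subject_id`, `limb`,
#'   `envelopes` (per-muscle `normalized_envelope`), `events`,
#'   `stride_length_m`, `step_length_m`, `prom` (list `womac_items`, `vas`),
#'   optionally `latent_severity`.
#' @param divisor co-contraction window divisor, see [cci_window()].
#' @return `data.frame` (feature names kept verbatim, e.g. `CCI_TA-G_SW_A`).
#' @export
build_feature_table <- function(limb_records, divisor = "count") {
  rows <- list()
  for (rec in limb_records) {
    if (!all(MUSCLES %in% names(rec$envelopes))) {
      warning(sprintf("limb %s/%s skipped: missing muscle(s) %s",
                      rec$subject_id, rec$limb,
                      paste(setdiff(MUSCLES, names(rec$envelopes)), collapse = ", ")),
              call. = FALSE)
      next
    }
    fv <- limb_feature_vector(rec$envelopes, rec$events, rec$stride_length_m,
                              rec$step_length_m, divisor)
    ws <- womac_scores(rec$prom$womac_items)
    row <- data.frame(subject_id = rec$subject_id, limb = rec$limb,
                      latent_severity = rec$latent_severity %||% NA_real_,
                      as.list(fv), womac_total = ws$total, pain = ws$pain,
                      stiffness = ws$stiffness,
                      physical_function = ws$physical_function,
                      vas = rec$prom$vas, check.names = FALSE)
    rows[[length(rows) + 1]] <- row
  }
  if (length(rows) == 0) stop("no complete limb records", call. = FALSE)
  do.call(rbind, rows)
}

#' Names of the EMG + temporospatial predictor columns in a feature table
#'
#' @param tbl a feature table from [build_feature_table()].
#' @return character vector of predictor column names.
#' @export
predictor_columns <- function(tbl) {
  setdiff(names(tbl), c("subject_id", "limb", "latent_severity",
                        "womac_total", "pain", "stiffness",
                        "physical_function", "vas"))
}

#' Full gait pipeline from a synthetic cohort to the feature table
#'
#' Preprocesses every limb of a generated cohort ([generate_cohort()]) and
#' assembles the feature table. Limbs losing all cycles of a muscle to the
#' SNR gate are skipped with a warning.
#'
#' @param cohort output of [generate_cohort()].
#' @param threshold_db SNR gate in dB.
#' @param divisor co-contraction window divisor, see [cci_window()].
#' @return a feature table `data.frame`.
#' @export
cohort_feature_table <- function(cohort, threshold_db = 18, divisor = "count") {
  recs <- list()
  for (subj in cohort) {
    for (lb in subj$limbs) {
      pre <- tryCatch(preprocess_limb(lb$trials, lb$events, threshold_db),
                      error = function(e) e)
      if (inherits(pre, "error")) {
        warning(sprintf("limb %s/%s skipped: %s", subj$subject_id, lb$limb,
                        conditionMessage(pre)), call. = FALSE)
        next
      }
      recs[[length(recs) + 1]] <- list(
        subject_id = subj$subject_id, limb = lb$limb,
        latent_severity = subj$latent_severity,
        envelopes = pre$envelopes, events = lb$events[[1]],
        stride_length_m = lb$stride_length_m,
        step_length_m = lb$step_length_m, prom = subj$prom)
    }
  }
  build_feature_table(recs, divisor = divisor)
}
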