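#' Specification of a synthetic gait-EMG cohort
#'
#' Bundles and validates the parameters of the synthetic cohort generator.
#' Defaults emulate the structure of a gait-lab study of advanced knee
#' osteoarthritis: ~75 subjects contributing both lower limbs, five walking
#' trials per limb recorded at 1500 Hz from four muscles (RF, MH, TA, G), a
#' latent severity in [0, 1] that drives both the patient-reported outcomes
#' (WOMAC, VAS) and the neuromuscular pattern (higher gastrocnemius activity
#' and higher antagonist co-contraction with worse severity), 60 Hz line
#' noise, and occasional low-SNR artifact epochs.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param limbs_per_subject limbs recorded per subject (1 or 2).
#' @param trials_per_limb walking trials per limb (averaged downstream).
#' @param cycles_per_trial gait cycles per trial.
#' @param fs sampling rate in Hz; must exceed 900.
#' @param severity_effect_cci slope linking latent severity to antagonist
#'   activity inside the agonist's active windows (raises Rudolph CCI).
#' @param severity_effect_g slope linking severity to gastrocnemius amplitude.
#' @param line_noise_amp amplitude of the injected 60 Hz component, relative
#'   to the unit-RMS EMG carrier.
#' @param artifact_prob probability that a cycle-by-muscle epoch is an
#'   electrode-lift-off artifact (in-band signal suppressed so its SNR falls
#'   below the 18 dB gate).
#' @param prom_noise_sd sd of the per-item PROM observation noise, on the
#'   0--4 item scale.
#' @param seed integer seed; the whole cohort is deterministic given the spec.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 75, limbs_per_subject = 2,
                        trials_per_limb = 5, cycles_per_trial = 6,
                        fs = 1500, severity_effect_cci = 0.6,
                        severity_effect_g = 0.8, line_noise_amp = 0.2,
                        artifact_prob = 0.02, prom_noise_sd = 0.5,
                        seed = 1L) {
  chk_count <- function(x, nm) {
    if (length(x) != 1 || !is.finite(x) || x < 1 || x != as.integer(x))
      stop_field(nm, "must be a single integer >= 1")
  }
  chk_count(n_subjects, "n_subjects")
  chk_count(limbs_per_subject, "limbs_per_subject")
  chk_count(trials_per_limb, "trials_per_limb")
  chk_count(cycles_per_trial, "cycles_per_trial")
  if (!is.finite(fs) || fs <= 900) stop_field("fs", "must exceed 900 Hz")
  if (!is.finite(artifact_prob) || artifact_prob < 0 || artifact_prob > 1)
    stop_field("artifact_prob", "must be a probability in [0, 1]")
  if (!is.finite(line_noise_amp) || line_noise_amp < 0)
    stop_field("line_noise_amp", "must be >= 0")
  if (!is.finite(prom_noise_sd) || prom_noise_sd < 0)
    stop_field("prom_noise_sd", "must be >= 0")
  if (!is.finite(severity_effect_cci)) stop_field("severity_effect_cci", "must be finite")
  if (!is.finite(severity_effect_g)) stop_field("severity_effect_g", "must be finite")
  if (length(seed) != 1 || !is.finite(seed)) stop_field("seed", "must be a single integer")
  structure(list(
    n_subjects = as.integer(n_subjects),
    limbs_per_subject = as.integer(limbs_per_subject),
    trials_per_limb = as.integer(trials_per_limb),
    cycles_per_trial = as.integer(cycles_per_trial),
    fs = fs, severity_effect_cci = severity_effect_cci,
    severity_effect_g = severity_effect_g, line_noise_amp = line_noise_amp,
    artifact_prob = artifact_prob, prom_noise_sd = prom_noise_sd,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

gauss_bump <- function(pct, center, width, amp) {
  amp * exp(-0.5 * ((pct - center) / width)^2)
}

#' Severity-dependent muscle activation template
#'
#' A 101-point activation shape (0--100% of the gait cycle) for one muscle,
#' built from phase-localized Gaussian bumps: TA bursts around heel strike
#' (cycle ends), RF and MH in early stance (weight acceptance), G in weight
#' acceptance and swing. Severity acts through two slopes only: `effect_g`
#' scales the gastrocnemius bumps and widens the swing burst (a shape change,
#' so the signal survives peak normalization) and `effect_cci` raises the antagonist
#' (TA in G's swing window, TA and the MH mid-stance plateau in stance), which
#' is what raises the Rudolph co-contraction index downstream. With both
#' slopes zero the template is severity-free.
#'
#' @param muscle one of `"RF"`, `"MH"`, `"TA"`, `"G"`.
#' @param severity latent severity in [0, 1].
#' @param effect_cci,effect_g severity slopes, defaults as in [cohort_spec()].
#' @return numeric vector of 101 nonnegative values.
#' @export
generate_activation_template <- function(muscle, severity,
                                         effect_cci = 0.6, effect_g = 0.8) {
  if (!muscle %in% MUSCLES)
    stop_field("muscle", sprintf("unknown label '%s' (expected RF, MH, TA or G)", muscle))
  if (!is.finite(severity) || severity < 0 || severity > 1)
    stop_field("severity", "must lie in [0, 1]")
  p <- 0:100
  floor_amp <- 0.04
  v <- switch(muscle,
    RF = gauss_bump(p, 8, 6, 0.9) + gauss_bump(p, 96, 6, 0.25),
    MH = gauss_bump(p, 5, 6, 0.9) + gauss_bump(p, 97, 5, 0.35) +
      gauss_bump(p, 35, 12, 0.15 + 0.5 * effect_cci * severity),
    TA = gauss_bump(p, 3, 5, 1.0) + gauss_bump(p, 97, 5, 0.9) +
      gauss_bump(p, 75, 8, 0.10 + 0.6 * effect_cci * severity) +
      gauss_bump(p, 35, 10, 0.05 + 0.2 * effect_cci * severity),
    G = gauss_bump(p, 10, 7, 0.35 + 0.45 * effect_g * severity) +
      gauss_bump(p, 75, 9 + 4 * effect_g * severity,
                 0.50 + 0.5 * effect_g * severity)
  )
  pmax(v + floor_amp, 0)
}

#' WOMAC and VAS record from a latent severity
#'
#' Each of the 24 WOMAC items is `round(4 * severity + noise)` clamped to
#' 0..4 (5 pain, 2 stiffness, 17 physical-function items); VAS is
#' `10 * severity + noise` clamped to [0, 10]. With zero noise the record
#' saturates exactly: severity 0 gives all-zero scores, severity 1 gives
#' WOMAC total 96 and VAS 10. Draws from the current RNG stream.
#'
#' @param latent_severity real in [0, 1].
#' @param prom_noise_sd sd of the per-item noise on the 0--4 scale; VAS noise
#'   is scaled by 2.5 to sit on the 0--10 scale.
#' @return list with `womac_items` (24 integers) and `vas`.
#' @export
prom_from_severity <- function(latent_severity, prom_noise_sd = 0.5) {
  if (!is.finite(latent_severity) || latent_severity < 0 || latent_severity > 1)
    stop_field("latent_severity", "must lie in [0, 1]")
  items <- 4 * latent_severity + rnorm(24, 0, prom_noise_sd)
  items <- as.integer(pmin(4, pmax(0, round(items))))
  vas <- 10 * latent_severity + rnorm(1, 0, 2.5 * prom_noise_sd)
  list(womac_items = items, vas = min(10, max(0, vas)))
}

#' Synthesize one raw EMG walking trial with its gait events
#'
#' The raw signal per muscle is a 20--450 Hz band-limited unit-RMS Gaussian
#' carrier, amplitude-modulated by the muscle's activation template mapped
#' onto each gait cycle (plus a small baseline tone), with an additive 60 Hz
#' line component. The first `rest_s` seconds are a quiet rest segment that
#' serves as the trial's noise reference for SNR gating. Artifact epochs
#' (drawn per cycle x muscle with probability `artifact_prob`) emulate
#' electrode lift-off: the in-band carrier is suppressed by a factor 0.2 --
#' driving the epoch's SNR to roughly 8--10 dB, below the 18 dB gate -- and a
#' high-amplitude sub-10 Hz transient is added (removed later by the
#' band-pass, so it is cosmetic). Cycle durations are severity-independent
#' (~1.1 s) so cadence carries no severity signal; toe-off falls near 60% of
#' each cycle. Draws from the current RNG stream.
#'
#' @param spec a [cohort_spec()].
#' @param severity latent severity in [0, 1].
#' @return list with `trial` (class `raw_emg_trial`: `signals` matrix, `fs`,
#'   `muscles`, `rest_window`) and `events` (class `gait_events`:
#'   `heel_strikes`, `toe_offs`).
#' @export
synthesize_raw_trial <- function(spec, severity) {
  fs <- spec$fs
  # generous quiet baseline: the 60 Hz notch (Q = 30) rings for ~0.16 s at
  # signal edges, so the SNR reference window starts well after the filter
  # transient has decayed
  rest_s <- 1.5
  durations <- pmax(0.8, rnorm(spec$cycles_per_trial, 1.1, 0.04))
  stance_frac <- pmin(0.65, pmax(0.55, rnorm(spec$cycles_per_trial, 0.60, 0.015)))
  heel_strikes <- rest_s + c(0, cumsum(durations))
  toe_offs <- heel_strikes[-length(heel_strikes)] + stance_frac * durations
  total_s <- heel_strikes[length(heel_strikes)] + 0.2
  n <- ceiling(total_s * fs)
  t <- (seq_len(n) - 1) / fs

  # per-sample % of gait cycle (NA in rest / tail)
  pct <- rep(NA_real_, n)
  cyc <- rep(NA_integer_, n)
  for (k in seq_len(spec$cycles_per_trial)) {
    sel <- t >= heel_strikes[k] & t < heel_strikes[k + 1]
    pct[sel] <- 100 * (t[sel] - heel_strikes[k]) / durations[k]
    cyc[sel] <- k
  }

  sig <- matrix(0, n, length(MUSCLES), dimnames = list(NULL, MUSCLES))
  m_floor <- 0.02
  for (m in MUSCLES) {
    tpl <- generate_activation_template(m, severity,
                                        spec$severity_effect_cci,
                                        spec$severity_effect_g)
    carrier <- bandpass_20_450(rnorm(n), fs)
    carrier <- carrier / sqrt(mean(carrier^2))
    mod <- rep(m_floor, n)
    in_gait <- !is.na(pct)
    mod[in_gait] <- m_floor + approx(0:100, tpl, xout = pct[in_gait])$y
    x <- carrier * mod
    # artifact epochs: suppress in-band signal, add low-frequency transient
    for (k in seq_len(spec$cycles_per_trial)) {
      if (runif(1) < spec$artifact_prob) {
        sel <- which(!is.na(cyc) & cyc == k)
        x[sel] <- 0.2 * x[sel]
        tc <- t[sel] - t[sel[1]]
        x[sel] <- x[sel] + 4 * exp(-((tc - mean(tc)) / 0.08)^2) * sin(2 * pi * 3 * tc)
      }
    }
    x <- x + spec$line_noise_amp * sin(2 * pi * 60 * t + runif(1, 0, 2 * pi))
    sig[, m] <- x
  }

  trial <- structure(list(signals = sig, fs = fs, muscles = MUSCLES,
                          rest_window = c(rest_s - 0.6, rest_s - 0.1)),
                     class = "raw_emg_trial")
  events <- structure(list(heel_strikes = heel_strikes, toe_offs = toe_offs),
                      class = "gait_events")
  list(trial = trial, events = events)
}

#' Generate a reproducible synthetic cohort
#'
#' Draws one latent severity per subject (uniform on [0, 1]), the PROM record
#' it implies, and per limb the walking trials, gait events and
#' temporospatial record. Stride and step length shrink with severity in
#' proportion to `severity_effect_g` (weaker plantar-flexor push-off; speed
#' follows, as stride over cycle duration); cadence is severity-independent.
#' With both effect slopes zero no feature -- EMG or temporospatial --
#' carries severity signal. Deterministic given the spec, including its seed.
#'
#' @param spec a [cohort_spec()].
#' @return list of subjects; each has `subject_id`, `latent_severity`,
#'   `prom`, and `limbs` -- a list with `limb` ("L"/"R"), `trials`, `events`
#'   (per trial), `stride_length_m`, `step_length_m`.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop_field("spec", "must be a cohort_spec")
  set.seed(spec$seed)
  lapply(seq_len(spec$n_subjects), function(s) {
    severity <- runif(1)
    prom <- prom_from_severity(severity, spec$prom_noise_sd)
    limbs <- lapply(seq_len(spec$limbs_per_subject), function(l) {
      trials <- vector("list", spec$trials_per_limb)
      events <- vector("list", spec$trials_per_limb)
      for (tr in seq_len(spec$trials_per_limb)) {
        st <- synthesize_raw_trial(spec, severity)
        trials[[tr]] <- st$trial
        events[[tr]] <- st$events
      }
      # stride shortens with severity in proportion to the gastrocnemius
      # slope (weaker push-off); with all effect slopes zero the cohort is
      # fully null -- no feature carries severity signal
      stride <- max(0.4, 1.25 - 0.44 * spec$severity_effect_g * severity +
                      rnorm(1, 0, 0.05))
      step <- max(0.2, stride / 2 + rnorm(1, 0, 0.02))
      list(limb = c("L", "R")[l], trials = trials, events = events,
           stride_length_m = stride, step_length_m = step)
    })
    list(subject_id = sprintf("S%03d", s), latent_severity = severity,
         prom = prom, limbs = limbs)
  })
}
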