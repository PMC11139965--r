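---
title: "From gait EMG to knee-OA severity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From gait EMG to knee-OA severity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`emgoa` estimates patient-reported knee-osteoarthritis severity (WOMAC and
VAS) from surface EMG recorded during level walking, and explains the
estimates feature-by-feature with exact Shapley values. This vignette is the
package's own account of the science: the processing model and its
assumptions, the tunable parameters and why their defaults are what they
are, what the synthetic cohort generator does and does not emulate, the
numerical choices, and the design decisions taken where the method
description left the design genuinely open. It states no empirical result
that the test suite does not itself compute.

## 1. Signal model and preprocessing chain

A walking trial yields four EMG channels (rectus femoris RF, medial
hamstring MH, tibialis anterior TA, gastrocnemius G) sampled at `fs` Hz
(1500 by default), plus heel-strike and toe-off times. The conditioning
chain is:

1. **Band-pass 20–450 Hz.** Surface EMG power lives in this band; below
   20 Hz sit motion artifacts, above 450 Hz mostly amplifier noise. The
   filter is a 4th-order Butterworth, realized as a cascade of a 4th-order
   high-pass at 20 Hz and a 4th-order low-pass at 450 Hz (biquad sections
   with Q = 0.5412 and 1.3066). With the corners more than a decade apart
   this cascade is indistinguishable from a true band-pass prototype at the
   tolerances that matter here (< 1 dB ripple at 200 Hz, < 0.1 amplitude at
   5 Hz, both verified in `test-filters.R`). `fs` must exceed 900 Hz so the
   450 Hz edge stays below Nyquist.
2. **60 Hz notch**, Q = 30 (≈ 2 Hz bandwidth), for power-line interference;
   50 and 70 Hz pass within 3 dB.
3. **SNR gating at 18 dB, per cycle and muscle.** SNR is defined as
   `20·log10(RMS(epoch) / RMS(reference))`, where the reference is a
   quiet-baseline segment recorded away from contraction. Epochs *below*
   18 dB are excluded; exactly 18 dB is retained (the exclusion rule is
   "below 18 dB"). All exclusions are logged with cycle id and measured SNR,
   and a muscle losing every cycle raises an explicit "no usable cycles"
   error rather than passing empty data downstream.
4. **Full-wave rectification**, then a **6 Hz 2nd-order Butterworth
   low-pass** producing the linear envelope. Small negative undershoots
   after filtering are clipped to zero.
5. **Time normalization**: each gait cycle (heel strike to next heel
   strike) is linearly interpolated onto 101 points (0–100% in 1% steps).
   The stance/swing boundary index is
   `round(100·(toe_off − heel_strike)/cycle_duration)`, clipped to [1, 99].
6. **Averaging and amplitude normalization**: surviving cycles are averaged
   pointwise across trials per muscle, and the average is divided by its own
   maximum (peak normalization — maximum-voluntary-contraction recordings
   are assumed unavailable, as is typical for patients awaiting knee
   replacement). The normalized envelope has maximum exactly 1.

Every filter is applied forward and backward (zero phase), because the
features include peak *latencies*: a causal filter's group delay would bias
them. The stated filter orders are the design orders before the
bidirectional pass, so effective orders double (the 6 Hz stage is
effectively 4th order). Filtering is linear, so the whole chain up to peak
normalization is homogeneous of degree 1 in the raw signal, and the final
envelope is invariant to positive rescaling of the input — both are tested
properties, and they mean electrode gain does not confound the features.

Two ordering decisions the method description leaves open: SNR is computed
on the *conditioned* (band-passed, notched) signal, so the gate measures
in-band quality rather than line-noise level; and rectification applies to
EMG only.

## 2. Features

For each muscle and each window (full cycle [0, 100], stance
[0, boundary], swing [boundary, 100] — the boundary sample is shared):
mean `A`, extrema `MAX`/`MIN`, their latencies `T_MAX`/`T_MIN` (first index
attaining the extremum, reported in % of the full cycle), and trapezoidal
`AUC` on the 1% grid. Co-contraction uses Rudolph's index,

$$\mathrm{CCI}(t) = \frac{EMG_L(t)}{EMG_H(t)}\,\bigl(EMG_L(t)+EMG_H(t)\bigr),$$

with the lower/higher assignment made *per time point*. The printed
formulations of this index are ambiguous about whether L/H are fixed
anatomical roles; the per-sample rule guarantees the ratio ≤ 1, makes the
index symmetric in its arguments, and is the convention in the
co-contraction literature. Where both envelopes are zero, CCI(t) := 0. The
window summary divides the inclusive sum over `t1..t2` by the sample count
`t2 − t1 + 1`; the printed divisor `t2 − t1` undercounts the inclusive range
by one and is kept available as `divisor = "printed"`. CCI is computed on
the amplitude-normalized envelopes, making it unit-free and bounded by 2.

Windows for CCI use a consensus stance boundary (rounded mean of the four
muscles' boundaries) so the feature table is invariant to muscle input
order. Temporospatial variables: cadence = 120 / mean cycle duration
(steps/min), speed = stride length / mean cycle duration; stride and step
length are passed through from the motion-capture record, whose computation
is out of scope. The table has 4 muscles × 3 windows × 6 statistics + 4
pairs × 3 windows × 3 CCI statistics + 4 temporospatial = 112 predictors
per limb, with deterministic column order and names like `G_SW_A`,
`MH_ST_MIN`, `CCI_TA-G_SW_A`. Limbs are analyzed as independent rows, with
subject identity retained so model evaluation can keep subjects intact.

## 3. PROM scoring and severity classes

WOMAC: 24 items scored 0–4, partitioned 5 pain / 2 stiffness / 17 physical
function, totals 0–20 / 0–8 / 0–68 / 0–96. Severity classes use the
midpoint rule: on the 0–4 item scale the mild/moderate midpoint is 1.5 and
moderate/severe 2.5; multiplying by the item count gives cut-offs (36, 60)
for the total. Boundary handling follows the literal wording "below 36,
between 36 and 60, above 60": both boundaries belong to the moderate class.
For VAS the same midpoint fractions (1.5/4, 2.5/4) rescaled to 0–10 give
(3.75, 6.25); the source never prints its VAS cut-offs, so these are
documented package defaults — consistent with mild/moderate/severe VAS
group means near 1.8 / 6.0 / 8.8. Subscale classes use the same rule with
n = 5, 2, 17. Group screens use classical equal-variance one-way ANOVA at a
0.001 significance level (type-I calibration is verified by simulation in
the acceptance suite), Welch t-tests between adjacent groups (pooled
Student form behind a flag), and pointwise mean ± 1.96·SE ensemble
waveforms.

## 4. Regression model

Each PROM target is regressed on the features with:

- an 80/20 train/test split, stratified by target terciles, keeping both
  limbs of a subject on the same side (`grouped_split = FALSE` pools limbs,
  mimicking a limb-level split);
- univariate selection of the `k = 15` highest-scoring features by the
  regression F statistic `F = (n−2)·r²/(1−r²)` (monotone in the squared
  Pearson correlation; ties break by column order), computed on training
  rows only;
- a bagged ensemble of CART regression trees (variance-reduction splits,
  bootstrap resampling, all features considered at each split, minimum
  leaf size 1 — the conventions of the standard reference implementation
  for random-forest regression), 500 trees by default;
- `max_depth` chosen from the grid {3, 5, 7, 9, 12} by 5-fold
  cross-validated R² within the training split (ties to the smaller
  depth), then a final refit on all training rows.

The forest is implemented in the package (C++/Rcpp) rather than imported:
no forest package is available in the target environment, and owning the
tree structure is what makes *exact* tree-path Shapley attribution possible.
Reported metrics: per-fold and mean CV R², held-out R² = 1 − SSE/SST, RMSE
in target units, and the Pearson correlation between actual and estimated
scores. Selection and tuning never see test rows — verified by a test that
plants a feature equal to the test-set target (noise on training rows) and
asserts it is never selected.

## 5. Shapley attribution

Attribution uses the interventional coalition value: `v(S)` is the mean
model output over a background set with the features in `S` overridden by
the explained instance. Three routes compute φ:

1. `shapley_exact`: direct subset enumeration of the factorially weighted
   sum (any model, ≤ 15 features — 2¹⁵ coalitions, tractable precisely
   because the pipeline selects 15 features);
2. `tree_shap`: for the package's forests, a closed-form per-leaf
   computation — for each (leaf, instance, background row), path features
   split into those only the instance passes (`S_x`) and those only the
   background row passes (`S_b`); the leaf's AND-game contributes
   `+v·(a−1)!·c!/(a+c)!` to features in `S_x` and `−v·a!·(c−1)!/(a+c)!` to
   those in `S_b`, with `a = |S_x|`, `c = |S_b|`. This is exact (no
   sampling, no path-weight approximation) and agrees with route 1 to
   machine precision;
3. a test-side oracle that literally averages marginal contributions over
   every permutation of the features (run at 7 features: 5040 permutations
   with memoized coalition values; 10! permutations would not be tractable
   at the required exactness, so the 10-feature check pairs routes 1 and 2).

Local accuracy (base value + Σφ = prediction), the dummy axiom (an unused
feature gets exactly 0) and symmetry are asserted in the acceptance suite.
The background set is a seeded subsample of the training split (size 50 by
default); the choice of background is a documented free parameter of
interventional Shapley values, not a fact recoverable from the method
description. Global importance is the mean |φ| per feature; the beeswarm
summary plot is replaced by a machine-checkable direction-of-effect table
(Spearman correlation between feature values and their Shapley values),
with constant features flagged and assigned direction 0.

## 6. The synthetic cohort generator

The generator exists so that every downstream stage is testable without
clinical data. It emulates, per subject: a latent severity uniform on
[0, 1]; a PROM record (each WOMAC item `round(4·severity + noise)` clamped
to 0–4, VAS `10·severity + noise` clamped to [0, 10] — so zero noise
saturates exactly at 0 and 96/10); and per limb, walking trials whose raw
EMG is a 20–450 Hz band-limited unit-RMS Gaussian carrier amplitude-
modulated by per-muscle activation templates, plus a 60 Hz line tone and a
1.5 s quiet rest segment used as the SNR reference (the reference window
sits at 0.9–1.4 s, past the notch filter's ~0.16 s edge transient — a
lesson learned from a failing test, recorded here because it is a real
hazard when gating short baselines on notched signals).

Activation templates are sums of phase-localized Gaussian bumps: TA bursts
at the cycle ends (heel strike), RF and MH in early stance, G in weight
acceptance (~10%) and swing (~75%). Bump centers and widths are generator
configuration, not claims about any particular cohort. Severity acts
through exactly two slopes:

- `severity_effect_g` scales the G bumps and widens the swing burst
  (amplitude alone would be removed by peak normalization — a deliberate
  reminder that *shape*, not gain, carries information after
  normalization), and scales the stride-length decline (weaker
  plantar-flexor push-off), with speed following as stride/duration;
- `severity_effect_cci` raises antagonist activity inside the agonist's
  active windows (TA in G's swing window, TA and the MH mid-stance plateau
  in stance), which is what raises the Rudolph CCI of TA–G, TA–MH and RF–G
  with severity.

Cycle durations are severity-independent, so cadence carries no severity
signal (matching the observation that cadence is not associated with
severity) and the generator's temporospatial record stays consistent with
the values recomputed from gait events. With both slopes zero the cohort is
*fully* null — no EMG or temporospatial feature correlates with severity
beyond sampling noise — which is the calibration the null-cohort tests
rely on. Artifact epochs (probability `artifact_prob` per cycle × muscle)
emulate electrode lift-off: the in-band carrier is suppressed by a factor
0.2 (driving the epoch's SNR to ~9–13 dB, below the 18 dB gate) and a
high-amplitude sub-10 Hz transient is added for realism; the transient
itself is removed by the band-pass, which is why a purely additive
low-frequency artifact cannot trip an in-band SNR gate — the suppression
is what the gate detects.

Defaults (75 subjects × 2 limbs × 5 trials × 6 cycles at 1500 Hz,
`severity_effect_cci = 0.6`, `severity_effect_g = 0.8`,
`line_noise_amp = 0.2`, `artifact_prob = 0.02`, `prom_noise_sd = 0.5`)
reproduce the scale of the motivating study (~150 limb-level records).
The effect sizes have no published values; they were chosen once so that
severity dominates but does not trivialize the features, and are documented
free parameters.

**What a green test does and does not establish.** The generator's noise is
Gaussian and stationary, its gait events are exact, its severity links are
monotone and low-noise, and both limbs of a subject share one severity.
Real cohorts have heteroscedastic muscle-specific noise, event-detection
error, crosstalk between channels, bilateral asymmetry, and PROMs only
loosely coupled to neuromuscular state. High CV R² on the default cohort
therefore validates the *pipeline's mechanics* (the features contain the
generator's severity signal and the model recovers it without leakage), not
clinical performance. The null cohort bounds the optimism of the whole
chain: with no planted signal, cross-validated R² stays near zero.

## 7. Numerical choices and degenerate inputs

- Zero-phase filtering uses odd-reflection padding (3 time constants of the
  lowest corner frequency) to suppress edge transients.
- `round()` half-even rounding applies to the stance boundary; boundaries
  clip to [1, 99] so stance and swing windows are never degenerate.
- Extremum latencies use the *first* index attaining the extremum.
- `CCI(t)` at double-zero envelopes is 0 by definition; window CCI of an
  all-zero series is 0.
- ANOVA raises an error on zero within-group variance instead of returning
  F = ∞; the SNR computation raises on a zero-RMS reference.
- All randomness flows through R's RNG from per-stage seeds derived from one
  root seed, so full runs are byte-reproducible (checksummed in the run
  manifest); the C++ forest consumes R's RNG stream, so `set.seed` governs
  it too.
- Configuration files are JSON (no YAML parser is assumed in the target
  environment).

## 8. Known limitations

- The cascade band-pass is not pole-identical to a true 8-pole band-pass
  Butterworth; at 20–450 Hz corners the response difference is far below
  the tested tolerances, but at narrow bands it would not be.
- Peak normalization ties every envelope's scale to its own maximum; MVC
  normalization, C3D parsing, kinematics/kinetics, frequency-domain EMG
  features and muscle-synergy analysis are out of scope.
- The exact enumeration route is exponential and refuses > 15 features by
  default; for larger feature sets only `tree_shap` applies.
- The regression forest is a from-scratch CART implementation: it matches
  the reference conventions (bootstrap bagging, all-features splits,
  depth-capped trees) but not any specific library tree-for-tree.
- VAS severity cut-offs are an interpretation (documented above), not a
  published constant.
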