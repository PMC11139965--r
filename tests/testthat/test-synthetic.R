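test_that("cohort_spec validates fields by name", {
  expect_error(cohort_spec(n_subjects = 0), "n_subjects")
  expect_error(cohort_spec(artifact_prob = 1.2), "artifact_prob")
  expect_error(cohort_spec(fs = 800), "fs")
  expect_error(cohort_spec(prom_noise_sd = -1), "prom_noise_sd")
})

test_that("generate_cohort is deterministic and has the requested shape", {
  spec <- cohort_spec(n_subjects = 3, trials_per_limb = 2, cycles_per_trial = 3,
                      seed = 5)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1, c2)
  spec10 <- cohort_spec(n_subjects = 10, limbs_per_subject = 2,
                        trials_per_limb = 1, cycles_per_trial = 2, seed = 6)
  coh <- generate_cohort(spec10)
  expect_length(coh, 10)
  expect_equal(sum(vapply(coh, function(s) length(s$limbs), numeric(1))), 20)
})

test_that("activation templates are nonnegative with physiological peaks", {
  for (m in c("RF", "MH", "TA", "G")) for (sev in c(0, 0.5, 1)) {
    tpl <- generate_activation_template(m, sev)
    expect_length(tpl, 101)
    expect_true(all(tpl >= 0))
  }
  # TA burst near heel strike: global max in first or last 10% of the cycle
  for (sev in c(0, 0.5, 1)) {
    i <- which.max(generate_activation_template("TA", sev)) - 1
    expect_true(i <= 10 || i >= 90)
  }
  # G swing activity strictly larger at severity 1 than 0
  sw <- 61:101
  expect_gt(mean(generate_activation_template("G", 1)[sw]),
            mean(generate_activation_template("G", 0)[sw]))
  expect_error(generate_activation_template("VL", 0.5), "muscle")
  expect_error(generate_activation_template("G", 1.5), "severity")
})

test_that("PROM generation saturates exactly and tracks severity", {
  set.seed(7)
  p0 <- prom_from_severity(0, prom_noise_sd = 0)
  expect_identical(p0$womac_items, rep(0L, 24))
  expect_identical(p0$vas, 0)
  p1 <- prom_from_severity(1, prom_noise_sd = 0)
  expect_identical(womac_scores(p1$womac_items),
                   list(pain = 20L, stiffness = 8L, physical_function = 68L,
                        total = 96L))
  expect_identical(p1$vas, 10)
  # monotone link at default noise
  set.seed(8)
  sev <- runif(500)
  tot <- vapply(sev, function(s) womac_scores(prom_from_severity(s)$womac_items)$total,
                numeric(1))
  expect_gt(cor(sev, tot, method = "spearman"), 0.8)
  # range safety under heavy noise
  set.seed(9)
  for (s in runif(50)) {
    p <- prom_from_severity(s, prom_noise_sd = 3)
    expect_true(all(p$womac_items >= 0 & p$womac_items <= 4))
    expect_true(p$vas >= 0 && p$vas <= 10)
  }
})

test_that("trial events are ordered and consistent with the signal", {
  set.seed(10)
  spec <- cohort_spec(n_subjects = 2, cycles_per_trial = 5)
  for (rep in 1:5) {
    st <- synthesize_raw_trial(spec, runif(1))
    hs <- st$events$heel_strikes
    to <- st$events$toe_offs
    expect_length(hs, 6)
    expect_length(to, 5)
    expect_true(all(diff(hs) > 0))
    expect_true(all(hs[-6] < to & to < hs[-1]))
    expect_gte(nrow(st$trial$signals), floor(max(hs) * spec$fs))
  }
})

test_that("injected 60 Hz power is removed by the notch stage", {
  set.seed(12)
  spec <- cohort_spec(n_subjects = 2, line_noise_amp = 0.5, artifact_prob = 0)
  st <- synthesize_raw_trial(spec, 0.5)
  fs <- spec$fs
  x <- st$trial$signals[, "G"]
  tt <- (seq_along(x) - 1) / fs
  power_60 <- function(z) {
    # amplitude of the 60 Hz component by quadrature demodulation
    (2 * mean(z * sin(2 * pi * 60 * tt)))^2 + (2 * mean(z * cos(2 * pi * 60 * tt)))^2
  }
  injected <- power_60(x)
  expect_gt(injected, 0.5 * 0.5^2)  # the injected line tone dominates at 60 Hz
  cleaned <- power_60(notch_60(x, fs))
  expect_lt(cleaned, 0.05 * injected)
})

test_that("null-effect cohort shows no severity-feature correlation", {
  spec <- cohort_spec(n_subjects = 200, limbs_per_subject = 1,
                      trials_per_limb = 2, cycles_per_trial = 4,
                      severity_effect_cci = 0, severity_effect_g = 0,
                      seed = 13)
  tbl <- suppressWarnings(cohort_feature_table(generate_cohort(spec)))
  expect_gte(nrow(tbl), 195)
  r <- vapply(predictor_columns(tbl), function(cn) {
    if (sd(tbl[[cn]]) == 0) return(0)
    cor(tbl$latent_severity, tbl[[cn]])
  }, numeric(1))
  expect_lt(max(abs(r)), 0.15)
})
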