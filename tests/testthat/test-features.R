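test_that("co-contraction series matches hand-computed cases", {
  c5 <- mk_env(rep(0.5, 101))
  expect_equal(cci_timeseries(c5, c5)$values, rep(1.0, 101))  # ratio 1, sum 2c
  expect_equal(cci_timeseries(mk_env(rep(1, 101)), mk_env(rep(0, 101)))$values,
               rep(0, 101))
  expect_equal(cci_timeseries(mk_env(rep(0.5, 101)), mk_env(rep(1, 101)))$values,
               rep(0.75, 101))
  expect_error(cci_timeseries(rep(1, 101), rep(1, 50)), "mismatch")
})

test_that("windowed co-contraction averages the inclusive sample range", {
  const <- structure(list(pair = "TA-G", values = rep(0.8, 101),
                          stance_boundary = 60L), class = "cci_series")
  expect_equal(cci_window(const, 0, 100), 0.8)
  expect_equal(cci_window(const, 30, 60), 0.8)
  expect_equal(cci_window(rep(0, 101), 0, 100), 0)
  expect_equal(cci_window((0:100) / 100, 0, 100), 0.5)  # mean of 0..1 grid
  # printed-formula variant divides by t2 - t1
  expect_equal(cci_window(const, 0, 100, divisor = "printed"), 0.8 * 101 / 100)
  expect_error(cci_window(const, 50, 50), "t1 < t2")
})

test_that("co-contraction equals the brute-force oracle, is symmetric,
           homogeneous and bounded", {
  set.seed(31)
  worst <- 0
  for (i in 1:200) {
    a <- runif(101)
    b <- runif(101)
    if (i %% 7 == 0) a[sample(101, 5)] <- 0
    if (i %% 11 == 0) b <- a  # exercise ties
    ours <- cci_timeseries(a, b)$values
    worst <- max(worst, max(abs(ours - oracle_cci_series(a, b))))
    expect_identical(ours, cci_timeseries(b, a)$values)  # symmetry, exact
    t1 <- sample(0:99, 1)
    t2 <- t1 + sample.int(100 - t1, 1)  # uniform on (t1, 100]
    expect_equal(cci_window(ours, t1, t2), oracle_cci_window(ours, t1, t2),
                 tolerance = 1e-12)
    # homogeneity of degree 1
    s <- runif(1, 0.1, 5)
    expect_equal(cci_timeseries(s * a, s * b)$values, s * ours, tolerance = 1e-12)
    # bound for unit-normalized inputs
    expect_true(all(ours <= a + b + 1e-12))
    expect_lte(cci_window(ours, t1, t2), 2)
  }
  expect_lt(worst, 1e-10)
})

test_that("fiducial features match closed forms on constructed envelopes", {
  const <- mk_env(rep(1, 101))
  f <- fiducial_features(const, "full")
  expect_equal(unname(f[c("A", "MAX", "MIN", "T_MAX", "T_MIN", "AUC")]),
               c(1, 1, 1, 0, 0, 100))
  spike <- rep(0, 101); spike[76] <- 1  # peak at 75% of cycle
  fs <- fiducial_features(mk_env(spike, sb = 60), "swing")
  expect_equal(unname(fs["T_MAX"]), 75)
  expect_equal(unname(fs["MAX"]), 1)
  ramp <- mk_env((0:100) / 100)
  fr <- fiducial_features(ramp, "full")
  expect_equal(unname(fr[c("A", "T_MIN", "T_MAX", "AUC")]), c(0.5, 0, 100, 50))
  # latencies reported in % of the full cycle even for stance/swing windows
  fst <- fiducial_features(ramp, "stance")
  expect_equal(unname(fst["T_MAX"]), 60)
  expect_error(fiducial_features(mk_env(rep(1, 101), sb = 1), "stance"), NA)
})

test_that("temporospatial variables follow their definitions", {
  ev <- structure(list(heel_strikes = c(0, 1, 2, 3), toe_offs = c(0.6, 1.6, 2.6)),
                  class = "gait_events")
  ts <- temporospatial_features(ev, stride_length_m = 1.2, step_length_m = 0.6)
  expect_equal(unname(ts["cadence"]), 120)
  expect_equal(unname(ts["speed"]), 1.2)
  ev2 <- structure(list(heel_strikes = c(0, 1.2), toe_offs = 0.7),
                   class = "gait_events")
  expect_equal(unname(temporospatial_features(ev2, 1.2, 0.6)["speed"]), 1.0)
  expect_error(temporospatial_features(
    structure(list(heel_strikes = 0, toe_offs = numeric(0)), class = "gait_events"),
    1, 0.5), "two heel strikes")
})

test_that("feature table has the documented columns and is order-invariant", {
  tbl <- small_tbl()
  expect_true(all(c("G_SW_A", "CCI_TA-G_SW_A", "MH_ST_MIN", "speed",
                    "step_length", "stride_length", "cadence", "G_AUC",
                    "TA_ST_T_MAX", "CCI_RF-MH_MIN") %in% names(tbl)))
  expect_length(predictor_columns(tbl), 4 * 3 * 6 + 4 * 3 * 3 + 4)
  # permuting muscle input order leaves the table unchanged
  spec <- cohort_spec(n_subjects = 1, trials_per_limb = 1, cycles_per_trial = 3,
                      seed = 33)
  subj <- generate_cohort(spec)[[1]]
  lb <- subj$limbs[[1]]
  pre <- preprocess_limb(lb$trials, lb$events)
  rec <- list(subject_id = "S1", limb = "L", latent_severity = subj$latent_severity,
              envelopes = pre$envelopes, events = lb$events[[1]],
              stride_length_m = lb$stride_length_m, step_length_m = lb$step_length_m,
              prom = subj$prom)
  rec_perm <- rec
  rec_perm$envelopes <- rec$envelopes[c("G", "TA", "RF", "MH")]
  expect_equal(build_feature_table(list(rec)), build_feature_table(list(rec_perm)))
  # missing muscle -> warned skip; nothing left -> error
  rec_missing <- rec
  rec_missing$envelopes$G <- NULL
  expect_warning(build_feature_table(list(rec, rec_missing)), "missing muscle")
  expect_error(suppressWarnings(build_feature_table(list(rec_missing))),
               "no complete limb")
})
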