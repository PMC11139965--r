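# Shared fixtures and independent oracles. Oracles are deliberately written
# as naive loops, independent of the package's vectorized implementations.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache, inherits = FALSE)
}

# default-scale synthetic cohort (150 limbs, strong effects), fixed seed
acc_default_tbl <- function() cached("tbl_default", {
  spec <- cohort_spec(n_subjects = 75, seed = 101)
  suppressWarnings(cohort_feature_table(generate_cohort(spec)))
})

# null-effect cohort of the same size, fixed seed
acc_null_tbl <- function() cached("tbl_null", {
  spec <- cohort_spec(n_subjects = 75, severity_effect_cci = 0,
                      severity_effect_g = 0, seed = 102)
  suppressWarnings(cohort_feature_table(generate_cohort(spec)))
})

# small cohort for cheap module tests
small_tbl <- function() cached("tbl_small", {
  spec <- cohort_spec(n_subjects = 8, trials_per_limb = 2, cycles_per_trial = 4,
                      seed = 11)
  suppressWarnings(cohort_feature_table(generate_cohort(spec)))
})

mk_env <- function(values, sb = 60L, muscle = "G") {
  structure(list(values = values, stance_boundary = as.integer(sb),
                 muscle = muscle, amplitude_scale = 1),
            class = "normalized_envelope")
}

# --- independent co-contraction oracle: literal transcription of the
#     lower/higher-activity ratio-times-sum definition and its window mean ---
oracle_cci_series <- function(a, b) {
  out <- numeric(length(a))
  for (t in seq_along(a)) {
    lo <- min(a[t], b[t])
    hi <- max(a[t], b[t])
    out[t] <- if (hi == 0) 0 else (lo / hi) * (lo + hi)
  }
  out
}

oracle_cci_window <- function(series, t1, t2) {
  s <- 0
  n <- 0
  for (t in t1:t2) {
    s <- s + series[t + 1]
    n <- n + 1
  }
  s / n
}

# --- independent Shapley oracle: literal average of marginal contributions
#     over every permutation of the feature order, with memoized coalition
#     values (interventional: subset features overridden by x over background)
oracle_shapley_perm <- function(predict_fn, x, background, features) {
  p <- length(features)
  memo <- new.env(parent = emptyenv())
  val <- function(S) {
    key <- paste(sort(S), collapse = "|")
    if (key == "") key <- "."
    if (!exists(key, envir = memo, inherits = FALSE)) {
      z <- background
      for (f in S) z[[f]] <- x[[f]][1]
      assign(key, mean(predict_fn(z)), envir = memo)
    }
    get(key, envir = memo, inherits = FALSE)
  }
  permute <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(permute(v[-i]), function(q) c(v[i], q))))
  }
  phi <- stats::setNames(numeric(p), features)
  for (perm in permute(seq_len(p))) {
    S <- character(0)
    v_before <- val(S)
    for (i in perm) {
      S <- c(S, features[i])
      v_after <- val(S)
      phi[features[i]] <- phi[features[i]] + (v_after - v_before)
      v_before <- v_after
    }
  }
  list(phi = phi / factorial(p), base_value = val(character(0)))
}

rf_predict_fn <- function(model) function(newdata) predict(model, newdata)
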