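test_that("univariate F selection finds perfect correlates and respects k", {
  set.seed(51)
  x <- as.data.frame(matrix(rnorm(200 * 10), 200, 10))
  names(x) <- paste0("f", 1:10)
  y <- x$f3 + rnorm(200, 0, 0.01)
  expect_identical(select_k_best(x, y, 1)$selected, "f3")
  y_indep <- rnorm(200)
  expect_length(select_k_best(x, y_indep, 5)$selected, 5)
  expect_error(select_k_best(x, rep(1, 200), 3), "constant target")
  expect_error(select_k_best(x, y, 11), "k")
  # deterministic tie-break by column order for duplicated columns
  x2 <- x
  x2$f3b <- x$f3
  expect_identical(select_k_best(x2, y, 2)$selected, c("f3", "f3b"))
  # constant feature scores 0, never beats an informative one
  x$f10 <- 1
  expect_false("f10" %in% select_k_best(x, y, 9)$selected)
})

test_that("random forest recovers a near-noiseless signal and not a permuted
           one, deterministically", {
  set.seed(52)
  n <- 300
  x <- as.data.frame(matrix(rnorm(n * 8), n, 8))
  names(x) <- paste0("f", 1:8)
  y <- 3 * x$f1 + rnorm(n, 0, 0.01)
  cfg <- model_config(k_features = 8, n_trees = 300, seed = 5, targets = "y")
  tr <- sample(n, 240)
  m <- fit_rf(x[tr, ], y[tr], cfg)
  expect_gt(evaluate_regression(m, x[-tr, ], y[-tr])$r2, 0.95)
  expect_true(m$chosen_depth %in% cfg$depth_grid)
  m_perm <- fit_rf(x[tr, ], sample(y[tr]), cfg)
  expect_lte(m_perm$cv_r2, 0.1)
  m2 <- fit_rf(x[tr, ], y[tr], cfg)
  expect_identical(m2$chosen_depth, m$chosen_depth)
  expect_identical(predict(m2, x[-tr, ]), predict(m, x[-tr, ]))
  expect_error(fit_rf(transform(x[tr, ], f1 = Inf), y[tr], cfg), "non-finite")
})

test_that("evaluation metrics follow their definitions", {
  y <- c(1, 2, 3, 4, 5)
  perfect <- evaluate_regression(y = y, predictions = y)
  expect_equal(perfect, list(r2 = 1, rmse = 0, pearson_r = 1))
  at_mean <- evaluate_regression(y = y, predictions = rep(mean(y), 5))
  expect_equal(at_mean$r2, 0)
  shifted <- evaluate_regression(y = y, predictions = y + 2)
  expect_equal(shifted$rmse, 2)
  expect_equal(shifted$pearson_r, 1)
  expect_equal(shifted$r2, 1 - 5 * 4 / sum((y - 3)^2))  # = -1 by definition
  expect_error(evaluate_regression(y = rep(2, 5), predictions = y),
               "zero-variance")
  # R^2 consistency identity
  set.seed(53)
  yy <- rnorm(40); pp <- yy + rnorm(40)
  ev <- evaluate_regression(y = yy, predictions = pp)
  expect_equal(ev$r2, 1 - 40 * ev$rmse^2 / sum((yy - mean(yy))^2),
               tolerance = 1e-12)
})

test_that("run_all_targets keeps selection and tuning inside the training
           split", {
  tbl <- small_tbl()
  cfg <- model_config(k_features = 8, n_trees = 80, depth_grid = c(3, 6),
                      cv_folds = 3, seed = 7)
  rep1 <- run_all_targets(tbl, cfg)
  expect_named(rep1, c("womac_total", "pain", "stiffness", "physical_function",
                       "vas"))
  for (r in rep1) {
    expect_length(intersect(r$split$train, r$split$test), 0)
    expect_setequal(c(r$split$train, r$split$test), seq_len(nrow(tbl)))
    # grouped split: no subject straddles train and test
    expect_length(intersect(tbl$subject_id[r$split$train],
                            tbl$subject_id[r$split$test]), 0)
    # selection is exactly what the training rows alone produce
    resel <- select_k_best(tbl[r$split$train, predictor_columns(tbl)],
                           tbl[[r$target]][r$split$train], cfg$k_features)
    expect_identical(r$selected_features, resel$selected)
  }
  expect_error(run_all_targets(tbl[, setdiff(names(tbl), "vas")], cfg),
               "vas")
  # a feature equal to the *test* target (noise on train) is never selected:
  # the split depends only on ids/targets/seed, so it can be constructed
  r_wt <- rep1$womac_total
  set.seed(54)
  leak_col <- rnorm(nrow(tbl))
  leak_col[r_wt$split$test] <- tbl$womac_total[r_wt$split$test]
  leak <- tbl
  leak[["LEAK"]] <- leak_col  # a predictor column; the split is unaffected
  rep2 <- run_all_targets(leak, cfg)
  expect_identical(rep2$womac_total$split, r_wt$split)
  expect_false("LEAK" %in% rep2$womac_total$selected_features)
})
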