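test_that("coalition value interpolates between base value and prediction", {
  f <- function(d) 2 * d$x1 + d$x2  # linear model as a prediction function
  bg <- data.frame(x1 = rep(0, 4), x2 = rep(0, 4))
  x <- data.frame(x1 = 1.5, x2 = -2)
  expect_equal(value_function(f, x, c("x1", "x2"), bg), 2 * 1.5 - 2)
  expect_equal(value_function(f, x, character(0), bg), 0)
  expect_equal(value_function(f, x, "x1", bg), 3)  # closed form for linear f
  bg2 <- data.frame(x1 = c(1, 3), x2 = c(2, 4))
  expect_equal(value_function(f, x, character(0), bg2), mean(2 * c(1, 3) + c(2, 4)))
  expect_error(value_function(f, x, "x1", bg2[0, ]), "empty background")
})

test_that("exact enumeration satisfies the Shapley axioms", {
  bg <- as.data.frame(matrix(0, 3, 4))
  names(bg) <- paste0("x", 1:4)
  x <- data.frame(x1 = 1, x2 = -2, x3 = 0.5, x4 = 3)
  additive <- function(d) d$x1 + d$x2 + d$x3 + d$x4
  at <- shapley_exact(additive, x, bg)
  expect_equal(unname(at$phi), c(1, -2, 0.5, 3))  # additivity
  expect_equal(at$base_value + sum(at$phi), at$prediction, tolerance = 1e-10)
  # dummy: x4 ignored by the model gets exactly zero
  no4 <- function(d) d$x1 * d$x2
  expect_identical(unname(shapley_exact(no4, x, bg)$phi[4]), 0)
  # symmetry: interchangeable features get equal attributions
  sym <- function(d) 3 * (d$x1 + d$x2) + d$x3^2
  xs <- data.frame(x1 = 2, x2 = 2, x3 = 1, x4 = 0)
  ph <- shapley_exact(sym, xs, bg)$phi
  expect_equal(ph[["x1"]], ph[["x2"]], tolerance = 1e-8)
  expect_error(
    shapley_exact(additive, x, as.data.frame(matrix(0, 2, 16,
      dimnames = list(NULL, paste0("f", 1:16))))),
    "tree_shap")
})

test_that("tree attribution puts all mass on the only split feature", {
  set.seed(61)
  n <- 80
  x <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  y <- ifelse(x$x1 > 0, 2, -2)
  m <- emgoa:::rf_fit_raw(x, y, n_trees = 30, max_depth = 1, min_node = 1)
  ts <- tree_shap(m, x[1:10, ], x[11:40, ])
  expect_true(all(ts$phi[, c("x2", "x3")] == 0))
  expect_true(all(abs(ts$phi[, "x1"]) > 0))
  expect_equal(unname(ts$base_value + rowSums(ts$phi)), ts$prediction,
               tolerance = 1e-8)
  expect_error(tree_shap(function(d) d$x1, x[1, ], x), "emgoa_rf")
})

test_that("permutation oracle, subset enumeration and tree attribution agree", {
  set.seed(62)
  n <- 70
  p <- 7
  x <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(x) <- paste0("f", 1:p)
  y <- 2 * x$f1 - x$f3 + x$f5 * x$f7 + rnorm(n, 0, 0.1)
  m <- emgoa:::rf_fit_raw(x, y, n_trees = 25, max_depth = 4, min_node = 2)
  bg <- x[1:10, ]
  ts <- tree_shap(m, x[41:45, ], bg)
  for (i in 1:5) {
    xi <- x[40 + i, ]
    ex <- shapley_exact(m, xi, bg)
    po <- oracle_shapley_perm(rf_predict_fn(m), xi, bg, names(x))
    expect_equal(max(abs(ex$phi - po$phi)), 0, tolerance = 1e-6)
    expect_equal(max(abs(ex$phi - ts$phi[i, ])), 0, tolerance = 1e-6)
    expect_equal(ex$base_value, po$base_value, tolerance = 1e-10)
  }
})

test_that("global importance ranks mean |phi| and flags degenerate summaries", {
  phi1 <- c(a = -0.5, b = 2, c = 0)
  gi <- global_importance(phi1)
  expect_equal(unname(gi$importance), c(2, 0.5, 0))  # single instance: |phi|
  expect_identical(names(gi$importance), c("b", "a", "c"))
  expect_identical(gi$top$rank, 1:3)
  # monotone fixture: feature driving predictions up gets positive direction
  set.seed(63)
  xv <- rnorm(50)
  phi <- cbind(up = xv * 0.8, flat = rep(0, 50))
  st <- shap_summary_table(phi, data.frame(up = xv, flat = rep(1, 50)))
  expect_gt(st$direction[st$feature == "up"], 0.99)
  expect_identical(st$direction[st$feature == "flat"], 0)
  expect_true(st$degenerate[st$feature == "flat"])
})

test_that("attribution is flat when the model has no signal", {
  set.seed(64)
  n <- 90
  x <- as.data.frame(matrix(rnorm(n * 8), n, 8))
  names(x) <- paste0("f", 1:8)
  y <- rnorm(n)  # pure noise target
  m <- emgoa:::rf_fit_raw(x, y, n_trees = 60, max_depth = 5, min_node = 2)
  ts <- tree_shap(m, x, x[1:25, ])
  imp <- global_importance(ts$phi)$importance
  expect_lt(max(imp), 3 * median(imp))
})
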