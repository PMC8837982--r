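test_that("design matrices enumerate the right monomials", {
  expect_equal(drop(build_design(2, model_spec("Y3"))), c(1, 2, 4, 8),
               ignore_attr = TRUE)
  r <- build_design(matrix(c(2, 3, 5), 1), model_spec("Y1", "ternary"))
  expect_equal(drop(r), c(1, 2, 3, 5), ignore_attr = TRUE)
  X2 <- build_design(matrix(rnorm(30), 10), model_spec("Y2", "ternary"))
  expect_identical(ncol(X2), 10L)   # 1 + 3 linear + 6 quadratic
  X3 <- build_design(matrix(rnorm(30), 10), model_spec("Y3", "ternary"))
  expect_identical(ncol(X3), 20L)
  expect_error(build_design(matrix(rnorm(20), 10),
                            model_spec("Y1", "ternary")), "3 features")
  expect_error(build_design(1:5, model_spec("Y4")), "nonlinear")
})

test_that("family aliases, arity rules and p counts are as specified", {
  expect_identical(model_spec("Y3")$family, "poly3")
  expect_identical(model_spec("Y3")$p, 3L)
  expect_identical(model_spec("Y4")$p, 1L)
  expect_identical(model_spec("Y5")$p, 2L)
  expect_identical(model_spec("Y3", "ternary")$p, 19L)
  expect_identical(model_spec("Y4", "ternary")$p, 3L)
  expect_error(model_spec("Y5", "ternary"), "ternary")
})

test_that("noiseless fits recover their generating models", {
  set.seed(31)
  x <- sort(runif(40, 0.5, 3))
  beta <- c(0.2, -0.4, 0.9, 0.3)
  y <- drop(build_design(x, model_spec("Y3")) %*% beta)
  fit <- fit_model(x, y, model_spec("Y3"))
  expect_equal(unname(fit$coefficients), beta, tolerance = 1e-8)
  expect_equal(fit$metrics$r2, 1, tolerance = 1e-10)
  # power1: y = 2 x^0.5
  y2 <- 2 * x^0.5
  pfit <- fit_model(x, y2, model_spec("Y4"))
  expect_equal(unname(pfit$coefficients[c("a", "b")]), c(2, 0.5),
               tolerance = 1e-6)
  # power2: y = 1.5 x^0.8 + 0.3
  y3 <- 1.5 * x^0.8 + 0.3
  p2 <- fit_model(x, y3, model_spec("Y5"))
  expect_equal(unname(p2$coefficients[c("a", "b", "c")]), c(1.5, 0.8, 0.3),
               tolerance = 1e-5)
  expect_error(fit_model(c(-1, x[-1]), y2, model_spec("Y4")), "positive")
})

test_that("pure-noise responses give near-zero R2 and AR below R2", {
  set.seed(55)
  x <- runif(60, 1, 10)
  y <- rnorm(60)
  fit <- fit_model(x, y, model_spec("Y2"))
  expect_lt(fit$metrics$r2, 0.2)
  expect_lt(fit$metrics$ar, fit$metrics$r2)
})

test_that("construction metrics follow the degrees-of-freedom convention", {
  # pinned worked examples from the construction-table arithmetic
  y <- seq_len(60)
  e <- sqrt(0.6730 / 60)
  m <- evaluate_fit(y, y - e, n = 60, p = 1)
  expect_equal(m$sse, 0.6730, tolerance = 1e-12)
  expect_equal(round(m$rmse, 4), 0.1077)
  expect_equal(m$rmse_plain, sqrt(0.6730 / 60), tolerance = 1e-12)
  # AR from a pinned R2 at n = 60, p = 2
  sst <- sum((y - mean(y))^2)
  e2 <- sqrt((1 - 0.5723) * sst / 60)
  m2 <- evaluate_fit(y, y - e2, n = 60, p = 2)
  expect_equal(m2$r2, 0.5723, tolerance = 1e-12)
  expect_equal(round(m2$ar, 4), 0.5573)
  # perfect prediction
  mp <- evaluate_fit(y, y, n = 60, p = 3)
  expect_equal(unlist(mp[c("sse", "rmse", "r2", "ar")]),
               c(sse = 0, rmse = 0, r2 = 1, ar = 1))
  expect_error(evaluate_fit(rep(1, 10), rep(0, 10), p = 1), "undefined")
})

test_that("validation metrics use MSE-based RMSE", {
  y <- seq_len(12)
  e <- sqrt(0.0837)
  v <- evaluate_validation(y, y - e, n = 12, p = 3)
  expect_equal(v$mse, 0.0837, tolerance = 1e-12)
  expect_equal(round(v$rmse, 4), 0.2893)
  expect_equal(evaluate_validation(y, y, p = 1)$mse, 0)
  expect_warning(evaluate_validation(y, y - 1, n = 12, p = 19), "NA")
})

test_that("the chronological split partitions the epochs", {
  s <- train_val_split(72, 60)
  expect_length(s$train, 60)
  expect_length(s$validation, 12)
  expect_identical(sort(c(s$train, s$validation)), 1:72)
  expect_length(intersect(s$train, s$validation), 0L)
  expect_false(is.unsorted(s$validation))
  expect_error(train_val_split(72, 0), "n_train")
  expect_error(train_val_split(72, 72), "n_train")
})

test_that("R2 via 1 - SSE/SST equals the regression-SS form for linear fits", {
  set.seed(77)
  x <- runif(60, 1, 20)
  y <- 0.3 + 0.05 * x + rnorm(60, sd = 0.1)
  for (fam in c("Y1", "Y2", "Y3")) {
    fit <- fit_model(x, y, model_spec(fam))
    yhat <- fit$predict(x)
    expect_equal(fit$metrics$r2,
                 sum((yhat - mean(y))^2) / sum((y - mean(y))^2),
                 tolerance = 1e-10)
  }
})

test_that("nested polynomial families never increase training SSE", {
  set.seed(91)
  x <- runif(60, 1, 20)
  y <- 0.5 + 0.02 * x - 0.001 * x^2 + rnorm(60, sd = 0.05)
  sses <- vapply(c("Y1", "Y2", "Y3"), function(f)
    fit_model(x, y, model_spec(f))$metrics$sse, numeric(1))
  expect_true(all(diff(sses) <= 1e-10))
})

test_that("the model grid emits one row per feature-family pair", {
  run <- tg_default_run()
  g <- suppressWarnings(run_model_grid(run$table))
  # 6 univariate x 5 families + 2 ternary x 4 families
  expect_identical(nrow(g), 38L)
  expect_identical(anyDuplicated(g[c("item", "model")]), 0L)
  # metric identities across the whole grid
  expect_equal(g$rmse^2 * (60 - g$p - 1), g$sse, tolerance = 1e-9)
  expect_equal(g$val_rmse^2, g$val_mse, tolerance = 1e-12)
  # rerun is deterministic
  g2 <- suppressWarnings(run_model_grid(run$table))
  expect_identical(g, g2)
})
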