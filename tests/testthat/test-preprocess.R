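test_that("Savitzky-Golay filter reproduces constants and exact-order data", {
  expect_equal(sg_filter(rep(2.5, 20), 5, 2), rep(2.5, 20))
  # order = window - 1 interpolates every window: series unchanged
  set.seed(4)
  x <- rnorm(30)
  expect_equal(sg_filter(x, 5, 4), x, tolerance = 1e-9)
  # exact reproduction of monomials up to the fitted order (interior
  # and, by mirror symmetry of the padding, constants at edges too)
  t <- seq_len(40)
  for (d in 0:2) {
    filtered <- sg_filter((t / 10)^d, 5, 2)
    expect_equal(filtered[3:38], ((t / 10)^d)[3:38], tolerance = 1e-10)
  }
})

test_that("filter equals the per-window least-squares oracle", {
  set.seed(12)
  for (s in 1:3) {
    x <- rnorm(72)
    expect_equal(sg_filter(x, 5, 2), tg_sg_oracle(x, 5, 2),
                 tolerance = 1e-10)
  }
  x <- rnorm(50)
  expect_equal(sg_filter(x, 7, 3), tg_sg_oracle(x, 7, 3), tolerance = 1e-10)
})

test_that("envelope mode never lowers a value below the raw series", {
  set.seed(21)
  for (s in 1:5) {
    x <- rnorm(60)
    expect_true(all(sg_filter(x, 5, 2, envelope = TRUE) >= x))
  }
})

test_that("filter rejects invalid parameters and short series", {
  expect_error(sg_filter(rnorm(20), 4, 2), "odd")
  expect_error(sg_filter(rnorm(20), 5, 5), "order")
  expect_error(sg_filter(rnorm(3), 5, 2), "shorter")
})

test_that("min-max scaling is exact, bounded and invertible", {
  s <- minmax_scale(c(2, 4, 6))
  expect_equal(as.numeric(s), c(0, 0.5, 1))
  set.seed(8)
  x <- rnorm(100) * 17 + 3
  sx <- minmax_scale(x)
  expect_true(all(sx >= 0 & sx <= 1))
  expect_equal(minmax_invert(sx), x, tolerance = 1e-12)
  expect_error(minmax_scale(rep(1, 5)), "constant")
  # reapplying training-scale parameters to new data
  y <- minmax_apply(c(3, 5), minmax_scale(c(2, 4, 6)))
  expect_equal(as.numeric(y), c(0.25, 0.75))
})

test_that("epoch aggregation averages the preceding half-open window", {
  soil <- tg_toy_soil(10, per_day = 24)
  agg <- aggregate_to_epochs(soil, as.Date("2020-01-06"), window_days = 5)
  expect_equal(agg$st, 15)
  expect_equal(agg$smc, 20)
  # readings only outside the window -> missing-epoch error naming it
  expect_error(aggregate_to_epochs(soil, as.Date("2020-03-01"), 5),
               "2020-03-01")
  # linear trend: the window mean equals the value at the mean timestamp
  soil2 <- tg_toy_soil(10, per_day = 24, st = function(d) 2 + 3 * d)
  ep <- as.Date("2020-01-06")
  agg2 <- aggregate_to_epochs(soil2, ep, window_days = 5)
  # readings cover day offsets 0 .. 5 - 1/24; midpoint (5 - 1/24)/2
  expect_equal(agg2$st, 2 + 3 * (5 - 1 / 24) / 2, tolerance = 1e-9)
})

test_that("aggregation is cadence-invariant for day-constant signals", {
  stepfun_st <- function(d) 10 + floor(d)
  a <- tg_toy_soil(10, per_day = 4, st = stepfun_st)
  b <- tg_toy_soil(10, per_day = 144, st = stepfun_st)
  ep <- as.Date("2020-01-08")
  expect_equal(aggregate_to_epochs(a, ep, 5)$st,
               aggregate_to_epochs(b, ep, 5)$st, tolerance = 1e-12)
})

test_that("cumulative features apply the above-zero rule", {
  daily <- data.frame(day = as.Date("2020-01-01") + 0:2,
                      st = c(5, -2, 3), smc = c(1, 1, 1), sec = c(0, 2, 2))
  cum <- cumulative_features(daily, daily$day)
  expect_equal(cum$sst, c(5, 5, 8))
  expect_equal(cum$ssmc, c(1, 2, 3))
  expect_equal(cum$ssec, c(0, 2, 4))   # a zero day contributes nothing
  # all-negative days accumulate to zero
  neg <- data.frame(day = daily$day, st = c(-1, -5, -2), smc = -1:-3,
                    sec = c(-1, -1, -1))
  expect_true(all(cumulative_features(neg, daily$day)$sst == 0))
  expect_error(cumulative_features(daily, as.Date("2019-12-25")),
               "precedes")
})

test_that("cumulative features are monotone and additive over date ranges", {
  run <- tg_default_run()
  daily <- daily_means(run$soil)
  dates <- epoch_dates(run$cfg)
  cum <- cumulative_features(daily, dates)
  expect_false(is.unsorted(cum$sst))
  expect_false(is.unsorted(cum$ssmc))
  # additivity: total = value at e1 plus the increment over (e1, e2]
  e1 <- dates[30]; e2 <- dates[60]
  inc <- daily[daily$day > e1 & daily$day <= e2, ]
  expect_equal(cum$sst[60], cum$sst[30] + sum(pmax(inc$st, 0)),
               tolerance = 1e-9)
})

test_that("correlation matrix is symmetric with exact unit diagonal", {
  set.seed(2)
  df <- data.frame(a = rnorm(20))
  df$b <- -df$a
  df$c <- rnorm(20)
  cm <- correlation_matrix(df)
  expect_equal(diag(cm), c(a = 1, b = 1, c = 1))
  expect_equal(cm, t(cm))
  expect_equal(cm["a", "b"], -1)
  df$z <- 1
  expect_error(correlation_matrix(df), "z")
})

test_that("epoch table assembles all features on the epoch dates", {
  run <- tg_default_run()
  tab <- run$table
  expect_identical(nrow(tab), 72L)
  expect_named(tab, c("date", "st", "smc", "sec", "sst", "ssmc", "ssec",
                      "ndvi_raw", "ndvi_filtered"))
  expect_true(all(tab$ndvi_filtered >= tab$ndvi_raw))  # envelope default
  expect_false(is.unsorted(tab$sst))
})
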