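# Flat-vector order used by the finite-difference checks
grad_vec <- function(g)
  unlist(g[c("Wz", "bz", "Wi", "bi", "Wf", "bf", "Wo", "bo",
             "w_out", "b_out")], use.names = FALSE)

zeroed_params <- function(input_dim, hidden) {
  p <- lstm_init(input_dim, hidden, seed = 1)
  for (nm in c("Wz", "Wi", "Wf", "Wo")) p[[nm]][] <- 0
  p$w_out[] <- 0; p$b_out <- 0
  p
}

test_that("the zero-weight cell has its closed form", {
  p <- zeroed_params(2, 3)
  c_prev <- matrix(c(0.4, -0.2, 1.1), 3, 1)
  out <- lstm_cell_forward(c(0.5, -0.3), matrix(0, 3, 1), c_prev, p)
  expect_equal(out$zi, matrix(0.5, 3, 1), ignore_attr = TRUE)
  expect_equal(out$zf, matrix(0.5, 3, 1), ignore_attr = TRUE)
  expect_equal(out$zo, matrix(0.5, 3, 1), ignore_attr = TRUE)
  expect_equal(out$z, matrix(0, 3, 1), ignore_attr = TRUE)
  expect_equal(out$c, 0.5 * c_prev)
  expect_equal(out$h, 0.5 * tanh(0.5 * c_prev))
})

test_that("a saturated input gate shuts the candidate path", {
  # z_i -> 0 as its pre-activation -> -Inf; with c_prev = 0, c_t -> 0
  p <- zeroed_params(1, 2)
  p$bi <- rep(-30, 2)
  out <- lstm_cell_forward(0.7, matrix(0, 2, 1), matrix(0, 2, 1), p)
  expect_equal(out$c, matrix(0, 2, 1), tolerance = 1e-12)
})

test_that("a two-unit cell matches a hand-worked forward pass", {
  p <- zeroed_params(1, 2)
  # hand-set small weights: rows are hidden units, cols [x, h1, h2]
  p$Wz <- matrix(c(0.5, -0.3, 0.2, 0.1, -0.1, 0.4), 2, 3)
  p$Wi <- matrix(c(0.3, 0.2, -0.2, 0.1, 0.05, -0.05), 2, 3)
  p$Wf <- matrix(c(-0.1, 0.4, 0.3, -0.3, 0.2, 0.1), 2, 3)
  p$Wo <- matrix(c(0.2, 0.2, 0.1, 0.1, -0.4, 0.3), 2, 3)
  p$bz <- c(0.01, -0.02); p$bi <- c(0.03, 0.04)
  p$bf <- c(-0.01, 0.02); p$bo <- c(0.05, -0.03)
  x <- 0.6; h0 <- c(0.1, -0.2); c0 <- c(0.05, 0.3)
  out <- lstm_cell_forward(x, matrix(h0), matrix(c0), p)
  # independent scalar walk through the gate equations
  a <- c(x, h0)
  z <- tanh(p$Wz %*% a + p$bz)
  zi <- 1 / (1 + exp(-(p$Wi %*% a + p$bi)))
  zf <- 1 / (1 + exp(-(p$Wf %*% a + p$bf)))
  zo <- 1 / (1 + exp(-(p$Wo %*% a + p$bo)))
  ct <- zf * c0 + zi * z
  ht <- zo * tanh(ct)
  expect_equal(out$c, ct, tolerance = 1e-12)
  expect_equal(out$h, ht, tolerance = 1e-12)
})

test_that("the unrolled forward pass respects base case and output range", {
  p <- lstm_init(3, 4, seed = 6)
  x1 <- matrix(rnorm(3), 3, 1)
  # length-1 window equals one cell step plus the output map
  one <- lstm_cell_forward(x1, matrix(0, 4, 1), matrix(0, 4, 1), p)
  expect_equal(lstm_forward(x1, p),
               drop(1 / (1 + exp(-(p$w_out %*% one$h + p$b_out)))))
  set.seed(3)
  X <- array(rnorm(3 * 5 * 11), c(3, 5, 11))
  yhat <- lstm_forward(X, p)
  expect_length(yhat, 11)
  expect_true(all(yhat > 0 & yhat < 1))
})

test_that("constant input drives the hidden state toward a fixed point", {
  p <- lstm_init(2, 3, seed = 9)
  x <- c(0.3, -0.5)
  h <- matrix(0, 3, 1); cc <- matrix(0, 3, 1)
  diffs <- numeric(40)
  for (t in 1:40) {
    s <- lstm_cell_forward(x, h, cc, p)
    diffs[t] <- max(abs(s$h - h))
    h <- s$h; cc <- s$c
  }
  expect_lt(diffs[40], 1e-6)
  expect_lt(diffs[40], diffs[5])
})

test_that("analytic gradients agree with central differences", {
  p <- lstm_init(2, 2, seed = 5)
  set.seed(9)
  X <- array(runif(2 * 3 * 4), c(2, 3, 4))
  y <- runif(4)
  lg <- lstm_loss_grad(p, X, y)
  th <- lstm_flatten(p)
  h <- 1e-6
  gnum <- vapply(seq_along(th), function(k) {
    tp <- th; tp[k] <- tp[k] + h
    tm <- th; tm[k] <- tm[k] - h
    (lstm_loss_grad(lstm_unflatten(tp, p), X, y)$loss -
       lstm_loss_grad(lstm_unflatten(tm, p), X, y)$loss) / (2 * h)
  }, numeric(1))
  ga <- grad_vec(lg$grads)
  rel <- sqrt(sum((ga - gnum)^2)) / max(sqrt(sum(ga^2)), sqrt(sum(gnum^2)))
  expect_lt(rel, 1e-5)
})

test_that("training fits a small noiseless mapping and is deterministic", {
  set.seed(20)
  X <- array(runif(3 * 2 * 20), c(3, 2, 20))
  # noiseless smooth target of the window means, inside (0, 1)
  y <- 0.2 + 0.6 * apply(X, 3, mean)
  m <- lstm_train(list(X = X, y = y), lr = 0.02, hidden = 8, epochs = 400,
                  seed = 2)
  expect_lt(m$loss_history[length(m$loss_history)], 1e-3)
  expect_true(all(is.finite(m$loss_history)))
  m2 <- lstm_train(list(X = X, y = y), lr = 0.02, hidden = 8, epochs = 400,
                   seed = 2)
  expect_identical(m$loss_history, m2$loss_history)
  expect_equal(predict(m, X), predict(m2, X))
})

test_that("flatten and unflatten round-trip the parameters", {
  p <- lstm_init(3, 5, seed = 8)
  expect_equal(lstm_unflatten(lstm_flatten(p), p), p)
})

test_that("sequence building gives the 50/21 chronological split", {
  tab <- tg_default_run()$table
  sq <- make_sequences(tab)
  expect_length(sq$train$y, 50)
  expect_length(sq$test$y, 21)
  expect_identical(dim(sq$train$X), c(3L, 2L, 50L))
  # no test target epoch appears in any training window
  train_rows <- unlist(lapply(sq$target_index$train,
                              function(t) (t - 1):t))
  expect_length(intersect(sq$target_index$test, train_rows), 0L)
  # normalization parameters come from the training portion only
  expect_equal(sq$scaling$y_min,
               min(tab$ndvi_filtered[sq$target_index$train]))
  # lookback 1: windows are single epochs, 72 - 0 of them
  sq1 <- make_sequences(tab, lookback = 1, n_train = 50)
  expect_length(sq1$train$y, 50)
  expect_length(sq1$test$y, 22)
  expect_error(make_sequences(tab, lookback = 80), "cannot form")
  # target denormalization round-trips
  expect_equal(denormalize_target(sq$train$y, sq),
               tab$ndvi_filtered[sq$target_index$train],
               tolerance = 1e-12)
})
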