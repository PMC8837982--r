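sigmoid <- function(x) 1 / (1 + exp(-x))

#' Initialize the parameters of a single-layer LSTM regressor
#'
#' One LSTM cell with hidden size `H` acting on the concatenation
#' `[x_t, h_{t-1}]`: a tanh-squashed candidate block `z` and three
#' sigmoid gates (input, forget, output), each with its own weight
#' matrix and bias, plus a sigmoid output map `y = sigma(w' h_L + b)`.
#' Weights are initialized uniformly in `[-init_scale, init_scale]`.
#'
#' @param input_dim number of input features per time step.
#' @param hidden hidden state size `H`.
#' @param seed integer seed for the initialization draw.
#' @param init_scale half-width of the uniform initialization.
#' @return list of class `"lstm_params"` with weight blocks `Wz`, `Wi`,
#'   `Wf`, `Wo` (each `H x (input_dim + H)`), biases `bz`, `bi`, `bf`,
#'   `bo`, and output weights `w_out` (length `H`), `b_out`.
#' @export
lstm_init <- function(input_dim, hidden, seed = 1L, init_scale = 0.1) {
  stopifnot(input_dim >= 1, hidden >= 1, init_scale > 0)
  set.seed(seed)
  m <- function(r, c) matrix(stats::runif(r * c, -init_scale, init_scale),
                             r, c)
  structure(list(
    Wz = m(hidden, input_dim + hidden), bz = rep(0, hidden),
    Wi = m(hidden, input_dim + hidden), bi = rep(0, hidden),
    Wf = m(hidden, input_dim + hidden), bf = rep(0, hidden),
    Wo = m(hidden, input_dim + hidden), bo = rep(0, hidden),
    w_out = drop(m(1, hidden)), b_out = 0,
    input_dim = as.integer(input_dim), hidden = as.integer(hidden)
  ), class = "lstm_params")
}

#' One LSTM cell step
#'
#' Computes the candidate `z = tanh(Wz [x, h])`, the gates
#' `z_i, z_f, z_o = sigma(W [x, h])`, the cell state
#' `c_t = z_f * c_{t-1} + z_i * z` and the hidden state
#' `h_t = z_o * tanh(c_t)`. All inputs may be matrices with one column
#' per sample.
#'
#' @param x_t input at time t (`input_dim x N` matrix or vector).
#' @param h_prev,c_prev previous hidden / cell state (`H x N`).
#' @param params an [lstm_init()] parameter list.
#' @return list with `h`, `c`, and the intermediate activations
#'   (`z`, `zi`, `zf`, `zo`, `a`) needed for backpropagation.
#' @export
lstm_cell_forward <- function(x_t, h_prev, c_prev, params) {
  x_t <- as.matrix(x_t); h_prev <- as.matrix(h_prev)
  c_prev <- as.matrix(c_prev)
  a <- rbind(x_t, h_prev)
  z <- tanh(params$Wz %*% a + params$bz)
  zi <- sigmoid(params$Wi %*% a + params$bi)
  zf <- sigmoid(params$Wf %*% a + params$bf)
  zo <- sigmoid(params$Wo %*% a + params$bo)
  c_t <- zf * c_prev + zi * z
  h_t <- zo * tanh(c_t)
  if (any(!is.finite(h_t)))
    stop("non-finite LSTM activation (|w_out| = ",
         signif(sqrt(sum(params$w_out^2)), 4), ")", call. = FALSE)
  list(h = h_t, c = c_t, z = z, zi = zi, zf = zf, zo = zo, a = a)
}

#' Forward pass over an input window
#'
#' Unrolls the cell over the `L` time steps of each window starting
#' from zero hidden and cell states, then maps the final hidden state
#' through the sigmoid output layer, so predictions lie in (0, 1) and
#' match min-max normalized targets.
#'
#' @param X input array of dimension `(input_dim, L, N)` (features x
#'   time x samples), or a `input_dim x L` matrix for a single window.
#' @param params an [lstm_init()] parameter list.
#' @param keep_cache return intermediate activations for
#'   backpropagation.
#' @return numeric vector of `N` predictions; with `keep_cache = TRUE`
#'   a list `(yhat, caches, h_last)`.
#' @export
lstm_forward <- function(X, params, keep_cache = FALSE) {
  if (length(dim(X)) == 2) dim(X) <- c(dim(X), 1L)
  d <- dim(X)
  stopifnot(d[1] == params$input_dim)
  L <- d[2]; N <- d[3]
  h <- matrix(0, params$hidden, N)
  cst <- matrix(0, params$hidden, N)
  caches <- if (keep_cache) vector("list", L) else NULL
  for (t in seq_len(L)) {
    x_t <- matrix(X[, t, ], d[1], N)
    step <- lstm_cell_forward(x_t, h, cst, params)
    if (keep_cache) {
      step$c_prev <- cst
      caches[[t]] <- step
    }
    h <- step$h; cst <- step$c
  }
  yhat <- drop(sigmoid(params$w_out %*% h + params$b_out))
  if (keep_cache) list(yhat = yhat, caches = caches, h_last = h)
  else yhat
}

#' Mean-squared-error loss and analytic gradients
#'
#' Full backpropagation through time of `mean((yhat - y)^2)` with
#' respect to every parameter, used both by [lstm_train()] and by
#' finite-difference gradient checks.
#'
#' @param params an [lstm_init()] parameter list.
#' @param X input array `(input_dim, L, N)`.
#' @param y targets, length `N`.
#' @return list with `loss` and `grads` (same shapes as `params`).
#' @export
lstm_loss_grad <- function(params, X, y) {
  if (length(dim(X)) == 2) dim(X) <- c(dim(X), 1L)
  fw <- lstm_forward(X, params, keep_cache = TRUE)
  N <- length(y)
  L <- dim(X)[2]; D <- params$input_dim; H <- params$hidden
  err <- fw$yhat - y
  loss <- mean(err^2)
  dyhat <- matrix(2 * err / N, 1, N)
  do_pre <- dyhat * fw$yhat * (1 - fw$yhat)       # sigmoid output layer
  g <- list(Wz = 0 * params$Wz, bz = 0 * params$bz,
            Wi = 0 * params$Wi, bi = 0 * params$bi,
            Wf = 0 * params$Wf, bf = 0 * params$bf,
            Wo = 0 * params$Wo, bo = 0 * params$bo,
            w_out = drop(do_pre %*% t(fw$h_last)),
            b_out = sum(do_pre))
  dh <- matrix(params$w_out, H, 1) %*% do_pre
  dc <- matrix(0, H, N)
  for (t in rev(seq_len(L))) {
    s <- fw$caches[[t]]
    tc <- tanh(s$c)
    dzo <- dh * tc
    dc <- dc + dh * s$zo * (1 - tc^2)
    dzf <- dc * s$c_prev
    dzi <- dc * s$z
    dz <- dc * s$zi
    gz <- dz * (1 - s$z^2)
    gi <- dzi * s$zi * (1 - s$zi)
    gf <- dzf * s$zf * (1 - s$zf)
    go <- dzo * s$zo * (1 - s$zo)
    g$Wz <- g$Wz + gz %*% t(s$a); g$bz <- g$bz + rowSums(gz)
    g$Wi <- g$Wi + gi %*% t(s$a); g$bi <- g$bi + rowSums(gi)
    g$Wf <- g$Wf + gf %*% t(s$a); g$bf <- g$bf + rowSums(gf)
    g$Wo <- g$Wo + go %*% t(s$a); g$bo <- g$bo + rowSums(go)
    da <- t(params$Wz) %*% gz + t(params$Wi) %*% gi +
      t(params$Wf) %*% gf + t(params$Wo) %*% go
    dh <- da[(D + 1):(D + H), , drop = FALSE]
    dc <- dc * s$zf
  }
  list(loss = loss, grads = g)
}

lstm_param_names <- c("Wz", "bz", "Wi", "bi", "Wf", "bf", "Wo", "bo",
                      "w_out", "b_out")

#' Flatten LSTM parameters to a numeric vector (and back)
#'
#' @param params an [lstm_init()] parameter list.
#' @return numeric vector of all weights and biases.
#' @export
lstm_flatten <- function(params)
  unlist(params[lstm_param_names], use.names = FALSE)

#' @rdname lstm_flatten
#' @param theta flat parameter vector.
#' @param template parameter list providing the shapes.
#' @export
lstm_unflatten <- function(theta, template) {
  out <- template
  pos <- 0L
  for (nm in lstm_param_names) {
    k <- length(template[[nm]])
    v <- theta[pos + seq_len(k)]
    out[[nm]] <- if (is.matrix(template[[nm]]))
      matrix(v, nrow(template[[nm]]), ncol(template[[nm]])) else v
    pos <- pos + k
  }
  out
}

#' Train the LSTM regressor by full-batch Adam
#'
#' Minimizes the mean squared error of the sigmoid output against
#' min-max normalized targets using backpropagation through time and
#' Adam updates over the whole (small) training set. Deterministic for
#' a fixed seed.
#'
#' @param data list with `X` (input array `(input_dim, L, N)`) and `y`
#'   (targets in (0, 1), length `N`), e.g. the `train` element of
#'   [make_sequences()].
#' @param lr learning rate; default 0.01.
#' @param hidden hidden size; default 16.
#' @param epochs number of full-batch updates; default 500.
#' @param seed initialization seed.
#' @param init_scale uniform initialization half-width.
#' @return object of class `"lstm_model"`: `params`, `loss_history`,
#'   and the training settings.
#' @export
lstm_train <- function(data, lr = 0.01, hidden = 16L, epochs = 500L,
                       seed = 1L, init_scale = 0.1) {
  stopifnot(lr > 0, hidden >= 1, epochs >= 1, length(data$y) >= 1)
  X <- data$X
  if (length(dim(X)) == 2) dim(X) <- c(dim(X), 1L)
  params <- lstm_init(dim(X)[1], hidden, seed = seed,
                      init_scale = init_scale)
  theta <- lstm_flatten(params)
  m <- v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    lg <- lstm_loss_grad(lstm_unflatten(theta, params), X, data$y)
    if (!is.finite(lg$loss))
      stop("training diverged at epoch ", ep, "; last finite loss ",
           signif(history[max(ep - 1, 1)], 6), call. = FALSE)
    history[ep] <- lg$loss
    gvec <- unlist(lg$grads[lstm_param_names], use.names = FALSE)
    m <- b1 * m + (1 - b1) * gvec
    v <- b2 * v + (1 - b2) * gvec^2
    mhat <- m / (1 - b1^ep)
    vhat <- v / (1 - b2^ep)
    theta <- theta - lr * mhat / (sqrt(vhat) + eps)
  }
  structure(list(params = lstm_unflatten(theta, params),
                 loss_history = history, lr = lr,
                 hidden = as.integer(hidden),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "lstm_model")
}

#' @export
predict.lstm_model <- function(object, newdata, ...) {
  X <- if (is.list(newdata) && !is.null(newdata$X)) newdata$X else newdata
  lstm_forward(X, object$params)
}

#' @export
print.lstm_model <- function(x, ...) {
  cat(sprintf("<lstm_model> hidden = %d, lr = %g, epochs = %d, final loss %.3g\n",
              x$hidden, x$lr, x$epochs,
              x$loss_history[length(x$loss_history)]))
  invisible(x)
}

#' Build chronological input windows from an epoch table
#'
#' Each sample is a window of `lookback` consecutive epochs of the soil
#' features with the NDVI at the window's final epoch as target. The
#' first `n_train` windows form the training set and the remainder the
#' test set; with 72 epochs and `lookback = 2` this gives the 71 usable
#' windows split 50/21. Features and targets are min-max normalized
#' with parameters fitted on the training portion only (no leakage).
#'
#' @param table an `epoch_table`.
#' @param lookback window length `L` in epochs; default 2.
#' @param n_train number of training windows; default 50.
#' @param feature_cols soil feature columns; default instantaneous
#'   ST/SMC/SEC.
#' @param target_col NDVI column; default `"ndvi_filtered"`.
#' @return list of class `"sequence_data"`: `train` and `test` (each
#'   `X` of dimension `(features, lookback, N)` and `y`), the scaling
#'   parameters, and `target_index` vectors giving the epoch row of
#'   each target.
#' @export
make_sequences <- function(table, lookback = 2L, n_train = 50L,
                           feature_cols = c("st", "smc", "sec"),
                           target_col = "ndvi_filtered") {
  lookback <- as.integer(lookback); n_train <- as.integer(n_train)
  n <- nrow(table)
  if (lookback < 1L) stop("`lookback` must be >= 1", call. = FALSE)
  n_win <- n - lookback + 1L
  if (n_win < 2L || n_train < 1L || n_train >= n_win)
    stop("cannot form ", n_train, " training plus >= 1 test windows from ",
         n, " epochs at lookback ", lookback, call. = FALSE)
  targets <- seq(lookback, n)
  # training windows touch feature rows 1 .. lookback-1+n_train only
  train_rows <- seq_len(lookback - 1L + n_train)
  feat <- as.matrix(table[feature_cols])
  y_all <- table[[target_col]]
  f_min <- apply(feat[train_rows, , drop = FALSE], 2, min)
  f_rng <- apply(feat[train_rows, , drop = FALSE], 2, max) - f_min
  if (any(f_rng == 0)) stop("constant feature column", call. = FALSE)
  y_tr <- y_all[targets[seq_len(n_train)]]
  y_min <- min(y_tr); y_rng <- max(y_tr) - y_min
  if (y_rng == 0) stop("constant target over the training split",
                       call. = FALSE)
  feat_n <- sweep(sweep(feat, 2, f_min), 2, f_rng, `/`)
  y_n <- (y_all - y_min) / y_rng
  build <- function(idx) {
    X <- array(0, dim = c(length(feature_cols), lookback, length(idx)))
    for (k in seq_along(idx)) {
      rows <- (targets[idx[k]] - lookback + 1L):targets[idx[k]]
      X[, , k] <- t(feat_n[rows, , drop = FALSE])
    }
    list(X = X, y = y_n[targets[idx]])
  }
  tr_idx <- seq_len(n_train)
  te_idx <- seq(n_train + 1L, n_win)
  structure(list(
    train = build(tr_idx), test = build(te_idx),
    scaling = list(f_min = f_min, f_rng = f_rng, y_min = y_min,
                   y_rng = y_rng),
    target_index = list(train = targets[tr_idx], test = targets[te_idx]),
    lookback = lookback, feature_cols = feature_cols,
    target_col = target_col
  ), class = "sequence_data")
}

#' Invert the target normalization of a sequence dataset
#'
#' @param y_norm predictions or targets on the normalized (0, 1) scale.
#' @param seqdata a [make_sequences()] result.
#' @return values on the original NDVI scale.
#' @export
denormalize_target <- function(y_norm, seqdata) {
  y_norm * seqdata$scaling$y_rng + seqdata$scaling$y_min
}
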