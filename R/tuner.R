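#' Hyperparameter search space for LSTM tuning
#'
#' The learning rate is searched on a log10 scale (it spans decades);
#' the hidden size is handled by continuous relaxation and rounded to
#' the nearest integer when a candidate is decoded.
#'
#' @param lr_bounds positive learning-rate bounds; default
#'   `c(1e-4, 1e-1)`.
#' @param hidden_bounds integer hidden-size bounds; default `c(2, 64)`.
#' @return object of class `"search_space"`.
#' @export
search_space <- function(lr_bounds = c(1e-4, 1e-1),
                         hidden_bounds = c(2L, 64L)) {
  if (any(lr_bounds <= 0) || lr_bounds[1] > lr_bounds[2])
    stop("`lr_bounds` must be positive and ordered", call. = FALSE)
  hidden_bounds <- as.integer(hidden_bounds)
  if (hidden_bounds[1] < 1L || hidden_bounds[1] > hidden_bounds[2])
    stop("`hidden_bounds` must be ordered positive integers",
         call. = FALSE)
  structure(list(lr_bounds = lr_bounds, hidden_bounds = hidden_bounds),
            class = "search_space")
}

#' Decode a continuous candidate into (learning rate, hidden size)
#'
#' @param candidate numeric vector `(log10 learning rate, hidden size)`.
#' @param space a [search_space()].
#' @return list with `lr` and integer `hidden`, both clipped into the
#'   space.
#' @export
decode_candidate <- function(candidate, space) {
  lr <- 10^candidate[1]
  lr <- min(max(lr, space$lr_bounds[1]), space$lr_bounds[2])
  hidden <- as.integer(round(candidate[2]))
  hidden <- min(max(hidden, space$hidden_bounds[1]), space$hidden_bounds[2])
  list(lr = lr, hidden = hidden)
}

#' Fitness of a hyperparameter candidate
#'
#' Decodes the candidate, trains the LSTM on the training windows under
#' a fixed inner seed, and returns the RMSE on the held-out windows, so
#' fitness is a deterministic function of the candidate and the
#' greedy-acceptance history of the optimizer is meaningful. A training
#' failure (divergence) is encoded as a large penalty.
#'
#' @param candidate numeric `(log10 lr, hidden size)` vector.
#' @param seqdata a [make_sequences()] dataset.
#' @param space a [search_space()].
#' @param inner_seed seed used for every training run.
#' @param epochs training epochs per evaluation.
#' @return held-out RMSE (penalty 1e6 on failure).
#' @export
lstm_fitness <- function(candidate, seqdata, space, inner_seed = 1L,
                         epochs = 300L) {
  dec <- decode_candidate(candidate, space)
  model <- tryCatch(
    lstm_train(seqdata$train, lr = dec$lr, hidden = dec$hidden,
               epochs = epochs, seed = inner_seed),
    error = function(e) NULL)
  if (is.null(model)) return(1e6)
  yhat <- lstm_forward(seqdata$test$X, model$params)
  rmse <- sqrt(mean((seqdata$test$y - yhat)^2))
  if (!is.finite(rmse)) 1e6 else rmse
}

#' Tune the LSTM with Bald Eagle Search
#'
#' Runs [bes_optimize()] over the 2-D encoded hyperparameter space with
#' [lstm_fitness()] as the objective, then retrains the final model at
#' the best decoded candidate. Decoded candidates are memoized so the
#' many continuous positions that round to the same (lr, hidden) pair
#' cost one training run. The search is warm-started from the package's
#' default configuration, so under the deterministic fitness the tuned
#' candidate can never be worse than the default on the held-out
#' windows.
#'
#' @param seqdata a [make_sequences()] dataset.
#' @param space a [search_space()].
#' @param pop_size,iterations,outer_seed Bald Eagle Search settings
#'   (see [bes_config()]).
#' @param inner_seed fixed seed for every training run.
#' @param epochs training epochs per evaluation and for the final
#'   model.
#' @param default_lr,default_hidden warm-start (and baseline)
#'   hyperparameters.
#' @return list of class `"bes_lstm"`: `lr`, `hidden`, `model` (final
#'   retrained [lstm_train()] fit), `history` (best fitness per
#'   iteration), `best_fitness`, and `n_evaluations` (distinct decoded
#'   candidates trained).
#' @export
tune_lstm <- function(seqdata, space = search_space(),
                      pop_size = 30L, iterations = 100L,
                      outer_seed = 1L, inner_seed = 1L, epochs = 300L,
                      default_lr = 0.01, default_hidden = 16L) {
  stopifnot(inherits(space, "search_space"))
  if (space$lr_bounds[1] == space$lr_bounds[2] &&
      space$hidden_bounds[1] == space$hidden_bounds[2]) {
    # degenerate space: the single admissible candidate is the answer
    lr <- space$lr_bounds[1]; hidden <- space$hidden_bounds[1]
    model <- lstm_train(seqdata$train, lr = lr, hidden = hidden,
                        epochs = epochs, seed = inner_seed)
    f <- lstm_fitness(c(log10(lr), hidden), seqdata, space,
                      inner_seed = inner_seed, epochs = epochs)
    return(structure(list(lr = lr, hidden = hidden, model = model,
                          history = rep(f, iterations), best_fitness = f,
                          n_evaluations = 1L),
                     class = "bes_lstm"))
  }
  config <- bes_config(
    pop_size = pop_size, iterations = iterations,
    lower = c(log10(space$lr_bounds[1]), space$hidden_bounds[1]),
    upper = c(log10(space$lr_bounds[2]), space$hidden_bounds[2]),
    seed = outer_seed)
  cache <- new.env(parent = emptyenv())
  objective <- function(cand) {
    dec <- decode_candidate(cand, space)
    key <- paste(signif(dec$lr, 12), dec$hidden)
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- lstm_fitness(cand, seqdata, space, inner_seed = inner_seed,
                      epochs = epochs)
    cache[[key]] <- f
    f
  }
  warm <- matrix(c(log10(default_lr), default_hidden), nrow = 1)
  res <- bes_optimize(objective, config, init = warm)
  dec <- decode_candidate(res$par, space)
  model <- lstm_train(seqdata$train, lr = dec$lr, hidden = dec$hidden,
                      epochs = epochs, seed = inner_seed)
  structure(list(lr = dec$lr, hidden = dec$hidden, model = model,
                 history = res$history, best_fitness = res$value,
                 n_evaluations = length(ls(cache))),
            class = "bes_lstm")
}

#' @export
print.bes_lstm <- function(x, ...) {
  cat(sprintf(
    "<bes_lstm> lr = %.5g, hidden = %d, held-out RMSE %.4f (%d trainings)\n",
    x$lr, x$hidden, x$best_fitness, x$n_evaluations))
  invisible(x)
}

#' Compare baseline and tuned LSTM on the same test windows
#'
#' Emits the five-metric suite (R2, RMSE, MSE, MAE, MAPE) for both
#' models on the normalized NDVI scale.
#'
#' @param tuned a [tune_lstm()] result or `lstm_model`.
#' @param baseline a baseline `lstm_model`.
#' @param test list with `X` and `y` (e.g. `seqdata$test`).
#' @return `data.frame` with rows `LSTM` and `BES-LSTM` and the five
#'   metric columns.
#' @export
compare_report <- function(tuned, baseline, test) {
  tuned_model <- if (inherits(tuned, "bes_lstm")) tuned$model else tuned
  rep_one <- function(model) {
    score(test$y, lstm_forward(test$X, model$params))
  }
  out <- rbind(rep_one(baseline), rep_one(tuned_model))
  cbind(model = c("LSTM", "BES-LSTM"), out)
}
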