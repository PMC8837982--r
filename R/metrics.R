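#' Prediction-quality metric suite
#'
#' Computes the five indicators used for network evaluation: coefficient
#' of determination R2 = 1 - SSE/SST, root mean square error, mean
#' square error, mean absolute error, and mean absolute percentage error
#' (in percent). R2 may be negative out of sample; the others are
#' nonnegative and satisfy `mae <= rmse` and `rmse = sqrt(mse)`.
#'
#' @param y observed values (length >= 2).
#' @param yhat predictions, same length.
#' @return one-row `data.frame` with columns `r2`, `rmse`, `mse`, `mae`,
#'   `mape`. If any `y` is zero, MAPE is undefined: it is returned as
#'   `NA` with a warning while the other metrics are still computed.
#' @export
score <- function(y, yhat) {
  if (length(y) != length(yhat))
    stop("`y` and `yhat` must have equal length", call. = FALSE)
  if (length(y) < 2) stop("need at least 2 observations", call. = FALSE)
  e <- y - yhat
  mse <- mean(e^2)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("R2 undefined: zero total sum of squares", call. = FALSE)
  mape <- if (any(y == 0)) {
    warning("MAPE undefined: target contains zeros; returning NA")
    NA_real_
  } else 100 * mean(abs(e) / abs(y))
  data.frame(r2 = 1 - sum(e^2) / sst, rmse = sqrt(mse), mse = mse,
             mae = mean(abs(e)), mape = mape)
}
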