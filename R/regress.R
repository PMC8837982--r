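#' Growth-response model specification
#'
#' The five families used for the growth-response regression, named
#' Y1-Y5: polynomials of degree 1, 2 and 3 (`poly1`..`poly3`) and power
#' models with one term (`power1`, `a*x^b`) and two terms (`power2`,
#' `a*x^b + c`). Each can be fitted on a single feature (`univariate`)
#' or on a ternary feature triple (`ternary`, the multiparameter-fusion
#' setting); the ternary family set is {poly1, poly2, poly3, power1},
#' where ternary power1 is the multivariate power law
#' `a * x1^b1 * x2^b2 * x3^b3`.
#'
#' The feature count `p` entering the adjusted-R2 penalty is the
#' polynomial degree for univariate polynomials, 1 for power1, 2 for
#' power2, the number of non-intercept basis terms for ternary
#' polynomials, and 3 for the ternary power law.
#'
#' @param family one of `"poly1"`, `"poly2"`, `"poly3"`, `"power1"`,
#'   `"power2"`, or the aliases `"Y1"`..`"Y5"`.
#' @param arity `"univariate"` or `"ternary"`.
#' @return object of class `"model_spec"`.
#' @export
model_spec <- function(family, arity = c("univariate", "ternary")) {
  aliases <- c(Y1 = "poly1", Y2 = "poly2", Y3 = "poly3",
               Y4 = "power1", Y5 = "power2")
  if (family %in% names(aliases)) family <- aliases[[family]]
  family <- match.arg(family, unname(aliases))
  arity <- match.arg(arity)
  if (arity == "ternary" && family == "power2")
    stop("the ternary family set is poly1, poly2, poly3, power1",
         call. = FALSE)
  degree <- switch(family, poly1 = 1L, poly2 = 2L, poly3 = 3L, NA_integer_)
  p <- if (family == "power1") {
    if (arity == "ternary") 3L else 1L
  } else if (family == "power2") {
    2L
  } else if (arity == "ternary") {
    # monomials of total degree 1..d in 3 variables
    as.integer(choose(degree + 3, 3) - 1)
  } else degree
  structure(list(family = family, arity = arity, degree = degree, p = p,
                 label = names(aliases)[match(family, aliases)]),
            class = "model_spec")
}

#' Polynomial basis (design) matrix for a model specification
#'
#' Univariate degree-d: columns `1, x, ..., x^d`. Ternary degree-d: all
#' monomials in the three features of total degree 0..d (intercept
#' first, then ordered by total degree). Power families have no linear
#' basis and are rejected.
#'
#' @param x numeric vector (univariate) or 3-column matrix / data frame
#'   (ternary).
#' @param spec a [model_spec()].
#' @return numeric design matrix with an intercept column.
#' @export
build_design <- function(x, spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$family %in% c("power1", "power2"))
    stop("power families are fitted in their nonlinear form", call. = FALSE)
  d <- spec$degree
  if (spec$arity == "univariate") {
    x <- as.numeric(x)
    out <- outer(x, 0:d, `^`)
    colnames(out) <- c("1", paste0("x^", seq_len(d)))
    return(out)
  }
  x <- as.matrix(x)
  if (ncol(x) != 3)
    stop("ternary arity requires exactly 3 features, got ", ncol(x),
         call. = FALSE)
  expo <- expand.grid(i = 0:d, j = 0:d, k = 0:d)
  expo <- expo[rowSums(expo) <= d, , drop = FALSE]
  expo <- expo[order(rowSums(expo), -expo$i, -expo$j, -expo$k), ,
               drop = FALSE]
  cols <- apply(expo, 1, function(e)
    x[, 1]^e[1] * x[, 2]^e[2] * x[, 3]^e[3])
  cols <- matrix(cols, nrow = nrow(x))
  colnames(cols) <- apply(expo, 1, function(e)
    paste0("x1^", e[1], ".x2^", e[2], ".x3^", e[3]))
  cols
}

# Multi-start nonlinear least squares for the power families.
# For fixed exponent(s) the amplitude (and offset) are linear, so the
# starts profile them out over a log-spaced exponent grid before
# Levenberg-Marquardt refinement.
fit_power <- function(x, y, spec) {
  two_term <- spec$family == "power2"
  if (spec$arity == "univariate") {
    x <- as.numeric(x)
    if (any(x <= 0))
      stop("power families require strictly positive features",
           call. = FALSE)
    b_grid <- seq(-3, 3, length.out = 25)
    best <- NULL
    for (b in b_grid) {
      xb <- x^b
      if (two_term) {
        co <- tryCatch(stats::lm.fit(cbind(xb, 1), y)$coefficients,
                       error = function(e) NULL)
        if (is.null(co) || any(!is.finite(co))) next
        start <- list(a = co[[1]], b = b, c = co[[2]])
        form <- y ~ a * x^b + c
      } else {
        a <- sum(y * xb) / sum(xb^2)
        if (!is.finite(a)) next
        start <- list(a = a, b = b)
        form <- y ~ a * x^b
      }
      fit <- tryCatch(
        minpack.lm::nlsLM(form, data = data.frame(x = x, y = y),
                          start = start,
                          control = minpack.lm::nls.lm.control(
                            maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
        error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss)
        best <- list(fit = fit, rss = rss)
    }
    if (is.null(best))
      stop("power fit failed to converge from every start", call. = FALSE)
    co <- stats::coef(best$fit)
    pred <- function(xnew) {
      xnew <- as.numeric(xnew)
      if (two_term) co[["a"]] * xnew^co[["b"]] + co[["c"]]
      else co[["a"]] * xnew^co[["b"]]
    }
    return(list(coefficients = co, predict = pred))
  }
  # ternary power law a * x1^b1 * x2^b2 * x3^b3, log-linear start
  X <- as.matrix(x)
  if (ncol(X) != 3 || any(X <= 0))
    stop("ternary power law requires 3 strictly positive features",
         call. = FALSE)
  ypos <- pmax(y, 1e-8)
  lin <- stats::lm.fit(cbind(1, log(X)), log(ypos))$coefficients
  start <- list(a = exp(lin[[1]]), b1 = lin[[2]], b2 = lin[[3]],
                b3 = lin[[4]])
  df <- data.frame(x1 = X[, 1], x2 = X[, 2], x3 = X[, 3], y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * x1^b1 * x2^b2 * x3^b3, data = df,
                      start = start,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
    error = function(e)
      stop("ternary power fit failed to converge", call. = FALSE))
  co <- stats::coef(fit)
  pred <- function(xnew) {
    Xn <- as.matrix(xnew)
    co[["a"]] * Xn[, 1]^co[["b1"]] * Xn[, 2]^co[["b2"]] * Xn[, 3]^co[["b3"]]
  }
  list(coefficients = co, predict = pred)
}

#' Fit one growth-response model
#'
#' Polynomial families are solved by linear least squares on the
#' [build_design()] basis; power families by multi-start
#' Levenberg-Marquardt nonlinear least squares (the amplitude is
#' profiled out over a log-spaced exponent grid, so the starts cover
#' exponents in \[-3, 3\]). Training metrics follow the
#' construction-table conventions of [evaluate_fit()].
#'
#' @param x feature vector (univariate) or 3-column matrix (ternary).
#' @param y response (NDVI), same length.
#' @param spec a [model_spec()].
#' @return object of class `"model_fit"` with elements `spec`,
#'   `coefficients`, `p`, `n`, `metrics` (training), and a `predict`
#'   closure.
#' @export
fit_model <- function(x, y, spec) {
  stopifnot(inherits(spec, "model_spec"))
  n <- length(y)
  if (n <= spec$p + 1)
    stop("need n > p + 1 observations (n = ", n, ", p = ", spec$p, ")",
         call. = FALSE)
  if (spec$family %in% c("power1", "power2")) {
    pw <- fit_power(x, y, spec)
    coefficients <- pw$coefficients
    predict_fn <- pw$predict
  } else {
    X <- build_design(x, spec)
    qr_fit <- stats::lm.fit(X, y)
    coefficients <- qr_fit$coefficients
    # aliased columns (rank-deficient basis, e.g. collinear cumulative
    # features in a ternary fit) drop out of the pivoted solve
    coefficients[is.na(coefficients)] <- 0
    predict_fn <- local({
      beta <- coefficients; sp <- spec
      function(xnew) drop(build_design(xnew, sp) %*% beta)
    })
  }
  yhat <- predict_fn(x)
  structure(list(spec = spec, coefficients = coefficients, p = spec$p,
                 n = n, metrics = evaluate_fit(y, yhat, n, spec$p),
                 predict = predict_fn),
            class = "model_fit")
}

#' @export
predict.model_fit <- function(object, newdata, ...) object$predict(newdata)

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> %s (%s, %s), n = %d, p = %d\n",
              x$spec$label, x$spec$family, x$spec$arity, x$n, x$p))
  cat("  coefficients:", signif(unlist(x$coefficients), 6), "\n")
  m <- x$metrics
  cat(sprintf("  SSE %.4f  RMSE %.4f  R2 %.4f  AR %.4f\n",
              m$sse, m$rmse, m$r2, m$ar))
  invisible(x)
}

#' Construction-split (training) metrics
#'
#' The degrees-of-freedom conventions that reproduce the construction
#' tables: `SSE = sum((y - yhat)^2)`, `RMSE = sqrt(SSE / (n - p - 1))`
#' (a residual standard error), `R2 = 1 - SSE / SST`, and
#' `AR = 1 - (1 - R2) (n - 1) / (n - p - 1)`. The plain root mean
#' square `sqrt(SSE / n)` is also reported as `rmse_plain`.
#'
#' @param y,yhat observed and predicted values.
#' @param n sample size (defaults to `length(y)`).
#' @param p feature count of the fitted model.
#' @return one-row `data.frame` with `sse`, `rmse`, `rmse_plain`, `r2`,
#'   `ar`.
#' @export
evaluate_fit <- function(y, yhat, n = length(y), p) {
  if (n <= p + 1) stop("need n > p + 1", call. = FALSE)
  sse <- sum((y - yhat)^2)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("R2 undefined: zero total sum of squares", call. = FALSE)
  r2 <- 1 - sse / sst
  data.frame(sse = sse, rmse = sqrt(sse / (n - p - 1)),
             rmse_plain = sqrt(sse / n), r2 = r2,
             ar = 1 - (1 - r2) * (n - 1) / (n - p - 1))
}

#' Validation-split metrics
#'
#' The held-out convention: `MSE = SSE / n`, `RMSE = sqrt(MSE)`, with R2
#' and adjusted R2 computed at the validation sample size. When the
#' feature count reaches the validation sample size (`n <= p + 1`, as
#' for a ternary cubic validated on 12 epochs) the adjusted R2 has no
#' degrees of freedom and is returned as `NA` with a warning.
#'
#' @inheritParams evaluate_fit
#' @return one-row `data.frame` with `mse`, `rmse`, `r2`, `ar`.
#' @export
evaluate_validation <- function(y, yhat, n = length(y), p) {
  sse <- sum((y - yhat)^2)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("R2 undefined: zero total sum of squares", call. = FALSE)
  r2 <- 1 - sse / sst
  mse <- sse / n
  ar <- if (n > p + 1) 1 - (1 - r2) * (n - 1) / (n - p - 1) else {
    warning("adjusted R2 undefined for n <= p + 1 (n = ", n, ", p = ", p,
            "); returning NA")
    NA_real_
  }
  data.frame(mse = mse, rmse = sqrt(mse), r2 = r2, ar = ar)
}

#' Chronological construction/validation split
#'
#' No shuffling: the first `n_train` epochs form the construction set,
#' the remainder the validation set.
#'
#' @param n total number of epochs (or a data frame, whose row count is
#'   used).
#' @param n_train construction sample size; default 60.
#' @return list with integer vectors `train` and `validation`.
#' @export
train_val_split <- function(n, n_train = 60) {
  if (is.data.frame(n)) n <- nrow(n)
  if (n_train < 1 || n_train >= n)
    stop("`n_train` must satisfy 1 <= n_train < n", call. = FALSE)
  list(train = seq_len(n_train), validation = seq(n_train + 1, n))
}

#' Fit the full feature-by-family model grid
#'
#' Fits every combination of feature set and model family on the
#' construction split and evaluates both splits, emitting one row per
#' model in the construction-table layout plus the validation metrics.
#'
#' @param table an `epoch_table` (or any data frame with the feature
#'   columns and the response).
#' @param features named list of feature sets; each element is one
#'   column name (univariate) or three (ternary). Default: the six
#'   univariate soil features plus the two ternary fusions `imp`
#'   (instantaneous) and `simp` (cumulative).
#' @param families families to fit per feature set; power2 is dropped
#'   automatically for ternary sets.
#' @param response response column; default `"ndvi_filtered"`.
#' @param n_train construction sample size; default 60.
#' @return `data.frame` with one row per (feature set, family):
#'   construction `sse`, `rmse`, `r2`, `ar` and validation `val_mse`,
#'   `val_rmse`, `val_r2`, `val_ar`.
#' @export
run_model_grid <- function(table,
                           features = list(
                             st = "st", smc = "smc", sec = "sec",
                             sst = "sst", ssmc = "ssmc", ssec = "ssec",
                             imp = c("st", "smc", "sec"),
                             simp = c("sst", "ssmc", "ssec")),
                           families = c("Y1", "Y2", "Y3", "Y4", "Y5"),
                           response = "ndvi_filtered",
                           n_train = 60) {
  split <- train_val_split(nrow(table), n_train)
  y <- table[[response]]
  rows <- list()
  for (item in names(features)) {
    cols <- features[[item]]
    arity <- if (length(cols) == 3) "ternary" else "univariate"
    fams <- if (arity == "ternary") setdiff(families, "Y5") else families
    xfull <- if (arity == "ternary") as.matrix(table[cols])
             else table[[cols]]
    for (fam in fams) {
      spec <- model_spec(fam, arity)
      xtr <- if (arity == "ternary") xfull[split$train, , drop = FALSE]
             else xfull[split$train]
      xva <- if (arity == "ternary") xfull[split$validation, , drop = FALSE]
             else xfull[split$validation]
      fit <- fit_model(xtr, y[split$train], spec)
      val <- evaluate_validation(y[split$validation], fit$predict(xva),
                                 p = spec$p)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(item = item, model = spec$label, arity = arity,
                   p = spec$p),
        fit$metrics[c("sse", "rmse", "r2", "ar")],
        stats::setNames(val, paste0("val_", names(val))))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
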