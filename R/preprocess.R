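#' Savitzky-Golay convolution weights
#'
#' Least-squares polynomial smoothing expressed as a fixed convolution:
#' the value returned for the window center is the degree-`order`
#' polynomial fit evaluated there, so the weights reproduce any
#' polynomial up to that degree exactly.
#'
#' @param window odd window length (2n + 1).
#' @param order polynomial order, `< window`.
#' @return numeric weight vector of length `window`.
#' @export
sg_weights <- function(window, order) {
  if (window %% 2 != 1 || window < 1)
    stop("`window` must be an odd positive integer", call. = FALSE)
  if (order < 0 || order >= window)
    stop("`order` must satisfy 0 <= order < window", call. = FALSE)
  half <- (window - 1) / 2
  X <- outer(seq(-half, half), 0:order, `^`)
  # fitted value at x = 0 is the intercept of the local fit
  drop(solve(crossprod(X), t(X))[1, ])
}

#' Savitzky-Golay filter with optional upper-envelope selection
#'
#' Smooths a series by local polynomial least squares (window `window`,
#' degree `order`) expressed as a convolution; edges are handled by
#' mirror padding about the end points, which preserves constants and
#' linear trends at the boundary. With `envelope = TRUE` every filtered
#' value is replaced by the pointwise maximum of the filtered and
#' original value ("maximum-value selection"), an upper-envelope
#' reconstruction that rejects cloud-induced negative drops in NDVI
#' while never lowering clean observations.
#'
#' @param x numeric series, or an `ndvi_series` / data frame with an
#'   `ndvi` column (filtered values are then added as `ndvi_filtered`).
#' @param window odd window length; default 5.
#' @param order polynomial order; default 2.
#' @param envelope apply maximum-value selection after filtering.
#' @return same shape as the input: a numeric vector, or the data frame
#'   with an `ndvi_filtered` column.
#' @export
sg_filter <- function(x, window = 5, order = 2, envelope = FALSE) {
  if (is.data.frame(x)) {
    if (!"ndvi" %in% names(x)) stop("data frame needs an `ndvi` column")
    x$ndvi_filtered <- sg_filter(x$ndvi, window, order, envelope)
    return(x)
  }
  w <- sg_weights(window, order)
  n <- length(x)
  if (n < window)
    stop("series length (", n, ") shorter than window (", window, ")",
         call. = FALSE)
  half <- (window - 1) / 2
  # mirror padding about the edge points (edge value not duplicated)
  padded <- c(x[(half + 1):2], x, x[(n - 1):(n - half)])
  out <- vapply(seq_len(n), function(i)
    sum(w * padded[i:(i + window - 1)]), numeric(1))
  if (envelope) out <- pmax(out, x)
  out
}

#' Min-max scale a sequence to [0, 1]
#'
#' The scaling parameters are attached as attributes so the transform
#' can be inverted with [minmax_invert()] or reapplied to new data with
#' `minmax_apply()`.
#'
#' @param x numeric vector with `max(x) > min(x)`.
#' @return scaled vector with attributes `scale_min`, `scale_range`.
#' @export
minmax_scale <- function(x) {
  rng <- range(x)
  if (!all(is.finite(rng)) || rng[1] == rng[2])
    stop("cannot min-max scale a constant or non-finite sequence",
         call. = FALSE)
  structure((x - rng[1]) / (rng[2] - rng[1]),
            scale_min = rng[1], scale_range = rng[2] - rng[1])
}

#' @rdname minmax_scale
#' @param scaled output of [minmax_scale()] (or any vector carrying the
#'   scaling attributes).
#' @export
minmax_invert <- function(scaled) {
  mn <- attr(scaled, "scale_min")
  rg <- attr(scaled, "scale_range")
  if (is.null(mn) || is.null(rg))
    stop("input carries no scaling attributes", call. = FALSE)
  as.numeric(scaled) * rg + mn
}

#' @rdname minmax_scale
#' @param reference a scaled vector whose parameters should be reused.
#' @export
minmax_apply <- function(x, reference) {
  mn <- attr(reference, "scale_min")
  rg <- attr(reference, "scale_range")
  if (is.null(mn) || is.null(rg))
    stop("`reference` carries no scaling attributes", call. = FALSE)
  structure((x - mn) / rg, scale_min = mn, scale_range = rg)
}

#' Mean soil state over the window preceding each epoch
#'
#' For each epoch date the ST/SMC/SEC readings falling in the half-open
#' calendar window `[epoch - window_days, epoch)` are averaged, aligning
#' the sensor stream with the satellite revisit schedule.
#'
#' @param soil a `soil_series`.
#' @param dates epoch dates (`Date`).
#' @param window_days window length in days; default 5.
#' @return `data.frame` with columns `date`, `st`, `smc`, `sec`.
#' @export
aggregate_to_epochs <- function(soil, dates, window_days = 5) {
  stopifnot(window_days > 0)
  day <- as.Date(soil$timestamp)
  rows <- lapply(dates, function(ep) {
    sel <- day >= ep - window_days & day < ep
    if (!any(sel))
      stop("no soil readings in the window preceding epoch ",
           format(ep), call. = FALSE)
    c(st = mean(soil$st[sel]), smc = mean(soil$smc[sel]),
      sec = mean(soil$sec[sel]))
  })
  out <- as.data.frame(do.call(rbind, rows))
  cbind(date = as.Date(dates), out)
}

#' Calendar-day means of a soil series
#'
#' @param soil a `soil_series`.
#' @return `data.frame` with columns `day` (Date), `st`, `smc`, `sec`.
#' @export
daily_means <- function(soil) {
  day <- as.Date(soil$timestamp)
  agg <- stats::aggregate(soil[c("st", "smc", "sec")],
                          by = list(day = day), FUN = mean)
  agg[order(agg$day), , drop = FALSE]
}

#' Cumulative (thermal-time style) soil exposure features
#'
#' Running sums of the daily ST/SMC/SEC means, counting only days whose
#' value exceeds zero (a day at or below zero contributes nothing),
#' accumulated from the season start and read off at each epoch date --
#' the soil analogue of growing degree days. SMC and SEC are nonnegative
#' by instrument range, so the threshold effectively acts on ST alone.
#'
#' @param daily output of [daily_means()] (columns `day`, `st`, `smc`,
#'   `sec`), covering the season start through the last epoch.
#' @param dates epoch dates at which to evaluate the running sums.
#' @param season_start first day of accumulation; defaults to the first
#'   day of the daily table.
#' @return `data.frame` with columns `date`, `sst`, `ssmc`, `ssec`.
#' @export
cumulative_features <- function(daily, dates, season_start = min(daily$day)) {
  dates <- as.Date(dates)
  if (any(dates < season_start))
    stop("epoch date precedes the season start", call. = FALSE)
  d <- daily[daily$day >= season_start, , drop = FALSE]
  d <- d[order(d$day), , drop = FALSE]
  run <- function(v) cumsum(ifelse(v > 0, v, 0))
  sums <- data.frame(sst = run(d$st), ssmc = run(d$smc), ssec = run(d$sec))
  # value at an epoch = last accumulated day <= epoch (0 if none)
  idx <- findInterval(dates, d$day)
  at <- function(col) ifelse(idx == 0, 0, col[pmax(idx, 1)])
  data.frame(date = dates, sst = at(sums$sst), ssmc = at(sums$ssmc),
             ssec = at(sums$ssec))
}

#' Pearson correlation matrix over epoch-table columns
#'
#' @param table data frame holding the columns.
#' @param columns character vector of column names; default every
#'   numeric column.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(table, columns = NULL) {
  if (is.null(columns))
    columns <- names(table)[vapply(table, is.numeric, logical(1))]
  m <- as.matrix(table[columns])
  if (nrow(m) < 3) stop("need at least 3 complete rows", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column(s): ",
         paste(columns[sds == 0], collapse = ", "), call. = FALSE)
  cm <- stats::cor(m)
  diag(cm) <- 1
  cm
}

#' Build the per-epoch feature table
#'
#' Runs the full preprocessing chain: NDVI upper-envelope reconstruction,
#' soil aggregation to epoch windows, daily means, and cumulative
#' exposure features, joined on the epoch dates.
#'
#' @param soil a `soil_series`.
#' @param ndvi an `ndvi_series` (columns `date`, `ndvi`).
#' @param window_days soil aggregation window, days.
#' @param sg_window,sg_order Savitzky-Golay parameters.
#' @param envelope use maximum-value selection in the reconstruction.
#' @return `data.frame` of class `"epoch_table"` with columns `date`,
#'   `st`, `smc`, `sec`, `sst`, `ssmc`, `ssec`, `ndvi_raw`,
#'   `ndvi_filtered`.
#' @export
build_epoch_table <- function(soil, ndvi, window_days = 5,
                              sg_window = 5, sg_order = 2,
                              envelope = TRUE) {
  dates <- as.Date(ndvi$date)
  inst <- aggregate_to_epochs(soil, dates, window_days)
  cum <- cumulative_features(daily_means(soil), dates)
  filt <- sg_filter(ndvi$ndvi, sg_window, sg_order, envelope)
  structure(
    data.frame(date = dates, st = inst$st, smc = inst$smc, sec = inst$sec,
               sst = cum$sst, ssmc = cum$ssmc, ssec = cum$ssec,
               ndvi_raw = ndvi$ndvi, ndvi_filtered = filt),
    class = c("epoch_table", "data.frame")
  )
}
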