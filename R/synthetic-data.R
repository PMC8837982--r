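#' Simulation configuration for the virtual tea-plantation site
#'
#' Bundles every knob of the synthetic soil-sensor and NDVI generator:
#' the calendar span, the sensor cadence, the satellite revisit schedule,
#' and the observation-noise / cloud-contamination model for NDVI.
#'
#' Defaults emulate a single subtropical growing year monitored at a
#' 10-minute cadence with 72 NDVI epochs on a 5-day revisit, the study
#' conditions the downstream analysis assumes. The five physical sensor
#' nodes of a distributed deployment are collapsed into one virtual site
#' by averaging `n_nodes` independently noisy replicates of the same
#' smooth field signal.
#'
#' @param start_date,end_date calendar span of the simulated year
#'   (`Date` or coercible).
#' @param sensor_interval_minutes sensor logging cadence, minutes.
#' @param epoch_interval_days satellite revisit interval, days.
#' @param n_epochs number of NDVI epochs to generate.
#' @param noise_sd_ndvi standard deviation of Gaussian NDVI observation
#'   noise (NDVI units).
#' @param cloud_drop_prob per-epoch probability of a cloud-induced
#'   negative NDVI shock.
#' @param cloud_drop_depth depth of a cloud shock (NDVI units),
#'   subtracted from the affected epoch before clipping.
#' @param noise_sd_st,noise_sd_smc,noise_sd_sec per-node sensor noise
#'   standard deviations (degC, %, uS/cm).
#' @param n_nodes number of sensor replicates averaged into the site
#'   series.
#' @param seed integer seed; fixed seeds give bit-identical output.
#' @return object of class `"sim_config"` (a validated list).
#' @export
sim_config <- function(start_date = "2020-01-01",
                       end_date = "2020-12-31",
                       sensor_interval_minutes = 10,
                       epoch_interval_days = 5L,
                       n_epochs = 72L,
                       noise_sd_ndvi = 0.02,
                       cloud_drop_prob = 0.10,
                       cloud_drop_depth = 0.25,
                       noise_sd_st = 0.3,
                       noise_sd_smc = 0.6,
                       noise_sd_sec = 6,
                       n_nodes = 5L,
                       seed = 1L) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (is.na(start_date) || is.na(end_date) || end_date <= start_date)
    stop("`start_date` must precede `end_date`", call. = FALSE)
  if (sensor_interval_minutes <= 0)
    stop("`sensor_interval_minutes` must be positive", call. = FALSE)
  epoch_interval_days <- as.integer(epoch_interval_days)
  n_epochs <- as.integer(n_epochs)
  if (epoch_interval_days < 1L || n_epochs < 1L)
    stop("epoch settings must be positive integers", call. = FALSE)
  span_days <- as.numeric(end_date - start_date) + 1
  if (n_epochs * epoch_interval_days > span_days)
    stop("date range too short: ", n_epochs, " epochs at ",
         epoch_interval_days, "-day spacing need ",
         n_epochs * epoch_interval_days, " days but the range spans ",
         span_days, call. = FALSE)
  if (noise_sd_ndvi < 0 || noise_sd_st < 0 || noise_sd_smc < 0 ||
      noise_sd_sec < 0)
    stop("noise standard deviations must be nonnegative", call. = FALSE)
  if (cloud_drop_prob < 0 || cloud_drop_prob > 1)
    stop("`cloud_drop_prob` must lie in [0, 1]", call. = FALSE)
  if (cloud_drop_depth < 0)
    stop("`cloud_drop_depth` must be nonnegative", call. = FALSE)
  if (n_nodes < 1L) stop("`n_nodes` must be >= 1", call. = FALSE)
  structure(list(
    start_date = start_date, end_date = end_date,
    sensor_interval_minutes = sensor_interval_minutes,
    epoch_interval_days = epoch_interval_days, n_epochs = n_epochs,
    noise_sd_ndvi = noise_sd_ndvi, cloud_drop_prob = cloud_drop_prob,
    cloud_drop_depth = cloud_drop_depth,
    noise_sd_st = noise_sd_st, noise_sd_smc = noise_sd_smc,
    noise_sd_sec = noise_sd_sec,
    n_nodes = as.integer(n_nodes), seed = as.integer(seed)
  ), class = "sim_config")
}

#' Epoch (satellite revisit) dates implied by a simulation configuration
#'
#' Epoch k falls on the last day of the k-th revisit interval, so the
#' aggregation window `[epoch - window, epoch)` covers the preceding
#' days of that interval.
#'
#' @param config a [sim_config()].
#' @return vector of `Date`s, length `config$n_epochs`.
#' @export
epoch_dates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  config$start_date + config$epoch_interval_days * seq_len(config$n_epochs) - 1
}

#' Ground-truth NDVI response parameters
#'
#' The generator drives NDVI through a cubic response to one cumulative
#' soil feature (growing-degree-day style), the same functional family the
#' downstream regression assumes, so correctly-specified fits must recover
#' these coefficients. Each response is a cubic in the feature normalized
#' to its annual [0, 1] range: `ndvi = c0 + c1*u + c2*u^2 + c3*u^3`.
#'
#' The default cubic rises slowly out of winter, fastest through the warm
#' season, and dips slightly once heat accumulation saturates (canopy
#' stress at the top of the range), staying inside [-1, 1] throughout.
#' All four coefficients are nonzero so relative recovery error is well
#' defined for every term.
#'
#' @param sst,ssmc,ssec length-4 cubic coefficient vectors (intercept
#'   first) for the response to each normalized cumulative feature.
#' @param ternary length-4 cubic applied to a weighted blend of the three
#'   normalized cumulative features.
#' @param ternary_weights nonnegative blend weights, summing to 1.
#' @param driver which response generates NDVI: one of `"sst"`, `"ssmc"`,
#'   `"ssec"`, `"ternary"`.
#' @return object of class `"truth_params"`.
#' @export
truth_params <- function(sst = c(0.10, 0.25, 1.60, -1.20),
                         ssmc = c(0.12, 0.20, 1.50, -1.10),
                         ssec = c(0.11, 0.22, 1.55, -1.15),
                         ternary = c(0.10, 0.25, 1.60, -1.20),
                         ternary_weights = c(0.5, 0.25, 0.25),
                         driver = c("sst", "ssmc", "ssec", "ternary")) {
  driver <- match.arg(driver)
  for (v in list(sst, ssmc, ssec, ternary))
    if (length(v) != 4 || !all(is.finite(v)))
      stop("each response needs 4 finite cubic coefficients", call. = FALSE)
  if (length(ternary_weights) != 3 || any(ternary_weights < 0))
    stop("`ternary_weights` must be 3 nonnegative reals", call. = FALSE)
  ternary_weights <- ternary_weights / sum(ternary_weights)
  # responses must stay within the physical NDVI range over u in [0, 1]
  u <- seq(0, 1, by = 0.01)
  for (v in list(sst, ssmc, ssec, ternary)) {
    r <- cubic_response(u, v)
    if (any(r < -1) || any(r > 1))
      stop("truth response leaves [-1, 1] over the unit feature range",
           call. = FALSE)
  }
  structure(list(sst = sst, ssmc = ssmc, ssec = ssec, ternary = ternary,
                 ternary_weights = ternary_weights, driver = driver),
            class = "truth_params")
}

#' Evaluate a cubic response
#'
#' @param u numeric input (typically a feature normalized to [0, 1]).
#' @param coef length-4 coefficient vector, intercept first.
#' @return numeric vector of responses.
#' @export
cubic_response <- function(u, coef) {
  stopifnot(length(coef) == 4)
  coef[1] + coef[2] * u + coef[3] * u^2 + coef[4] * u^3
}

# Smooth seasonal + diurnal field signals at fractional day-of-study d
# (days since start) and hour-of-day h. Phases put the ST minimum in
# mid-January (~13 degC, a subtropical winter) and the maximum in
# mid-July (~28 degC); moisture and conductivity run in anti-phase with
# temperature (winter-wet / summer-dry seasonality with monsoon
# shortfall in the hot months).
soil_signal <- function(d, h) {
  ann <- cos(2 * pi * (d - 14) / 365.25)
  list(
    st = 20.5 - 7.5 * ann + 1.2 * sin(2 * pi * (h - 9) / 24),
    smc = 24 + 6 * ann + 0.3 * sin(2 * pi * (h - 3) / 24),
    sec = 110 + 50 * ann + 2.0 * sin(2 * pi * (h - 3) / 24)
  )
}

#' Simulate one year of soil-sensor readings
#'
#' Generates timestamped soil temperature (ST, degC), volumetric soil
#' moisture content (SMC, %) and soil electrical conductivity
#' (SEC, uS/cm) at the configured cadence: a smooth annual seasonal cycle
#' plus a diurnal ripple, with independent Gaussian sensor noise per
#' virtual node, averaged across nodes. Readings are clipped to the
#' instrument ranges ST in [-40, 80] degC, SMC in [0, 100] %, SEC in
#' [0, 5000] uS/cm.
#'
#' @param config a [sim_config()].
#' @return `data.frame` of class `"soil_series"` with columns
#'   `timestamp` (POSIXct, UTC), `st`, `smc`, `sec`, in chronological
#'   order.
#' @export
simulate_soil_series <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  t0 <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste(config$end_date, "23:59:59"), tz = "UTC")
  times <- seq(t0, t1, by = config$sensor_interval_minutes * 60)
  d <- as.numeric(difftime(times, t0, units = "days"))
  h <- (d %% 1) * 24
  sig <- soil_signal(d, h)
  n <- length(times)
  set.seed(config$seed)
  avg_noise <- function(sd) {
    if (sd == 0) return(rep(0, n))
    rowMeans(matrix(stats::rnorm(n * config$n_nodes, sd = sd),
                    nrow = n, ncol = config$n_nodes))
  }
  st <- pmin(pmax(sig$st + avg_noise(config$noise_sd_st), -40), 80)
  smc <- pmin(pmax(sig$smc + avg_noise(config$noise_sd_smc), 0), 100)
  sec <- pmin(pmax(sig$sec + avg_noise(config$noise_sd_sec), 0), 5000)
  structure(
    data.frame(timestamp = times, st = st, smc = smc, sec = sec),
    class = c("soil_series", "data.frame")
  )
}

#' Simulate the per-epoch NDVI series from a soil series
#'
#' Inverts the modelling assumption of the analysis: true NDVI at each
#' epoch is a cubic response to the driving cumulative soil feature
#' (normalized to its annual range), to which Gaussian observation noise
#' and sporadic cloud-induced negative shocks are added. Cloud
#' contamination is modelled as additive drops, not missing values,
#' because optical-sensor distortion depresses the index rather than
#' deleting the epoch. Values are clipped to [-1, 1].
#'
#' @param soil a `soil_series` covering all epoch dates.
#' @param truth a [truth_params()].
#' @param config the [sim_config()] used to generate `soil`.
#' @return `data.frame` of class `"ndvi_series"` with columns `date`,
#'   `ndvi` (observed) and `ndvi_true` (noiseless, unclipped response).
#' @export
simulate_ndvi_series <- function(soil, truth, config) {
  stopifnot(inherits(soil, "soil_series"), inherits(truth, "truth_params"),
            inherits(config, "sim_config"))
  dates <- epoch_dates(config)
  if (as.Date(max(soil$timestamp)) < max(dates))
    stop("soil series does not cover the last epoch date", call. = FALSE)
  daily <- daily_means(soil)
  cum <- cumulative_features(daily, dates)
  unit <- function(v) {
    if (max(v) == min(v)) stop("degenerate cumulative feature", call. = FALSE)
    (v - min(v)) / (max(v) - min(v))
  }
  u <- switch(truth$driver,
    sst = cubic_response(unit(cum$sst), truth$sst),
    ssmc = cubic_response(unit(cum$ssmc), truth$ssmc),
    ssec = cubic_response(unit(cum$ssec), truth$ssec),
    ternary = cubic_response(
      truth$ternary_weights[1] * unit(cum$sst) +
        truth$ternary_weights[2] * unit(cum$ssmc) +
        truth$ternary_weights[3] * unit(cum$ssec),
      truth$ternary)
  )
  if (any(u > 1 + 1e-6) || any(u < -1 - 1e-6))
    warning("truth response leaves [-1, 1] before clipping")
  # independent noise stream from the soil-sensor stream
  set.seed(config$seed + 104729L)
  ndvi <- u + stats::rnorm(length(u), sd = config$noise_sd_ndvi)
  dropped <- stats::runif(length(u)) < config$cloud_drop_prob
  ndvi[dropped] <- ndvi[dropped] - config$cloud_drop_depth
  structure(
    data.frame(date = dates, ndvi = pmin(pmax(ndvi, -1), 1), ndvi_true = u),
    class = c("ndvi_series", "data.frame")
  )
}

#' Normalized Difference Vegetation Index from band reflectances
#'
#' `NDVI = (IR - R) / (IR + R)` for infrared and red band values; lies in
#' (-1, 1) for positive bands.
#'
#' @param ir,red nonnegative band values (vectorized).
#' @return numeric NDVI.
#' @export
compute_ndvi <- function(ir, red) {
  if (any(ir < 0) || any(red < 0))
    stop("band values must be nonnegative", call. = FALSE)
  if (any(ir + red == 0))
    stop("NDVI undefined where ir + red = 0", call. = FALSE)
  (ir - red) / (ir + red)
}

#' Write a soil series in the field-log CSV layout
#'
#' Columns `no, st_c, smc_pct, sec_us_cm, timestamp` (ISO 8601), matching
#' the layout of raw logger exports.
#'
#' @param soil a `soil_series`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_soil_csv <- function(soil, path) {
  out <- data.frame(
    no = seq_len(nrow(soil)),
    st_c = soil$st, smc_pct = soil$smc, sec_us_cm = soil$sec,
    timestamp = format(soil$timestamp, "%Y-%m-%dT%H:%M:%S")
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an NDVI series as CSV
#'
#' @param ndvi an `ndvi_series`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ndvi_csv <- function(ndvi, path) {
  utils::write.csv(data.frame(date = ndvi$date, ndvi = ndvi$ndvi),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
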