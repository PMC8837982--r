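# Shared fixtures, generated once per test run and cached.
.tg_cache <- new.env(parent = emptyenv())

# Default-condition simulated year (soil + NDVI + epoch table).
tg_default_run <- function() {
  if (is.null(.tg_cache$default)) {
    cfg <- sim_config(seed = 7)
    soil <- simulate_soil_series(cfg)
    truth <- truth_params()
    ndvi <- simulate_ndvi_series(soil, truth, cfg)
    .tg_cache$default <- list(cfg = cfg, soil = soil, truth = truth,
                              ndvi = ndvi,
                              table = build_epoch_table(soil, ndvi))
  }
  .tg_cache$default
}

# Low-noise, cloud-free year for parameter-recovery checks.
tg_clean_run <- function() {
  if (is.null(.tg_cache$clean)) {
    cfg <- sim_config(seed = 11, noise_sd_ndvi = 1e-4, cloud_drop_prob = 0)
    soil <- simulate_soil_series(cfg)
    truth <- truth_params()
    ndvi <- simulate_ndvi_series(soil, truth, cfg)
    .tg_cache$clean <- list(cfg = cfg, soil = soil, truth = truth,
                            ndvi = ndvi,
                            table = build_epoch_table(soil, ndvi,
                                                      envelope = FALSE))
  }
  .tg_cache$clean
}

# A tiny synthetic soil series: one reading per `per_day` hours over
# `days` days, with user-supplied generator functions of fractional day.
tg_toy_soil <- function(days, per_day = 4,
                        st = function(d) 15 + 0 * d,
                        smc = function(d) 20 + 0 * d,
                        sec = function(d) 100 + 0 * d,
                        start = as.Date("2020-01-01")) {
  t0 <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
  times <- t0 + seq(0, days * 86400 - 1, by = 86400 / per_day)
  d <- as.numeric(difftime(times, t0, units = "days"))
  structure(data.frame(timestamp = times, st = st(d), smc = smc(d),
                       sec = sec(d)),
            class = c("soil_series", "data.frame"))
}

# Per-window least-squares Savitzky-Golay oracle with mirror padding:
# fits a degree-`order` polynomial to each centered window by lm() and
# evaluates it at the center. Independent of the convolution path.
tg_sg_oracle <- function(x, window, order) {
  half <- (window - 1) / 2
  n <- length(x)
  padded <- c(x[(half + 1):2], x, x[(n - 1):(n - half)])
  vapply(seq_len(n), function(i) {
    yw <- padded[i:(i + window - 1)]
    tw <- seq(-half, half)
    unname(stats::coef(stats::lm(yw ~ poly(tw, order, raw = TRUE)))[1])
  }, numeric(1))
}
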