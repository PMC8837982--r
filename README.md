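# teagrowth

Soil-driven growth monitoring for perennial crops (tea plantations in
particular): an analysis pipeline linking in-situ soil sensing to
satellite NDVI, for agronomists and crop-modelling researchers who want
to test whether *accumulated* soil state explains canopy development
better than instantaneous state.

## What it computes

* **NDVI reconstruction.** NDVI = (IR − R)/(IR + R) observed every 5
  days is contaminated by cloud-induced drops. A Savitzky–Golay filter
  (window 5, order 2, mirror-padded) combined with maximum-value
  selection — `max(filtered, original)` pointwise — gives an
  upper-envelope reconstruction that rejects negative shocks without
  lowering clean observations.
* **Epoch features.** 10-minute soil temperature / moisture /
  conductivity (ST/SMC/SEC) logs are averaged over the five days
  preceding each revisit epoch; running sums of above-zero daily means
  give cumulative exposure features SST/SSMC/SSEC, the soil analogue of
  growing degree days.
* **Growth-response families.** Five families fitted per feature and for
  ternary feature fusion: polynomials of degree 1–3 (Y1–Y3) and power
  laws a·x^b (Y4) and a·x^b + c (Y5), under a chronological 60/12
  construction/validation split, with the matching degrees-of-freedom
  metric conventions (construction RMSE = √(SSE/(n−p−1)),
  AR = 1 − (1−R²)(n−1)/(n−p−1); validation RMSE = √(SSE/n)).
* **BES–LSTM.** A from-scratch Bald Eagle Search metaheuristic
  (select / search / swoop phases with greedy acceptance) tunes the
  learning rate and hidden size of a minimal single-layer LSTM mapping
  soil windows to NDVI, against a default-configuration baseline.
* **Synthetic data.** A generator produces one monitored year with a
  known cubic NDVI response to cumulative soil temperature, so the whole
  chain is testable by parameter recovery.

See `vignettes/tea-growth-monitoring.Rmd` for the models, assumptions
and design choices, and `analysis/01_simulate.R` …
`analysis/05_tune_lstm.R` for the narrated workflow (each writes its
tables under `results/`).

## Worked example

```r
library(teagrowth)

cfg  <- sim_config(seed = 42)                  # one virtual year
soil <- simulate_soil_series(cfg)              # 52,704 sensor readings
ndvi <- simulate_ndvi_series(soil, truth_params(), cfg)
tab  <- build_epoch_table(soil, ndvi)          # 72 epochs, all features

round(cor(tab$ndvi_filtered,
          tab[c("st", "smc", "sec", "sst", "ssmc", "ssec")]), 3)
#>         st    smc    sec   sst  ssmc  ssec
#> [1,] 0.285 -0.285 -0.285 0.979 0.955 0.938
```

Instantaneous features correlate weakly (moisture and conductivity
negatively); cumulative exposure correlates above 0.9 — the signature
that motivates the cumulative models. Fitting the cubic family on
normalized cumulative soil temperature:

```r
u <- as.numeric(minmax_scale(tab$sst))
fit_model(u[1:60], tab$ndvi_filtered[1:60], model_spec("Y3"))
#> <model_fit> Y3 (poly3, univariate), n = 60, p = 3
#>   coefficients: 0.10608 0.139285 1.86951 -1.36536
#>   SSE 0.0967  RMSE 0.0416  R2 0.9690  AR 0.9674
```

The cubic wins the family comparison on the cumulative driver
(R² 0.969 vs 0.954–0.964 for Y1/Y2/Y4/Y5), and at low observation noise
its coefficients recover the generator's ground truth
(0.10, 0.25, 1.60, −1.20) to under 1% relative error — the package's
core end-to-end check.

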