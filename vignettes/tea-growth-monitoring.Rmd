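---
title: "Soil-driven growth monitoring: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soil-driven growth monitoring: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teagrowth)
```

## The monitoring problem

Perennial crops such as tea respond to the *accumulated* soil environment:
canopy vigor, observed from satellites as NDVI
$\mathrm{NDVI} = (IR - R)/(IR + R)$, integrates weeks of soil temperature
(ST, °C), volumetric moisture (SMC, %) and electrical conductivity
(SEC, µS/cm) rather than tracking their instantaneous values. This package
implements a complete analysis chain for one monitored year:

1. reconstruct a cloud-contaminated NDVI series observed at a 5-day
   satellite revisit (72 epochs/year);
2. align a 10-minute soil-sensor stream with those epochs and build
   cumulative exposure features (SST/SSMC/SSEC, the soil analogue of
   growing degree days);
3. fit five growth-response families to NDVI and compare them under a
   chronological construction/validation split;
4. train a minimal LSTM regressor from soil windows to NDVI and tune its
   learning rate and hidden size with a Bald Eagle Search (BES)
   metaheuristic.

Because no field dataset ships with the package, a synthetic-data module
generates the study conditions with *known* ground-truth response
parameters, which is what makes end-to-end recovery testing possible.

## The synthetic year

`simulate_soil_series()` produces a smooth annual cycle plus diurnal
ripple plus Gaussian sensor noise, averaged over five virtual sensor
nodes (a distributed deployment collapsed to one pooled series, which is
how the downstream analysis treats the site). Defaults describe a
subtropical monsoon site: winter soil temperature near 13 °C, summer near
28 °C (annual mean ≈ 20 °C), with moisture and conductivity running in
anti-phase with temperature (winter-wet, summer-dry — seasonal water
shortage in the hot months). The anti-phase choice is deliberate: it
gives the instantaneous features the documented sign structure
(NDVI positively correlated with ST, negatively with SMC and SEC) while
all three cumulative features remain strongly positive. Readings are
clipped to the instrument ranges ST ∈ [−40, 80] °C, SMC ∈ [0, 100] %,
SEC ∈ [0, 5000] µS/cm.

`simulate_ndvi_series()` inverts the modelling assumption: true NDVI at
each epoch is a cubic response to cumulative soil temperature normalized
to its annual range,
$y = c_0 + c_1 u + c_2 u^2 + c_3 u^3$, with default coefficients
$(0.10,\ 0.25,\ 1.60,\ -1.20)$ — slow emergence from winter, fastest gain
mid-season, slight decline once heat accumulation saturates (canopy
stress at the top of the range). All four coefficients are nonzero so
relative recovery error is defined for every term. Observation noise is
Gaussian (default sd 0.02, a free choice: the magnitude of real NDVI
observation noise is site-dependent and not pinned by any published
value we rely on) and cloud contamination is an additive negative shock
(default depth 0.25 with probability 0.10 per epoch) — a *drop*, not a
missing value, because optical distortion depresses the index rather
than deleting the epoch.

What the generator does **not** emulate: winter canopy senescence (the
simulated NDVI never falls back, because its driver is a nondecreasing
cumulative feature), irrigation or rainfall events, sensor dropouts, and
spatial heterogeneity across the plantation. Passing tests therefore
demonstrate internal consistency of the pipeline — filters, features,
fits and tuning behave as specified on data obeying the model's own
assumptions — not predictive skill on real plantations.

## NDVI reconstruction

`sg_filter()` is a Savitzky–Golay filter: a degree-`order` polynomial is
fitted by least squares in each centred window and evaluated at the
centre, which reduces to a fixed convolution (window 5, order 2 by
default). Edges use mirror padding (the reflected interior, edge point
not duplicated), chosen because it preserves constants and linear trends
at the boundary. With `envelope = TRUE` (the default in
`build_epoch_table()`) each smoothed value is replaced by
`max(filtered, original)` — maximum-value selection. A single filter pass
plus pointwise maximum is used rather than an iterated envelope: the
contamination model is one-sided negative shocks, and one pass already
rejects isolated drops while never lowering clean observations.

## Epoch features

Soil readings are averaged over the half-open window
`[epoch − 5 d, epoch)`, i.e. the five days preceding each revisit.
Cumulative features are running sums of **daily means** (not raw
10-minute readings) exceeding zero, accumulated from the first calendar
day of the year; a day at or below zero contributes nothing. The
threshold acts on each variable in its native unit, so in practice it
affects only ST (SMC and SEC are nonnegative by instrument range).
Normalization, where requested, is min–max to [0, 1] and is applied
*after* cumulation — cumulate-then-normalize keeps the accumulated
quantity physically interpretable; the reverse order is available by
scaling the daily table first.

## Growth-response families and metric conventions

The five families are Y1–Y3 (polynomials of degree 1–3), Y4
($a x^b$) and Y5 ($a x^b + c$). Ternary (multiparameter-fusion) fits use
all monomials of total degree ≤ d in the three features; the ternary
power law is $a\,x_1^{b_1} x_2^{b_2} x_3^{b_3}$. Feature counts for the
adjusted-R² penalty: the degree for univariate polynomials, 1 and 2 for
the power families, the number of non-intercept basis terms for ternary
polynomials (9 for quadratic, 19 for cubic), 3 for the ternary power
law.

Two metric conventions coexist and are kept deliberately distinct:

* **Construction split** (`evaluate_fit()`): SSE,
  $\mathrm{RMSE} = \sqrt{\mathrm{SSE}/(n-p-1)}$ (the residual standard
  error reported by curve-fitting toolboxes),
  $R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$, and
  $\bar R^2 = 1 - (1-R^2)(n-1)/(n-p-1)$. The plain
  $\sqrt{\mathrm{SSE}/n}$ is also reported as `rmse_plain`.
* **Validation split** (`evaluate_validation()`):
  $\mathrm{MSE} = \mathrm{SSE}/n$ and
  $\mathrm{RMSE} = \sqrt{\mathrm{MSE}}$. When the feature count reaches
  the validation sample size (a ternary cubic validated on 12 epochs),
  adjusted R² has no degrees of freedom left and is reported as `NA`.

Polynomial fits are pivoted linear least squares; aliased columns (the
three cumulative features are strongly collinear, so high-order ternary
bases are rank-deficient) get zero coefficients, the standard dropped-
column convention. Power fits are multi-start Levenberg–Marquardt: the
exponent is swept over 25 points in [−3, 3], the amplitude (and offset)
profiled out linearly at each start, and the best start refined with
tolerances of 1e−12; features containing zeros need the caller to apply
a small positive shift, as power laws are undefined at 0.

The split is chronological (first 60 epochs fit, last 12 validate), so
validation is an *extrapolation* test: the late-season feature values lie
outside the fitted range and validation R² can be strongly negative even
for the correct family. The analysis scripts print this rather than hide
it.

## Bald Eagle Search

Three phases per iteration, in select → search → swoop order:

* select: $P_{best} + \alpha\,\gamma\,(P_{mean} - P_i)$, fresh
  $\gamma \sim U(0,1)$ per individual;
* search: $P_i + x_i(P_i - P_{mean}) + y_i(P_i - P_{i+1})$ with polar
  spiral coordinates $\theta_i = a\pi\,\mathrm{rand}$,
  $r_i = \theta_i + R\,\mathrm{rand}$, $x, y$ the sin/cos components
  max-normalized over the population; the neighbour index wraps
  circularly;
* swoop: $\mathrm{rand}\,P_{best} + x1_i(P_i - c_1 P_{mean}) +
  y1_i(P_i - c_2 P_{best})$ with hyperbolic (sinh/cosh) coordinates and
  $r_i = \theta_i$ — the swoop radius deliberately omits the
  $R\,\mathrm{rand}$ term, matching the phase's own definition.

Candidates are clipped to the box bounds and accepted **greedily**
(only on improvement), which guarantees a monotone nonincreasing
best-fitness history — an invariant the tests assert on every run. The
population mean is recomputed after every accepted move. Defaults
(population 30, 100 iterations, $\alpha = 2$, $a = 10$, $R = 1.5$,
$c_1 = c_2 = 2$) sit at the conventional ends of the documented
parameter ranges. Non-finite objective values reject the candidate
rather than aborting the run.

## The LSTM and its tuning

One cell, hidden size $H$: candidate $z = \tanh(W[x_t, h_{t-1}])$, gates
$z_i, z_f, z_o = \sigma(W_{\{i,f,o\}}[x_t, h_{t-1}])$, state updates
$c_t = z_f \odot c_{t-1} + z_i \odot z$, $h_t = z_o \odot \tanh c_t$,
and a sigmoid output $y = \sigma(w' h_L + b)$. The sigmoid output is
kept (rather than the identity map usual for regression) and targets are
min–max normalized into (0, 1) to match. "Network size" is the number of
hidden units of this single layer. Training is full-batch
backpropagation through time with Adam (β₁ = 0.9, β₂ = 0.999), uniform
±0.1 initialization, default 500 epochs — free choices, recorded in the
interface; the dataset (≤ 72 windows) is far too small for mini-batching
to matter. Analytic gradients are verified against central differences
in the tests.

`make_sequences()` builds windows of `lookback` consecutive epochs of
instantaneous ST/SMC/SEC with the NDVI at the window's final epoch as
target. Lookback defaults to 2: from 72 epochs this yields 71 usable
windows, split 50 train / 21 test chronologically. Normalization
parameters come from the training portion only.

`tune_lstm()` runs BES over (log₁₀ learning rate, hidden size):
the rate is searched on a log scale because it spans decades, the hidden
size by continuous relaxation with rounding. Every fitness evaluation
trains under the *same* inner seed, so fitness is a deterministic
function of the decoded candidate — without this, greedy acceptance
would compare initialization noise and the monotone-history invariant
would be meaningless. Decoded candidates are memoized. The search is
warm-started from the package's default configuration (lr 0.01, 16
units), so the tuned candidate can never be worse than the default on
the tuning criterion. Fitness is the RMSE on the held-out windows; note
the resulting comparison conflates model selection with final
evaluation — both networks are scored on the same 21 windows the tuner
saw. This mirrors the common (flawed) practice in small-sample tuning
studies and is the honest reading of the protocol implemented here; with
only 50 training windows a three-way split would leave the tuner almost
nothing to score against.

On the synthetic defaults both networks show *negative* test R²: the
instantaneous-feature mapping is ill-posed when NDVI is driven by
cumulative exposure, because spring and autumn share soil states but not
canopy state, and a 2-epoch window cannot disambiguate them. The tuning
comparison is therefore about *ordering* (tuned ⪰ default), which holds
deterministically, not about absolute skill.

## Problem sizes and numerical settings

The shipped analyses and tests use: one simulated year (52,704 sensor
readings, 72 epochs); filter window 5/order 2; 60/12 regression split;
BES at population 30 × 100 iterations for the closed-form benchmarks and
a compact budget (population 5–6, 5–8 iterations, 150–300 training
epochs per evaluation) for the tuning experiments, which the memoized,
warm-started search handles comfortably on this 2-D space. Seeds are
fixed everywhere; identical seeds give bit-identical results, including
the full tuning loop.

## Known limitations

* The generator's NDVI never declines seasonally, so the late-season
  splits test extrapolation, not interpolation; validation R² values are
  accordingly pessimistic.
* Cumulative features are near-collinear by construction; ternary
  polynomial coefficients are not individually interpretable (only the
  fitted surface is).
* The tuning fitness reuses the test windows (see above).
* Single site, single year, no missing data: the pipeline validates the
  method chain, not field-scale transferability.
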