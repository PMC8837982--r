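#!/usr/bin/env Rscript
# Simulate one monitored year of the virtual tea-plantation site:
# 10-minute soil-sensor logs (ST/SMC/SEC averaged over five noisy
# nodes) and the 72-epoch NDVI series driven by a known cubic response
# to cumulative soil temperature, with observation noise and sporadic
# cloud-induced drops. Writes the raw logs, the NDVI table and the
# ground-truth response coefficients under results/.

suppressPackageStartupMessages(library(teagrowth))

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

cfg <- sim_config(seed = 42)
truth <- truth_params()

soil <- simulate_soil_series(cfg)
ndvi <- simulate_ndvi_series(soil, truth, cfg)

write_soil_csv(soil, file.path(out_dir, "soil_series.csv"))
write_ndvi_csv(ndvi, file.path(out_dir, "ndvi_series.csv"))
write.csv(data.frame(term = c("intercept", "u", "u2", "u3"),
                     coefficient = truth$sst),
          file.path(out_dir, "truth_sst_response.csv"), row.names = FALSE)

cat(sprintf("soil readings: %d (%s .. %s)\n", nrow(soil),
            format(min(soil$timestamp)), format(max(soil$timestamp))))
cat(sprintf("ST range %.1f..%.1f degC, SMC %.1f..%.1f %%, SEC %.0f..%.0f uS/cm\n",
            min(soil$st), max(soil$st), min(soil$smc), max(soil$smc),
            min(soil$sec), max(soil$sec)))
cat(sprintf("NDVI epochs: %d, observed range %.3f..%.3f, %d cloud-depressed\n",
            nrow(ndvi), min(ndvi$ndvi), max(ndvi$ndvi),
            sum(ndvi$ndvi < ndvi$ndvi_true - 0.1)))
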