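#!/usr/bin/env Rscript
# Benchmark the Bald Eagle Search implementation on closed-form test
# problems before entrusting it with hyperparameter tuning: the 2-D
# sphere (optimum 0 at the origin) and a shifted 1-D quadratic.

suppressPackageStartupMessages(library(teagrowth))

sphere <- function(x) sum(x^2)
best <- numeric(20)
for (s in 1:20) {
  res <- bes_optimize(sphere, bes_config(lower = c(-5, -5),
                                         upper = c(5, 5), seed = s))
  best[s] <- res$value
  stopifnot(!is.unsorted(rev(res$history)))   # greedy acceptance
}
write.csv(data.frame(seed = 1:20, best_fitness = best),
          "results/bes_sphere.csv", row.names = FALSE)
cat(sprintf("sphere (pop 30, 100 iters): %d/20 seeds reach <= 1e-2; median %.2e\n",
            sum(best <= 1e-2), median(best)))

q <- bes_optimize(function(x) (x - 3)^2,
                  bes_config(lower = -10, upper = 10, seed = 1))
cat(sprintf("1-D quadratic: minimum located at %.4f (true 3)\n", q$par))

res <- bes_optimize(sphere, bes_config(lower = c(-5, -5), upper = c(5, 5),
                                       seed = 1))
write.csv(data.frame(iteration = seq_along(res$history),
                     best_fitness = res$history),
          "results/bes_history.csv", row.names = FALSE)
cat("per-iteration best-fitness trace written for seed 1\n")
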