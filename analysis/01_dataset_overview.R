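#!/usr/bin/env Rscript
# Step 1: load the bundled sumatriptan / SC-CO2 dataset, summarize the
# isothermal structure, and locate the crossover-pressure interval where the
# temperature dependence of solubility changes sign.

suppressPackageStartupMessages(library(scfsol))
dir.create("results", showWarnings = FALSE)

d <- load_dataset("sumatriptan")
print(d)

cat(sprintf("\nMole-fraction range: %.2e .. %.2e\n", min(d$y), max(d$y)))

cx <- find_crossover(d)
cat(sprintf("Crossover pressure between %g and %g MPa\n",
            cx$interval[1], cx$interval[2]))
cat("Spearman correlation of y with T at each grid pressure:\n")
print(cx$trend, row.names = FALSE)

write.csv(as.data.frame(d), "results/dataset.csv", row.names = FALSE)
write.csv(cx$trend, "results/crossover_trend.csv", row.names = FALSE)
cat("\nwrote results/dataset.csv, results/crossover_trend.csv\n")
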