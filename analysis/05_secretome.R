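#!/usr/bin/env Rscript
# Stage 5 — growth-normalized secretome: subtract medium-only control
# cytokine levels, convert Neubauer counts to cell numbers, divide net
# secretion by the area under the exponential growth curve, and compare
# early vs late induced cultures with a paired Wilcoxon signed-rank test
# (pairing unit: cytokine x activation dose).
library(cordtrack)

run_dir <- "results/run"
cfg <- read_config(file.path(run_dir, "config.yaml"))
stage_secretome(cfg, run_dir)

norm <- read.table(file.path(run_dir, "secretome_normalized.tsv"),
                   sep = "\t", header = TRUE, check.names = FALSE)
agg <- aggregate(rate_pg_per_cell_day ~ cytokine + dose_ifng + epoch,
                 norm, mean)
wide <- merge(agg[agg$epoch == "early", ], agg[agg$epoch == "late", ],
              by = c("cytokine", "dose_ifng"))
cat(sprintf("median late/early secretion-rate ratio: %.2f over %d pairs\n",
            median(wide$rate_pg_per_cell_day.y /
                     wide$rate_pg_per_cell_day.x), nrow(wide)))

wt <- read.table(file.path(run_dir, "secretome_wilcoxon.tsv"), sep = "\t",
                 header = TRUE)
cat(sprintf("paired Wilcoxon signed-rank: V = %g, p = %.3g (n = %d pairs)\n",
            wt$statistic, wt$p_value, wt$n_pairs))
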