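#!/usr/bin/env Rscript
# Stage 4 — clonal composition: build the clone x sample relative
# abundance matrix over the serial inductions and the UCP end point,
# classify UCP-shared vs UCP-absent ("gray") clones, compute diversity
# statistics and render the stacked bar chart.
library(cordtrack)

run_dir <- "results/run"
cfg <- read_config(file.path(run_dir, "config.yaml"))
stage_compose(cfg, run_dir)

div <- read.table(file.path(run_dir, "diversity.tsv"), sep = "\t",
                  header = TRUE)
cat("per-sample diversity:\n")
print(div, row.names = FALSE, digits = 3)
traj <- read.table(file.path(run_dir, "shared_fraction.tsv"), sep = "\t",
                   header = TRUE)
cat(sprintf("UCP-shared abundance fraction: %.2f (first induction) -> %.2f (last)\n",
            traj$shared_fraction[1], traj$shared_fraction[nrow(traj)]))

# stacked bar chart (colored = UCP-shared clones, gray = UCP-absent)
clustered <- read.table(file.path(run_dir, "clustered.tsv"), sep = "\t",
                        header = TRUE)
meta <- read.table(file.path(run_dir, "metadata.tsv"), sep = "\t",
                   header = TRUE)
m <- build_matrix(tibble::as_tibble(clustered), tibble::as_tibble(meta))
p <- plot_stacked_bars(m)
chart <- file.path(run_dir, "stacked_bars.svg")
ggplot2::ggsave(chart, p, device = grDevices::svg, width = 8, height = 4)
cat("chart written to", chart, "\n")
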