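#!/usr/bin/env Rscript
# Stage 3 — error-correct the barcodes: collapse unlikely-close variants
# (Hamming distance <= 2, child/parent count ratio <= 0.1) onto the most
# frequent barcode, within each sample and fluorophore label.
library(cordtrack)

run_dir <- "results/run"
cfg <- read_config(file.path(run_dir, "config.yaml"))
stage_cluster(cfg, run_dir)

raw <- read.table(file.path(run_dir, "counts.tsv"), sep = "\t", header = TRUE)
cl <- read.table(file.path(run_dir, "clustered.tsv"), sep = "\t",
                 header = TRUE)
stopifnot(sum(raw$count) == sum(cl$count))  # conservation
cat("raw barcode rows:", nrow(raw), "-> clustered:", nrow(cl),
    "(counts conserved:", sum(cl$count), "reads)\n")

truth <- read.table(file.path(run_dir, "truth.tsv"), sep = "\t",
                    header = TRUE)
true_clones <- unique(paste0(truth$fluorophore, ":", truth$barcode))
est_clones <- unique(paste0(cl$fluorophore, ":", cl$barcode))
cat(sprintf("true barcodes recovered as representatives: %.1f%% of %d\n",
            100 * mean(true_clones %in% est_clones), length(true_clones)))
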