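#!/usr/bin/env Rscript
# Stage 2 — deconvolute the reads: assign each read to its sample by the
# inner-PCR tag, screen for the barcode flanks TACCATCTAGA / CTCGAGACT to
# reject unspecific amplicons, split the 31-nt region into the 15-nt
# fluorophore tag and the 16-nt random barcode.
library(cordtrack)

run_dir <- "results/run"
cfg <- read_config(file.path(run_dir, "config.yaml"))
stage_extract(cfg, run_dir)

qc <- read.table(file.path(run_dir, "qc.tsv"), sep = "\t", header = TRUE)
tot <- aggregate(n ~ status, qc, sum)
cat("read status tallies:\n")
print(tot, row.names = FALSE)
cat(sprintf("accepted %.1f%% of %d reads\n",
            100 * tot$n[tot$status == "ok"] / sum(tot$n), sum(tot$n)))
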