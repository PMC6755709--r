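# cordtrack

Clonal barcode tracking and growth-normalized secretome analysis for
umbilical-cord MSC explant cultures.

## The problem

Umbilical cord pieces (UCPs) in explant culture seed mesenchymal stromal
cell explant monolayers (MSC-EMs) again and again: after each monolayer
grows out, the tissue piece is transferred to a fresh dish and initiates
the next culture, for months. Two questions decide whether late-induced
cultures are usable for cell therapy:

1. **Who seeds the cultures?** UCPs transduced once with integrating
   lentiviral vectors carry a genetic barcode — a 15-nt tag specific to
   the fluorescent marker (Cerulean, mCherry or Venus) plus 16 random
   nucleotides (4¹⁶ ≈ 4.3 × 10⁹ identities) — flanked by the constant
   motifs `TACCATCTAGA` and `CTCGAGACT` in the sequenced amplicon.
   Deconvoluting amplicon reads per sample yields a clone × sample
   abundance matrix across serial inductions, with each clone classified
   as UCP-shared (still resident in the tissue at the end) or UCP-absent.
2. **Does the secretome hold up?** Cytokine concentrations in
   conditioned medium from early vs late cultures, activated with
   0/1/5/25 ng/mL IFN-γ + TNF-α, are made comparable by subtracting
   medium-only controls and dividing net secretion by the area under the
   exponential growth curve, AUC = N₀(e^{rt} − 1)/r cell·days with
   r = ln(N₁/N₀)/t. Early and late rates are compared by a paired
   Wilcoxon signed-rank test, pairing on (cytokine, activation dose).

The pipeline is: **simulate → extract → cluster → compose → secretome**.
Extraction assigns reads to samples by the inner-PCR tag, screens for
both flanks to reject unspecific amplicons and splits the 31-nt region
into fluorophore tag and random barcode. Clustering collapses
"unlikely close" barcode variants (Hamming ≤ 2, child/parent count
ratio ≤ 0.1) onto the most frequent sequence. Because the study's raw
reads are not deposited, a first-class synthetic module generates
amplicon reads (with substitution/indel errors) and growth/cytokine
tables with known ground truth, so every stage is testable end to end.

## Worked example

The numbered drivers under `analysis/` run the whole study on the
default synthetic conditions (50 clones, 20% long-term, 15 inductions +
1 UCP end point, 2,000 reads/sample, 1% substitution errors):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_extract.R
Rscript analysis/03_cluster.R
Rscript analysis/04_compose.R
Rscript analysis/05_secretome.R
```

which prints, stage by stage:

```
simulated 32000 reads across 16 samples; 50 distinct true barcodes
accepted 75.6% of 32000 reads
raw barcode rows: 2550 -> clustered: 299 (counts conserved: 24186 reads)
true barcodes recovered as representatives: 100.0% of 50
UCP-shared abundance fraction: 0.22 (first induction) -> 1.00 (last)
median late/early secretion-rate ratio: 2.11 over 20 pairs
paired Wilcoxon signed-rank: V = 210, p = 1.91e-06 (n = 20 pairs)
```

Reading these numbers: exact flank screening discards the ~24% of reads
with an error in the tag or the 28 constant flank bases; clustering
collapses 2,550 raw barcode variants onto 299 representatives without
losing a read, recovering all 50 true barcodes. Early monolayers are
rich in clones never seen in the tissue again (only 22% of their reads
come from UCP-shared clones), while the last inductions consist almost
entirely of tissue-resident clones — the hierarchical picture of
long-term culture-initiating cells with short-lived progeny. The
secretome comparison recovers the simulated twofold late-vs-early
secretion increase and rejects equality decisively.

All artifacts land in `results/run/` as plain-text tables (counts, QC
tallies, the clone × sample matrix, diversity statistics, normalized
secretion rates) plus a stacked-bar SVG in the style of the clonal
tracking figure: colored segments are UCP-shared clones, gray shades are
clones never refound in the tissue.

Programmatic use mirrors the drivers:

```r
library(cordtrack)
cfg <- default_config(seed = 1)
run_pipeline(cfg, "results/run")   # all five stages, bit-reproducible
```

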