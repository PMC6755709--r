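# Independent oracles and tiny fixture builders used across the suite.
# These re-derive expected values by brute force or closed form and are
# deliberately written without reusing the package's own code paths.

# Position-wise mismatch count via an explicit loop.
oracle_hamming <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  d <- 0L
  for (i in seq_along(ca)) if (ca[i] != cb[i]) d <- d + 1L
  d
}

# Naive transliteration of the greedy collapse specification: rank by
# (count desc, barcode asc); walk the ranking; each unclaimed barcode is
# a representative and absorbs lower-ranked unclaimed barcodes within
# max_distance whose count is <= ratio * the representative's raw count.
oracle_greedy <- function(barcodes, counts, max_distance, ratio) {
  n <- length(barcodes)
  rank_order <- order(-counts, barcodes)
  representative <- rep(NA_character_, n)
  for (pos in seq_len(n)) {
    i <- rank_order[pos]
    if (!is.na(representative[i])) next
    representative[i] <- barcodes[i]
    if (pos < n) {
      for (pos2 in (pos + 1L):n) {
        j <- rank_order[pos2]
        if (!is.na(representative[j])) next
        if (oracle_hamming(barcodes[j], barcodes[i]) <= max_distance &&
            counts[j] <= ratio * counts[i]) {
          representative[j] <- barcodes[i]
        }
      }
    }
  }
  agg <- tapply(counts, representative, sum)
  sort_by_name <- sort(names(agg))
  data.frame(barcode = sort_by_name, count = as.integer(agg[sort_by_name]),
             stringsAsFactors = FALSE)
}

# Exact two-sided signed-rank p-value by enumeration of all 2^n sign
# assignments (requires distinct non-zero |d|).
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% rk)
  p_low <- mean(v_all <= v_obs)
  p_high <- mean(v_all >= v_obs)
  min(1, 2 * min(p_low, p_high))
}

# A small layout with explicitly chosen tags, for hand-constructed reads.
toy_layout <- function(sample_ids = c("S1", "S2", "S3")) {
  tags <- c("ACGTACGT", "TTGGCCAA", "GATCGATC")[seq_along(sample_ids)]
  amplicon_layout(stats::setNames(tags, sample_ids))
}

# Assemble a clean read for a toy layout.
toy_read <- function(layout, sample_id, fluor = "Venus",
                     barcode = strrep("A", 16), pad = "NNN") {
  paste0(pad, layout$sample_tags[[sample_id]], layout$left_flank,
         layout$fluor_tags[[fluor]], barcode, layout$right_flank, pad)
}

# Aggregate a truth table into the count-table shape for comparison.
truth_counts <- function(truth) {
  agg <- stats::aggregate(list(count = truth$read_id),
                          by = list(sample_id = truth$sample_id,
                                    fluorophore = truth$fluorophore,
                                    barcode = truth$barcode),
                          FUN = length)
  agg[order(agg$sample_id, -agg$count, agg$barcode), ]
}
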