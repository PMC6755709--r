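#' Assign reads to samples by their inner-PCR primer tag
#'
#' Searches each read for every configured sample tag (substitutions
#' only, up to `max_mismatch`) and returns the id of the unique sample
#' whose tag matches at the smallest distance. Reads with no tag within
#' budget are `"unassigned"`; reads where two or more samples tie at the
#' best distance are `"ambiguous"` and are excluded downstream — ties are
#' never broken by iteration order.
#'
#' @param seqs character vector of read sequences.
#' @param sample_tags named character vector (sample id -> tag); tags
#'   must be unique.
#' @param max_mismatch maximum substitutions tolerated in the tag.
#' @param window optional tag search window: a single integer restricts
#'   the search to the first `window` bases, a length-2 vector
#'   `c(start, end)` to that base range (e.g. the known tag offset when
#'   the amplicon design fixes it); default searches the whole read.
#' @return character vector of sample ids, `"unassigned"` or
#'   `"ambiguous"`, one per read.
#' @export
demultiplex <- function(seqs, sample_tags, max_mismatch = 0L, window = NULL) {
  stopifnot(max_mismatch >= 0L)
  if (anyDuplicated(sample_tags))
    stop("duplicate sample tags in configuration", call. = FALSE)
  n <- length(seqs)
  if (n == 0L) return(character(0))
  searched <- if (is.null(window)) {
    seqs
  } else if (length(window) == 2L) {
    substr(seqs, window[1], window[2])
  } else {
    substr(seqs, 1L, window)
  }
  subj <- Biostrings::DNAStringSet(searched)
  dist <- matrix(Inf, n, length(sample_tags))
  for (j in seq_along(sample_tags)) {
    for (d in 0:max_mismatch) {
      cnt <- Biostrings::vcountPattern(sample_tags[[j]], subj,
                                       max.mismatch = d)
      hit <- is.infinite(dist[, j]) & cnt > 0L
      dist[hit, j] <- d
      if (all(is.finite(dist[, j]))) break
    }
  }
  best <- do.call(pmin, as.data.frame(dist))
  nbest <- rowSums(dist == best)
  out <- rep("unassigned", n)
  one <- is.finite(best) & nbest == 1L
  out[one] <- names(sample_tags)[
    max.col(-dist[one, , drop = FALSE], ties.method = "first")]
  out[is.finite(best) & nbest > 1L] <- "ambiguous"
  out
}

#' Screen reads for the barcode flanking sequences
#'
#' Finds the left flank and then the right flank downstream of it and
#' returns the between-flanks region. This removes unspecific amplicons:
#' reads missing either flank are `no_flanks`; regions whose length is
#' not `fluor_tag_len + random_len` are `bad_length`, unless
#' `length_tolerant = TRUE`, which rescues regions one base shorter or
#' longer (single indel) by anchoring on the flanks.
#'
#' @param seqs character vector of read sequences.
#' @param layout an [amplicon_layout()].
#' @param max_mismatch per-flank substitution budget (default exact).
#' @param length_tolerant accept region lengths of the target +/- 1.
#' @return tibble with `status` (`ok`, `no_flanks`, `bad_length`) and
#'   `region` (NA unless ok).
#' @export
screen_flanks <- function(seqs, layout, max_mismatch = 0L,
                          length_tolerant = FALSE) {
  n <- length(seqs)
  target <- layout$fluor_tag_len + layout$random_len
  if (n == 0L)
    return(tibble::tibble(status = character(0), region = character(0)))
  if (max_mismatch == 0L) {
    lpos <- regexpr(layout$left_flank, seqs, fixed = TRUE)
    lend <- lpos + nchar(layout$left_flank) - 1L
    rest <- ifelse(lpos > 0L, substr(seqs, lend + 1L, nchar(seqs)), "")
    rpos <- regexpr(layout$right_flank, rest, fixed = TRUE)
    found <- lpos > 0L & rpos > 0L
    region <- ifelse(found, substr(rest, 1L, rpos - 1L), NA_character_)
  } else {
    subj <- Biostrings::DNAStringSet(seqs)
    first_match <- function(flank, set) {
      m <- Biostrings::vmatchPattern(flank, set, max.mismatch = max_mismatch)
      starts <- Biostrings::startIndex(m)
      vapply(starts, function(s) if (length(s)) min(s) else NA_integer_,
             integer(1))
    }
    lpos <- first_match(layout$left_flank, subj)
    lend <- lpos + nchar(layout$left_flank) - 1L
    rest <- ifelse(!is.na(lpos), substr(seqs, lend + 1L, nchar(seqs)), "")
    rpos <- first_match(layout$right_flank,
                        Biostrings::DNAStringSet(rest))
    found <- !is.na(lpos) & !is.na(rpos)
    region <- ifelse(found, substr(rest, 1L, ifelse(is.na(rpos), 1L, rpos) - 1L),
                     NA_character_)
  }
  len_ok <- if (length_tolerant) {
    found & abs(nchar(region) - target) <= 1L
  } else {
    found & nchar(region) == target
  }
  status <- ifelse(!found, "no_flanks",
                   ifelse(len_ok, "ok", "bad_length"))
  tibble::tibble(status = status,
                 region = ifelse(status == "ok", region, NA_character_))
}

#' Split a barcode region and assign the fluorophore label
#'
#' The leading `fluor_tag_len` bases are matched against the reference
#' fluorophore tags by Hamming distance; the label is the unique nearest
#' tag within `fluor_max_mismatch`, otherwise the read is unassigned
#' (distance ties are also unassigned, never broken arbitrarily). The
#' trailing `random_len` bases are returned verbatim: random-barcode
#' error correction belongs to the clustering stage, not here. Regions of
#' length target +/- 1 (from `length_tolerant` screening) are split with
#' the same trailing-16 rule and the remainder is matched by edit
#' distance.
#'
#' @param regions character vector of between-flank regions.
#' @param layout an [amplicon_layout()].
#' @param fluor_max_mismatch maximum distance to accept a fluorophore tag.
#' @return tibble with `fluorophore` (label or NA), `fluor_status`
#'   (`assigned`, `tie`, `no_match`) and `barcode`.
#' @export
split_and_assign <- function(regions, layout, fluor_max_mismatch = 3L) {
  n <- length(regions)
  target <- layout$fluor_tag_len + layout$random_len
  if (n == 0L)
    return(tibble::tibble(fluorophore = character(0),
                          fluor_status = character(0),
                          barcode = character(0)))
  lens <- nchar(regions)
  if (any(abs(lens - target) > 1L))
    stop("region length must be ", target, " (+/- 1 in tolerant mode)",
         call. = FALSE)
  barcode <- substr(regions, lens - layout$random_len + 1L, lens)
  head_part <- substr(regions, 1L, lens - layout$random_len)
  tags <- layout$fluor_tags
  dist <- matrix(NA_real_, n, length(tags))
  exact_len <- nchar(head_part) == layout$fluor_tag_len
  for (j in seq_along(tags)) {
    if (any(exact_len))
      dist[exact_len, j] <- hamming_to(head_part[exact_len], tags[[j]])
    if (any(!exact_len))
      dist[!exact_len, j] <- as.vector(
        utils::adist(head_part[!exact_len], tags[[j]]))
  }
  best <- apply(dist, 1L, min)
  nbest <- rowSums(dist == best)
  status <- ifelse(best > fluor_max_mismatch, "no_match",
                   ifelse(nbest > 1L, "tie", "assigned"))
  fluor <- rep(NA_character_, n)
  ok <- status == "assigned"
  fluor[ok] <- names(tags)[apply(dist[ok, , drop = FALSE], 1L, which.min)]
  tibble::tibble(fluorophore = fluor, fluor_status = status,
                 barcode = barcode)
}

#' Run the full read-level extraction
#'
#' Applies, in order: sample-tag demultiplexing, flank screening,
#' region splitting and fluorophore assignment. Every read lands in
#' exactly one status bucket: `ok`, `no_sample_tag`, `ambiguous` (tag
#' tie), `no_flanks`, `bad_length`, or `no_fluor_tag` (fluorophore tag
#' too distant, or tied). With `both_strands = TRUE`, reads that fail at
#' the tag or flank stage are retried on their reverse complement.
#'
#' @param reads tibble with `read_id` and `sequence`.
#' @param layout an [amplicon_layout()].
#' @param max_mismatch_sample,flank_max_mismatch,fluor_max_mismatch
#'   per-stage mismatch budgets.
#' @param length_tolerant passed to [screen_flanks()].
#' @param both_strands retry failed reads on the reverse complement.
#' @param window passed to [demultiplex()].
#' @return tibble: `read_id`, `sample_id` (NA unless assigned), `status`,
#'   `fluorophore`, `barcode`.
#' @export
extract_reads <- function(reads, layout,
                          max_mismatch_sample = 0L,
                          flank_max_mismatch = 0L,
                          fluor_max_mismatch = 3L,
                          length_tolerant = FALSE,
                          both_strands = FALSE,
                          window = NULL) {
  run_once <- function(seqs) {
    res <- tibble::tibble(
      sample_id = NA_character_,
      status = NA_character_,
      fluorophore = NA_character_,
      barcode = NA_character_,
      .rows = length(seqs))
    dm <- demultiplex(seqs, layout$sample_tags, max_mismatch_sample, window)
    res$status[dm == "unassigned"] <- "no_sample_tag"
    res$status[dm == "ambiguous"] <- "ambiguous"
    assigned <- is.na(res$status)
    res$sample_id[assigned] <- dm[assigned]
    fl <- screen_flanks(seqs[assigned], layout, flank_max_mismatch,
                        length_tolerant)
    idx <- which(assigned)
    res$status[idx[fl$status != "ok"]] <- fl$status[fl$status != "ok"]
    good <- idx[fl$status == "ok"]
    if (length(good)) {
      sp <- split_and_assign(fl$region[fl$status == "ok"], layout,
                             fluor_max_mismatch)
      res$barcode[good] <- sp$barcode
      res$fluorophore[good] <- sp$fluorophore
      res$status[good] <- ifelse(sp$fluor_status == "assigned", "ok",
                                 "no_fluor_tag")
    }
    res
  }
  res <- run_once(reads$sequence)
  if (both_strands) {
    retry <- which(res$status %in% c("no_sample_tag", "no_flanks"))
    if (length(retry)) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(reads$sequence[retry])))
      res2 <- run_once(rc)
      better <- res2$status == "ok"
      res[retry[better], ] <- res2[better, ]
    }
  }
  dplyr::bind_cols(tibble::tibble(read_id = reads$read_id), res)
}

#' Aggregate extraction results into a per-sample count table
#'
#' `ok` reads are counted per (sample, fluorophore, barcode); all reads,
#' accepted or rejected, are tallied by status for QC, so the status
#' partition conserves the total read count.
#'
#' @param results tibble from [extract_reads()].
#' @return list with `counts` (tibble: `sample_id`, `fluorophore`,
#'   `barcode`, `count`) and `qc` (tibble: `sample_id`, `status`, `n`;
#'   unassigned reads appear under sample_id `"unassigned"`).
#' @export
build_count_table <- function(results) {
  ok <- results[results$status == "ok", ]
  counts <- dplyr::summarise(
    dplyr::group_by(ok, .data$sample_id, .data$fluorophore, .data$barcode),
    count = dplyr::n(), .groups = "drop")
  counts <- dplyr::arrange(counts, .data$sample_id,
                           dplyr::desc(.data$count), .data$barcode)
  qc <- results
  qc$sample_id[is.na(qc$sample_id)] <- "unassigned"
  qc <- dplyr::summarise(
    dplyr::group_by(qc, .data$sample_id, .data$status),
    n = dplyr::n(), .groups = "drop")
  list(counts = counts, qc = qc)
}
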