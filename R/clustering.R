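#' Clustering parameters
#'
#' Sequencing errors scatter each true 16-nt barcode into a cloud of rare
#' close variants. The collapse rule treats a lower-abundance barcode as
#' an error child of a more frequent one when it lies within
#' `max_distance` and its count is at most `min_count_ratio` times the
#' parent's: two independent random 16-mers are essentially never that
#' close, while error-derived children are rare relative to their parent.
#'
#' @param max_distance maximal distance to a representative (default 2).
#' @param min_count_ratio child/parent count ceiling in `(0, 1]`
#'   (default 0.1).
#' @param scope `"within-fluorophore"` (default; a variant carrying a
#'   different fluorophore tag is a different integration) or `"global"`.
#' @param metric `"hamming"` (default) or `"edit"` (Levenshtein).
#' @return list of class `cluster_params`.
#' @export
cluster_params <- function(max_distance = 2L, min_count_ratio = 0.1,
                           scope = c("within-fluorophore", "global"),
                           metric = c("hamming", "edit")) {
  stopifnot(max_distance >= 0L, min_count_ratio > 0, min_count_ratio <= 1)
  structure(list(max_distance = as.integer(max_distance),
                 min_count_ratio = min_count_ratio,
                 scope = match.arg(scope),
                 metric = match.arg(metric)),
            class = "cluster_params")
}

#' Distance between two barcodes
#'
#' @param a,b barcode strings.
#' @param metric `"hamming"` (requires equal lengths) or `"edit"`.
#' @return non-negative integer distance.
#' @export
barcode_distance <- function(a, b, metric = c("hamming", "edit")) {
  metric <- match.arg(metric)
  if (metric == "hamming") {
    if (nchar(a) != nchar(b))
      stop("Hamming distance requires equal lengths", call. = FALSE)
    hamming_to(a, b)
  } else {
    as.integer(utils::adist(a, b))
  }
}

# Greedy collapse of one group of (barcode, count) rows, already scoped
# to a single sample (and fluorophore, if scoped). Barcodes are ranked by
# descending count with lexicographic tie-break; descending through that
# ranking, each unclaimed barcode becomes a representative and absorbs
# every lower-ranked unclaimed barcode within max_distance whose count is
# at most min_count_ratio times the representative's own (raw) count.
greedy_collapse <- function(barcodes, counts, params) {
  n <- length(barcodes)
  ord <- order(-counts, barcodes)
  rep_of <- integer(n)          # index of representative, 0 = unclaimed
  same_len <- length(unique(nchar(barcodes))) == 1L
  m <- if (params$metric == "hamming" && same_len) char_matrix(barcodes)
  for (pos in seq_len(n)) {
    i <- ord[pos]
    if (rep_of[i] != 0L) next
    rep_of[i] <- i
    if (pos == n) next
    lower <- ord[(pos + 1L):n]
    lower <- lower[rep_of[lower] == 0L]
    if (!length(lower)) next
    d <- if (!is.null(m)) {
      colSums(m[, lower, drop = FALSE] != m[, i])
    } else {
      as.vector(utils::adist(barcodes[lower], barcodes[i]))
    }
    absorb <- lower[d <= params$max_distance &
                    counts[lower] <= params$min_count_ratio * counts[i]]
    rep_of[absorb] <- i
  }
  barcodes[rep_of]
}

#' Collapse error variants onto the most frequent barcode
#'
#' Applies the greedy collapse independently within each sample (and
#' each fluorophore label, under the default scope). Counts are summed
#' onto the representative, so per-sample totals are conserved exactly;
#' the provenance map records which raw barcode went to which
#' representative. A single deterministic pass with lexicographic
#' tie-breaks: no iterative re-centering.
#'
#' @param counts tibble with `sample_id`, `fluorophore`, `barcode`,
#'   `count` (as produced by [build_count_table()]).
#' @param params a [cluster_params()].
#' @return list with `counts` (clustered tibble, same columns) and
#'   `provenance` (tibble: `sample_id`, `fluorophore`, `barcode`,
#'   `representative`).
#' @export
cluster_counts <- function(counts, params = cluster_params()) {
  if (nrow(counts) == 0L) {
    return(list(counts = counts,
                provenance = tibble::tibble(
                  sample_id = character(0), fluorophore = character(0),
                  barcode = character(0), representative = character(0))))
  }
  stopifnot(all(counts$count >= 0), all(counts$count == round(counts$count)))
  key <- if (params$scope == "within-fluorophore") {
    paste(counts$sample_id, counts$fluorophore, sep = "\r")
  } else {
    counts$sample_id
  }
  reps <- character(nrow(counts))
  rep_fluor <- counts$fluorophore
  for (g in unique(key)) {
    idx <- which(key == g)
    reps[idx] <- greedy_collapse(counts$barcode[idx], counts$count[idx],
                                 params)
    # under global scope an absorbed variant adopts its representative's
    # fluorophore label (the variant's own label may be error-derived)
    if (params$scope == "global")
      rep_fluor[idx] <- counts$fluorophore[idx][
        match(reps[idx], counts$barcode[idx])]
  }
  prov <- tibble::tibble(sample_id = counts$sample_id,
                         fluorophore = counts$fluorophore,
                         barcode = counts$barcode,
                         representative = reps)
  out <- counts
  out$barcode <- reps
  out$fluorophore <- rep_fluor
  out <- dplyr::summarise(
    dplyr::group_by(out, .data$sample_id, .data$fluorophore, .data$barcode),
    count = sum(.data$count), .groups = "drop")
  out <- dplyr::arrange(out, .data$sample_id, dplyr::desc(.data$count),
                        .data$barcode)
  list(counts = out, provenance = prov)
}

#' Merge clustered counts into a shared clone namespace
#'
#' Representatives that agree in sequence and fluorophore label are the
#' same clone across samples (no re-clustering across samples); clones
#' absent from a sample get an explicit zero.
#'
#' @param clustered clustered counts tibble (from
#'   [cluster_counts()]`$counts`), covering all samples of a run.
#' @return tibble with one row per clone (`clone_id`, `fluorophore`,
#'   `barcode`) and one integer count column per sample id.
#' @export
merge_clustering_across_samples <- function(clustered) {
  samples <- sort(unique(clustered$sample_id))
  clones <- dplyr::distinct(clustered[, c("fluorophore", "barcode")])
  clones <- dplyr::arrange(clones, .data$fluorophore, .data$barcode)
  clones <- tibble::tibble(
    clone_id = paste0(clones$fluorophore, ":", clones$barcode),
    fluorophore = clones$fluorophore, barcode = clones$barcode)
  for (s in samples) {
    sub <- clustered[clustered$sample_id == s, ]
    ix <- match(paste0(clones$fluorophore, ":", clones$barcode),
                paste0(sub$fluorophore, ":", sub$barcode))
    clones[[s]] <- ifelse(is.na(ix), 0L, sub$count[ix])
  }
  clones
}
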