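#' Build the clone-by-sample relative abundance matrix
#'
#' Columns are serial MSC-EM inductions in order, followed by the UCP
#' end-point sample(s); each column is normalized to sum to 1 (empty
#' samples stay all-zero). A clone is flagged `ucp_shared` when it has a
#' non-zero count in at least one UCP-class sample — the clones shown in
#' color in a stacked bar chart, versus the shades of gray for clones
#' never seen in the initiating tissue piece.
#'
#' @param clustered clustered counts tibble (`sample_id`, `fluorophore`,
#'   `barcode`, `count`).
#' @param metadata tibble with `sample_id`, `class` (`"MSC-EM"` or
#'   `"UCP"`) and `induction` (integer, NA for UCP samples). Every sample
#'   in `clustered` must appear here; metadata-only samples contribute
#'   empty columns.
#' @return object of class `clonal_matrix`: list with `abundance`
#'   (matrix, rows = clones, columns = samples), `samples` (metadata in
#'   column order) and `clones` (tibble: `clone_id`, `fluorophore`,
#'   `barcode`, `ucp_shared`).
#' @export
build_matrix <- function(clustered, metadata) {
  stopifnot(all(c("sample_id", "class", "induction") %in% names(metadata)))
  missing <- setdiff(unique(clustered$sample_id), metadata$sample_id)
  if (length(missing))
    stop("samples without metadata: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!all(metadata$class %in% c("MSC-EM", "UCP")))
    stop("sample class must be 'MSC-EM' or 'UCP'", call. = FALSE)
  meta <- metadata[order(metadata$class != "MSC-EM", metadata$induction), ]
  wide <- merge_clustering_across_samples(clustered)
  for (s in setdiff(meta$sample_id, names(wide))) wide[[s]] <- 0L
  cnt <- as.matrix(wide[, meta$sample_id, drop = FALSE])
  rownames(cnt) <- wide$clone_id
  tot <- colSums(cnt)
  ab <- sweep(cnt, 2L, ifelse(tot > 0, tot, 1), "/")
  ucp_cols <- meta$sample_id[meta$class == "UCP"]
  ucp_shared <- if (length(ucp_cols)) {
    rowSums(cnt[, ucp_cols, drop = FALSE]) > 0
  } else {
    rep(FALSE, nrow(cnt))
  }
  # order clones by first sample of appearance, then descending total
  first_seen <- apply(cnt > 0, 1L, function(z) {
    w <- which(z); if (length(w)) w[1] else Inf
  })
  ord <- order(first_seen, -rowSums(ab), rownames(cnt))
  structure(
    list(abundance = ab[ord, , drop = FALSE],
         samples = tibble::as_tibble(meta),
         clones = tibble::tibble(
           clone_id = wide$clone_id,
           fluorophore = wide$fluorophore,
           barcode = wide$barcode,
           ucp_shared = ucp_shared)[ord, ]),
    class = "clonal_matrix")
}

#' @export
print.clonal_matrix <- function(x, ...) {
  cat("<clonal_matrix> ", nrow(x$abundance), " clones x ",
      ncol(x$abundance), " samples (",
      sum(x$samples$class == "UCP"), " UCP); ",
      sum(x$clones$ucp_shared), " UCP-shared clones\n", sep = "")
  invisible(x)
}

#' Fraction of abundance from UCP-shared clones, per induction
#'
#' For each MSC-EM sample, the summed relative abundance of clones that
#' were also detected in the UCP end-point sample(s). On the hierarchical
#' model this trajectory rises over induction cycles: early monolayers
#' are dominated by transient clones never seen again in the tissue
#' piece, later monolayers by the long-term UCP-resident clones.
#'
#' @param m a `clonal_matrix`.
#' @return named numeric vector (one value in `[0, 1]` per MSC-EM
#'   sample, in induction order).
#' @export
shared_fraction_trajectory <- function(m) {
  if (!any(m$samples$class == "UCP"))
    stop("no UCP sample: shared/non-shared classification is undefined",
         call. = FALSE)
  em <- m$samples$sample_id[m$samples$class == "MSC-EM"]
  if (!length(em)) stop("no MSC-EM sample in matrix", call. = FALSE)
  colSums(m$abundance[m$clones$ucp_shared, em, drop = FALSE])
}

#' Per-sample clonal diversity statistics
#'
#' Operationalizes barcode "variability": richness (number of detected
#' clones), Shannon index (natural log; zero-abundance terms contribute
#' 0), the top clone's fraction, and the cumulative fraction of the top
#' `k` clones. Empty samples get richness 0 and NA for the remaining
#' statistics.
#'
#' @param m a `clonal_matrix`.
#' @param top_k number of top clones for the cumulative fraction.
#' @return tibble: `sample_id`, `class`, `richness`, `shannon`,
#'   `top_clone_fraction`, `top_k_fraction`.
#' @export
diversity <- function(m, top_k = 5L) {
  stats_one <- function(p) {
    p <- p[p > 0]
    if (!length(p))
      return(c(richness = 0, shannon = NA_real_, top1 = NA_real_,
               topk = NA_real_))
    ps <- unname(sort(p, decreasing = TRUE))
    c(richness = length(p), shannon = -sum(p * log(p)), top1 = ps[1],
      topk = sum(ps[seq_len(min(top_k, length(ps)))]))
  }
  res <- t(apply(m$abundance, 2L, stats_one))
  tibble::tibble(sample_id = m$samples$sample_id, class = m$samples$class,
                 richness = as.integer(unname(res[, "richness"])),
                 shannon = unname(res[, "shannon"]),
                 top_clone_fraction = unname(res[, "top1"]),
                 top_k_fraction = unname(res[, "topk"]))
}

#' Clone overlap between two samples
#'
#' Shared clone count and Jaccard index on the non-zero support sets.
#'
#' @param m a `clonal_matrix`.
#' @param a,b sample ids.
#' @return list with `shared` (integer) and `jaccard` (numeric; NA when
#'   both samples are empty).
#' @export
overlap <- function(m, a, b) {
  stopifnot(a %in% m$samples$sample_id, b %in% m$samples$sample_id)
  sa <- m$abundance[, a] > 0
  sb <- m$abundance[, b] > 0
  union <- sum(sa | sb)
  shared <- sum(sa & sb)
  list(shared = as.integer(shared),
       jaccard = if (union == 0) NA_real_ else shared / union)
}

#' Plot-ready long table for the stacked bar chart
#'
#' One row per (sample, detected clone). UCP-shared clones receive stable
#' clone numbers (descending total abundance) and distinct hues;
#' non-shared clones get shades of gray. Deterministic for identical
#' input.
#'
#' @param m a `clonal_matrix`.
#' @return tibble: `sample_id`, `class`, `clone_id`, `abundance`,
#'   `ucp_shared`, `clone_number` (NA for non-shared clones),
#'   `display_color` (hex).
#' @export
stacked_bar_data <- function(m) {
  tot <- rowSums(m$abundance)
  shared_ids <- m$clones$clone_id[m$clones$ucp_shared]
  shared_ids <- shared_ids[order(-tot[match(shared_ids, m$clones$clone_id)],
                                 shared_ids)]
  number <- stats::setNames(seq_along(shared_ids), shared_ids)
  col_shared <- if (length(shared_ids)) {
    stats::setNames(grDevices::hcl(
      h = seq(15, 375, length.out = length(shared_ids) + 1L)[seq_along(shared_ids)],
      c = 100, l = 60), shared_ids)
  } else {
    character(0)
  }
  gray_ids <- m$clones$clone_id[!m$clones$ucp_shared]
  col_gray <- if (length(gray_ids)) {
    stats::setNames(
      grDevices::gray.colors(length(gray_ids), start = 0.25, end = 0.85),
      gray_ids)
  } else {
    character(0)
  }
  cols <- c(col_shared, col_gray)
  idx <- which(m$abundance > 0, arr.ind = TRUE)
  cl <- m$clones$clone_id[idx[, 1L]]
  smp <- m$samples$sample_id[idx[, 2L]]
  out <- tibble::tibble(
    sample_id = smp,
    class = m$samples$class[match(smp, m$samples$sample_id)],
    clone_id = cl,
    abundance = m$abundance[idx],
    ucp_shared = m$clones$ucp_shared[match(cl, m$clones$clone_id)],
    clone_number = unname(number[cl]),
    display_color = unname(cols[cl]))
  dplyr::arrange(out, match(.data$sample_id, m$samples$sample_id),
                 dplyr::desc(.data$abundance), .data$clone_id)
}

#' Render the stacked bar chart
#'
#' Serial MSC-EM samples left to right with the UCP end-point last; bar
#' segments are clones, colored when UCP-shared, gray otherwise.
#'
#' @param m a `clonal_matrix`.
#' @return a ggplot object.
#' @export
plot_stacked_bars <- function(m) {
  d <- stacked_bar_data(m)
  d$sample_id <- factor(d$sample_id, levels = m$samples$sample_id)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample_id, y = .data$abundance,
                                  fill = .data$display_color)) +
    ggplot2::geom_col(width = 0.9, color = NA) +
    ggplot2::scale_fill_identity() +
    ggplot2::labs(x = NULL, y = "Barcode abundance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
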