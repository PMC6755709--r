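#' Default fluorophore-specific tag sequences
#'
#' The barcode cassette carries a 15-nt tag identifying which fluorescent
#' marker (Cerulean, mCherry or Venus) the integrating vector encodes,
#' followed by a 16-nt random barcode. The vector-specific tag sequences
#' are not published, so the package ships three fixed 15-mers chosen to
#' be mutually distant (pairwise Hamming distance >= 9), which lets the
#' extractor assign a fluorophore label even in the presence of several
#' sequencing errors.
#'
#' @return named character vector of three 15-nt tags.
#' @export
default_fluor_tags <- function() {
  c(Cerulean = "AAAACTCCATGTGTA",
    mCherry  = "ACTCCGGAAGTAGAA",
    Venus    = "TCTTGCACTCGGCCT")
}

#' Amplicon layout for barcode extraction
#'
#' Describes the structure of the nested-PCR amplicon:
#' `[5' pad][sample tag][left flank][15-nt fluorophore tag][16-nt random
#' barcode][right flank][3' pad]`. The constant flanks (`TACCATCTAGA` and
#' `CTCGAGACT`) bracket the barcode region and are used to reject
#' unspecific PCR products; the inner-PCR sample tag assigns each read to
#' its sample.
#'
#' @param sample_tags named character vector: sample id -> tag sequence.
#'   All tags must be unique and of equal length.
#' @param left_flank,right_flank constant flanking sequences.
#' @param fluor_tags named character vector of fluorophore-specific tags,
#'   all of length `fluor_tag_len`.
#' @param fluor_tag_len,random_len lengths of the fixed and random parts
#'   of the barcode region.
#' @return an object of class `amplicon_layout`.
#' @export
amplicon_layout <- function(sample_tags,
                            left_flank = "TACCATCTAGA",
                            right_flank = "CTCGAGACT",
                            fluor_tags = default_fluor_tags(),
                            fluor_tag_len = 15L,
                            random_len = 16L) {
  stopifnot(nchar(left_flank) > 0L, nchar(right_flank) > 0L)
  if (grepl(left_flank, right_flank, fixed = TRUE) ||
      grepl(right_flank, left_flank, fixed = TRUE))
    stop("flanks must not be substrings of each other", call. = FALSE)
  if (is.null(names(fluor_tags)) || any(names(fluor_tags) == ""))
    stop("fluor_tags must be named", call. = FALSE)
  if (any(nchar(fluor_tags) != fluor_tag_len))
    stop("all fluor_tags must have length fluor_tag_len", call. = FALSE)
  if (length(sample_tags) > 0L) {
    if (is.null(names(sample_tags)) || any(names(sample_tags) == ""))
      stop("sample_tags must be named by sample id", call. = FALSE)
    if (anyDuplicated(sample_tags))
      stop("duplicate sample tags in configuration", call. = FALSE)
    if (anyDuplicated(names(sample_tags)))
      stop("duplicate sample ids in configuration", call. = FALSE)
    if (length(unique(nchar(sample_tags))) != 1L)
      stop("all sample tags must have equal length", call. = FALSE)
  }
  structure(
    list(sample_tags = sample_tags,
         left_flank = left_flank, right_flank = right_flank,
         fluor_tags = fluor_tags,
         fluor_tag_len = as.integer(fluor_tag_len),
         random_len = as.integer(random_len)),
    class = "amplicon_layout")
}

#' @export
print.amplicon_layout <- function(x, ...) {
  cat("<amplicon_layout>\n")
  cat("  flanks:", x$left_flank, "...", x$right_flank, "\n")
  cat("  region:", x$fluor_tag_len, "nt fluorophore tag +",
      x$random_len, "nt random barcode\n")
  cat("  fluorophores:", paste(names(x$fluor_tags), collapse = ", "), "\n")
  cat("  samples:", length(x$sample_tags), "\n")
  invisible(x)
}

#' Generate mutually distant sample tags
#'
#' Greedy rejection sampling: random candidate tags are accepted only if
#' they sit at Hamming distance >= `min_distance` from every accepted tag,
#' so single sequencing errors cannot flip a read between samples.
#'
#' @param sample_ids character vector of sample ids.
#' @param tag_len tag length in nt.
#' @param min_distance minimal pairwise Hamming distance between tags.
#' @param seed integer seed.
#' @return named character vector (sample id -> tag).
#' @export
make_sample_tags <- function(sample_ids, tag_len = 8L, min_distance = 3L,
                             seed = 1L) {
  set.seed(as.integer(seed))
  tags <- character(0)
  tries <- 0L
  while (length(tags) < length(sample_ids)) {
    cand <- random_dna(1L, tag_len)
    tries <- tries + 1L
    if (tries > 10000L)
      stop("could not place ", length(sample_ids), " tags of length ",
           tag_len, " at distance ", min_distance, call. = FALSE)
    if (length(tags) == 0L || all(hamming_to(tags, cand) >= min_distance))
      tags <- c(tags, cand)
  }
  stats::setNames(tags, sample_ids)
}
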