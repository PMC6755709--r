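#' @keywords internal
#' @importFrom dplyr .data
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

#' Random DNA sequences
#'
#' Draws `n` independent uniform-random DNA sequences of length `len`.
#' Consumes the current RNG stream; callers control reproducibility by
#' seeding before the call.
#'
#' @param n number of sequences.
#' @param len sequence length in nucleotides.
#' @return character vector of length `n`.
#' @keywords internal
random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = len)
  collapse_columns(m)
}

# Paste a (len x n) character matrix back into n strings, column-wise.
collapse_columns <- function(m) {
  if (ncol(m) == 0L) return(character(0))
  do.call(paste0, lapply(seq_len(nrow(m)), function(i) m[i, ]))
}

# Split equal-length strings into a (len x n) character matrix.
char_matrix <- function(x) {
  if (length(x) == 0L) return(matrix(character(0), nrow = 0L))
  len <- unique(nchar(x))
  if (length(len) != 1L)
    stop("all strings must have equal length", call. = FALSE)
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE), nrow = len)
}

# Hamming distance from each string in `x` to the single string `ref`
# (all the same length). Vectorised over `x`.
hamming_to <- function(x, ref) {
  if (length(x) == 0L) return(integer(0))
  m <- char_matrix(x)
  if (nrow(m) != nchar(ref))
    stop("Hamming distance requires equal lengths", call. = FALSE)
  as.integer(colSums(m != strsplit(ref, "", fixed = TRUE)[[1]]))
}

#' Derive independent per-stage seeds from one top-level seed
#'
#' All pipeline randomness flows from a single seed; each stage receives
#' its own derived stream so that running a stage standalone reproduces
#' the fused pipeline exactly.
#'
#' @param seed top-level integer seed.
#' @param n number of derived seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 1]`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, n)
}
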