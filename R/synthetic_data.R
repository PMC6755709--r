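#' Sequencing error model
#'
#' Per-base, independent error process applied to assembled amplicons:
#' substitutions first, then insertions/deletions. Ion Torrent chemistry
#' is indel-prone in homopolymers; setting `homopolymer_bias = TRUE`
#' doubles the indel probability at positions that extend a homopolymer
#' run. All rates default to zero so that error-free round trips are the
#' baseline behaviour.
#'
#' @param substitution,insertion,deletion per-base rates in `[0, 1)`.
#' @param homopolymer_bias logical; weight indels towards homopolymers.
#' @return an object of class `error_model`.
#' @export
error_model <- function(substitution = 0, insertion = 0, deletion = 0,
                        homopolymer_bias = FALSE) {
  rates <- c(substitution = substitution, insertion = insertion,
             deletion = deletion)
  if (any(rates < 0) || any(rates >= 1))
    stop("error rates must lie in [0, 1)", call. = FALSE)
  structure(list(substitution = substitution, insertion = insertion,
                 deletion = deletion,
                 homopolymer_bias = isTRUE(homopolymer_bias)),
            class = "error_model")
}

#' Simulate a pool of barcoded clones
#'
#' Each transduced MSC-initiating cell is identified by a clone identity:
#' a fluorophore label (Cerulean, mCherry or Venus, one per vector) plus a
#' 16-nt random barcode, unique within the pool. Clones are additionally
#' labelled by longevity: long-term clones persist in the umbilical cord
#' piece (UCP) niche and keep seeding explant monolayers, transient clones
#' appear only in early induction cycles.
#'
#' @param n_clones number of clones (at most `4^16`, the size of the
#'   random-barcode space).
#' @param fluor_weights proportions of the three fluorophores; recycled
#'   against `names(default_fluor_tags())`.
#' @param frac_long_term fraction of clones labelled long-term (the
#'   deterministic count `round(frac_long_term * n_clones)` is drawn at
#'   random from the pool).
#' @param seed integer seed.
#' @return tibble with columns `clone_id`, `fluorophore`, `barcode`,
#'   `long_term`.
#' @export
make_clone_pool <- function(n_clones, fluor_weights = c(1, 1, 1) / 3,
                            frac_long_term = 0.2, seed = 1L) {
  stopifnot(n_clones >= 1)
  if (n_clones > 4^16)
    stop("n_clones exceeds the 4^16 random-barcode space; pool impossible",
         call. = FALSE)
  stopifnot(length(fluor_weights) == 3L,
            abs(sum(fluor_weights) - 1) < 1e-8,
            frac_long_term >= 0, frac_long_term <= 1)
  set.seed(as.integer(seed))
  fluors <- sample(names(default_fluor_tags()), n_clones, replace = TRUE,
                   prob = fluor_weights)
  barcodes <- random_dna(n_clones, 16L)
  while (anyDuplicated(barcodes)) {
    dup <- duplicated(barcodes)
    barcodes[dup] <- random_dna(sum(dup), 16L)
  }
  n_long <- round(frac_long_term * n_clones)
  long_term <- logical(n_clones)
  long_term[sample.int(n_clones, n_long)] <- TRUE
  tibble::tibble(
    clone_id = paste0(fluors, ":", barcodes),
    fluorophore = fluors, barcode = barcodes, long_term = long_term)
}

#' Simulate clonal compositions of serial explant monolayers
#'
#' Emulates the hierarchical clonal structure observed across serial
#' MSC-EM inductions: early monolayers are seeded by both transient and
#' long-term clones, later monolayers by long-term clones only, and the
#' UCP sampled at the end of the experiment contains exactly the
#' long-term clones. Within each sample, clone weights are a Dirichlet
#' draw whose concentration decays geometrically with induction index, so
#' later cultures become increasingly dominated by few clones.
#'
#' @param pool clone pool from [make_clone_pool()].
#' @param n_inductions number of serial MSC-EM samples (>= 1).
#' @param dominance decay rate of the Dirichlet concentration per
#'   induction; 0 keeps all inductions equally even.
#' @param transient_horizon last induction index in which transient
#'   clones still contribute.
#' @param alpha0 Dirichlet concentration at induction 1 (floored at 0.1
#'   after decay to keep draws numerically stable).
#' @param seed integer seed.
#' @return list of compositions; each is a list with `sample_id`, `class`
#'   (`"MSC-EM"` or `"UCP"`), `induction` (NA for UCP) and `abundances`,
#'   a named weight vector over clone ids summing to 1 (empty for an
#'   empty sample).
#' @export
simulate_serial_compositions <- function(pool, n_inductions = 15L,
                                         dominance = 0.2,
                                         transient_horizon = 3L,
                                         alpha0 = 1,
                                         seed = 1L) {
  if (nrow(pool) == 0L) stop("pool must be non-empty", call. = FALSE)
  if (n_inductions < 1L) stop("n_inductions must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  draw <- function(ids, alpha) {
    if (length(ids) == 0L)
      return(stats::setNames(numeric(0), character(0)))
    w <- stats::rgamma(length(ids), shape = alpha)
    if (sum(w) == 0) w <- rep(1, length(ids))
    stats::setNames(w / sum(w), ids)
  }
  out <- vector("list", n_inductions + 1L)
  for (k in seq_len(n_inductions)) {
    eligible <- pool$clone_id[pool$long_term | k <= transient_horizon]
    alpha_k <- max(alpha0 * exp(-dominance * (k - 1)), 0.1)
    out[[k]] <- list(sample_id = sprintf("EM%02d", k), class = "MSC-EM",
                     induction = k, abundances = draw(eligible, alpha_k))
  }
  out[[n_inductions + 1L]] <- list(
    sample_id = "UCP", class = "UCP", induction = NA_integer_,
    abundances = draw(pool$clone_id[pool$long_term], alpha0))
  out
}

# Apply the error model to a vector of equal-length sequences.
# Substitutions are applied position-wise and always change the base;
# indels are then applied per position (deletion removes the base,
# insertion appends a random base after it).
apply_errors <- function(seqs, err) {
  if (length(seqs) == 0L) return(seqs)
  if (err$substitution == 0 && err$insertion == 0 && err$deletion == 0)
    return(seqs)
  m <- char_matrix(seqs)
  len <- nrow(m); n <- ncol(m)
  if (err$substitution > 0) {
    hit <- which(stats::runif(len * n) < err$substitution)
    if (length(hit)) {
      shift <- sample.int(3L, length(hit), replace = TRUE)
      m[hit] <- DNA_BASES[(match(m[hit], DNA_BASES) - 1L + shift) %% 4L + 1L]
    }
  }
  if (err$insertion > 0 || err$deletion > 0) {
    pdel <- matrix(err$deletion, len, n)
    pins <- matrix(err$insertion, len, n)
    if (err$homopolymer_bias && len > 1L) {
      run <- rbind(FALSE, m[-1L, , drop = FALSE] == m[-len, , drop = FALSE])
      pdel[run] <- pmin(2 * pdel[run], 0.999)
      pins[run] <- pmin(2 * pins[run], 0.999)
    }
    del <- matrix(stats::runif(len * n) < pdel, len, n)
    ins <- matrix(stats::runif(len * n) < pins, len, n)
    if (any(del) || any(ins)) {
      m[del] <- ""
      if (any(ins))
        m[ins] <- paste0(m[ins], sample(DNA_BASES, sum(ins), replace = TRUE))
      return(collapse_columns(m))
    }
  }
  collapse_columns(m)
}

#' Emit error-bearing amplicon reads for one sample
#'
#' Draws `depth` reads multinomially over the composition's clone
#' abundances, assembles each amplicon as
#' `[5' pad][sample tag][left flank][fluorophore tag][random barcode]
#' [right flank][3' pad]` with random pads, and applies the error model to
#' the assembled sequence. The clone of origin is recorded in a truth
#' table keyed by read id, so extraction and clustering can be scored
#' against ground truth.
#'
#' @param comp one composition from [simulate_serial_compositions()].
#' @param depth number of reads (>= 1); an empty composition yields zero
#'   reads.
#' @param layout [amplicon_layout()] whose `sample_tags` include
#'   `comp$sample_id`.
#' @param err [error_model()].
#' @param seed integer seed.
#' @param pad_len length of the random pads on both sides.
#' @return list with `reads` (tibble: `read_id`, `sequence`) and `truth`
#'   (tibble: `read_id`, `sample_id`, `fluorophore`, `barcode`).
#' @export
emit_reads <- function(comp, depth, layout, err = error_model(),
                       seed = 1L, pad_len = 10L) {
  stopifnot(depth >= 1L)
  empty <- list(
    reads = tibble::tibble(read_id = character(0), sequence = character(0)),
    truth = tibble::tibble(read_id = character(0), sample_id = character(0),
                           fluorophore = character(0), barcode = character(0)))
  if (length(comp$abundances) == 0L) return(empty)
  tag <- layout$sample_tags[[comp$sample_id]]
  if (is.null(tag))
    stop("sample ", comp$sample_id, " has no tag in the layout", call. = FALSE)
  set.seed(as.integer(seed))
  ids <- names(comp$abundances)
  counts <- as.vector(stats::rmultinom(1L, depth, comp$abundances))
  fl <- sub(":.*$", "", ids)
  bc <- sub("^.*:", "", ids)
  fl <- rep(fl, counts); bc <- rep(bc, counts)
  n <- length(fl)
  pad5 <- if (pad_len > 0L) random_dna(n, pad_len) else character(n)
  pad3 <- if (pad_len > 0L) random_dna(n, pad_len) else character(n)
  body <- paste0(pad5, tag, layout$left_flank, layout$fluor_tags[fl], bc,
                 layout$right_flank, pad3)
  seqs <- apply_errors(body, err)
  read_id <- sprintf("%s_r%06d", comp$sample_id, seq_len(n))
  list(reads = tibble::tibble(read_id = read_id, sequence = seqs),
       truth = tibble::tibble(read_id = read_id, sample_id = comp$sample_id,
                              fluorophore = fl, barcode = bc))
}

#' Write / read reads as FASTQ or FASTA
#'
#' Thin wrappers around Biostrings. FASTQ is written Phred+33 with a
#' constant quality character (quality scores are not modelled).
#'
#' @param reads tibble with `read_id` and `sequence`.
#' @param path file path.
#' @param quality single quality character for every base.
#' @return `path`, invisibly (writers); a reads tibble (reader).
#' @export
write_fastq <- function(reads, path, quality = "I") {
  dna <- Biostrings::DNAStringSet(stats::setNames(reads$sequence, reads$read_id))
  qual <- Biostrings::PhredQuality(Biostrings::BStringSet(
    strrep(quality, nchar(reads$sequence))))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' @rdname write_fastq
#' @export
write_fasta <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(stats::setNames(reads$sequence, reads$read_id))
  Biostrings::writeXStringSet(dna, path, format = "fasta")
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.f(ast)?q(\\.gz)?$", path)) "fastq" else "fasta"
  dna <- Biostrings::readDNAStringSet(path, format = fmt)
  tibble::tibble(read_id = sub("\\s.*$", "", names(dna)),
                 sequence = as.character(dna))
}

#' Default secretome effect model
#'
#' Baselines are rough pg/mL scales for the five most abundant cytokines
#' in activated MSC conditioned medium (CXCL10, IL-6, IL-8, RANTES,
#' MCP-1); secretion increases multiplicatively with the activation dose
#' of IFN-gamma/TNF-alpha and, for late-induced cultures, by a constant
#' epoch multiplier. `background` is the cytokine content of the fresh
#' medium itself, measured in the medium-only controls and subtracted
#' during normalization.
#'
#' @param baseline named numeric, pg/mL secreted at dose 0 (early epoch).
#' @param dose_coef multiplicative gain per ng/mL of activating cytokine.
#' @param late_multiplier fold-change of secretion in the late epoch.
#' @param noise lognormal noise (sdlog) on concentrations and growth.
#' @param background named numeric, pg/mL present in fresh medium.
#' @return list of class `effect_model`.
#' @export
effect_model <- function(baseline = c(CXCL10 = 800, `IL-6` = 1500,
                                      `IL-8` = 1200, RANTES = 300,
                                      `MCP-1` = 2000),
                         dose_coef = 0.4,
                         late_multiplier = 2,
                         noise = 0.2,
                         background = NULL) {
  if (is.null(background)) background <- 0.05 * baseline
  stopifnot(all(names(background) == names(baseline)), noise >= 0,
            late_multiplier > 0)
  structure(list(baseline = baseline, dose_coef = dose_coef,
                 late_multiplier = late_multiplier, noise = noise,
                 background = background),
            class = "effect_model")
}

#' Simulate growth and cytokine fixture tables
#'
#' Generates one row per conditioned culture in the schema of the
#' secretome raw-data table: Neubauer chamber counts before seeding
#' (`Count.B`, `Squares.B`, `Volume.B`), conditioning interval (`Days`),
#' counts after conditioning (`Count.A`, `Squares.A`, `Volume.A`),
#' conditioned-medium volume (`Medium`), and one pg/mL column per
#' cytokine, plus medium-only control rows (`Epoch == "control"`, counts
#' `NA`). With `noise = 0`, early and late cultures of the same dose and
#' replicate share identical growth, so normalized late/early rate ratios
#' equal the epoch multiplier exactly.
#'
#' @param n_cultures replicate cultures per (epoch, dose).
#' @param doses activation doses in ng/mL (applied to both IFN-gamma and
#'   TNF-alpha, as in the activation protocol).
#' @param model an [effect_model()].
#' @param seed integer seed.
#' @param n0 seeded cell number per culture.
#' @param growth_rate exponential growth rate per day.
#' @param days conditioning interval in days.
#' @param medium_volume conditioned-medium volume in mL.
#' @param chamber_factor Neubauer conversion (cells/mL per count in one
#'   large square), used to back-compute chamber counts.
#' @return tibble in the schema described above.
#' @export
simulate_growth_cytokines <- function(n_cultures = 3L,
                                      doses = c(0, 1, 5, 25),
                                      model = effect_model(),
                                      seed = 1L,
                                      n0 = 2e5,
                                      growth_rate = 0.2,
                                      days = 5,
                                      medium_volume = 3,
                                      chamber_factor = 1e4) {
  set.seed(as.integer(seed))
  cyts <- names(model$baseline)
  grid <- expand.grid(epoch = c("early", "late"), dose = doses,
                      replicate = seq_len(n_cultures),
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$dose, grid$replicate, grid$epoch), ]
  lognoise <- function(n) {
    if (model$noise == 0) rep(1, n)
    else exp(stats::rnorm(n, sd = model$noise))
  }
  # growth is drawn per (dose, replicate) and shared by the two epochs so
  # the epoch contrast acts on secretion only
  gkey <- paste(grid$dose, grid$replicate)
  ukey <- unique(gkey)
  r_culture <- stats::setNames(growth_rate * lognoise(length(ukey)), ukey)
  squares <- 4L; volume <- 1
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    r <- r_culture[[paste(g$dose, g$replicate)]]
    cells_b <- n0
    cells_a <- n0 * exp(r * days)
    # chamber counts are back-computed exactly (not rounded to integers)
    # so noiseless growth round-trips recover the generator rate exactly
    count_b <- cells_b * squares / (chamber_factor * volume)
    count_a <- cells_a * squares / (chamber_factor * volume)
    mult <- if (g$epoch == "late") model$late_multiplier else 1
    conc <- model$background +
      model$baseline * (1 + model$dose_coef * g$dose) * mult *
      lognoise(length(cyts))
    row <- tibble::tibble(
      Culture = sprintf("%s_d%g_rep%d", g$epoch, g$dose, g$replicate),
      Epoch = g$epoch, Dose.IFNg = g$dose, Dose.TNFa = g$dose,
      Count.B = count_b, Squares.B = squares, Volume.B = volume,
      Days = days,
      Count.A = count_a, Squares.A = squares, Volume.A = volume,
      Medium = medium_volume)
    row[cyts] <- as.list(unname(conc))
    rows[[i]] <- row
  }
  controls <- vector("list", n_cultures)
  for (j in seq_len(n_cultures)) {
    row <- tibble::tibble(
      Culture = sprintf("control_rep%d", j),
      Epoch = "control", Dose.IFNg = 0, Dose.TNFa = 0,
      Count.B = NA_real_, Squares.B = NA_integer_, Volume.B = NA_real_,
      Days = NA_real_,
      Count.A = NA_real_, Squares.A = NA_integer_, Volume.A = NA_real_,
      Medium = medium_volume)
    row[cyts] <- as.list(unname(model$background * lognoise(length(cyts))))
    controls[[j]] <- row
  }
  dplyr::bind_rows(c(rows, controls))
}
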