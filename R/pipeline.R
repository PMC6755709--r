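#' Default pipeline run configuration
#'
#' A fully serializable list driving every stage: simulation conditions
#' (clone pool, serial compositions, sequencing depth and error rates),
#' extraction and clustering parameters, and the secretome generator. All
#' randomness flows from the single top-level `seed` through per-stage
#' derived streams, so a run is reproducible bit-for-bit from
#' (config, seed) and a stage run standalone reproduces the fused
#' pipeline.
#'
#' @param seed top-level integer seed.
#' @return nested named list (class `run_config`).
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    simulate = list(
      n_clones = 50L, fluor_weights = c(1, 1, 1) / 3,
      frac_long_term = 0.2, n_inductions = 15L, dominance = 0.2,
      transient_horizon = 3L, depth = 2000L, pad_len = 10L,
      tag_len = 8L,
      error = list(substitution = 0.01, insertion = 0, deletion = 0)),
    extract = list(max_mismatch_sample = 0L, flank_max_mismatch = 0L,
                   fluor_max_mismatch = 3L, length_tolerant = FALSE,
                   both_strands = FALSE),
    cluster = list(max_distance = 2L, min_count_ratio = 0.1,
                   scope = "within-fluorophore", metric = "hamming"),
    secretome = list(n_cultures = 3L, doses = c(0, 1, 5, 25),
                     late_multiplier = 2, noise = 0.2,
                     chamber_factor = 1e4)),
    class = "run_config")
}

#' Validate a run configuration
#'
#' @param config a config list (e.g. from [default_config()] or read
#'   from YAML with [read_config()]).
#' @return the config, invisibly; stops with a message listing every
#'   offending key otherwise.
#' @export
validate_config <- function(config) {
  bad <- character(0)
  need <- function(key, test) {
    val <- config
    for (k in strsplit(key, "$", fixed = TRUE)[[1]]) val <- val[[k]]
    if (is.null(val) || !test(val)) bad <<- c(bad, key)
  }
  pos_int <- function(x) is.numeric(x) && length(x) == 1L && x >= 1
  prob <- function(x) is.numeric(x) && all(x >= 0) && all(x <= 1)
  need("seed", function(x) is.numeric(x) && length(x) == 1L)
  need("simulate$n_clones", pos_int)
  need("simulate$n_inductions", pos_int)
  need("simulate$depth", pos_int)
  need("simulate$frac_long_term", prob)
  need("simulate$fluor_weights",
       function(x) is.numeric(x) && length(x) == 3L &&
         abs(sum(x) - 1) < 1e-6)
  need("simulate$error$substitution", function(x) prob(x) && x < 1)
  need("simulate$error$insertion", function(x) prob(x) && x < 1)
  need("simulate$error$deletion", function(x) prob(x) && x < 1)
  need("cluster$max_distance", function(x) is.numeric(x) && x >= 0)
  need("cluster$min_count_ratio", function(x) prob(x) && x > 0)
  need("secretome$n_cultures", pos_int)
  need("secretome$chamber_factor", function(x) is.numeric(x) && x > 0)
  if (length(bad))
    stop("invalid run config; offending keys: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(config)
}

#' @rdname validate_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

#' @rdname validate_config
#' @param config a run config.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 12L)
  invisible(path)
}

# Deterministic TSV/CSV writers: fixed quoting, '.' decimal, full
# precision, no row names, so identical inputs give identical bytes.
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

write_csv <- function(x, path) {
  utils::write.table(x, path, sep = ",", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      colClasses = NA, na.strings = "NA",
                                      check.names = FALSE,
                                      stringsAsFactors = FALSE))
}

#' Pipeline stages
#'
#' Each stage reads the previous stage's plain-text files from the run
#' directory and writes its own, so stages can be run standalone or fused
#' via [run_pipeline()] with identical results.
#'
#' `stage_simulate` writes `reads.fastq`, `truth.tsv`, `sample_tags.tsv`,
#' `compositions.tsv`, `metadata.tsv` and `growth_cytokines.csv`;
#' `stage_extract` writes `counts.tsv` and `qc.tsv`; `stage_cluster`
#' writes `clustered.tsv` and `provenance.tsv`; `stage_compose` writes
#' `matrix_wide.csv`, `matrix_long.tsv`, `diversity.tsv` and
#' `shared_fraction.tsv`; `stage_secretome` writes
#' `secretome_normalized.tsv` and `secretome_wilcoxon.tsv`.
#'
#' @param config validated run config.
#' @param dir run directory.
#' @return invisibly, the run directory.
#' @export
stage_simulate <- function(config, dir) {
  validate_config(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- config$simulate
  seeds <- derive_seeds(config$seed, 4L + sim$n_inductions + 1L)
  pool <- make_clone_pool(sim$n_clones, sim$fluor_weights,
                          sim$frac_long_term, seed = seeds[1])
  comps <- simulate_serial_compositions(
    pool, sim$n_inductions, sim$dominance, sim$transient_horizon,
    seed = seeds[2])
  tags <- make_sample_tags(vapply(comps, `[[`, "", "sample_id"),
                           tag_len = sim$tag_len, seed = seeds[3])
  layout <- amplicon_layout(tags)
  err <- error_model(sim$error$substitution, sim$error$insertion,
                     sim$error$deletion)
  all_reads <- vector("list", length(comps))
  all_truth <- vector("list", length(comps))
  for (i in seq_along(comps)) {
    em <- emit_reads(comps[[i]], sim$depth, layout, err,
                     seed = seeds[4L + i], pad_len = sim$pad_len)
    all_reads[[i]] <- em$reads
    all_truth[[i]] <- em$truth
  }
  reads <- dplyr::bind_rows(all_reads)
  truth <- dplyr::bind_rows(all_truth)
  write_fastq(reads, file.path(dir, "reads.fastq"))
  write_tsv(truth, file.path(dir, "truth.tsv"))
  write_tsv(tibble::tibble(sample_id = names(tags), tag = unname(tags)),
            file.path(dir, "sample_tags.tsv"))
  comp_tbl <- dplyr::bind_rows(lapply(comps, function(cc) {
    if (!length(cc$abundances))
      return(tibble::tibble(sample_id = character(0), clone_id = character(0),
                            weight = numeric(0)))
    tibble::tibble(sample_id = cc$sample_id, clone_id = names(cc$abundances),
                   weight = unname(cc$abundances))
  }))
  write_tsv(comp_tbl, file.path(dir, "compositions.tsv"))
  meta <- tibble::tibble(
    sample_id = vapply(comps, `[[`, "", "sample_id"),
    class = vapply(comps, `[[`, "", "class"),
    induction = vapply(comps, function(cc) as.integer(cc$induction),
                       integer(1)))
  write_tsv(meta, file.path(dir, "metadata.tsv"))
  sec <- config$secretome
  growth <- simulate_growth_cytokines(
    n_cultures = sec$n_cultures, doses = sec$doses,
    model = effect_model(late_multiplier = sec$late_multiplier,
                         noise = sec$noise),
    seed = seeds[4], chamber_factor = sec$chamber_factor)
  write_csv(growth, file.path(dir, "growth_cytokines.csv"))
  invisible(dir)
}

#' @rdname stage_simulate
#' @export
stage_extract <- function(config, dir) {
  tags_tbl <- read_tsv(file.path(dir, "sample_tags.tsv"))
  layout <- amplicon_layout(stats::setNames(tags_tbl$tag, tags_tbl$sample_id))
  reads <- read_reads(file.path(dir, "reads.fastq"))
  ex <- config$extract
  # the simulated amplicon design places the tag right after the 5' pad,
  # so the tag search window is the known offset range
  pad <- config$simulate$pad_len
  tag_len <- nchar(tags_tbl$tag[1])
  res <- extract_reads(reads, layout,
                       max_mismatch_sample = ex$max_mismatch_sample,
                       flank_max_mismatch = ex$flank_max_mismatch,
                       fluor_max_mismatch = ex$fluor_max_mismatch,
                       length_tolerant = ex$length_tolerant,
                       both_strands = ex$both_strands,
                       window = c(pad + 1L, pad + tag_len))
  tab <- build_count_table(res)
  write_tsv(tab$counts, file.path(dir, "counts.tsv"))
  write_tsv(tab$qc, file.path(dir, "qc.tsv"))
  invisible(dir)
}

#' @rdname stage_simulate
#' @export
stage_cluster <- function(config, dir) {
  counts <- read_tsv(file.path(dir, "counts.tsv"))
  params <- cluster_params(config$cluster$max_distance,
                           config$cluster$min_count_ratio,
                           config$cluster$scope, config$cluster$metric)
  cl <- cluster_counts(counts, params)
  write_tsv(cl$counts, file.path(dir, "clustered.tsv"))
  write_tsv(cl$provenance, file.path(dir, "provenance.tsv"))
  invisible(dir)
}

#' @rdname stage_simulate
#' @export
stage_compose <- function(config, dir) {
  clustered <- read_tsv(file.path(dir, "clustered.tsv"))
  meta <- read_tsv(file.path(dir, "metadata.tsv"))
  if (!any(meta$class == "UCP"))
    stop("compose requires at least one UCP-class sample", call. = FALSE)
  m <- build_matrix(clustered, meta)
  wide <- tibble::as_tibble(cbind(
    m$clones[, c("clone_id", "fluorophore", "barcode", "ucp_shared")],
    tibble::as_tibble(m$abundance)))
  write_csv(wide, file.path(dir, "matrix_wide.csv"))
  write_tsv(stacked_bar_data(m), file.path(dir, "matrix_long.tsv"))
  write_tsv(diversity(m), file.path(dir, "diversity.tsv"))
  traj <- shared_fraction_trajectory(m)
  write_tsv(tibble::tibble(sample_id = names(traj),
                           shared_fraction = unname(traj)),
            file.path(dir, "shared_fraction.tsv"))
  invisible(dir)
}

#' @rdname stage_simulate
#' @export
stage_secretome <- function(config, dir) {
  growth <- tibble::as_tibble(utils::read.csv(
    file.path(dir, "growth_cytokines.csv"), check.names = FALSE))
  norm <- normalize_secretome(growth,
                              chamber_factor = config$secretome$chamber_factor)
  write_tsv(norm, file.path(dir, "secretome_normalized.tsv"))
  wt <- paired_wilcoxon_early_late(norm)
  write_tsv(tibble::tibble(statistic = wt$statistic, p_value = wt$p_value,
                           n_pairs = wt$n_pairs,
                           degenerate = wt$degenerate),
            file.path(dir, "secretome_wilcoxon.tsv"))
  invisible(dir)
}

#' Run the full pipeline
#'
#' simulate -> extract -> cluster -> compose -> secretome, writing all
#' intermediate and final artifacts as plain-text tables under `dir`,
#' plus a provenance manifest (`config.yaml`, its MD5 hash, seed and
#' package version). Running the same config twice produces byte-identical
#' tabular outputs.
#'
#' @param config run config (validated on entry).
#' @param dir output directory.
#' @return invisibly, the run directory.
#' @export
run_pipeline <- function(config, dir) {
  validate_config(config)
  stage_simulate(config, dir)
  stage_extract(config, dir)
  stage_cluster(config, dir)
  stage_compose(config, dir)
  stage_secretome(config, dir)
  cfg_path <- file.path(dir, "config.yaml")
  write_config(config, cfg_path)
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("cordtrack")))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
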