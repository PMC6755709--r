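test_that("barcode distances match a position-wise oracle", {
  expect_identical(barcode_distance("AAAA", "AAAA"), 0L)
  expect_identical(barcode_distance("AAAA", "AAAT"), 1L)
  expect_error(barcode_distance("AAAA", "AAA"), "equal lengths")
  expect_identical(barcode_distance("AAAA", "AAA", metric = "edit"), 1L)

  set.seed(17)
  for (i in 1:50) {
    a <- paste(sample(c("A", "C", "G", "T"), 16, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 16, TRUE), collapse = "")
    expect_identical(barcode_distance(a, b), oracle_hamming(a, b))
    expect_identical(barcode_distance(a, b), barcode_distance(b, a))
  }
})

cnt_tbl <- function(barcodes, counts, sample = "S1", fluor = "Venus") {
  tibble::tibble(sample_id = sample, fluorophore = fluor,
                 barcode = barcodes, count = as.integer(counts))
}

test_that("close rare variants are summed onto the most frequent barcode", {
  b1 <- strrep("A", 16)
  b1_err <- paste0(strrep("A", 15), "T")
  res <- cluster_counts(cnt_tbl(c(b1, b1_err), c(100, 3)),
                        cluster_params(max_distance = 1,
                                       min_count_ratio = 0.5))
  expect_identical(res$counts$count, 103L)
  expect_identical(res$counts$barcode, b1)
  expect_identical(res$provenance$representative, c(b1, b1))

  # abundant close pair: the "unlikely close" guard keeps both
  res2 <- cluster_counts(cnt_tbl(c(b1, b1_err), c(100, 90)),
                         cluster_params(max_distance = 1,
                                        min_count_ratio = 0.5))
  expect_identical(sort(res2$counts$count), c(90L, 100L))

  # boundary: child exactly at ratio * parent is absorbed (<=)
  res3 <- cluster_counts(cnt_tbl(c(b1, b1_err), c(100, 50)),
                         cluster_params(max_distance = 1,
                                        min_count_ratio = 0.5))
  expect_identical(res3$counts$count, 150L)
})

test_that("greedy clustering agrees with the naive oracle on random instances", {
  set.seed(23)
  alphabet <- c("A", "C", "G", "T")
  for (i in 1:150) {
    n <- sample(1:20, 1)
    # seed a few parents, then scatter children near them plus noise
    parents <- replicate(max(1, n %/% 4), paste(
      sample(alphabet, 16, TRUE), collapse = ""))
    barcodes <- character(n)
    for (j in seq_len(n)) {
      base <- sample(parents, 1)
      chars <- strsplit(base, "")[[1]]
      nmut <- sample(0:4, 1)
      if (nmut > 0) {
        at <- sample(16, nmut)
        chars[at] <- sample(alphabet, nmut, TRUE)
      }
      barcodes[j] <- paste(chars, collapse = "")
    }
    keep <- !duplicated(barcodes)
    barcodes <- barcodes[keep]
    counts <- sample(1:100, length(barcodes), replace = TRUE)
    prm <- cluster_params(max_distance = sample(0:3, 1),
                          min_count_ratio = sample(c(0.1, 0.5, 1), 1))
    got <- cluster_counts(cnt_tbl(barcodes, counts), prm)$counts
    want <- oracle_greedy(barcodes, counts, prm$max_distance,
                          prm$min_count_ratio)
    got <- got[order(got$barcode), ]
    expect_identical(got$barcode, want$barcode)
    expect_identical(got$count, want$count)
  }
})

test_that("clustering conserves counts, is idempotent, and distance 0 is identity", {
  set.seed(29)
  pool <- make_clone_pool(20, seed = 29)
  comps <- simulate_serial_compositions(pool, 2, seed = 29)
  lay <- toy_layout(c("EM01", "EM02"))
  reads <- dplyr::bind_rows(
    emit_reads(comps[[1]], 800, lay, error_model(substitution = 0.02),
               seed = 1)$reads,
    emit_reads(comps[[2]], 800, lay, error_model(substitution = 0.02),
               seed = 2)$reads)
  raw <- build_count_table(extract_reads(reads, lay))$counts

  cl <- cluster_counts(raw)
  for (s in unique(raw$sample_id)) {
    expect_identical(sum(cl$counts$count[cl$counts$sample_id == s]),
                     sum(raw$count[raw$sample_id == s]))
  }
  # every representative maps to itself
  reps <- unique(cl$provenance[, c("sample_id", "fluorophore",
                                   "representative")])
  self <- merge(reps, cl$provenance,
                by.x = c("sample_id", "fluorophore", "representative"),
                by.y = c("sample_id", "fluorophore", "barcode"))
  expect_true(all(self$representative == self$representative.y))

  # idempotence is guaranteed when the ratio guard is inactive (ratio 1):
  # surviving representatives are pairwise farther than max_distance, so
  # a second pass can never absorb anything. (With ratio < 1 a second
  # pass may absorb children that the summed representative count now
  # admits; see the methods vignette.)
  prm1 <- cluster_params(min_count_ratio = 1)
  cl1 <- cluster_counts(raw, prm1)
  cl1b <- cluster_counts(cl1$counts, prm1)
  expect_identical(dplyr::arrange(cl1b$counts, sample_id, barcode),
                   dplyr::arrange(cl1$counts, sample_id, barcode))

  # max_distance = 0 is the identity clustering
  id <- cluster_counts(raw, cluster_params(max_distance = 0))
  expect_identical(dplyr::arrange(id$counts, sample_id, barcode),
                   dplyr::arrange(raw, sample_id, barcode))

  # empty input passes through
  empty <- cluster_counts(raw[0, ])
  expect_identical(nrow(empty$counts), 0L)
})

test_that("clustering scope separates fluorophores by default", {
  b <- strrep("G", 16)
  bmut <- paste0(strrep("G", 15), "C")
  tbl <- tibble::tibble(sample_id = "S1",
                        fluorophore = c("Venus", "mCherry"),
                        barcode = c(b, bmut), count = c(100L, 3L))
  within <- cluster_counts(tbl, cluster_params(scope = "within-fluorophore"))
  expect_identical(nrow(within$counts), 2L)
  global <- cluster_counts(tbl, cluster_params(scope = "global"))
  expect_identical(nrow(global$counts), 1L)
})

test_that("merged representatives form one clone namespace across samples", {
  tbl <- tibble::tibble(
    sample_id = c("S1", "S1", "S2"),
    fluorophore = c("Venus", "mCherry", "Venus"),
    barcode = c(strrep("A", 16), strrep("C", 16), strrep("A", 16)),
    count = c(10L, 5L, 7L))
  wide <- merge_clustering_across_samples(tbl)
  expect_identical(nrow(wide), 2L)
  venus <- wide[wide$fluorophore == "Venus", ]
  expect_identical(venus$S1, 10L)
  expect_identical(venus$S2, 7L)
  mch <- wide[wide$fluorophore == "mCherry", ]
  expect_identical(mch$S2, 0L)

  # error-free simulation: clone ids biject with the simulated pool
  pool <- make_clone_pool(15, seed = 33)
  comps <- simulate_serial_compositions(pool, 3, seed = 33,
                                        transient_horizon = 3)
  lay <- toy_layout(c("EM01", "EM02", "EM03"))
  ems <- lapply(1:3, function(i)
    emit_reads(comps[[i]], 2000, lay, error_model(), seed = i))
  reads <- dplyr::bind_rows(lapply(ems, `[[`, "reads"))
  truth <- dplyr::bind_rows(lapply(ems, `[[`, "truth"))
  raw <- build_count_table(extract_reads(reads, lay))$counts
  cl <- cluster_counts(raw)
  wide <- merge_clustering_across_samples(cl$counts)
  expect_setequal(wide$clone_id,
                  unique(paste0(truth$fluorophore, ":", truth$barcode)))
})
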