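simple_matrix <- function() {
  tbl <- tibble::tibble(
    sample_id = c("EM01", "EM01", "EM02", "UCP"),
    fluorophore = c("Venus", "mCherry", "Venus", "Venus"),
    barcode = c(strrep("A", 16), strrep("C", 16), strrep("A", 16),
                strrep("A", 16)),
    count = c(60L, 40L, 10L, 5L))
  meta <- tibble::tibble(sample_id = c("EM01", "EM02", "UCP"),
                         class = c("MSC-EM", "MSC-EM", "UCP"),
                         induction = c(1L, 2L, NA))
  build_matrix(tbl, meta)
}

test_that("abundance matrix is column-stochastic with correct shared flags", {
  m <- simple_matrix()
  expect_equal(unname(colSums(m$abundance)), c(1, 1, 1), tolerance = 1e-9)
  expect_equal(sort(unname(m$abundance[, "EM01"])), c(0.4, 0.6))

  venus <- paste0("Venus:", strrep("A", 16))
  mch <- paste0("mCherry:", strrep("C", 16))
  expect_true(m$clones$ucp_shared[m$clones$clone_id == venus])
  expect_false(m$clones$ucp_shared[m$clones$clone_id == mch])

  # clone appearing only in the UCP: shared, zero in all MSC-EM columns
  tbl <- tibble::tibble(sample_id = c("EM01", "UCP"),
                        fluorophore = "Venus",
                        barcode = c(strrep("A", 16), strrep("G", 16)),
                        count = c(10L, 8L))
  meta <- tibble::tibble(sample_id = c("EM01", "UCP"),
                         class = c("MSC-EM", "UCP"), induction = c(1L, NA))
  m2 <- build_matrix(tbl, meta)
  gid <- paste0("Venus:", strrep("G", 16))
  expect_true(m2$clones$ucp_shared[m2$clones$clone_id == gid])
  expect_identical(unname(m2$abundance[gid, "EM01"]), 0)

  expect_error(build_matrix(tbl, meta[1, ]), "without metadata")
})

test_that("shared-fraction trajectory matches truth recomputation", {
  m <- simple_matrix()
  traj <- shared_fraction_trajectory(m)
  expect_equal(unname(traj), c(0.6, 1))

  # no UCP sample -> classification undefined
  tbl <- tibble::tibble(sample_id = "EM01", fluorophore = "Venus",
                        barcode = strrep("A", 16), count = 5L)
  meta <- tibble::tibble(sample_id = "EM01", class = "MSC-EM",
                         induction = 1L)
  expect_error(shared_fraction_trajectory(build_matrix(tbl, meta)), "UCP")

  # synthetic run: trajectory equals a direct recomputation from the
  # error-free truth compositions
  pool <- make_clone_pool(30, frac_long_term = 0.3, seed = 41)
  comps <- simulate_serial_compositions(pool, 6, seed = 41)
  lay_all <- amplicon_layout(
    make_sample_tags(c(sprintf("EM%02d", 1:6), "UCP"), seed = 99))
  ems <- lapply(seq_along(comps), function(i)
    emit_reads(comps[[i]], 1500, lay_all, error_model(), seed = 50 + i))
  truth <- dplyr::bind_rows(lapply(ems, `[[`, "truth"))
  cl <- cluster_counts(tibble::as_tibble(truth_counts(truth)))
  meta <- tibble::tibble(sample_id = c(sprintf("EM%02d", 1:6), "UCP"),
                         class = c(rep("MSC-EM", 6), "UCP"),
                         induction = c(1:6, NA))
  m <- build_matrix(cl$counts, meta)
  traj <- shared_fraction_trajectory(m)

  ucp_clones <- unique(truth$barcode[truth$sample_id == "UCP"])
  for (s in sprintf("EM%02d", 1:6)) {
    tt <- truth[truth$sample_id == s, ]
    want <- sum(tt$barcode %in% ucp_clones) / nrow(tt)
    expect_lt(abs(traj[[s]] - want), 1e-12)
  }
})

test_that("diversity statistics agree with closed forms and re-summation", {
  tbl <- tibble::tibble(sample_id = "S1", fluorophore = "Venus",
                        barcode = vapply(1:4, function(i)
                          paste(rep(c("A", "C", "G", "T")[i], 16),
                                collapse = ""), character(1)),
                        count = rep(25L, 4))
  meta <- tibble::tibble(sample_id = c("S1", "UCP"),
                         class = c("MSC-EM", "UCP"),
                         induction = c(1L, NA))
  m <- build_matrix(tbl, meta)
  d <- diversity(m)
  s1 <- d[d$sample_id == "S1", ]
  expect_equal(s1$shannon, log(4), tolerance = 1e-12)
  expect_identical(s1$richness, 4L)
  expect_equal(s1$top_clone_fraction, 0.25)

  # single clone: Shannon 0, top fraction 1
  tbl1 <- tbl[1, ]
  m1 <- build_matrix(tbl1, meta)
  d1 <- diversity(m1)[1, ]
  expect_equal(d1$shannon, 0)
  expect_equal(d1$top_clone_fraction, 1)

  # random column vs direct re-summation
  set.seed(43)
  k <- 12
  counts <- sample(1:500, k)
  tblr <- tibble::tibble(sample_id = "S1", fluorophore = "Venus",
                         barcode = replicate(k, paste(
                           sample(c("A", "C", "G", "T"), 16, TRUE),
                           collapse = "")),
                         count = counts)
  mr <- build_matrix(tblr, meta)
  p <- counts / sum(counts)
  want <- 0
  for (pi in p) want <- want - pi * log(pi)
  expect_lt(abs(diversity(mr)$shannon[1] - want), 1e-12)
})

test_that("overlap counts shared clones and the Jaccard index", {
  m <- simple_matrix()
  expect_equal(overlap(m, "EM01", "EM01")$jaccard, 1)

  tbl <- tibble::tibble(
    sample_id = c(rep("S1", 3), rep("S2", 3), "UCP"),
    fluorophore = "Venus",
    barcode = c(strrep("A", 16), strrep("C", 16), strrep("G", 16),
                strrep("C", 16), strrep("G", 16), strrep("T", 16),
                strrep("A", 16)),
    count = 10L)
  meta <- tibble::tibble(sample_id = c("S1", "S2", "UCP"),
                         class = c("MSC-EM", "MSC-EM", "UCP"),
                         induction = c(1L, 2L, NA))
  m2 <- build_matrix(tbl, meta)
  ov <- overlap(m2, "S1", "S2")
  expect_identical(ov$shared, 2L)
  expect_equal(ov$jaccard, 0.5)
  expect_equal(overlap(m2, "S1", "S1")$jaccard, 1)
})

test_that("stacked bar data reproduces the shared/gray chart semantics", {
  m <- simple_matrix()
  d <- stacked_bar_data(m)
  expect_identical(nrow(d), sum(m$abundance > 0))
  expect_setequal(d$clone_id[!d$ucp_shared],
                  m$clones$clone_id[!m$clones$ucp_shared])
  # gray clones carry gray hex colors (equal RGB channels), shared do not
  grays <- unique(d$display_color[!d$ucp_shared])
  expect_true(all(substr(grays, 2, 3) == substr(grays, 4, 5) &
                    substr(grays, 4, 5) == substr(grays, 6, 7)))
  expect_true(all(is.na(d$clone_number[!d$ucp_shared])))
  expect_false(any(is.na(d$clone_number[d$ucp_shared])))

  # deterministic for identical input
  expect_identical(d, stacked_bar_data(simple_matrix()))

  p <- plot_stacked_bars(m)
  expect_s3_class(p, "ggplot")
})

test_that("degenerate longevity fractions produce all-colored or all-gray charts", {
  run_frac <- function(frac) {
    pool <- make_clone_pool(10, frac_long_term = frac, seed = 47)
    comps <- simulate_serial_compositions(pool, 3, seed = 47)
    lay <- toy_layout(c("EM01", "EM02", "EM03"))
    lay <- amplicon_layout(c(lay$sample_tags,
                             make_sample_tags("UCP", seed = 7)))
    ems <- lapply(seq_along(comps), function(i) {
      if (length(comps[[i]]$abundances) == 0) return(NULL)
      emit_reads(comps[[i]], 500, lay, error_model(), seed = i)
    })
    ems <- Filter(Negate(is.null), ems)
    raw <- build_count_table(
      extract_reads(dplyr::bind_rows(lapply(ems, `[[`, "reads")), lay))
    meta <- tibble::tibble(sample_id = c("EM01", "EM02", "EM03", "UCP"),
                           class = c(rep("MSC-EM", 3), "UCP"),
                           induction = c(1:3, NA))
    build_matrix(cluster_counts(raw$counts)$counts, meta)
  }
  m1 <- run_frac(1)
  expect_true(all(m1$clones$ucp_shared))
  m0 <- run_frac(0)
  expect_false(any(m0$clones$ucp_shared))
  expect_equal(unname(shared_fraction_trajectory(m0)), rep(0, 3))
})
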