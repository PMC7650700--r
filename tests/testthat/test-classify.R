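mk_hits <- function(start, end, score, class = "P", id = "prot") {
  tibble::tibble(
    protein_id = id, motif_class = class,
    start = as.integer(start), end = as.integer(end), score = score
  )
}

test_that("non-overlapping hits are all kept, ordered by start", {
  h <- mk_hits(c(40, 1, 80), c(74, 35, 114), c(5, 9, 7))
  tiled <- tile_hits(h)
  expect_equal(tiled$start, c(1L, 40L, 80L))
  expect_equal(nrow(tiled), 3)
})

test_that("the higher-scoring of two overlapping hits wins", {
  h <- mk_hits(c(1, 20), c(35, 54), c(12.0, 7.0))
  tiled <- tile_hits(h)
  expect_equal(nrow(tiled), 1)
  expect_equal(tiled$score, 12.0)
})

test_that("tiling rejects hits from multiple proteins", {
  h <- dplyr::bind_rows(mk_hits(1, 35, 5, id = "a"), mk_hits(1, 35, 5, id = "b"))
  expect_error(tile_hits(h), "single protein")
})

test_that("greedy tiling is maximal and within half of the optimum", {
  withr::local_seed(2024)
  for (case in 1:20) {
    n <- sample(4:10, 1)
    start <- sample(1:120, n, replace = TRUE)
    len <- sample(10:40, n, replace = TRUE)
    h <- mk_hits(start, start + len - 1, round(stats::runif(n, 1, 20), 2),
                 class = sample(c("P", "L", "S"), n, replace = TRUE))
    tiled <- tile_hits(h)
    # maximality: every rejected hit overlaps an accepted one
    for (i in seq_len(nrow(h))) {
      overlaps <- any(h$start[i] <= tiled$end & h$end[i] >= tiled$start)
      expect_true(overlaps || any(
        tiled$start == h$start[i] & tiled$end == h$end[i] &
          tiled$score == h$score[i]
      ))
    }
    expect_gte(sum(tiled$score), 0.5 * oracle_best_tiling_score(h))
  }
})

test_that("subgroup labels follow the retention and C-terminal rules", {
  expect_equal(classify_architecture(character(0)), "excluded")
  expect_equal(classify_architecture("P"), "excluded")
  expect_equal(classify_architecture(c("L", "S", "E1", "DYW")), "excluded")
  expect_equal(classify_architecture(c("P", "P", "P")), "P")
  expect_equal(classify_architecture(c("P", "L", "S", "P", "L", "S")), "PLS")
  expect_equal(classify_architecture(c("P", "L", "S", "P", "L", "S", "E1")), "E1")
  expect_equal(
    classify_architecture(c("P", "L", "S", "P", "L", "S", "E1", "E2")), "E2"
  )
  expect_equal(
    classify_architecture(c("P", "L", "S", "P", "E1", "E2", "E+")), "E+"
  )
  expect_equal(
    classify_architecture(c("P", "L", "S", "P", "L", "S", "E1", "E2", "DYW")),
    "DYW"
  )
  # DYW outranks other extensions in the C-terminal block
  expect_equal(classify_architecture(c("P", "P", "E1", "DYW")), "DYW")
  # orphan extension after a pure P tract still names the subgroup
  expect_equal(classify_architecture(c("P", "P", "E2")), "E2")
  # extensions buried before the last repeat are ignored
  expect_equal(classify_architecture(c("P", "E1", "P", "L", "S")), "PLS")
})

test_that("classification is idempotent and assigns exactly one label each", {
  sim <- simulate_ppr_proteins(watermelon_family_templates(0.05), seed = 5)
  small <- sim$proteins[seq(1, 422, by = 8), ]
  a1 <- classify_proteins(small)
  a2 <- classify_proteins(small)
  expect_identical(a1, a2)
  expect_equal(nrow(a1), nrow(small))
  expect_true(all(a1$label %in% c("excluded", "P", "PLS", "E1", "E2", "E+", "DYW")))
})

test_that("family summary conserves counts and rolls up subfamilies", {
  arch <- tibble::tibble(
    protein_id = sprintf("p%02d", 1:12),
    label = c("P", "P", "PLS", "E1", "E2", "E2", "E+", "DYW", "DYW", "DYW",
              "excluded", "excluded"),
    motif_string = "",
    p_count = c(rep(4L, 10), 1L, 0L),
    total_motifs = c(rep(8L, 10), 1L, 0L)
  )
  fs <- family_summary(arch)
  expect_equal(fs$n_total, 12)
  expect_equal(fs$n_excluded, 2)
  expect_equal(fs$n_retained, 10)
  expect_equal(sum(fs$label_counts$n), fs$n_retained)
  expect_equal(fs$subfamily_counts$n, c(2, 8))
  expect_equal(sum(fs$motif_histogram$n), fs$n_retained)
  g <- glance(fs)
  expect_equal(g$n_p_subfamily + g$n_pls_subfamily, g$n_retained)
  td <- tidy(fs)
  expect_equal(sum(td$proportion), 1)
})

test_that("an empty family yields an all-zero summary", {
  arch <- tibble::tibble(
    protein_id = character(), label = character(),
    motif_string = character(), p_count = integer(), total_motifs = integer()
  )
  fs <- family_summary(arch)
  expect_equal(fs$n_total, 0)
  expect_true(all(fs$label_counts$n == 0))
})

test_that("motif-count histogram modes fall in the planted ranges", {
  counts <- c(P = 40, PLS = 5, E1 = 2, E2 = 15, `E+` = 3, DYW = 15)
  sim <- simulate_ppr_proteins(
    watermelon_family_templates(0, counts = counts), seed = 77
  )
  fs <- family_summary(classify_proteins(sim$proteins))
  hist <- fs$motif_histogram
  p_counts <- hist$total_motifs[hist$subfamily == "P"]
  pls_counts <- hist$total_motifs[hist$subfamily == "PLS"]
  expect_true(all(p_counts >= 7 & p_counts <= 12))
  expect_true(all(pls_counts >= 13 & pls_counts <= 17))
})

test_that("architectures can be labeled from an imported hit table", {
  sim <- simulate_ppr_proteins(
    dplyr::bind_rows(
      architecture_template("P", rep("P", 6), 2),
      architecture_template("DYW", c("P", "L", "S", "P", "E1", "E2", "E+", "DYW"), 2)
    ),
    seed = 9
  )
  hits <- scan_proteins(sim$proteins)
  arch <- classify_hits(hits)
  expect_equal(nrow(arch), 4)
  expect_equal(
    arch$label[match(sim$truth$protein_id, arch$protein_id)],
    sim$truth$label
  )
})

test_that("genes are named sequentially along the genome", {
  tbl <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    chromosome = c("chr02", "chr01", "chr01"),
    position = c(50L, 900L, 100L)
  )
  named <- name_by_position(tbl, prefix = "ClPPR")
  expect_equal(named$gene_id, c("g3", "g2", "g1"))
  expect_equal(named$family_name, c("ClPPR1", "ClPPR2", "ClPPR3"))
})
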