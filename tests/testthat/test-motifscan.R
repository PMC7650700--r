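test_that("profile weights follow the log-odds formula (hand arithmetic)", {
  seeds <- c("AAAAAAAAAC", "AAAAAAAAAC", "AAAAAAAAAD")
  p <- build_profile(seeds, "toy", pseudocount = 1)
  # column 10: C appears 2/3, D 1/3, others 0/3; n = 3, 20 residues
  expect_equal(unname(p$weights["C", 10]), log((2 + 1) / (3 + 20)) - log(1 / 20))
  expect_equal(unname(p$weights["D", 10]), log((1 + 1) / (3 + 20)) - log(1 / 20))
  expect_equal(unname(p$weights["E", 10]), log((0 + 1) / (3 + 20)) - log(1 / 20))
  # column 1: all A
  expect_equal(unname(p$weights["A", 1]), log((3 + 1) / (3 + 20)) - log(1 / 20))
})

test_that("single-seed profiles are dominated by the seed sequence", {
  seed <- "MKLVNNPQRSTWYACDEFGH"
  p <- build_profile(seed, "toy")
  expect_equal(p$consensus, seed)
  # consensus score equals the sum of per-position maxima by definition
  maxima <- apply(p$weights[1:20, ], 2, max)
  expect_equal(p$max_score, sum(maxima))
  expect_equal(oracle_scan_scores(seed, p), p$max_score)
})

test_that("profile construction rejects ragged or non-standard input", {
  expect_error(build_profile(c("AAAAAAAAAA", "AAAAAAAAAAA"), "x"), "same length")
  expect_error(build_profile("AAAAAAAAAJ", "x"), "non-standard")
  expect_error(build_profile("AAAAAAAAA", "x"), "at least 10")
  expect_error(build_profile(character(0), "x"), "at least one")
})

test_that("a tandem array of P consensus units is hit at each unit offset", {
  profs <- ppr_profiles()
  unit <- PPR_LENGTH <- nchar(ppr_consensus()$consensus[1])
  seq4 <- strrep(ppr_consensus()$consensus[1], 4)
  hits <- scan_protein(seq4, profs)
  p_hits <- hits[hits$motif_class == "P", ]
  expect_true(all(c(1, 36, 71, 106) %in% p_hits$start))
  # unit-offset hits score maximally
  expect_equal(
    p_hits$score[p_hits$start %in% c(1, 36, 71, 106)],
    rep(profs$P$max_score, 4)
  )
})

test_that("sequences shorter than every profile yield an empty hit table", {
  hits <- scan_protein("MKLVNNPQRS", ppr_profiles())
  expect_equal(nrow(hits), 0)
  expect_named(hits, c("protein_id", "motif_class", "start", "end", "score"))
})

test_that("scanning equals exhaustive window scoring on random sequences", {
  withr::local_seed(404)
  profs <- ppr_profiles()[c("P", "S", "DYW")]
  total_hits <- 0
  total_res <- 0
  for (i in 1:30) {
    sq <- random_protein(300)
    total_res <- total_res + 300
    hits <- scan_protein(sq, profs)
    for (p in profs) {
      sc <- oracle_scan_scores(sq, p)
      expected_starts <- which(sc >= p$threshold)
      got <- hits[hits$motif_class == p$motif_class, ]
      expect_equal(got$start, expected_starts)
      if (length(expected_starts) > 0) {
        expect_equal(got$score, sc[expected_starts], tolerance = 1e-12)
      }
      total_hits <- total_hits + length(expected_starts)
    }
  }
  # chance-hit calibration: at most 0.1 false hits per 1,000 residues
  expect_lte(total_hits / (total_res / 1000), 0.1)
})

test_that("hit coordinates shift with a sequence prefix, scores unchanged", {
  withr::local_seed(7)
  profs <- ppr_profiles()[c("P", "E2")]
  core <- paste0(
    PPR_CONS <- ppr_consensus()$consensus[1],
    ppr_consensus()$consensus[5]
  )
  prefix <- random_protein(17)
  h0 <- scan_protein(core, profs)
  h1 <- scan_protein(paste0(prefix, core), profs)
  h1_core <- h1[h1$start > 17 - 35, ] # ignore chance hits inside the prefix
  expect_equal(h1_core$start, h0$start + 17)
  expect_equal(h1_core$score, h0$score)
})

test_that("domtblout rows are parsed, mapped and E-value filtered", {
  dom <- c(
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------",
    "prot1 - 400 PPR_P - 35 1e-20 60.1 0.1 1 2 1e-12 1e-10 30.2 0.0 1 35 10 44 8 46 0.95 -",
    "prot1 - 400 PPR_P - 35 1e-20 60.1 0.1 2 2 1e-11 2e-09 28.7 0.0 1 35 50 84 48 86 0.95 -",
    "prot2 - 300 PPR_DYW - 100 0.2 8.0 0.1 1 1 0.3 0.5 7.0 0.0 1 90 10 99 5 104 0.70 -"
  )
  path <- withr::local_tempfile(fileext = ".domtbl")
  writeLines(dom, path)
  hits <- read_hmmer_domtbl(path, c(P = "PPR_P", DYW = "PPR_DYW"))
  # the i-Evalue 0.5 row fails the default 0.1 cutoff
  expect_equal(nrow(hits), 2)
  expect_equal(hits$protein_id, c("prot1", "prot1"))
  expect_equal(hits$motif_class, c("P", "P"))
  expect_equal(hits$start, c(8L, 48L))   # envelope coordinates
  expect_equal(hits$end, c(46L, 86L))

  # comments-only file is empty, not an error
  empty <- withr::local_tempfile(fileext = ".domtbl")
  writeLines("# nothing here", empty)
  expect_equal(nrow(read_hmmer_domtbl(empty, c(P = "PPR_P"))), 0)

  # unmapped query names are reported
  expect_error(read_hmmer_domtbl(path, c(P = "PPR_P")), "PPR_DYW")

  # truncated rows are reported with their line number
  bad <- withr::local_tempfile(fileext = ".domtbl")
  writeLines(c(dom[3], "prot3 - 400 PPR_P"), bad)
  expect_error(read_hmmer_domtbl(bad, c(P = "PPR_P")), "2")
})

test_that("hit tables round-trip through the tab-separated format", {
  withr::local_seed(12)
  sim <- simulate_ppr_proteins(
    architecture_template("P", rep("P", 4), 2), seed = 12
  )
  hits <- scan_proteins(sim$proteins)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_motif_hits(hits, path)
  expect_equal(read_motif_hits(path), hits)
})
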