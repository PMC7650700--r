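test_that("the bundled enzyme table is well-formed", {
  enz <- restriction_enzymes()
  expect_gte(nrow(enz), 30)
  expect_true(all(nchar(enz$pattern) >= 4))
  expect_true(all(enz$cut_offset >= 0 & enz$cut_offset <= nchar(enz$pattern)))
})

test_that("restriction sites are found with IUPAC semantics", {
  # EcoRI in a 10-mer
  hits <- find_sites("AAGAATTCTT", "GAATTC")
  expect_equal(hits$start, 3L)
  expect_equal(hits$end, 8L)
  # HinfI GANTC matches any middle base
  expect_equal(find_sites("AAGATTCAA", "GANTC")$start, 3L)
  expect_equal(find_sites("AAGACTCAA", "GANTC")$start, 3L)
  # N in the sequence never matches, even against pattern N
  expect_equal(nrow(find_sites("AAGANTCAA", "GANTC")), 0)
  # overlapping occurrences are all reported
  expect_equal(find_sites("CCCGGG", "CCNGG")$start, c(1L, 2L))
  # invalid pattern letters are rejected
  expect_error(find_sites("ACGT", "GAQTC"), "IUPAC")
})

test_that("non-palindromic patterns are scanned on both strands", {
  enz <- list(name = "toy", pattern = "GGTGA", cut_offset = 1L)
  # plus-strand site at 3; reverse complement TCACC at 11
  hits <- find_sites("AAGGTGAAAATCACCAA", enz)
  expect_equal(hits$strand, c("+", "-"))
  expect_equal(hits$start, c(3L, 11L))
  # palindromic pattern reported once per locus
  expect_equal(nrow(find_sites("AAGAATTCTT", "GAATTC")), 1)
})

test_that("site finding equals brute-force IUPAC matching on random sequences", {
  withr::local_seed(2001)
  patterns <- c("GAATTC", "GANTC", "CCWWGG", "GGTGA", "RAATTY")
  for (i in 1:100) {
    sq <- random_dna(80)
    pat <- sample(patterns, 1)
    got <- find_sites(sq, pat)
    plus <- oracle_iupac_starts(sq, pat)
    rc <- oracle_revcomp(pat)
    minus <- if (rc == pat) integer(0) else oracle_iupac_starts(sq, rc)
    expect_equal(got$start[got$strand == "+"], plus)
    expect_equal(got$start[got$strand == "-"], minus)
  }
})

test_that("class-specific SNP filtering matches the brute-force oracle exactly", {
  panel <- toy_panel(seed = 301, planted = 2, background = 40)
  for (cls in c("red", "yellow", "orange")) {
    got <- class_specific_snps(panel, cls)
    expect_setequal(got$variant_id, oracle_class_specific(panel, cls))
    # planted set recovered exactly: precision = recall = 1
    expect_setequal(
      got$variant_id,
      panel$truth$variant_id[panel$truth$class == cls]
    )
    # supporting counts cover the whole panel at zero missingness
    expect_true(all(got$n_class + got$n_other == 70))
  }
})

test_that("heterozygotes and fixed variants fail the three criteria", {
  panel <- toy_panel(seed = 302, planted = 1, background = 0)
  v <- panel$truth$variant_id[1]
  cls <- panel$truth$class[1]
  in_acc <- panel$phenotypes$accession[panel$phenotypes$class == cls]
  # one heterozygote inside the class breaks criterion (1)
  het <- panel
  het$calls[v, in_acc[1]] <- "0/1"
  expect_false(v %in% class_specific_snps(het, cls)$variant_id)
  # a variant homozygous-ref everywhere fails criterion (3)
  fixed <- panel
  fixed$calls[v, ] <- "0/0"
  expect_equal(nrow(class_specific_snps(fixed, cls)), 0)
  expect_error(class_specific_snps(panel, "purple"), "Unknown")
})

test_that("missing calls are tolerated up to the configured fraction", {
  panel <- toy_panel(seed = 303, planted = 1, background = 0)
  v <- panel$truth$variant_id[1]
  cls <- panel$truth$class[1]
  in_acc <- panel$phenotypes$accession[panel$phenotypes$class == cls]
  panel$calls[v, in_acc[1]] <- "./."
  expect_false(v %in% class_specific_snps(panel, cls)$variant_id)
  got <- class_specific_snps(panel, cls, max_missing_fraction = 0.1)
  expect_true(v %in% got$variant_id)
  expect_equal(got$n_class[got$variant_id == v], length(in_acc) - 1L)
  expect_setequal(
    got$variant_id,
    oracle_class_specific(panel, cls, max_missing = 0.1)
  )
})

test_that("allele substitution into a flank is exact and involutive", {
  expect_equal(apply_snp_to_flank("AAGAATTTTT", 7, "T", "C"), "AAGAATCTTT")
  expect_error(apply_snp_to_flank("AAGAATTTTT", 7, "G", "C"), "expected G")
  expect_error(apply_snp_to_flank("AAGAATTTTT", 99, "T", "C"), "outside")
  alt <- apply_snp_to_flank("AAGAATTTTT", 7, "T", "C")
  expect_equal(apply_snp_to_flank(alt, 7, "C", "T"), "AAGAATTTTT")
})

test_that("a SNP completing a recognition site becomes a CAPS candidate", {
  withr::local_seed(41)
  left <- random_dna(20)
  right <- random_dna(20)
  # ref carries GAATTT; the T>C SNP at position 26 completes EcoRI GAATTC
  flank <- paste0(left, "GAATTT", right)
  cand <- snp_to_caps(flank, 26, "T", "C",
                      enzymes = restriction_enzymes()[1:10, ])
  ecor <- cand[cand$enzyme == "EcoRI", ]
  expect_equal(nrow(ecor), 1)
  expect_equal(ecor$allele_with_site, "alt")
  expect_equal(ecor$site_position, 21L)
  expect_equal(sum(ecor$fragments_alt[[1]]), nchar(flank))
  expect_equal(ecor$fragments_ref[[1]], nchar(flank))
})

test_that("sites not covering the SNP never create candidates", {
  # constant EcoRI site 30 bp from a SNP that touches no pattern
  flank <- paste0(
    strrep("A", 25), "GAATTC", strrep("A", 24), "T", strrep("A", 30)
  )
  snp_pos <- 25 + 6 + 24 + 1
  expect_equal(substr(flank, snp_pos, snp_pos), "T")
  cand <- snp_to_caps(flank, snp_pos, "T", "G",
                      enzymes = restriction_enzymes()[1:5, ])
  expect_equal(nrow(cand), 0)
})

test_that("flanks too short to scan every placement are rejected", {
  expect_error(
    snp_to_caps("ACGTACGTA", 2, "C", "G", enzymes = restriction_enzymes()),
    "Flank too short"
  )
})

test_that("fragment prediction partitions the amplicon", {
  ecor <- list(name = "EcoRI", pattern = "GAATTC", cut_offset = 1L)
  expect_equal(predict_fragments("ACGTACGTACGT", ecor), 12L)
  # site at position 3, cut offset 1: cut after base 3 -> fragments 3 and 9
  expect_equal(predict_fragments("AAGAATTCTTTT", ecor), c(9L, 3L))
  # multi-site amplicon equals the brute-force partition
  amp <- paste0("AA", "GAATTC", strrep("C", 10), "GAATTC", "TT")
  starts <- oracle_iupac_starts(amp, "GAATTC")
  cuts <- sort(starts - 1 + 1)
  expected <- sort(diff(c(0, cuts, nchar(amp))), decreasing = TRUE)
  expect_equal(predict_fragments(amp, ecor), as.integer(expected))
})

test_that("fragment lengths always sum to the amplicon length", {
  withr::local_seed(42)
  enz <- restriction_enzymes()
  for (i in 1:50) {
    amp <- random_dna(sample(50:200, 1))
    e <- as.list(enz[sample(nrow(enz), 1), ])
    expect_equal(sum(predict_fragments(amp, e)), nchar(amp))
  }
})

test_that("panel-wide candidates are differential-site sound", {
  panel <- toy_panel(seed = 305, planted = 3, background = 10)
  snps <- dplyr::bind_rows(lapply(
    c("red", "yellow", "orange"),
    function(cls) class_specific_snps(panel, cls)
  ))
  cand <- caps_candidates(panel, snps)
  snp_pos <- panel$flank_length + 1
  if (nrow(cand) > 0) {
    for (i in seq_len(nrow(cand))) {
      row <- cand[i, ]
      v <- panel$variants[panel$variants$variant_id == row$variant_id, ]
      ref_flank <- panel$flanks[[row$variant_id]]
      alt_flank <- apply_snp_to_flank(ref_flank, snp_pos, v$ref, v$alt)
      enz <- list(pattern = row$pattern, cut_offset = 0L)
      cover <- function(s) s[s$start <= snp_pos & s$end >= snp_pos, ]
      key <- function(s) paste(s$start, s$strand)
      expect_false(setequal(
        key(cover(find_sites(ref_flank, enz))),
        key(cover(find_sites(alt_flank, enz)))
      ))
      expect_equal(sum(row$fragments_ref[[1]]), nchar(ref_flank))
      expect_equal(sum(row$fragments_alt[[1]]), nchar(alt_flank))
    }
  }
  # property over random enzymes/SNPs: non-candidates really are inert
  withr::local_seed(43)
  enzymes <- restriction_enzymes()
  for (i in 1:20) {
    flank <- random_dna(61)
    ref <- substr(flank, 31, 31)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    cand2 <- snp_to_caps(flank, 31, ref, alt, enzymes)
    alt_flank <- apply_snp_to_flank(flank, 31, ref, alt)
    for (j in seq_len(nrow(enzymes))) {
      e <- as.list(enzymes[j, ])
      cover <- function(s) s[s$start <= 31 & s$end >= 31, ]
      key <- function(s) paste(s$start, s$strand)
      differs <- !setequal(
        key(cover(find_sites(flank, e))),
        key(cover(find_sites(alt_flank, e)))
      )
      expect_equal(e$name %in% cand2$enzyme, differs)
    }
  }
})
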