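# Independent brute-force oracles used to cross-check the implementation.
# Each is written as plainly as possible and shares no code with R/.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

oracle_revcomp <- function(pattern) {
  comp <- c(
    A = "T", C = "G", G = "C", T = "A", M = "K", R = "Y", W = "W",
    S = "S", Y = "R", K = "M", V = "B", H = "D", D = "H", B = "V", N = "N"
  )
  paste(rev(comp[strsplit(pattern, "")[[1]]]), collapse = "")
}

# all 1-based start positions where the IUPAC pattern matches exactly;
# any sequence letter outside ACGT (e.g. N) never matches
oracle_iupac_starts <- function(sequence, pattern) {
  sc <- strsplit(sequence, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  L <- length(pc)
  if (length(sc) < L) return(integer(0))
  out <- integer(0)
  for (s in 1:(length(sc) - L + 1)) {
    ok <- TRUE
    for (j in 1:L) {
      if (!(sc[s + j - 1] %in% IUPAC_SETS[[pc[j]]])) {
        ok <- FALSE
        break
      }
    }
    if (ok) out <- c(out, s)
  }
  out
}

# window-by-window profile scoring with explicit character loops
oracle_scan_scores <- function(sequence, profile) {
  chars <- strsplit(sequence, "")[[1]]
  L <- profile$length
  n <- length(chars)
  if (n < L) return(numeric(0))
  vapply(1:(n - L + 1), function(s) {
    tot <- 0
    for (j in 1:L) {
      a <- chars[s + j - 1]
      row <- if (a %in% rownames(profile$weights)) a else "X"
      tot <- tot + profile$weights[row, j]
    }
    tot
  }, numeric(1))
}

ORACLE_CODE <- Biostrings::GENETIC_CODE

# NG86 site counts by direct enumeration of the nine single-base mutants
oracle_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    syn <- 0
    nonstop <- 0
    for (b in bases[bases != substr(codon, pos, pos)]) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (ORACLE_CODE[[mut]] == "*") next
      nonstop <- nonstop + 1
      if (ORACLE_CODE[[mut]] == ORACLE_CODE[[codon]]) syn <- syn + 1
    }
    if (nonstop > 0) s <- s + syn / nonstop
  }
  c(s, 3 - s)
}

# NG86 pathway averaging by recursive enumeration (independent of the
# permutation-based implementation)
oracle_diffs <- function(a, b) {
  walk <- function(cur, sd, nd) {
    pos <- which(strsplit(cur, "")[[1]] != strsplit(b, "")[[1]])
    if (length(pos) == 0) return(list(c(sd, nd)))
    res <- list()
    for (p in pos) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (ORACLE_CODE[[nxt]] == "*") next
      step_syn <- ORACLE_CODE[[nxt]] == ORACLE_CODE[[cur]]
      res <- c(res, walk(nxt, sd + step_syn, nd + !step_syn))
    }
    res
  }
  paths <- walk(a, 0, 0)
  if (length(paths) == 0) return(c(NA_real_, NA_real_))
  m <- do.call(rbind, paths)
  colMeans(m)
}

# brute-force class-specific SNP filter over a genotype_panel
oracle_class_specific <- function(panel, target_class, max_missing = 0) {
  in_acc <- panel$phenotypes$accession[panel$phenotypes$class == target_class]
  out_acc <- panel$phenotypes$accession[panel$phenotypes$class != target_class]
  hits <- character(0)
  for (v in rownames(panel$calls)) {
    gi <- panel$calls[v, in_acc]
    go <- panel$calls[v, out_acc]
    if (mean(gi == "./.") > max_missing || mean(go == "./.") > max_missing) next
    gi <- gi[gi != "./."]
    go <- go[go != "./."]
    if (length(gi) == 0 || length(go) == 0) next
    ui <- unique(gi)
    uo <- unique(go)
    if (length(ui) == 1 && length(uo) == 1 &&
        ui %in% c("0/0", "1/1") && uo %in% c("0/0", "1/1") && ui != uo) {
      hits <- c(hits, v)
    }
  }
  hits
}

# exhaustive maximum-weight non-overlapping subset of <= ~12 hits
oracle_best_tiling_score <- function(hits) {
  n <- nrow(hits)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) < 2) {
      sc <- sum(hits$score[idx])
    } else {
      h <- hits[idx, ]
      ok <- TRUE
      for (i in 1:(nrow(h) - 1)) {
        for (j in (i + 1):nrow(h)) {
          if (h$start[i] <= h$end[j] && h$end[i] >= h$start[j]) {
            ok <- FALSE
            break
          }
        }
        if (!ok) break
      }
      if (!ok) next
      sc <- sum(h$score)
    }
    if (sc > best) best <- sc
  }
  best
}

# small three-class panel used across snpcaps/matchrate tests
toy_panel <- function(seed = 11, flip_rate = 0, planted = 2, background = 20) {
  simulate_genotype_panel(panel_spec(
    class_sizes = c(red = 33, yellow = 17, orange = 20),
    planted_per_class = planted,
    background_snps = background,
    flip_rate = flip_rate,
    seed = seed
  ))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein <- function(n) {
  aa <- c(
    "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
  )
  paste(sample(aa, n, replace = TRUE), collapse = "")
}
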