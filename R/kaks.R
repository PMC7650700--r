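#' @importFrom stats na.omit setNames
NULL

GENETIC_CODE_TBL <- NULL  # populated lazily from Biostrings::GENETIC_CODE

genetic_code <- function() {
  Biostrings::GENETIC_CODE
}

is_stop <- function(codon) {
  genetic_code()[[codon]] == "*"
}

#' Synonymous and nonsynonymous site counts for one codon (NG86)
#'
#' For each codon position, the synonymous-site fraction is the number of
#' the three single-base changes at that position that are synonymous and do
#' not create a stop codon, divided by the number of non-stop-producing
#' changes (the stop adjustment). The codon's `s` is the sum of the three
#' fractions and `n = 3 - s`. Standard nuclear genetic code.
#'
#' @param codon Three-letter string over `ACGT`, not a stop codon.
#' @return Named numeric vector `c(s = , n = )` with `s + n = 3`.
#' @export
#' @examples
#' count_sites("TTT")  # Phe: s = 1/3
#' count_sites("ATG")  # Met: s = 0
count_sites <- function(codon) {
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon)) {
    abort(paste0("Invalid codon (ambiguous or malformed): ", codon))
  }
  code <- genetic_code()
  if (code[[codon]] == "*") abort(paste0("Stop codon supplied: ", codon))
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    syn <- 0L
    non_stop <- 0L
    for (b in setdiff(bases, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (code[[mut]] == "*") next
      non_stop <- non_stop + 1L
      if (code[[mut]] == code[[codon]]) syn <- syn + 1L
    }
    if (non_stop > 0) s <- s + syn / non_stop
  }
  c(s = s, n = 3 - s)
}

#' Synonymous and nonsynonymous difference counts between two codons (NG86)
#'
#' Averages synonymous/nonsynonymous change counts over all minimal
#' mutational pathways between the codons (orderings of the differing
#' positions), excluding pathways that pass through a stop codon. When at
#' least one stop-free pathway exists, `sd + nd` equals the number of
#' differing positions.
#'
#' @param codon_a,codon_b Sense codons over `ACGT`.
#' @return Named numeric vector `c(sd = , nd = )`, or `c(sd = NA, nd = NA)`
#'   (with a warning) when every pathway passes through a stop codon.
#' @export
#' @examples
#' count_diffs("TTT", "TTC")  # Phe -> Phe: one synonymous difference
count_diffs <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a)
  codon_b <- toupper(codon_b)
  code <- genetic_code()
  for (cd in c(codon_a, codon_b)) {
    if (!grepl("^[ACGT]{3}$", cd)) abort(paste0("Invalid codon: ", cd))
    if (code[[cd]] == "*") abort(paste0("Stop codon supplied: ", cd))
  }
  diff_pos <- which(
    strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]]
  )
  if (length(diff_pos) == 0) return(c(sd = 0, nd = 0))

  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  sd_tot <- 0
  nd_tot <- 0
  n_valid <- 0L
  for (path in perms(diff_pos)) {
    cur <- codon_a
    sd <- 0L
    nd <- 0L
    ok <- TRUE
    for (pos in path) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(codon_b, pos, pos)
      if (code[[nxt]] == "*") {
        ok <- FALSE
        break
      }
      if (code[[nxt]] == code[[cur]]) sd <- sd + 1L else nd <- nd + 1L
      cur <- nxt
    }
    if (ok) {
      sd_tot <- sd_tot + sd
      nd_tot <- nd_tot + nd
      n_valid <- n_valid + 1L
    }
  }
  if (n_valid == 0) {
    warn(paste0(
      "No stop-free mutational pathway between ", codon_a, " and ", codon_b,
      "; codon pair skipped."
    ))
    return(c(sd = NA_real_, nd = NA_real_))
  }
  c(sd = sd_tot / n_valid, nd = nd_tot / n_valid)
}

jukes_cantor <- function(p) {
  if (is.na(p) || p >= 3 / 4) return(NA_real_)
  -(3 / 4) * log(1 - (4 / 3) * p)
}

#' Ka, Ks and omega for one codon-aligned sequence pair (NG86 + JC)
#'
#' Nei-Gojobori (1986) pathway counting with Jukes-Cantor correction:
#' synonymous (S) and nonsynonymous (N) site counts are averaged over the
#' two sequences, per-codon differences are pathway-averaged with
#' [count_diffs()], proportions `pS = Sd/S` and `pN = Nd/N` are corrected by
#' `d = -(3/4) ln(1 - (4/3) p)`, and `omega = Ka/Ks`. Codons containing a
#' gap (`-`) in either sequence are dropped before counting; codon pairs
#' with no stop-free pathway are skipped with a warning. A proportion at or
#' above 3/4 puts the correction outside its log domain and the
#' corresponding distance (and omega) is reported as `NA` with
#' `selection = "undefined"`.
#'
#' @param seq_a,seq_b Aligned nucleotide strings over `ACGT-` of equal
#'   length divisible by 3 after gap-codon dropping.
#' @param pair_id Identifier recorded in the result.
#' @return A `kaks_result`: list with `pair_id`, `n_codons`, `S`, `N`, `Sd`,
#'   `Nd`, `pS`, `pN`, `Ks`, `Ka`, `omega` and
#'   `selection` (one of `"purifying", "neutral", "positive", "undefined"`).
#' @export
#' @examples
#' r <- kaks("TTTGGAGGA", "TTCGGAGGA")
#' r$Ks > 0 && r$Ka == 0
kaks <- function(seq_a, seq_b, pair_id = "pair") {
  seq_a <- toupper(seq_a)
  seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) {
    abort("Aligned sequences must have equal length.")
  }
  if (!grepl("^[ACGT-]*$", seq_a) || !grepl("^[ACGT-]*$", seq_b)) {
    abort("Alignment alphabet must be ACGT- only.")
  }
  if (nchar(seq_a) %% 3 != 0) abort("Alignment length must be divisible by 3.")
  cod_a <- substring(seq_a, seq(1, nchar(seq_a), 3), seq(3, nchar(seq_a), 3))
  cod_b <- substring(seq_b, seq(1, nchar(seq_b), 3), seq(3, nchar(seq_b), 3))
  keep <- !grepl("-", cod_a, fixed = TRUE) & !grepl("-", cod_b, fixed = TRUE)
  cod_a <- cod_a[keep]
  cod_b <- cod_b[keep]
  if (length(cod_a) == 0) abort("Alignment is empty after dropping gap codons.")
  code <- genetic_code()
  if (any(code[cod_a] == "*") || any(code[cod_b] == "*")) {
    abort("Internal stop codon in alignment after gap dropping.")
  }
  sites_a <- vapply(cod_a, count_sites, numeric(2))
  sites_b <- vapply(cod_b, count_sites, numeric(2))
  S <- (sum(sites_a["s", ]) + sum(sites_b["s", ])) / 2
  N <- (sum(sites_a["n", ]) + sum(sites_b["n", ])) / 2
  diffs <- vapply(
    seq_along(cod_a),
    function(i) count_diffs(cod_a[i], cod_b[i]),
    numeric(2)
  )
  Sd <- sum(diffs["sd", ], na.rm = TRUE)
  Nd <- sum(diffs["nd", ], na.rm = TRUE)
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  Ks <- jukes_cantor(pS)
  Ka <- jukes_cantor(pN)
  omega <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  selection <- if (is.na(omega)) {
    "undefined"
  } else if (omega < 1) {
    "purifying"
  } else if (omega > 1) {
    "positive"
  } else {
    "neutral"
  }
  structure(
    list(
      pair_id = pair_id, n_codons = length(cod_a),
      S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
      Ks = Ks, Ka = Ka, omega = omega, selection = selection
    ),
    class = "kaks_result"
  )
}

#' @method print kaks_result
#' @export
print.kaks_result <- function(x, ...) {
  cat(
    "<kaks_result> ", x$pair_id, ": Ka = ", format(x$Ka, digits = 4),
    ", Ks = ", format(x$Ks, digits = 4),
    ", omega = ", format(x$omega, digits = 4),
    " (", x$selection, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a Ka/Ks result into a one-row tibble
#'
#' @param x A `kaks_result`.
#' @param ... Unused.
#' @return One-row tibble with all count, rate and flag fields.
#' @export
tidy.kaks_result <- function(x, ...) {
  tibble(
    pair_id = x$pair_id, n_codons = x$n_codons,
    S = x$S, N = x$N, Sd = x$Sd, Nd = x$Nd,
    pS = x$pS, pN = x$pN, Ks = x$Ks, Ka = x$Ka,
    omega = x$omega, selection = x$selection
  )
}

#' @rdname tidy.kaks_result
#' @export
glance.kaks_result <- function(x, ...) {
  tibble(Ka = x$Ka, Ks = x$Ks, omega = x$omega, selection = x$selection)
}

#' Ka/Ks for a table of codon-aligned pairs
#'
#' @param pairs Tibble with columns `pair_id`, `seq_a`, `seq_b` (e.g. from
#'   [simulate_coding_pairs()]).
#' @return Tibble with one [kaks()] result row per pair.
#' @export
kaks_pairs <- function(pairs) {
  stopifnot(all(c("pair_id", "seq_a", "seq_b") %in% names(pairs)))
  purrr::pmap_dfr(
    pairs[, c("pair_id", "seq_a", "seq_b")],
    function(pair_id, seq_a, seq_b) tidy(kaks(seq_a, seq_b, pair_id))
  )
}
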