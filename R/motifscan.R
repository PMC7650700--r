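#' Build a position-specific log-odds profile for one motif class
#'
#' Turns an ungapped alignment of seed motif instances into a
#' position-specific scoring matrix of log-odds weights against a uniform
#' 1/20 amino-acid background:
#' `w[a, j] = log((count[a, j] + pseudocount) / (n + 20 * pseudocount)) - log(1/20)`.
#'
#' The reporting threshold, when not given, is calibrated so that the
#' expected number of chance hits on uniform-random sequence stays well
#' below 0.1 per 1,000 residues: the exact distribution of the window score
#' under the uniform background is computed by convolving the per-position
#' score distributions on a 0.01 grid, and the threshold is the smallest
#' score whose upper-tail probability is at most `1e-7` per window
#' (about 1e-4 expected chance hits per 1,000 residues), plus half a grid
#' step per position against rounding drift.
#'
#' @param seeds Character vector of equal-length amino-acid sequences.
#' @param motif_class Motif class label, one of
#'   `"P", "L", "S", "E1", "E2", "E+", "DYW"` (other labels are allowed for
#'   custom profiles).
#' @param pseudocount Additive pseudocount per residue (default 1).
#' @param threshold Minimum window score to report; `NULL` (default) uses
#'   the calibrated chance-hit threshold described above.
#' @return An object of class `motif_profile`: a list with elements
#'   `motif_class`, `length`, `weights` (21 x length matrix; row 21 is the
#'   zero-weight row used for degenerate residues), `threshold`,
#'   `max_score` (score of the per-position argmax sequence) and
#'   `consensus` (that argmax sequence).
#' @export
#' @examples
#' p <- build_profile("ACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQR", "P")
#' p$length
build_profile <- function(seeds, motif_class, pseudocount = 1, threshold = NULL) {
  if (length(seeds) < 1) abort("`seeds` must contain at least one sequence.")
  seeds <- toupper(seeds)
  lens <- nchar(seeds)
  if (length(unique(lens)) != 1) {
    abort("All seed sequences must have the same length (ragged alignment).")
  }
  len <- lens[[1]]
  if (len < 10) abort("Profile length must be at least 10 residues.")
  mat <- do.call(rbind, strsplit(seeds, "", fixed = TRUE))
  if (!all(mat %in% AA_ALPHABET)) {
    bad <- sort(unique(mat[!(mat %in% AA_ALPHABET)]))
    abort(paste0(
      "Seed sequences contain non-standard amino-acid symbols: ",
      paste(bad, collapse = ", ")
    ))
  }
  n <- length(seeds)
  counts <- vapply(
    seq_len(len),
    function(j) tabulate(match(mat[, j], AA_ALPHABET), nbins = 20L),
    numeric(20)
  )
  w <- log((counts + pseudocount) / (n + 20 * pseudocount)) - log(1 / 20)
  weights <- rbind(w, 0)  # row 21: degenerate residues score as background
  rownames(weights) <- c(AA_ALPHABET, "X")

  # Chance-hit calibration: exact tail of the window-score distribution
  # under the uniform background (see calibrate_threshold).
  mu_j <- colMeans(w)
  var_j <- colMeans(w^2) - mu_j^2
  rand_mean <- sum(mu_j)
  rand_sd <- sqrt(sum(var_j))
  if (is.null(threshold)) {
    threshold <- calibrate_threshold(w, p_window = 1e-7)
  }
  if (!is.finite(threshold)) abort("Profile threshold must be finite.")

  consensus_idx <- apply(w, 2, which.max)
  structure(
    list(
      motif_class = motif_class,
      length = len,
      weights = weights,
      threshold = threshold,
      max_score = sum(w[cbind(consensus_idx, seq_len(len))]),
      consensus = paste(AA_ALPHABET[consensus_idx], collapse = ""),
      random_mean = rand_mean,
      random_sd = rand_sd
    ),
    class = "motif_profile"
  )
}

#' @method print motif_profile
#' @export
print.motif_profile <- function(x, ...) {
  cat(
    "<motif_profile> class ", x$motif_class, ", length ", x$length,
    ", threshold ", format(x$threshold, digits = 4),
    ", max score ", format(x$max_score, digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Default scanning profiles for the seven PPR motif classes
#'
#' Builds one [build_profile()] log-odds profile per motif class from the
#' bundled consensus sequences ([ppr_consensus()]).
#'
#' @param pseudocount Pseudocount forwarded to [build_profile()].
#' @return Named list of `motif_profile` objects, one per motif class.
#' @export
ppr_profiles <- function(pseudocount = 1) {
  profs <- lapply(names(PPR_CONSENSUS), function(cl) {
    build_profile(PPR_CONSENSUS[[cl]], cl, pseudocount = pseudocount)
  })
  names(profs) <- names(PPR_CONSENSUS)
  profs
}

# Scores of every window of length ncol-of-weights along an integer-encoded
# sequence; vectorized over windows (one indexed lookup per profile column).
score_windows <- function(seq_idx, weights) {
  len <- ncol(weights)
  n <- length(seq_idx)
  if (n < len) return(numeric(0))
  nw <- n - len + 1L
  s <- numeric(nw)
  for (j in seq_len(len)) {
    s <- s + unname(weights[seq_idx[j:(j + nw - 1L)], j])
  }
  s
}

# Exact upper-tail quantile of the window score under the uniform 1/20
# background: the per-position score distributions (20 equiprobable weights
# each) are convolved on a 0.01 grid, and the smallest score whose tail
# probability is <= p_window is returned.
calibrate_threshold <- function(w, p_window) {
  res <- 0.01
  wi <- round(w / res)
  dist <- 1
  base <- 0
  for (j in seq_len(ncol(wi))) {
    vals <- wi[, j]
    mn <- min(vals)
    base <- base + mn
    shifted <- vals - mn
    nd <- numeric(length(dist) + max(shifted))
    for (v in shifted) {
      idx <- seq_along(dist) + v
      nd[idx] <- nd[idx] + dist / 20
    }
    dist <- nd
  }
  tail_p <- rev(cumsum(rev(dist)))
  k <- which(tail_p <= p_window)[1]
  if (is.na(k)) k <- length(dist) + 1L
  # half a grid step per position guards against rounding drift
  (base + k - 1) * res + res / 2 * ncol(wi)
}

#' Scan one protein sequence for motif occurrences
#'
#' Slides every profile along the sequence and reports each window whose
#' log-odds score reaches the profile threshold. Overlapping hits are
#' allowed at this stage; use [tile_hits()] to resolve them into an
#' architecture.
#'
#' @param sequence Amino-acid string (length >= 1). Degenerate residues
#'   (X, B, Z, ...) score as background (0 log-odds).
#' @param profiles Named list of `motif_profile` objects (must be
#'   non-empty), e.g. from [ppr_profiles()].
#' @param protein_id Identifier recorded in the output (default `"protein"`).
#' @return Tibble of hits with columns `protein_id`, `motif_class`, `start`,
#'   `end` (1-based inclusive residue coordinates) and `score`, sorted by
#'   `(start, motif_class)`. A sequence shorter than every profile yields
#'   zero rows.
#' @export
#' @examples
#' prof <- ppr_profiles()
#' seq4 <- strrep(ppr_consensus()$consensus[1], 4)
#' scan_protein(seq4, prof)
scan_protein <- function(sequence, profiles, protein_id = "protein") {
  if (length(profiles) == 0) abort("`profiles` must contain at least one profile.")
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) < 1) {
    abort("`sequence` must be a single non-empty string.")
  }
  seq_idx <- aa_encode(sequence)
  hits <- purrr::map_dfr(profiles, function(p) {
    s <- score_windows(seq_idx, p$weights)
    keep <- which(s >= p$threshold)
    tibble(
      protein_id = protein_id,
      motif_class = p$motif_class,
      start = keep,
      end = keep + p$length - 1L,
      score = s[keep]
    )
  })
  arrange(hits, .data$start, .data$motif_class)
}

#' Scan a table of proteins for motif occurrences
#'
#' @param proteins Data frame with columns `protein_id` and `sequence`.
#' @param profiles Named list of `motif_profile` objects
#'   (default [ppr_profiles()]).
#' @return Tibble of hits as in [scan_protein()], one block per protein.
#' @export
scan_proteins <- function(proteins, profiles = ppr_profiles()) {
  stopifnot(all(c("protein_id", "sequence") %in% names(proteins)))
  purrr::map2_dfr(
    proteins$protein_id, proteins$sequence,
    function(id, sq) scan_protein(sq, profiles, protein_id = id)
  )
}

#' Read motif hits from a HMMER3 per-domain table (domtblout)
#'
#' Parses the whitespace-delimited per-domain tabular output of `hmmsearch
#' --domtblout`, mapping model (query) names to motif classes and dropping
#' domains whose independent E-value exceeds the cutoff (default 0.1).
#' Envelope coordinates are used as the hit span.
#'
#' @param path Path to a HMMER3 domtblout file.
#' @param class_map Named character vector mapping motif class to the model
#'   name used in the file, e.g. `c(P = "PPR_P", L = "PPR_L")`.
#' @param max_ievalue Maximum independent E-value to retain (default 0.1).
#' @return Tibble with columns `protein_id`, `motif_class`, `start`, `end`,
#'   `score`, sorted by `(protein_id, start, motif_class)`.
#' @export
read_hmmer_domtbl <- function(path, class_map, max_ievalue = 0.1) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(
      protein_id = character(), motif_class = character(),
      start = integer(), end = integer(), score = double()
    ))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  n_fields <- lengths(fields)
  if (any(n_fields < 22)) {
    abort(paste0(
      "Malformed domtblout: line(s) ",
      paste(which(n_fields < 22), collapse = ", "),
      " have fewer than 22 columns."
    ))
  }
  rows <- tibble(
    protein_id = purrr::map_chr(fields, 1),
    query = purrr::map_chr(fields, 4),
    i_evalue = as.numeric(purrr::map_chr(fields, 13)),
    score = as.numeric(purrr::map_chr(fields, 14)),
    start = as.integer(purrr::map_chr(fields, 20)),
    end = as.integer(purrr::map_chr(fields, 21))
  )
  unmapped <- setdiff(unique(rows$query), unname(class_map))
  if (length(unmapped) > 0) {
    abort(paste0(
      "domtblout query name(s) not in `class_map`: ",
      paste(unmapped, collapse = ", ")
    ))
  }
  inv_map <- stats::setNames(names(class_map), unname(class_map))
  rows |>
    filter(.data$i_evalue < max_ievalue) |>
    mutate(motif_class = unname(inv_map[.data$query])) |>
    select("protein_id", "motif_class", "start", "end", "score") |>
    arrange(.data$protein_id, .data$start, .data$motif_class)
}

#' Write / read a motif hit table in the package tab-separated format
#'
#' Columns: `protein_id`, `motif_class`, `start`, `end`, `score`.
#'
#' @param hits Tibble of motif hits.
#' @param path File path.
#' @return `write_motif_hits()` returns `path` invisibly;
#'   `read_motif_hits()` returns the hit tibble.
#' @export
write_motif_hits <- function(hits, path) {
  utils::write.table(
    hits, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_motif_hits
#' @export
read_motif_hits <- function(path) {
  as_tibble(utils::read.table(
    path,
    header = TRUE, sep = "\t",
    colClasses = c("character", "character", "integer", "integer", "numeric")
  ))
}
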