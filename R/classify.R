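#' Resolve overlapping motif hits into a tiled architecture
#'
#' Greedy selection: hits are ranked by score (descending), then start
#' (ascending), then motif class (alphabetical), and accepted when they
#' overlap no previously accepted hit. The result is maximal (no rejected
#' hit could still be added) and fully reproducible under the stated
#' tie-break; it is a greedy, not necessarily optimal, weighted interval
#' selection.
#'
#' @param hits Tibble of motif hits for a single protein (columns
#'   `protein_id`, `motif_class`, `start`, `end`, `score`).
#' @return The accepted hits, sorted by `start`.
#' @export
tile_hits <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  if (length(unique(hits$protein_id)) > 1) {
    abort("`tile_hits()` expects hits from a single protein.")
  }
  ord <- hits[order(-hits$score, hits$start, hits$motif_class), ]
  acc_start <- integer(0)
  acc_end <- integer(0)
  keep <- logical(nrow(ord))
  for (i in seq_len(nrow(ord))) {
    s <- ord$start[i]
    e <- ord$end[i]
    if (!any(s <= acc_end & e >= acc_start)) {
      keep[i] <- TRUE
      acc_start <- c(acc_start, s)
      acc_end <- c(acc_end, e)
    }
  }
  out <- ord[keep, ]
  out[order(out$start), ]
}

#' Assign a subfamily/subgroup label to a tiled motif architecture
#'
#' Implements the retention and subgroup rules used for plant PPR families:
#' proteins with fewer than two P motifs are `excluded`; pure P tracts are
#' subfamily `P`; otherwise the protein belongs to the PLS subfamily and its
#' subgroup is named by the highest-priority extension motif
#' (`DYW > E+ > E2 > E1`) found C-terminal of the last P/L/S repeat, falling
#' back to `PLS` when no extension follows the repeat tract.
#'
#' @param motif_classes Character vector of motif-class symbols in N- to
#'   C-terminal (start) order, e.g. `c("P","L","S","E1")`.
#' @return One of `"excluded", "P", "PLS", "E1", "E2", "E+", "DYW"`.
#' @export
#' @examples
#' classify_architecture(c("P", "P", "P"))
#' classify_architecture(c("P", "L", "S", "P", "L", "S", "E1", "E2", "DYW"))
classify_architecture <- function(motif_classes) {
  p_count <- sum(motif_classes == "P")
  if (p_count < 2) return("excluded")
  ext <- c("E1", "E2", "E+", "DYW")
  if (!any(motif_classes %in% c("L", "S", ext))) return("P")
  repeat_pos <- which(motif_classes %in% c("P", "L", "S"))
  tail_classes <- if (max(repeat_pos) < length(motif_classes)) {
    motif_classes[(max(repeat_pos) + 1):length(motif_classes)]
  } else {
    character(0)
  }
  for (cl in c("DYW", "E+", "E2", "E1")) {
    if (cl %in% tail_classes) return(cl)
  }
  "PLS"
}

#' Scan, tile and label a table of proteins
#'
#' End-to-end classification: each protein is scanned against the profiles,
#' overlapping hits are tiled with [tile_hits()], and the architecture is
#' labeled with [classify_architecture()].
#'
#' @param proteins Tibble with `protein_id` and `sequence`.
#' @param profiles Named list of `motif_profile` objects
#'   (default [ppr_profiles()]).
#' @return Tibble with one row per protein: `protein_id`, `label`,
#'   `motif_string` (comma-separated tiled classes), `p_count`,
#'   `total_motifs`.
#' @export
classify_proteins <- function(proteins, profiles = ppr_profiles()) {
  stopifnot(all(c("protein_id", "sequence") %in% names(proteins)))
  rows <- purrr::map2(
    proteins$protein_id, proteins$sequence,
    function(id, sq) {
      tiled <- tile_hits(scan_protein(sq, profiles, protein_id = id))
      cls <- tiled$motif_class
      tibble(
        protein_id = id,
        label = classify_architecture(cls),
        motif_string = paste(cls, collapse = ","),
        p_count = sum(cls == "P"),
        total_motifs = length(cls)
      )
    }
  )
  bind_rows(rows)
}

#' Label architectures from a precomputed hit table
#'
#' Like [classify_proteins()] but starting from motif hits (e.g. imported
#' with [read_hmmer_domtbl()]) instead of sequences.
#'
#' @param hits Tibble of motif hits covering one or more proteins.
#' @return Architecture tibble as in [classify_proteins()].
#' @export
classify_hits <- function(hits) {
  hits |>
    group_by(.data$protein_id) |>
    group_modify(function(df, key) {
      tiled <- tile_hits(mutate(df, protein_id = key$protein_id))
      cls <- tiled$motif_class
      tibble(
        label = classify_architecture(cls),
        motif_string = paste(cls, collapse = ","),
        p_count = sum(cls == "P"),
        total_motifs = length(cls)
      )
    }) |>
    ungroup()
}

#' Summarize a classified PPR family
#'
#' Tallies subgroup labels (excluded proteins counted separately), rolls the
#' PLS-subfamily subgroups (PLS, E1, E2, E+, DYW) into a subfamily total,
#' and histograms motif counts per subfamily. When gene models are supplied
#' (a tibble with `gene_id` matching `protein_id` and a `chromosome`
#' column), per-chromosome counts are joined in.
#'
#' @param architectures Architecture tibble from [classify_proteins()].
#' @param gene_models Optional tibble with `gene_id` and `chromosome`.
#' @return A `ppr_family_summary` object with elements `label_counts`,
#'   `subfamily_counts`, `motif_histogram`, `n_total`, `n_retained`,
#'   `n_excluded` and optionally `chromosome_counts`.
#' @export
family_summary <- function(architectures, gene_models = NULL) {
  labs <- c("P", "PLS", "E1", "E2", "E+", "DYW")
  label_counts <- architectures |>
    filter(.data$label != "excluded") |>
    count(.data$label) |>
    right_join(tibble(label = labs), by = "label") |>
    mutate(n = tidyr::replace_na(.data$n, 0L)) |>
    arrange(match(.data$label, labs))
  n_excluded <- sum(architectures$label == "excluded")
  n_retained <- nrow(architectures) - n_excluded
  subfam <- tibble(
    subfamily = c("P", "PLS"),
    n = c(
      label_counts$n[label_counts$label == "P"],
      sum(label_counts$n[label_counts$label != "P"])
    )
  )
  hist <- architectures |>
    filter(.data$label != "excluded") |>
    mutate(subfamily = if_else(.data$label == "P", "P", "PLS")) |>
    count(.data$subfamily, .data$total_motifs)
  out <- list(
    label_counts = label_counts,
    subfamily_counts = subfam,
    motif_histogram = hist,
    n_total = nrow(architectures),
    n_retained = n_retained,
    n_excluded = n_excluded
  )
  if (!is.null(gene_models)) {
    out$chromosome_counts <- architectures |>
      filter(.data$label != "excluded") |>
      inner_join(gene_models, by = c(protein_id = "gene_id")) |>
      count(.data$chromosome)
  }
  structure(out, class = "ppr_family_summary")
}

#' @method print ppr_family_summary
#' @export
print.ppr_family_summary <- function(x, ...) {
  cat("<ppr_family_summary> ", x$n_total, " proteins (",
      x$n_retained, " retained, ", x$n_excluded, " excluded)\n", sep = "")
  cat("  subgroups: ",
      paste(sprintf("%s=%d", x$label_counts$label, x$label_counts$n),
            collapse = ", "), "\n", sep = "")
  cat("  subfamilies: P=", x$subfamily_counts$n[1],
      ", PLS=", x$subfamily_counts$n[2], "\n", sep = "")
  invisible(x)
}

#' Tidy a family summary into per-subgroup counts
#'
#' @param x A `ppr_family_summary`.
#' @param ... Unused.
#' @return Tibble with `label`, `n` and `proportion` of retained proteins.
#' @export
tidy.ppr_family_summary <- function(x, ...) {
  x$label_counts |>
    mutate(proportion = .data$n / max(x$n_retained, 1L))
}

#' One-row overview of a family summary
#'
#' @param x A `ppr_family_summary`.
#' @param ... Unused.
#' @return One-row tibble with totals and subfamily counts.
#' @export
glance.ppr_family_summary <- function(x, ...) {
  tibble(
    n_total = x$n_total,
    n_retained = x$n_retained,
    n_excluded = x$n_excluded,
    n_p_subfamily = x$subfamily_counts$n[1],
    n_pls_subfamily = x$subfamily_counts$n[2]
  )
}

#' Name genes by chromosomal order
#'
#' Convenience helper: orders retained genes by chromosome and position and
#' assigns sequential names with a common prefix (the convention used to
#' number family members along the genome).
#'
#' @param gene_tbl Tibble with `gene_id`, `chromosome` and a position column
#'   (`position` or `start`).
#' @param prefix Name prefix (default `"PPR"`).
#' @return `gene_tbl` with a `family_name` column added.
#' @export
name_by_position <- function(gene_tbl, prefix = "PPR") {
  pos_col <- intersect(c("position", "start"), names(gene_tbl))[1]
  if (is.na(pos_col)) abort("Need a `position` or `start` column.")
  gene_tbl |>
    arrange(.data$chromosome, .data[[pos_col]]) |>
    mutate(family_name = paste0(prefix, dplyr::row_number()))
}
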