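#' Count introns per gene from a GFF3 document
#'
#' Parses gene/mRNA/exon features and reports, per gene, the intron count of
#' its representative transcript: the mRNA with the greatest summed exon
#' length (ties broken by lexicographically smallest transcript id). The
#' intron count is the representative transcript's exon count minus one.
#'
#' @param x Path to a GFF3 file, or a `GRanges` with `type`, `ID`, `Parent`
#'   metadata columns (e.g. from [simulate_gene_models()]).
#' @return Tibble with `gene_id`, `chromosome`, `introns`, sorted by
#'   `gene_id`.
#' @export
intron_counts <- function(x) {
  gr <- if (methods::is(x, "GRanges")) x else rtracklayer::import(x, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ids <- as.character(md$ID)
  parents <- vapply(as.list(md$Parent), function(p) {
    if (length(p) == 0) NA_character_ else p[[1]]
  }, character(1))

  genes <- which(type == "gene")
  mrnas <- which(type == "mRNA")
  exons <- which(type == "exon")
  gene_ids <- ids[genes]
  gene_chrom <- as.character(GenomicRanges::seqnames(gr))[genes]

  mrna_gene <- stats::setNames(parents[mrnas], ids[mrnas])
  unknown <- stats::na.omit(setdiff(unname(mrna_gene), gene_ids))
  if (length(unknown) > 0) {
    abort(paste0(
      "mRNA record(s) with unknown parent gene: ",
      paste(unknown, collapse = ", ")
    ))
  }
  exon_tbl <- tibble(
    transcript_id = parents[exons],
    width = GenomicRanges::width(gr)[exons]
  )
  if (anyNA(exon_tbl$transcript_id)) abort("Exon record without a Parent.")
  unknown_tx <- setdiff(unique(exon_tbl$transcript_id), names(mrna_gene))
  if (length(unknown_tx) > 0) {
    abort(paste0(
      "Exon record(s) with unknown parent transcript: ",
      paste(unknown_tx, collapse = ", ")
    ))
  }
  empty_tx <- setdiff(names(mrna_gene), unique(exon_tbl$transcript_id))
  if (length(empty_tx) > 0) {
    abort(paste0(
      "mRNA record(s) without exons: ", paste(empty_tx, collapse = ", ")
    ))
  }
  per_tx <- exon_tbl |>
    group_by(.data$transcript_id) |>
    summarise(n_exons = dplyr::n(), total_len = sum(.data$width)) |>
    mutate(gene_id = unname(mrna_gene[.data$transcript_id]))
  rep_tx <- per_tx |>
    group_by(.data$gene_id) |>
    arrange(desc(.data$total_len), .data$transcript_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  tibble(gene_id = gene_ids, chromosome = gene_chrom) |>
    inner_join(
      rep_tx |> transmute(.data$gene_id, introns = .data$n_exons - 1L),
      by = "gene_id"
    ) |>
    arrange(.data$gene_id)
}

#' Bin intron counts into the standard 0 / 1 / 2-5 / >=6 bins
#'
#' @param counts Integer vector of per-gene intron counts (or a tibble from
#'   [intron_counts()], whose `introns` column is used). Must be non-empty.
#' @return Tibble with `bin`, `n` and `proportion` over the four bins
#'   (proportions sum to 1).
#' @export
#' @examples
#' bin_intron_counts(c(0, 0, 0, 1, 3, 7))
bin_intron_counts <- function(counts) {
  if (is.data.frame(counts)) counts <- counts$introns
  if (length(counts) == 0) abort("Cannot bin an empty set of intron counts.")
  if (any(counts < 0)) abort("Intron counts must be >= 0.")
  bin <- cut(
    counts,
    breaks = c(-0.5, 0.5, 1.5, 5.5, Inf),
    labels = c("0", "1", "2-5", ">=6")
  )
  tibble(bin = factor(c("0", "1", "2-5", ">=6"), levels = levels(bin))) |>
    left_join(
      tibble(bin = bin) |> count(.data$bin),
      by = "bin"
    ) |>
    mutate(
      n = tidyr::replace_na(.data$n, 0L),
      proportion = .data$n / length(counts)
    )
}

#' Per-chromosome gene counts and percentages
#'
#' @param gene_tbl Tibble with at least a `chromosome` column (one row per
#'   gene).
#' @return Tibble with `chromosome`, `n` and `percent` (percentages sum to
#'   100), sorted by chromosome.
#' @export
chrom_distribution <- function(gene_tbl) {
  stopifnot("chromosome" %in% names(gene_tbl))
  gene_tbl |>
    count(.data$chromosome) |>
    mutate(percent = 100 * .data$n / sum(.data$n)) |>
    arrange(.data$chromosome)
}
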