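#' Define a protein architecture template
#'
#' @param label Subgroup label the template emulates: one of
#'   `"P", "PLS", "E1", "E2", "E+", "DYW", "fragment"`.
#' @param motif_string Character vector of motif-class symbols in N- to
#'   C-terminal order, e.g. `c("P","L","S","E1")`; may be empty only for
#'   `label = "fragment"`.
#' @param count Number of proteins to emit from this template (>= 0).
#' @param substitution_rate Per-residue probability of replacing a consensus
#'   residue with a uniformly random amino acid (0-1).
#' @return One-row tibble with a list-column `motif_string`.
#' @export
architecture_template <- function(label, motif_string, count,
                                  substitution_rate = 0) {
  lab_ok <- c("P", "PLS", "E1", "E2", "E+", "DYW", "fragment")
  if (!label %in% lab_ok) {
    abort(paste0("Unknown template label: ", label))
  }
  if (length(motif_string) == 0 && label != "fragment") {
    abort("`motif_string` may be empty only for fragment templates.")
  }
  if (count < 0) abort("`count` must be >= 0.")
  if (substitution_rate < 0 || substitution_rate > 1) {
    abort("`substitution_rate` must be in [0, 1].")
  }
  tibble(
    label = label,
    motif_string = list(motif_string),
    count = as.integer(count),
    substitution_rate = substitution_rate
  )
}

#' Template set reproducing the watermelon PPR family composition
#'
#' Builds a template table whose subgroup totals match the watermelon PPR
#' family: 197 P, 15 PLS, 3 E1, 97 E2, 10 E+ and 100 DYW proteins (422 in
#' all). P-subfamily proteins carry pure P tracts of 7-12 motifs;
#' PLS-subfamily proteins carry interleaved P-L-S tracts plus the subgroup's
#' C-terminal extension cascade, for 13-17 motifs in total. Motif counts
#' cycle through their range so each subgroup spans it evenly.
#'
#' @param substitution_rate Per-residue substitution rate applied to every
#'   template (default 0).
#' @param counts Named integer vector of proteins per subgroup.
#' @return Template tibble suitable for [simulate_ppr_proteins()].
#' @export
#' @examples
#' tpl <- watermelon_family_templates()
#' sum(tpl$count)
watermelon_family_templates <- function(
    substitution_rate = 0,
    counts = c(P = 197, PLS = 15, E1 = 3, E2 = 97, `E+` = 10, DYW = 100)) {
  tails <- list(
    PLS = character(0),
    E1 = "E1",
    E2 = c("E1", "E2"),
    `E+` = c("E1", "E2", "E+"),
    DYW = c("E1", "E2", "E+", "DYW")
  )
  split_count <- function(total, sizes) {
    # spread `total` proteins across the motif-count range, cycling
    k <- length(sizes)
    base <- total %/% k
    extra <- total %% k
    base + c(rep(1L, extra), rep(0L, k - extra))
  }
  rows <- list()
  if (counts[["P"]] > 0) {
    sizes <- 7:12
    per <- split_count(counts[["P"]], sizes)
    for (i in seq_along(sizes)) {
      if (per[i] > 0) {
        rows[[length(rows) + 1]] <- architecture_template(
          "P", rep("P", sizes[i]), per[i], substitution_rate
        )
      }
    }
  }
  for (lab in names(tails)) {
    if (!lab %in% names(counts) || counts[[lab]] == 0) next
    sizes <- 13:17
    per <- split_count(counts[[lab]], sizes)
    tail <- tails[[lab]]
    for (i in seq_along(sizes)) {
      if (per[i] == 0) next
      core_n <- sizes[i] - length(tail)
      core <- rep(c("P", "L", "S"), length.out = core_n)
      rows[[length(rows) + 1]] <- architecture_template(
        lab, c(core, tail), per[i], substitution_rate
      )
    }
  }
  bind_rows(rows)
}

# Emit one protein sequence from a motif string: consensus units
# concatenated (optionally with 0-3 residue jitter spacers), random N/C
# flanks of 5-30 residues, then per-residue substitutions.
emit_protein <- function(motif_string, substitution_rate, jitter = FALSE) {
  unknown <- setdiff(motif_string, names(PPR_CONSENSUS))
  if (length(unknown) > 0) {
    abort(paste0(
      "Unknown motif-class symbol(s): ", paste(unknown, collapse = ", ")
    ))
  }
  rand_aa <- function(n) {
    paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
  }
  units <- PPR_CONSENSUS[motif_string]
  if (jitter && length(units) > 1) {
    spacers <- vapply(
      seq_len(length(units) - 1),
      function(i) rand_aa(sample(0:3, 1)),
      character(1)
    )
    body <- paste0(paste0(units[-length(units)], spacers, collapse = ""),
                   units[length(units)])
  } else {
    body <- paste(units, collapse = "")
  }
  seq <- paste0(rand_aa(sample(5:30, 1)), body, rand_aa(sample(5:30, 1)))
  if (substitution_rate > 0) {
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    hit <- stats::runif(length(chars)) < substitution_rate
    if (any(hit)) {
      chars[hit] <- sample(AA_ALPHABET, sum(hit), replace = TRUE)
      seq <- paste(chars, collapse = "")
    }
  }
  seq
}

#' Simulate PPR proteins with known motif architectures
#'
#' Each protein is the concatenation of bundled consensus motif units in the
#' template's order, flanked N- and C-terminally by 5-30 random residues,
#' with independent per-residue substitutions at the template's rate.
#' Deterministic for a fixed seed.
#'
#' @param templates Template tibble, e.g. rows from
#'   [architecture_template()] or [watermelon_family_templates()].
#' @param seed Integer seed for the generator.
#' @param jitter Insert 0-3 random residues between adjacent motif units
#'   (default `FALSE`: PPR tracts are tandem and contiguous).
#' @return List with `proteins` (tibble `protein_id`, `sequence`) and
#'   `truth` (tibble `protein_id`, `label`).
#' @export
#' @examples
#' sim <- simulate_ppr_proteins(
#'   architecture_template("P", rep("P", 5), 3), seed = 1
#' )
#' sim$truth
simulate_ppr_proteins <- function(templates, seed, jitter = FALSE) {
  if (is.null(templates) || nrow(templates) == 0) {
    return(list(
      proteins = tibble(protein_id = character(), sequence = character()),
      truth = tibble(protein_id = character(), label = character())
    ))
  }
  withr::with_seed(seed, {
    labels <- rep(templates$label, templates$count)
    strings <- rep(templates$motif_string, templates$count)
    rates <- rep(templates$substitution_rate, templates$count)
    ids <- sprintf("PPR%04d", seq_along(labels))
    seqs <- vapply(
      seq_along(ids),
      function(i) emit_protein(strings[[i]], rates[[i]], jitter = jitter),
      character(1)
    )
    list(
      proteins = tibble(protein_id = ids, sequence = seqs),
      truth = tibble(protein_id = ids, label = labels)
    )
  })
}

#' Write protein records to FASTA
#'
#' @param proteins Tibble with `protein_id` and `sequence`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path) {
  x <- Biostrings::AAStringSet(proteins$sequence)
  names(x) <- proteins$protein_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read protein records from FASTA
#'
#' @param path FASTA path.
#' @return Tibble with `protein_id` and `sequence`.
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  tibble(protein_id = names(x), sequence = as.character(x))
}

# Parse intron-distribution bin names: "0", "1", "2-5", ">=6" (or any
# integer / integer range / ">=k").
parse_intron_bins <- function(dist) {
  if (is.null(names(dist)) || any(!nzchar(names(dist)))) {
    abort("`intron_distribution` must be a named numeric vector.")
  }
  if (any(dist < 0) || abs(sum(dist) - 1) > 1e-9) {
    abort("`intron_distribution` probabilities must be >= 0 and sum to 1.")
  }
  lapply(names(dist), function(nm) {
    if (grepl("^\\d+$", nm)) {
      as.integer(nm):as.integer(nm)
    } else if (grepl("^\\d+-\\d+$", nm)) {
      parts <- as.integer(strsplit(nm, "-", fixed = TRUE)[[1]])
      parts[1]:parts[2]
    } else if (grepl("^>=\\d+$", nm)) {
      lo <- as.integer(sub(">=", "", nm, fixed = TRUE))
      lo:(lo + 4L)  # open-ended bin sampled over a bounded support
    } else {
      abort(paste0("Malformed intron-distribution bin name: ", nm))
    }
  })
}

# Largest-remainder quota allocation of n items over probabilities p.
quota_allocate <- function(n, p) {
  exact <- n * p
  base <- floor(exact)
  rem <- exact - base
  short <- n - sum(base)
  if (short > 0) {
    up <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[up] <- base[up] + 1
  }
  as.integer(base)
}

#' Simulate multi-exon gene models as GFF3
#'
#' Emits `n_genes` gene/mRNA/exon models across `n_chromosomes` chromosomes.
#' Genes are allocated to intron-count bins by largest-remainder quota on
#' the target distribution, so the emitted corpus matches the requested bin
#' proportions as closely as integer counts allow at any `n`; within a
#' multi-count bin the exact intron count is drawn uniformly. Exon lengths
#' are drawn from 80-300 bp and intron lengths from 80-500 bp; genes are
#' laid out sequentially per chromosome with random intergenic gaps.
#' The default distribution is the watermelon PPR family's:
#' 71.8% intronless, 14.7% one intron, 9.2% 2-5 introns, 4.3% six or more.
#'
#' @param n_genes Number of genes (>= 0).
#' @param intron_distribution Named numeric vector of bin probabilities
#'   (names `"0"`, `"1"`, `"2-5"`, `">=6"` or any integer/range); must sum
#'   to 1 within 1e-9.
#' @param seed Integer seed.
#' @param n_chromosomes Number of chromosomes genes are spread over
#'   (default 12).
#' @param chromosome_weights Optional probability weights for assigning
#'   genes to chromosomes (default uniform).
#' @return List with `gff` (a `GRanges` with gene/mRNA/exon features, GFF3
#'   conventions, exportable via [write_gene_models()]) and `truth` (tibble
#'   `gene_id`, `chromosome`, `introns`).
#' @export
simulate_gene_models <- function(
    n_genes,
    intron_distribution = c("0" = 0.718, "1" = 0.147, "2-5" = 0.092, ">=6" = 0.043),
    seed = 1,
    n_chromosomes = 12,
    chromosome_weights = NULL) {
  if (n_genes < 0) abort("`n_genes` must be >= 0.")
  bins <- parse_intron_bins(intron_distribution)
  withr::with_seed(seed, {
    per_bin <- quota_allocate(n_genes, as.numeric(intron_distribution))
    introns <- unlist(lapply(seq_along(bins), function(i) {
      if (per_bin[i] == 0) return(integer(0))
      sample(bins[[i]], per_bin[i], replace = TRUE)
    }))
    introns <- if (length(introns)) sample(introns) else integer(0)
    if (is.null(chromosome_weights)) {
      chromosome_weights <- rep(1 / n_chromosomes, n_chromosomes)
    }
    chrom_of <- sample(
      seq_len(n_chromosomes), n_genes,
      replace = TRUE, prob = chromosome_weights
    )
    gene_ids <- sprintf("gene%04d", seq_len(n_genes))
    chrom_names <- sprintf("chr%02d", chrom_of)

    cursor <- stats::setNames(rep(1L, n_chromosomes), sprintf("chr%02d", 1:n_chromosomes))
    feats <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      n_ex <- introns[i] + 1L
      ex_len <- sample(80:300, n_ex, replace = TRUE)
      in_len <- if (n_ex > 1) sample(80:500, n_ex - 1, replace = TRUE) else integer(0)
      chr <- chrom_names[i]
      start <- cursor[[chr]] + sample(200:2000, 1)
      ex_start <- start + cumsum(c(0L, ex_len[-n_ex] + in_len))
      ex_end <- ex_start + ex_len - 1L
      strand <- sample(c("+", "-"), 1)
      cursor[[chr]] <- ex_end[n_ex]
      gid <- gene_ids[i]
      tid <- paste0(gid, ".t1")
      feats[[i]] <- tibble(
        seqnames = chr,
        start = c(start, start, ex_start),
        end = c(ex_end[n_ex], ex_end[n_ex], ex_end),
        strand = strand,
        type = c("gene", "mRNA", rep("exon", n_ex)),
        ID = c(gid, tid, paste0(tid, ".exon", seq_len(n_ex))),
        Parent = c(NA_character_, gid, rep(tid, n_ex))
      )
    }
    tbl <- bind_rows(feats)
    gff <- GenomicRanges::GRanges(
      seqnames = tbl$seqnames,
      ranges = IRanges::IRanges(tbl$start, tbl$end),
      strand = tbl$strand
    )
    S4Vectors::mcols(gff)$type <- tbl$type
    S4Vectors::mcols(gff)$ID <- tbl$ID
    S4Vectors::mcols(gff)$Parent <- IRanges::CharacterList(
      lapply(tbl$Parent, function(p) if (is.na(p)) character(0) else p)
    )
    list(
      gff = gff,
      truth = tibble(
        gene_id = gene_ids,
        chromosome = chrom_names,
        introns = as.integer(introns)
      )
    )
  })
}

#' Write simulated gene models to a GFF3 file
#'
#' @param models Result of [simulate_gene_models()] or a `GRanges` with
#'   `type`/`ID`/`Parent` metadata columns.
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  gr <- if (is.list(models) && !methods::is(models, "GRanges")) models$gff else models
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Specify a synthetic genotype panel
#'
#' @param class_sizes Named integer vector, accessions per phenotype class;
#'   the default `c(red = 33, yellow = 17, orange = 20)` is a 70-line
#'   three-color validation panel.
#' @param planted_per_class SNPs planted to co-segregate perfectly with each
#'   class (before noise); default 4 per class.
#' @param background_snps Random variants with calls independent of class;
#'   the default 356 gives a 368-variant panel with the default planting.
#' @param flip_rate Probability that a planted-SNP call is flipped to the
#'   other homozygote (genotyping noise); default 0.
#' @param flank_length Reference bases emitted on each side of every variant
#'   (>= 30; default 60).
#' @param seed Integer seed.
#' @return A `panel_spec` list.
#' @export
panel_spec <- function(class_sizes = c(red = 33, yellow = 17, orange = 20),
                       planted_per_class = 4,
                       background_snps = 356,
                       flip_rate = 0,
                       flank_length = 60,
                       seed = 1) {
  if (any(class_sizes < 0) || planted_per_class < 0 || background_snps < 0) {
    abort("All counts must be >= 0.")
  }
  if (flip_rate < 0 || flip_rate > 1) abort("`flip_rate` must be in [0, 1].")
  if (flank_length < 30) abort("`flank_length` must be >= 30.")
  if (planted_per_class > 0 && (length(class_sizes) == 0 || all(class_sizes == 0))) {
    abort("Planting class-specific SNPs requires at least one accession.")
  }
  structure(
    list(
      class_sizes = class_sizes,
      planted_per_class = as.integer(planted_per_class),
      background_snps = as.integer(background_snps),
      flip_rate = flip_rate,
      flank_length = as.integer(flank_length),
      seed = as.integer(seed)
    ),
    class = "panel_spec"
  )
}

#' Simulate a genotype panel with planted class-specific SNPs
#'
#' Generates diploid calls (`0/0`, `0/1`, `1/1`, `./.`) for a panel of
#' accessions split into phenotype classes. Planted SNPs are homozygous-alt
#' in exactly their target class and homozygous-ref everywhere else before
#' noise; background SNPs draw calls independently of class from
#' Hardy-Weinberg proportions at a random allele frequency. `flip_rate`
#' noise flips planted-SNP calls to the opposite homozygote. Every variant
#' gets a random reference flank with the ref allele at its center.
#' Deterministic for a fixed seed.
#'
#' @param spec A [panel_spec()].
#' @return A `genotype_panel` object: list with `variants` (tibble
#'   `variant_id`, `chromosome`, `position`, `ref`, `alt`), `calls`
#'   (character matrix, variants x accessions), `phenotypes` (tibble
#'   `accession`, `class`), `flanks` (named vector of reference flanks; the
#'   SNP base is at position `flank_length + 1`), `flank_length`, and
#'   `truth` (tibble `variant_id`, `class` for planted SNPs).
#' @export
#' @examples
#' panel <- simulate_genotype_panel(panel_spec(background_snps = 10, seed = 7))
#' dim(panel$calls)
simulate_genotype_panel <- function(spec = panel_spec()) {
  stopifnot(inherits(spec, "panel_spec"))
  withr::with_seed(spec$seed, {
    classes <- rep(names(spec$class_sizes), spec$class_sizes)
    n_acc <- length(classes)
    accessions <- sprintf("acc%03d", seq_len(n_acc))
    phen <- tibble(accession = accessions, class = classes)

    n_planted <- spec$planted_per_class * length(spec$class_sizes)
    n_var <- n_planted + spec$background_snps
    bases <- c("A", "C", "G", "T")
    if (n_var == 0) {
      return(structure(
        list(
          variants = tibble(
            variant_id = character(), chromosome = character(),
            position = integer(), ref = character(), alt = character()
          ),
          calls = matrix(
            character(0), 0, n_acc,
            dimnames = list(NULL, accessions)
          ),
          phenotypes = phen,
          flanks = character(0),
          flank_length = spec$flank_length,
          truth = tibble(variant_id = character(), class = character())
        ),
        class = "genotype_panel"
      ))
    }
    ref <- sample(bases, n_var, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
    variants <- tibble(
      variant_id = sprintf("snp%04d", seq_len(n_var)),
      chromosome = sprintf("chr%02d", sample(1:12, n_var, replace = TRUE)),
      position = sort(sample(1:5e6, n_var)),
      ref = ref,
      alt = unname(alt)
    )
    planted_class <- rep(names(spec$class_sizes), each = spec$planted_per_class)
    truth <- tibble(
      variant_id = variants$variant_id[seq_len(n_planted)],
      class = planted_class
    )
    calls <- matrix("0/0", n_var, n_acc, dimnames = list(variants$variant_id, accessions))
    for (i in seq_len(n_planted)) {
      calls[i, classes == planted_class[i]] <- "1/1"
    }
    if (spec$background_snps > 0) {
      for (i in (n_planted + 1):n_var) {
        p <- stats::runif(1, 0.1, 0.9)
        calls[i, ] <- sample(
          c("0/0", "0/1", "1/1"), n_acc,
          replace = TRUE, prob = c((1 - p)^2, 2 * p * (1 - p), p^2)
        )
      }
    }
    if (spec$flip_rate > 0 && n_planted > 0) {
      for (i in seq_len(n_planted)) {
        flip <- stats::runif(n_acc) < spec$flip_rate
        calls[i, flip] <- ifelse(calls[i, flip] == "1/1", "0/0", "1/1")
      }
    }
    flanks <- vapply(seq_len(n_var), function(i) {
      left <- paste(sample(bases, spec$flank_length, replace = TRUE), collapse = "")
      right <- paste(sample(bases, spec$flank_length, replace = TRUE), collapse = "")
      paste0(left, variants$ref[i], right)
    }, character(1))
    names(flanks) <- variants$variant_id

    structure(
      list(
        variants = variants,
        calls = calls,
        phenotypes = phen,
        flanks = flanks,
        flank_length = spec$flank_length,
        truth = truth
      ),
      class = "genotype_panel"
    )
  })
}

#' @method print genotype_panel
#' @export
print.genotype_panel <- function(x, ...) {
  cat(
    "<genotype_panel> ", nrow(x$variants), " variants x ",
    ncol(x$calls), " accessions (",
    paste(
      sprintf("%s: %d", unique(x$phenotypes$class),
              as.integer(table(x$phenotypes$class)[unique(x$phenotypes$class)])),
      collapse = ", "
    ), ")\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a genotype panel into a long call table
#'
#' @param x A `genotype_panel`.
#' @param ... Unused.
#' @return Tibble with one row per variant x accession call, joined with
#'   the accession's phenotype class.
#' @export
tidy.genotype_panel <- function(x, ...) {
  calls <- as_tibble(x$calls, rownames = "variant_id") |>
    tidyr::pivot_longer(-"variant_id", names_to = "accession", values_to = "call")
  calls |>
    left_join(x$phenotypes, by = "accession") |>
    left_join(x$variants, by = "variant_id")
}

#' Write a genotype panel to VCF (v4.2) plus a phenotype sidecar
#'
#' The VCF is written through `vcfR` (gzip-compressed, readable back with
#' [read_genotype_panel()]); phenotypes go to a two-column tab-separated
#' file `accession<TAB>class`, and flanks to FASTA when a path is given.
#'
#' @param panel A `genotype_panel`.
#' @param vcf_path Output VCF path (will be gzip-compressed by `vcfR`).
#' @param phenotype_path Output tab-separated phenotype path.
#' @param flank_path Optional FASTA path for reference flanks.
#' @return Invisible list of the paths written.
#' @export
write_genotype_panel <- function(panel, vcf_path, phenotype_path,
                                 flank_path = NULL) {
  n_var <- nrow(panel$variants)
  fix <- cbind(
    CHROM = panel$variants$chromosome,
    POS = as.character(panel$variants$position),
    ID = panel$variants$variant_id,
    REF = panel$variants$ref,
    ALT = panel$variants$alt,
    QUAL = rep(".", n_var),
    FILTER = rep("PASS", n_var),
    INFO = rep(".", n_var)
  )
  gt <- cbind(FORMAT = rep("GT", n_var), panel$calls)
  vcf <- methods::new(
    methods::getClass("vcfR", where = asNamespace("vcfR")),
    meta = c(
      "##fileformat=VCFv4.2",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
    ),
    fix = fix,
    gt = gt
  )
  vcfR::write.vcf(vcf, vcf_path)
  utils::write.table(
    panel$phenotypes, phenotype_path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  if (!is.null(flank_path) && length(panel$flanks) > 0) {
    x <- Biostrings::DNAStringSet(panel$flanks)
    Biostrings::writeXStringSet(x, flank_path)
  }
  invisible(list(vcf = vcf_path, phenotypes = phenotype_path, flanks = flank_path))
}

#' Read a genotype panel from VCF plus a phenotype sidecar
#'
#' @param vcf_path VCF path (plain or gzipped).
#' @param phenotype_path Two-column tab-separated file
#'   `accession<TAB>class` (no header).
#' @param flank_path Optional FASTA of reference flanks keyed by variant id.
#' @param flank_length Flank length to record when flanks are supplied.
#' @return A `genotype_panel` (with an empty truth table).
#' @export
read_genotype_panel <- function(vcf_path, phenotype_path, flank_path = NULL,
                                flank_length = NULL) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt[is.na(gt)] <- "./."
  variants <- tibble(
    variant_id = fix[, "ID"],
    chromosome = fix[, "CHROM"],
    position = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"]
  )
  rownames(gt) <- variants$variant_id
  phen <- utils::read.table(
    phenotype_path,
    sep = "\t", header = FALSE,
    col.names = c("accession", "class"), colClasses = "character"
  )
  bad <- setdiff(colnames(gt), phen$accession)
  if (length(bad) > 0) {
    abort(paste0(
      "Accession(s) in VCF without a phenotype: ", paste(bad, collapse = ", ")
    ))
  }
  flanks <- character(0)
  if (!is.null(flank_path)) {
    x <- Biostrings::readDNAStringSet(flank_path)
    flanks <- stats::setNames(as.character(x), names(x))
    if (is.null(flank_length)) {
      flank_length <- (nchar(flanks[[1]]) - 1L) %/% 2L
    }
  }
  structure(
    list(
      variants = variants,
      calls = gt,
      phenotypes = as_tibble(phen),
      flanks = flanks,
      flank_length = flank_length,
      truth = tibble(variant_id = character(), class = character())
    ),
    class = "genotype_panel"
  )
}

#' Simulate codon-aligned duplicated coding-sequence pairs
#'
#' Generates ancestral sequences of random sense codons and derives two
#' descendants by proposing random single-base mutations; proposals that
#' would create a stop codon are rejected, synonymous proposals are always
#' accepted and nonsynonymous proposals are accepted with probability
#' `1 / ns_suppression`. A suppression factor above 1 emulates purifying
#' selection on duplicated gene pairs.
#'
#' `ns_suppression = Inf` yields strictly synonymous divergence: each
#' descendant then receives one synonymous substitution in each of
#' `n_mutations` codons, the two descendants mutating disjoint codon sets
#' (so every aligned codon pair differs by at most one base — repeated
#' synonymous hits on one codon would otherwise create codon pairs whose
#' mutational pathways pass through different amino acids and count
#' nonsynonymous under pathway averaging). Requires
#' `2 * n_mutations <= n_codons`.
#'
#' @param n_pairs Number of pairs.
#' @param n_codons Codons per sequence (default 30).
#' @param n_mutations Accepted mutations per sequence (default 10).
#' @param ns_suppression Acceptance odds divisor for nonsynonymous
#'   proposals (default 5); `Inf` for strictly synonymous divergence.
#' @param seed Integer seed.
#' @return Tibble with `pair_id`, `seq_a`, `seq_b`.
#' @export
simulate_coding_pairs <- function(n_pairs, n_codons = 30, n_mutations = 10,
                                  ns_suppression = 5, seed = 1) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  bases <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    mutate_seq <- function(codons) {
      accepted <- 0L
      guard <- 0L
      while (accepted < n_mutations && guard < 10000L) {
        guard <- guard + 1L
        ci <- sample(length(codons), 1)
        pos <- sample(3, 1)
        old <- codons[ci]
        new <- old
        substr(new, pos, pos) <- sample(setdiff(bases, substr(old, pos, pos)), 1)
        if (code[[new]] == "*") next
        syn <- code[[new]] == code[[old]]
        if (syn || stats::runif(1) < 1 / ns_suppression) {
          codons[ci] <- new
          accepted <- accepted + 1L
        }
      }
      codons
    }
    syn_mutants <- function(codon) {
      out <- character(0)
      for (pos in 1:3) {
        for (b in setdiff(bases, substr(codon, pos, pos))) {
          mut <- codon
          substr(mut, pos, pos) <- b
          if (code[[mut]] == code[[codon]]) out <- c(out, mut)
        }
      }
      out
    }
    mutate_syn_only <- function(codons, targets) {
      for (ci in targets) {
        muts <- syn_mutants(codons[ci])
        if (length(muts) > 0) codons[ci] <- sample(muts, 1)
      }
      codons
    }
    if (!is.finite(ns_suppression) && 2 * n_mutations > n_codons) {
      abort("Synonymous-only mode needs 2 * n_mutations <= n_codons.")
    }
    rows <- lapply(seq_len(n_pairs), function(i) {
      anc <- sample(sense, n_codons, replace = TRUE)
      if (is.finite(ns_suppression)) {
        a <- mutate_seq(anc)
        b <- mutate_seq(anc)
      } else {
        idx <- sample(n_codons)
        a <- mutate_syn_only(anc, idx[seq_len(n_mutations)])
        b <- mutate_syn_only(anc, idx[n_mutations + seq_len(n_mutations)])
      }
      tibble(
        pair_id = sprintf("pair%03d", i),
        seq_a = paste(a, collapse = ""),
        seq_b = paste(b, collapse = "")
      )
    })
    bind_rows(rows)
  })
}
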