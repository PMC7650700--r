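#' Bundled restriction-enzyme table
#'
#' Loads the packaged table of common 4-6-cutter restriction enzymes
#' (name, IUPAC recognition pattern, top-strand cut offset within the
#' pattern), or any user table in the same three-column tab-separated
#' format (REBASE-style tables are easily reshaped to it).
#'
#' @param path Optional path to a custom enzyme table; default uses the
#'   bundled one.
#' @return Tibble with columns `name`, `pattern`, `cut_offset`.
#' @export
#' @examples
#' head(restriction_enzymes())
restriction_enzymes <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "restriction_enzymes.tsv", package = "pprcaps")
  }
  tbl <- as_tibble(utils::read.table(
    path,
    header = TRUE, sep = "\t",
    colClasses = c("character", "character", "integer")
  ))
  validate_enzyme <- function(name, pattern, cut_offset) {
    if (nchar(pattern) < 4) {
      abort(paste0("Enzyme ", name, ": pattern must be at least 4 bases."))
    }
    check_iupac(pattern)
    if (cut_offset < 0 || cut_offset > nchar(pattern)) {
      abort(paste0("Enzyme ", name, ": cut offset outside the pattern."))
    }
  }
  purrr::pwalk(tbl, validate_enzyme)
  tbl
}

check_iupac <- function(pattern) {
  letters_ok <- names(Biostrings::IUPAC_CODE_MAP)
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, letters_ok)
  if (length(bad) > 0) {
    abort(paste0(
      "Invalid IUPAC letter(s) in pattern: ", paste(bad, collapse = ", ")
    ))
  }
  invisible(pattern)
}

as_enzyme <- function(enzyme) {
  if (is.character(enzyme) && length(enzyme) == 1) {
    enzyme <- list(name = enzyme, pattern = enzyme, cut_offset = 0L)
  }
  stopifnot(all(c("pattern") %in% names(enzyme)))
  if (is.null(enzyme$name)) enzyme$name <- enzyme$pattern
  if (is.null(enzyme$cut_offset)) enzyme$cut_offset <- 0L
  check_iupac(enzyme$pattern)
  enzyme
}

is_palindromic <- function(pattern) {
  p <- Biostrings::DNAString(pattern)
  as.character(Biostrings::reverseComplement(p)) == as.character(p)
}

#' Find restriction sites in a sequence
#'
#' Reports every (including overlapping) occurrence of the enzyme's IUPAC
#' recognition pattern on the top strand, and — when the pattern is not its
#' own reverse complement — occurrences of the reverse-complement pattern,
#' flagged by strand. `N` in the sequence never matches.
#'
#' @param sequence DNA string over `ACGTN`.
#' @param enzyme One row of [restriction_enzymes()] (as list/tibble row), or
#'   a bare IUPAC pattern string.
#' @return Tibble with `start`, `end` (1-based inclusive, top strand) and
#'   `strand`, sorted by `start`.
#' @export
#' @examples
#' find_sites("AAGAATTCTT", "GAATTC")  # EcoRI at position 3
find_sites <- function(sequence, enzyme) {
  enzyme <- as_enzyme(enzyme)
  sequence <- toupper(sequence)
  if (!grepl("^[ACGTN]*$", sequence)) {
    abort("`sequence` must be over the ACGTN alphabet.")
  }
  subj <- Biostrings::DNAString(sequence)
  n_pos <- as.integer(gregexpr("N", sequence, fixed = TRUE)[[1]])
  n_pos <- n_pos[n_pos > 0]
  match_one <- function(pattern, strand) {
    if (nchar(pattern) > nchar(sequence)) {
      return(tibble(start = integer(), end = integer(), strand = character()))
    }
    m <- Biostrings::matchPattern(
      Biostrings::DNAString(pattern), subj,
      fixed = c(pattern = FALSE, subject = TRUE)
    )
    out <- tibble(
      start = BiocGenerics::start(m),
      end = BiocGenerics::end(m),
      strand = rep(strand, length(m))
    )
    # an undetermined base (N) in the sequence never supports a site
    if (length(n_pos) > 0 && nrow(out) > 0) {
      bad <- vapply(
        seq_len(nrow(out)),
        function(i) any(n_pos >= out$start[i] & n_pos <= out$end[i]),
        logical(1)
      )
      out <- out[!bad, , drop = FALSE]
    }
    out
  }
  hits <- match_one(toupper(enzyme$pattern), "+")
  if (!is_palindromic(enzyme$pattern)) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(enzyme$pattern)
    ))
    hits <- bind_rows(hits, match_one(rc, "-"))
  }
  arrange(hits, .data$start, .data$strand)
}

#' Filter a genotype panel for phenotype-class-specific SNPs
#'
#' A variant passes for a target class iff (1) all non-missing calls inside
#' the class are the same homozygote, (2) all non-missing calls outside the
#' class are the same homozygote, (3) the two homozygotes differ.
#' Heterozygous calls break monomorphism (strict), and the missing-call
#' fraction must not exceed `max_missing_fraction` on either side.
#'
#' @param panel A `genotype_panel`.
#' @param target_class Phenotype class to select for (must exist in the
#'   panel).
#' @param max_missing_fraction Maximum tolerated fraction of `./.` calls on
#'   each side (default 0).
#' @return Tibble of passing variants: `variant_id`, `chromosome`,
#'   `position`, `ref`, `alt`, `target_class`, `class_allele`,
#'   `other_allele` (bases), `class_genotype`, `other_genotype`, `n_class`,
#'   `n_other` (non-missing accessions supporting each side).
#' @export
class_specific_snps <- function(panel, target_class, max_missing_fraction = 0) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (nrow(panel$variants) == 0) abort("Empty genotype panel.")
  if (!target_class %in% panel$phenotypes$class) {
    abort(paste0("Unknown phenotype class: ", target_class))
  }
  in_class <- panel$phenotypes$accession[panel$phenotypes$class == target_class]
  out_class <- setdiff(panel$phenotypes$accession, in_class)
  if (length(in_class) == 0 || length(out_class) == 0) {
    abort("Need at least one accession inside and outside the target class.")
  }
  hom <- c("0/0", "1/1")
  side_genotype <- function(calls, n_side) {
    # unique homozygote of a side, or NA when the side fails monomorphism
    missing <- calls == "./."
    if (sum(missing) / n_side > max_missing_fraction) return(NA_character_)
    obs <- calls[!missing]
    if (length(obs) == 0) return(NA_character_)
    u <- unique(obs)
    if (length(u) != 1 || !(u %in% hom)) return(NA_character_)
    u
  }
  rows <- lapply(seq_len(nrow(panel$variants)), function(i) {
    gin <- side_genotype(panel$calls[i, in_class], length(in_class))
    gout <- side_genotype(panel$calls[i, out_class], length(out_class))
    if (is.na(gin) || is.na(gout) || gin == gout) return(NULL)
    v <- panel$variants[i, ]
    allele_of <- function(g) if (g == "0/0") v$ref else v$alt
    tibble(
      variant_id = v$variant_id,
      chromosome = v$chromosome,
      position = v$position,
      ref = v$ref,
      alt = v$alt,
      target_class = target_class,
      class_allele = allele_of(gin),
      other_allele = allele_of(gout),
      class_genotype = gin,
      other_genotype = gout,
      n_class = sum(panel$calls[i, in_class] != "./."),
      n_other = sum(panel$calls[i, out_class] != "./.")
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    tibble(
      variant_id = character(), chromosome = character(),
      position = integer(), ref = character(), alt = character(),
      target_class = character(), class_allele = character(),
      other_allele = character(), class_genotype = character(),
      other_genotype = character(), n_class = integer(), n_other = integer()
    )
  } else {
    out
  }
}

#' Substitute the alternate allele into a reference flank
#'
#' @param flank Reference flanking sequence.
#' @param offset 1-based position of the SNP within the flank.
#' @param ref,alt Single-base reference and alternate alleles; the flank
#'   base at `offset` must equal `ref` (case-insensitive).
#' @return The flank with `alt` at `offset` (differs from the input at
#'   exactly that position).
#' @export
#' @examples
#' apply_snp_to_flank("AAGAATTTTT", 7, "T", "C")
apply_snp_to_flank <- function(flank, offset, ref, alt) {
  if (offset < 1 || offset > nchar(flank)) {
    abort("`offset` is outside the flank sequence.")
  }
  observed <- substr(flank, offset, offset)
  if (toupper(observed) != toupper(ref)) {
    abort(paste0(
      "Reference mismatch at offset ", offset, ": expected ", toupper(ref),
      ", observed ", toupper(observed), "."
    ))
  }
  out <- flank
  substr(out, offset, offset) <- alt
  out
}

#' Convert a SNP into CAPS candidates by differential site scanning
#'
#' For each enzyme, restriction sites are located on the reference and
#' alternate versions of the flank and restricted to sites whose pattern
#' span covers the SNP base (only those can be explained by the SNP); a
#' candidate is emitted iff the restricted site sets differ between the two
#' alleles. Digestion fragments over the full flank (treated as the
#' amplicon) are predicted for both alleles.
#'
#' @param ref_flank Reference flanking sequence containing the SNP.
#' @param snp_pos 1-based position of the SNP within `ref_flank`.
#' @param ref,alt SNP alleles; `ref_flank[snp_pos]` must equal `ref`.
#' @param enzymes Enzyme table (default [restriction_enzymes()]).
#' @return Tibble of candidates: `enzyme`, `pattern`, `allele_with_site`
#'   (`"ref"` or `"alt"`), `site_position` (start of the differential site),
#'   `site_strand`, `n_sites_ref`, `n_sites_alt` (SNP-covering sites per
#'   allele), and list-columns `fragments_ref`, `fragments_alt` with
#'   predicted fragment lengths (each summing to the amplicon length).
#'   Zero rows when no enzyme's site set is altered by the SNP.
#' @export
snp_to_caps <- function(ref_flank, snp_pos, ref, alt,
                        enzymes = restriction_enzymes()) {
  max_len <- max(nchar(enzymes$pattern))
  if (snp_pos < max_len || nchar(ref_flank) - snp_pos < max_len - 1) {
    abort(paste0(
      "Flank too short to scan every pattern placement over the SNP: need ",
      "at least ", max_len - 1, " bases on each side of the SNP (flank of ",
      2 * max_len - 1, "+ bases)."
    ))
  }
  alt_flank <- apply_snp_to_flank(ref_flank, snp_pos, ref, alt)
  covering <- function(sites) {
    sites[sites$start <= snp_pos & sites$end >= snp_pos, , drop = FALSE]
  }
  site_key <- function(sites) paste(sites$start, sites$strand)
  rows <- lapply(seq_len(nrow(enzymes)), function(i) {
    enz <- as.list(enzymes[i, ])
    s_ref <- covering(find_sites(ref_flank, enz))
    s_alt <- covering(find_sites(alt_flank, enz))
    if (setequal(site_key(s_ref), site_key(s_alt))) return(NULL)
    only_ref <- s_ref[!(site_key(s_ref) %in% site_key(s_alt)), , drop = FALSE]
    only_alt <- s_alt[!(site_key(s_alt) %in% site_key(s_ref)), , drop = FALSE]
    gained <- if (nrow(only_alt) >= nrow(only_ref)) only_alt else only_ref
    allele_with_site <- if (nrow(only_alt) >= nrow(only_ref)) "alt" else "ref"
    tibble(
      enzyme = enz$name,
      pattern = enz$pattern,
      allele_with_site = allele_with_site,
      site_position = gained$start[1],
      site_strand = gained$strand[1],
      n_sites_ref = nrow(s_ref),
      n_sites_alt = nrow(s_alt),
      fragments_ref = list(predict_fragments(ref_flank, enz)),
      fragments_alt = list(predict_fragments(alt_flank, enz))
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    tibble(
      enzyme = character(), pattern = character(),
      allele_with_site = character(), site_position = integer(),
      site_strand = character(), n_sites_ref = integer(),
      n_sites_alt = integer(),
      fragments_ref = list(), fragments_alt = list()
    )
  } else {
    out
  }
}

#' CAPS candidates for a table of class-specific SNPs from a panel
#'
#' Applies [snp_to_caps()] to each SNP in a [class_specific_snps()] result,
#' using the panel's stored reference flanks.
#'
#' @param panel A `genotype_panel` with flanks.
#' @param snps Tibble from [class_specific_snps()].
#' @param enzymes Enzyme table (default [restriction_enzymes()]).
#' @return Combined candidate tibble with `variant_id` and `target_class`
#'   prepended to the [snp_to_caps()] columns.
#' @export
caps_candidates <- function(panel, snps, enzymes = restriction_enzymes()) {
  stopifnot(inherits(panel, "genotype_panel"))
  snp_pos <- panel$flank_length + 1L
  purrr::pmap_dfr(
    snps[, c("variant_id", "target_class", "ref", "alt")],
    function(variant_id, target_class, ref, alt) {
      flank <- panel$flanks[[variant_id]]
      cand <- snp_to_caps(flank, snp_pos, ref, alt, enzymes)
      bind_cols(
        tibble(
          variant_id = rep(variant_id, nrow(cand)),
          target_class = rep(target_class, nrow(cand))
        ),
        cand
      )
    }
  )
}

#' Predict restriction-digestion fragment lengths
#'
#' Cuts the amplicon at every site of the enzyme (top-strand cut positions;
#' minus-strand sites of non-palindromic enzymes cut at the mirrored
#' offset) and returns the fragment lengths in descending order. With no
#' site, the single fragment is the whole amplicon; lengths always sum to
#' the amplicon length.
#'
#' @param amplicon DNA string (the PCR product to digest).
#' @param enzyme Enzyme row (list with `pattern` and `cut_offset`) or
#'   pattern string.
#' @return Integer vector of fragment lengths, sorted descending.
#' @export
#' @examples
#' predict_fragments("AAGAATTCTTTT", list(pattern = "GAATTC", cut_offset = 1))
predict_fragments <- function(amplicon, enzyme) {
  enzyme <- as_enzyme(enzyme)
  sites <- find_sites(amplicon, enzyme)
  len <- nchar(amplicon)
  plen <- nchar(enzyme$pattern)
  cuts <- integer(0)
  if (nrow(sites) > 0) {
    cuts <- ifelse(
      sites$strand == "+",
      sites$start - 1L + enzyme$cut_offset,
      sites$end - enzyme$cut_offset
    )
    cuts <- sort(unique(cuts[cuts > 0 & cuts < len]))
  }
  sort(diff(c(0L, cuts, len)), decreasing = TRUE)
}

#' Derive CAPS marker digestion calls from panel genotypes
#'
#' Translates each accession's diploid genotype at a marker SNP into the
#' expected digestion state: the homozygote carrying the allele with the
#' restriction site digests (`cut`), the other homozygote does not
#' (`uncut`), heterozygotes are collapsed to `cut` by default (partial
#' digestion scores dominant), and missing genotypes stay `missing`.
#'
#' @param panel A `genotype_panel`.
#' @param variant_id Marker variant.
#' @param allele_with_site `"ref"` or `"alt"`: which allele carries the
#'   restriction site (from [snp_to_caps()]).
#' @param target_class Phenotype class the marker diagnoses.
#' @param class_genotype The homozygote (`"0/0"` or `"1/1"`) expected in the
#'   target class (from [class_specific_snps()]).
#' @param het_as State assigned to heterozygotes, `"cut"` (default,
#'   dominant scoring) or `"uncut"`.
#' @return A [marker_calls()] object with `positive_genotype` set to the
#'   digestion state expected for the target class.
#' @export
caps_marker_calls <- function(panel, variant_id, allele_with_site,
                              target_class, class_genotype,
                              het_as = c("cut", "uncut")) {
  het_as <- match.arg(het_as)
  stopifnot(variant_id %in% rownames(panel$calls))
  gt <- panel$calls[variant_id, ]
  site_hom <- if (allele_with_site == "alt") "1/1" else "0/0"
  other_hom <- if (site_hom == "1/1") "0/0" else "1/1"
  state <- dplyr::case_when(
    gt == site_hom ~ "cut",
    gt == other_hom ~ "uncut",
    gt == "./." ~ "missing",
    TRUE ~ het_as
  )
  positive <- if (class_genotype == site_hom) "cut" else "uncut"
  marker_calls(
    marker_id = variant_id,
    target_class = target_class,
    positive_genotype = positive,
    calls = tibble(accession = names(gt), call = unname(state))
  )
}
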