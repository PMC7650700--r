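#' @importFrom rlang .data %||% abort warn
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Motif-class alphabet used throughout. Order encodes the C-terminal
# subgroup priority (DYW > E+ > E2 > E1) used by the classifier.
MOTIF_CLASSES <- c("P", "L", "S", "E1", "E2", "E+", "DYW")

AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# One fixed consensus per motif class. PPR repeats are degenerate 31-36 aa
# helix-turn-helix units: canonical P is 35 aa, the long (L) variant 36 aa
# and the short (S) variant 31 aa; E1/E2/E+ are C-terminal extension motifs
# and the DYW domain (~100 aa) ends in the literal Asp-Tyr-Trp tripeptide.
# The sequences below follow published per-class consensus patterns in
# length and flavor but are fixed package constants, not fitted models.
PPR_CONSENSUS <- c(
  P   = "VTYNTLIDGLCKAGKLDEALELFEEMKEKGIKPDV",
  L   = "FSWTILIRGFAQNGDPHKALDYFHRMLEEGVEPDEV",
  S   = "GYARQVFDEMPERNVVSWNSMISGYAQNGQA",
  E1  = "AEKLFELDPENAGPYVLLSNIYAAAGRWDDVAKV",
  E2  = "RKEPGCSWIEVQNKVHEFLVGDKSHPQSEEIYAK",
  `E+` = "LDHHSEKLAIAFGLLNLPPGTTIRVFKNLRV",
  DYW = paste0(
    "CSYHSEKLAIAFGLISTPPGTPLRIFKNLRVCGDCHNAIKLISKVYNREIIVRDRNRFHHF",
    "KDGVCSCKALNTRLKELSGEKWDQEIRVGSAVEVHSDYW"
  )
)

#' Bundled PPR motif consensus sequences
#'
#' Returns the fixed consensus amino-acid sequence bundled for each PPR
#' motif class: the canonical 35-aa P repeat, the long (L, 36 aa) and short
#' (S, 31 aa) variants, the C-terminal extension motifs E1/E2 (34 aa each)
#' and E+ (31 aa), and the 100-aa DYW domain ending in the literal
#' tripeptide `DYW`. These consensus units seed both the synthetic protein
#' generator and the default scanning profiles.
#'
#' @return A tibble with columns `motif_class`, `consensus` and `length`.
#' @export
#' @examples
#' ppr_consensus()
ppr_consensus <- function() {
  tibble(
    motif_class = names(PPR_CONSENSUS),
    consensus = unname(PPR_CONSENSUS),
    length = nchar(unname(PPR_CONSENSUS))
  )
}

# Integer-encode an amino-acid string against AA_ALPHABET; degenerate or
# unknown residues (X, B, Z, U, *, ...) map to index 21, a zero-weight row.
aa_encode <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  idx <- match(chars, AA_ALPHABET)
  idx[is.na(idx)] <- 21L
  idx
}
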