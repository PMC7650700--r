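---
title: "PPR family classification and SNP-to-CAPS marker design: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PPR family classification and SNP-to-CAPS marker design: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pprcaps)
```

## Scope

`pprcaps` implements the computational chain used to characterize a plant
pentatricopeptide repeat (PPR) gene family and to derive phenotype-diagnostic
CAPS markers from it: motif detection and subfamily classification of PPR
proteins, gene-structure summaries from GFF3, Ka/Ks estimates for duplicated
gene pairs, class-specific SNP filtering from a genotype panel, SNP-to-CAPS
conversion by differential restriction-site scanning, and marker–phenotype
match-rate validation. A synthetic-data module provides inputs with known
ground truth at the scale of the motivating study system — a watermelon
panel of 70 lines (33 red, 17 yellow, 20 orange flesh) and a 422-member PPR
family. Upstream steps that in practice are run with dedicated external
tools (homology search and domain retrieval, collinearity detection,
codon alignment, phylogeny, primer design, read mapping and variant
calling) are out of scope: their outputs are this package's inputs.

## Motif model and scanning

PPR proteins carry 2–30 tandem copies of a degenerate repeat: the canonical
P motif (35 aa), its long (L, 36 aa) and short (S, 31 aa) variants, and the
C-terminal extension motifs E1/E2 (34 aa), E+ (31 aa) and the ~100-aa DYW
domain ending in the literal Asp-Tyr-Trp tripeptide. The package bundles
one fixed consensus sequence per class (`ppr_consensus()`), styled on
published per-class consensus patterns; no claim is made that they are
fitted to any particular proteome.

`build_profile()` turns seed sequences into a position-specific scoring
matrix of log-odds weights against a uniform 1/20 background,

\[ w_{aj} = \log\frac{c_{aj} + \kappa}{n + 20\kappa} - \log\frac{1}{20}, \]

with pseudocount \(\kappa = 1\) by default. A window's score is the sum of
per-position weights, so scores are additive and scanning is exhaustive
over all windows. Degenerate residues (X, B, Z, and anything outside the
20-letter alphabet) score exactly 0 — the background — at every position.
Coordinates are 1-based inclusive externally (the HMMER/GFF convention);
internal offsets are 0-based.

**Threshold calibration.** Each profile's reporting threshold is set so
that chance hits on random sequence are negligible: the exact distribution
of the window score under the uniform background is obtained by convolving
the 20-point per-position score distributions on a 0.01 grid, and the
threshold is the smallest score with upper-tail probability ≤ 1e-7 per
window (plus half a grid step per position against rounding drift). That
bounds expected chance hits at roughly 1e-4 per 1,000 residues — far under
the 0.1/kaa design target, which the test suite also verifies empirically
against a brute-force window scorer. An exact convolution was chosen over
simulation (deterministic, seed-free) and over a normal approximation: the
score distribution is strongly right-skewed (a chance hit needs many
improbable consensus matches), and a Gaussian tail underestimates it by
orders of magnitude. The wide margin between threshold (≈ 4.5–6 bits-like
units) and consensus score (≈ 20–64) is what makes classification robust
to ~10% residue substitution.

As an alternative hit source, `read_hmmer_domtbl()` ingests HMMER3
per-domain tables (envelope coordinates, independent E-value < 0.1 by
default, matching common practice for PPR domain retrieval), with a
user-supplied model-name → motif-class map, since published analyses
differ in which HMM definitions produce the P/L/S calls.

## Architecture assembly and classification

Raw hits may overlap; `tile_hits()` resolves them greedily: sort by score
(descending), then start, then class name — a fully specified tie-break for
reproducibility — and accept each hit that overlaps no accepted hit. The
result is maximal (no rejected hit still fits) but not guaranteed optimal;
the test suite documents on random cases that its total score stays within
half of the exhaustive optimum, and in practice on tandem PPR arrays the
true motifs outscore all straddling windows, so the greedy and optimal
tilings coincide.

`classify_architecture()` applies the family's retention and naming rules:

1. fewer than two P motifs → **excluded** (the standard retention rule for
   plant PPR surveys; only P-class motifs count, not L/S — the literal
   reading of the rule);
2. a repeat tract with no L/S and no extension motifs → subfamily **P**;
3. otherwise the protein is PLS-subfamily and its subgroup is named by the
   highest-priority extension motif (**DYW** > **E+** > **E2** > **E1**)
   occurring C-terminal of the last P/L/S repeat; no extension after the
   tract → **PLS**.

Orphan extensions after a pure P tract (≥2 P, no L/S, but an E/DYW tail)
are labeled by the subgroup rule rather than forced to P, since
subfamily/cluster mismatches are a real feature of these families.
`family_summary()` counts labels (excluded proteins reported separately),
rolls PLS + E1 + E2 + E+ + DYW into the PLS-subfamily total, and histograms
motif counts per subfamily.

## Synthetic proteins: what the generator emulates

`simulate_ppr_proteins()` concatenates consensus motif units in a
template's order, adds random N/C flanks of 5–30 residues, and applies
independent per-residue substitutions (uniform replacement) at the
template's rate. `watermelon_family_templates()` reproduces the motivating
family's composition — 197 P, 15 PLS, 3 E1, 97 E2, 10 E+, 100 DYW (422
proteins), P tracts of 7–12 motifs and PLS-subfamily architectures of 13–17
motifs, matching the observed motif-count peaks. Motif units are contiguous
by default (PPR tracts are tandem); an optional jitter flag inserts 0–3
random residues between units.

This is a deliberately simple emission model: consensus plus uniform
substitution, not a claim about real PPR sequence evolution. Real repeats
are degenerate in position-specific ways, carry indels, and drift between
classes; passing tests on this generator therefore demonstrates that the
scanning/tiling/labeling machinery is correct and noise-tolerant, not that
the bundled profiles would reproduce a published family from real proteome
FASTA. For real data, per-class HMM hits via `read_hmmer_domtbl()` are the
recommended input.

## Synthetic gene models and intron bins

`simulate_gene_models()` emits valid GFF3 (gene/mRNA/exon, 1-based
inclusive, exons sorted and non-overlapping) across 12 chromosomes by
default, with exon lengths of 80–300 bp and introns of 80–500 bp. Genes
are allocated to intron-count bins (defaults 71.8% intronless, 14.7% one
intron, 9.2% with 2–5, 4.3% with ≥6 — the bins observed for the watermelon
family) by largest-remainder quota rather than multinomial sampling: the
generator's purpose is to emit a corpus *drawn to* a target composition,
and quota allocation achieves it to integer resolution at any n, whereas a
multinomial draw at n = 422 would add sampling noise (SE ≈ 0.022 on the
0.718 bin) larger than the structural differences of interest. Within a
multi-count bin the exact intron count is uniform; the open-ended ≥6 bin
is sampled over 6–10.

`intron_counts()` re-derives intron counts from any GFF3 via the
representative transcript, defined here as the mRNA with the greatest
summed exon length (ties broken by lexicographically smallest transcript
id) — a deterministic stand-in for the unstated transcript choices of
gene-structure display tools. Malformed inputs (mRNA without exons,
orphan parents) are errors naming the offending record.

## Ka/Ks: NG86 with Jukes–Cantor correction

The motivating analyses report only that duplicated PPR pairs show
ω = Ka/Ks < 1; the estimator behind the printed statement is not specified.
The package implements the Nei–Gojobori (1986) counting method — standard,
deterministic, and fully specifiable — with the Jukes–Cantor correction
\(d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)\):

* **Sites** (`count_sites()`): per codon position, the synonymous fraction
  is (synonymous, non-stop single-base changes) / (non-stop changes), the
  stop adjustment; s + n = 3 per codon. Standard nuclear code only.
* **Differences** (`count_diffs()`): averaged over all minimal mutational
  pathways (orderings of the differing positions), excluding pathways
  through stop codons. If every pathway is blocked — impossible for
  single-position differences and vanishingly rare otherwise — the codon
  pair is skipped with a warning, but stays in the site counts so that
  S + N = 3 × (codons) holds.
* **Rates** (`kaks()`): S and N averaged over the two sequences, pS = Sd/S
  and pN = Nd/N corrected to Ks and Ka. Gap-containing codons are dropped
  before counting; internal stops are an error. A proportion ≥ 3/4 is
  outside the correction's log domain, and the distance, ω and selection
  flag are reported as undefined rather than extrapolated.

`simulate_coding_pairs()` generates duplicate pairs by proposing random
single-base changes on a common ancestor of random sense codons, rejecting
stop-creating proposals and accepting nonsynonymous ones with probability
1/`ns_suppression` (default 5, a purifying-selection regime). With
`ns_suppression = Inf` the generator switches to strictly synonymous
divergence: one synonymous substitution per codon, the two descendants
mutating disjoint codon sets. The restriction matters: two synonymous hits
on the same codon can yield a codon pair whose mutational pathways traverse
different amino acids, which NG86 pathway averaging rightly counts as
partly nonsynonymous — so "synonymous-only" is only well-defined per site.

## Class-specific SNPs and CAPS conversion

`class_specific_snps()` applies three criteria to a diploid genotype panel
(calls 0/0, 0/1, 1/1, ./.): the variant must be monomorphic (a single
homozygote) among the target class, monomorphic among all other classes,
and polymorphic between the two sides. Heterozygotes break monomorphism
(strict reading), and the missing-call fraction per side must not exceed
`max_missing_fraction` (default 0); both choices are configurable since the
source procedure is silent on them.

`snp_to_caps()` re-implements SNP-to-CAPS conversion: for each enzyme the
recognition-site sets of the reference and alternate flank are compared
*restricted to sites whose pattern span covers the SNP base*. Only those
sites can be causally explained by the SNP; coincidental differences
elsewhere in the amplicon would score genotype-independent length
variation. Patterns are IUPAC-degenerate, matched with overlaps allowed;
non-palindromic patterns are also scanned as their reverse complement
(flagged by strand), palindromic ones once; an undetermined base (N) in the
sequence never supports a site. `predict_fragments()` cuts the amplicon at
`site start − 1 + cut offset` on the plus strand (mirrored for minus-strand
sites) and returns descending fragment lengths that always sum to the
amplicon length. The bundled table of 36 common 4–6-cutters ships as a
three-column tab-separated file (name, IUPAC pattern, top-strand cut
offset) and any REBASE-style table reshaped to that format can be supplied
instead.

The panel generator plants class-specific SNPs (homozygous-alt in exactly
the target class before noise), adds background variants drawn from
Hardy–Weinberg proportions at a random allele frequency independent of
class, applies genotype-flip noise (planted calls flipped to the opposite
homozygote with probability `flip_rate`), and emits 60-bp reference flanks
around each variant. Defaults — 33/17/20 accessions, 4 planted SNPs per
class plus 356 background variants (368 total) — mirror the motivating
study's validation panel and SNP-matrix scale.

## Match rates

A marker's match rate is two-sided concordance over all surveyed lines:
an accession matches iff (its digestion state equals the marker's positive
state) ⇔ (its phenotype is the target class). The two-sided definition is
deliberate — a red-flesh marker must also be negative on non-red lines —
and missing calls are excluded from numerator and denominator.
`caps_marker_calls()` maps genotypes to digestion states, collapsing
heterozygotes to "cut" by default (partial digestion scores dominant;
configurable).

For joint genotyping with several markers of one class,
`joint_match_rate()` combines per-marker positives under OR (default), AND,
or majority, and always reports the rule. The default is OR because the
published joint figure this mirrors (0.94 from single rates 0.79 and 0.76)
cannot be an arithmetic mean and is most consistent with either-marker
scoring that repairs disjoint false negatives; since the intended rule is
not stated in the source, the rule is a visible, configurable parameter
rather than a hidden assumption, and no rule is presented as ground truth.
An accession missing on any member marker is missing for the joint marker.

## Numerical and design choices

* Background model: uniform 1/20; pseudocount 1.
* Tiling tie-break fully specified (score desc, start asc, class asc).
* Profile-threshold grid 0.01 with a half-step-per-position safety margin.
* Binomial noise calibration of the panel generator, quota allocation for
  intron bins, and one seeded PRNG per generator call
  (`withr::with_seed`; no global RNG state is touched).
* Genotype encoding fixed to 0/0, 0/1, 1/1, ./.; planted SNPs are never
  heterozygous before noise.
* Degenerate inputs error early with named offenders (unknown motif
  symbols, ragged alignments, stop codons, reference-base mismatches,
  flanks too short to scan every pattern placement over the SNP).

## Problem sizes in the test suite

The suite exercises the full study scale where that is the point — the
422-protein corpus (clean and at 10% substitution), the 368-variant ×
70-accession panel, 500 Ka/Ks replicates under 5× nonsynonymous
suppression, 500 random sequences against the brute-force IUPAC matcher —
and reduced sizes (tens of sequences/pairs) for properties that are
scale-free, such as oracle equality of window scanning and pathway
counting. The whole suite runs in about two minutes on one CPU.

## Known limitations

* The bundled consensus profiles are for synthetic and demonstration use;
  real-proteome classification should import per-class HMM hits.
* The profile scan has no insert/delete states; it is a fixed-length
  window model, not a profile HMM.
* NG86 is a counting method; it will differ numerically from ML estimators
  (e.g. codeml) on divergent pairs, though the ω < 1 direction is robust.
* Fragment prediction assumes complete digestion and reports top-strand
  cut positions only; heteroduplex and partial-digestion artifacts of real
  gels are out of scope.
* The match-rate module validates co-segregation; it does not model linkage
  or population structure.
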