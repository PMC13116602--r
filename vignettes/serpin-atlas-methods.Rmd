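---
title: "Methods: building and validating a serpin gene atlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and validating a serpin gene atlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the methods it implements: the
discovery model and its assumptions, the parameters that matter, the design
choices that were genuinely open, and what the synthetic-genome tests do and
do not establish about real data.

## The discovery model

Serpins share a conserved fold but diverge heavily in sequence; the
reactive-center loop (RCL) near the C-terminus is both the most conserved
*location* and the functional business end. `scan_protein()` therefore
searches only the last `window_len` residues of each predicted protein
(default 100; shorter proteins are scanned in full) and compares each seed
RCL peptide against **every** subsequence of exactly the seed's length inside
that window. Matching is substitution-only — no indels — because the
mismatch-run constraint below is positional, and because RCLs of a family are
essentially colinear. Two rules make a window admissible:

* **Budget**: at most `floor(max_mismatch_fraction * query_length)`
  substitutions (default fraction 0.30). The floor is the conservative
  reading of "up to 30%": for a 17-mer the budget is 5, never 6.
* **Run constraint**: no two mismatch positions may be adjacent. A run of two
  or more consecutive mismatches disqualifies the window even inside the
  budget. This filters the diffuse, low-complexity similarity that random
  C-terminal sequence produces while tolerating scattered point divergence.

Per protein a single best match is retained — fewest mismatches, then
smallest start offset, then seed order. Seed order is made deterministic by
sorting seed ids, so results cannot depend on input file order. Comparison is
case-insensitive and `X` mismatches everything, including another `X`: an
ambiguous residue can never help a window qualify.

`iterate_to_fixed_point()` re-seeds the scan with the matched RCL
subsequences of each round's hits. Because enlarging the seed set can only
add admissible proteins, the hit set is monotone non-decreasing and the
iteration stops at the first round with no growth. The tests plant a "bridge"
protein whose RCL is 8 substitutions from the original seed (inadmissible)
but 4 from a round-one discovery, and verify it appears exactly in round two.

## Locus features

* **Sequons** are all positions matching Asn-X-Ser/Thr with X ≠ Pro,
  overlapping occurrences included.
* The **hinge** scaffold motif (default NAVYFKG) is searched only in the
  N-terminal half with a 1-substitution budget, which accepts the NAIYFKG
  variant seen in tick serpins while rejecting C-terminal artifacts.
* **Molecular weight** uses average (isotope-averaged) residue masses plus
  one water — the convention behind "calculated MW" in annotation reports.
  `X` contributes the mean of the twenty residue masses.
* **Isoelectric point** solves net charge = 0 by bisection on pH 0–14 with
  the EMBOSS pKa table (N-term 8.6, C-term 3.6, C 8.5, D 3.9, E 4.1, H 6.5,
  K 10.8, R 12.5, Y 10.1); the table is an argument, so other conventions can
  be swapped in. Net charge is strictly decreasing in pH, so bisection is
  exact to its tolerance (0.001 pH by default, well inside the 0.01 the
  pipeline needs).
* **Signal peptides** are never predicted internally; calls from an external
  predictor attach by protein id, missing ids become "unknown" and are
  counted separately. Whether reported MW should use the full-length or
  mature chain is not decidable without a call, so `build_atlas()` reports
  full-length values and keeps the call as a flag.

Loci are named `S<k>c<chromosome>` with `k` serialized along the genome
(numeric chromosomes first, then unplaced scaffolds); a locus on a WGS-style
scaffold gets `S<k>j<contig#>`, parsing the contig serial after the two-digit
WGS version (e.g. `...010000234.1` → `j234`).

## Tandem clusters and the genome-level statistics

A cluster is a maximal chain of same-chromosome serpin loci in which each
neighboring pair is within `max_distance` bp **boundary-to-boundary**
(`next.start − prev.end − 1`, using gene spans — outermost transcript
boundaries — not CDS) *and* separated by at most `max_intervening_genes`
annotated genes of any biotype lying strictly between the two spans (defaults
100 kb and 10). Unchained loci are singleton clusters, so the clusters always
partition the loci; `sensitivity_sweep()` re-calls the partition over a
threshold grid and flags plateaus (identical partitions), which is how the
defaults were justified in the source study. Orientation of an adjacent pair
follows gene geometry: same strand → head-to-tail; `−`,`+` → head-to-head
(5′ ends facing); `+`,`−` → tail-to-tail. Note that 5′-facing pairs are
called "convergent" in some of the literature and "divergent" in other parts;
this package follows the geometric definition just stated and uses only the
three explicit labels.

Strand bias uses `stats::binom.test()` against 0.5 — the minimum-likelihood
two-sided definition, which at p = 0.5 equals doubling the smaller tail.
Chromosomal concentration uses a χ² goodness-of-fit test with expectations
proportional to chromosome length (`E_i = N·L_i/ΣL`, df = #chromosomes − 1);
chromosomes with zero serpins still contribute, and loci on unplaced
scaffolds must be excluded by the caller (their "chromosome" has no defined
length). Testing this statistic against the published value requires the real
assembly's fifteen chromosome lengths, which are an external input (the
assembly sequence report); the package ships no stand-in values, so that one
check reports as failing until the table is supplied.

## Pairwise identity and duplication tiers

All-vs-all alignment uses Needleman–Wunsch (global) and Smith–Waterman
(local) via `Biostrings::pairwiseAlignment` with BLOSUM62 and affine gaps
open 11 / extend 1 — BLASTP's defaults, chosen because the source methods
name the algorithms but no parameters; `align_scoring()` makes them explicit
and overridable. **Global identity divides by every alignment column,
terminal-gap columns included** — so `"ACDEFG"` vs `"ACDEF"` is 5/6 ≈ 83.3%,
not 100%. Local identity divides by the local alignment's columns only.
Tiers are contiguous half-open bins — exact duplicate at 100, recent paralog
[98, 100), diverged paralog [70, 98), else non-homologous — because the
verbal ranges "70–97%" and "≥98%" would leave (97, 98) unassigned; the bin
edges are recorded in the output attributes. In the tests the aligners are
cross-checked against independent hand-written Gotoh dynamic-programming
oracles on short random pairs, and against exact closed-form identities for
substitution-only mutants.

## P1 rule engine

`number_rcl()` places Schechter–Berger positions around a scissile bond whose
location inside the RCL is **metadata on the seed** (`p1_offset`), not
inferred from sequence: since matches are ungapped, the bond position
propagates to every hit by alignment position. `classify_by_p1()` is a total
function on (P1, P1′) with a fixed rule order — dual (V/I + small P1′)
strictly before the hydrophobic rule, then R/K, then F/Y/W/L/I/V/M, then
A/S/G, else unknown — and every output is screening-level: P4–P2 context,
exosites and cofactors can shift real specificity, which is why confirmed
targets attach verbatim with a concordance flag instead of overwriting the
prediction.

## Motif occurrence and two-step clustering

The occurrence matrix is binary (presence of ≥ 1 hit passing the q-value
threshold, default q < 0.05), keeps all-zero rows, and is idempotent under
duplicated hits. Column entropy counts the gap as a 21st symbol so alignment
columns that are half-gap register as variable. The two-step clustering
standardizes columns, picks k by mean silhouette over `k_range` (default
2–10; the source study reports six groups but not how k was chosen, so the
package selects it from the data), trains a random forest on the provisional
labels under a fixed seed, re-weights columns by normalized Gini importance
and re-clusters. Group labels are canonicalized by first appearance, making
the whole procedure deterministic for a fixed seed. De novo motif discovery
is out of scope: catalogs come from parsed MEME text, FIMO TSV, or the
internal consensus scanner (full-sequence fuzzy matching, default mismatch
fraction 0.2).

## The synthetic atlas

`simulate_atlas()` exists so that every stage can be tested against a known
answer without downloads. Planted proteins are 372–455 aa with an N-terminal
hinge, a guaranteed sequon, the conserved TVFLPK|FKLETKYSL junction segment
(two-exon loci place their intron exactly at the protein-level "|", on a
codon boundary), and a C-terminal RCL copied from a named seed with a planned
number of non-adjacent substitutions that spare P1/P1′. Reverse translation
draws codons uniformly (no codon-usage model — none of the tested statistics
depend on codon bias), intergenic sequence is i.i.d. uniform nucleotides, and
minus-strand genes are reverse-complemented into the chromosome. Decoy genes
are random proteins re-sampled until they carry no admissible RCL, and eleven
decoys sit in every inter-cluster gap so the planted partition is enforced by
the intervening-gene rule as well as by distance — mirroring the plateau
behaviour of the real data, where the 10-gene rule stabilizes the partition
across distance cutoffs. Identity-pair planting uses substitution-only
mutants with initial count ⌊L·(1−t/100)⌋, verified by `global_identity()` and
adjusted until within ±0.5 points; starting from the floor keeps a planted
98% pair at or above 98, so its tier can never fall into the diverged bin by
rounding.

The default configuration *is* the study condition: 74 loci over eight
numbered chromosomes plus one unplaced scaffold (4/2/2/2/6/50/6/1/1), strand
totals 46/28, 20 two-exon loci with introns within 498–7613 bp, intra-cluster
gaps within 679–43,544 bp, chromosome 10 partitioned into 17 clusters
including a 21-gene array, and duplicate/paralog pairs at 100/98/85% global
identity. One detail could not be copied verbatim: the published chromosome-10
partition (9 singletons, 3 pairs, 3 triples, one 4-array, one 21-array) sums
to 49 loci, while chromosome 10 carries 50 gene copies; the default plan uses
8 singletons and 4 pairs so that all 50 copies, including the duplicated one,
live inside the 17 clusters.

**What passing these tests shows — and does not.** Recovery on synthetic
atlases establishes that the pipeline's bookkeeping is exact: coordinates,
strands, mismatch counts, partitions, orientations, tiers and P1 classes all
round-trip. It does not establish sensitivity on real proteomes, where gene
models can be truncated or fused, RCLs can diverge beyond any seed's budget,
and paralogs recombine; the iterative re-seeding exists precisely because a
fixed seed set under-reaches on real data. Decoy specificity is likewise
by construction: random sequence essentially never carries a within-budget
RCL, so a 0% false-positive rate on decoys says nothing about pseudo-serpins
or non-inhibitory serpin-fold proteins.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere (GFF3 convention); half-open
  arithmetic is confined to conversions. RCL match coordinates in proteins
  are 1-based inclusive too, for consistency with the rest of the package.
* Representative transcript = longest CDS, ties broken by lexicographic
  transcript id; translation drops the leading `phase` bases, requires length
  divisible by 3, removes the trailing stop, and treats an internal stop as a
  pseudogene-like error.
* Empty proteins scan to "no match"; singleton clusters have undefined
  spacing (NA) but a defined span; a local alignment with no positive-scoring
  segment returns length 0; zero-variance matrix columns are left centered
  but unscaled; a zero-importance forest falls back to uniform weights.
* Problem sizes in the test suite: oracle scans use 1000 proteins of ≤ 200
  aa; alignment oracles use pairs of ≤ 30 aa; the full-pipeline check runs
  one 74-locus simulated genome (~6 Mb over nine sequences, ~280 decoy
  genes). These sizes were chosen to exercise every rule path while keeping
  the suite comfortably reproducible on a laptop.

## Known limitations

* Substitution-only RCL matching cannot find RCLs with indels relative to
  every seed, and profile/HMM detection is explicitly out of scope.
* The P1 rules are screening-level by design; discordance with experiments
  (documented for small-P1 serpins) is expected and surfaced, not corrected.
* Global-identity tiers depend on the scoring scheme; with very diverged
  pairs the "non-homologous" label means only "below 70% global identity
  under this scoring", not an evolutionary statement.
* The χ² density check against the real assembly requires its chromosome
  lengths as an external input, as described above.
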