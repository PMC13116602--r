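# serpinatlas

Builds a genome-wide atlas of **serpin** (serine protease inhibitor) genes
from a genome assembly and its gene annotation, and validates every stage of
the pipeline on synthetic genomes with planted ground truth.

Serpins inhibit proteases through a "suicide" mechanism: an exposed
C-terminal reactive-center loop (RCL) baits the target protease, and cleavage
at the P1|P1′ scissile bond traps it covalently. Because the RCL is the most
recognizable — and functionally decisive — part of a serpin, this package
discovers serpin genes by *fuzzy RCL matching*: each seed RCL peptide is
compared against every same-length subsequence within the last 100 residues
of each predicted protein, allowing up to 30% substitutions
(budget = ⌊0.30 × query length⌋) with the extra constraint that no two
mismatch positions may be adjacent. Per protein, one best match is kept
(fewest mismatches, then earliest offset), and newly discovered RCLs are fed
back as seeds until the hit set stops growing.

Downstream of discovery the package provides:

- **Locus features** — hinge motif (NAVYFKG/NAIYFKG), N-glycosylation sequons
  (Asn-X-Ser/Thr, X ≠ Pro), molecular weight (average masses), isoelectric
  point (Henderson–Hasselbalch with the EMBOSS pKa table, solved by
  bisection), and externally supplied signal-peptide calls. Loci are named
  `S<k>c<chromosome>` in genome order (`S<k>j<contig>` on unplaced
  scaffolds).
- **Tandem clusters** — maximal runs of serpin loci where each neighboring
  pair is ≤ 100 kb apart boundary-to-boundary *and* separated by ≤ 10
  intervening annotated genes; adjacent-pair orientations (head-to-tail /
  head-to-head / tail-to-tail), spacing statistics, a threshold sensitivity
  sweep, an exact binomial strand-bias test, and a length-weighted χ²
  goodness-of-fit test of per-chromosome counts
  (E_i = N·L_i/ΣL, df = #chromosomes − 1).
- **Duplication tiers** — all-vs-all Needleman–Wunsch and Smith–Waterman
  alignments (BLOSUM62, gap 11/1) with global identity computed over the full
  alignment length *including* terminal-gap columns; tiers: exact duplicate
  (100%), recent paralog [98, 100), diverged paralog [70, 98), otherwise
  non-homologous.
- **P1 rule engine** — Schechter–Berger numbering of the RCL (P15…P1 |
  P1′…P4′) and screening-level target-class prediction: V/I with small P1′ →
  dual; R/K → coagulation/complement (trypsin-like); F/Y/W/L/I/V/M →
  inflammation control (chymotrypsin-like); A/S/G → tissue protection
  (elastase-like); otherwise unknown.
- **Motif groups** — binary sequence-by-motif occurrence matrices (from FIMO
  TSV, MEME text, or the internal consensus scanner), sliding-window Shannon
  entropy over alignments, and a two-step importance-weighted agglomerative
  clustering (Ward → random-forest importances → weighted Ward).
- **Synthetic atlases** — `simulate_atlas()` reverse-engineers serpin-like
  proteins (hinge, sequon, conserved TVFLPK|FKLETKYSL splice junction,
  seeded RCL with planned mismatches) into chromosomes with planted clusters,
  strand patterns, duplicate pairs at chosen identities, and decoy genes,
  emitting full truth tables.

## Worked example

```r
library(serpinatlas)

sim      <- simulate_atlas(default_atlas_config(seed = 1))
proteome <- extract_proteome(sim$genome, sim$genes)
hits     <- scan_proteome(proteome, sim$seed_rcls)
atlas    <- build_atlas(hits, sim$genes, proteome)
s        <- atlas_summary(atlas)

s$n_loci                         # 74
s$chromosome_share_pct["Chr10"]  # 67.6
c(s$n_plus, s$n_minus)           # 46 28
s$multi_exon                     # numerator 20, denominator 74

cl <- call_clusters(atlas, sim$genes)
table(cl$n_members[cl$chromosome == "Chr10"])
#  1  2  3  4 21
#  8  4  3  1  1

strand_bias_test(atlas)$p_two_sided
# 0.04739298
```

The simulated genome plants 74 serpin loci (50 on chromosome 10, in 17
tandem clusters including one 21-gene array), 46 on the plus strand and 28 on
the minus strand, and 20 two-exon genes — the scan recovers all of them and
none of the decoy genes, so the summary above reproduces the planted
structure exactly. The binomial p-value for a 46/28 strand split is 0.047.

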