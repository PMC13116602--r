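Package: serpinatlas
Title: Genome-Wide Atlas of Serpin Genes from Fuzzy Reactive-Center-Loop Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a genome-wide atlas of serine protease inhibitor (serpin)
    genes from a genome assembly and its gene annotation. Candidate serpins are
    discovered by fuzzy matching of seed reactive-center-loop (RCL) peptides
    within the C-terminal window of each predicted protein, with a mismatch
    budget and a no-adjacent-mismatch run constraint, iterated to a fixed point
    by re-seeding with newly discovered RCLs. Each locus is annotated with hinge
    motif, N-glycosylation sequons, molecular weight, isoelectric point and
    externally supplied signal-peptide calls; tandem gene clusters are called
    from boundary-to-boundary distance and intervening-gene rules; all-vs-all
    global and local alignments classify duplication tiers; Schechter-Berger
    P1/P1' rules predict target protease classes; and motif occurrence matrices
    are clustered by a two-step importance-weighted agglomerative procedure.
    A synthetic-genome generator plants serpin loci with full ground truth so
    every pipeline stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    cluster,
    randomForest,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
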