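test_that("read_annotation builds gene models from GFF3", {
  path <- withr::local_tempfile(fileext = ".gff3")
  write_tiny_gff3(path)
  genes <- read_annotation(path)
  expect_named(genes, c("g1", "g2"))
  expect_equal(genes$g1$strand, "+")
  expect_equal(genes$g1$span_start, 101)
  expect_equal(genes$g1$span_end, 250)
  t1 <- genes$g1$transcripts[["g1.t1"]]
  expect_equal(nrow(t1$exons), 2)
  expect_equal(intron_lengths(t1), 40L)
  expect_equal(t1$coding_length, 110L)
  # single-exon gene
  expect_equal(nrow(genes$g2$transcripts[["g2.t1"]]$exons), 1)
})

test_that("a two-exon transcript with a 1 kb gap yields intron length 1000", {
  t <- transcript_model("t", data.frame(start = c(1, 1101), end = c(100, 1200)))
  expect_equal(intron_lengths(t), 1000L)
})

test_that("a CDS lacking a parent transcript is an error naming the orphan", {
  path <- withr::local_tempfile(fileext = ".gff3")
  write_tiny_gff3(path, orphan_cds = TRUE)
  expect_error(read_annotation(path), "orphan1|missing.t1")
})

test_that("malformed annotation lines are reported with their line number", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "Chr1\ttest\tgene\t1\t100\t.\t+\t.\tID=g1",
               "Chr1\tbroken line without enough fields"), path)
  expect_error(read_annotation(path), "line 3")
})

test_that("records with unknown strand are rejected with a warning", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "Chr1\ttest\tgene\t1\t90\t.\t+\t.\tID=g1",
               "Chr1\ttest\tmRNA\t1\t90\t.\t+\t.\tID=g1.t1;Parent=g1",
               "Chr1\ttest\tCDS\t1\t90\t.\t+\t0\tParent=g1.t1",
               "Chr1\ttest\tgene\t200\t290\t.\t.\t.\tID=g2"), path)
  expect_warning(genes <- read_annotation(path), "unknown strand")
  expect_named(genes, "g1")
})

test_that("GTF dialect parsing groups features by gene_id/transcript_id", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("Chr2\tsrc\texon\t11\t70\t.\t+\t.\t",
           "gene_id \"gA\"; transcript_id \"gA.t1\";"),
    paste0("Chr2\tsrc\tCDS\t11\t70\t.\t+\t0\t",
           "gene_id \"gA\"; transcript_id \"gA.t1\";")), path)
  genes <- read_annotation(path, dialect = "gtf")
  expect_named(genes, "gA")
  expect_equal(genes$gA$transcripts[["gA.t1"]]$coding_length, 60L)
})

test_that("representative transcript maximizes coding length, ties by id", {
  mk <- function(id, len)
    transcript_model(id, data.frame(start = 1, end = len),
                     data.frame(start = 1, end = len, phase = 0))
  g <- gene_model("g", "Chr1", "+", list(a = mk("t_a", 900), b = mk("t_b", 1200)))
  expect_equal(select_representative_transcript(g)$transcript_id, "t_b")
  # single transcript: identity
  g1 <- gene_model("g1", "Chr1", "+", list(a = mk("only", 300)))
  expect_equal(select_representative_transcript(g1)$transcript_id, "only")
  # ties: lexicographically smallest id, in either insertion order
  gt1 <- gene_model("g", "Chr1", "+", list(mk("tB", 900), mk("tA", 900)))
  gt2 <- gene_model("g", "Chr1", "+", list(mk("tA", 900), mk("tB", 900)))
  expect_equal(select_representative_transcript(gt1)$transcript_id, "tA")
  expect_equal(select_representative_transcript(gt2)$transcript_id, "tA")
  # no coding transcript is an error naming the gene
  gnc <- gene_model("gX", "Chr1", "+",
                    list(transcript_model("t", data.frame(start = 1, end = 30))))
  expect_error(select_representative_transcript(gnc), "gX")
})

test_that("translation follows the standard code, both strands, stop trimmed", {
  genome <- Biostrings::DNAStringSet(c(Chr1 = "ATGGCTTAA"))
  t <- transcript_model("t1", data.frame(start = 1, end = 9),
                        data.frame(start = 1, end = 9, phase = 0))
  g <- gene_model("g", "Chr1", "+", list(t1 = t))
  expect_equal(translate_representative(genome, g), "MA")

  # same CDS on the minus strand of its reverse complement
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString("ATGGCTTAA")))
  genome2 <- Biostrings::DNAStringSet(setNames(rc, "Chr1"))
  g2 <- gene_model("g", "Chr1", "-", list(t1 = t))
  expect_equal(translate_representative(genome2, g2), "MA")

  # internal stop codon flags a pseudogene-like model
  genome3 <- Biostrings::DNAStringSet(c(Chr1 = "ATGTAAGCTTAA"))
  t3 <- transcript_model("t1", data.frame(start = 1, end = 12),
                         data.frame(start = 1, end = 12, phase = 0))
  g3 <- gene_model("g", "Chr1", "+", list(t1 = t3))
  expect_error(translate_representative(genome3, g3), "pseudogene")

  # length not divisible by 3
  t4 <- transcript_model("t1", data.frame(start = 1, end = 8),
                         data.frame(start = 1, end = 8, phase = 0))
  g4 <- gene_model("g", "Chr1", "+", list(t1 = t4))
  expect_error(translate_representative(genome, g4), "divisible by 3")
})

test_that("serpin GFF3 output round-trips through read_annotation", {
  sim <- simulate_atlas(tiny_config())
  prote <- extract_proteome(sim$genome, sim$genes)
  hits <- scan_proteome(prote, sim$seed_rcls)
  atlas <- build_atlas(hits, sim$genes, prote)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_serpin_gff(atlas, path, genes = sim$genes)
  back <- read_annotation(path)
  expect_setequal(names(back), atlas$gene_id)
  for (i in seq_len(nrow(atlas))) {
    g <- back[[atlas$gene_id[i]]]
    expect_equal(g$span_start, atlas$gene_start[i])
    expect_equal(g$span_end, atlas$gene_end[i])
    expect_equal(g$strand, atlas$strand[i])
  }
  # RCL sub-features are present and inside their gene span
  gr <- rtracklayer::import(path, format = "gff3")
  rcl <- gr[gr$type == "serpin_rcl"]
  expect_gte(length(rcl), nrow(atlas))
  # empty atlas gives a header-only file
  path2 <- withr::local_tempfile(fileext = ".gff3")
  write_serpin_gff(atlas[0, ], path2)
  expect_equal(readLines(path2), "##gff-version 3")
})

test_that("exon lengths of the representative transcript sum to coding length", {
  sim <- simulate_atlas(tiny_config())
  for (g in sim$genes) {
    t <- select_representative_transcript(g)
    expect_equal(sum(t$exons$end - t$exons$start + 1), t$coding_length)
  }
})
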