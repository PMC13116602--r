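# Independent oracles used to cross-check the implementation. These are kept
# deliberately naive and share no code with the package internals.

# Brute-force best-RCL search: enumerate every (query, offset) pair in the
# C-terminal window, apply the budget and adjacency rules position by
# position, and pick fewest mismatches -> smallest offset -> query order
# (queries pre-sorted by id).
oracle_scan <- function(protein, queries, window_len = 100,
                        max_mismatch_fraction = 0.30) {
  queries <- queries[order(names(queries))]
  L <- nchar(protein)
  best <- NULL
  for (qi in seq_along(queries)) {
    q <- toupper(queries[[qi]])
    m <- nchar(q)
    budget <- floor(max_mismatch_fraction * m)
    lo <- max(1, L - window_len + 1)
    if (lo + m - 1 > L) next
    for (s in lo:(L - m + 1)) {
      mism <- 0; prev_mism <- FALSE; ok <- TRUE
      for (k in 1:m) {
        ca <- toupper(substr(protein, s + k - 1, s + k - 1))
        cb <- substr(q, k, k)
        is_mis <- (ca != cb) || ca == "X" || cb == "X"
        if (is_mis) {
          mism <- mism + 1
          if (prev_mism) { ok <- FALSE; break }
        }
        prev_mism <- is_mis
      }
      if (!ok || mism > budget) next
      if (is.null(best) || mism < best$mismatches ||
          (mism == best$mismatches && s < best$start)) {
        best <- list(query_id = names(queries)[qi], start = s,
                     end = s + m - 1, mismatches = mism)
      }
    }
  }
  best
}

# Gotoh global alignment score with affine gaps (cost open + extend * L) and
# penalized end gaps, matrix-free of the package code.
oracle_global_score <- function(a, b, submat, open = 11, extend = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -(open + extend * (i - 1))
  for (j in 2:(m + 1)) Iy[1, j] <- -(open + extend * (j - 1))
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[av[i - 1], bv[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - open - extend, Ix[i - 1, j] - extend)
      Iy[i, j] <- max(M[i, j - 1] - open - extend, Iy[i, j - 1] - extend)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# Gotoh local (Smith-Waterman) score.
oracle_local_score <- function(a, b, submat, open = 11, extend = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(0, n + 1, m + 1); F <- matrix(0, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - extend, E[i, j - 1] - extend)
      F[i, j] <- max(H[i - 1, j] - open - extend, F[i - 1, j] - extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + submat[av[i - 1], bv[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

random_protein_fixed <- function(n, seed) withr::with_seed(seed, random_protein(n))

random_protein <- function(n) {
  paste(sample(c("A","R","N","D","C","E","Q","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V"), n, replace = TRUE),
        collapse = "")
}

# printed per-chromosome gene counts shipped with the package
shipped_counts <- function() {
  utils::read.delim(system.file("extdata", "serpin_counts_per_chromosome.tsv",
                                package = "serpinatlas"))
}

shipped_p1_catalog <- function() {
  utils::read.delim(system.file("extdata", "serpin_p1_catalog.tsv",
                                package = "serpinatlas"),
                    na.strings = "NA", colClasses = "character")
}

# Chromosome lengths of the real assembly are an external input (they are not
# printed in a form this package can ship); tests that need them load this
# table and fail with a clear message when it is absent.
load_assembly_chrom_lengths <- function() {
  path <- system.file("extdata", "assembly_chrom_lengths.tsv",
                      package = "serpinatlas")
  if (!nzchar(path))
    stop("assembly chromosome-length table not bundled; supply ",
         "inst/extdata/assembly_chrom_lengths.tsv (chromosome, length_bp) ",
         "from the assembly sequence report")
  utils::read.delim(path)
}

# One study-scale simulation shared across test files (expensive to build).
.sim_cache <- new.env(parent = emptyenv())
study_sim <- function() {
  if (is.null(.sim_cache$sim))
    .sim_cache$sim <- simulate_atlas(default_atlas_config(seed = 101L))
  .sim_cache$sim
}
study_proteome <- function() {
  if (is.null(.sim_cache$proteome))
    .sim_cache$proteome <- extract_proteome(study_sim()$genome, study_sim()$genes)
  .sim_cache$proteome
}
study_atlas <- function() {
  if (is.null(.sim_cache$atlas)) {
    sim <- study_sim()
    hits <- scan_proteome(study_proteome(), sim$seed_rcls)
    .sim_cache$atlas <- build_atlas(hits, sim$genes, study_proteome())
  }
  .sim_cache$atlas
}

# small simulation plan: 6 loci on two chromosomes, mixed architectures and
# strands, one exact-duplicate pair, one cluster of three
tiny_config <- function(seed = 11L) {
  plan <- data.frame(
    locus_id = sprintf("tg%02d", 1:6),
    chromosome = c("Chr1", "Chr1", "Chr1", "Chr1", "Chr2", "Chr2"),
    cluster = c(1, 1, 1, 2, 1, 2),
    gap_within = c(NA, 5000L, 20000L, NA, NA, NA),
    strand = c("+", "+", "-", "+", "-", "+"),
    architecture = c("intronless", "intronless", "two_exon", "intronless",
                     "two_exon", "intronless"),
    intron_length = c(NA, NA, 800L, NA, 1500L, NA),
    aa_length = c(400L, 400L, 380L, 372L, 455L, 410L),
    rcl_seed = c("rcl_coag", "rcl_coag", "rcl_chym", "rcl_dual", "rcl_elas",
                 "rcl_nonc"),
    rcl_mismatches = c(0L, 0L, 2L, 3L, 1L, 4L),
    parent = c(NA, "tg01", NA, NA, NA, NA),
    target_identity = c(NA, 100, NA, NA, NA, NA),
    stringsAsFactors = FALSE)
  atlas_sim_config(plan, seed = seed)
}

# tiny deterministic GFF3 fixture: two genes on Chr1, one two-exon
write_tiny_gff3 <- function(path, orphan_cds = FALSE) {
  lines <- c(
    "##gff-version 3",
    "Chr1\ttest\tgene\t101\t250\t.\t+\t.\tID=g1",
    "Chr1\ttest\tmRNA\t101\t250\t.\t+\t.\tID=g1.t1;Parent=g1",
    "Chr1\ttest\texon\t101\t160\t.\t+\t.\tParent=g1.t1",
    "Chr1\ttest\texon\t201\t250\t.\t+\t.\tParent=g1.t1",
    "Chr1\ttest\tCDS\t101\t160\t.\t+\t0\tParent=g1.t1",
    "Chr1\ttest\tCDS\t201\t250\t.\t+\t0\tParent=g1.t1",
    "Chr1\ttest\tgene\t1001\t1090\t.\t-\t.\tID=g2",
    "Chr1\ttest\tmRNA\t1001\t1090\t.\t-\t.\tID=g2.t1;Parent=g2",
    "Chr1\ttest\texon\t1001\t1090\t.\t-\t.\tParent=g2.t1",
    "Chr1\ttest\tCDS\t1001\t1090\t.\t-\t0\tParent=g2.t1")
  if (orphan_cds)
    lines <- c(lines, "Chr1\ttest\tCDS\t2001\t2090\t.\t+\t0\tID=orphan1;Parent=missing.t1")
  writeLines(lines, path)
  path
}
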