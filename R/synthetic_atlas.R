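# Synthetic genomes with planted serpin loci and full ground truth.
#
# The generator reverse-engineers serpin-like proteins into chromosome
# sequences: every planted protein carries an N-terminal hinge (NAVYFKG), at
# least one N-glycosylation sequon, a conserved splice-junction segment
# (TVFLPK|FKLETKYSL, where two-exon loci place their intron at the protein
# position of the "|"), and a C-terminal RCL copied from a named seed with a
# planned number of non-adjacent substitutions that spare P1/P1'. Decoy genes
# are random proteins verified to carry no within-budget RCL. All coordinates,
# strands, cluster memberships, pair identities and P1 classes are emitted as
# truth tables, so the whole pipeline can be checked against a known answer.

.AA20 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.JUNCTION_MOTIF <- "TVFLPKFKLETKYSL"  # exon1 ends after the K of TVFLPK
.JUNCTION_EXON1_AA <- 6L              # residues of the motif on exon 1
.HINGE_MOTIF <- "NAVYFKG"

#' Default seed RCL peptides for the synthetic atlas
#'
#' Five 17-mer seeds sharing a hinge-proximal prefix but pairwise >= 11
#' substitutions apart, so a planted RCL with <= 4 mismatches can never be
#' admissible (budget `floor(0.3 * 17) = 5`) against the wrong seed. Each
#' seed carries its scissile-bond metadata (`p1_offset` = 16) and the target
#' class implied by its P1/P1' residues.
#'
#' @return data.frame with columns `id`, `seq`, `p1_offset`, `class`.
#' @export
default_seed_rcls <- function() {
  df <- data.frame(
    id = c("rcl_coag", "rcl_chym", "rcl_elas", "rcl_dual", "rcl_nonc"),
    seq = c("EEGTVAAAATGVVIVRS",   # P1 = R -> coagulation_complement
            "EEGSEGMQHDWNKFDLT",   # P1 = L -> inflammation_control
            "EEGDQWHRCCDFEYHGL",   # P1 = G -> tissue_protection
            "EEGWMDEWGQHNQQYVS",   # P1 = V, P1' = S -> dual
            "EEGYHPYIVTYTMWINQ"),  # P1 = N -> unknown
    p1_offset = 16L,
    stringsAsFactors = FALSE)
  df$class <- classify_by_p1(substr(df$seq, df$p1_offset, df$p1_offset),
                             substr(df$seq, df$p1_offset + 1L, df$p1_offset + 1L))
  df
}

random_aa <- function(n) paste(sample(.AA20, n, replace = TRUE), collapse = "")

# Non-adjacent mismatch positions within 1..max_pos (P1/P1' spared by caller
# via max_pos), sampled without order bias.
sample_mismatch_positions <- function(n, max_pos) {
  if (n == 0) return(integer(0))
  pool <- seq_len(max_pos)
  picked <- integer(0)
  while (length(picked) < n) {
    if (!length(pool)) stop("cannot place ", n, " non-adjacent mismatches in ",
                            max_pos, " positions")
    p <- if (length(pool) == 1) pool else sample(pool, 1)
    picked <- c(picked, p)
    pool <- setdiff(pool, c(p - 1L, p, p + 1L))
  }
  sort(picked)
}

mutate_rcl <- function(rcl, n_mismatches, spare = integer(0)) {
  v <- strsplit(rcl, "", fixed = TRUE)[[1]]
  allowed <- setdiff(seq_along(v), spare)
  # sample non-adjacent positions from the allowed range
  pos <- integer(0); pool <- allowed
  while (length(pos) < n_mismatches) {
    if (!length(pool)) stop("cannot place ", n_mismatches,
                            " non-adjacent mismatches in the RCL")
    p <- if (length(pool) == 1) pool else sample(pool, 1)
    pos <- c(pos, p)
    pool <- setdiff(pool, c(p - 1L, p, p + 1L))
  }
  for (p in sort(pos)) v[p] <- sample(setdiff(.AA20, v[p]), 1)
  list(seq = paste(v, collapse = ""), positions = sort(pos))
}

#' Build one synthetic serpin-like protein
#'
#' @param aa_length Total protein length (residues).
#' @param rcl Planted RCL peptide (already mutated as planned).
#' @return List with `seq` and the planted feature coordinates (`hinge_start`,
#'   `sequon_pos`, `junction_end_aa` — last residue of exon 1 for two-exon
#'   loci — `rcl_start`, `rcl_end`).
#' @keywords internal
make_serpin_protein <- function(aa_length, rcl) {
  rl <- nchar(rcl)
  stopifnot(aa_length >= 120 + rl)
  hinge_start <- 30L
  sequon_pos <- 45L
  junction_start <- as.integer(floor(aa_length * 0.5))
  rcl_start <- aa_length - rl - 4L
  rcl_end <- rcl_start + rl - 1L
  v <- strsplit(random_aa(aa_length), "", fixed = TRUE)[[1]]
  v[1] <- "M"
  hv <- strsplit(.HINGE_MOTIF, "", fixed = TRUE)[[1]]
  v[hinge_start:(hinge_start + length(hv) - 1L)] <- hv
  v[sequon_pos:(sequon_pos + 2L)] <- c("N", "Q", "S")
  jv <- strsplit(.JUNCTION_MOTIF, "", fixed = TRUE)[[1]]
  v[junction_start:(junction_start + length(jv) - 1L)] <- jv
  v[rcl_start:rcl_end] <- strsplit(rcl, "", fixed = TRUE)[[1]]
  list(seq = paste(v, collapse = ""),
       hinge_start = hinge_start, sequon_pos = sequon_pos,
       junction_end_aa = junction_start + .JUNCTION_EXON1_AA - 1L,
       rcl_start = rcl_start, rcl_end = rcl_end)
}

#' Substitution-only mutant at a target global identity
#'
#' Mutates a protein at randomly chosen non-frozen positions so that its
#' global percent identity to the source (under the package's alignment
#' scoring) lies within +/- 0.5 percentage points of `target_identity`; the
#' initial substitution count is `floor(L * (1 - target/100))`, so the
#' achieved identity starts at or above the target, and is then verified with
#' [global_identity()] and adjusted if needed.
#'
#' @param protein Source protein string.
#' @param target_identity Target global identity in percent (0 < t <= 100).
#' @param frozen Integer positions that must not be mutated (e.g. the RCL and
#'   hinge).
#' @param scoring An [align_scoring()] object used for verification.
#' @return Mutated protein string (unchanged when `target_identity` is 100).
#' @export
mutate_to_identity <- function(protein, target_identity, frozen = integer(0),
                               scoring = align_scoring()) {
  stopifnot(target_identity > 0, target_identity <= 100)
  if (target_identity == 100) return(protein)
  v <- strsplit(protein, "", fixed = TRUE)[[1]]
  L <- length(v)
  candidates <- setdiff(seq_len(L), frozen)
  k <- floor(L * (1 - target_identity / 100))
  if (k > length(candidates))
    stop("target identity ", target_identity,
         "% infeasible: needs ", k, " substitutions but only ",
         length(candidates), " mutable positions")
  mutate_k <- function(k) {
    w <- v
    pos <- sample(candidates, k)
    for (p in pos) w[p] <- sample(setdiff(.AA20, w[p]), 1)
    paste(w, collapse = "")
  }
  out <- mutate_k(k)
  for (round in 1:20) {
    achieved <- global_identity(protein, out, scoring)$identity
    if (abs(achieved - target_identity) <= 0.5) return(out)
    k <- k + if (achieved > target_identity) 1L else -1L
    if (k < 0 || k > length(candidates))
      stop("cannot reach target identity ", target_identity, "% under constraints")
    out <- mutate_k(k)
  }
  stop("failed to converge to target identity ", target_identity, "%")
}

# amino acid -> codons lookup from the standard genetic code
.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)
}

reverse_translate <- function(aa, codons = .codon_table()) {
  v <- strsplit(aa, "", fixed = TRUE)[[1]]
  picks <- vapply(v, function(a) {
    cs <- codons[[a]]
    if (is.null(cs)) stop("cannot reverse-translate residue ", a)
    if (length(cs) == 1) cs else sample(cs, 1)
  }, character(1))
  paste(c(picks, "TAA"), collapse = "")
}

revcomp_chr <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' Synthetic-atlas configuration
#'
#' @param loci data.frame with one row per planted serpin locus:
#'   `locus_id`, `chromosome`, `cluster` (integer label per chromosome; loci
#'   sharing a label are laid out as one tandem cluster), `gap_within` (bp gap
#'   to the previous member of the same cluster; ignored for the first
#'   member), `strand`, `architecture` (`"intronless"`/`"two_exon"`),
#'   `intron_length`, `aa_length`, `rcl_seed`, `rcl_mismatches`, `parent`
#'   (locus_id or NA), `target_identity`.
#' @param seed Integer seed; identical seeds reproduce identical artifacts
#'   byte-for-byte.
#' @param inter_cluster_gap bp between consecutive clusters on a chromosome.
#' @param decoys_in_gaps Place decoy (non-serpin) genes inside every
#'   inter-cluster gap, so that consecutive clusters are separated by more
#'   than `max_intervening_genes` annotated genes as well as by distance.
#' @param n_gap_decoys Number of decoys spread across each inter-cluster gap
#'   (the default 11 exceeds the 10-intervening-gene cluster rule, so the
#'   planted partition is stable under any distance cutoff).
#' @param n_tail_decoys Extra decoys appended after the last locus of each
#'   chromosome.
#' @param seed_rcls Seed catalog as from [default_seed_rcls()].
#' @return List of class `atlas_sim_config`.
#' @export
atlas_sim_config <- function(loci, seed = 1L, inter_cluster_gap = 150000,
                             decoys_in_gaps = TRUE, n_gap_decoys = 11L,
                             n_tail_decoys = 1L,
                             seed_rcls = default_seed_rcls()) {
  need <- c("locus_id", "chromosome", "cluster", "gap_within", "strand",
            "architecture", "intron_length", "aa_length", "rcl_seed",
            "rcl_mismatches", "parent", "target_identity")
  miss <- setdiff(need, names(loci))
  if (length(miss)) stop("loci plan lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(loci$locus_id)) stop("duplicate locus_id in plan")
  bad_parent <- !is.na(loci$parent) & !loci$parent %in% loci$locus_id
  if (any(bad_parent))
    stop("unknown parent locus: ", paste(loci$parent[bad_parent], collapse = ", "))
  structure(list(loci = loci, seed = as.integer(seed),
                 inter_cluster_gap = inter_cluster_gap,
                 decoys_in_gaps = isTRUE(decoys_in_gaps),
                 n_gap_decoys = as.integer(n_gap_decoys),
                 n_tail_decoys = as.integer(n_tail_decoys),
                 seed_rcls = seed_rcls),
            class = "atlas_sim_config")
}

tier_of_identity <- function(target) {
  ifelse(is.na(target), NA_character_,
  ifelse(target >= 100, "exact_duplicate",
  ifelse(target >= 98, "recent_paralog",
  ifelse(target >= 70, "diverged_paralog", "non_homologous"))))
}

#' Simulate a genome with planted serpin loci
#'
#' Lays the planned loci out chromosome by chromosome (cluster members
#' separated by their planned `gap_within`, clusters by `inter_cluster_gap`),
#' reverse-translates each planted protein into the chromosome respecting
#' strand and architecture, adds decoy genes whose proteins verifiably carry
#' no within-budget RCL, and emits truth tables.
#'
#' @param config An [atlas_sim_config()].
#' @param scan Scan parameters used to verify decoys, and the budget context
#'   for planted mismatches.
#' @return List with `genome` ([Biostrings::DNAStringSet]), `genes` (named
#'   list of [gene_model()]s, serpins and decoys), `proteins` (named
#'   [Biostrings::AAStringSet] of representative proteins), `seed_rcls`
#'   (named vector for scanning), `seed_info` (seed metadata incl.
#'   `p1_offset`), and `truth` (list of `loci`, `clusters`, `pairs`,
#'   `strand_counts` tables).
#' @export
simulate_atlas <- function(config, scan = scan_params()) {
  stopifnot(inherits(config, "atlas_sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)
  codons <- .codon_table()
  seeds <- config$seed_rcls
  seed_vec <- stats::setNames(seeds$seq, seeds$id)
  plan <- config$loci

  # --- proteins (parents before children) -------------------------------
  proteins <- list(); feats <- list()
  order_idx <- order(!is.na(plan$parent))  # parents (parent NA) first
  for (i in order_idx) {
    row <- plan[i, ]
    if (is.na(row$parent)) {
      srow <- seeds[seeds$id == row$rcl_seed, ]
      if (!nrow(srow)) stop("unknown rcl_seed: ", row$rcl_seed)
      spare <- c(srow$p1_offset, srow$p1_offset + 1L)
      mut <- mutate_rcl(srow$seq, row$rcl_mismatches, spare = spare)
      pr <- make_serpin_protein(row$aa_length, mut$seq)
      pr$rcl_mismatch_positions <- mut$positions
    } else {
      parent_feat <- feats[[row$parent]]
      frozen <- c(1L,
                  parent_feat$hinge_start:(parent_feat$hinge_start + 6L),
                  parent_feat$sequon_pos:(parent_feat$sequon_pos + 2L),
                  (parent_feat$junction_end_aa - .JUNCTION_EXON1_AA + 1L):
                    (parent_feat$junction_end_aa + nchar(.JUNCTION_MOTIF) -
                       .JUNCTION_EXON1_AA),
                  parent_feat$rcl_start:parent_feat$rcl_end)
      pr <- parent_feat
      pr$seq <- mutate_to_identity(proteins[[row$parent]],
                                   row$target_identity, frozen = frozen)
    }
    proteins[[row$locus_id]] <- pr$seq
    feats[[row$locus_id]] <- pr
  }

  # --- layout ------------------------------------------------------------
  plan$gene_len <- 3L * (plan$aa_length + 1L) +
    ifelse(plan$architecture == "two_exon", plan$intron_length, 0L)
  plan$start <- NA_integer_; plan$end <- NA_integer_
  decoy_spots <- list()
  for (chrom in unique(plan$chromosome)) {
    idx <- which(plan$chromosome == chrom)
    cursor <- 50000L
    prev_cluster <- NA
    for (i in idx) {
      if (!is.na(prev_cluster) && identical(plan$cluster[i], prev_cluster)) {
        gap <- plan$gap_within[i]
      } else {
        gap <- config$inter_cluster_gap
        if (config$decoys_in_gaps && !is.na(prev_cluster)) {
          offs <- as.integer(round(gap * seq(0.12, 0.88,
                                             length.out = config$n_gap_decoys)))
          for (o in offs)
            decoy_spots[[length(decoy_spots) + 1L]] <-
              list(chromosome = chrom, start = cursor + o)
        }
      }
      plan$start[i] <- cursor + as.integer(gap) + 1L
      plan$end[i] <- plan$start[i] + plan$gene_len[i] - 1L
      cursor <- plan$end[i]
      prev_cluster <- plan$cluster[i]
    }
    for (d in seq_len(config$n_tail_decoys))
      decoy_spots[[length(decoy_spots) + 1L]] <-
        list(chromosome = chrom, start = cursor + 60000L * d)
  }
  # overlap check before any output
  for (chrom in unique(plan$chromosome)) {
    p <- plan[plan$chromosome == chrom, ]
    p <- p[order(p$start), ]
    if (nrow(p) > 1 && any(p$start[-1] <= p$end[-nrow(p)]))
      stop("overlapping locus plans on ", chrom)
  }

  # --- decoys -------------------------------------------------------------
  decoys <- list()
  for (k in seq_along(decoy_spots)) {
    spot <- decoy_spots[[k]]
    repeat {
      aa <- paste0("M", random_aa(299L))
      if (is.null(scan_protein(aa, seed_vec, scan, protein_id = "decoy"))) break
    }
    decoys[[k]] <- list(decoy_id = sprintf("decoy%03d", k),
                        chromosome = spot$chromosome, start = spot$start,
                        strand = sample(c("+", "-"), 1), seq = aa)
  }

  # --- assemble chromosomes and gene models -------------------------------
  chrom_ids <- unique(c(plan$chromosome,
                        vapply(decoys, function(d) d$chromosome, character(1))))
  chrom_len <- vapply(chrom_ids, function(ch) {
    ends <- c(plan$end[plan$chromosome == ch],
              vapply(Filter(function(d) d$chromosome == ch, decoys),
                     function(d) as.numeric(d$start) + 1000, numeric(1)))
    max(ends) + 50000
  }, numeric(1))
  chrom_seq <- lapply(chrom_len, function(n) random_aa_dna(n))
  names(chrom_seq) <- chrom_ids

  genes <- list()
  truth_rows <- list()
  for (i in seq_len(nrow(plan))) {
    row <- plan[i, ]
    feat <- feats[[row$locus_id]]
    nt <- reverse_translate(feat$seq, codons)  # CDS incl. stop, mRNA sense
    two_exon <- row$architecture == "two_exon"
    if (two_exon) {
      n1 <- 3L * feat$junction_end_aa
      n2 <- nchar(nt) - n1
      intron <- random_aa_dna(row$intron_length)
      if (row$strand == "+") {
        cds <- data.frame(start = c(row$start, row$start + n1 + row$intron_length),
                          end = c(row$start + n1 - 1L, row$end),
                          phase = c(0L, 0L))
        gseq <- paste0(substr(nt, 1, n1), intron, substr(nt, n1 + 1L, nchar(nt)))
      } else {
        cds <- data.frame(start = c(row$start, row$start + n2 + row$intron_length),
                          end = c(row$start + n2 - 1L, row$end),
                          phase = c(0L, 0L))
        gseq <- revcomp_chr(paste0(substr(nt, 1, n1), intron,
                                   substr(nt, n1 + 1L, nchar(nt))))
      }
    } else {
      cds <- data.frame(start = row$start, end = row$end, phase = 0L)
      gseq <- if (row$strand == "+") nt else revcomp_chr(nt)
    }
    stopifnot(nchar(gseq) == row$gene_len)
    substr(chrom_seq[[row$chromosome]], row$start, row$end) <- gseq
    tid <- paste0(row$locus_id, ".t1")
    genes[[row$locus_id]] <- gene_model(
      row$locus_id, row$chromosome, row$strand,
      stats::setNames(list(transcript_model(tid, cds[, c("start", "end")], cds)), tid))
    truth_rows[[i]] <- data.frame(
      locus_id = row$locus_id, protein_id = tid,
      chromosome = row$chromosome, strand = row$strand,
      gene_start = row$start, gene_end = row$end,
      architecture = row$architecture,
      exon_count = if (two_exon) 2L else 1L,
      intron_length = if (two_exon) row$intron_length else NA_integer_,
      aa_length = nchar(feat$seq),
      cluster = row$cluster, gap_within = row$gap_within,
      rcl_seed = row$rcl_seed, rcl_mismatches = row$rcl_mismatches,
      rcl_start = feat$rcl_start, rcl_end = feat$rcl_end,
      hinge_start = feat$hinge_start,
      p1 = substr(feat$seq, feat$rcl_start + 15L, feat$rcl_start + 15L),
      p1_prime = substr(feat$seq, feat$rcl_start + 16L, feat$rcl_start + 16L),
      parent = row$parent, target_identity = row$target_identity,
      protein = feat$seq, stringsAsFactors = FALSE)
  }
  for (d in decoys) {
    nt <- reverse_translate(d$seq, codons)
    dend <- d$start + nchar(nt) - 1L
    gseq <- if (d$strand == "+") nt else revcomp_chr(nt)
    substr(chrom_seq[[d$chromosome]], d$start, dend) <- gseq
    tid <- paste0(d$decoy_id, ".t1")
    cds <- data.frame(start = d$start, end = dend, phase = 0L)
    genes[[d$decoy_id]] <- gene_model(
      d$decoy_id, d$chromosome, d$strand,
      stats::setNames(list(transcript_model(tid, cds[, c("start", "end")], cds)), tid))
  }

  truth_loci <- do.call(rbind, truth_rows)
  truth_loci$p1_class <- classify_by_p1(truth_loci$p1, truth_loci$p1_prime)
  truth_loci$tier <- tier_of_identity(truth_loci$target_identity)
  # planted serpin names, derived from planted coordinates
  truth_loci$serpin_name <- assign_serpin_names(
    data.frame(chromosome = truth_loci$chromosome,
               gene_start = truth_loci$gene_start))

  # planted cluster truth: membership, orientations, spacings per cluster
  truth_clusters <- do.call(rbind, lapply(
    split(truth_loci, list(truth_loci$chromosome, truth_loci$cluster),
          drop = TRUE),
    function(m) {
      m <- m[order(m$gene_start), ]
      k <- nrow(m)
      data.frame(
        chromosome = m$chromosome[1], cluster = m$cluster[1], n_members = k,
        start = m$gene_start[1], end = m$gene_end[k],
        members = I(list(m$serpin_name)),
        orientations = I(list(if (k > 1)
          classify_pair_orientation(m$strand[-k], m$strand[-1]) else character(0))),
        intergenic_distances = I(list(if (k > 1)
          as.integer(m$gene_start[-1] - m$gene_end[-k] - 1L) else integer(0))),
        stringsAsFactors = FALSE)
    }))
  truth_clusters <- truth_clusters[order(chromosome_rank(truth_clusters$chromosome),
                                         truth_clusters$start), ]
  rownames(truth_clusters) <- NULL

  rel <- truth_loci[!is.na(truth_loci$parent),
                    c("locus_id", "parent", "target_identity", "tier")]
  prot_all <- c(stats::setNames(vapply(truth_loci$locus_id,
                                       function(id) proteins[[id]], character(1)),
                                truth_loci$protein_id),
                stats::setNames(vapply(decoys, function(d) d$seq, character(1)),
                                vapply(decoys, function(d) paste0(d$decoy_id, ".t1"),
                                       character(1))))

  list(
    genome = Biostrings::DNAStringSet(vapply(chrom_seq, identity, character(1))),
    genes = genes,
    proteins = Biostrings::AAStringSet(prot_all),
    seed_rcls = seed_vec,
    seed_info = seeds,
    truth = list(loci = truth_loci, clusters = truth_clusters, pairs = rel,
                 strand_counts = c(`+` = sum(truth_loci$strand == "+"),
                                   `-` = sum(truth_loci$strand == "-"))),
    config = config)
}

random_aa_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                   collapse = "")

#' Write simulated artifacts to disk
#'
#' @param sim Result of [simulate_atlas()].
#' @param dir Output directory (created if needed): `genome.fa`,
#'   `annotation.gff3`, `proteins.fa`, `truth_loci.tsv`, `truth_clusters.tsv`.
#' @return `dir`, invisibly.
#' @export
write_atlas_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  write_annotation_gff3(sim$genes, file.path(dir, "annotation.gff3"))
  write_protein_fasta(sim$proteins, file.path(dir, "proteins.fa"))
  tl <- sim$truth$loci
  utils::write.table(tl, file.path(dir, "truth_loci.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tc <- sim$truth$clusters
  tc$members <- vapply(tc$members, paste, character(1), collapse = ",")
  tc$orientations <- vapply(tc$orientations, paste, character(1), collapse = ",")
  tc$intergenic_distances <- vapply(tc$intergenic_distances,
                                    function(x) paste(x, collapse = ","),
                                    character(1))
  utils::write.table(tc, file.path(dir, "truth_clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Default study-scale synthetic atlas configuration
#'
#' Mirrors the structure of the tick serpin repertoire: 74 loci over eight
#' numbered chromosomes plus one unplaced scaffold (4/2/2/2/6/50/6/1/1 on
#' Chr1/2/3/4/5/10/11/13/unplaced); chromosome 10 carries 50 loci in 17
#' tandem clusters (8 singletons, 4 pairs, 3 triples, one 4-gene array and
#' one 21-gene array); strand totals 46 plus / 28 minus; 20 two-exon loci
#' with intron lengths within 498-7613 bp; intra-cluster gaps within
#' 679-43544 bp; duplicate/paralog pairs planted at 100, 98 and 85 percent
#' global identity.
#'
#' @param seed Integer seed (also used by [simulate_atlas()]).
#' @return An [atlas_sim_config()].
#' @export
default_atlas_config <- function(seed = 1L) {
  set.seed(seed)
  # per-chromosome cluster sizes and strand patterns
  chrom_plan <- list(
    Chr1 = list(sizes = c(2, 1, 1), strands = c("+", "+", "+", "-")),
    Chr2 = list(sizes = 2, strands = c("+", "+")),
    Chr3 = list(sizes = c(1, 1), strands = c("+", "-")),
    Chr4 = list(sizes = 2, strands = c("-", "-")),
    Chr5 = list(sizes = c(2, 2, 1, 1), strands = c("+", "+", "-", "-", "+", "-")),
    Chr10 = list(
      sizes = c(21, 4, 3, 3, 3, 2, 2, 2, 2, rep(1, 8)),
      strands = c(rep("+", 10), "-", "-", rep("+", 4), "-", "-", "-", "-", "-",  # 21
                  "+", "+", "+", "-",                                            # 4
                  "+", "+", "+",  "+", "-", "+",  "-", "-", "-",                 # 3x3
                  "+", "+",  "+", "+",  "-", "+",  "+", "-",                     # 4x2
                  "+", "+", "+", "-", "-", "-", "-", "-")),                      # 8x1
    Chr11 = list(sizes = c(3, 1, 1, 1), strands = c("+", "+", "-", "+", "-", "+")),
    Chr13 = list(sizes = 1, strands = "+"),
    JSYNTH010000234.1 = list(sizes = 1, strands = "+"))

  seeds <- default_seed_rcls()
  rows <- list()
  n <- 0L
  for (chrom in names(chrom_plan)) {
    cp <- chrom_plan[[chrom]]
    stopifnot(sum(cp$sizes) == length(cp$strands))
    pos <- 0L
    for (ci in seq_along(cp$sizes)) {
      for (j in seq_len(cp$sizes[ci])) {
        n <- n + 1L; pos <- pos + 1L
        rows[[n]] <- data.frame(
          locus_id = sprintf("sg%03d", n), chromosome = chrom, cluster = ci,
          gap_within = if (j == 1) NA_integer_ else sample(679:43544, 1),
          strand = cp$strands[pos],
          architecture = "intronless", intron_length = NA_integer_,
          aa_length = sample(372:455, 1),
          rcl_seed = seeds$id[((n - 1L) %% nrow(seeds)) + 1L],
          rcl_mismatches = sample(0:4, 1),
          parent = NA_character_, target_identity = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  plan <- do.call(rbind, rows)

  # 20 two-exon loci spread over the genome (none of them a planted
  # identity-pair member, so architecture is independent of the pair plan)
  two_exon_ids <- sprintf("sg%03d", c(1, 3, 7, 9, 15, 21, 23, 25, 27, 29,
                                      31, 33, 35, 44, 46, 56, 59, 61, 67, 69))
  sel <- plan$locus_id %in% two_exon_ids
  plan$architecture[sel] <- "two_exon"
  plan$intron_length[sel] <- sample(498:7613, sum(sel))

  # planted identity pairs: children point at the previous locus in the plan
  # (same cluster), inheriting architecture/seed so the pair is comparable
  make_child <- function(plan, child, parent, identity) {
    i <- match(child, plan$locus_id); j <- match(parent, plan$locus_id)
    plan$parent[i] <- parent
    plan$target_identity[i] <- identity
    plan$aa_length[i] <- plan$aa_length[j]
    plan$architecture[i] <- plan$architecture[j]
    plan$intron_length[i] <- plan$intron_length[j]
    plan$rcl_seed[i] <- plan$rcl_seed[j]
    plan$rcl_mismatches[i] <- plan$rcl_mismatches[j]
    plan
  }
  # exact duplicates (4 pairs): Chr2 pair, both Chr5 pairs, one Chr10 pair
  plan <- make_child(plan, "sg006", "sg005", 100)   # Chr2
  plan <- make_child(plan, "sg012", "sg011", 100)   # Chr5 pair A
  plan <- make_child(plan, "sg014", "sg013", 100)   # Chr5 pair B
  # Chr10 loci are sg017..sg066 (21-array sg017..sg037, quad sg038..sg041,
  # triples sg042..sg050, pairs sg051..sg058, singletons sg059..sg066)
  plan <- make_child(plan, "sg052", "sg051", 100)   # Chr10 pair
  # recent paralogs at 98%
  plan <- make_child(plan, "sg018", "sg017", 98)
  plan <- make_child(plan, "sg020", "sg019", 98)
  plan <- make_child(plan, "sg054", "sg053", 98)
  # diverged paralogs at 85%
  plan <- make_child(plan, "sg039", "sg038", 85)
  plan <- make_child(plan, "sg043", "sg042", 85)

  atlas_sim_config(plan, seed = seed)
}
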