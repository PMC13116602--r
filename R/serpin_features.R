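# Protein-level features of candidate serpins: N-glycosylation sequons,
# the conserved N-terminal hinge motif, molecular weight, isoelectric point,
# and externally supplied signal-peptide calls.

# Average (isotope-averaged) residue masses in Da, Expasy values.
.AA_AVG_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.WATER_MASS <- 18.01524

# EMBOSS pKa values used for the isoelectric point.
.EMBOSS_PKA <- c(Nterm = 8.6, Cterm = 3.6,
                 C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5, Y = 10.1)

#' Find N-glycosylation sequons (Asn-X-Ser/Thr, X != Pro)
#'
#' All (possibly overlapping) positions `i` with `seq[i] == N`,
#' `seq[i+1] != P` and `seq[i+2]` in `{S, T}` are reported.
#'
#' @param seq Protein string.
#' @return Integer vector of 1-based positions of the Asn.
#' @export
find_sequons <- function(seq) {
  v <- strsplit(toupper(as.character(seq)), "", fixed = TRUE)[[1]]
  n <- length(v)
  if (n < 3) return(integer(0))
  i <- seq_len(n - 2L)
  i[v[i] == "N" & v[i + 1L] != "P" & v[i + 2L] %in% c("S", "T")]
}

#' Locate the conserved N-terminal hinge motif
#'
#' Returns the earliest window, lying entirely within the N-terminal half of
#' the protein, with at most `max_mismatches` substitutions against the motif.
#' The default tolerance of one mismatch accepts both the NAVYFKG and NAIYFKG
#' variants of the serpin scaffold signature.
#'
#' @param seq Protein string.
#' @param motif Hinge motif peptide.
#' @param max_mismatches Substitution budget.
#' @return 1-based start position, or `NA_integer_` if not found.
#' @export
find_hinge <- function(seq, motif = "NAVYFKG", max_mismatches = 1L) {
  stopifnot(nchar(motif) >= 1L)
  v <- strsplit(toupper(as.character(seq)), "", fixed = TRUE)[[1]]
  mv <- strsplit(toupper(motif), "", fixed = TRUE)[[1]]
  m <- length(mv)
  half_end <- floor(length(v) / 2)
  if (half_end < m) return(NA_integer_)
  for (s in 1:(half_end - m + 1L)) {
    w <- v[s:(s + m - 1L)]
    if (sum(w != mv | w == "X" | mv == "X") <= max_mismatches) return(s)
  }
  NA_integer_
}

#' Molecular weight of a protein (average masses)
#'
#' Sum of average residue masses plus one water. `X` contributes the mean of
#' the twenty residue masses; any other non-standard letter is an error.
#'
#' @param seq Protein string.
#' @return Mass in Da.
#' @export
molecular_weight <- function(seq) {
  v <- strsplit(toupper(as.character(seq)), "", fixed = TRUE)[[1]]
  unknown <- setdiff(unique(v), c(names(.AA_AVG_MASS), "X"))
  if (length(unknown))
    stop("unknown residue(s): ", paste(unknown, collapse = ", "))
  masses <- .AA_AVG_MASS[v]
  masses[v == "X"] <- mean(.AA_AVG_MASS)
  sum(masses) + .WATER_MASS
}

# Net charge at a given pH under Henderson-Hasselbalch.
protein_net_charge <- function(counts, pH, pKa = .EMBOSS_PKA) {
  pos <- 1 / (1 + 10^(pH - pKa["Nterm"])) +
    counts["K"] / (1 + 10^(pH - pKa["K"])) +
    counts["R"] / (1 + 10^(pH - pKa["R"])) +
    counts["H"] / (1 + 10^(pH - pKa["H"]))
  neg <- 1 / (1 + 10^(pKa["Cterm"] - pH)) +
    counts["D"] / (1 + 10^(pKa["D"] - pH)) +
    counts["E"] / (1 + 10^(pKa["E"] - pH)) +
    counts["C"] / (1 + 10^(pKa["C"] - pH)) +
    counts["Y"] / (1 + 10^(pKa["Y"] - pH))
  unname(pos - neg)
}

#' Isoelectric point by bisection
#'
#' pH at which the Henderson-Hasselbalch net charge over the termini and the
#' ionizable residues (D, E, C, Y, H, K, R) crosses zero. The pKa table
#' defaults to the EMBOSS values and can be overridden.
#'
#' @param seq Protein string.
#' @param pKa Named numeric vector with entries `Nterm`, `Cterm`, `C`, `D`,
#'   `E`, `H`, `K`, `R`, `Y`.
#' @param tol Bisection tolerance in pH units.
#' @return Estimated pI.
#' @export
isoelectric_point <- function(seq, pKa = .EMBOSS_PKA, tol = 0.001) {
  v <- strsplit(toupper(as.character(seq)), "", fixed = TRUE)[[1]]
  counts <- vapply(c("K", "R", "H", "D", "E", "C", "Y"),
                   function(a) sum(v == a), numeric(1))
  lo <- 0; hi <- 14
  # net charge is monotone decreasing in pH
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (protein_net_charge(counts, mid, pKa) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Attach external signal-peptide calls to atlas loci
#'
#' Signal-peptide prediction is never re-implemented here; calls come from an
#' external run (e.g. SignalP) as a two-column table. Loci without a call get
#' `NA` ("unknown"), which summaries count separately.
#'
#' @param loci Atlas data.frame with a `protein_id` column.
#' @param calls data.frame with columns `protein_id` and `signal_peptide`
#'   (logical). Duplicate, conflicting calls for one id are an error.
#' @return `loci` with a `signal_peptide` column (logical, NA = unknown).
#' @export
attach_signal_peptides <- function(loci, calls) {
  if (is.null(calls) || nrow(calls) == 0) {
    loci$signal_peptide <- NA
    return(loci)
  }
  stopifnot(all(c("protein_id", "signal_peptide") %in% names(calls)))
  agg <- tapply(calls$signal_peptide, calls$protein_id,
                function(x) length(unique(x)))
  if (any(agg > 1))
    stop("conflicting signal-peptide calls for: ",
         paste(names(agg)[agg > 1], collapse = ", "))
  calls <- calls[!duplicated(calls$protein_id), ]
  loci$signal_peptide <- calls$signal_peptide[match(loci$protein_id,
                                                    calls$protein_id)]
  loci
}

# Chromosome token used in serpin names: trailing integer of a chromosome-like
# id ("Chr10" -> "c10"), or "j<contig#>" for unplaced WGS-style scaffolds
# ("JAMZAT010000234.1" -> "j234", dropping the two-digit WGS version after the
# letter prefix and leading zeros of the serial).
chromosome_token <- function(id) {
  vapply(id, function(x) {
    base <- sub("\\.\\d+$", "", x)
    if (grepl("^(chr|chromosome[_ ]?)?\\d+$", base, ignore.case = TRUE)) {
      paste0("c", sub("^\\D*", "", base))
    } else if (grepl("^[A-Za-z]{4,6}\\d{4,}$", base)) {
      digits <- sub("^[A-Za-z]+", "", base)
      serial <- substring(digits, 3)
      paste0("j", as.integer(serial))
    } else if (grepl("\\d+$", base)) {
      paste0("j", as.integer(sub("^.*?(\\d+)$", "\\1", base)))
    } else {
      paste0("j_", base)
    }
  }, character(1), USE.NAMES = FALSE)
}

# Rank used to order chromosomes for naming: numbered chromosomes first (by
# number), then unplaced scaffolds (by id). Equal ids share one rank.
chromosome_rank <- function(id) {
  u <- unique(id)
  base <- sub("\\.\\d+$", "", u)
  isnum <- grepl("^(chr|chromosome[_ ]?)?\\d+$", base, ignore.case = TRUE)
  num <- suppressWarnings(as.integer(sub("^\\D*", "", base)))
  num[!isnum] <- NA_integer_
  r <- order(order(is.na(num), num, u))
  r[match(id, u)]
}

#' Assign atlas serpin names
#'
#' Names follow `S<k>c<chromosome>` with `k` numbered sequentially along the
#' genome (chromosomes in numeric order, loci by start coordinate); loci on
#' unplaced scaffolds get `S<k>j<contig#>`.
#'
#' @param loci data.frame with `chromosome` and `gene_start` columns.
#' @return Character vector of serpin names aligned with `loci` rows.
#' @export
assign_serpin_names <- function(loci) {
  rank <- chromosome_rank(loci$chromosome)
  ord <- order(rank, loci$gene_start)
  serial <- integer(nrow(loci))
  serial[ord] <- seq_len(nrow(loci))
  paste0("S", serial, chromosome_token(loci$chromosome))
}

#' Build the serpin atlas table
#'
#' Joins RCL scan hits back to gene models and the genome: one row per serpin
#' locus with gene coordinates, exon structure, RCL coordinates (protein and
#' genome space), hinge position, sequon count, molecular weight, isoelectric
#' point and (optional) signal-peptide call.
#'
#' @param hits Scan hits from [scan_proteome()] / [iterate_to_fixed_point()].
#' @param genes Named list of `gene_model`s; hit protein ids must be
#'   representative transcript ids of these genes.
#' @param proteins Named character vector / `AAStringSet` of the proteome.
#' @param signalp Optional signal-peptide call table
#'   (see [attach_signal_peptides()]).
#' @param hinge_motif,hinge_max_mismatches Hinge search settings.
#' @return Atlas data.frame, one row per locus, ordered and named along the
#'   genome.
#' @export
build_atlas <- function(hits, genes, proteins, signalp = NULL,
                        hinge_motif = "NAVYFKG", hinge_max_mismatches = 1L) {
  prot <- as_named_character(proteins)
  reps <- lapply(genes, select_representative_transcript)
  tx2gene <- stats::setNames(
    vapply(genes, function(g) g$gene_id, character(1)),
    vapply(reps, function(t) t$transcript_id, character(1)))

  rows <- lapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    gid <- tx2gene[[h$protein_id]]
    if (is.null(gid)) stop("hit protein ", h$protein_id,
                           " is not a representative transcript of any gene")
    g <- genes[[gid]]
    t <- reps[[gid]]
    aa <- prot[[h$protein_id]]
    sequons <- find_sequons(aa)
    data.frame(
      serpin_name = NA_character_,
      gene_id = gid, transcript_id = t$transcript_id,
      protein_id = h$protein_id,
      chromosome = g$chromosome, strand = g$strand,
      gene_start = g$span_start, gene_end = g$span_end,
      exon_count = nrow(t$exons),
      protein_length = nchar(aa),
      rcl_query = h$query_id, rcl_start = h$start, rcl_end = h$end,
      rcl_mismatches = h$mismatches,
      rcl_genomic = rcl_genomic_coords(g, t, h$start, h$end),
      hinge_position = find_hinge(aa, hinge_motif, hinge_max_mismatches),
      n_sequons = length(sequons),
      molecular_weight = molecular_weight(aa),
      isoelectric_point = isoelectric_point(aa),
      stringsAsFactors = FALSE)
  })
  atlas <- do.call(rbind, rows)
  rownames(atlas) <- NULL
  atlas$serpin_name <- assign_serpin_names(atlas)
  atlas <- atlas[order(chromosome_rank(atlas$chromosome), atlas$gene_start), ]
  rownames(atlas) <- NULL
  atlas <- attach_signal_peptides(atlas, signalp)
  atlas
}

#' Summarize an atlas
#'
#' Recomputes (never caches) the headline descriptive statistics: per
#' chromosome counts and shares, strand totals, protein length / molecular
#' weight / isoelectric point ranges, multi-exon counts (with explicit
#' numerator and denominator) and signal-peptide tallies.
#'
#' @param atlas Atlas data.frame from [build_atlas()] (or the counts-only
#'   variant used by [chromosome_share()]).
#' @return A list of summary components.
#' @export
atlas_summary <- function(atlas) {
  per_chrom <- sort(table(atlas$chromosome), decreasing = TRUE)
  n <- nrow(atlas)
  multi <- sum(atlas$exon_count > 1)
  list(
    n_loci = n,
    per_chromosome = per_chrom,
    chromosome_share_pct = round(100 * per_chrom / n, 1),
    n_plus = sum(atlas$strand == "+"),
    n_minus = sum(atlas$strand == "-"),
    length_range = range(atlas$protein_length),
    mw_range_kda = range(atlas$molecular_weight) / 1000,
    pi_range = range(atlas$isoelectric_point),
    pi_median = stats::median(atlas$isoelectric_point),
    multi_exon = c(numerator = multi, denominator = n),
    multi_exon_pct = round(100 * multi / n, 1),
    signal_peptide = c(yes = sum(atlas$signal_peptide %in% TRUE),
                       no = sum(atlas$signal_peptide %in% FALSE),
                       unknown = sum(is.na(atlas$signal_peptide))))
}

#' Share of loci on one chromosome from a count table
#'
#' @param counts Named integer vector of per-chromosome locus counts.
#' @param chromosome Chromosome of interest.
#' @return Percentage (0-100), rounded to one decimal.
#' @export
chromosome_share <- function(counts, chromosome) {
  round(100 * counts[[chromosome]] / sum(counts), 1)
}

#' Write the atlas as TSV
#' @param atlas Atlas data.frame.
#' @param path Output path.
#' @export
write_atlas_tsv <- function(atlas, path) {
  utils::write.table(atlas, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
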