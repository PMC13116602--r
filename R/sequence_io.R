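# Genome / annotation I/O and gene-model handling.
#
# All coordinates in this package are 1-based inclusive (GFF3 convention).
# Gene models are plain S3 lists so they can be built both from parsed
# annotation files and from the synthetic-atlas generator.

#' Read a genome FASTA
#'
#' @param path Path to a (possibly multi-record) nucleotide FASTA file.
#' @return A named [Biostrings::DNAStringSet]; names are the sequence ids
#'   (first whitespace-delimited token of each header).
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate sequence ids in genome FASTA: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  x
}

#' Construct a transcript model
#'
#' @param transcript_id Transcript identifier.
#' @param exons data.frame with columns `start`, `end` (1-based inclusive).
#' @param cds data.frame with columns `start`, `end`, `phase` (phase may be NA,
#'   treated as 0). May have zero rows for non-coding transcripts.
#' @return An object of class `transcript_model` with computed `coding_length`.
#' @export
transcript_model <- function(transcript_id, exons, cds = exons[0, c("start", "end")]) {
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop("overlapping exons in transcript ", transcript_id)
  cds <- as.data.frame(cds)
  if (!"phase" %in% names(cds)) cds$phase <- rep(0L, nrow(cds))
  cds$phase[is.na(cds$phase)] <- 0L
  cds <- cds[order(cds$start), , drop = FALSE]
  coding_length <- if (nrow(cds)) sum(cds$end - cds$start + 1L) else 0L
  structure(
    list(transcript_id = transcript_id, exons = exons, cds = cds,
         coding_length = as.integer(coding_length)),
    class = "transcript_model")
}

#' Intron lengths of a transcript
#'
#' Gaps between consecutive exons, in bp.
#' @param t A `transcript_model`.
#' @return Integer vector (empty for single-exon transcripts).
#' @export
intron_lengths <- function(t) {
  ex <- t$exons
  if (nrow(ex) < 2) return(integer(0))
  as.integer(ex$start[-1] - ex$end[-nrow(ex)] - 1L)
}

#' Construct a gene model
#'
#' @param gene_id Gene identifier.
#' @param chromosome Sequence id the gene lies on.
#' @param strand `"+"` or `"-"`.
#' @param transcripts List of `transcript_model` objects.
#' @return An object of class `gene_model`; `span_start`/`span_end` cover all
#'   transcript exons.
#' @export
gene_model <- function(gene_id, chromosome, strand, transcripts) {
  if (!strand %in% c("+", "-"))
    stop("gene ", gene_id, ": strand must be '+' or '-', got '", strand, "'")
  starts <- unlist(lapply(transcripts, function(t) t$exons$start))
  ends <- unlist(lapply(transcripts, function(t) t$exons$end))
  structure(
    list(gene_id = gene_id, chromosome = chromosome, strand = strand,
         transcripts = transcripts,
         span_start = if (length(starts)) min(starts) else NA_integer_,
         span_end = if (length(ends)) max(ends) else NA_integer_),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model %s  %s:%s-%s (%s)  %d transcript(s)>\n",
              x$gene_id, x$chromosome, x$span_start, x$span_end, x$strand,
              length(x$transcripts)))
  invisible(x)
}

# Light syntactic pre-check so malformed rows are reported with a line number
# (rtracklayer's own errors do not carry one).
validate_annotation_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !grepl("^\\s*(#|$)", lines)
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 8)
  if (length(bad))
    stop("annotation parse error at line ", which(body)[bad[1]],
         ": expected >= 8 tab-separated fields, found ", nf[bad[1]])
  coord_ok <- vapply(fields, function(f)
    !is.na(suppressWarnings(as.integer(f[4]))) &&
      !is.na(suppressWarnings(as.integer(f[5]))), logical(1))
  if (any(!coord_ok))
    stop("annotation parse error at line ", which(body)[which(!coord_ok)[1]],
         ": start/end are not integers")
  invisible(TRUE)
}

#' Read a GFF3 or GTF annotation into gene models
#'
#' Parses the file with [rtracklayer::import()] and assembles a list of
#' [gene_model()] objects: features are grouped by gene, transcripts attached,
#' strand preserved. Records with a strand other than `+`/`-` are rejected
#' with a warning. A CDS feature whose parent transcript does not exist is an
#' error naming the orphan feature.
#'
#' @param path Annotation file path.
#' @param dialect `"gff3"`, `"gtf"`, or `"auto"` (by file extension).
#' @return Named list of `gene_model` objects (names are gene ids).
#' @export
read_annotation <- function(path, dialect = c("auto", "gff3", "gtf")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.(gtf)(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "gff3"
  validate_annotation_lines(path)
  gr <- rtracklayer::import(path, format = if (dialect == "gtf") "gtf" else "gff3")
  if (dialect == "gtf") assemble_genes_gtf(gr) else assemble_genes_gff3(gr)
}

reject_bad_strands <- function(df, id) {
  bad <- !df$strand %in% c("+", "-")
  if (any(bad)) {
    warning("rejected ", sum(bad), " record(s) with unknown strand: ",
            paste(utils::head(id[bad], 5), collapse = ", "), call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  df
}

granges_to_df <- function(gr) {
  data.frame(
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type), stringsAsFactors = FALSE)
}

assemble_genes_gff3 <- function(gr) {
  df <- granges_to_df(gr)
  df$id <- as.character(gr$ID)
  parent <- gr$Parent
  df$parent <- vapply(seq_along(parent), function(i) {
    p <- parent[[i]]
    if (length(p)) as.character(p[1]) else NA_character_
  }, character(1))
  df$phase <- if (!is.null(gr$phase)) as.integer(gr$phase) else NA_integer_
  df <- reject_bad_strands(df, ifelse(is.na(df$id), df$parent, df$id))

  tx_types <- c("mRNA", "transcript")
  tx_rows <- df[df$type %in% tx_types, , drop = FALSE]
  exon_rows <- df[df$type == "exon", , drop = FALSE]
  cds_rows <- df[df$type == "CDS", , drop = FALSE]

  known_tx <- tx_rows$id
  orphan <- !cds_rows$parent %in% known_tx
  if (any(orphan))
    stop("CDS feature(s) lack a parent transcript: ",
         paste(unique(ifelse(is.na(cds_rows$id[orphan]),
                             cds_rows$parent[orphan],
                             cds_rows$id[orphan])), collapse = ", "))
  orphan_ex <- !exon_rows$parent %in% known_tx
  if (any(orphan_ex))
    stop("exon feature(s) lack a parent transcript: ",
         paste(unique(exon_rows$parent[orphan_ex]), collapse = ", "))

  genes <- list()
  gene_rows <- df[df$type == "gene", , drop = FALSE]
  for (k in seq_len(nrow(gene_rows))) {
    gid <- gene_rows$id[k]
    tx_here <- tx_rows[tx_rows$parent %in% gid, , drop = FALSE]
    txs <- lapply(seq_len(nrow(tx_here)), function(j) {
      tid <- tx_here$id[j]
      ex <- exon_rows[exon_rows$parent == tid, c("start", "end"), drop = FALSE]
      cd <- cds_rows[cds_rows$parent == tid, c("start", "end", "phase"), drop = FALSE]
      if (!nrow(ex)) ex <- cd[, c("start", "end"), drop = FALSE]
      transcript_model(tid, ex, cd)
    })
    names(txs) <- tx_here$id
    genes[[gid]] <- gene_model(gid, gene_rows$chromosome[k],
                               gene_rows$strand[k], txs)
  }
  genes
}

assemble_genes_gtf <- function(gr) {
  df <- granges_to_df(gr)
  df$gene_id <- as.character(gr$gene_id)
  df$transcript_id <- if (!is.null(gr$transcript_id))
    as.character(gr$transcript_id) else NA_character_
  df$phase <- if (!is.null(gr$phase)) as.integer(gr$phase) else NA_integer_
  df <- reject_bad_strands(df, df$gene_id)

  feat <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  orphan <- is.na(feat$transcript_id) | feat$transcript_id == ""
  if (any(orphan))
    stop("CDS/exon feature(s) lack a parent transcript (no transcript_id) for gene(s): ",
         paste(unique(feat$gene_id[orphan]), collapse = ", "))

  genes <- list()
  for (gid in unique(feat$gene_id)) {
    sub <- feat[feat$gene_id == gid, , drop = FALSE]
    txs <- lapply(unique(sub$transcript_id), function(tid) {
      ex <- sub[sub$transcript_id == tid & sub$type == "exon",
                c("start", "end"), drop = FALSE]
      cd <- sub[sub$transcript_id == tid & sub$type == "CDS",
                c("start", "end", "phase"), drop = FALSE]
      if (!nrow(ex)) ex <- cd[, c("start", "end"), drop = FALSE]
      transcript_model(tid, ex, cd)
    })
    names(txs) <- unique(sub$transcript_id)
    genes[[gid]] <- gene_model(gid, sub$chromosome[1], sub$strand[1], txs)
  }
  genes
}

#' Select the representative (longest-coding) transcript of a gene
#'
#' The representative model is the transcript with the longest CDS; ties are
#' broken by lexicographically smallest transcript id so the choice is
#' deterministic.
#'
#' @param gene A `gene_model`.
#' @return A `transcript_model`.
#' @export
select_representative_transcript <- function(gene) {
  coding <- Filter(function(t) t$coding_length > 0, gene$transcripts)
  if (!length(coding))
    stop("gene ", gene$gene_id, " has no coding transcript")
  len <- vapply(coding, function(t) t$coding_length, integer(1))
  ids <- vapply(coding, function(t) t$transcript_id, character(1))
  best <- which(len == max(len))
  coding[[best[order(ids[best])[1]]]]
}

#' Translate the coding sequence of a transcript
#'
#' Concatenates CDS segments in genomic order (reverse-complemented for the
#' minus strand), drops the leading `phase` bases of the first translated
#' segment, translates with the standard genetic code and removes the trailing
#' stop. An internal stop codon is an error (pseudogene-like model), as is a
#' CDS length not divisible by 3 after phase adjustment.
#'
#' @param genome Named [Biostrings::DNAStringSet] (or named character vector).
#' @param gene A `gene_model` supplying chromosome and strand.
#' @param transcript A `transcript_model`; defaults to the representative one.
#' @return Single protein string (character).
#' @export
translate_representative <- function(genome, gene,
                                     transcript = select_representative_transcript(gene)) {
  chrom <- gene$chromosome
  if (!chrom %in% names(genome))
    stop("chromosome ", chrom, " not present in genome")
  cds <- transcript$cds
  if (!nrow(cds)) stop("transcript ", transcript$transcript_id, " has no CDS")
  chrom_seq <- if (methods::is(genome, "DNAStringSet")) genome[[chrom]]
               else Biostrings::DNAString(genome[[chrom]])
  if (max(cds$end) > length(chrom_seq) || min(cds$start) < 1L)
    stop("CDS coordinates of ", transcript$transcript_id,
         " exceed chromosome bounds")
  segs <- Biostrings::DNAStringSet(Biostrings::Views(chrom_seq, cds$start, cds$end))
  nt <- Biostrings::DNAString(paste(as.character(segs), collapse = ""))
  first_phase <- if (gene$strand == "+") cds$phase[1] else cds$phase[nrow(cds)]
  if (gene$strand == "-") nt <- Biostrings::reverseComplement(nt)
  if (first_phase > 0) nt <- Biostrings::subseq(nt, start = first_phase + 1L)
  if (length(nt) %% 3L != 0L)
    stop("CDS length of ", transcript$transcript_id,
         " is not divisible by 3 after phase adjustment")
  aa <- as.character(Biostrings::translate(nt, if.fuzzy.codon = "X"))
  aa <- sub("\\*$", "", aa)
  if (grepl("*", aa, fixed = TRUE))
    stop("internal stop codon in ", transcript$transcript_id,
         " (pseudogene-like model)")
  aa
}

#' Translate the representative transcript of every gene
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param genes Named list of `gene_model`s.
#' @return Named [Biostrings::AAStringSet]; names are the representative
#'   transcript ids, with a `gene_id` metadata column mapping back.
#' @export
extract_proteome <- function(genome, genes) {
  reps <- lapply(genes, select_representative_transcript)
  aa <- vapply(seq_along(genes),
               function(i) translate_representative(genome, genes[[i]], reps[[i]]),
               character(1))
  out <- Biostrings::AAStringSet(aa)
  names(out) <- vapply(reps, function(t) t$transcript_id, character(1))
  S4Vectors::mcols(out)$gene_id <- vapply(genes, function(g) g$gene_id, character(1))
  out
}

gff3_attr_escape <- function(x) gsub("([;=,\t])", "%", x)

#' Write serpin loci (with RCL sub-features) as GFF3
#'
#' Emits one `gene` feature per locus and one `serpin_rcl` sub-feature per
#' contiguous genomic segment of the RCL match (two segments when the RCL
#' straddles an intron). When `genes` is supplied, the representative
#' transcript's `mRNA`/`exon`/`CDS` features are written too, so the file
#' round-trips through [read_annotation()].
#'
#' @param loci Atlas data.frame (see [build_atlas()]); an empty data.frame
#'   yields a header-only file.
#' @param path Output path.
#' @param genes Optional named list of `gene_model`s keyed by `gene_id`.
#' @return `path`, invisibly.
#' @export
write_serpin_gff <- function(loci, path, genes = NULL) {
  lines <- "##gff-version 3"
  src <- "serpinatlas"
  for (i in seq_len(nrow(loci))) {
    r <- loci[i, ]
    gid <- gff3_attr_escape(r$gene_id)
    lines <- c(lines, paste(
      r$chromosome, src, "gene", r$gene_start, r$gene_end, ".", r$strand, ".",
      sprintf("ID=%s;Name=%s", gid, gff3_attr_escape(r$serpin_name)),
      sep = "\t"))
    if (!is.null(genes) && r$gene_id %in% names(genes)) {
      tr <- select_representative_transcript(genes[[r$gene_id]])
      tid <- gff3_attr_escape(tr$transcript_id)
      lines <- c(lines, paste(
        r$chromosome, src, "mRNA", min(tr$exons$start), max(tr$exons$end), ".",
        r$strand, ".", sprintf("ID=%s;Parent=%s", tid, gid), sep = "\t"))
      for (j in seq_len(nrow(tr$exons)))
        lines <- c(lines, paste(
          r$chromosome, src, "exon", tr$exons$start[j], tr$exons$end[j], ".",
          r$strand, ".", sprintf("Parent=%s", tid), sep = "\t"))
      for (j in seq_len(nrow(tr$cds)))
        lines <- c(lines, paste(
          r$chromosome, src, "CDS", tr$cds$start[j], tr$cds$end[j], ".",
          r$strand, tr$cds$phase[j], sprintf("Parent=%s", tid), sep = "\t"))
    }
    if (!is.null(r$rcl_genomic) && !is.na(r$rcl_genomic) && nzchar(r$rcl_genomic)) {
      segs <- strsplit(r$rcl_genomic, ",", fixed = TRUE)[[1]]
      for (k in seq_along(segs)) {
        se <- as.integer(strsplit(segs[k], "-", fixed = TRUE)[[1]])
        lines <- c(lines, paste(
          r$chromosome, src, "serpin_rcl", se[1], se[2], ".", r$strand, ".",
          sprintf("ID=%s_rcl_%d;Parent=%s;rcl_query=%s;mismatches=%s",
                  gid, k, gid, r$rcl_query, r$rcl_mismatches),
          sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Map protein positions of an RCL match to genomic segments
#'
#' @param gene A `gene_model`.
#' @param transcript Its representative `transcript_model`.
#' @param aa_start,aa_end 1-based inclusive protein coordinates.
#' @return Character scalar `"start-end"` or `"s1-e1,s2-e2"` (genomic,
#'   1-based inclusive, segments in genomic order).
#' @export
rcl_genomic_coords <- function(gene, transcript, aa_start, aa_end) {
  cds <- transcript$cds
  widths <- cds$end - cds$start + 1L
  # coding-nucleotide offsets of the match, 1-based along the mRNA
  nt_start <- (aa_start - 1L) * 3L + 1L
  nt_end <- aa_end * 3L
  first_phase <- if (gene$strand == "+") cds$phase[1] else cds$phase[nrow(cds)]
  nt_start <- nt_start + first_phase
  nt_end <- nt_end + first_phase
  # walk CDS blocks in translation order
  ord <- if (gene$strand == "+") seq_len(nrow(cds)) else rev(seq_len(nrow(cds)))
  segs <- character(0)
  offset <- 0L
  for (b in ord) {
    w <- widths[b]
    lo <- max(nt_start, offset + 1L)
    hi <- min(nt_end, offset + w)
    if (lo <= hi) {
      if (gene$strand == "+") {
        g1 <- cds$start[b] + (lo - offset - 1L)
        g2 <- cds$start[b] + (hi - offset - 1L)
      } else {
        g2 <- cds$end[b] - (lo - offset - 1L)
        g1 <- cds$end[b] - (hi - offset - 1L)
      }
      segs <- c(segs, sprintf("%d-%d", g1, g2))
    }
    offset <- offset + w
  }
  # report in genomic order
  starts <- as.integer(sub("-.*", "", segs))
  paste(segs[order(starts)], collapse = ",")
}

#' Write a full annotation (gene/mRNA/exon/CDS) as GFF3
#'
#' @param genes Named list of `gene_model`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  src <- "serpinatlas"
  for (g in genes) {
    gid <- gff3_attr_escape(g$gene_id)
    lines <- c(lines, paste(g$chromosome, src, "gene", g$span_start, g$span_end,
                            ".", g$strand, ".", sprintf("ID=%s", gid), sep = "\t"))
    for (t in g$transcripts) {
      tid <- gff3_attr_escape(t$transcript_id)
      lines <- c(lines, paste(g$chromosome, src, "mRNA", min(t$exons$start),
                              max(t$exons$end), ".", g$strand, ".",
                              sprintf("ID=%s;Parent=%s", tid, gid), sep = "\t"))
      for (j in seq_len(nrow(t$exons)))
        lines <- c(lines, paste(g$chromosome, src, "exon", t$exons$start[j],
                                t$exons$end[j], ".", g$strand, ".",
                                sprintf("Parent=%s", tid), sep = "\t"))
      for (j in seq_len(nrow(t$cds)))
        lines <- c(lines, paste(g$chromosome, src, "CDS", t$cds$start[j],
                                t$cds$end[j], ".", g$strand, t$cds$phase[j],
                                sprintf("Parent=%s", tid), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a protein FASTA
#'
#' @param proteins Named character vector or [Biostrings::AAStringSet].
#' @param path Output path.
#' @export
write_protein_fasta <- function(proteins, path) {
  if (!methods::is(proteins, "AAStringSet"))
    proteins <- Biostrings::AAStringSet(proteins)
  Biostrings::writeXStringSet(proteins, path)
  invisible(path)
}
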