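# All-vs-all pairwise protein alignment and duplication-tier classification.
#
# Global identity is the fraction of identical aligned residue pairs over the
# FULL alignment length, terminal-gap columns included; local identity is over
# the columns of the optimal local alignment. Alignments use BLOSUM62 with
# affine gaps (open 11, extend 1; BLASTP defaults) unless overridden.

#' Alignment scoring settings
#'
#' @param matrix Name of a substitution matrix bundled with Biostrings
#'   (e.g. `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return List of class `align_scoring`.
#' @export
align_scoring <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  structure(list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend),
            class = "align_scoring")
}

.get_submat <- function(scoring) {
  e <- new.env()
  utils::data(list = scoring$matrix, package = "Biostrings", envir = e)
  get(scoring$matrix, envir = e)
}

.identity_from_aligned <- function(pa, sa) {
  a <- strsplit(pa, "", fixed = TRUE)[[1]]
  b <- strsplit(sa, "", fixed = TRUE)[[1]]
  matches <- sum(a == b & a != "-")
  list(identity = 100 * matches / length(a), length = length(a))
}

#' Global (Needleman-Wunsch) percent identity
#'
#' @param a,b Protein strings (non-empty).
#' @param scoring An [align_scoring()] object.
#' @return List with `identity` (percent over all alignment columns, terminal
#'   gaps included) and `length` (alignment columns).
#' @export
global_identity <- function(a, b, scoring = align_scoring()) {
  if (!nchar(a) || !nchar(b)) stop("empty sequence")
  sm <- .get_submat(scoring)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = sm, gapOpening = scoring$gap_open,
    gapExtension = scoring$gap_extend, type = "global")
  .identity_from_aligned(as.character(Biostrings::alignedPattern(aln)),
                         as.character(Biostrings::alignedSubject(aln)))
}

#' Local (Smith-Waterman) alignment metrics
#'
#' @inheritParams global_identity
#' @return List with `identity` (percent over local alignment columns),
#'   `length` (local alignment columns), `start`, `end` (1-based in `a`).
#'   When no positive-scoring segment exists, `length` is 0 and the other
#'   fields are NA.
#' @export
local_alignment <- function(a, b, scoring = align_scoring()) {
  if (!nchar(a) || !nchar(b)) stop("empty sequence")
  sm <- .get_submat(scoring)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = sm, gapOpening = scoring$gap_open,
    gapExtension = scoring$gap_extend, type = "local")
  pa <- as.character(Biostrings::pattern(aln))
  if (!nchar(pa) || Biostrings::score(aln) <= 0)
    return(list(identity = NA_real_, length = 0L,
                start = NA_integer_, end = NA_integer_))
  id <- .identity_from_aligned(pa, as.character(Biostrings::subject(aln)))
  list(identity = id$identity, length = id$length,
       start = Biostrings::start(Biostrings::pattern(aln)),
       end = Biostrings::end(Biostrings::pattern(aln)))
}

#' All-vs-all pairwise identity table
#'
#' Computes global and local alignment metrics for every unordered pair of
#' proteins: exactly `n * (n - 1) / 2` rows, in canonical (sorted-id) order,
#' independent of input order.
#'
#' @param proteins Named character vector or [Biostrings::AAStringSet]
#'   (>= 2 sequences, unique ids).
#' @param scoring An [align_scoring()] object.
#' @return data.frame with columns `id_a`, `id_b`, `global_identity`,
#'   `global_aln_length`, `local_identity`, `local_aln_length`,
#'   `query_start`, `query_end` (local coordinates in `id_a`).
#' @export
all_vs_all <- function(proteins, scoring = align_scoring()) {
  prot <- as_named_character(proteins)
  ids <- names(prot)
  if (is.null(ids)) stop("proteins must be named")
  if (anyDuplicated(ids))
    stop("duplicate protein ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(prot) < 2) stop("need at least 2 proteins")
  ord <- order(ids)
  prot <- prot[ord]; ids <- ids[ord]
  n <- length(prot)
  sm <- .get_submat(scoring)
  aa <- Biostrings::AAStringSet(prot)

  rows <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    rest <- aa[(i + 1):n]
    g <- Biostrings::pairwiseAlignment(
      rest, aa[[i]], substitutionMatrix = sm, gapOpening = scoring$gap_open,
      gapExtension = scoring$gap_extend, type = "global")
    # NB: in this orientation the set is the *pattern* and protein i the
    # subject, so local query coordinates in protein i come from subject().
    l <- Biostrings::pairwiseAlignment(
      rest, aa[[i]], substitutionMatrix = sm, gapOpening = scoring$gap_open,
      gapExtension = scoring$gap_extend, type = "local")
    gp <- as.character(Biostrings::alignedPattern(g))
    gs <- as.character(Biostrings::alignedSubject(g))
    gid <- vapply(seq_along(gp), function(k) {
      r <- .identity_from_aligned(gp[k], gs[k]); c(r$identity, r$length)
    }, numeric(2))
    lp <- as.character(Biostrings::pattern(l))
    ls <- as.character(Biostrings::subject(l))
    lsc <- Biostrings::score(l)
    lid <- vapply(seq_along(lp), function(k) {
      if (!nchar(lp[k]) || lsc[k] <= 0)
        return(c(NA_real_, 0, NA_real_, NA_real_))
      r <- .identity_from_aligned(lp[k], ls[k])
      c(r$identity, r$length,
        Biostrings::start(Biostrings::subject(l))[k],
        Biostrings::end(Biostrings::subject(l))[k])
    }, numeric(4))
    rows[[i]] <- data.frame(
      id_a = ids[i], id_b = ids[(i + 1):n],
      global_identity = gid[1, ], global_aln_length = as.integer(gid[2, ]),
      local_identity = lid[1, ], local_aln_length = as.integer(lid[2, ]),
      query_start = as.integer(lid[3, ]), query_end = as.integer(lid[4, ]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify duplication tiers from global identity
#'
#' Contiguous half-open bins: exact duplicate at 100%, recent paralog in
#' `[98, 100)`, diverged paralog in `[70, 98)`, below 70% treated as
#' non-homologous at the level of global alignment. Bin edges are recorded as
#' an attribute and configurable.
#'
#' @param pairs data.frame from [all_vs_all()].
#' @param recent_edge,diverged_edge Lower bin edges (percent identity).
#' @return `pairs` with a `tier` column; tier counts in
#'   `attr(, "tier_counts")` and bin edges in `attr(, "tier_edges")`.
#' @export
classify_tiers <- function(pairs, recent_edge = 98, diverged_edge = 70) {
  g <- pairs$global_identity
  tier <- ifelse(g >= 100, "exact_duplicate",
          ifelse(g >= recent_edge, "recent_paralog",
          ifelse(g >= diverged_edge, "diverged_paralog", "non_homologous")))
  pairs$tier <- factor(tier, levels = c("exact_duplicate", "recent_paralog",
                                        "diverged_paralog", "non_homologous"))
  attr(pairs, "tier_counts") <- table(pairs$tier)
  attr(pairs, "tier_edges") <- c(exact = 100, recent = recent_edge,
                                 diverged = diverged_edge)
  pairs
}

#' Write the pairwise identity table as TSV
#' @param pairs data.frame from [all_vs_all()] / [classify_tiers()].
#' @param path Output path.
#' @export
write_pairs_tsv <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
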