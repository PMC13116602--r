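# Fuzzy reactive-center-loop (RCL) scanning.
#
# Serpin discovery works by comparing each seed RCL peptide against every
# same-length subsequence lying entirely within the C-terminal window of a
# protein. A candidate window is admissible when the number of substitutions
# stays within the mismatch budget AND no two mismatch positions are adjacent
# (a run of >= 2 consecutive mismatches disqualifies the window). Per protein
# only one best match is kept: fewest mismatches, then earliest offset, then
# seed order (seeds sorted by id).

#' Scan parameters for RCL matching
#'
#' @param window_len C-terminal window, in residues. Proteins shorter than
#'   this are scanned in full.
#' @param max_mismatch_fraction Mismatch budget as a fraction of the query
#'   length; the per-query budget is `floor(fraction * nchar(query))`.
#' @param forbid_adjacent_mismatches Disallow two adjacent mismatch positions.
#' @return A list of class `scan_params`.
#' @export
scan_params <- function(window_len = 100L, max_mismatch_fraction = 0.30,
                        forbid_adjacent_mismatches = TRUE) {
  stopifnot(window_len >= 1L,
            max_mismatch_fraction >= 0, max_mismatch_fraction < 1)
  structure(list(window_len = as.integer(window_len),
                 max_mismatch_fraction = max_mismatch_fraction,
                 forbid_adjacent_mismatches = isTRUE(forbid_adjacent_mismatches)),
            class = "scan_params")
}

#' Hamming distance with a no-adjacent-mismatch constraint
#'
#' Counts substitution mismatches between two equal-length peptides and tests
#' admissibility: count within `budget` and (optionally) no two mismatch
#' positions adjacent. Comparison is case-insensitive; `X` mismatches every
#' residue, including another `X`.
#'
#' @param a,b Equal-length peptide strings.
#' @param budget Maximum allowed mismatches.
#' @param forbid_adjacent Disallow adjacent mismatch positions.
#' @return List with `count`, `admissible`, and 1-based `positions`.
#' @export
hamming_with_run_constraint <- function(a, b, budget, forbid_adjacent = TRUE) {
  if (nchar(a) != nchar(b))
    stop("sequences must have equal length (", nchar(a), " vs ", nchar(b), ")")
  av <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  bv <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  mis <- which(av != bv | av == "X" | bv == "X")
  ok <- length(mis) <= budget &&
    (!forbid_adjacent || length(mis) < 2 || all(diff(mis) > 1L))
  list(count = length(mis), admissible = ok, positions = mis)
}

# Internal vectorized core: mismatch positions of query chars `qv` against
# window chars of `pv` starting at `s` (both uppercase character vectors).
.mismatch_positions <- function(qv, pv, s) {
  w <- pv[s:(s + length(qv) - 1L)]
  which(qv != w | qv == "X" | w == "X")
}

# as.character() drops names on plain vectors; this keeps them.
as_named_character <- function(x) {
  nm <- names(x)
  out <- as.character(x)
  names(out) <- nm
  out
}

as_query_vector <- function(queries) {
  q <- as_named_character(queries)
  if (is.null(names(q)) || any(!nzchar(names(q))))
    names(q) <- sprintf("rcl_%03d", seq_along(q))
  q[order(names(q))]
}

#' Best admissible RCL match within a protein's C-terminal window
#'
#' Candidate subsequences are all windows of exactly the query's length whose
#' span lies entirely within the last `window_len` residues of the protein
#' (the whole protein when shorter). Among all admissible (query, offset)
#' pairs the match with fewest mismatches wins; ties go to the smallest start
#' offset, then to seed order (seeds are sorted by id).
#'
#' @param protein Protein string (may be named; the name becomes `protein_id`).
#' @param queries Named character vector (or `AAStringSet`) of seed RCL
#'   peptides.
#' @param params A [scan_params()] object.
#' @param protein_id Identifier recorded in the match.
#' @return A list of class `rcl_match` with fields `protein_id`, `query_id`,
#'   `start`, `end` (1-based inclusive, in the full protein), `mismatches`,
#'   `mismatch_positions` (1-based within the match), or `NULL` when no
#'   admissible match exists.
#' @export
scan_protein <- function(protein, queries, params = scan_params(),
                         protein_id = names(protein)[1] %||% NA_character_) {
  protein <- as.character(protein)
  L <- nchar(protein)
  if (L == 0L) return(NULL)
  q <- as_query_vector(queries)
  if (!length(q)) return(NULL)
  pv <- strsplit(toupper(protein), "", fixed = TRUE)[[1]]
  win_start <- max(1L, L - params$window_len + 1L)

  best <- NULL
  for (j in seq_along(q)) {
    qv <- strsplit(toupper(q[[j]]), "", fixed = TRUE)[[1]]
    m <- length(qv)
    budget <- floor(params$max_mismatch_fraction * m)
    if (m > L - win_start + 1L) next
    for (s in win_start:(L - m + 1L)) {
      mis <- .mismatch_positions(qv, pv, s)
      if (length(mis) > budget) next
      if (params$forbid_adjacent_mismatches && length(mis) > 1 &&
          any(diff(mis) == 1L)) next
      if (is.null(best) || length(mis) < best$mismatches ||
          (length(mis) == best$mismatches && s < best$start)) {
        best <- list(protein_id = protein_id, query_id = names(q)[j],
                     start = s, end = s + m - 1L,
                     mismatches = length(mis), mismatch_positions = mis)
      }
    }
    # later queries can only win on strictly fewer mismatches or earlier start,
    # both handled by the comparison above, so keep scanning all queries
  }
  if (!is.null(best)) class(best) <- "rcl_match"
  best
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

#' Scan a whole proteome for serpin candidates
#'
#' @param proteins Named character vector or [Biostrings::AAStringSet].
#' @param seed_rcls Named character vector (or `AAStringSet`) of seed RCLs.
#' @param params A [scan_params()] object.
#' @return data.frame with one row per protein that has an admissible match:
#'   `protein_id`, `query_id`, `start`, `end`, `mismatches`,
#'   `mismatch_positions` (comma-joined).
#' @export
scan_proteome <- function(proteins, seed_rcls, params = scan_params()) {
  prot <- as_named_character(proteins)
  ids <- names(prot)
  if (is.null(ids)) stop("proteins must be named")
  rows <- lapply(seq_along(prot), function(i) {
    m <- scan_protein(prot[[i]], seed_rcls, params, protein_id = ids[i])
    if (is.null(m)) return(NULL)
    data.frame(protein_id = m$protein_id, query_id = m$query_id,
               start = m$start, end = m$end, mismatches = m$mismatches,
               mismatch_positions = paste(m$mismatch_positions, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(protein_id = character(0), query_id = character(0),
                      start = integer(0), end = integer(0),
                      mismatches = integer(0),
                      mismatch_positions = character(0))
  rownames(out) <- NULL
  out
}

#' Iterative serpin discovery with RCL re-seeding
#'
#' After each scan round, the matched RCL subsequences of all hits are added
#' (deduplicated) to the seed set and the proteome is re-scanned, until the
#' hit set stops growing or `max_rounds` is reached. The hit set is monotone
#' non-decreasing across rounds.
#'
#' @inheritParams scan_proteome
#' @param max_rounds Maximum number of scan rounds (>= 1).
#' @return List with `hits` (final hit data.frame), `rounds` (integer vector
#'   of per-round hit counts) and `seeds` (final seed set).
#' @export
iterate_to_fixed_point <- function(proteins, seed_rcls, params = scan_params(),
                                   max_rounds = 10L) {
  stopifnot(max_rounds >= 1L)
  prot <- as_named_character(proteins)
  seeds <- as_query_vector(seed_rcls)
  counts <- integer(0)
  hits <- NULL
  for (r in seq_len(max_rounds)) {
    hits <- scan_proteome(prot, seeds, params)
    counts <- c(counts, nrow(hits))
    if (r > 1 && counts[r] == counts[r - 1]) break
    new_seqs <- substr(prot[hits$protein_id], hits$start, hits$end)
    new <- new_seqs[!new_seqs %in% seeds]
    if (!length(new)) {
      if (r < max_rounds && counts[r] != 0) {
        # no new seed material: already a fixed point
      }
      break
    }
    names(new) <- paste0(hits$protein_id[match(new, new_seqs)], "_rcl")
    seeds <- c(seeds, new[!duplicated(new)])
    seeds <- seeds[order(names(seeds))]
  }
  list(hits = hits, rounds = counts, seeds = seeds)
}
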