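# Motif occurrence matrix and two-step importance-weighted clustering.
#
# De novo motif discovery (MEME's EM) is not re-implemented: motif catalogs
# and hits come either from parsed external files (MEME text, FIMO TSV) or
# from the package's simple internal consensus scanner, which reuses the
# constrained fuzzy matcher over full sequences.

#' Sliding-window Shannon entropy of an alignment
#'
#' Per-column Shannon entropy (bits) over residue frequencies, with the gap
#' character counted as a 21st symbol; a sliding mean over `window` columns;
#' the `top_k` non-overlapping windows by mean entropy are returned (ties go
#' to the leftmost window).
#'
#' @param msa Character vector of aligned, equal-length sequences (or an
#'   `AAStringSet` / `AAMultipleAlignment`).
#' @param window Window width in alignment columns.
#' @param top_k Number of non-overlapping windows to report.
#' @return data.frame with `start`, `end`, `mean_entropy`, ordered by
#'   decreasing mean entropy.
#' @export
entropy_windows <- function(msa, window, top_k = 5L) {
  if (methods::is(msa, "AAMultipleAlignment")) msa <- as.character(msa)
  msa <- as.character(msa)
  if (!length(msa)) stop("empty alignment")
  if (length(unique(nchar(msa))) != 1) stop("alignment rows differ in length")
  L <- nchar(msa[1])
  if (window > L) stop("window exceeds alignment length")
  m <- do.call(rbind, strsplit(toupper(msa), "", fixed = TRUE))
  col_entropy <- apply(m, 2, function(col) {
    p <- table(col) / length(col)
    -sum(p * log2(p))
  })
  k <- L - window + 1L
  means <- vapply(seq_len(k), function(s) mean(col_entropy[s:(s + window - 1L)]),
                  numeric(1))
  picked <- integer(0)
  taken <- logical(k)
  ord <- order(-means, seq_len(k))   # mean desc, leftmost on ties
  for (s in ord) {
    if (length(picked) >= top_k) break
    if (taken[s]) next
    picked <- c(picked, s)
    lo <- max(1L, s - window + 1L); hi <- min(k, s + window - 1L)
    taken[lo:hi] <- TRUE
  }
  data.frame(start = picked, end = picked + window - 1L,
             mean_entropy = means[picked])
}

#' Build a binary sequence-by-motif occurrence matrix
#'
#' A cell is 1 iff the sequence has at least one hit for the motif passing the
#' q-value threshold (when hits carry q-values). All sequences are kept as
#' rows, including all-zero ones; duplicate hits are idempotent.
#'
#' @param hits data.frame with columns `motif_id`, `sequence_id` and
#'   optionally `qvalue`.
#' @param sequence_ids Character vector of all sequence ids (matrix rows).
#' @param q_threshold Keep hits with `qvalue < q_threshold` (ignored when the
#'   hits carry no q-values).
#' @return Binary integer matrix, rows = sequences, columns = sorted motif
#'   ids, with a `weights` attribute (initially all 1).
#' @export
build_occurrence_matrix <- function(hits, sequence_ids, q_threshold = 0.05) {
  bad <- !hits$sequence_id %in% sequence_ids
  if (any(bad))
    stop("hit(s) for unknown sequence: ",
         paste(unique(hits$sequence_id[bad]), collapse = ", "))
  if (!is.null(hits$qvalue))
    hits <- hits[is.na(hits$qvalue) | hits$qvalue < q_threshold, , drop = FALSE]
  motifs <- sort(unique(hits$motif_id))
  mat <- matrix(0L, nrow = length(sequence_ids), ncol = length(motifs),
                dimnames = list(sequence_ids, motifs))
  if (nrow(hits))
    mat[cbind(match(hits$sequence_id, sequence_ids),
              match(hits$motif_id, motifs))] <- 1L
  attr(mat, "weights") <- stats::setNames(rep(1, length(motifs)), motifs)
  mat
}

.standardize_cols <- function(mat) {
  s <- apply(mat, 2, stats::sd)
  s[s == 0] <- 1
  scale(mat, center = TRUE, scale = s)
}

.silhouette_k <- function(d, hc, k_range, n) {
  k_range <- k_range[k_range >= 2 & k_range < n]
  sil <- vapply(k_range, function(k) {
    cl <- stats::cutree(hc, k)
    if (length(unique(cl)) < 2) return(-1)
    mean(cluster::silhouette(cl, d)[, "sil_width"])
  }, numeric(1))
  k_range[which.max(sil)]
}

.canonical_labels <- function(cl) {
  # relabel groups by order of first appearance
  first <- !duplicated(cl)
  map <- stats::setNames(seq_along(cl[first]), cl[first])
  unname(map[as.character(cl)])
}

#' Two-step importance-weighted agglomerative clustering
#'
#' Step 1: standardize motif columns and cluster (Ward linkage on Euclidean
#' distance), choosing k from `k_range` by mean silhouette width — the
#' provisional groups. Step 2: train a random-forest classifier on the
#' provisional labels (fixed seed), normalize its column importances, weight
#' the standardized columns by them, and re-cluster — the final groups,
#' enriched for the discriminative motifs. Labels are canonicalized by order
#' of first appearance, so the result is deterministic for a fixed seed.
#'
#' @param mat Occurrence matrix from [build_occurrence_matrix()] (>= 2 rows,
#'   >= 1 column).
#' @param k_range Candidate group counts.
#' @param seed Integer seed for the random-forest step.
#' @return List with `provisional`, `final` (named integer vectors),
#'   `k_provisional`, `k_final`, `importances` (normalized, sum 1).
#' @export
two_step_cluster <- function(mat, k_range = 2:10, seed = 42L) {
  n <- nrow(mat)
  if (n < 2 || ncol(mat) < 1) stop("need >= 2 sequences and >= 1 motif column")
  if (all(k_range >= n))
    stop("k_range exceeds the number of sequences (", n, ")")
  z <- .standardize_cols(mat)
  d <- stats::dist(z)
  hc <- stats::hclust(d, method = "ward.D2")
  k1 <- .silhouette_k(d, hc, k_range, n)
  provisional <- .canonical_labels(stats::cutree(hc, k1))
  names(provisional) <- rownames(mat)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  rf <- randomForest::randomForest(x = as.data.frame(z),
                                   y = factor(provisional), ntree = 500)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  imp <- randomForest::importance(rf)[, "MeanDecreaseGini"]
  imp <- pmax(imp, 0)
  if (sum(imp) == 0) imp[] <- 1
  imp <- imp / sum(imp)

  w <- sweep(z, 2, imp, `*`)
  d2 <- stats::dist(w)
  hc2 <- stats::hclust(d2, method = "ward.D2")
  k2 <- .silhouette_k(d2, hc2, k_range, n)
  final <- .canonical_labels(stats::cutree(hc2, k2))
  names(final) <- rownames(mat)
  list(provisional = provisional, final = final,
       k_provisional = k1, k_final = k2,
       importances = stats::setNames(imp, colnames(mat)))
}

#' Scan sequences with consensus motifs (internal fallback scanner)
#'
#' Reuses the constrained fuzzy matcher of the RCL scanner over the full
#' sequence (no C-terminal window): every admissible occurrence of each
#' consensus is reported, with budget `floor(max_mismatch_fraction * width)`
#' and no two adjacent mismatches.
#'
#' @param sequences Named character vector / `AAStringSet`.
#' @param consensus Named character vector of ungapped consensus peptides.
#' @param max_mismatch_fraction Mismatch budget fraction.
#' @return data.frame of hits: `motif_id`, `sequence_id`, `start`, `end`,
#'   `mismatches`.
#' @export
internal_motif_scan <- function(sequences, consensus, max_mismatch_fraction = 0.2) {
  seqs <- as_named_character(sequences)
  if (is.null(names(seqs))) stop("sequences must be named")
  cons <- as_query_vector(consensus)
  rows <- list()
  for (sid in names(seqs)) {
    pv <- strsplit(toupper(seqs[[sid]]), "", fixed = TRUE)[[1]]
    L <- length(pv)
    for (mid in names(cons)) {
      qv <- strsplit(toupper(cons[[mid]]), "", fixed = TRUE)[[1]]
      m <- length(qv)
      if (m > L) next
      budget <- floor(max_mismatch_fraction * m)
      for (s in 1:(L - m + 1L)) {
        mis <- .mismatch_positions(qv, pv, s)
        if (length(mis) > budget) next
        if (length(mis) > 1 && any(diff(mis) == 1L)) next
        rows[[length(rows) + 1L]] <- data.frame(
          motif_id = mid, sequence_id = sid, start = s, end = s + m - 1L,
          mismatches = length(mis), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(motif_id = character(0), sequence_id = character(0),
                      start = integer(0), end = integer(0),
                      mismatches = integer(0))
  out
}

#' Parse external motif hits (FIMO TSV or MEME text)
#'
#' FIMO TSV yields hits with q-values; MEME (minimal motif text format) yields
#' a motif catalog with widths and consensus strings (argmax of the
#' letter-probability matrix). The format is detected from the content when
#' `format = "auto"`; an unrecognized file is an error naming the first
#' offending line.
#'
#' @param path File path.
#' @param format `"auto"`, `"fimo"` or `"meme"`.
#' @return List with `catalog` (data.frame `motif_id`, `width`, `consensus`;
#'   NULL for FIMO input) and `hits` (data.frame `motif_id`, `sequence_id`,
#'   `start`, `end`, `score`, `qvalue`; NULL for MEME input).
#' @export
parse_external_hits <- function(path, format = c("auto", "fimo", "meme")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    head1 <- lines[nzchar(lines)][1]
    format <- if (!is.na(head1) && grepl("MEME version", head1)) "meme"
      else if (!is.na(head1) && grepl("motif_id\tmotif_alt_id|^motif_id\t", head1)) "fimo"
      else stop("unrecognized motif file format at line 1: ",
                substr(head1 %||% "<empty>", 1, 60))
  }
  if (format == "fimo") list(catalog = NULL, hits = parse_fimo_lines(lines))
  else list(catalog = parse_meme_lines(lines), hits = NULL)
}

parse_fimo_lines <- function(lines) {
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("motif_id", "sequence_name", "start", "stop")
  if (!all(need %in% header))
    stop("not a FIMO TSV: header line lacks ",
         paste(setdiff(need, header), collapse = ", "))
  body <- lines[-1]
  if (!length(body))
    return(data.frame(motif_id = character(0), sequence_id = character(0),
                      start = integer(0), end = integer(0),
                      score = numeric(0), qvalue = numeric(0)))
  f <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(f) < length(header))
  if (length(bad))
    stop("FIMO TSV parse error at data line ", bad[1], ": expected ",
         length(header), " fields, found ", lengths(f)[bad[1]])
  get_col <- function(name) vapply(f, function(x) x[match(name, header)], character(1))
  data.frame(
    motif_id = get_col("motif_id"),
    sequence_id = get_col("sequence_name"),
    start = as.integer(get_col("start")),
    end = as.integer(get_col("stop")),
    score = if ("score" %in% header) as.numeric(get_col("score")) else NA_real_,
    qvalue = if ("q-value" %in% header) as.numeric(get_col("q-value")) else NA_real_,
    stringsAsFactors = FALSE)
}

parse_meme_lines <- function(lines) {
  if (!any(grepl("MEME version", lines)))
    stop("not a MEME motif text file: no 'MEME version' line")
  alph_line <- grep("^ALPHABET", lines, value = TRUE)
  alphabet <- if (length(alph_line))
    strsplit(sub("^ALPHABET=\\s*", "", alph_line[1]), "")[[1]]
  else strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  motif_idx <- grep("^MOTIF\\s+", lines)
  if (!length(motif_idx)) stop("MEME text contains no MOTIF blocks")
  rows <- lapply(motif_idx, function(i) {
    id <- strsplit(sub("^MOTIF\\s+", "", lines[i]), "\\s+")[[1]][1]
    j <- i
    while (j <= length(lines) && !grepl("letter-probability matrix", lines[j]))
      j <- j + 1
    if (j > length(lines))
      stop("MEME parse error: motif ", id,
           " has no letter-probability matrix (truncated file?)")
    w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", lines[j]))
    probs <- lines[(j + 1):(j + w)]
    if (any(is.na(probs)) || length(probs) < w)
      stop("MEME parse error: truncated probability matrix for motif ", id)
    cons <- vapply(probs, function(row) {
      p <- suppressWarnings(as.numeric(strsplit(trimws(row), "\\s+")[[1]]))
      if (anyNA(p) || length(p) != length(alphabet))
        stop("MEME parse error in probability row: ", substr(row, 1, 60))
      alphabet[which.max(p)]
    }, character(1))
    data.frame(motif_id = id, width = w,
               consensus = paste(cons, collapse = ""), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
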