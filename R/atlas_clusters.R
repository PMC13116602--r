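# Tandem-cluster calling, adjacent-pair orientation, and the strand-bias and
# chromosome-density statistics.
#
# A cluster is a maximal run of serpin loci on one chromosome in which every
# neighboring pair is within `max_distance` bp boundary-to-boundary AND
# separated by at most `max_intervening_genes` annotated genes (of any
# biotype) lying strictly between the two spans. Unchained loci are singleton
# clusters.

#' Cluster-calling parameters
#'
#' @param max_distance Maximum boundary-to-boundary gap between neighboring
#'   cluster members, in bp.
#' @param max_intervening_genes Maximum number of annotated genes strictly
#'   between two neighboring members.
#' @return List of class `cluster_params`.
#' @export
cluster_params <- function(max_distance = 100000, max_intervening_genes = 10) {
  stopifnot(max_distance > 0, max_intervening_genes >= 0)
  structure(list(max_distance = max_distance,
                 max_intervening_genes = max_intervening_genes),
            class = "cluster_params")
}

# Normalize an annotation (list of gene_model or data.frame) to a gene table.
as_gene_table <- function(all_genes) {
  if (is.data.frame(all_genes)) {
    stopifnot(all(c("gene_id", "chromosome", "start", "end") %in% names(all_genes)))
    return(all_genes)
  }
  data.frame(
    gene_id = vapply(all_genes, function(g) g$gene_id, character(1)),
    chromosome = vapply(all_genes, function(g) g$chromosome, character(1)),
    start = vapply(all_genes, function(g) g$span_start, integer(1)),
    end = vapply(all_genes, function(g) g$span_end, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify the relative orientation of an adjacent gene pair
#'
#' With `left` upstream of `right` on the same chromosome: same strand is
#' head-to-tail (tandem); `-`/`+` is head-to-head (5' ends facing inward);
#' `+`/`-` is tail-to-tail (3' ends facing). Note that this geometric
#' head-to-head definition is sometimes called "divergent" elsewhere in the
#' literature; the labels here follow the 5'-facing geometry.
#'
#' @param left_strand,right_strand Strands of the left (smaller start) and
#'   right gene. Vectorized.
#' @return Character vector in
#'   `{head_to_tail, head_to_head, tail_to_tail}`.
#' @export
classify_pair_orientation <- function(left_strand, right_strand) {
  stopifnot(all(left_strand %in% c("+", "-")), all(right_strand %in% c("+", "-")))
  ifelse(left_strand == right_strand, "head_to_tail",
         ifelse(left_strand == "-", "head_to_head", "tail_to_tail"))
}

#' Call tandem serpin clusters
#'
#' @param loci Atlas data.frame with columns `serpin_name`, `chromosome`,
#'   `strand`, `gene_start`, `gene_end`.
#' @param all_genes Full annotation: named list of `gene_model`s or a
#'   data.frame with `gene_id`, `chromosome`, `start`, `end`. Used for the
#'   intervening-gene rule; genes overlapping either serpin span are not
#'   counted.
#' @param params A [cluster_params()] object.
#' @return data.frame with one row per cluster: `cluster_id`, `chromosome`,
#'   `n_members`, `start`, `end`, `span`, and list-columns `members` (serpin
#'   names in coordinate order), `orientations`, `intergenic_distances`,
#'   `intervening_genes` (per adjacent pair).
#' @export
call_clusters <- function(loci, all_genes, params = cluster_params()) {
  genes <- as_gene_table(all_genes)
  if (!all(loci$chromosome %in% genes$chromosome))
    stop("loci on chromosome(s) absent from the annotation: ",
         paste(setdiff(loci$chromosome, genes$chromosome), collapse = ", "))
  out <- list()
  for (chrom in unique(loci$chromosome)) {
    l <- loci[loci$chromosome == chrom, , drop = FALSE]
    l <- l[order(l$gene_start), , drop = FALSE]
    g <- genes[genes$chromosome == chrom, , drop = FALSE]
    n <- nrow(l)
    if (n == 1) {
      chain_break <- logical(0)
    } else {
      gaps <- l$gene_start[-1] - l$gene_end[-n] - 1L
      interv <- vapply(seq_len(n - 1), function(i) {
        sum(g$start > l$gene_end[i] & g$end < l$gene_start[i + 1] &
              !g$gene_id %in% c(l$gene_id[i], l$gene_id[i + 1]))
      }, numeric(1))
      chain_break <- gaps > params$max_distance |
        interv > params$max_intervening_genes
    }
    cluster_idx <- cumsum(c(1L, as.integer(chain_break)))
    for (ci in unique(cluster_idx)) {
      m <- l[cluster_idx == ci, , drop = FALSE]
      k <- nrow(m)
      pair_gaps <- if (k > 1) m$gene_start[-1] - m$gene_end[-k] - 1L else integer(0)
      pair_interv <- if (k > 1) vapply(seq_len(k - 1), function(i) {
        sum(g$start > m$gene_end[i] & g$end < m$gene_start[i + 1] &
              !g$gene_id %in% c(m$gene_id[i], m$gene_id[i + 1]))
      }, numeric(1)) else numeric(0)
      orient <- if (k > 1)
        classify_pair_orientation(m$strand[-k], m$strand[-1]) else character(0)
      out[[length(out) + 1L]] <- data.frame(
        cluster_id = NA_character_, chromosome = chrom,
        n_members = k, start = m$gene_start[1], end = m$gene_end[k],
        span = m$gene_end[k] - m$gene_start[1] + 1L,
        members = I(list(m$serpin_name)),
        orientations = I(list(orient)),
        intergenic_distances = I(list(as.integer(pair_gaps))),
        intervening_genes = I(list(as.integer(pair_interv))),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(chromosome_rank(res$chromosome), res$start), , drop = FALSE]
  res$cluster_id <- sprintf("%s_cl%02d", res$chromosome,
                            as.integer(stats::ave(seq_len(nrow(res)),
                                                  res$chromosome,
                                                  FUN = seq_along)))
  rownames(res) <- NULL
  res
}

#' Sensitivity sweep over cluster thresholds
#'
#' Re-calls clusters over a grid of distance and intervening-gene thresholds,
#' reporting the number of multi-member clusters, the share of loci assigned
#' to clusters of size >= 2, and a partition signature so identical partitions
#' (plateaus) can be detected across rows.
#'
#' @param loci,all_genes As in [call_clusters()].
#' @param max_distances Numeric vector of distance cutoffs (bp); `Inf` removes
#'   the distance rule.
#' @param max_intervening Numeric vector of intervening-gene cutoffs; `Inf`
#'   removes the gene rule.
#' @return data.frame with one row per parameter combination.
#' @export
sensitivity_sweep <- function(loci, all_genes,
                              max_distances = c(50000, 100000, 200000),
                              max_intervening = c(Inf, 10)) {
  grid <- expand.grid(max_distance = max_distances,
                      max_intervening_genes = max_intervening)
  if (!nrow(grid)) stop("empty parameter grid")
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cl <- call_clusters(loci, all_genes,
                        cluster_params(grid$max_distance[i],
                                       grid$max_intervening_genes[i]))
    clustered <- sum(cl$n_members[cl$n_members >= 2])
    sig <- paste(vapply(cl$members[cl$n_members >= 2],
                        function(m) paste(m, collapse = "+"), character(1)),
                 collapse = "|")
    data.frame(max_distance = grid$max_distance[i],
               max_intervening_genes = grid$max_intervening_genes[i],
               n_clusters = sum(cl$n_members >= 2),
               n_singletons = sum(cl$n_members == 1),
               pct_in_clusters = round(100 * clustered / nrow(loci), 1),
               partition = sig, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$plateau <- duplicated(res$partition) | duplicated(res$partition, fromLast = TRUE)
  res
}

#' Exact binomial strand-bias test
#'
#' Two-sided exact binomial test of plus- versus minus-strand counts against
#' equal probability (the minimum-likelihood two-sided definition of
#' [stats::binom.test()], which at p = 0.5 equals doubling the smaller tail).
#'
#' @param loci Atlas data.frame with a `strand` column, or omit and pass
#'   counts directly.
#' @param n_plus,n_minus Optional explicit counts (override `loci`).
#' @return List with `n_plus`, `n_minus`, `p_two_sided`.
#' @export
strand_bias_test <- function(loci = NULL, n_plus = NULL, n_minus = NULL) {
  if (is.null(n_plus)) {
    stopifnot(!is.null(loci), nrow(loci) >= 1)
    n_plus <- sum(loci$strand == "+")
    n_minus <- sum(loci$strand == "-")
  }
  p <- stats::binom.test(n_plus, n_plus + n_minus, p = 0.5)$p.value
  list(n_plus = n_plus, n_minus = n_minus, p_two_sided = p)
}

#' Length-weighted chi-square test of chromosomal density
#'
#' Goodness-of-fit test in which the expected count on chromosome i is
#' proportional to its length: `E_i = N * L_i / sum(L)`. Chromosomes with zero
#' observed loci still contribute; loci on unplaced scaffolds must be excluded
#' by the caller.
#'
#' @param counts Named integer vector of observed loci per chromosome
#'   (chromosomes missing from `counts` but present in `lengths` count as 0).
#' @param lengths Named numeric vector of chromosome lengths in bp; every
#'   chromosome to be tested must appear here with a positive length.
#' @return List of class `density_test` with `observed`, `lengths`,
#'   `expected`, `chi2`, `df`, `p`.
#' @export
chrom_density_test <- function(counts, lengths) {
  if (any(lengths <= 0)) stop("all chromosome lengths must be positive")
  if (!all(names(counts) %in% names(lengths)))
    stop("counts refer to chromosome(s) without a length: ",
         paste(setdiff(names(counts), names(lengths)), collapse = ", "))
  obs <- stats::setNames(numeric(length(lengths)), names(lengths))
  obs[names(counts)] <- counts
  N <- sum(obs)
  expected <- N * lengths / sum(lengths)
  chi2 <- sum((obs - expected)^2 / expected)
  df <- length(lengths) - 1L
  structure(list(observed = obs, lengths = lengths, expected = expected,
                 chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE)),
            class = "density_test")
}

#' @export
print.density_test <- function(x, ...) {
  cat(sprintf("Length-weighted chi-square: X2 = %.3f, df = %d, p = %.3g\n",
              x$chi2, x$df, x$p))
  invisible(x)
}

#' Spacing statistics of one cluster
#'
#' Intergenic distance between neighbors is `next.start - prev.end - 1`;
#' the span is `last.end - first.start + 1`. Spacing is undefined (NA) for
#' singletons; the span is always defined.
#'
#' @param cluster One row of the [call_clusters()] result (or any list with
#'   `intergenic_distances`, `start`, `end`).
#' @return List with `mean`, `min`, `max` intergenic bp and `span` bp.
#' @export
cluster_spacing_stats <- function(cluster) {
  gaps <- unlist(cluster$intergenic_distances)
  span <- cluster$end - cluster$start + 1
  if (!length(gaps))
    return(list(mean = NA_real_, min = NA_real_, max = NA_real_, span = span))
  list(mean = mean(gaps), min = min(gaps), max = max(gaps), span = span)
}
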