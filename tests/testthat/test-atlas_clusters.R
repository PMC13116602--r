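mk_loci <- function(starts, ends, strands, chrom = "Chr1",
                    names = paste0("L", seq_along(starts))) {
  data.frame(serpin_name = names, gene_id = names, chromosome = chrom,
             strand = strands, gene_start = starts, gene_end = ends,
             stringsAsFactors = FALSE)
}

mk_genes <- function(starts, ends, chrom = "Chr1",
                     ids = paste0("G", seq_along(starts))) {
  data.frame(gene_id = ids, chromosome = chrom, start = starts, end = ends,
             stringsAsFactors = FALSE)
}

test_that("pair orientation follows the 5'-facing geometry", {
  expect_equal(classify_pair_orientation("+", "+"), "head_to_tail")
  expect_equal(classify_pair_orientation("-", "-"), "head_to_tail")
  expect_equal(classify_pair_orientation("-", "+"), "head_to_head")
  expect_equal(classify_pair_orientation("+", "-"), "tail_to_tail")
  # mirror symmetry: swapping both strands and mirroring coordinates keeps
  # each gene's reading direction but reverses the pair order, mapping
  # head_to_head <-> tail_to_tail and fixing head_to_tail
  for (l in c("+", "-")) for (r in c("+", "-")) {
    orig <- classify_pair_orientation(l, r)
    mirrored <- classify_pair_orientation(r, l)
    want <- c(head_to_tail = "head_to_tail", head_to_head = "tail_to_tail",
              tail_to_tail = "head_to_head")[[orig]]
    expect_equal(unname(mirrored), want)
  }
})

test_that("two serpins 50 kb apart form one cluster unless 11 genes intervene", {
  loci <- mk_loci(c(1000, 53000), c(2000, 54000), c("+", "+"))
  genes <- rbind(mk_genes(c(1000, 53000), c(2000, 54000), ids = c("L1", "L2")))
  cl <- call_clusters(loci, genes)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_members, 2)
  expect_equal(cl$orientations[[1]], "head_to_tail")

  decoys <- mk_genes(seq(5000, 45000, length.out = 11),
                     seq(5000, 45000, length.out = 11) + 500,
                     ids = paste0("D", 1:11))
  cl2 <- call_clusters(loci, rbind(genes, decoys))
  expect_equal(nrow(cl2), 2)
  expect_true(all(cl2$n_members == 1))

  # with exactly 10 intervening genes the pair still chains
  cl3 <- call_clusters(loci, rbind(genes, decoys[1:10, ]))
  expect_equal(nrow(cl3), 1)
})

test_that("clusters partition the loci and are invariant to input order", {
  sim <- study_sim()
  atlas <- study_atlas()
  cl <- call_clusters(atlas, sim$genes)
  expect_setequal(unlist(cl$members), atlas$serpin_name)
  expect_equal(sum(cl$n_members), nrow(atlas))
  shuffled <- atlas[withr::with_seed(1, sample(nrow(atlas))), ]
  cl2 <- call_clusters(shuffled, sim$genes)
  expect_equal(cl$members, cl2$members)
})

test_that("relaxing a threshold never splits clusters; sweep detects plateaus", {
  sim <- study_sim()
  atlas <- study_atlas()
  sweep <- sensitivity_sweep(atlas, sim$genes,
                             max_distances = c(50000, 100000, 200000),
                             max_intervening = c(Inf, 10))
  # loosening distance never decreases the clustered share
  for (gi in unique(sweep$max_intervening_genes)) {
    rows <- sweep[sweep$max_intervening_genes == gi, ]
    rows <- rows[order(rows$max_distance), ]
    expect_true(all(diff(rows$pct_in_clusters) >= 0))
  }
  # the synthetic atlas separates clusters by construction, so the partition
  # plateaus across 50/100/200 kb under the 10-gene rule
  plateau_rows <- sweep[sweep$max_intervening_genes == 10, ]
  expect_equal(length(unique(plateau_rows$partition)), 1)
  expect_true(all(plateau_rows$plateau))
})

test_that("strand bias test reproduces forced binomial cases", {
  expect_equal(strand_bias_test(n_plus = 37, n_minus = 37)$p_two_sided, 1)
  expect_equal(strand_bias_test(n_plus = 74, n_minus = 0)$p_two_sided,
               2 * 0.5^74)
  loci <- data.frame(strand = c(rep("+", 5), rep("-", 5)))
  r <- strand_bias_test(loci)
  expect_equal(r$n_plus, 5)
  expect_equal(r$p_two_sided, 1)
})

test_that("length-weighted chi-square matches hand arithmetic", {
  # 3-chromosome toy: L = 1,2,1 Mb; O = 4,0,0 -> E = 1,2,1; chi2 = 9+2+1
  r <- chrom_density_test(c(c1 = 4), c(c1 = 1e6, c2 = 2e6, c3 = 1e6))
  expect_equal(r$chi2, 12)
  expect_equal(r$df, 2L)
  expect_equal(unname(r$expected), c(1, 2, 1))
  expect_equal(sum(r$expected), sum(r$observed))
  # equal lengths, equal counts
  r2 <- chrom_density_test(c(a = 3, b = 3, c = 3), c(a = 1e6, b = 1e6, c = 1e6))
  expect_equal(r2$chi2, 0)
  expect_equal(r2$p, 1)
  # textbook cross-check
  r3 <- chrom_density_test(c(a = 10, b = 5, c = 3),
                           c(a = 5e6, b = 3e6, c = 1e6))
  want <- suppressWarnings(stats::chisq.test(c(10, 5, 3), p = c(5, 3, 1) / 9))
  expect_equal(r3$chi2, unname(want$statistic))
  expect_equal(r3$p, want$p.value)
  expect_error(chrom_density_test(c(a = 1), c(a = 0, b = 10)), "positive")
  expect_error(chrom_density_test(c(z = 1), c(a = 10)), "without a length")
})

test_that("cluster spacing stats follow the boundary arithmetic", {
  loci <- mk_loci(c(1, 201), c(100, 300), c("+", "+"))
  cl <- call_clusters(loci, mk_genes(c(1, 201), c(100, 300), ids = c("L1", "L2")))
  st <- cluster_spacing_stats(cl[1, ])
  expect_equal(st$mean, 100)
  expect_equal(st$span, 300)
  # singleton: spacing undefined, span defined
  single <- call_clusters(mk_loci(500, 900, "+"), mk_genes(500, 900, ids = "L1"))
  st2 <- cluster_spacing_stats(single[1, ])
  expect_true(is.na(st2$mean))
  expect_equal(st2$span, 401)
})

test_that("planted cluster gaps are recovered exactly", {
  sim <- study_sim()
  atlas <- study_atlas()
  cl <- call_clusters(atlas, sim$genes)
  big <- cl[cl$n_members == 21, ]
  expect_equal(nrow(big), 1)
  tbig <- sim$truth$clusters[sim$truth$clusters$n_members == 21, ]
  expect_equal(big$intergenic_distances[[1]], tbig$intergenic_distances[[1]])
  st <- cluster_spacing_stats(big[1, ])
  expect_equal(st$min, min(tbig$intergenic_distances[[1]]))
  expect_equal(st$max, max(tbig$intergenic_distances[[1]]))
  expect_true(all(big$intergenic_distances[[1]] >= 679 &
                    big$intergenic_distances[[1]] <= 43544))
})
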