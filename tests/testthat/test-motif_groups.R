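test_that("column entropy is zero when conserved and 1 bit for a 50/50 column", {
  msa <- c("AAAA", "AAAA", "AAAA", "AAAA")
  ew <- entropy_windows(msa, window = 2, top_k = 2)
  expect_true(all(ew$mean_entropy == 0))
  # one column with two equiprobable residues
  msa2 <- c("AAWA", "AAWA", "AACA", "AACA")
  ew2 <- entropy_windows(msa2, window = 1, top_k = 1)
  expect_equal(ew2$start, 3)
  expect_equal(ew2$mean_entropy, 1)
  expect_error(entropy_windows(character(0), 2), "empty")
  expect_error(entropy_windows(msa, window = 10), "exceeds")
})

test_that("window ranking equals a direct per-column recomputation", {
  set.seed(31)
  msa <- vapply(1:12, function(i) random_protein(60), character(1))
  w <- 7
  ew <- entropy_windows(msa, window = w, top_k = 3)
  m <- do.call(rbind, strsplit(msa, ""))
  ce <- apply(m, 2, function(col) {
    p <- table(col) / length(col); -sum(p * log2(p))
  })
  means <- vapply(1:(60 - w + 1), function(s) mean(ce[s:(s + w - 1)]), numeric(1))
  # reported windows carry their true mean entropy, the best one first,
  # and no unpicked window beats the best picked one
  expect_equal(ew$mean_entropy, means[ew$start])
  expect_equal(ew$start[1], which.max(means))
  expect_true(all(diff(ew$mean_entropy) <= 1e-12))
  # non-overlapping
  expect_true(all(diff(sort(ew$start)) >= w))
})

test_that("occurrence matrix is binary, idempotent, order-invariant", {
  hits <- data.frame(motif_id = c("m2", "m1", "m1", "m1"),
                     sequence_id = c("s1", "s1", "s1", "s3"),
                     qvalue = c(0.001, 0.01, 0.01, 0.2))
  mat <- build_occurrence_matrix(hits, c("s1", "s2", "s3"))
  expect_equal(dim(mat), c(3L, 2L))
  expect_equal(unname(mat["s1", ]), c(1L, 1L))
  expect_equal(unname(mat["s2", ]), c(0L, 0L))   # all-zero rows kept
  expect_equal(unname(mat["s3", "m1"]), 0L)      # q-value filtered
  mat2 <- build_occurrence_matrix(hits[sample(nrow(hits)), ], c("s1", "s2", "s3"))
  expect_equal(mat, mat2)
  expect_error(build_occurrence_matrix(
    data.frame(motif_id = "m1", sequence_id = "nope"), c("s1")), "unknown")
  empty <- build_occurrence_matrix(hits[0, ], c("s1", "s2"))
  expect_equal(sum(empty), 0)
})

test_that("two perfectly separable motif blocks give two identical clusterings", {
  mat <- rbind(
    matrix(rep(c(1L, 1L, 1L, 0L, 0L, 0L), each = 5), nrow = 5),
    matrix(rep(c(0L, 0L, 0L, 1L, 1L, 1L), each = 5), nrow = 5))
  dimnames(mat) <- list(paste0("s", 1:10), paste0("m", 1:6))
  res <- two_step_cluster(mat, k_range = 2:5, seed = 1)
  expect_equal(res$k_provisional, 2)
  expect_equal(res$k_final, 2)
  expect_equal(res$provisional, res$final)
  expect_equal(unname(res$provisional), rep(c(1L, 2L), each = 5))
  # determinism contract
  res2 <- two_step_cluster(mat, k_range = 2:5, seed = 1)
  expect_identical(res, res2)
  expect_error(two_step_cluster(mat[1:2, ], k_range = 5:6), "k_range")
})

test_that("a planted 6-group matrix with noise columns is recovered", {
  set.seed(202)
  n_per <- 6; k <- 6
  groups <- rep(1:k, each = n_per)
  # three signature motifs per group (present with prob .95 inside,
  # .05 outside => between-group overlap well under 20%), plus noise columns
  sig <- matrix(0L, length(groups), 3 * k)
  for (g in 1:k) {
    cols <- (3 * (g - 1) + 1):(3 * g)
    sig[, cols] <- rbinom(length(groups) * 3, 1, 0.05)
    sig[groups == g, cols] <- rbinom(n_per * 3, 1, 0.95)
  }
  noise <- matrix(rbinom(length(groups) * 6, 1, 0.5), length(groups))
  mat <- cbind(sig, noise)
  dimnames(mat) <- list(sprintf("s%02d", seq_along(groups)),
                        sprintf("m%02d", seq_len(ncol(mat))))
  res <- two_step_cluster(mat, k_range = 2:10, seed = 99)
  ari_final <- mclust::adjustedRandIndex(res$final, groups)
  ari_prov <- mclust::adjustedRandIndex(res$provisional, groups)
  expect_gte(ari_final, 0.9)
  expect_gte(ari_final, ari_prov - 1e-9)
  # discriminative signature columns outweigh noise columns on average
  imp <- res$importances
  expect_gt(mean(imp[1:(3 * k)]), mean(imp[(3 * k + 1):length(imp)]))
})

test_that("the internal consensus scanner reports all admissible occurrences", {
  cons <- c(mA = "NAVYFKGWWL")
  s <- paste0("MM", "NAVYFKGWWL", random_protein_fixed(50, 51), "NAVYFKGWWL")
  hits <- internal_motif_scan(c(p1 = s), cons, max_mismatch_fraction = 0.2)
  exact <- hits[hits$mismatches == 0, ]
  expect_equal(exact$start, c(3L, 63L))
  # absent beyond budget: no hit
  none <- internal_motif_scan(c(p1 = random_protein_fixed(60, 52)),
                              c(mA = "WWWWWWWWWW"), 0.1)
  expect_equal(nrow(none), 0)
  # agreement with brute force on short sequences
  set.seed(53)
  for (i in 1:20) {
    s2 <- random_protein(40)
    got <- internal_motif_scan(c(x = s2), c(m = "NAVY"), 0.25)
    v <- strsplit(s2, "")[[1]]; q <- strsplit("NAVY", "")[[1]]
    want <- 0L
    for (st in 1:37) {
      mism <- which(v[st:(st + 3)] != q)
      if (length(mism) <= 1) want <- want + 1L
    }
    expect_equal(nrow(got), want)
  }
})

test_that("FIMO TSV and MEME text parse; truncated files fail loudly", {
  fimo <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "motif_id\tmotif_alt_id\tsequence_name\tstart\tstop\tstrand\tscore\tp-value\tq-value\tmatched_sequence",
    "m1\tMEME-1\tseqA\t10\t19\t+\t15.2\t1e-6\t0.001\tNAVYFKGWWL",
    "m2\tMEME-2\tseqB\t3\t12\t+\t11.0\t1e-4\t0.04\tEEGTVAAAAT"), fimo)
  out <- parse_external_hits(fimo)
  expect_equal(nrow(out$hits), 2)
  expect_equal(out$hits$sequence_id, c("seqA", "seqB"))
  expect_equal(out$hits$qvalue, c(0.001, 0.04))

  meme <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "MEME version 5.5.0", "",
    "ALPHABET= ACDEFGHIKLMNPQRSTVWY", "",
    "MOTIF m1", "letter-probability matrix: alength= 20 w= 2 nsites= 10 E= 1e-5",
    paste(c(1, rep(0, 19)), collapse = " "),
    paste(c(rep(0, 4), 1, rep(0, 15)), collapse = " "),
    "MOTIF m2", "letter-probability matrix: alength= 20 w= 1 nsites= 8 E= 1e-3",
    paste(c(rep(0, 19), 1), collapse = " "),
    "MOTIF m3", "letter-probability matrix: alength= 20 w= 1 nsites= 8 E= 1e-3",
    paste(c(rep(0, 9), 1, rep(0, 10)), collapse = " ")), meme)
  out2 <- parse_external_hits(meme)
  expect_equal(nrow(out2$catalog), 3)
  expect_equal(out2$catalog$width, c(2L, 1L, 1L))
  expect_equal(out2$catalog$consensus, c("AF", "Y", "L"))

  trunc <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("MEME version 5.5.0", "MOTIF m1",
               "letter-probability matrix: alength= 20 w= 3 nsites= 2 E= 1",
               paste(c(1, rep(0, 19)), collapse = " ")), trunc)
  expect_error(parse_external_hits(trunc), "truncated|parse error")

  garbage <- withr::local_tempfile(fileext = ".txt")
  writeLines("this is not a motif file", garbage)
  expect_error(parse_external_hits(garbage), "unrecognized")
})

test_that("a motif shared by most sequences shows the expected column sum", {
  sim <- simulate_atlas(tiny_config())
  prot <- setNames(sim$truth$loci$protein, sim$truth$loci$protein_id)
  hits <- internal_motif_scan(prot, c(hinge = "NAVYFKG"), 0.2)
  mat <- build_occurrence_matrix(hits, names(prot))
  expect_equal(unname(colSums(mat)["hinge"]), length(prot))
})
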