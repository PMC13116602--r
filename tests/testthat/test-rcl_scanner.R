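test_that("hamming_with_run_constraint counts and adjudicates correctly", {
  expect_equal(hamming_with_run_constraint("AVVA", "AVVA", 1),
               list(count = 0L, admissible = TRUE, positions = integer(0)))
  r1 <- hamming_with_run_constraint("AVVA", "AVGA", 1)
  expect_equal(r1$count, 1L)
  expect_true(r1$admissible)
  # adjacent mismatches at offsets 2,3 are inadmissible even within budget
  r2 <- hamming_with_run_constraint("AVVA", "AGGA", 2)
  expect_equal(r2$count, 2L)
  expect_false(r2$admissible)
  expect_equal(r2$positions, c(2L, 3L))
  # X mismatches everything, including X
  expect_equal(hamming_with_run_constraint("AXA", "AXA", 3)$count, 1L)
  expect_error(hamming_with_run_constraint("AV", "AVV", 5), "equal length")
})

test_that("hamming verdicts agree with a brute-force checker on random pairs", {
  set.seed(42)
  for (i in 1:300) {
    a <- random_protein(10); b <- random_protein(10)
    budget <- sample(0:5, 1)
    got <- hamming_with_run_constraint(a, b, budget)
    mism <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    want_ok <- length(mism) <= budget &&
      (length(mism) < 2 || all(diff(mism) > 1))
    expect_equal(got$count, length(mism))
    expect_equal(got$admissible, want_ok)
  }
})

test_that("scan_protein finds exact C-terminal copies and honors the window", {
  q <- c(seedA = "EEGTVAAAATGVVIVRS")
  p <- paste0(random_protein_fixed(250, 1), "EEGTVAAAATGVVIVRS", "AAAA")
  m <- scan_protein(p, q)
  expect_equal(m$mismatches, 0L)
  expect_equal(m$start, 251L)
  expect_equal(m$end, 267L)
  expect_equal(m$query_id, "seedA")

  # the same RCL 150 residues from the C-terminus of a 300-aa protein is
  # outside the 100-residue window
  left <- random_protein_fixed(300 - 17 - 150, 2)
  p2 <- paste0(left, "EEGTVAAAATGVVIVRS", random_protein_fixed(150, 3))
  expect_equal(nchar(p2), 300)
  expect_null(scan_protein(p2, q))

  # empty protein and empty seed set
  expect_null(scan_protein("", q))
  expect_equal(nrow(scan_proteome(c(p1 = p), character(0))), 0)
})

test_that("fewest mismatches wins, then earliest offset", {
  q <- c(seedA = "AAAAAAAAAA")
  # two admissible sites: 2 mismatches at offset 1, 1 mismatch at offset 21
  p <- paste0("ACACAAAAAA", "WWWWWWWWWW", "ACAAAAAAAA", "WWWWWWWWWW")
  m <- scan_protein(p, q, scan_params(window_len = 100,
                                      max_mismatch_fraction = 0.30))
  expect_equal(m$start, 21L)
  expect_equal(m$mismatches, 1L)
  # equal counts: earlier offset wins
  p2 <- paste0("ACAAAAAAAA", "WWWWWWWWWW", "ACAAAAAAAA")
  m2 <- scan_protein(p2, q)
  expect_equal(m2$start, 1L)
})

test_that("scan_protein equals the brute-force oracle on random proteins", {
  set.seed(7)
  queries <- c(q1 = "EEGTVAAAATGVVIVRS", q2 = "NAVYFKGFW", q3 = "MKLTEWVAQNDC")
  n_agree <- 0
  for (i in 1:150) {
    p <- random_protein(sample(30:200, 1))
    got <- scan_protein(p, queries)
    want <- oracle_scan(p, queries)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$query_id, want$query_id)
      expect_equal(got$start, want$start)
      expect_equal(got$mismatches, want$mismatches)
      n_agree <- n_agree + 1
    }
  }
  # planted cases so the loop is guaranteed to exercise real matches
  for (i in 1:50) {
    p <- paste0(random_protein(sample(100:300, 1)), "EEGTVAAAATGVVIVRS",
                random_protein(sample(0:10, 1)))
    got <- scan_protein(p, queries)
    want <- oracle_scan(p, queries)
    expect_equal(got[c("query_id", "start", "mismatches")],
                 want[c("query_id", "start", "mismatches")])
  }
})

test_that("enlarging budget or window never removes an admissible protein", {
  set.seed(13)
  queries <- c(q1 = "EEGTVAAAATGVVIVRS")
  prots <- setNames(
    vapply(1:40, function(i) {
      mut <- strsplit("EEGTVAAAATGVVIVRS", "")[[1]]
      k <- sample(0:5, 1)
      if (k > 0) {
        pos <- sample(seq(1, 17, by = 2), k)
        for (p in pos) mut[p] <- sample(setdiff(LETTERS, c(mut[p], "B","J","O","U","X","Z")), 1)
      }
      paste0(random_protein(sample(50:150, 1)), paste(mut, collapse = ""),
             random_protein(sample(0:60, 1)))
    }, character(1)), paste0("p", 1:40))
  tight <- scan_proteome(prots, queries,
                         scan_params(window_len = 60, max_mismatch_fraction = 0.15))
  loose <- scan_proteome(prots, queries,
                         scan_params(window_len = 100, max_mismatch_fraction = 0.30))
  expect_true(all(tight$protein_id %in% loose$protein_id))
})

test_that("duplicate proteins yield duplicate hits with identical coordinates", {
  q <- c(seedA = "EEGTVAAAATGVVIVRS")
  p <- paste0(random_protein_fixed(200, 5), "EEGTVAAAATGVVIVRS")
  hits <- scan_proteome(c(a = p, b = p), q)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$start[1], hits$start[2])
  expect_equal(hits$end[1], hits$end[2])
})

test_that("iteration re-seeds with discovered RCLs and reaches a fixed point", {
  seed <- c(s0 = "EEGTVAAAATGVVIVRS")
  sv <- strsplit(seed[[1]], "")[[1]]
  # rclA: 4 substitutions vs seed (admissible, budget 5)
  rclA <- sv; rclA[c(1, 3, 5, 7)] <- c("W", "W", "W", "W")
  # rclB: 4 further substitutions at other positions -> 8 vs seed
  # (inadmissible in round 1), 4 vs rclA (found in round 2)
  rclB <- rclA; rclB[c(9, 11, 13, 15)] <- c("W", "W", "W", "W")
  protA <- paste0(random_protein_fixed(220, 6), paste(rclA, collapse = ""))
  protB <- paste0(random_protein_fixed(240, 7), paste(rclB, collapse = ""))
  prots <- c(bridge_target = protB, first_round = protA)

  one <- scan_proteome(prots, seed)
  expect_equal(one$protein_id, "first_round")

  it <- iterate_to_fixed_point(prots, seed, max_rounds = 5)
  expect_equal(nrow(it$hits), 2)
  expect_true(all(diff(it$rounds) >= 0))
  expect_equal(it$rounds[1], 1)
  expect_true(2 %in% it$rounds)

  # max_rounds = 1 equals a plain proteome scan
  it1 <- iterate_to_fixed_point(prots, seed, max_rounds = 1)
  expect_equal(it1$hits, one)

  # re-running on its own output changes nothing
  it2 <- iterate_to_fixed_point(prots, it$seeds, max_rounds = 5)
  expect_equal(sort(it2$hits$protein_id), sort(it$hits$protein_id))
  expect_equal(it2$rounds[length(it2$rounds)], nrow(it$hits))
})
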