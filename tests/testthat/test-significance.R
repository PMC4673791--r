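test_that("all three estimators are exactly 1 on homopolymers", {
  homo <- strrep("A", 100)
  for (k in 3:6) {
    for (est in c("markov_k2", "boundary", "iid")) {
      sc <- kmer_scores(homo, k, estimator = est, strand = "forward")
      w <- strrep("A", k)
      # expectation 1 and observed 1 -> score (1 - 1)/1 = 0, flag FALSE
      expect_false(sc$zero_expectation[[w]])
      expect_equal(sc$scores[[w]], 0)
    }
  }
  # the low-level operations return the expectation itself
  p1 <- c(A = 1, C = 0, G = 0, T = 0)
  p2 <- setNames(rep(0, 16), all_kmers(2))
  p2["AA"] <- 1
  p3 <- setNames(rep(0, 64), all_kmers(3))
  p3["AAA"] <- 1
  expect_equal(markov_expectation(p3, p2, "AAAA"), 1)
  expect_equal(boundary_expectation(p1, p3, "AAAA"), 1)
  expect_equal(iid_expectation(p1, "AAAA"), 1)
})

test_that("empirical probabilities match the naive oracle", {
  expect_equal(empirical_probability(count_kmers(strrep("A", 100), 4,
                                                 strand = "forward"), "AAAA"), 1)
  expect_equal(empirical_probability(count_kmers("ACGT", 2,
                                                 strand = "forward"), "AC"),
               1 / 3)
  withr::with_seed(31, {
    s <- random_dna(500)
    for (len in c(1, 2, 3, 4)) {
      ck <- count_kmers(s, len, strand = "forward")
      want <- naive_count(s, len, strand = "forward")
      for (w in sample(names(ck$counts), min(5, length(ck$counts)))) {
        naive_p <- if (w %in% names(want$counts)) {
          want$counts[[w]] / want$valid
        } else 0
        expect_equal(empirical_probability(ck, w), naive_p)
      }
    }
  })
})

test_that("null-model expectations match brute-forced sub-word statistics", {
  withr::with_seed(32, {
    s <- random_dna(500)
    for (strand in c("forward", "both")) {
      p4 <- kmer_frequencies(count_kmers(s, 4, strand = strand))
      p3 <- kmer_frequencies(count_kmers(s, 3, strand = strand))
      p2 <- kmer_frequencies(count_kmers(s, 2, strand = strand))
      p1 <- kmer_frequencies(count_kmers(s, 1, strand = strand))
      sc_m <- kmer_scores(s, 4, "markov_k2", strand = strand)
      sc_b <- kmer_scores(s, 4, "boundary", strand = strand)
      sc_i <- kmer_scores(s, 4, "iid", strand = strand)
      for (w in c("ACGT", "TTAG", "GGGG", "CATG")) {
        em <- markov_expectation(p3, p2, w)
        eb <- boundary_expectation(p1, p3, w)
        ei <- iid_expectation(p1, w)
        for (pair in list(list(sc_m, em), list(sc_b, eb), list(sc_i, ei))) {
          expected <- pair[[2]]
          score <- pair[[1]]$scores[[w]]
          if (expected == 0) {
            expect_equal(score, 0)
          } else {
            expect_equal(score, (p4[[w]] - expected) / expected,
                         tolerance = 1e-12)
          }
        }
      }
    }
  })
})

test_that("z-score identities and zero-expectation policy hold", {
  expect_equal(z_score(0.004, 0.004), 0)
  expect_equal(z_score(0.008, 0.004), 1)
  expect_equal(z_score(0.1, 0), 0)
  expect_true(is.na(z_score(0.1, 0, zero_policy = "drop_feature")))
  # sign and scale invariance
  withr::with_seed(33, {
    p <- runif(50)
    q <- runif(50)
    z <- z_score(p, q)
    expect_equal(z > 0, p > q)
    expect_equal(z_score(3.7 * p, 3.7 * q), z)
  })
})

test_that("scores are invariant under reverse complement with both strands", {
  withr::with_seed(34, {
    s <- random_dna(800)
    for (est in c("markov_k2", "boundary", "iid")) {
      sc <- kmer_scores(s, 4, estimator = est, strand = "both")$scores
      rc <- revcomp(names(sc))
      expect_equal(unname(sc), unname(sc[rc]), tolerance = 1e-12)
    }
  })
})

test_that("markov estimator requires k >= 3", {
  expect_error(kmer_scores("ACGTACGT", 2, estimator = "markov_k2"),
               class = "kmerules_param_error")
})

test_that("drop_feature policy removes flagged rows from the matrix", {
  # genomes missing some interior words entirely -> zero expectations
  g <- tibble::tibble(
    id = c("g1", "g2"),
    sequence = c(strrep("AC", 200), strrep("AG", 200)),
    species = c("x", "y"), genus = NA, order = NA, class = NA, phylum = NA
  )
  x_keep <- kmer_matrix(g, k = 4, estimator = "markov_k2",
                        zero_policy = "score_zero")
  x_drop <- kmer_matrix(g, k = 4, estimator = "markov_k2",
                        zero_policy = "drop_feature")
  expect_equal(nrow(x_keep$values), 256L)
  expect_lt(nrow(x_drop$values), 256L)
})
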