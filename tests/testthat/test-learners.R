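# Shared fixture: two classes cleanly separated by one planted word.
sep_matrix <- function() {
  g <- toy_two_class_genomes(n_per_class = 10, len = 3000)
  kmer_matrix(g, k = 4)
}

test_that("ripper learns a single one-literal rule on separable data", {
  x <- sep_matrix()
  # an exhaustive oracle confirms a single-literal separation exists
  X <- t(x$values)
  pos <- matrix_labels(x, "species") == "a"
  expect_true(oracle_single_literal_separable(X, pos))
  m <- ripper(x, "species", seed = 1)
  expect_equal(length(m$rules), 1L)
  expect_equal(length(m$rules[[1]]$literals), 1L)
  expect_equal(m$rules[[1]]$conclusion, "a")  # classes tied -> first learned
  expect_equal(mean(predict(m, x) == matrix_labels(x, "species")), 1)
})

test_that("part matches ripper's predictions on separable data", {
  x <- sep_matrix()
  mr <- ripper(x, "species", seed = 1)
  mp <- part(x, "species", seed = 1)
  expect_equal(predict(mp, x), predict(mr, x))
  expect_equal(mean(predict(mp, x) == matrix_labels(x, "species")), 1)
})

test_that("single-class input yields a default-only model with warning", {
  g <- toy_two_class_genomes(n_per_class = 6, len = 800)
  g <- g[g$species == "a", ]
  x <- kmer_matrix(g, k = 3)
  expect_warning(m <- ripper(x, "species", seed = 1), "single class")
  expect_equal(length(m$rules), 0L)
  expect_equal(m$default_class, "a")
  expect_equal(predict(m, x), rep("a", 6))
  expect_warning(mp <- part(x, "species", seed = 1), "single class")
  expect_equal(length(mp$rules), 0L)
})

test_that("part solves an XOR-style interaction no single literal can", {
  # 2 features, 4 cells, 3 samples per cell; class = XOR of the cells
  cells <- expand.grid(f1 = c(0.1, 0.9), f2 = c(0.1, 0.9))
  vals <- cells[rep(1:4, each = 3), ]
  y <- ifelse(xor(vals$f1 > 0.5, vals$f2 > 0.5), "odd", "even")
  values <- t(as.matrix(vals))
  rownames(values) <- c("AAAA", "AAAC")
  colnames(values) <- paste0("s", seq_len(ncol(values)))
  labels <- tibble::tibble(id = colnames(values), species = y)
  x <- kmerules:::new_kmer_matrix(4L, values, labels, "both", "none")
  # no single-literal list reaches perfect training accuracy
  expect_false(oracle_single_literal_separable(t(values), y == "odd"))
  m <- part(x, "species", cuts = "midpoints", seed = 3)
  expect_gte(length(m$rules), 2L)
  expect_equal(mean(predict(m, x) == y), 1)
})

test_that("rule coverage bookkeeping replays exactly on training data", {
  bench <- small_benchmark()
  x <- bench$matrix
  for (fit in list(ripper(x, "species", seed = 5),
                   part(x, "species", seed = 5))) {
    X <- t(x$values)
    y <- matrix_labels(x, "species")
    for (r in fit$rules) {
      m <- kmerules:::rule_matches(r, X)
      expect_equal(unname(r$coverage["p"]), sum(m & y == r$conclusion))
      expect_equal(unname(r$coverage["n"]), sum(m & y != r$conclusion))
    }
  }
})

test_that("learners are deterministic given a seed", {
  bench <- small_benchmark()
  x <- bench$matrix
  for (learner in list(ripper, part)) {
    m1 <- learner(x, "genus", seed = 9)
    m2 <- learner(x, "genus", seed = 9)
    expect_identical(write_rules_json(m1), write_rules_json(m2))
  }
})

test_that("learned rules on the planted benchmark recover the signatures", {
  bench <- small_benchmark()
  x <- bench$matrix
  m <- ripper(x, "species", seed = 2)
  expect_gte(length(m$rules), 3L)  # 4 species, most prevalent is default
  rec <- recovery_score(m, bench$signatures, bench$lineages)
  expect_gte(rec, 0.8)
  cx <- model_complexity(m)
  expect_lte(cx$mean_literals_per_rule, 3)
})

test_that("predict is pure: repeated application gives identical labels", {
  bench <- small_benchmark()
  x <- bench$matrix
  m <- part(x, "phylum", seed = 4)
  p1 <- predict(m, x)
  p2 <- predict(m, x)
  expect_identical(p1, p2)
})
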