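test_that("count_kmers matches hand enumerations", {
  ck <- count_kmers("AAAA", 3, strand = "forward")
  expect_equal(unname(ck$counts["AAA"]), 2L)
  expect_equal(ck$valid_windows, 2L)
  expect_equal(sum(ck$counts), 2L)

  ck2 <- count_kmers("ACGT", 2, strand = "both")
  expect_equal(unname(ck2$counts[c("AC", "CG", "GT")]), c(2L, 2L, 2L))
  expect_equal(ck2$valid_windows, 6L)

  ck3 <- count_kmers("ANAA", 2, strand = "forward")
  expect_equal(unname(ck3$counts["AA"]), 1L)
  expect_equal(ck3$valid_windows, 1L)
})

test_that("k exceeding sequence length warns and yields empty counts", {
  expect_warning(ck <- count_kmers("ACG", 5), "exceeds")
  expect_equal(ck$valid_windows, 0L)
  expect_true(all(ck$counts == 0))
  expect_error(count_kmers("ACGT", 0), class = "kmerules_param_error")
})

test_that("count_kmers equals the naive substring-scan oracle", {
  withr::with_seed(101, {
    for (i in 1:200) {
      n <- sample(20:1000, 1)
      k <- sample(3:6, 1)
      strand <- sample(c("forward", "both"), 1)
      s <- random_dna(n, alphabet = c("A", "C", "G", "T", "N"))
      got <- count_kmers(s, k, strand = strand)
      want <- naive_count(s, k, strand = strand)
      expect_equal(got$valid_windows, want$valid)
      expect_equal(sum(got$counts), want$valid)
      nz <- got$counts[got$counts > 0]
      expect_equal(sort(names(nz)), sort(names(want$counts)))
      expect_equal(nz[sort(names(nz))],
                   want$counts[sort(names(want$counts))],
                   ignore_attr = FALSE)
    }
  })
})

test_that("frequencies sum to one and are strand-symmetric", {
  withr::with_seed(202, {
    for (i in 1:25) {
      s <- random_dna(sample(50:400, 1), alphabet = c("A", "C", "G", "T", "N"))
      k <- sample(2:5, 1)
      f <- kmer_frequencies(count_kmers(s, k, strand = "both"))
      expect_equal(sum(f), 1, tolerance = 1e-9)
      rc <- revcomp(names(f))
      expect_equal(unname(f), unname(f[rc]))
    }
  })
})

test_that("degenerate frequency input warns and returns zeros", {
  ck <- suppressWarnings(count_kmers("NNNN", 2))
  expect_warning(f <- kmer_frequencies(ck), "no valid windows")
  expect_true(all(f == 0))
})

test_that("feature matrix has 4^k lexicographic rows and matches vectors", {
  g <- toy_two_class_genomes(n_per_class = 2, len = 500)
  x3 <- kmer_matrix(g, k = 3)
  expect_equal(dim(x3), c(64L, 4L))
  x4 <- kmer_matrix(g, k = 4)
  expect_equal(dim(x4), c(256L, 4L))
  expect_equal(rownames(x4$values)[1:3], c("AAAA", "AAAC", "AAAG"))
  expect_equal(rownames(x4$values), sort(rownames(x4$values)))
  # column j equals the frequency vector of genome j
  for (j in seq_len(nrow(g))) {
    f <- kmer_frequencies(count_kmers(g$sequence[j], 4, strand = "both"))
    expect_equal(unname(x4$values[, j]), unname(f))
  }
  expect_error(kmer_matrix(g[0, ]), class = "kmerules_validation_error")
})

test_that("rare-class filter enforces the nine-specimen boundary", {
  make <- function(cls, n) {
    tibble::tibble(
      id = paste0(cls, seq_len(n)), sequence = strrep("ACGT", 30),
      species = cls, genus = cls, order = cls, class = cls, phylum = cls
    )
  }
  g <- dplyr::bind_rows(make("big", 10), make("edge", 9), make("small", 2))
  g$id <- paste0(g$id, "_", seq_len(nrow(g)))
  x <- kmer_matrix(g, k = 3)
  f <- filter_rare_classes(x, "species")
  expect_equal(ncol(f$values), 19L)
  expect_setequal(unique(matrix_labels(f, "species")), c("big", "edge"))
  # class with 8 members removed, 9 kept
  g8 <- dplyr::bind_rows(make("big", 10), make("eight", 8))
  g8$id <- paste0(g8$id, "_", seq_len(nrow(g8)))
  f8 <- filter_rare_classes(kmer_matrix(g8, k = 3), "species")
  expect_setequal(unique(matrix_labels(f8, "species")), "big")
  # no-op when everything is large enough
  f0 <- filter_rare_classes(x, "species", min_specimens = 2)
  expect_equal(dim(f0$values), dim(x$values))
  expect_error(filter_rare_classes(x, "species", min_specimens = 100),
               class = "kmerules_filter_error")
})

test_that("matrix TSV round-trips values and labels", {
  g <- toy_two_class_genomes(n_per_class = 3, len = 400)
  x <- kmer_matrix(g, k = 3)
  path <- tempfile(fileext = ".tsv")
  write_matrix_tsv(x, path, rank = "species")
  x2 <- read_matrix_tsv(path)
  expect_equal(signif(x$values, 12), x2$values)
  expect_equal(matrix_labels(x, "species"), matrix_labels(x2, "species"))
})
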