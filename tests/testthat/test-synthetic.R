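test_that("simulated taxonomy has the requested shape and disjoint signatures", {
  spec <- sim_spec(seed = 3L)
  tax <- simulate_taxonomy(spec)
  expect_equal(nrow(tax$lineages), 4L)            # 2 phyla x 2 species
  expect_equal(length(unique(tax$lineages$species)), 4L)
  expect_equal(length(unique(tax$lineages$genus)), 2L)
  expect_equal(length(unique(tax$lineages$phylum)), 2L)
  # two signatures per taxon (12 taxa across the five ranks), all distinct,
  # and no word is another's revcomp
  expect_equal(nrow(tax$signatures), 12L * 2L)
  expect_equal(anyDuplicated(tax$signatures$kmer), 0L)
  rc <- revcomp(tax$signatures$kmer)
  expect_length(intersect(rc, tax$signatures$kmer),
                sum(rc == tax$signatures$kmer))  # only palindromes may match
  # determinism
  tax2 <- simulate_taxonomy(spec)
  expect_identical(tax, tax2)
})

test_that("requesting more signatures than available words errors", {
  spec <- sim_spec(k_sig = 2, n_signatures_per_taxon = 3, seed = 1)
  expect_error(simulate_taxonomy(spec), class = "kmerules_param_error")
})

test_that("planted signature frequencies hit the target enrichment", {
  spec <- sim_spec(seed = 13L)
  tax <- simulate_taxonomy(spec)
  for (i in c(1L, 4L)) {
    g <- simulate_genome(tax$lineages[i, ], spec, tax$signatures, seed = 100 + i)
    ck <- count_kmers(g$sequence, 4, strand = "forward")
    f <- kmer_frequencies(ck)
    lineage_taxa <- unlist(g[1, c("species", "genus", "order", "class", "phylum")])
    sig <- tax$signatures[tax$signatures$taxon %in% lineage_taxa, ]
    ratio <- f[sig$kmer] / (1 / 256)
    expect_true(all(ratio >= 4 & ratio <= 6))
    # within +/- 20% of the planted target
    expect_true(all(abs(f[sig$kmer] - sig$target_frequency) <
                      0.2 * sig$target_frequency))
  }
})

test_that("bias zero plants nothing and matches binomial background", {
  spec <- sim_spec(bias = 0, genome_length = 20000, seed = 21L)
  tax <- simulate_taxonomy(spec)
  p0 <- 1 / 256
  for (rep in 1:20) {
    g <- simulate_genome(tax$lineages[1, ], spec, tax$signatures, seed = rep)
    ck <- count_kmers(g$sequence, 4, strand = "forward")
    w <- ck$valid_windows
    sdev <- sqrt(w * p0 * (1 - p0))
    # every signature k-mer count within 4 binomial standard deviations
    sig_counts <- ck$counts[unique(tax$signatures$kmer)]
    expect_true(all(abs(sig_counts - w * p0) <= 4 * sdev))
  }
})

test_that("simulation is a deterministic function of the spec", {
  spec <- sim_spec(genome_length = 5000, seed = 5L)
  s1 <- simulate_genomes(spec)
  s2 <- simulate_genomes(spec)
  expect_identical(s1$genomes$sequence, s2$genomes$sequence)
  # and writing to FASTA gives byte-identical files
  f1 <- tempfile(); f2 <- tempfile()
  write_genomes(s1$genomes, f1)
  write_genomes(s2$genomes, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("benchmark suite returns a labelled 256-row matrix", {
  bench <- small_benchmark()
  expect_s3_class(bench$matrix, "kmer_matrix")
  expect_equal(nrow(bench$matrix$values), 256L)
  expect_equal(ncol(bench$matrix$values), 40L)
  for (r in c("species", "genus", "order", "class", "phylum")) {
    expect_false(any(is.na(matrix_labels(bench$matrix, r))))
  }
})

test_that("saturating signature mass is rejected", {
  spec <- sim_spec(bias = 100, n_signatures_per_taxon = 2, seed = 1)
  expect_error(simulate_taxonomy(spec), class = "kmerules_param_error")
})
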