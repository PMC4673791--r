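# Independent brute-force oracles used across tests.  Deliberately naive:
# plain string scans and exhaustive searches, no shared code with the
# package internals.

# Naive O(n * k) sliding-window k-mer count over one strand.
naive_count_strand <- function(seq, k) {
  n <- nchar(seq)
  counts <- new.env(parent = emptyenv())
  valid <- 0L
  if (k <= n) {
    for (i in seq_len(n - k + 1)) {
      w <- substr(seq, i, i + k - 1)
      if (grepl("N", w, fixed = TRUE)) next
      valid <- valid + 1L
      cur <- mget(w, counts, ifnotfound = 0L)[[1]]
      assign(w, cur + 1L, counts)
    }
  }
  list(counts = counts, valid = valid)
}

naive_revcomp <- function(seq) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(seq, "", fixed = TRUE)[[1]]]), collapse = "")
}

# Naive both/forward-strand count as a named vector over observed words.
naive_count <- function(seq, k, strand = "both") {
  f <- naive_count_strand(seq, k)
  valid <- f$valid
  if (strand == "both") {
    r <- naive_count_strand(naive_revcomp(seq), k)
    valid <- valid + r$valid
    for (w in ls(r$counts)) {
      cur <- mget(w, f$counts, ifnotfound = 0L)[[1]]
      assign(w, cur + get(w, r$counts), f$counts)
    }
  }
  words <- ls(f$counts)
  list(counts = setNames(vapply(words, get, integer(1), envir = f$counts),
                         words),
       valid = valid)
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Exhaustive recursive MDLP discretization: tries every midpoint between
# consecutive distinct sorted values (not only class boundaries), accepts
# the entropy-minimising cut iff it passes the MDL test, recurses.
oracle_entropy <- function(y) {
  p <- table(y) / length(y)
  -sum(p * log2(p))
}

oracle_mdlp <- function(values, labels) {
  ord <- order(values)
  v <- values[ord]
  y <- labels[ord]
  n <- length(v)
  if (n < 2 || length(unique(y)) < 2) return(numeric(0))
  dv <- unique(v)
  if (length(dv) < 2) return(numeric(0))
  mids <- (dv[-1] + dv[-length(dv)]) / 2
  best_cut <- NA
  best_e <- Inf
  for (m in mids) {
    left <- y[v < m]
    right <- y[v >= m]
    e <- length(left) / n * oracle_entropy(left) +
      length(right) / n * oracle_entropy(right)
    if (e < best_e - 1e-12) {
      best_e <- e
      best_cut <- m
    }
  }
  E <- oracle_entropy(y)
  gain <- E - best_e
  left <- y[v < best_cut]
  right <- y[v >= best_cut]
  k_all <- length(unique(y))
  k1 <- length(unique(left))
  k2 <- length(unique(right))
  delta <- log2(3^k_all - 2) -
    (k_all * E - k1 * oracle_entropy(left) - k2 * oracle_entropy(right))
  if (gain <= (log2(n - 1) + delta) / n) return(numeric(0))
  sort(c(oracle_mdlp(values[values < best_cut], labels[values < best_cut]),
         best_cut,
         oracle_mdlp(values[values >= best_cut], labels[values >= best_cut])))
}

# Exhaustive search for a zero-training-error single-literal decision list
# on a binary problem: does some threshold on some feature separate?
oracle_single_literal_separable <- function(X, pos) {
  for (f in colnames(X)) {
    v <- sort(unique(X[, f]))
    if (length(v) < 2) next
    for (t in (v[-1] + v[-length(v)]) / 2) {
      ge <- X[, f] >= t
      if (all(ge == pos) || all(ge == !pos)) return(TRUE)
    }
  }
  FALSE
}

# Small deterministic genome tibble with planted two-class signal on one
# feature, for learner unit tests: class "a" genomes are enriched for the
# word `sig`, class "b" genomes are not.
toy_two_class_genomes <- function(n_per_class = 10, len = 3000, sig = "ACGT",
                                  copies = min(60, len %/% 10), seed = 42) {
  withr::with_seed(seed, {
    make <- function(cls, i, plant) {
      s <- random_dna(len)
      if (plant) {
        slots <- sample.int(len %/% 8, copies) * 8 - 7
        for (p in slots) substr(s, p, p + nchar(sig) - 1) <- sig
      }
      tibble::tibble(id = paste0(cls, i), sequence = s, species = cls,
                     genus = cls, order = cls, class = cls, phylum = cls)
    }
    dplyr::bind_rows(c(
      lapply(seq_len(n_per_class), function(i) make("a", i, TRUE)),
      lapply(seq_len(n_per_class), function(i) make("b", i, FALSE))
    ))
  })
}

# Shared small benchmark simulation (cached per test run) so several test
# files can reuse one simulation without repeating the cost.
small_benchmark <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- kmerules::sim_spec(genome_length = 20000, seed = 7L)
      cache <<- kmerules::benchmark_suite(spec)
    }
    cache
  }
})

# Full-scale benchmark at the default study conditions (4 species nested in
# 2 genera / 2 phyla, 10 genomes per species, 50 kb, k = 4, bias 5, seed 1);
# cached because several acceptance checks share it.
full_benchmark <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- kmerules::benchmark_suite(kmerules::sim_spec(seed = 1L))
    }
    cache
  }
})
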