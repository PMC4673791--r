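#' Enumerate all k-mers in lexicographic order
#'
#' @param k Word length.
#' @return Character vector of the `4^k` words over A < C < G < T.
#' @export
all_kmers <- function(k) {
  if (k < 1 || k > 12) abort_param("k must be in [1, 12]")
  grids <- rep(list(c("A", "C", "G", "T")), k)
  do.call(paste0, rev(expand.grid(rev(grids), stringsAsFactors = FALSE)))
}

#' Count k-mers in a sequence
#'
#' Slides a window of length `k` over the forward strand and, when
#' `strand = "both"`, independently over the reverse complement; counts from
#' the two scans are summed and windows never span the junction.  Windows
#' containing `N` are skipped and do not count as valid windows.
#'
#' @param sequence A single nucleotide string over `{A, C, G, T, N}`.
#' @param k Word length (1--12).
#' @param strand `"both"` (forward + reverse complement, the default used by
#'   the classification pipeline) or `"forward"`.
#' @return An object of class `kmer_counts`: a list with `k`, `counts` (named
#'   integer vector over all `4^k` words), `valid_windows`, and `strand`.
#' @export
count_kmers <- function(sequence, k, strand = c("both", "forward")) {
  strand <- match.arg(strand)
  if (length(sequence) != 1 || !is.character(sequence)) {
    abort_param("count_kmers() expects a single sequence string")
  }
  if (!is.numeric(k) || k < 1) abort_param("k must be a positive integer")
  k <- as.integer(k)
  if (k > 12) abort_param("k > 12 is not supported (4^k feature blow-up)")
  n <- nchar(sequence)
  kmers <- all_kmers(k)
  if (k > n) {
    warn(paste0("k = ", k, " exceeds sequence length ", n,
                "; returning empty counts"))
    counts <- setNames(integer(length(kmers)), kmers)
    return(new_kmer_counts(k, counts, 0L, strand))
  }
  dna <- Biostrings::DNAString(sequence)
  cnt <- Biostrings::oligonucleotideFrequency(dna, width = k)
  if (strand == "both") {
    cnt <- cnt + Biostrings::oligonucleotideFrequency(
      Biostrings::reverseComplement(dna), width = k)
  }
  counts <- setNames(as.integer(cnt[kmers]), kmers)
  new_kmer_counts(k, counts, sum(counts), strand)
}

new_kmer_counts <- function(k, counts, valid_windows, strand) {
  structure(
    list(k = k, counts = counts, valid_windows = as.integer(valid_windows),
         strand = strand),
    class = "kmer_counts"
  )
}

#' @export
print.kmer_counts <- function(x, ...) {
  cat("<kmer_counts> k =", x$k, "| strand =", x$strand,
      "| valid windows =", x$valid_windows, "\n")
  nz <- x$counts[x$counts > 0]
  cat("  ", length(nz), "of", length(x$counts), "words observed\n")
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.kmer_counts <- function(x, ...) {
  tibble(kmer = names(x$counts), count = as.integer(x$counts))
}

#' Convert k-mer counts to relative frequencies
#'
#' Each word's frequency is its count divided by the number of valid windows
#' (the classical `c_i / (n - k + 1)` denominator, generalised so that
#' windows containing `N` do not distort frequencies).  Frequencies sum to 1
#' whenever any window was valid.
#'
#' @param counts A `kmer_counts` object.
#' @return Named numeric vector over all `4^k` words.
#' @export
kmer_frequencies <- function(counts) {
  stopifnot(inherits(counts, "kmer_counts"))
  if (counts$valid_windows == 0) {
    warn("no valid windows; returning all-zero frequency vector")
    return(setNames(numeric(length(counts$counts)), names(counts$counts)))
  }
  counts$counts / counts$valid_windows
}

#' Build the k-mer feature matrix for a set of genomes
#'
#' The central data object of the pipeline: one row per k-mer (all `4^k`, in
#' lexicographic order), one column per genome, holding relative frequencies
#' or, when `estimator` is not `"none"`, null-model significance scores
#' (see [kmer_scores()]).  Taxon labels at every rank present in `genomes`
#' travel with the matrix.
#'
#' @param genomes Genome tibble (columns `id`, `sequence`, rank columns).
#' @param k Word length, default 4.
#' @param strand `"both"` or `"forward"` (see [count_kmers()]).
#' @param estimator Significance transform: `"none"` (raw frequencies),
#'   `"markov_k2"`, `"boundary"`, or `"iid"`.
#' @param mask_low_complexity Apply [dust_mask()] before counting?
#' @param zero_policy What to do when a null-model expectation is zero:
#'   `"score_zero"` (score the word 0, default) or `"drop_feature"` (remove
#'   the word's row from the matrix).
#' @return An object of class `kmer_matrix`.
#' @export
kmer_matrix <- function(genomes, k = 4, strand = c("both", "forward"),
                        estimator = c("none", "markov_k2", "boundary", "iid"),
                        mask_low_complexity = FALSE,
                        zero_policy = c("score_zero", "drop_feature")) {
  strand <- match.arg(strand)
  estimator <- match.arg(estimator)
  zero_policy <- match.arg(zero_policy)
  if (!is.data.frame(genomes) || nrow(genomes) == 0) {
    abort_validation("kmer_matrix() needs a non-empty genome table")
  }
  if (anyDuplicated(genomes$id)) {
    abort_validation("duplicate genome ids")
  }
  k <- as.integer(k)
  seqs <- genomes$sequence
  if (mask_low_complexity) seqs <- dust_mask(seqs)

  kmers <- all_kmers(k)
  cols <- vector("list", nrow(genomes))
  flagged <- setNames(logical(length(kmers)), kmers)
  for (i in seq_along(seqs)) {
    if (estimator == "none") {
      cols[[i]] <- kmer_frequencies(count_kmers(seqs[i], k, strand))
    } else {
      sc <- kmer_scores(seqs[i], k, estimator = estimator, strand = strand,
                        zero_policy = zero_policy)
      cols[[i]] <- sc$scores
      flagged <- flagged | sc$zero_expectation
    }
  }
  values <- do.call(cbind, cols)
  dimnames(values) <- list(kmers, genomes$id)
  if (estimator != "none" && zero_policy == "drop_feature" && any(flagged)) {
    values <- values[!flagged, , drop = FALSE]
  }
  ranks <- intersect(TAX_RANKS, names(genomes))
  labels <- genomes[, c("id", ranks), drop = FALSE]
  new_kmer_matrix(k, values, labels, strand, estimator, mask_low_complexity)
}

new_kmer_matrix <- function(k, values, labels, strand, estimator,
                            masked = FALSE) {
  structure(
    list(k = k, values = values, labels = as_tibble(labels), strand = strand,
         estimator = estimator, masked = masked),
    class = "kmer_matrix"
  )
}

#' @export
print.kmer_matrix <- function(x, ...) {
  cat("<kmer_matrix> ", nrow(x$values), " k-mers (k = ", x$k, ") x ",
      ncol(x$values), " genomes\n", sep = "")
  cat("  strand = ", x$strand, ", estimator = ", x$estimator, "\n", sep = "")
  ranks <- setdiff(names(x$labels), "id")
  for (r in ranks) {
    lv <- unique(stats::na.omit(x$labels[[r]]))
    cat("  ", r, ": ", length(lv), " class(es)\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.kmer_matrix <- function(x) dim(x$values)

#' Long-format view of a feature matrix
#'
#' @param x A `kmer_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `kmer`, `id`, `value` plus rank labels.
#' @exportS3Method tibble::as_tibble
as_tibble.kmer_matrix <- function(x, ...) {
  long <- tibble(
    kmer = rep(rownames(x$values), times = ncol(x$values)),
    id = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values)
  )
  dplyr::left_join(long, x$labels, by = "id")
}

#' Class labels of a feature matrix at one rank
#'
#' @param x A `kmer_matrix`.
#' @param rank One of `"species"`, `"genus"`, `"order"`, `"class"`,
#'   `"phylum"`.
#' @return Character vector aligned with the matrix columns.
#' @export
matrix_labels <- function(x, rank) {
  stopifnot(inherits(x, "kmer_matrix"))
  rank <- match.arg(rank, TAX_RANKS)
  if (!rank %in% names(x$labels)) {
    abort_validation(paste0("no labels at rank '", rank, "'"))
  }
  x$labels[[rank]][match(colnames(x$values), x$labels$id)]
}

subset_matrix <- function(x, keep) {
  x$values <- x$values[, keep, drop = FALSE]
  x$labels <- x$labels[x$labels$id %in% colnames(x$values), , drop = FALSE]
  x
}

#' Drop classes with too few specimens
#'
#' Removes every genome whose class at `rank` has fewer than `min_specimens`
#' members, so that the classifiers have enough examples per class to train
#' on.  The conventional cut is nine specimens.
#'
#' @param x A `kmer_matrix`.
#' @param rank Taxonomic rank whose classes are filtered.
#' @param min_specimens Minimum class size to keep (default 9).
#' @return The filtered `kmer_matrix`.
#' @export
filter_rare_classes <- function(x, rank, min_specimens = 9) {
  stopifnot(inherits(x, "kmer_matrix"))
  lab <- matrix_labels(x, rank)
  sizes <- table(lab[!is.na(lab)])
  keep_classes <- names(sizes)[sizes >= min_specimens]
  keep <- !is.na(lab) & lab %in% keep_classes
  if (!any(keep)) {
    abort_filter(paste0(
      "no class at rank '", rank, "' has >= ", min_specimens, " specimens"
    ))
  }
  subset_matrix(x, keep)
}

#' Write / read a feature matrix as TSV
#'
#' The layout mirrors the classical frequency-vector table: the first header
#' line carries the genome ids, the second the class labels at one rank, and
#' each following line one k-mer row.  Values are written with 12 significant
#' digits so the round trip is exact at that precision.
#'
#' @param x A `kmer_matrix`.
#' @param path Output path.
#' @param rank Rank whose labels go into the second header line.
#' @return `x`, invisibly.
#' @export
write_matrix_tsv <- function(x, path, rank = "species") {
  stopifnot(inherits(x, "kmer_matrix"))
  lab <- matrix_labels(x, rank)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("kmer", colnames(x$values)), collapse = "\t"), con)
  writeLines(paste(c(paste0("#", rank), ifelse(is.na(lab), "", lab)),
                   collapse = "\t"), con)
  body <- apply(x$values, 1, function(v)
    paste(signif(v, 12), collapse = "\t"))
  writeLines(paste(rownames(x$values), body, sep = "\t"), con)
  invisible(x)
}

#' @rdname write_matrix_tsv
#' @param k Word length of the stored matrix (inferred from row names when
#'   `NULL`).
#' @export
read_matrix_tsv <- function(path, k = NULL) {
  lines <- readLines(path)
  if (length(lines) < 3) abort_format("matrix TSV too short")
  ids <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
  lab_fields <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  rank <- sub("^#", "", lab_fields[1])
  labels <- lab_fields[-1]
  labels[labels == ""] <- NA_character_
  body <- strsplit(lines[-c(1, 2)], "\t", fixed = TRUE)
  kmers <- vapply(body, `[[`, character(1), 1)
  values <- t(vapply(body, function(f) as.numeric(f[-1]),
                     numeric(length(ids))))
  if (length(ids) == 1) values <- matrix(values, ncol = 1)
  dimnames(values) <- list(kmers, ids)
  if (is.null(k)) k <- nchar(kmers[1])
  labtab <- tibble(id = ids)
  labtab[[rank]] <- labels
  new_kmer_matrix(as.integer(k), values, labtab, strand = "both",
                  estimator = "none")
}
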