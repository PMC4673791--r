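#' Empirical probability of a word
#'
#' `occurrences(W) / valid_windows` for windows of length `|W|`, the
#' empirical estimate of the probability that a random window of the
#' sequence equals `W`.
#'
#' @param counts A `kmer_counts` object at word length `nchar(W)`.
#' @param W A word over `{A, C, G, T}`.
#' @return A probability in `[0, 1]`.
#' @export
empirical_probability <- function(counts, W) {
  stopifnot(inherits(counts, "kmer_counts"))
  if (nchar(W) != counts$k) {
    abort_param("word length does not match counts$k")
  }
  if (counts$valid_windows == 0) {
    warn("no valid windows; empirical probability is 0")
    return(0)
  }
  unname(counts$counts[W]) / counts$valid_windows
}

#' Null-model expectations for a k-mer's probability
#'
#' Three estimators of the expected probability of a word `W` of length `k`:
#'
#' * `markov_expectation()`: `p(W[1..k-1]) * p(W[2..k]) / p(W[2..k-1])`,
#'   exact if the sequence were generated by a Markov chain of order `k - 2`
#'   or smaller.  Requires `k >= 3`.
#' * `boundary_expectation()`:
#'   `(f(W[1]) * f(W[2..k]) + f(W[1..k-1]) * f(W[k])) / 2`, derived assuming
#'   the interior of `W` and its boundary characters occur independently.
#' * `iid_expectation()`: the product of single-nucleotide frequencies
#'   `prod(f(W[i]))`.
#'
#' All take named numeric vectors of sub-word probabilities/frequencies as
#' produced by [kmer_frequencies()] at the relevant lengths.  When a needed
#' denominator or sub-word value is zero/absent the expectation is 0; the
#' caller decides what to do with the zero (see [z_score()]).
#'
#' @param p_km1,p_km2 Probabilities of words of length `k - 1` and `k - 2`.
#' @param W The word of length `k`.
#' @return The expected probability (non-negative).
#' @export
markov_expectation <- function(p_km1, p_km2, W) {
  k <- nchar(W)
  if (k < 3) abort_param("markov expectation requires k >= 3")
  interior <- substr(W, 2, k - 1)
  den <- p_km2[[interior]]
  if (is.null(den) || is.na(den) || den == 0) return(0)
  unname(p_km1[[substr(W, 1, k - 1)]] * p_km1[[substr(W, 2, k)]] / den)
}

#' @rdname markov_expectation
#' @param f1,f_km1 Frequencies of single nucleotides and `(k-1)`-mers.
#' @export
boundary_expectation <- function(f1, f_km1, W) {
  k <- nchar(W)
  if (k < 2) abort_param("boundary expectation requires k >= 2")
  left <- f1[[substr(W, 1, 1)]] * f_km1[[substr(W, 2, k)]]
  right <- f_km1[[substr(W, 1, k - 1)]] * f1[[substr(W, k, k)]]
  unname((left + right) / 2)
}

#' @rdname markov_expectation
#' @export
iid_expectation <- function(f1, W) {
  bases <- strsplit(W, "", fixed = TRUE)[[1]]
  prod(f1[bases])
}

#' Relative-deviation significance score
#'
#' `z = (p - p_expected) / p_expected`: positive when a word is
#' over-represented relative to the null model, negative when depleted,
#' 0 when the null model matches.  Scale-invariant in `(p, p_expected)`.
#'
#' @param p Observed probability.
#' @param p_expected Null-model expectation.
#' @param zero_policy When `p_expected` is 0: `"score_zero"` returns 0
#'   (default); `"drop_feature"` signals the caller to exclude the word.
#' @return The score; with `zero_policy = "drop_feature"` a zero expectation
#'   yields `NA` so the caller can drop the row.
#' @export
z_score <- function(p, p_expected, zero_policy = c("score_zero", "drop_feature")) {
  zero_policy <- match.arg(zero_policy)
  out <- (p - p_expected) / p_expected
  zero <- p_expected == 0
  out[zero] <- if (zero_policy == "score_zero") 0 else NA_real_
  out
}

#' Significance-score vector of one genome
#'
#' Computes, for every word of length `k`, the relative deviation of its
#' empirical probability from a null-model expectation.  Sub-word
#' probabilities are counted on the same sequence with the same strand mode,
#' so the null model is internally consistent.
#'
#' @param sequence Nucleotide string.
#' @param k Word length (`>= 3` for `markov_k2`).
#' @param estimator `"markov_k2"`, `"boundary"`, or `"iid"`.
#' @param strand Strand mode, as in [count_kmers()].
#' @param zero_policy See [z_score()].
#' @return List with `scores` (named numeric over all `4^k` words, zero
#'   policy already applied as 0) and `zero_expectation` (named logical
#'   flagging words whose expectation was 0).
#' @export
kmer_scores <- function(sequence, k,
                        estimator = c("markov_k2", "boundary", "iid"),
                        strand = c("both", "forward"),
                        zero_policy = c("score_zero", "drop_feature")) {
  estimator <- match.arg(estimator)
  strand <- match.arg(strand)
  zero_policy <- match.arg(zero_policy)
  k <- as.integer(k)
  if (estimator == "markov_k2" && k < 3) {
    abort_param("estimator 'markov_k2' requires k >= 3")
  }
  ck <- count_kmers(sequence, k, strand)
  kmers <- names(ck$counts)
  p <- kmer_frequencies(ck)

  expectation <- switch(
    estimator,
    markov_k2 = {
      p_km1 <- kmer_frequencies(count_kmers(sequence, k - 1L, strand))
      p_km2 <- if (k - 2L >= 1L) {
        kmer_frequencies(count_kmers(sequence, k - 2L, strand))
      } else {
        c(setNames(1, ""))
      }
      pref <- p_km1[substr(kmers, 1, k - 1)]
      suff <- p_km1[substr(kmers, 2, k)]
      interior <- p_km2[substr(kmers, 2, k - 1)]
      ex <- ifelse(interior == 0, 0, pref * suff / interior)
      setNames(as.numeric(ex), kmers)
    },
    boundary = {
      f1 <- kmer_frequencies(count_kmers(sequence, 1L, strand))
      f_km1 <- kmer_frequencies(count_kmers(sequence, k - 1L, strand))
      left <- f1[substr(kmers, 1, 1)] * f_km1[substr(kmers, 2, k)]
      right <- f_km1[substr(kmers, 1, k - 1)] * f1[substr(kmers, k, k)]
      setNames(as.numeric((left + right) / 2), kmers)
    },
    iid = {
      f1 <- kmer_frequencies(count_kmers(sequence, 1L, strand))
      ex <- rep(1, length(kmers))
      for (pos in seq_len(k)) {
        ex <- ex * f1[substr(kmers, pos, pos)]
      }
      setNames(as.numeric(ex), kmers)
    }
  )
  zero <- expectation == 0
  scores <- numeric(length(kmers))
  scores[!zero] <- (p[!zero] - expectation[!zero]) / expectation[!zero]
  list(
    scores = setNames(scores, kmers),
    zero_expectation = setNames(zero, kmers)
  )
}
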