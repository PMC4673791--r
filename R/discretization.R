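# Shannon entropy (bits) of a label vector.
label_entropy <- function(y) {
  p <- tabulate(y) / length(y)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Supervised MDL discretization of one feature
#'
#' Recursive entropy-based partitioning with the minimum-description-length
#' stopping rule.  Candidate cut points are midpoints between consecutive
#' distinct sorted values whose boundary separates differing class labels;
#' the entropy-minimising cut is accepted iff its information gain exceeds
#' `log2(N - 1)/N + delta/N` with
#' `delta = log2(3^c - 2) - (c*E - c1*E1 - c2*E2)`, and the procedure then
#' recurses on both sides.  Ties in entropy are broken toward the smallest
#' cut value.
#'
#' @param values Numeric feature values.
#' @param labels Class labels, same length.
#' @return Sorted numeric vector of cut points (possibly empty).  A value
#'   `v` falls in interval `i` iff `cuts[i] <= v < cuts[i + 1]` (half-open).
#' @export
mdl_cutpoints <- function(values, labels) {
  if (length(values) != length(labels)) {
    abort_validation("values and labels must have equal length")
  }
  if (length(values) == 0) return(numeric(0))
  y <- as.integer(factor(labels))
  ord <- order(values)
  sort(mdl_recurse(values[ord], y[ord]))
}

mdl_recurse <- function(v, y) {
  n <- length(v)
  if (n < 2 || length(unique(y)) < 2) return(numeric(0))
  # candidate boundaries between distinct values with differing labels across
  runs <- which(diff(v) > 0)             # boundary after position i
  if (length(runs) == 0) return(numeric(0))
  # a boundary is a class boundary unless both sides' value-groups are pure
  # with the same single class; checking labels immediately around suffices
  # only for sorted-within-value purity, so group labels per distinct value.
  grp <- cumsum(c(1L, as.integer(diff(v) > 0)))
  n_grp <- grp[n]
  grp_single <- vapply(split(y, grp), function(g) {
    u <- unique(g)
    if (length(u) == 1) u else -1L
  }, integer(1))
  cand <- integer(0)
  for (b in seq_len(n_grp - 1L)) {
    l <- grp_single[b]; r <- grp_single[b + 1L]
    if (l == -1L || r == -1L || l != r) cand <- c(cand, b)
  }
  if (length(cand) == 0) return(numeric(0))
  grp_end <- cumsum(tabulate(grp))       # last index of each value group
  # entropies of left/right parts via cumulative class counts
  K <- max(y)
  cum <- apply(sapply(seq_len(K), function(c) cumsum(y == c)), 2, identity)
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = n)
  total <- cum[n, ]
  ent_from_counts <- function(cnt) {
    s <- sum(cnt)
    p <- cnt[cnt > 0] / s
    -sum(p * log2(p))
  }
  best <- NULL
  best_ent <- Inf
  for (b in cand) {
    i <- grp_end[b]
    cl <- cum[i, ]
    cr <- total - cl
    e <- (i / n) * ent_from_counts(cl) + ((n - i) / n) * ent_from_counts(cr)
    if (e < best_ent - 1e-12) {
      best_ent <- e
      best <- i
    }
  }
  E <- ent_from_counts(total)
  gain <- E - best_ent
  cl <- cum[best, ]; cr <- total - cl
  c_all <- sum(total > 0)
  c1 <- sum(cl > 0); c2 <- sum(cr > 0)
  E1 <- ent_from_counts(cl); E2 <- ent_from_counts(cr)
  delta <- log2(3^c_all - 2) - (c_all * E - c1 * E1 - c2 * E2)
  if (gain <= (log2(n - 1) + delta) / n) return(numeric(0))
  cut <- (v[best] + v[best + 1]) / 2
  c(mdl_recurse(v[seq_len(best)], y[seq_len(best)]),
    cut,
    mdl_recurse(v[(best + 1):n], y[(best + 1):n]))
}

#' Equal-frequency discretization of one feature
#'
#' Cut points at the `j/n` empirical quantiles, `j = 1 .. n - 1`, computed
#' as midpoints between the order statistics flanking each quantile
#' position; duplicate or degenerate cuts are collapsed.
#'
#' @param values Numeric feature values.
#' @param n_intervals Number of intervals, at least 2.
#' @return Sorted numeric vector of cut points (possibly empty).
#' @export
equal_frequency_cutpoints <- function(values, n_intervals) {
  if (n_intervals < 2) abort_param("n_intervals must be >= 2")
  v <- sort(values)
  N <- length(v)
  cuts <- numeric(0)
  for (j in seq_len(n_intervals - 1)) {
    idx <- ceiling(j * N / n_intervals)
    if (idx >= N) next
    if (v[idx] < v[idx + 1]) {
      cuts <- c(cuts, (v[idx] + v[idx + 1]) / 2)
    }
  }
  sort(unique(cuts))
}

#' Map values to half-open interval indices
#'
#' Interval `i` (0-based) is `[cuts[i], cuts[i+1])`; a value equal to a cut
#' point belongs to the interval above it.  With no cuts every value maps
#' to interval 0.  The mapping is monotone in the value.
#'
#' @param values Numeric vector.
#' @param cuts Sorted cut points.
#' @return Integer vector of 0-based interval indices.
#' @export
apply_cutpoints <- function(values, cuts) {
  if (length(cuts) == 0) return(rep(0L, length(values)))
  findInterval(values, cuts)
}

#' Fit cut points for every feature of a matrix
#'
#' @param x A `kmer_matrix` (training data only — fit cut points inside
#'   cross-validation folds to avoid test-set leakage).
#' @param rank Rank whose labels supervise the MDL criterion.
#' @param method `"mdl"` (default), `"equal_frequency"`, or `"none"`.
#' @param n_intervals Interval count for `"equal_frequency"`.
#' @return Named list of numeric cut-point vectors, one per k-mer.
#' @export
fit_cutpoints <- function(x, rank, method = c("mdl", "equal_frequency", "none"),
                          n_intervals = 3) {
  stopifnot(inherits(x, "kmer_matrix"))
  method <- match.arg(method)
  lab <- matrix_labels(x, rank)
  out <- vector("list", nrow(x$values))
  names(out) <- rownames(x$values)
  for (i in seq_len(nrow(x$values))) {
    out[[i]] <- switch(
      method,
      mdl = mdl_cutpoints(x$values[i, ], lab),
      equal_frequency = equal_frequency_cutpoints(x$values[i, ], n_intervals),
      none = numeric(0)
    )
  }
  out
}

#' Serialize / deserialize cut points as JSON
#'
#' Values stay on the raw scale of the matrix (relative frequencies in
#' `[0, 1]` or significance scores); any display scaling is cosmetic only.
#'
#' @param cuts Named list of cut-point vectors.
#' @param path Output path.
#' @export
write_cutpoints <- function(cuts, path) {
  jsonlite::write_json(cuts[lengths(cuts) > 0], path, digits = NA)
  invisible(cuts)
}

#' @rdname write_cutpoints
#' @export
read_cutpoints <- function(path) {
  lapply(jsonlite::read_json(path, simplifyVector = TRUE), as.numeric)
}
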