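# Partial-tree rule induction (PART-style): repeatedly build a pruned
# C4.5-style decision tree (binary gain-ratio splits at candidate
# thresholds, pessimistic error pruning), turn its best leaf into a rule,
# remove the samples that leaf covers, and repeat until no samples remain
# or the tree collapses to a single leaf.

#' Fit a partial-tree (PART-style) rule model
#'
#' @inheritParams ripper
#' @param confidence Confidence factor of the pessimistic pruning upper
#'   bound (default 0.25, the classical C4.5 value).
#' @param min_leaf Minimum number of samples per leaf (default 2).
#' @return A `rule_model`.
#' @export
part <- function(x, rank, cuts = NULL, confidence = 0.25, min_leaf = 2,
                 seed = NULL) {
  fit_common(x, rank, cuts, seed, learner = "part",
             params = list(confidence = confidence, min_leaf = min_leaf),
             fit_fun = part_fit_impl)
}

part_fit_impl <- function(X, y, thresholds, params) {
  z <- stats::qnorm(1 - params$confidence)
  rules <- list()
  remaining <- rep(TRUE, nrow(X))
  default <- NULL
  repeat {
    if (!any(remaining)) break
    idx <- which(remaining)
    tree <- build_tree(X[idx, , drop = FALSE], y[idx], thresholds,
                       params$min_leaf, z)
    if (tree$leaf) {  # single leaf: residual becomes the default
      default <- majority_class(y[idx])
      break
    }
    leaf <- best_leaf(tree)
    lits <- merge_literals(leaf$path)
    rule <- new_rule(lits, leaf$class)
    covered <- rule_matches(rule, X[idx, , drop = FALSE])
    if (!any(covered)) break
    rules[[length(rules) + 1]] <- rule
    remaining[idx[covered]] <- FALSE
  }
  list(rules = rules, default = default)
}

# Pessimistic upper bound on the error rate (C4.5-style normal
# approximation to the binomial upper confidence limit).
pessimistic_error <- function(errors, n, z) {
  if (n == 0) return(0)
  f <- errors / n
  (f + z^2 / (2 * n) + z * sqrt(f * (1 - f) / n + z^2 / (4 * n^2))) /
    (1 + z^2 / n)
}

build_tree <- function(X, y, thresholds, min_leaf, z, path = list()) {
  n <- length(y)
  maj <- majority_class(y)
  errors <- sum(y != maj)
  leaf_node <- list(leaf = TRUE, class = maj, n = n, errors = errors,
                    path = path)
  if (n < 2 * min_leaf || length(unique(y)) < 2) return(leaf_node)
  split <- best_split(X, y, thresholds, min_leaf)
  if (is.null(split)) return(leaf_node)
  m <- X[, split$f] >= split$t
  left <- build_tree(X[!m, , drop = FALSE], y[!m], thresholds, min_leaf, z,
                     c(path, list(new_literal(split$f, -Inf, split$t))))
  right <- build_tree(X[m, , drop = FALSE], y[m], thresholds, min_leaf, z,
                      c(path, list(new_literal(split$f, split$t, Inf))))
  subtree_err <- subtree_pessimistic(left, z) + subtree_pessimistic(right, z)
  leaf_err <- n * pessimistic_error(errors, n, z)
  if (leaf_err <= subtree_err) return(leaf_node)  # prune to a leaf
  list(leaf = FALSE, f = split$f, t = split$t, left = left, right = right,
       n = n, path = path)
}

subtree_pessimistic <- function(node, z) {
  if (node$leaf) return(node$n * pessimistic_error(node$errors, node$n, z))
  subtree_pessimistic(node$left, z) + subtree_pessimistic(node$right, z)
}

# Gain-ratio-maximising binary split over candidate thresholds.
# Ties: higher information gain, then wider separation margin at the
# threshold, then lexicographically smaller feature, then lower
# threshold.  When no split has positive gain, the best
# zero-gain split is used as a last resort so that pure interactions
# (XOR-like class structure) can still be carved out; pessimistic pruning
# removes such splits when they do not pay off.
best_split <- function(X, y, thresholds, min_leaf) {
  n <- length(y)
  yi <- as.integer(factor(y))
  E <- label_entropy(yi)
  best <- NULL
  best_zero <- NULL
  for (f in names(thresholds)) {
    ths <- thresholds[[f]]
    if (length(ths) == 0) next
    v <- X[, f]
    for (t in ths) {
      m <- v >= t
      nr <- sum(m)
      nl <- n - nr
      if (nl < min_leaf || nr < min_leaf) next
      el <- label_entropy(yi[!m])
      er <- label_entropy(yi[m])
      gain <- E - (nl / n) * el - (nr / n) * er
      if (gain <= 1e-12) {
        if (is.null(best_zero)) best_zero <- list(f = f, t = t)
        next
      }
      si <- -(nl / n) * log2(nl / n) - (nr / n) * log2(nr / n)
      ratio <- gain / si
      gap <- threshold_gap(v, t)
      better <- is.null(best) ||
        ratio > best$ratio + 1e-12 ||
        (abs(ratio - best$ratio) <= 1e-12 &&
           (gain > best$gain + 1e-12 ||
              (abs(gain - best$gain) <= 1e-12 &&
                 (gap > best$gap + 1e-15 ||
                    (abs(gap - best$gap) <= 1e-15 &&
                       (f < best$f || (f == best$f && t < best$t)))))))
      if (better) best <- list(f = f, t = t, ratio = ratio, gain = gain,
                               gap = gap)
    }
  }
  best %||% best_zero
}

# The leaf covering the most training samples; ties favour fewer errors,
# then paths dominated by over-representation (>=) conditions — a class
# is preferentially described by its own enriched words rather than by
# the absence of another's — then depth-first order.
best_leaf <- function(tree) {
  leaves <- collect_leaves(tree)
  ns <- vapply(leaves, `[[`, numeric(1), "n")
  errs <- vapply(leaves, `[[`, numeric(1), "errors")
  geq_frac <- vapply(leaves, function(l) {
    if (length(l$path) == 0) return(0)
    mean(vapply(l$path, function(lit) is.finite(lit$lo), logical(1)))
  }, numeric(1))
  ord <- order(-ns, errs, -geq_frac)
  leaves[[ord[1]]]
}

collect_leaves <- function(node) {
  if (node$leaf) return(list(node))
  c(collect_leaves(node$left), collect_leaves(node$right))
}
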