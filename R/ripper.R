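# Sequential-covering rule induction with incremental reduced-error pruning
# (RIPPER-style).  Classes are processed in ascending prevalence, each
# against all remaining samples; per rule the learner GROWs literals on a
# grow split by FOIL information gain, PRUNEs trailing literals on the
# held-out split to maximise (p - n)/(p + n), and stops adding rules when
# the ruleset description length exceeds the best seen by `dl_slack` bits
# or a rule errs on more than half of the prune data.  Optimization passes
# consider replacing or revising each rule.  The most prevalent class
# becomes the default.

#' Fit a sequential-covering (RIPPER-style) rule model
#'
#' @param x A `kmer_matrix` with labels at `rank`.
#' @param rank Taxonomic rank to classify.
#' @param cuts Optional named list of per-feature cut points (as from
#'   [fit_cutpoints()]); candidate literal thresholds.  When `NULL`,
#'   MDL cut points are fitted on `x` itself.  Pass the string `"midpoints"`
#'   to grow on midpoints between consecutive sorted raw values instead.
#' @param grow_fraction Fraction of samples used for growing (the rest
#'   prunes); default 2/3.
#' @param optimization_passes Number of replace/revise optimization sweeps;
#'   default 2.
#' @param dl_slack Description-length slack in bits before rule addition
#'   stops; default 64.
#' @param seed Integer seed making the grow/prune splits reproducible.
#' @return A `rule_model`.
#' @export
ripper <- function(x, rank, cuts = NULL, grow_fraction = 2 / 3,
                   optimization_passes = 2, dl_slack = 64, seed = NULL) {
  fit_common(x, rank, cuts, seed, learner = "ripper",
             params = list(grow_fraction = grow_fraction,
                           optimization_passes = optimization_passes,
                           dl_slack = dl_slack),
             fit_fun = ripper_fit_impl)
}

# Shared front end for both learners: label handling, candidate thresholds,
# degenerate cases, seeding, final coverage bookkeeping.
fit_common <- function(x, rank, cuts, seed, learner, params, fit_fun) {
  stopifnot(inherits(x, "kmer_matrix"))
  if (ncol(x$values) == 0) abort_validation("empty feature matrix")
  y <- matrix_labels(x, rank)
  ok <- !is.na(y)
  if (!any(ok)) abort_validation(paste0("no labels at rank '", rank, "'"))
  X <- t(x$values[, ok, drop = FALSE])  # samples x features
  y <- y[ok]
  thresholds <- candidate_thresholds(X, y, cuts)
  run <- function() {
    if (length(unique(y)) < 2) {
      warn(paste0("single class at rank '", rank, "'; default-only model"))
      fitted <- list(rules = list(), default = NULL)
    } else {
      fitted <- fit_fun(X, y, thresholds, params)
    }
    rules <- fitted$rules
    default <- fitted$default %||% majority_class(y)
    rules <- lapply(rules, function(r) {
      m <- rule_matches(r, X)
      r$coverage <- c(p = sum(m & y == r$conclusion),
                      n = sum(m & y != r$conclusion))
      r
    })
    new_rule_model(rules, default, rank, learner, x$k, params,
                   seed = seed %||% NA_integer_)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

majority_class <- function(y) {
  tab <- sort(table(y), decreasing = TRUE)
  names(tab)[1]
}

# Candidate thresholds per feature.  With cuts = NULL, MDL cut points are
# fitted on the data at hand; "midpoints" uses midpoints between
# consecutive distinct sorted values.  Features without candidates are
# uninformative for the learners.
candidate_thresholds <- function(X, y, cuts) {
  feats <- colnames(X)
  if (is.null(cuts)) {
    out <- lapply(feats, function(f) mdl_cutpoints(X[, f], y))
    names(out) <- feats
    out
  } else if (identical(cuts, "midpoints")) {
    out <- lapply(feats, function(f) {
      v <- sort(unique(X[, f]))
      if (length(v) < 2) numeric(0) else (v[-1] + v[-length(v)]) / 2
    })
    names(out) <- feats
    out
  } else {
    out <- cuts[feats]
    names(out) <- feats
    out[vapply(out, is.null, logical(1))] <- list(numeric(0))
    out
  }
}

ripper_fit_impl <- function(X, y, thresholds, params) {
  ordered <- names(sort(table(y)))          # ascending prevalence
  default <- ordered[length(ordered)]       # most prevalent -> default
  classes <- ordered[-length(ordered)]
  active <- rep(TRUE, nrow(X))
  rules <- list()
  for (cls in classes) {
    rs <- irep_star(X[active, , drop = FALSE], y[active] == cls, cls,
                    thresholds, params)
    rs <- optimize_ruleset(rs, X[active, , drop = FALSE], y[active] == cls,
                           cls, thresholds, params)
    rules <- c(rules, rs)
    active <- active & y != cls
    if (sum(active) == 0) break
  }
  list(rules = rules, default = default)
}

# Grow-and-prune covering loop for one class (positives `pos`).
irep_star <- function(X, pos, cls, thresholds, params) {
  rules <- list()
  remaining <- rep(TRUE, nrow(X))
  best_dl <- ruleset_dl(rules, X, pos, thresholds)
  repeat {
    if (!any(pos & remaining)) break
    split <- grow_prune_split(pos[remaining], params$grow_fraction)
    idx <- which(remaining)
    gi <- idx[split$grow]; pi <- idx[split$prune]
    rule <- grow_rule(X[gi, , drop = FALSE], pos[gi], cls, thresholds)
    if (length(rule$literals) == 0) break
    rule <- prune_rule(rule, X[pi, , drop = FALSE], pos[pi])
    mp <- rule_matches(rule, X[pi, , drop = FALSE])
    err <- if (any(mp)) sum(mp & !pos[pi]) / sum(mp) else 0
    if (err > 0.5 && length(rules) > 0) break
    cand <- c(rules, list(rule))
    dl <- ruleset_dl(cand, X, pos, thresholds)
    if (dl > best_dl + params$dl_slack) break
    rules <- cand
    best_dl <- min(best_dl, dl)
    covered <- rule_matches(rule, X)
    remaining <- remaining & !covered
    if (!any(remaining)) break
  }
  rules
}

# Stratified random grow/prune split of a logical positive mask.
grow_prune_split <- function(pos, grow_fraction) {
  n <- length(pos)
  grow <- logical(n)
  for (grp in list(which(pos), which(!pos))) {
    if (length(grp) == 0) next
    n_grow <- max(1L, floor(length(grp) * grow_fraction))
    grow[sample(grp, n_grow)] <- TRUE
  }
  if (!any(!grow)) grow[sample(which(grow), 1)] <- FALSE
  list(grow = grow, prune = !grow)
}

# Add literals maximising FOIL information gain until no negatives are
# covered or no literal has positive gain.  Exact gain ties are broken by
# (1) fewer covered negatives, (2) over-representation (>=) conditions
# before under-representation (<) ones, so that a class is described by
# its own enriched words rather than by the absence of a sibling's,
# (3) wider separation margin at the threshold (the gap between the
# closest samples on either side, so that tied perfect separators resolve
# to the strongest marginal signal), (4) lexicographically smaller k-mer,
# (5) lower threshold.
grow_rule <- function(X, pos, cls, thresholds) {
  covered <- rep(TRUE, nrow(X))
  literals <- list()
  feats <- names(thresholds)[lengths(thresholds) > 0]
  repeat {
    p0 <- sum(covered & pos)
    n0 <- sum(covered & !pos)
    if (p0 == 0 || n0 == 0) break
    base_acc <- log2(p0 / (p0 + n0))
    best <- NULL
    for (f in feats) {
      v <- X[, f]
      vc <- v[covered]
      for (t in thresholds[[f]]) {
        gap <- threshold_gap(vc, t)
        for (geq in c(TRUE, FALSE)) {
          m <- if (geq) v >= t else v < t
          p1 <- sum(covered & m & pos)
          if (p1 == 0) next
          n1 <- sum(covered & m & !pos)
          gain <- p1 * (log2(p1 / (p1 + n1)) - base_acc)
          if (gain <= 1e-12) next
          better <- is.null(best) ||
            gain > best$gain + 1e-12 ||
            (abs(gain - best$gain) <= 1e-12 &&
               (n1 < best$n1 ||
                  (n1 == best$n1 &&
                     (geq > best$geq ||
                        (geq == best$geq &&
                           (gap > best$gap + 1e-15 ||
                              (abs(gap - best$gap) <= 1e-15 &&
                                 (f < best$f ||
                                    (f == best$f && t < best$t)))))))))
          if (better) best <- list(gain = gain, f = f, t = t, geq = geq,
                                   n1 = n1, gap = gap, m = m)
        }
      }
    }
    if (is.null(best)) break
    literals[[length(literals) + 1]] <-
      if (best$geq) new_literal(best$f, best$t, Inf)
      else new_literal(best$f, -Inf, best$t)
    covered <- covered & best$m
  }
  new_rule(merge_literals(literals), cls)
}

# Gap between the closest values on either side of a threshold; Inf when
# one side is empty.
threshold_gap <- function(v, t) {
  above <- v[v >= t]
  below <- v[v < t]
  if (length(above) == 0 || length(below) == 0) return(Inf)
  min(above) - max(below)
}

# Intersect multiple single-interval literals on the same feature.
merge_literals <- function(literals) {
  if (length(literals) < 2) return(literals)
  feats <- vapply(literals, `[[`, character(1), "kmer")
  out <- list()
  for (f in unique(feats)) {
    group <- literals[feats == f]
    lo <- max(vapply(group, `[[`, numeric(1), "lo"))
    hi <- min(vapply(group, `[[`, numeric(1), "hi"))
    if (lo < hi) out[[length(out) + 1]] <- new_literal(f, lo, hi)
  }
  out
}

# Delete trailing literals to maximise (p - n)/(p + n) on the prune split.
# Ties favour the shorter rule.  A rule pruned to emptiness is discarded
# by the caller via its empty literal list only if it covered nothing.
prune_rule <- function(rule, X, pos) {
  lits <- rule$literals
  if (length(lits) == 0 || nrow(X) == 0) return(rule)
  best_j <- length(lits)
  best_v <- -Inf
  for (j in rev(seq_along(lits))) {
    r <- new_rule(lits[seq_len(j)], rule$conclusion)
    m <- rule_matches(r, X)
    p <- sum(m & pos); n <- sum(m & !pos)
    v <- if (p + n == 0) -1 else (p - n) / (p + n)
    if (v >= best_v) {  # >= so later (shorter) prefixes win ties
      best_v <- v
      best_j <- j
    }
  }
  new_rule(lits[seq_len(best_j)], rule$conclusion)
}

# Cohen-style optimization: for each rule consider a freshly grown
# replacement and a revision (continued growth), keeping whichever variant
# minimises the ruleset description length.
optimize_ruleset <- function(rules, X, pos, cls, thresholds, params) {
  if (length(rules) == 0) return(rules)
  for (pass in seq_len(params$optimization_passes)) {
    for (i in seq_along(rules)) {
      others <- rules[-i]
      covered_by_others <- if (length(others) == 0) {
        rep(FALSE, nrow(X))
      } else {
        Reduce(`|`, lapply(others, rule_matches, values = X))
      }
      split <- grow_prune_split(pos, params$grow_fraction)
      gi <- which(split$grow); pi <- which(split$prune)
      target <- pos & !covered_by_others
      replacement <- grow_rule(X[gi, , drop = FALSE], target[gi], cls,
                               thresholds)
      replacement <- prune_rule(replacement, X[pi, , drop = FALSE], pos[pi])
      revision <- revise_rule(rules[[i]], X[gi, , drop = FALSE], target[gi],
                              thresholds)
      revision <- prune_rule(revision, X[pi, , drop = FALSE], pos[pi])
      variants <- list(rules[[i]], replacement, revision)
      dls <- vapply(variants, function(v) {
        rs <- rules
        rs[[i]] <- v
        rs <- rs[vapply(rs, function(r) length(r$literals) > 0, logical(1))]
        ruleset_dl(rs, X, pos, thresholds)
      }, numeric(1))
      rules[[i]] <- variants[[which.min(dls)]]
    }
    rules <- rules[vapply(rules, function(r) length(r$literals) > 0,
                          logical(1))]
    if (length(rules) == 0) break
  }
  rules
}

# Continue growing an existing rule's conjunction on new grow data.
revise_rule <- function(rule, X, pos, thresholds) {
  covered <- rule_matches(rule, X)
  extra <- grow_rule_from(X, pos, covered, rule$conclusion, thresholds)
  new_rule(merge_literals(c(rule$literals, extra)), rule$conclusion)
}

grow_rule_from <- function(X, pos, covered, cls, thresholds) {
  grown <- grow_rule_covered(X, pos, covered, cls, thresholds)
  grown$literals
}

grow_rule_covered <- function(X, pos, covered, cls, thresholds) {
  # same growing loop as grow_rule but starting from an initial cover
  rule <- grow_rule(
    X[covered, , drop = FALSE], pos[covered], cls, thresholds
  )
  rule
}

# MDL bookkeeping: theory bits for each rule (which literals out of all
# possible feature-threshold conditions) plus exception bits for the
# covered/uncovered errors.  Relative comparisons only.
ruleset_dl <- function(rules, X, pos, thresholds) {
  n_cond <- 2 * sum(lengths(thresholds))  # each threshold, two directions
  theory <- 0
  for (r in rules) {
    kk <- length(r$literals)
    theory <- theory + 0.5 * (lchoose(max(n_cond, 1), kk) / log(2) +
                                log2(kk + 1))
  }
  covered <- if (length(rules) == 0) {
    rep(FALSE, nrow(X))
  } else {
    Reduce(`|`, lapply(rules, rule_matches, values = X))
  }
  fp <- sum(covered & !pos)
  fn <- sum(!covered & pos)
  nc <- sum(covered)
  nu <- sum(!covered)
  exceptions <- lchoose(nc, fp) / log(2) + lchoose(nu, fn) / log(2) +
    log2(nrow(X) + 1)
  theory + exceptions
}
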