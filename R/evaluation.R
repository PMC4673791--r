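#' Classification accuracy
#'
#' The correct rate `A = c / t`: correctly classified test sequences over
#' total test sequences.
#'
#' @param correct Number of correct predictions.
#' @param total Number of predictions.
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(correct, total) {
  if (total <= 0) abort_param("accuracy undefined for total = 0")
  if (correct < 0 || correct > total) {
    abort_param("need 0 <= correct <= total")
  }
  correct / total
}

#' Stratified k-fold cross-validation of a rule learner
#'
#' Samples are partitioned into `n_folds` folds stratified by class (fold
#' sizes differ by at most one per class).  Within each fold the
#' discretization cut points are fitted on the training part only, the
#' learner is fitted, and the held-out part is predicted.  The aggregate
#' accuracy pools correct counts over all folds (`A = c / t` on the union
#' of test sets).  Classes with a single member cannot be stratified and
#' are excluded with a warning; when the smallest class has fewer members
#' than `n_folds`, the fold count is reduced to that size.
#'
#' @param x A `kmer_matrix`.
#' @param rank Taxonomic rank to classify.
#' @param learner `"ripper"` or `"part"`.
#' @param n_folds Number of folds (default 10).
#' @param discretizer `"mdl"` (default), `"equal_frequency"`, or `"none"`
#'   (learners fall back to midpoint thresholds).
#' @param n_intervals Interval count for the equal-frequency discretizer.
#' @param seed Integer seed; the whole procedure is deterministic given it.
#' @param ... Passed to the learner ([ripper()] or [part()]).
#' @return An object of class `cv_result`.
#' @export
cv_rules <- function(x, rank, learner = c("ripper", "part"), n_folds = 10,
                     discretizer = c("mdl", "equal_frequency", "none"),
                     n_intervals = 3, seed = 1L, ...) {
  stopifnot(inherits(x, "kmer_matrix"))
  learner <- match.arg(learner)
  discretizer <- match.arg(discretizer)
  if (n_folds < 2) abort_param("n_folds must be >= 2")
  y_all <- matrix_labels(x, rank)
  keep <- !is.na(y_all)
  sizes <- table(y_all[keep])
  singletons <- names(sizes)[sizes < 2]
  if (length(singletons) > 0) {
    warn(paste0(
      "excluding ", length(singletons), " class(es) with a single specimen",
      " at rank '", rank, "': ", paste(singletons, collapse = ", ")
    ))
    keep <- keep & !(y_all %in% singletons)
  }
  if (!any(keep)) abort_validation("no usable classes for cross-validation")
  xm <- subset_matrix(x, keep)
  y <- matrix_labels(xm, rank)
  min_class <- min(table(y))
  if (n_folds > min_class) {
    warn(paste0("reducing n_folds from ", n_folds, " to smallest class size ",
                min_class))
    n_folds <- min_class
  }
  classes <- sort(unique(y))

  withr::with_seed(seed, {
    fold <- integer(length(y))
    for (cls in classes) {
      members <- which(y == cls)
      fold[members] <- sample(rep_len(seq_len(n_folds), length(members)))
    }
    fold_acc <- numeric(n_folds)
    fold_n <- integer(n_folds)
    confusion <- matrix(0L, length(classes), length(classes),
                        dimnames = list(truth = classes, predicted = classes))
    complexity <- vector("list", n_folds)
    for (f in seq_len(n_folds)) {
      train <- subset_matrix(xm, fold != f)
      test <- subset_matrix(xm, fold == f)
      cuts <- switch(
        discretizer,
        mdl = fit_cutpoints(train, rank, "mdl"),
        equal_frequency = fit_cutpoints(train, rank, "equal_frequency",
                                        n_intervals = n_intervals),
        none = "midpoints"
      )
      model <- switch(
        learner,
        ripper = ripper(train, rank, cuts = cuts, ...),
        part = part(train, rank, cuts = cuts, ...)
      )
      pred <- predict(model, test)
      truth <- matrix_labels(test, rank)
      fold_acc[f] <- mean(pred == truth)
      fold_n[f] <- length(truth)
      for (i in seq_along(truth)) {
        pr <- if (pred[i] %in% classes) pred[i] else NA
        if (!is.na(pr)) confusion[truth[i], pr] <- confusion[truth[i], pr] + 1L
      }
      complexity[[f]] <- model_complexity(model)
    }
    cpx <- dplyr::bind_rows(complexity)
    structure(
      list(
        rank = rank, learner = learner, n_folds = n_folds, seed = seed,
        fold_accuracy = fold_acc, fold_n = fold_n,
        accuracy = sum(fold_acc * fold_n) / sum(fold_n),
        confusion = confusion,
        complexity = dplyr::summarise(cpx, dplyr::across(
          dplyr::everything(), mean)),
        n = sum(fold_n)
      ),
      class = "cv_result"
    )
  })
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$learner, " @ ", x$rank, ": accuracy ",
      sprintf("%.2f%%", 100 * x$accuracy), " (", x$n_folds, "-fold, n = ",
      x$n, ")\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cv_result <- function(x, ...) {
  tibble(
    rank = x$rank, learner = x$learner, fold = seq_len(x$n_folds),
    accuracy = x$fold_accuracy, n = x$fold_n
  )
}

#' @exportS3Method generics::glance
glance.cv_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble(rank = x$rank, learner = x$learner, accuracy = x$accuracy,
           n_folds = x$n_folds, n = x$n, seed = x$seed),
    x$complexity
  )
}

#' Per-rank accuracy report
#'
#' Runs rare-class filtering followed by cross-validation for every
#' requested rank and learner, mirroring the classical per-taxonomic-level
#' accuracy table.  Ranks where no class survives the specimen filter are
#' reported as `NA` (rendered `-` in the TSV).
#'
#' @param genomes Genome tibble (or a prebuilt `kmer_matrix`).
#' @param ranks Ranks to evaluate (default all five).
#' @param learners Learners to evaluate (default both).
#' @param k,strand,estimator Passed to [kmer_matrix()] when `genomes` is a
#'   tibble.
#' @param min_specimens Rare-class filter threshold (default 9).
#' @inheritParams cv_rules
#' @return A tibble with one row per rank: accuracy per learner plus
#'   `avg` and `sd` columns (proportions in `[0, 1]`).
#' @export
per_rank_report <- function(genomes, ranks = TAX_RANKS,
                            learners = c("ripper", "part"), k = 4,
                            strand = "both", estimator = "none",
                            min_specimens = 9, n_folds = 10,
                            discretizer = "mdl", seed = 1L) {
  x <- if (inherits(genomes, "kmer_matrix")) {
    genomes
  } else {
    kmer_matrix(genomes, k = k, strand = strand, estimator = estimator)
  }
  rows <- lapply(ranks, function(r) {
    accs <- setNames(rep(NA_real_, length(learners)), learners)
    for (l in learners) {
      res <- tryCatch(
        cv_rules(x2 <- filter_rare_classes(x, r, min_specimens), r,
                 learner = l, n_folds = n_folds, discretizer = discretizer,
                 seed = seed),
        kmerules_filter_error = function(e) NULL,
        kmerules_validation_error = function(e) NULL
      )
      if (!is.null(res)) accs[l] <- res$accuracy
    }
    vals <- accs[!is.na(accs)]
    tibble(
      rank = r, !!!as.list(accs),
      avg = if (length(vals)) mean(vals) else NA_real_,
      sd = if (length(vals) > 1) stats::sd(vals) else NA_real_
    )
  })
  dplyr::bind_rows(rows)
}

#' Write a per-rank report as TSV
#'
#' Accuracies are printed as percentages with two decimals; missing entries
#' (ranks with no usable classes) as `-`.
#'
#' @param report Tibble from [per_rank_report()].
#' @param path Output path.
#' @return `report`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  out <- report
  for (col in setdiff(names(out), "rank")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "-",
                         sprintf("%.2f", 100 * out[[col]]))
  }
  names(out)[1] <- "level"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(report)
}
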