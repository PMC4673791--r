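# A literal is a condition on one k-mer's value: membership in a union of
# half-open intervals [lo, hi) (lo may be -Inf, hi +Inf).  Learned rules
# always use a single interval; the union form exists so that published
# rules containing a disjunction on one word parse to a single rule.
new_literal <- function(kmer, lo, hi) {
  stopifnot(length(lo) == length(hi), all(lo < hi))
  list(kmer = kmer, lo = as.numeric(lo), hi = as.numeric(hi))
}

literal_matches <- function(literal, values) {
  v <- values[[literal$kmer]]
  if (is.null(v) || all(is.na(v))) {
    abort_validation(paste0("feature vector lacks k-mer '", literal$kmer, "'"))
  }
  out <- rep(FALSE, length(v))
  for (j in seq_along(literal$lo)) {
    out <- out | (v >= literal$lo[j] & v < literal$hi[j])
  }
  out
}

new_rule <- function(literals, conclusion, coverage = c(p = NA_real_, n = NA_real_)) {
  list(literals = literals, conclusion = conclusion, coverage = coverage)
}

# TRUE for each row of `values` (matrix samples x features, or named vector)
# matched by the conjunction of the rule's literals.
rule_matches <- function(rule, values) {
  if (is.null(dim(values))) values <- t(as.matrix(values))
  out <- rep(TRUE, nrow(values))
  for (lit in rule$literals) {
    v <- values[, lit$kmer]
    m <- rep(FALSE, length(v))
    for (j in seq_along(lit$lo)) {
      m <- m | (v >= lit$lo[j] & v < lit$hi[j])
    }
    out <- out & m
  }
  out
}

new_rule_model <- function(rules, default_class, rank, learner, k,
                           params = list(), seed = NA_integer_) {
  structure(
    list(rules = rules, default_class = default_class, rank = rank,
         learner = learner, k = k, params = params, seed = seed),
    class = "rule_model"
  )
}

#' Predict taxa from a rule model
#'
#' A rule model is an ordered decision list: the prediction is the
#' conclusion of the first rule whose conditions all hold, and the default
#' class when no rule matches.  Deterministic.
#'
#' @param object A `rule_model`.
#' @param newdata A `kmer_matrix`, a samples-by-features numeric matrix with
#'   k-mer column names, or a single named numeric vector.
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.rule_model <- function(object, newdata, ...) {
  values <- as_sample_matrix(newdata)
  needed <- unique(unlist(lapply(object$rules, function(r)
    vapply(r$literals, `[[`, character(1), "kmer"))))
  absent <- setdiff(needed, colnames(values))
  if (length(absent) > 0) {
    abort_validation(paste0(
      "feature vector lacks k-mer(s): ", paste(absent, collapse = ", ")
    ))
  }
  out <- rep(object$default_class, nrow(values))
  decided <- rep(FALSE, nrow(values))
  for (rule in object$rules) {
    if (all(decided)) break
    m <- rule_matches(rule, values) & !decided
    out[m] <- rule$conclusion
    decided <- decided | m
  }
  out
}

# samples x features numeric matrix from the accepted newdata forms
as_sample_matrix <- function(newdata) {
  if (inherits(newdata, "kmer_matrix")) {
    t(newdata$values)
  } else if (is.matrix(newdata)) {
    newdata
  } else if (is.numeric(newdata) && !is.null(names(newdata))) {
    t(as.matrix(newdata))
  } else {
    abort_param("newdata must be a kmer_matrix, matrix, or named vector")
  }
}

#' Complexity statistics of a rule model
#'
#' @param model A `rule_model`.
#' @return Tibble with `n_rules` (default rule excluded),
#'   `mean_literals_per_rule` (0 for a default-only model), and
#'   `n_distinct_kmers` (unique words used across all literals).
#' @export
model_complexity <- function(model) {
  stopifnot(inherits(model, "rule_model"))
  n_rules <- length(model$rules)
  lits <- unlist(lapply(model$rules, function(r)
    vapply(r$literals, `[[`, character(1), "kmer")))
  tibble(
    n_rules = n_rules,
    mean_literals_per_rule = if (n_rules == 0) 0 else length(lits) / n_rules,
    n_distinct_kmers = length(unique(lits))
  )
}

#' @export
print.rule_model <- function(x, scale = 1e5, ...) {
  cat("<rule_model> ", x$learner, " | rank = ", x$rank, " | ",
      length(x$rules), " rule(s) + default\n", sep = "")
  cat(format_rules(x, scale = scale), sep = "\n")
  invisible(x)
}

#' Render a rule model as human-readable text
#'
#' Frequencies are multiplied by `scale` (default `1e5`) for readability,
#' mirroring the conventional display of tetranucleotide frequencies.
#'
#' @param model A `rule_model`.
#' @param scale Display multiplier applied to interval bounds.
#' @return Character vector, one line per rule plus the default.
#' @export
format_rules <- function(model, scale = 1e5) {
  fmt <- function(v) trimws(formatC(v * scale, format = "fg", digits = 6))
  lines <- vapply(model$rules, function(r) {
    conds <- vapply(r$literals, function(l) {
      pieces <- vapply(seq_along(l$lo), function(j) {
        lo <- l$lo[j]; hi <- l$hi[j]
        if (is.infinite(lo) && is.infinite(hi)) {
          paste0("f(", l$kmer, ") any")
        } else if (is.infinite(lo)) {
          paste0("f(", l$kmer, ")<", fmt(hi))
        } else if (is.infinite(hi)) {
          paste0("f(", l$kmer, ")>=", fmt(lo))
        } else {
          paste0(fmt(lo), "<=f(", l$kmer, ")<", fmt(hi))
        }
      }, character(1))
      if (length(pieces) > 1) {
        paste0("(", paste(pieces, collapse = " | "), ")")
      } else {
        pieces
      }
    }, character(1))
    paste0("if ", paste(conds, collapse = " & "), " then ", r$conclusion)
  }, character(1))
  c(lines, paste0("else ", model$default_class))
}

#' Parse rules from text
#'
#' Reads decision-list rules in the textual form produced by
#' [format_rules()] or stored as a two-column TSV (`class<TAB>condition`).
#' Conditions are conjunctions joined by `&` of per-word interval tests:
#' `a<=f(W)<b`, `f(W)>=a`, `f(W)<b`, `f(W)>a`, `f(W)<=b`; a parenthesised
#' disjunction of tests on the *same* word, joined by `|`, parses to one
#' literal holding the union of the intervals.
#'
#' @param lines Character vector of rule lines (`if ... then CLASS`, or
#'   `CLASS\tcondition`).
#' @param scale Divisor applied to parsed bounds (use `1e5` when the text
#'   displays frequencies multiplied by `1e5`).
#' @param default_class Default class for the resulting model.
#' @param rank Rank annotation for the model.
#' @param k Word length (inferred from the first word when `NULL`).
#' @return A `rule_model`.
#' @export
parse_rules <- function(lines, scale = 1, default_class = "other",
                        rank = "species", k = NULL) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rules <- list()
  for (line in lines) {
    if (startsWith(line, "else ")) {
      default_class <- trimws(sub("^else ", "", line))
      next
    }
    if (grepl("^if ", line) && grepl(" then ", line)) {
      cond <- sub("^if ", "", sub(" then .*$", "", line))
      cls <- trimws(sub("^.* then ", "", line))
    } else if (grepl("\t", line, fixed = TRUE)) {
      parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(parts) != 2) abort_format(paste0("cannot parse rule: ", line))
      cls <- trimws(parts[1])
      cond <- parts[2]
    } else {
      abort_format(paste0("cannot parse rule: ", line))
    }
    rules[[length(rules) + 1]] <- new_rule(parse_conjunction(cond, scale), cls)
  }
  if (is.null(k)) {
    km <- unlist(lapply(rules, function(r)
      vapply(r$literals, `[[`, character(1), "kmer")))
    k <- if (length(km) > 0) nchar(km[1]) else NA_integer_
  }
  new_rule_model(rules, default_class, rank, learner = "parsed", k = k)
}

parse_conjunction <- function(cond, scale) {
  cond <- gsub("∧", "&", cond)   # accept logical-and glyphs
  cond <- gsub("∨", "|", cond)
  # split on & at paren depth 0
  parts <- split_top_level(cond, "&")
  lapply(parts, function(term) parse_literal_term(trimws(term), scale))
}

split_top_level <- function(x, sep) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  depth <- 0
  breaks <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1
    if (chars[i] == ")") depth <- depth - 1
    if (chars[i] == sep && depth == 0) breaks <- c(breaks, i)
  }
  starts <- c(1, breaks + 1)
  ends <- c(breaks - 1, length(chars))
  vapply(seq_along(starts), function(j)
    paste(chars[starts[j]:ends[j]], collapse = ""), character(1))
}

parse_literal_term <- function(term, scale) {
  if (startsWith(term, "(") && endsWith(term, ")")) {
    inner <- substr(term, 2, nchar(term) - 1)
    pieces <- lapply(split_top_level(inner, "|"), function(p)
      parse_single_test(trimws(p), scale))
    kmers <- vapply(pieces, `[[`, character(1), "kmer")
    if (length(unique(kmers)) != 1) {
      abort_format("disjunction within a rule must test a single k-mer")
    }
    ord <- order(vapply(pieces, function(p) p$lo, numeric(1)))
    new_literal(kmers[1],
                lo = vapply(pieces[ord], function(p) p$lo, numeric(1)),
                hi = vapply(pieces[ord], function(p) p$hi, numeric(1)))
  } else {
    with(parse_single_test(term, scale), new_literal(kmer, lo, hi))
  }
}

parse_single_test <- function(term, scale) {
  num <- "[0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?"
  fx <- "f\\(([ACGT]+)\\)"
  m <- regmatches(term, regexec(paste0("^(", num, ")<=", fx, "<(", num, ")$"), term))[[1]]
  if (length(m)) {
    return(list(kmer = m[3], lo = as.numeric(m[2]) / scale,
                hi = as.numeric(m[4]) / scale))
  }
  m <- regmatches(term, regexec(paste0("^", fx, ">=(", num, ")$"), term))[[1]]
  if (length(m)) return(list(kmer = m[2], lo = as.numeric(m[3]) / scale, hi = Inf))
  m <- regmatches(term, regexec(paste0("^", fx, ">(", num, ")$"), term))[[1]]
  if (length(m)) return(list(kmer = m[2], lo = as.numeric(m[3]) / scale, hi = Inf))
  m <- regmatches(term, regexec(paste0("^", fx, "<=(", num, ")$"), term))[[1]]
  if (length(m)) return(list(kmer = m[2], lo = -Inf, hi = as.numeric(m[3]) / scale))
  m <- regmatches(term, regexec(paste0("^", fx, "<(", num, ")$"), term))[[1]]
  if (length(m)) return(list(kmer = m[2], lo = -Inf, hi = as.numeric(m[3]) / scale))
  abort_format(paste0("cannot parse condition: ", term))
}

#' Read rules from a file
#'
#' @param path Path to a rule file in one of the formats of [parse_rules()].
#' @inheritParams parse_rules
#' @return A `rule_model`.
#' @export
read_rules <- function(path, scale = 1, default_class = "other",
                       rank = "species") {
  parse_rules(readLines(path), scale = scale, default_class = default_class,
              rank = rank)
}

#' Serialize a rule model to JSON
#'
#' @param model A `rule_model`.
#' @param path Output path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_rules_json <- function(model, path = NULL) {
  obj <- list(
    learner = model$learner,
    rank = model$rank,
    k = model$k,
    seed = model$seed,
    params = model$params,
    default = model$default_class,
    rules = lapply(model$rules, function(r) {
      list(
        literals = lapply(r$literals, function(l)
          list(kmer = l$kmer, lo = l$lo, hi = l$hi)),
        class = r$conclusion,
        coverage = list(p = unname(r$coverage["p"]), n = unname(r$coverage["n"]))
      )
    })
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(as.character(json))
}

#' @rdname write_rules_json
#' @export
read_rules_json <- function(path) {
  obj <- jsonlite::read_json(path)
  rules <- lapply(obj$rules, function(r) {
    lits <- lapply(r$literals, function(l) {
      new_literal(l$kmer,
                  lo = vapply(if (is.list(l$lo)) l$lo else list(l$lo),
                              null_to_inf, numeric(1), -1),
                  hi = vapply(if (is.list(l$hi)) l$hi else list(l$hi),
                              null_to_inf, numeric(1), 1))
    })
    cov <- c(p = null_to_na(r$coverage$p), n = null_to_na(r$coverage$n))
    new_rule(lits, r$class, cov)
  })
  new_rule_model(rules, obj$default, obj$rank, obj$learner, obj$k,
                 params = obj$params,
                 seed = null_to_na(obj$seed))
}

# jsonlite renders Inf/-Inf/NA as the strings "Inf", "-Inf", "NA"
null_to_inf <- function(x, sign) {
  if (is.null(x)) return(sign * Inf)
  if (is.character(x)) {
    return(switch(x, "Inf" = Inf, "-Inf" = -Inf, sign * Inf))
  }
  as.numeric(x)
}

null_to_na <- function(x) {
  if (is.null(x) || identical(x, "NA")) NA_real_ else as.numeric(x)
}

#' @exportS3Method generics::tidy
tidy.rule_model <- function(x, ...) {
  if (length(x$rules) == 0) {
    return(tibble(rule = integer(0), conclusion = character(0),
                  kmer = character(0), lo = numeric(0), hi = numeric(0),
                  pos_covered = numeric(0), neg_covered = numeric(0)))
  }
  purrr::map_dfr(seq_along(x$rules), function(i) {
    r <- x$rules[[i]]
    if (length(r$literals) == 0) {
      return(tibble(rule = i, conclusion = r$conclusion,
                    kmer = NA_character_, lo = -Inf, hi = Inf,
                    pos_covered = unname(r$coverage["p"]),
                    neg_covered = unname(r$coverage["n"])))
    }
    purrr::map_dfr(r$literals, function(l) {
      tibble(rule = i, conclusion = r$conclusion, kmer = l$kmer,
             lo = l$lo, hi = l$hi,
             pos_covered = unname(r$coverage["p"]),
             neg_covered = unname(r$coverage["n"]))
    })
  })
}

#' @exportS3Method generics::glance
glance.rule_model <- function(x, ...) {
  dplyr::bind_cols(
    tibble(learner = x$learner, rank = x$rank, k = x$k,
           default_class = x$default_class),
    model_complexity(x)
  )
}
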