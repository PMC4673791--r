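published_rules <- function() {
  path <- system.file("extdata", "bacteria_species_rules.tsv",
                      package = "kmerules")
  read_rules(path, scale = 1e5, default_class = "other")
}

test_that("rule text parsing handles all interval forms and disjunctions", {
  m <- parse_rules(c(
    "X\tf(ACGT)>=0.5",
    "Y\t0.1<=f(GGCT)<0.2 & f(ACGT)<0.5",
    "Z\t(f(AAAA)<0.1 | f(AAAA)>=0.9) & f(TTTT)<0.4"
  ))
  expect_equal(length(m$rules), 3L)
  expect_equal(m$rules[[3]]$literals[[1]]$lo, c(-Inf, 0.9))
  expect_equal(m$rules[[3]]$literals[[1]]$hi, c(0.1, Inf))
  # prediction walks the ordered list
  v <- c(ACGT = 0.6, GGCT = 0.15, AAAA = 0.95, TTTT = 0.1)
  expect_equal(predict(m, v), "X")
  v["ACGT"] <- 0.2
  expect_equal(predict(m, v), "Y")
  v["GGCT"] <- 0.5
  expect_equal(predict(m, v), "Z")
  v["AAAA"] <- 0.5
  expect_equal(predict(m, v), "other")
})

test_that("prediction is first-match, default on no match, strict on features", {
  m <- parse_rules(c("A\tf(AC)>=0.5", "B\tf(AC)>=0.2"))
  expect_equal(predict(m, c(AC = 0.7)), "A")
  expect_equal(predict(m, c(AC = 0.3)), "B")
  expect_equal(predict(m, c(AC = 0.1)), "other")
  expect_error(predict(m, c(GG = 0.5)), class = "kmerules_validation_error")
  empty <- parse_rules(character(0), default_class = "fallback")
  expect_equal(predict(empty, c(AC = 1)), "fallback")
})

test_that("the published 25-species decision list parses faithfully", {
  m <- published_rules()
  cx <- model_complexity(m)
  expect_equal(cx$n_rules, 25L)
  # the printed sample of rules uses 14 distinct tetranucleotides
  expect_equal(cx$n_distinct_kmers, 14L)
  # most rules are conjunctions of conditions on just two 4-mers
  expect_lte(cx$mean_literals_per_rule, 2.1)
  n_two_or_fewer <- sum(vapply(m$rules, function(r)
    length(r$literals) <= 2, logical(1)))
  expect_gte(n_two_or_fewer / 25, 0.9)
})

test_that("interval membership honours the half-open convention (x1e5 scale)", {
  m <- published_rules()
  hp <- Filter(function(r) r$conclusion == "H. pylori", m$rules)[[1]]
  single <- new_rule_model(list(hp), "other", "species", "parsed", 4)
  base <- setNames(rep(0, 256), all_kmers(4))
  v <- base; v["GTAC"] <- 20e-5
  expect_equal(predict(single, v), "H. pylori")
  v["GTAC"] <- 42.82e-5
  expect_equal(predict(single, v), "other")
  v["GTAC"] <- 5.56e-5   # lower bound included
  expect_equal(predict(single, v), "H. pylori")
})

test_that("model complexity counts rules, literals, distinct words", {
  m0 <- new_rule_model(list(), "d", "species", "test", 4)
  expect_equal(unlist(model_complexity(m0)), c(n_rules = 0,
                                               mean_literals_per_rule = 0,
                                               n_distinct_kmers = 0))
  m2 <- parse_rules(c("A\tf(ACGT)>=0.5",
                      "B\t0.1<=f(ACGT)<0.3 & f(GGCT)<0.2 & f(TTAA)>=0.1"))
  cx <- model_complexity(m2)
  expect_equal(cx$n_rules, 2L)
  expect_equal(cx$mean_literals_per_rule, 2)
  expect_equal(cx$n_distinct_kmers, 3L)
})

test_that("format/parse and JSON round trips preserve the decision list", {
  m <- published_rules()
  # text round trip at the display scale
  txt <- format_rules(m, scale = 1e5)
  m2 <- parse_rules(txt, scale = 1e5)
  expect_equal(m2$default_class, m$default_class)
  json <- tempfile(fileext = ".json")
  write_rules_json(m, json)
  m3 <- read_rules_json(json)
  expect_equal(length(m3$rules), length(m$rules))
  # predictions agree on random vectors for all three representations
  withr::with_seed(77, {
    base <- setNames(rep(0, 256), all_kmers(4))
    for (i in 1:25) {
      v <- base
      v[sample(names(v), 30)] <- stats::runif(30, 0, 1.3e-2)
      p <- predict(m, v)
      expect_equal(predict(m2, v), p)
      expect_equal(predict(m3, v), p)
    }
  })
})

test_that("tidy and glance expose the decision list as tibbles", {
  m <- published_rules()
  td <- tidy(m)
  expect_true(all(c("rule", "conclusion", "kmer", "lo", "hi") %in% names(td)))
  expect_equal(length(unique(td$rule)), 25L)
  gl <- glance(m)
  expect_equal(gl$n_rules, 25L)
  expect_equal(gl$default_class, "other")
})
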