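#' Specification of a synthetic benchmark
#'
#' Describes a nested taxonomy (branching per rank, phylum down to species)
#' and how taxon-specific k-mer signatures are planted into i.i.d.
#' background genomes.  Each taxon at each rank gets
#' `n_signatures_per_taxon` signature words; every genome of that taxon
#' carries them at a target frequency of `bias` times the background
#' expectation (capped at 0.05).  Signature words are globally unique and
#' no word is the reverse complement of another taxon's word, so that
#' strand-symmetric counting keeps ground truth unambiguous.
#'
#' @param taxa_per_level Named integer branching factors per rank, highest
#'   rank first.  The default gives 2 phyla, one class/order/genus lineage
#'   each, and 2 species per genus (4 species total).
#' @param genomes_per_species Genomes simulated per species (default 10,
#'   honouring the rare-class filter's 9-specimen minimum).
#' @param genome_length Background genome length in bases (default 50000).
#' @param k_sig Signature word length (default 4).
#' @param n_signatures_per_taxon Signature words per taxon (default 2).
#' @param bias Target multiplicative enrichment of each signature word's
#'   frequency over its background expectation (default 5).
#' @param background Base composition, a probability vector over A, C, G, T
#'   (default uniform).
#' @param seed Integer seed (default 1).
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(taxa_per_level = c(phylum = 2, class = 1, order = 1,
                                        genus = 1, species = 2),
                     genomes_per_species = 10, genome_length = 50000,
                     k_sig = 4, n_signatures_per_taxon = 2, bias = 5,
                     background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                     seed = 1L) {
  ranks <- rev(TAX_RANKS)  # phylum ... species
  if (is.null(names(taxa_per_level))) names(taxa_per_level) <- ranks
  if (!all(ranks %in% names(taxa_per_level))) {
    abort_param("taxa_per_level must name all five ranks")
  }
  if (any(taxa_per_level < 1)) abort_param("branching factors must be >= 1")
  if (genomes_per_species < 1) abort_param("genomes_per_species must be >= 1")
  if (bias < 0) abort_param("bias must be >= 0")
  background <- background / sum(background)
  structure(
    list(taxa_per_level = taxa_per_level[ranks],
         genomes_per_species = as.integer(genomes_per_species),
         genome_length = as.integer(genome_length),
         k_sig = as.integer(k_sig),
         n_signatures_per_taxon = as.integer(n_signatures_per_taxon),
         bias = bias, background = background, seed = as.integer(seed)),
    class = "sim_spec"
  )
}

# Background expectation of a word under the i.i.d. base composition.
word_expectation <- function(word, background) {
  prod(background[strsplit(word, "", fixed = TRUE)[[1]]])
}

#' Simulate a nested taxonomy with planted signatures
#'
#' @param spec A [sim_spec()].
#' @return List with `lineages` (tibble: one row per species lineage,
#'   columns `species` ... `phylum`) and `signatures` (tibble: `rank`,
#'   `taxon`, `kmer`, `target_frequency`).  Deterministic in `spec$seed`.
#' @export
simulate_taxonomy <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  ranks <- names(spec$taxa_per_level)  # phylum ... species
  withr::with_seed(spec$seed, {
    lineages <- tibble(phylum = paste0("p", seq_len(spec$taxa_per_level["phylum"])))
    short <- c(phylum = "p", class = "c", order = "o", genus = "g",
               species = "s")
    for (i in seq_along(ranks)[-1]) {
      r <- ranks[i]
      b <- spec$taxa_per_level[r]
      lineages <- tidyr::expand_grid(lineages, .branch = seq_len(b))
      lineages[[r]] <- paste0(lineages[[ranks[i - 1]]], "_", short[r],
                              lineages$.branch)
      lineages$.branch <- NULL
    }
    taxa <- dplyr::bind_rows(lapply(ranks, function(r)
      tibble(rank = r, taxon = unique(lineages[[r]]))))
    n_needed <- nrow(taxa) * spec$n_signatures_per_taxon
    pool <- all_kmers(spec$k_sig)
    sig_list <- character(0)
    available <- pool
    draws <- character(n_needed)
    for (j in seq_len(n_needed)) {
      if (length(available) == 0) {
        abort_param("not enough distinct k-mers for the requested signatures")
      }
      w <- sample(available, 1)
      draws[j] <- w
      available <- setdiff(available, c(w, revcomp(w)))
    }
    signatures <- tidyr::expand_grid(taxa,
                                     .s = seq_len(spec$n_signatures_per_taxon))
    signatures$kmer <- draws
    signatures$.s <- NULL
    signatures$target_frequency <- pmin(
      spec$bias * vapply(signatures$kmer, word_expectation, numeric(1),
                         background = spec$background),
      0.05
    )
    # per-genome planted mass: a lineage crosses each rank once, so sum the
    # worst-case per-taxon signature frequency at each rank
    per_genome <- signatures |>
      dplyr::group_by(.data$rank) |>
      dplyr::summarise(m = max(tapply(.data$target_frequency, .data$taxon, sum)))
    if (sum(per_genome$m) > 0.30) {
      abort_param(paste0(
        "planted signature mass ", sprintf("%.2f", sum(per_genome$m)),
        " exceeds 30% of window frequency; lower bias or n_signatures"
      ))
    }
    list(lineages = lineages[, TAX_RANKS], signatures = signatures)
  })
}

#' Simulate one genome for a lineage
#'
#' Draws an i.i.d. background sequence from the base composition, then for
#' each rank of the lineage overwrites non-overlapping slots (on a
#' `k_sig`-aligned grid, uniformly sampled) with copies of that taxon's
#' signature words until each word's planted count plus its expected
#' background count reaches the target frequency.
#'
#' @param lineage One row of `simulate_taxonomy()$lineages` (or a named
#'   list/character with entries for each rank).
#' @param spec A [sim_spec()].
#' @param signatures The signature tibble from [simulate_taxonomy()].
#' @param seed Integer seed for this genome.
#' @return A one-row genome tibble (`id`, `sequence`, rank columns).
#' @export
simulate_genome <- function(lineage, spec, signatures, seed = 1L) {
  stopifnot(inherits(spec, "sim_spec"))
  lineage <- as.list(lineage)
  n <- spec$genome_length
  k <- spec$k_sig
  withr::with_seed(seed, {
    bases <- names(spec$background)
    seqv <- sample(bases, n, replace = TRUE, prob = spec$background)
    sig <- signatures[signatures$taxon %in% unlist(lineage[TAX_RANKS]), ,
                      drop = FALSE]
    if (nrow(sig) > 0) {
      windows <- n - k + 1
      planted <- vapply(seq_len(nrow(sig)), function(i) {
        expected_bg <- word_expectation(sig$kmer[i], spec$background) * windows
        max(0L, as.integer(round(sig$target_frequency[i] * windows -
                                   expected_bg)))
      }, integer(1))
      total <- sum(planted)
      n_slots <- n %/% k
      if (total > n_slots) {
        abort_param("planted signature copies exceed available genome slots")
      }
      if (total > 0) {
        slots <- sample.int(n_slots, total)
        word_of_slot <- rep(seq_len(nrow(sig)), planted)
        for (j in seq_along(slots)) {
          pos <- (slots[j] - 1L) * k + 1L
          seqv[pos:(pos + k - 1L)] <-
            strsplit(sig$kmer[word_of_slot[j]], "", fixed = TRUE)[[1]]
        }
      }
    }
    out <- tibble(id = NA_character_, sequence = paste(seqv, collapse = ""))
    for (r in TAX_RANKS) out[[r]] <- lineage[[r]] %||% NA_character_
    out
  })
}

#' Simulate a full labeled genome set
#'
#' Runs [simulate_taxonomy()] and [simulate_genome()] for every species and
#' replicate.  Everything is a deterministic function of `spec` (identical
#' seeds give identical sequences).
#'
#' @param spec A [sim_spec()].
#' @return List with `genomes` (tibble ready for [kmer_matrix()]),
#'   `signatures`, and `lineages`.
#' @export
simulate_genomes <- function(spec = sim_spec()) {
  tax <- simulate_taxonomy(spec)
  rows <- vector("list", nrow(tax$lineages) * spec$genomes_per_species)
  idx <- 1L
  for (i in seq_len(nrow(tax$lineages))) {
    for (rep in seq_len(spec$genomes_per_species)) {
      g <- simulate_genome(tax$lineages[i, ], spec, tax$signatures,
                           seed = genome_seed(spec$seed, i, rep))
      g$id <- paste0(tax$lineages$species[i], "_g", rep)
      rows[[idx]] <- g
      idx <- idx + 1L
    }
  }
  list(genomes = dplyr::bind_rows(rows), signatures = tax$signatures,
       lineages = tax$lineages)
}

# Deterministic per-genome sub-seed, kept within 32-bit integer range.
genome_seed <- function(seed, lineage_idx, rep) {
  as.integer((seed * 7919L + lineage_idx * 613L + rep * 31L) %% 2147483630L) + 1L
}

#' Full benchmark: simulated genomes plus their feature matrix
#'
#' @param spec A [sim_spec()].
#' @param k Word length for the feature matrix (default `spec$k_sig`).
#' @param ... Passed to [kmer_matrix()].
#' @return List with `matrix` (a `kmer_matrix`), `genomes`, `signatures`,
#'   `lineages`.
#' @export
benchmark_suite <- function(spec = sim_spec(), k = spec$k_sig, ...) {
  sim <- simulate_genomes(spec)
  sim$matrix <- kmer_matrix(sim$genomes, k = k, ...)
  sim
}

#' Fraction of rule literals that hit planted signatures
#'
#' A literal counts as recovered when its k-mer (or the k-mer's reverse
#' complement) is a planted signature of any taxon on the lineage of the
#' rule's concluded class.
#'
#' @param model A `rule_model` whose conclusions are taxa of the simulated
#'   taxonomy.
#' @param signatures Signature tibble from the simulation.
#' @param lineages Lineage tibble from the simulation.
#' @return Fraction in `[0, 1]`; `NA` for a default-only model.
#' @export
recovery_score <- function(model, signatures, lineages) {
  stopifnot(inherits(model, "rule_model"))
  if (length(model$rules) == 0) return(NA_real_)
  hits <- 0L
  total <- 0L
  for (r in model$rules) {
    lineage_rows <- lineages[
      apply(lineages, 1, function(row) model_conclusion_in(r$conclusion, row)),
      , drop = FALSE]
    taxa <- unique(unlist(lineage_rows))
    sigs <- signatures$kmer[signatures$taxon %in% taxa]
    sigs <- unique(c(sigs, revcomp(sigs)))
    for (l in r$literals) {
      total <- total + 1L
      if (l$kmer %in% sigs) hits <- hits + 1L
    }
  }
  hits / total
}

model_conclusion_in <- function(conclusion, lineage_row) {
  conclusion %in% unlist(lineage_row)
}
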