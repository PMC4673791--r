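#' Read genomes from a multi-FASTA file
#'
#' Reads one genome per FASTA record into a tibble, normalising sequences to
#' the alphabet `{A, C, G, T, N}`: letters are uppercased and every non-ACGT
#' character (ambiguity codes, gaps, ...) becomes `N`.  Downstream k-mer
#' counting treats `N` as an invalid position, so a single sentinel suffices.
#'
#' @param path Path to a FASTA file.
#' @param taxonomy Optional taxonomy table: either a path to a tab-separated
#'   file with header `id<TAB>species<TAB>genus<TAB>order<TAB>class<TAB>phylum`
#'   (empty cells allowed) or a data frame with those columns.  Records
#'   without a taxonomy entry get `NA` at every rank.
#' @return A tibble with columns `id`, `sequence`, and one column per
#'   taxonomic rank (`species`, `genus`, `order`, `class`, `phylum`).
#' @export
read_genomes <- function(path, taxonomy = NULL) {
  if (!file.exists(path)) {
    abort_format(paste0("FASTA file not found: ", path))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      abort_format(paste0("malformed FASTA in '", path, "': ", conditionMessage(e)))
    }
  )
  if (length(set) == 0) {
    abort_format(paste0("no FASTA records in '", path, "'"))
  }
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) {
    abort_validation("FASTA record with empty identifier")
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort_validation(paste0(
      "duplicate sequence id(s): ", paste(dup, collapse = ", ")
    ))
  }
  genomes <- tibble(
    id = ids,
    sequence = unname(normalize_sequence(as.character(set)))
  )
  attach_taxonomy(genomes, taxonomy)
}

normalize_sequence <- function(x) {
  x <- toupper(x)
  gsub("[^ACGT]", "N", x)
}

#' Read a taxonomy table
#'
#' @param path Path to a tab-separated file with header
#'   `id`, `species`, `genus`, `order`, `class`, `phylum`.
#' @return A tibble with those columns; empty cells become `NA`.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) {
    abort_format(paste0("taxonomy file not found: ", path))
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("", "NA"))
  missing <- setdiff(c("id", TAX_RANKS), names(tab))
  if (length(missing) > 0) {
    abort_format(paste0(
      "taxonomy table lacks column(s): ", paste(missing, collapse = ", ")
    ))
  }
  as_tibble(tab[, c("id", TAX_RANKS)])
}

attach_taxonomy <- function(genomes, taxonomy) {
  if (is.null(taxonomy)) {
    for (r in TAX_RANKS) genomes[[r]] <- NA_character_
    return(genomes)
  }
  if (is.character(taxonomy) && length(taxonomy) == 1) {
    taxonomy <- read_taxonomy(taxonomy)
  }
  taxonomy <- as_tibble(taxonomy)
  missing <- setdiff(c("id", TAX_RANKS), names(taxonomy))
  if (length(missing) > 0) {
    abort_format(paste0(
      "taxonomy lacks column(s): ", paste(missing, collapse = ", ")
    ))
  }
  if (anyDuplicated(taxonomy$id)) {
    abort_validation("duplicate ids in taxonomy table")
  }
  dplyr::left_join(genomes, taxonomy[, c("id", TAX_RANKS)], by = "id")
}

#' Write genomes to FASTA (and optionally a taxonomy TSV)
#'
#' @param genomes A genome tibble as returned by [read_genomes()] or
#'   [simulate_genomes()].
#' @param path Output FASTA path.
#' @param taxonomy_path Optional path for a companion taxonomy TSV.
#' @param width Line width for sequence wrapping.
#' @return `genomes`, invisibly.
#' @export
write_genomes <- function(genomes, path, taxonomy_path = NULL, width = 70L) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(genomes))) {
    writeLines(paste0(">", genomes$id[i]), con)
    seq <- genomes$sequence[i]
    starts <- seq(1L, nchar(seq), by = width)
    writeLines(substring(seq, starts, pmin(starts + width - 1L, nchar(seq))), con)
  }
  if (!is.null(taxonomy_path)) {
    tax <- genomes[, c("id", intersect(TAX_RANKS, names(genomes)))]
    utils::write.table(tax, taxonomy_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  invisible(genomes)
}

#' Reverse complement of nucleotide sequences
#'
#' Vectorised over `x`.  `N` is its own complement; any character outside
#' `{A, C, G, T, N}` is an error.  Applying the function twice returns the
#' input (involution).
#'
#' @param x Character vector of sequences over `{A, C, G, T, N}`.
#' @return Character vector of reversed complements.
#' @export
revcomp <- function(x) {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    abort_validation(paste0(
      "sequence contains characters outside {A,C,G,T,N}: ",
      substr(x[bad][1], 1, 40)
    ))
  }
  vapply(x, function(s) {
    if (nchar(s) == 0) return("")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Mask low-complexity regions (DUST-style)
#'
#' Scores every window of length `window` (shorter at the tail, minimum 4) by
#' triplet over-representation: with `c_t` the counts of the `m = L - 2`
#' overlapping triplets in the window, the score is
#' `sum(c_t * (c_t - 1) / 2) / (m - 1)`.  Windows scoring above `threshold`
#' are masked to `N`.  Scores are computed on the input and all masks applied
#' afterwards, so the operation is idempotent and never changes the length.
#' Triplets containing `N` are ignored.
#'
#' @param x Character vector of sequences over `{A, C, G, T, N}`.
#' @param window Window length, at least 4 (default 64).
#' @param threshold Score above which a window is masked (default 2.0).
#' @return Sequences with masked positions set to `N`.
#' @export
dust_mask <- function(x, window = 64L, threshold = 2.0) {
  if (window < 4) {
    abort_param("dust_mask() requires window >= 4")
  }
  vapply(x, dust_mask_one, character(1), window = as.integer(window),
         threshold = threshold, USE.NAMES = FALSE)
}

dust_mask_one <- function(seq, window, threshold) {
  n <- nchar(seq)
  if (n < 4) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  code <- match(chars, c("A", "C", "G", "T")) - 1L  # NA for N
  # base-4 triplet codes at positions 1..n-2; NA when any base is N
  tri <- code[seq_len(n - 2L)] * 16L +
    code[seq_len(n - 2L) + 1L] * 4L +
    code[seq_len(n - 2L) + 2L] + 1L
  mask <- logical(n)
  counts <- integer(64)
  pairs <- 0           # running sum of c_t * (c_t - 1) / 2
  lo <- 1L             # current window = positions [lo, hi] of `tri`
  hi <- 0L
  for (start in seq_len(n)) {
    L <- min(window, n - start + 1L)
    if (L < 4L) break
    new_hi <- start + L - 3L  # last triplet index in window
    while (hi < new_hi) {
      hi <- hi + 1L
      tc <- tri[hi]
      if (!is.na(tc)) {
        pairs <- pairs + counts[tc]
        counts[tc] <- counts[tc] + 1L
      }
    }
    while (lo < start) {
      tc <- tri[lo]
      if (!is.na(tc)) {
        counts[tc] <- counts[tc] - 1L
        pairs <- pairs - counts[tc]
      }
      lo <- lo + 1L
    }
    m <- L - 2L
    if (pairs / (m - 1L) > threshold) {
      mask[start:(start + L - 1L)] <- TRUE
    }
  }
  if (!any(mask)) return(seq)
  chars[mask] <- "N"
  paste(chars, collapse = "")
}
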