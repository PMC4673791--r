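Package: kmerules
Title: Interpretable Rule-Based Classification of Genomes from k-mer
    Composition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Alignment-free taxonomic classification of whole genomes from
    the relative frequencies of short nucleotide words (k-mers).  Genomes
    are turned into 4^k-dimensional frequency vectors (optionally rescaled
    by Markov or single-nucleotide null-model expectations), discretized
    with supervised minimum-description-length binning, and classified
    with compact if-then decision lists learned by sequential-covering
    (RIPPER-style) or partial-tree (PART-style) rule induction.  Includes
    stratified cross-validation with per-rank accuracy reports, a
    low-complexity (DUST-style) masking filter, a planted-signature
    genome simulator for benchmarking, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
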