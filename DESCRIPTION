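Package: coagvar
Title: Variant Characterization for Coagulation Genes Interacting with
    SARS-CoV-2 Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Characterizes genetic variants of coagulation-related genes
    (VKORC1, SERPING1, PABPC4) whose products interact with SARS-CoV-2
    proteins.  Provides multiple sequence alignment conservation scoring
    with affinity-propagation deduplication on Levenshtein distances,
    relative synonymous codon (pair) usage and %MinMax profiles for coding
    variants, mRNA minimum-free-energy change estimation with Z-score
    normalization against a resampling null, splicing and miRNA
    change-aggregation rules for annotation tables, population allele
    frequency analytics including Hardy-Weinberg carrier probabilities,
    and synthetic-data generators with known ground truth for every input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
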