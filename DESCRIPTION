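Package: indelscope
Title: Somatic Indel Annotation, Germline Filtering and Cohort Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Comparative analysis of small insertions and deletions (indels)
    called in tumour cohorts. Normalizes VCF indel records to a minimal
    anchored representation, removes germline leakage by exact identity
    matching against a panel, measures cross-cohort sharing with a
    position-window match, classifies indels against a representative
    transcript into coding sequence and untranslated regions, calls
    frameshift/non-frameshift status, attributes affected protein residues to
    three-state secondary structure, computes overlap with predicted
    transcription factor binding sites, scores indel positions with per-base
    conservation tracks (insertion flanks, deletion spans), and builds cohort
    summary tables with chi-squared comparisons, gene rankings and
    hypergeometric gene-set enrichment. Includes a deterministic
    synthetic-cohort simulator with per-indel ground-truth labels for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    withr,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
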