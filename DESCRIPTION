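Package: pollenmotif
Title: Discovery of Cis-Regulatory Motifs Driving Pollen-Specific Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative promoter-analysis pipeline for identifying
    cis-regulatory motifs that explain pollen-specific expression of
    hydroxyproline-rich glycoprotein (HRGP) genes. Computes the Tau
    tissue-specificity index from multi-tissue RNA-seq expression, selects
    pollen-specific foreground and non-pollen background gene sets, performs
    discriminative de novo motif discovery (hypergeometric k-mer seeding
    followed by ZOOPS expectation-maximisation refinement), scans promoters
    with position weight matrices using exact dynamic-programming p-values,
    compares motifs to a known transcription-factor motif database with a
    column-correlation similarity statistic, tests cross-species promoter
    conservation by pairwise alignment, applies occurrence/conservation and
    known-TF filters, and models pollen expression from motif scan scores
    with gradient-boosted regression trees under cross-validation. A
    synthetic-data generator produces expression matrices, promoters with
    planted motif sites, mutated orthologous promoters, and known-motif
    databases with the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
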