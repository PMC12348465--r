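Package: calluscope
Title: Callus-Specific Promoter Discovery and Base-Editing Outcome Genotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering tissue-specific (callus-specific) candidate
    genes and promoters from bulk expression data, scanning promoter sequences
    for plant cis-regulatory elements with an IUPAC consensus catalog,
    genotyping CRISPR cytosine base-editing outcomes from amplicon read-count
    tables (mutation frequency, zygosity classification, cohort editing
    statistics), enumerating and ranking sgRNA off-target sites, and computing
    relative expression from RT-qPCR cycle thresholds. Includes seeded
    synthetic-data generators with ground-truth manifests so every stage of
    the pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
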