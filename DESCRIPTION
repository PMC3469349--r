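Package: gaclassify
Title: Discovery and Validation of Binary Gene Expression Classifiers of
    Chemical Exposure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering compact gene expression classifiers that
    separate chemically treated from control samples in multi-condition
    transcriptomic studies, and for validating them as gene sets on
    independent expression profiles. Implements genetic-algorithm feature
    subset search with support-vector-machine or k-nearest-neighbour fitness,
    run transcriptome-wide or restricted to transcription-factor networks;
    Fisher's discriminant ratio summaries of condition data complexity;
    candidate prioritisation by model union, cluster-bifurcation
    qualification, cross-condition deduplication and network-count ranking;
    gene set enrichment analysis with phenotype-permutation significance; and
    probe cross-mapping between two microarray designs by sequence identity,
    local alignment and coordinate proximity. A synthetic-data module
    generates two-class log-intensity studies with planted differential
    features, network structure and dual probe designs with recorded ground
    truth, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    limma,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
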