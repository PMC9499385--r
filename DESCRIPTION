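Package: plasmiR
Title: Anticoagulant Bias in Circulating Plasma miRNA Profiles
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of how the anticoagulant in blood
    collection tubes biases circulating plasma microRNA profiles measured
    by small RNA sequencing. Provides small-RNA read preprocessing
    (3' adapter trimming, randomized-base removal, length gating),
    miRNA/isomiR quantification against a hairpin-anchored mature
    reference, abundance and isoform filters with sample QC gates,
    diversity and principal-component profiling, spectrophotometric and
    miRNA-based hemolysis scoring, red-blood-cell versus platelet origin
    attribution, TMM-normalized blocked pairwise differential expression,
    and qPCR validation statistics including NormFinder reference-gene
    stability. A synthetic plasma-cohort generator with known ground
    truth (subject baselines, hemolysis contamination, isomiR variation,
    absorbances and Cq tables) makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    edgeR,
    vegan,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
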