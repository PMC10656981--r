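Package: rad2bm
Title: Species-Level Microbiome Profiling from Type IIB Restriction Tags
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements the 2b-RAD-M workflow for species-level microbiome
    quantification: in-silico digestion of microbial genomes with type IIB
    restriction enzymes (e.g. BcgI) into equal-length tags, construction of a
    species-specific marker database, read assignment with G-score screening
    of candidate species, and marker-normalized relative abundance. Includes
    the downstream ecology statistics used in case-control oral-microbiome
    studies (alpha diversity, Bray-Curtis/Jaccard/Euclidean beta diversity
    with PERMANOVA, rank-sum tests, shared-species counts, inter-kingdom
    Spearman correlation networks) and biomarker discovery (indicator-value
    analysis, a simplified LEfSe-style effect size, random-forest importance
    ranking, ROC/AUC), plus a synthetic-data module that generates genomes,
    tag reads, and two-group abundance studies with planted differential taxa
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    vegan,
    randomForest,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
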