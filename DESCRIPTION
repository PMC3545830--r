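Package: BerrySeq
Title: Developmental Transcriptome Analysis of Grape Berry RNA-Seq Time Courses
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing bulk RNA-Seq expression across the four
    Eichhorn-Lorenz stages of grape berry development (young berry, early
    veraison, late veraison, harvest-ripe). Implements RPKM quantification
    with proportional allocation of multi-mapped reads anchored on unique
    read counts, detection calls and abundance binning, floored fold-change
    classification of stage-specifically up-regulated transcripts (including
    joint veraison calls), scale-and-centre profile normalisation followed
    by k-means clustering with a run-stability criterion and archetype
    labelling, hypergeometric Gene Ontology enrichment with
    Benjamini-Hochberg control and aggregate group-significance scoring,
    and cross-platform comparison of RNA-Seq expression against microarray
    probeset intensities by Spearman rank correlation. A synthetic-data
    generator with known ground truth (planted expression archetypes,
    planted enriched GO terms, calibrated platform correlation) drives
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
biocViews: Transcriptomics, RNASeq, GeneExpression, Clustering,
    DifferentialExpression, GO
RoxygenNote: 7.3.3
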