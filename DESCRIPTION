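Package: acnesig
Title: Paired Transcriptomic Signatures of Acne Papule Resolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for paired multi-condition skin transcriptomics studies of
    acne papule resolution under topical treatment. Implements empirical-Bayes
    moderated paired t-tests with Benjamini-Hochberg correction, derivation of
    papule / vehicle / trifarotene contrast signatures with three-set Venn
    partitioning and treatment-reversal classification, average-linkage
    correlation-distance gene clustering, preranked gene-set enrichment with a
    gene-permutation null, and marker-panel cell-type scoring (including
    macrophage subclasses) with Wilcoxon rank-sum group comparisons. A
    synthetic-study generator emulating the paired 9-subject, 4-biopsy design
    with planted differential-expression structure provides ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    limma,
    SummarizedExperiment,
    S4Vectors,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'acnesig-package.R'
    'study.R'
    'celltype.R'
    'preprocess.R'
    'diffexpr.R'
    'enrichment.R'
    'io.R'
    'methods.R'
    'signatures.R'
    'simulate.R'
    'pipeline.R'
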