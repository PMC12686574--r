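Package: ageaccel
Title: Accelerated Ageing Signatures from Time-Course Brain RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting telomerase-dependent acceleration of
    transcriptomic ageing in a two-genotype, multi-age bulk RNA-seq design.
    Implements median-of-ratios normalisation and a negative-binomial Wald
    test for genotype-by-age contrasts, short time-series profile clustering
    with permutation significance, classification of old-age differentially
    expressed genes whose change occurs at an earlier age in a mutant than in
    sibling wild types, hypergeometric over-representation analysis against
    gene-set collections (including single-cell marker programmes and
    senescence-associated secretory phenotype sets), keyword-based mapping of
    Gene Ontology annotations to ageing transcriptomic hallmarks, and the
    bench-assay quantification formulas used alongside the transcriptomics
    (chitotriosidase activity, delta-delta-Ct fold change, telomere/centromere
    intensity ratio, percent-positive cells). A seeded synthetic-data module
    generates count matrices with planted gene classes and matching annotation
    fixtures so the whole pipeline can be exercised against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    fgsea,
    SummarizedExperiment
Config/testthat/edition: 3
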