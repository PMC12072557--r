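Package: paleogdh
Title: Ancient-Genome Coding-Sequence Analysis of Glutamate Dehydrogenase Genes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing and interpreting protein-coding gene
    evolution from high-coverage ancient human genomes, built around the
    glutamate dehydrogenase paralogs GLUD1 and GLUD2 and their pseudogenes.
    Provides strand-aware CDS extraction and consensus building from variant
    calls, deamination-aware classification of substitutions into the TS1
    (A>G/T>C) and TS2 (C>T/G>A) damage classes with expected-damage estimation
    from a control gene, HGVS-style protein consequence calling, Kimura
    2-parameter distances with neighbor-joining, bootstrap support, pruning
    likelihood and marginal maximum-likelihood ancestral reconstruction,
    affine-gap Smith-Waterman scanning of miRNA sink sites against
    reverse-complemented transcripts, Spearman correlation screens of gene and
    pseudogene expression across tissues, and a synthetic-data module that
    generates every pipeline input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    vcfR,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
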