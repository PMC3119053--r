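Package: piebaldnet
Title: Regulatory and Epistatic Network Analysis of Case-Control SNP and
    Two-Colour Microarray Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrated pipeline for dissecting a polygenic pigmentation
    phenotype (piebald spotting in Merino sheep) from three data types:
    SNP genotypes, two-colour microarray gene expression, and transcription
    factor binding site (TFBS) predictions. Provides identity-by-state
    allele-sharing computation with greedy matched-control selection,
    single-SNP allelic association with a dual significance rule
    (genotype-difference outliers plus chi-square), an exhaustive two-locus
    epistasis scan on 9x2 genotype contingency tables, EM-REML mixed-model
    normalization of a dye-swap loop-design microarray with seven
    differential-expression contrasts, SNP-to-nearest-gene annotation with
    cis/proximal/distal distance classes, and construction, hub reduction
    and intersection of TFBS-derived regulatory and epistasis-derived gene
    networks with Cytoscape-compatible export. A synthetic-data generator
    with planted association, epistasis, differential expression and TF
    membership signals makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    lme4,
    vcfR,
    withr,
    xml2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
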