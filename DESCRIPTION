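Package: svcrkit
Title: Sparse Variant Call Representation and Rare-Variant Association QC at Desk Scale
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for working with sparse cohort representations of gVCF data and the
    quality-control machinery of large exome association resources. Implements the
    Scalable Variant Call Representation (SVCR) with GQ-bin block compression,
    deterministic allele merging, hierarchical merging and on-the-fly densification;
    genotype-, variant- and sample-level QC rules (adj filtering, hard filters,
    random-forest variant classification, sex-karyotype imputation, MAD outlier
    detection, relatedness pruning); random-phenotype calibration of association
    tests with empirical significance thresholds, genomic-control lambda and
    expected-allele-count filtering; and frequency-matched gene-set enrichment with
    power calculations. A synthetic-cohort generator produces gVCFs with reference
    blocks and trios, sparse relatedness matrices, annotations and phenotypes so the
    full pipeline runs end-to-end on simulated data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    IRanges,
    S4Vectors,
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
Config/testthat/edition: 3
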