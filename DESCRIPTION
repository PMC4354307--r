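Package: tetraQK
Title: Dosage-Aware Q+K Association Mapping for Autotetraploid
    Candidate-Gene Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end candidate-gene association pipeline for
    autotetraploid crops such as potato. Calls allele dosage (0-4 copies)
    from microsatellite peak areas, bidirectional Sanger trace fractions
    and InDel band intensities; adjusts replicated field-trial phenotypes
    for spatial trend with an AR(1) x AR(1) residual REML model; estimates
    population structure by an expectation-maximisation admixture model
    with Evanno delta-K model selection and Loiselle pairwise kinship; and
    tests each marker allele with a Q+K mixed model on adjusted line
    means, reporting allele substitution effects, minor allele
    frequencies and Storey bootstrap q-values. A synthetic-data generator
    emulating a 193-line tetraploid panel makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
LinkingTo: Rcpp, RcppArmadillo
biocViews: Genetics, SNP, Microsatellite, GenomeWideAssociationStudy,
    StatisticalMethod, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'tetraQK-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'dosage-calling.R'
    'admixture.R'
    'field-layout.R'
    'spatial-reml.R'
    'kinship.R'
    'association.R'
    'evanno.R'
    'io-tsv.R'
    'qvalue.R'
    'vcf.R'
    'simconfig.R'
    'simulate.R'
    'pipeline.R'
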