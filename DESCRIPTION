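Package: stimqtl
Title: Condition-Aware eQTL Mapping in Paired Resting and Stimulated Immune Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for mapping expression quantitative trait loci (eQTLs) in
    paired-condition study designs, such as resting versus stimulated immune
    cells from the same individuals. Implements per-condition cis-eQTL scans
    with hierarchical (eigen-based local plus Benjamini-Hochberg global)
    multiple-testing correction and per-gene nominal thresholds,
    forward/backward conditional dissection of independent signals,
    response-eQTL detection by genotype-by-condition interaction in a linear
    mixed model with a within-individual permutation null, cross-chromosome
    trans-eQTL scans under three correction schemes, mediation analysis of
    trans effects through cis genes with bootstrap inference, Bayesian
    colocalisation of eQTL and GWAS signals via approximate Bayes factors,
    two-sample Mendelian randomisation with four estimators and a consensus
    rule, and Storey pi1 replication-rate estimation. A synthetic-data
    generator with planted effects makes the whole pipeline testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tools,
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'stimqtl-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'constructors.R'
    'methods.R'
    'preprocess.R'
    'multiple-testing.R'
    'cis-scan.R'
    'signals.R'
    'reqtl.R'
    'trans.R'
    'mediation.R'
    'coloc.R'
    'mr.R'
    'replication.R'
    'io.R'
    'pipeline.R'
    'simulate-genotypes.R'
    'simulate-expression.R'
    'simulate-gwas.R'
    'utils.R'
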