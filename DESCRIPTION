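Package: geneAse
Title: Gene-Level Static and Condition-Dependent Allele-Specific
    Expression from RNA-Seq Allele Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection of static and individual condition-dependent
    allele-specific expression (ASE) at the variant and gene level from
    RNA-seq allele counts, without haplotype information. Per-variant
    effect sizes (allelic-fraction deviation and condition log-odds
    ratio) are normalised by their standard errors and combined within
    genes by Stouffer's method; significance is assessed against
    resampled null distributions drawn from a beta-binomial null model
    fitted to DNA allele counts. Includes Fisher's-method meta-analysis
    across individuals and a count-level simulator for calibration,
    power, ROC and mapping-bias robustness experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    pROC
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'betabinom.R'
    'io.R'
    'snv-tests.R'
    'gene-ase.R'
    'meta.R'
    'simulate.R'
    'experiments.R'
    'vcf.R'
    'geneAse-package.R'
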