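#' Access the ASE mode of an object
#'
#' Returns which flavour of allele-specific expression an object carries:
#' `"static"` (one condition, 2x1 allele-count tables) or `"icd"`
#' (individual condition-dependent, paired-condition 2x2 tables).
#'
#' @param x An [AseCountTable-class], [GeneAseResult-class] or
#'   [SimScenario-class] object.
#' @return A character scalar, `"static"` or `"icd"`.
#' @export
setGeneric("aseMode", function(x) standardGeneric("aseMode"))

#' Access the allele-count table
#'
#' @param x An [AseCountTable-class].
#' @return A `data.frame` of validated allele counts (one row per variant
#'   and sample; for icd data, one row carries both conditions).
#' @export
setGeneric("aseCounts", function(x) standardGeneric("aseCounts"))

#' Access per-gene test results
#'
#' @param x A [GeneAseResult-class] or the output of [metaAnalysis()].
#' @return A `data.frame` with one row per tested gene (and sample).
#' @export
setGeneric("geneResults", function(x) standardGeneric("geneResults"))

#' Simulate an allele-count dataset from a scenario
#'
#' @param scenario A [SimScenario-class] describing the generative
#'   settings (mode, gene count, variants per gene, depth, effect size,
#'   overdispersion, fraction of null genes).
#' @return A list with elements `counts` (an [AseCountTable-class]) and
#'   `truth` (a `data.frame` with columns `gene_id`, `is_ase`).
#' @export
setGeneric("simulateAseData", function(scenario) standardGeneric("simulateAseData"))
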