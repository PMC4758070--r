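.ASE_MODES <- c("static", "icd")

.STATIC_COLS <- c("sample_id", "variant_id", "gene_id", "ref_count", "alt_count")
.ICD_COLS <- c("sample_id", "variant_id", "gene_id",
               "ref_count_U", "alt_count_U", "ref_count_T", "alt_count_T")

.countCols <- function(mode) {
  if (mode == "static") c("ref_count", "alt_count")
  else c("ref_count_U", "alt_count_U", "ref_count_T", "alt_count_T")
}

#' AseCountTable: validated allele counts for ASE analysis
#'
#' Container for per-variant reference/alternative allele read counts.
#' In `static` mode each row is one heterozygous SNV in one sample
#' (a 2x1 table of counts); in `icd` mode each row carries the counts
#' of both the untreated (`U`) and treated (`T`) condition of one
#' individual (a 2x2 table). Optional columns: `in_dbsnp` (logical,
#' default `TRUE`) and, for static data, `null_ratio` (the
#' mapping-bias-adjusted binomial null allele ratio, default 0.5).
#'
#' @slot counts A `data.frame` with the mode's schema (see
#'   [readAseCounts()]).
#' @slot aseMode `"static"` or `"icd"`.
#' @export
setClass("AseCountTable",
         representation(counts = "data.frame", aseMode = "character"))

setValidity("AseCountTable", function(object) {
  mode <- object@aseMode
  df <- object@counts
  if (length(mode) != 1L || !mode %in% .ASE_MODES)
    return("aseMode must be 'static' or 'icd'")
  req <- if (mode == "static") .STATIC_COLS else .ICD_COLS
  missing <- setdiff(req, names(df))
  if (length(missing))
    return(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  for (cc in .countCols(mode)) {
    v <- df[[cc]]
    if (!is.numeric(v) || anyNA(v))
      return(paste0("column '", cc, "' must be numeric without NA"))
    bad <- which(v < 0 | v != round(v))
    if (length(bad))
      return(paste0("column '", cc, "' has negative or non-integer count at row ",
                    bad[1L]))
  }
  key <- paste(df$sample_id, df$variant_id, sep = "\r")
  if (anyDuplicated(key))
    return(paste0("duplicate (sample_id, variant_id) at row ",
                  which(duplicated(key))[1L]))
  if (!is.null(df$null_ratio)) {
    nr <- df$null_ratio
    if (anyNA(nr) || any(nr <= 0 | nr >= 1))
      return("null_ratio must lie strictly in (0, 1)")
  }
  if (!is.null(df$in_dbsnp) && !is.logical(df$in_dbsnp))
    return("in_dbsnp must be logical")
  TRUE
})

#' Construct an AseCountTable
#'
#' @param counts A `data.frame` following the static or icd schema
#'   (see [readAseCounts()]). Missing `in_dbsnp` defaults to `TRUE`;
#'   missing `null_ratio` (static) defaults to 0.5.
#' @param mode `"static"` or `"icd"`.
#' @return An [AseCountTable-class].
#' @examples
#' df <- data.frame(sample_id = "s1", variant_id = c("rs1", "rs2"),
#'                  gene_id = "g1", ref_count = c(5L, 8L),
#'                  alt_count = c(5L, 2L))
#' AseCountTable(df, "static")
#' @export
AseCountTable <- function(counts, mode = c("static", "icd")) {
  mode <- match.arg(mode)
  counts <- as.data.frame(counts)
  for (cc in c("sample_id", "variant_id", "gene_id"))
    if (!is.null(counts[[cc]])) counts[[cc]] <- as.character(counts[[cc]])
  if (is.null(counts$in_dbsnp)) counts$in_dbsnp <- rep(TRUE, nrow(counts))
  if (mode == "static" && is.null(counts$null_ratio))
    counts$null_ratio <- rep(0.5, nrow(counts))
  rownames(counts) <- NULL
  new("AseCountTable", counts = counts, aseMode = mode)
}

#' @describeIn AseCountTable-class number of variant rows
#' @param x,object An `AseCountTable`.
#' @export
setMethod("length", "AseCountTable", function(x) nrow(x@counts))

#' @rdname aseMode
#' @export
setMethod("aseMode", "AseCountTable", function(x) x@aseMode)

#' @rdname aseCounts
#' @export
setMethod("aseCounts", "AseCountTable", function(x) x@counts)

#' @describeIn AseCountTable-class coerce to the underlying data.frame
#' @param row.names,optional,... passed on for signature compatibility.
#' @export
setMethod("as.data.frame", "AseCountTable",
          function(x, row.names = NULL, optional = FALSE, ...) x@counts)

setMethod("show", "AseCountTable", function(object) {
  df <- object@counts
  cat("AseCountTable (", object@aseMode, " mode): ",
      nrow(df), " variant rows, ",
      length(unique(df$gene_id)), " genes, ",
      length(unique(df$sample_id)), " sample(s)\n", sep = "")
  if (nrow(df)) {
    print(utils::head(df, 4L))
    if (nrow(df) > 4L) cat("... and", nrow(df) - 4L, "more rows\n")
  }
})

#' BetaBinomNull: fitted variant-level beta-binomial null model
#'
#' The null model for allele counts at a heterozygous site,
#' \eqn{alt \sim BB(n, p^0, \rho^0)}, fitted to DNA allele counts.
#' \eqn{p^0} is the mean alternative-allele fraction and \eqn{\rho^0}
#' the overdispersion (intraclass correlation); \eqn{\rho^0 = 0}
#' recovers an ordinary binomial.
#'
#' @slot p0 Mean allele fraction, in (0, 1).
#' @slot rho0 Overdispersion, in [0, 1).
#' @slot nSites Number of DNA sites used in the fit.
#' @slot logLik Maximised log-likelihood.
#' @export
setClass("BetaBinomNull",
         representation(p0 = "numeric", rho0 = "numeric",
                        nSites = "integer", logLik = "numeric"))

setValidity("BetaBinomNull", function(object) {
  if (length(object@p0) != 1L || object@p0 <= 0 || object@p0 >= 1)
    return("p0 must lie in (0, 1)")
  if (length(object@rho0) != 1L || object@rho0 < 0 || object@rho0 >= 1)
    return("rho0 must lie in [0, 1)")
  TRUE
})

#' Construct a BetaBinomNull directly
#'
#' Mostly useful for simulations; real analyses obtain one from
#' [fitBetaBinomNull()].
#'
#' @param p0 Mean allele fraction in (0, 1).
#' @param rho0 Overdispersion in [0, 1).
#' @param nSites Number of sites behind the estimate (0 if synthetic).
#' @param logLik Fitted log-likelihood (`NA` if synthetic).
#' @return A [BetaBinomNull-class].
#' @export
BetaBinomNull <- function(p0, rho0, nSites = 0L, logLik = NA_real_) {
  new("BetaBinomNull", p0 = as.numeric(p0), rho0 = as.numeric(rho0),
      nSites = as.integer(nSites), logLik = as.numeric(logLik))
}

#' @describeIn BetaBinomNull-class mean allele fraction \eqn{p^0}
#' @param object A `BetaBinomNull`.
#' @export
nullP0 <- function(object) object@p0

#' @describeIn BetaBinomNull-class overdispersion \eqn{\rho^0}
#' @export
nullRho0 <- function(object) object@rho0

setMethod("show", "BetaBinomNull", function(object) {
  cat("BetaBinomNull: p0 = ", signif(object@p0, 4),
      ", rho0 = ", signif(object@rho0, 4),
      " (", object@nSites, " sites, logLik = ",
      signif(object@logLik, 6), ")\n", sep = "")
})

#' NullDistribution: resampled gene-statistic null for a given k
#'
#' `N` Stouffer-combined statistics of `k` pseudo-SNVs resampled from
#' the variant null model, used to convert observed gene statistics to
#' empirical p-values.
#'
#' @slot k Number of variants combined per replicate (for aggregated
#'   nulls beyond the k cap, the representative label).
#' @slot values The `N` combined null statistics (all non-negative).
#' @slot N Number of resampling replicates.
#' @export
setClass("NullDistribution",
         representation(k = "integer", values = "numeric", N = "integer"))

setValidity("NullDistribution", function(object) {
  if (length(object@values) != object@N)
    return("length(values) must equal N")
  if (any(object@values < 0)) return("null statistics must be non-negative")
  TRUE
})

setMethod("show", "NullDistribution", function(object) {
  cat("NullDistribution: k = ", object@k, ", N = ", object@N,
      ", median = ", signif(stats::median(object@values), 4), "\n", sep = "")
})

#' GeneAseResult: per-gene ASE test results
#'
#' @slot results `data.frame` with columns `sample_id`, `gene_id`, `k`
#'   (variants combined), `statistic` (Stouffer-combined), `p_value`
#'   (empirical, add-one convention, so always > 0), `p_adjusted`
#'   (Benjamini-Hochberg within sample).
#' @slot aseMode `"static"` or `"icd"`.
#' @slot nSamples Null-resampling sample size N.
#' @export
setClass("GeneAseResult",
         representation(results = "data.frame", aseMode = "character",
                        nSamples = "integer"))

setValidity("GeneAseResult", function(object) {
  req <- c("sample_id", "gene_id", "k", "statistic", "p_value", "p_adjusted")
  missing <- setdiff(req, names(object@results))
  if (length(missing))
    return(paste0("missing result column(s): ", paste(missing, collapse = ", ")))
  p <- object@results$p_value
  if (length(p) && (any(p <= 0) || any(p > 1)))
    return("p_value must lie in (0, 1]")
  if (length(p) && any(object@results$p_adjusted < p - 1e-12))
    return("p_adjusted must be >= p_value")
  TRUE
})

#' @rdname geneResults
#' @export
setMethod("geneResults", "GeneAseResult", function(x) x@results)

#' @rdname aseMode
#' @export
setMethod("aseMode", "GeneAseResult", function(x) x@aseMode)

#' @describeIn GeneAseResult-class coerce results to a data.frame
#' @param x A `GeneAseResult`.
#' @param row.names,optional,... passed on for signature compatibility.
#' @export
setMethod("as.data.frame", "GeneAseResult",
          function(x, row.names = NULL, optional = FALSE, ...) x@results)

setMethod("show", "GeneAseResult", function(object) {
  df <- object@results
  cat("GeneAseResult (", object@aseMode, " mode): ", nrow(df),
      " gene/sample tests, N = ", object@nSamples, " null resamples\n",
      sep = "")
  cat(sum(df$p_adjusted <= 0.05), "tests at BH-adjusted p <= 0.05\n")
  if (nrow(df)) print(utils::head(df, 5L))
})

#' SimScenario: generative settings for synthetic allele counts
#'
#' @slot aseMode `"static"` or `"icd"`.
#' @slot nGenes Number of genes to simulate.
#' @slot kPool Variants per gene: each gene draws k uniformly from this
#'   pool (a single value fixes k).
#' @slot depth Read depth pool (per condition per variant for icd);
#'   each variant draws its depth uniformly from this pool.
#' @slot effect Static allelic-fraction deviation `e` in [0, 0.5) or
#'   icd odds-ratio >= 1. Zero / one generates null genes only.
#' @slot rho Beta-binomial overdispersion in [0, 1).
#' @slot nullFraction Proportion of genes generated under the null.
#' @slot p0 Baseline allele fraction of null genes (default 0.5; set to
#'   the fitted null's p0 for exact calibration experiments).
#' @export
setClass("SimScenario",
         representation(aseMode = "character", nGenes = "integer",
                        kPool = "integer", depth = "integer",
                        effect = "numeric", rho = "numeric",
                        nullFraction = "numeric", p0 = "numeric"))

setValidity("SimScenario", function(object) {
  if (!object@aseMode %in% .ASE_MODES) return("aseMode must be 'static' or 'icd'")
  if (object@aseMode == "static") {
    if (object@effect < 0 || object@effect >= 0.5)
      return("static effect must lie in [0, 0.5)")
  } else if (object@effect < 1) {
    return("icd effect is an odds-ratio and must be >= 1")
  }
  if (object@rho < 0 || object@rho >= 1) return("rho must lie in [0, 1)")
  if (object@nullFraction < 0 || object@nullFraction > 1)
    return("nullFraction must lie in [0, 1]")
  if (any(object@depth < 1)) return("depths must be >= 1")
  if (any(object@kPool < 1)) return("kPool must be >= 1")
  if (object@p0 <= 0 || object@p0 >= 1) return("p0 must lie in (0, 1)")
  TRUE
})

#' Construct a simulation scenario
#'
#' @param mode `"static"` or `"icd"`.
#' @param nGenes Number of genes.
#' @param kPool Pool of variants-per-gene values (uniform draw per gene).
#' @param depth Read-depth pool (uniform draw per variant, per condition
#'   for icd).
#' @param effect Static deviation in [0, 0.5) or icd odds-ratio >= 1.
#' @param rho Beta-binomial overdispersion in [0, 1).
#' @param nullFraction Proportion of genes generated under the null.
#' @param p0 Baseline (null) allele fraction.
#' @return A [SimScenario-class].
#' @examples
#' sc <- simScenario("icd", nGenes = 100, kPool = 2, depth = 50,
#'                   effect = 10, rho = 0.22, nullFraction = 0.5)
#' sim <- simulateAseData(sc)
#' head(aseCounts(sim$counts))
#' @export
simScenario <- function(mode = c("static", "icd"), nGenes, kPool = 1:5,
                        depth = 50L, effect = 0, rho = 0,
                        nullFraction = 0.5, p0 = 0.5) {
  mode <- match.arg(mode)
  if (mode == "icd" && effect == 0) effect <- 1
  new("SimScenario", aseMode = mode, nGenes = as.integer(nGenes),
      kPool = as.integer(kPool), depth = as.integer(depth),
      effect = as.numeric(effect), rho = as.numeric(rho),
      nullFraction = as.numeric(nullFraction), p0 = as.numeric(p0))
}

#' @rdname aseMode
#' @export
setMethod("aseMode", "SimScenario", function(x) x@aseMode)

setMethod("show", "SimScenario", function(object) {
  cat("SimScenario (", object@aseMode, "): ", object@nGenes, " genes, k in {",
      paste(object@kPool, collapse = ","), "}, depth pool of ",
      length(object@depth), ", effect = ", object@effect,
      ", rho = ", object@rho, ", null fraction = ", object@nullFraction,
      "\n", sep = "")
})
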