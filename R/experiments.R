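# Fit a null model from companion simulated DNA data at the scenario's
# noise level; the gene-level data of a calibration experiment are then
# generated *under that fitted null*, which makes observed and
# resampled statistics exchangeable.
.fitCompanionNull <- function(rho, depth, nSites = 5000L, p0 = 0.5) {
  dna <- simulateDnaCounts(nSites, depth = depth, p0 = p0, rho = rho)
  fitBetaBinomNull(dna, minDepth = 0)
}

#' Calibration experiment: p-value uniformity under the null
#'
#' Fits the variant null model to companion simulated DNA counts,
#' simulates `nGenes` genes under that fitted null, runs the full
#' gene-level pipeline, and reports the Kolmogorov-Smirnov comparison
#' of the gene p-values against U(0, 1) together with the empirical
#' type-I error at the requested alpha levels.
#'
#' @param mode `"static"` or `"icd"`.
#' @param nGenes Number of null genes (default 2000).
#' @param k Variants per gene (scalar or pool).
#' @param depth Read-depth pool.
#' @param rho Generative (and fitted) overdispersion.
#' @param nSamples Null-resampling size N.
#' @param alpha Nominal levels for the type-I error report.
#' @param nDnaSites Companion DNA sites for the null fit.
#' @return A list with `pValues`, `ksStatistic`, `ksP`, and a `report`
#'   `data.frame` (metric/value rows: `ks_uniformity` = KS p-value and
#'   one `fpr` row per alpha).
#' @export
runCalibration <- function(mode = c("static", "icd"), nGenes = 2000L,
                           k = 2L, depth = 50L, rho = 0.22,
                           nSamples = 1e4, alpha = c(0.05, 0.1),
                           nDnaSites = 5000L) {
  mode <- match.arg(mode)
  null <- .fitCompanionNull(rho, depth, nDnaSites)
  sc <- simScenario(mode, nGenes = nGenes, kPool = k, depth = depth,
                    effect = 0, rho = null@rho0, nullFraction = 1,
                    p0 = null@p0)
  sim <- simulateAseData(sc)
  res <- runGeneAse(sim$counts, null, nSamples = nSamples,
                    minVariants = min(k))
  p <- geneResults(res)$p_value
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  fpr <- vapply(alpha, function(a) mean(p <= a), numeric(1))
  report <- data.frame(
    metric = c("ks_uniformity", paste0("fpr_", alpha)),
    value = c(ks$p.value, fpr))
  list(pValues = p, ksStatistic = unname(ks$statistic),
       ksP = ks$p.value, report = report)
}

#' Power experiment at fixed depth and effect size
#'
#' Simulates a mix of alternative and null genes (null genes drawn from
#' the fitted null model; alternative genes at the stated effect around
#' a balanced baseline), runs the gene-level test, BH-adjusts at
#' `fdrLevel`, and reports power as the fraction of alternative genes
#' declared significant.
#'
#' @param mode `"static"` or `"icd"`.
#' @param depth Per-variant read depth (per condition for icd).
#' @param effect Static deviation in [0, 0.5) or icd odds-ratio >= 1.
#' @param rho Overdispersion of both the generator and the null fit.
#' @param nAltGenes,nNullGenes Genes per arm (defaults 500/500).
#' @param k Variants per gene (default 2).
#' @param fdrLevel BH level (default 0.05).
#' @param nSamples Null-resampling size N.
#' @param null Optional pre-fitted [BetaBinomNull-class]; fitted from
#'   companion simulated DNA when `NULL`.
#' @return A list with `power`, `fpr` (fraction of null genes called),
#'   `nSignificant`, the per-gene `results` `data.frame` (with an
#'   `is_alt` column), and the simulated `counts`.
#' @export
runPower <- function(mode = c("static", "icd"), depth, effect, rho = 0.22,
                     nAltGenes = 500L, nNullGenes = 500L, k = 2L,
                     fdrLevel = 0.05, nSamples = 1e4, null = NULL) {
  mode <- match.arg(mode)
  if (is.null(null)) null <- .fitCompanionNull(rho, depth)
  nullSc <- simScenario(mode, nGenes = nNullGenes, kPool = k, depth = depth,
                        effect = 0, rho = null@rho0, nullFraction = 1,
                        p0 = null@p0)
  altSc <- simScenario(mode, nGenes = nAltGenes, kPool = k, depth = depth,
                       effect = effect, rho = rho, nullFraction = 0)
  simNull <- simulateAseData(nullSc)
  simAlt <- simulateAseData(altSc)
  altDf <- aseCounts(simAlt$counts)
  altDf$gene_id <- paste0("alt_", altDf$gene_id)
  altDf$variant_id <- paste0("alt_", altDf$variant_id)
  counts <- AseCountTable(rbind(aseCounts(simNull$counts), altDf), mode)
  res <- runGeneAse(counts, null, nSamples = nSamples, minVariants = min(k))
  df <- geneResults(res)
  df$is_alt <- startsWith(df$gene_id, "alt_")
  sig <- df$p_adjusted <= fdrLevel
  list(power = mean(sig[df$is_alt]), fpr = mean(sig[!df$is_alt]),
       nSignificant = sum(sig), results = df, counts = counts)
}

# Naive comparator: per-variant exact-test p-values (modified binomial
# for static, Fisher's exact for icd) converted to two-sided z-scores
# and Stouffer-combined within gene.
.naiveGeneScore <- function(counts) {
  df <- aseCounts(counts)
  p <- if (aseMode(counts) == "static")
    modifiedBinomTest(df$ref_count, df$alt_count, df$null_ratio)
  else
    fisherExactIcd(df$alt_count_T, df$ref_count_T,
                   df$alt_count_U, df$ref_count_U)
  z <- stats::qnorm(1 - pmin(p, 1 - 1e-12) / 2)
  byGene <- rowsum(z, df$gene_id)
  k <- as.integer(table(df$gene_id)[rownames(byGene)])
  data.frame(gene_id = rownames(byGene),
             score = as.vector(byGene) / sqrt(k),
             stringsAsFactors = FALSE)
}

#' ROC experiment over a grid of effect sizes
#'
#' For each effect size, simulates equal numbers of alternative and
#' null genes, ranks genes by the gene-level p-value, and computes the
#' ROC AUC (via \pkg{pROC}). A naive comparator — Stouffer combination
#' of per-variant z-scores from the modified binomial (static) or
#' Fisher's exact (icd) test — is evaluated on the same simulated
#' counts.
#'
#' @param mode `"static"` or `"icd"`.
#' @param effects Non-empty grid of effect sizes.
#' @param depth Read-depth pool.
#' @param rho Overdispersion.
#' @param nGenesPerEffect Genes per arm per effect (default 200).
#' @param k Variants per gene.
#' @param nSamples Null-resampling size N.
#' @param null Optional pre-fitted null model.
#' @return A `data.frame` with one row per effect: `effect`,
#'   `auc_gene`, `auc_naive`.
#' @export
runRoc <- function(mode = c("static", "icd"), effects, depth = 50L,
                   rho = 0.22, nGenesPerEffect = 200L, k = 2L,
                   nSamples = 1e4, null = NULL) {
  mode <- match.arg(mode)
  if (!length(effects)) stop("empty effect grid")
  if (is.null(null)) null <- .fitCompanionNull(rho, depth)
  out <- lapply(effects, function(eff) {
    pw <- runPower(mode, depth = depth, effect = eff, rho = rho,
                   nAltGenes = nGenesPerEffect, nNullGenes = nGenesPerEffect,
                   k = k, nSamples = nSamples, null = null)
    df <- pw$results
    aucGene <- as.numeric(pROC::auc(
      pROC::roc(df$is_alt, -df$p_value, quiet = TRUE, direction = "<")))
    naive <- .naiveGeneScore(pw$counts)
    naive$is_alt <- startsWith(naive$gene_id, "alt_")
    aucNaive <- as.numeric(pROC::auc(
      pROC::roc(naive$is_alt, naive$score, quiet = TRUE, direction = "<")))
    data.frame(effect = eff, auc_gene = aucGene, auc_naive = aucNaive)
  })
  do.call(rbind, out)
}

#' Count-level FDR of the per-variant tests
#'
#' Simulates a labelled mix of null and alternative variants, applies
#' the per-variant test (Fisher's exact for icd, modified binomial for
#' static), BH-adjusts at `fdrLevel`, and reports the realised false
#' discovery rate among the calls. This is a count-level analogue: it
#' does not model read-level artefacts (multiple variants per read,
#' remapping), which push empirical FDRs higher on real data.
#'
#' @param mode `"static"` or `"icd"`.
#' @param depth Per-variant (per condition) read depth.
#' @param effect Static deviation or icd odds-ratio of the alternative
#'   variants.
#' @param rho Overdispersion.
#' @param nNullVariants,nAltVariants Variants per arm.
#' @param fdrLevel BH level (default 0.05).
#' @return A list with `fdr` (`NA` when nothing is called), `nCalled`,
#'   `nFalse`.
#' @export
runSnvFdr <- function(mode = c("static", "icd"), depth = 50L, effect,
                      rho = 0, nNullVariants = 1000L, nAltVariants = 200L,
                      fdrLevel = 0.05) {
  mode <- match.arg(mode)
  sc <- function(n, eff) simScenario(mode, nGenes = n, kPool = 1L,
                                     depth = depth, effect = eff, rho = rho,
                                     nullFraction = if (eff %in% c(0, 1)) 1 else 0)
  nullEff <- if (mode == "static") 0 else 1
  simN <- simulateAseData(sc(nNullVariants, nullEff))
  df <- aseCounts(simN$counts)
  if (nAltVariants > 0L) {
    dfA <- aseCounts(simulateAseData(sc(nAltVariants, effect))$counts)
    dfA$gene_id <- paste0("alt_", dfA$gene_id)
    dfA$variant_id <- paste0("alt_", dfA$variant_id)
    df <- rbind(df, dfA)
  }
  counts <- AseCountTable(df, mode)
  res <- snvAseTest(counts)
  called <- res$p_adjusted <= fdrLevel
  nFalse <- sum(called & !startsWith(res$gene_id, "alt_"))
  list(fdr = if (any(called)) nFalse / sum(called) else NA_real_,
       nCalled = sum(called), nFalse = nFalse)
}
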