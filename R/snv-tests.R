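#' Static ASE effect size
#'
#' The deviation of the alternative-allele fraction from balance:
#' \eqn{|p - 0.5|} with \eqn{p = c_{alt}/(c_{alt} + c_{ref})}. Balanced
#' counts give 0 (no ASE); monoallelic counts give 0.5 (complete ASE).
#'
#' @param ref,alt Non-negative allele counts (vectors, paired); each
#'   pair must have positive total depth.
#' @return Numeric vector of effect sizes in [0, 0.5].
#' @examples
#' staticEffectSize(5, 5)   # 0
#' staticEffectSize(0, 10)  # 0.5
#' @export
staticEffectSize <- function(ref, alt) {
  n <- ref + alt
  if (any(n <= 0)) stop("zero total depth: effect size undefined")
  abs(alt / n - 0.5)
}

#' Condition-dependent ASE effect size (log2 odds-ratio)
#'
#' The change in allelic imbalance between a treated (T) and untreated
#' (U) condition: \eqn{\log_2(odds(p_T)/odds(p_U))} with
#' \eqn{odds = p/(1-p)} and \eqn{p} the alternative-allele fraction in
#' each condition. Zero cells must be pseudo-count-augmented first (see
#' [addPseudocounts()]); otherwise the odds are infinite and an error is
#' raised.
#'
#' @param altT,refT,altU,refU Allele counts per condition (vectors,
#'   paired).
#' @return Numeric vector of log2 odds-ratios.
#' @examples
#' icdEffectSize(8, 2, 2, 8)  # log2(16) = 4
#' @export
icdEffectSize <- function(altT, refT, altU, refU) {
  if (any(c(altT, refT, altU, refU) == 0))
    stop("zero cell: apply addPseudocounts() before computing the log-odds ratio")
  log2((altT / refT) / (altU / refU))
}

#' Mapping-bias-aware exact binomial test for static ASE
#'
#' Two-sided exact binomial test of the alternative-allele count against
#' a variant-specific null ratio (0.5 in the absence of mapping bias;
#' the mapping-bias-adjusted simulated-read ratio otherwise). The
#' two-sided p-value uses the minimum-likelihood rule, as implemented by
#' [stats::binom.test()].
#'
#' @param ref,alt Allele counts (vectors, paired; positive total depth).
#' @param nullRatio Null alternative-allele probability per variant, in
#'   (0, 1); recycled. Default 0.5.
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' modifiedBinomTest(10, 0)          # 2 * 0.5^10
#' modifiedBinomTest(2, 8, 0.8)      # 1: 8/10 is the modal outcome
#' @export
modifiedBinomTest <- function(ref, alt, nullRatio = 0.5) {
  n <- ref + alt
  if (any(n <= 0)) stop("zero total depth: binomial test undefined")
  nullRatio <- rep_len(nullRatio, length(n))
  if (any(nullRatio <= 0 | nullRatio >= 1))
    stop("nullRatio must lie strictly in (0, 1)")
  vapply(seq_along(n), function(i)
    stats::binom.test(alt[i], n[i], p = nullRatio[i])$p.value, numeric(1))
}

#' Fisher's exact test for condition-dependent ASE at one variant
#'
#' Two-sided Fisher's exact test on the 2x2 table of raw allele counts
#' in the two conditions (minimum-likelihood rule over the
#' hypergeometric support, as implemented by [stats::fisher.test()]).
#' Both conditions must have reads.
#'
#' @param altT,refT,altU,refU Raw allele counts per condition (vectors,
#'   paired).
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' fisherExactIcd(10, 0, 0, 10)  # 2 / choose(20, 10)
#' @export
fisherExactIcd <- function(altT, refT, altU, refU) {
  if (any(altT + refT <= 0) || any(altU + refU <= 0))
    stop("degenerate margin: a condition has zero total reads")
  vapply(seq_along(altT), function(i)
    stats::fisher.test(matrix(c(altT[i], refT[i], altU[i], refU[i]),
                              nrow = 2, byrow = TRUE))$p.value,
    numeric(1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH adjusted p-values in the input order (a thin, documented
#' wrapper around [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, elementwise >= `p`, capped at 1.
#' @export
bhAdjust <- function(p) {
  if (length(p) && (any(p <= 0) || any(p > 1)))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Within-gene signal-to-noise ratio of condition-dependent ASE
#'
#' Mean of the per-variant effect magnitudes divided by their sample
#' standard deviation. `Inf` when the spread is zero but the mean is
#' positive. A gene with SNR >= 2 is conventionally called consistent.
#'
#' @param deltaAse Numeric vector of `|log2 odds-ratio|` magnitudes for
#'   the variants of one gene; at least two values.
#' @return A list with elements `snr` and logical `consistent`
#'   (SNR >= 2).
#' @examples
#' geneSnr(c(1, 3))     # 2 / sqrt(2)
#' geneSnr(c(2, 2, 2))  # Inf, consistent
#' @export
geneSnr <- function(deltaAse) {
  if (length(deltaAse) < 2L)
    stop("SNR requires at least two variants in the gene")
  s <- stats::sd(deltaAse)
  m <- mean(deltaAse)
  snr <- if (s == 0) { if (m > 0) Inf else NaN } else m / s
  list(snr = snr, consistent = is.finite(snr) && snr >= 2 || is.infinite(snr))
}

#' Variants with a sustained condition-dependent effect across individuals
#'
#' Returns the variants whose effect magnitude exceeds a threshold in at
#' least `minIndividuals` individuals — a read-depth-robust complement
#' to demanding per-individual significance. The threshold may be given
#' directly or derived as a percentile (type-7 linear interpolation
#' between order statistics) of a supplied set of significant-effect
#' magnitudes.
#'
#' @param effects A `data.frame` with columns `variant_id`, `sample_id`
#'   (one row per variant per individual) and `delta_ase` (the
#'   `|log2 odds-ratio|` magnitude).
#' @param threshold Magnitude threshold (>= 0); ignored when
#'   `percentileOf` is given.
#' @param percentileOf Optional numeric vector whose `percentile`
#'   quantile becomes the threshold.
#' @param percentile Percentile in [0, 1] used with `percentileOf`
#'   (default 0.9).
#' @param minIndividuals Minimum number of individuals over threshold
#'   (default 2).
#' @return A list with the character vector `variants` and the
#'   `threshold` used.
#' @export
sustainedEffectVariants <- function(effects, threshold = 0.61,
                                    percentileOf = NULL, percentile = 0.9,
                                    minIndividuals = 2L) {
  if (!is.null(percentileOf))
    threshold <- unname(stats::quantile(percentileOf, percentile, type = 7))
  if (threshold < 0) stop("threshold must be >= 0")
  hit <- effects[abs(effects$delta_ase) > threshold, , drop = FALSE]
  nInd <- tapply(hit$sample_id, hit$variant_id,
                 function(s) length(unique(s)))
  list(variants = names(nInd)[nInd >= minIndividuals], threshold = threshold)
}

#' Per-variant ASE tests over a count table
#'
#' Runs the variant-level test appropriate to the data's mode over all
#' rows: the mapping-bias-aware binomial test with the per-variant null
#' ratio (static) or Fisher's exact test on the two-condition 2x2 table
#' (icd), with BH adjustment within each sample. Effect sizes are
#' [staticEffectSize()] and [icdEffectSize()] (the latter on
#' pseudo-count-augmented cells).
#'
#' @param x An [AseCountTable-class] (depth-filter beforehand with
#'   [filterByDepth()] as desired).
#' @return A `data.frame` with columns `sample_id`, `variant_id`,
#'   `gene_id`, `effect_size`, `p_value`, `p_adjusted`.
#' @examples
#' df <- data.frame(sample_id = "s", variant_id = c("v1", "v2"),
#'                  gene_id = "g", ref_count = c(20L, 5L),
#'                  alt_count = c(2L, 6L))
#' snvAseTest(AseCountTable(df, "static"))
#' @export
snvAseTest <- function(x) {
  stopifnot(is(x, "AseCountTable"))
  df <- aseCounts(x)
  if (aseMode(x) == "static") {
    eff <- staticEffectSize(df$ref_count, df$alt_count)
    p <- modifiedBinomTest(df$ref_count, df$alt_count, df$null_ratio)
  } else {
    aug <- addPseudocounts(df$alt_count_T, df$ref_count_T,
                           df$alt_count_U, df$ref_count_U)
    eff <- icdEffectSize(aug$altT, aug$refT, aug$altU, aug$refU)
    p <- fisherExactIcd(df$alt_count_T, df$ref_count_T,
                        df$alt_count_U, df$ref_count_U)
  }
  out <- data.frame(sample_id = df$sample_id, variant_id = df$variant_id,
                    gene_id = df$gene_id, effect_size = eff, p_value = p,
                    stringsAsFactors = FALSE)
  out$p_adjusted <- stats::ave(out$p_value, out$sample_id, FUN = bhAdjust)
  out
}
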