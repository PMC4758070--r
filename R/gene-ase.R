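#' Pseudo-count augmentation of allele-count tables
#'
#' If any cell of a table is zero, 1 is added to every cell of that
#' table, so that odds and log-odds stay finite; tables without zeros
#' are returned unchanged. Works row-wise on vectors: give two vectors
#' for 2x1 static tables or four for 2x2 condition tables.
#'
#' @param ... Two (alt, ref) or four (altT, refT, altU, refU) equal-length
#'   non-negative integer vectors.
#' @return A named list of the augmented vectors, in the input order,
#'   with names `alt`,`ref` (2x1) or `altT`,`refT`,`altU`,`refU` (2x2).
#' @examples
#' addPseudocounts(0, 7)           # (1, 8)
#' addPseudocounts(5, 0, 3, 2)     # every cell + 1
#' addPseudocounts(5, 2, 3, 2)     # unchanged
#' @export
addPseudocounts <- function(...) {
  cells <- list(...)
  if (!length(cells) %in% c(2L, 4L))
    stop("expected 2 (static) or 4 (icd) count vectors")
  m <- do.call(cbind, cells)
  if (any(m < 0)) stop("counts must be non-negative")
  bump <- rowSums(m == 0) > 0
  m[bump, ] <- m[bump, , drop = FALSE] + 1L
  out <- lapply(seq_len(ncol(m)), function(j) m[, j])
  names(out) <- if (length(cells) == 2L) c("alt", "ref")
                else c("altT", "refT", "altU", "refU")
  out
}

# Standard error of the log-odds via the Wilson score interval: compute
# the 95% Wilson interval for the allele fraction, map both endpoints to
# the log-odds scale, and take half the width over z. Finite even at
# extreme fractions (cells are >= 1 after pseudo-counts).
.wilsonLogOddsSE <- function(alt, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ph <- alt / n
  denom <- 1 + z^2 / n
  centre <- (ph + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2))
  (stats::qlogis(centre + half) - stats::qlogis(centre - half)) / (2 * z)
}

# Delta-method (Woolf) alternative for the static log-odds se.
.deltaLogOddsSE <- function(alt, ref) sqrt(1 / alt + 1 / ref)

#' Per-variant statistic for static ASE
#'
#' Effect = natural-log odds of the alternative-allele fraction,
#' `ln(alt/ref)`; standard error from the Wilson score interval mapped
#' to the log-odds scale (or the delta-method `sqrt(1/alt + 1/ref)`
#' with `seMethod = "delta"`); statistic = |effect| / se. The absolute
#' value makes the statistic phase-free. Counts are pseudo-count
#' augmented internally.
#'
#' @param ref,alt Allele counts (vectors, paired).
#' @param seMethod `"wilson"` (default) or `"delta"`.
#' @return A `data.frame` with columns `effect`, `se`, `statistic`.
#' @examples
#' snvStatStatic(5, 5)$statistic  # 0
#' @export
snvStatStatic <- function(ref, alt, seMethod = c("wilson", "delta")) {
  seMethod <- match.arg(seMethod)
  aug <- addPseudocounts(alt, ref)
  effect <- log(aug$alt / aug$ref)
  se <- if (seMethod == "wilson")
    .wilsonLogOddsSE(aug$alt, aug$alt + aug$ref)
  else .deltaLogOddsSE(aug$alt, aug$ref)
  data.frame(effect = effect, se = se, statistic = abs(effect) / se)
}

#' Per-variant statistic for condition-dependent ASE
#'
#' Effect = natural-log odds-ratio of the 2x2 condition table (the log
#' stabilises the variance); standard error is Woolf's
#' `sqrt(1/a + 1/b + 1/c + 1/d)`; statistic = |effect| / se. Cells are
#' pseudo-count augmented internally.
#'
#' @param altT,refT,altU,refU Allele counts per condition (vectors,
#'   paired).
#' @return A `data.frame` with columns `effect`, `se`, `statistic`.
#' @examples
#' snvStatIcd(8, 2, 2, 8)$statistic  # log(16)/sqrt(1.25)
#' @export
snvStatIcd <- function(altT, refT, altU, refU) {
  aug <- addPseudocounts(altT, refT, altU, refU)
  effect <- log((aug$altT / aug$refT) / (aug$altU / aug$refU))
  se <- sqrt(1 / aug$altT + 1 / aug$refT + 1 / aug$altU + 1 / aug$refU)
  data.frame(effect = effect, se = se, statistic = abs(effect) / se)
}

#' Stouffer combination of per-variant statistics
#'
#' @param statistics Numeric vector of k finite per-variant statistics.
#' @return `sum(statistics) / sqrt(k)`.
#' @examples
#' stoufferCombine(c(1, 3))  # 4 / sqrt(2)
#' @export
stoufferCombine <- function(statistics) {
  if (!length(statistics)) stop("cannot combine an empty statistic list")
  if (any(!is.finite(statistics))) stop("statistics must be finite")
  sum(statistics) / sqrt(length(statistics))
}

# Latent per-variant allele fractions under the null model.
.rNullTheta <- function(n, null) {
  if (null@rho0 == 0) return(rep.int(null@p0, n))
  sh <- .bbShapes(null@p0, null@rho0)
  pmin(pmax(stats::rbeta(n, sh[["alpha"]], sh[["beta"]]), 1e-9), 1 - 1e-9)
}

# Draw per-variant null statistics for `nTot` pseudo-SNVs. Depths are
# drawn with replacement from the pooled empirical depth distribution
# (per condition for icd) and alt counts from the fitted beta-binomial
# null. For icd, the latent allele fraction drawn from the null model
# is a variant property (baseline imbalance, mapping bias) and is
# therefore shared by the two conditions: the icd null states that the
# imbalance does not *change*, so each condition's count is binomial
# around the same latent fraction. For static tables a beta-binomial
# draw is exactly latent-fraction-then-binomial.
.nullSnvStats <- function(nTot, depthPool, depthPoolT, null, mode, seMethod) {
  if (mode == "static") {
    d <- depthPool[sample.int(length(depthPool), nTot, replace = TRUE)]
    alt <- rBetaBinom(nTot, d, null@p0, null@rho0)
    snvStatStatic(d - alt, alt, seMethod)$statistic
  } else {
    dU <- depthPool[sample.int(length(depthPool), nTot, replace = TRUE)]
    dT <- depthPoolT[sample.int(length(depthPoolT), nTot, replace = TRUE)]
    theta <- .rNullTheta(nTot, null)
    altU <- stats::rbinom(nTot, dU, theta)
    altT <- stats::rbinom(nTot, dT, theta)
    snvStatIcd(altT, dT - altT, altU, dU - altU)$statistic
  }
}

#' Resample the null distribution of the gene statistic for k variants
#'
#' For each of `N` replicates, draws `k` pseudo-SNVs: a depth from the
#' pooled empirical depth distribution (per condition for icd), an
#' alternative-allele count from the fitted variant null model, then
#' the per-variant statistic after pseudo-count augmentation; the k
#' statistics are Stouffer-combined. When `k` is a vector, each
#' replicate draws its variant count uniformly from it (used for the
#' aggregated null beyond the k cap).
#'
#' @param k Number of variants per gene (scalar), or a pool of counts.
#' @param depthPool Non-empty integer vector of observed read depths
#'   (condition U for icd).
#' @param null A [BetaBinomNull-class].
#' @param N Number of replicates (default 1e5, minimum 1000).
#' @param mode `"static"` or `"icd"`.
#' @param depthPoolT Depth pool for condition T (icd; defaults to
#'   `depthPool`).
#' @param seMethod Standard-error method for the static statistic.
#' @return A [NullDistribution-class].
#' @examples
#' set.seed(1)
#' nd <- buildNullDistribution(2, depthPool = 50L,
#'                             null = BetaBinomNull(0.5, 0.22),
#'                             N = 1000, mode = "icd")
#' nd
#' @export
buildNullDistribution <- function(k, depthPool, null, N = 1e5,
                                  mode = c("static", "icd"),
                                  depthPoolT = NULL,
                                  seMethod = c("wilson", "delta")) {
  mode <- match.arg(mode)
  seMethod <- match.arg(seMethod)
  stopifnot(is(null, "BetaBinomNull"))
  N <- as.integer(N)
  if (N < 1000L) stop("N must be at least 1000 for a usable null")
  if (!length(depthPool)) stop("empty depth pool")
  if (is.null(depthPoolT)) depthPoolT <- depthPool
  k <- as.integer(k)
  if (length(k) == 1L) {
    kRep <- rep.int(k, N)
  } else {
    kRep <- k[sample.int(length(k), N, replace = TRUE)]
  }
  stat <- .nullSnvStats(sum(kRep), depthPool, depthPoolT, null, mode, seMethod)
  grp <- rep.int(seq_len(N), kRep)
  values <- as.vector(rowsum(stat, grp)) / sqrt(kRep)
  new("NullDistribution", k = k[1L], values = values, N = N)
}

#' Empirical p-value against a resampled null
#'
#' Two conventions are offered. `"random"` (the default) is the
#' randomized add-one p-value
#' \eqn{p = (\#\{null > obs\} + U\,(1 + \#\{null = obs\})) / (N + 1)}
#' with \eqn{U \sim U(0,1)}: under exchangeability of observed and null
#' statistics it is exactly uniform even when the test statistic is
#' discrete, so the test is neither optimistic nor conservative; it is
#' reproducible under `set.seed()`. `"conservative"` is the
#' deterministic add-one rule
#' \eqn{p = (1 + \#\{null \ge obs\}) / (N + 1)} (ties count as extreme,
#' p never below \eqn{1/(N+1)}), which is slightly conservative where
#' the statistic has atoms. Both are strictly positive.
#'
#' @param observed Numeric vector of observed statistics.
#' @param nullValues A [NullDistribution-class] or numeric vector of
#'   null statistics.
#' @param ties `"random"` or `"conservative"`.
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' empiricalPValue(2, c(0.5, 1, 3), ties = "conservative")  # (1 + 1) / 4
#' @export
empiricalPValue <- function(observed, nullValues,
                            ties = c("random", "conservative")) {
  ties <- match.arg(ties)
  if (is(nullValues, "NullDistribution")) nullValues <- nullValues@values
  if (!length(nullValues)) stop("empty null distribution")
  s <- sort(nullValues)
  N <- length(s)
  nBelow <- findInterval(observed, s, left.open = TRUE)   # #{null < obs}
  if (ties == "conservative") return((1 + N - nBelow) / (N + 1))
  nBelowEq <- findInterval(observed, s)                   # #{null <= obs}
  nGreater <- N - nBelowEq
  nEqual <- nBelowEq - nBelow
  u <- stats::runif(length(observed))
  (nGreater + u * (1 + nEqual)) / (N + 1)
}

.snvStatistics <- function(df, mode, seMethod) {
  if (mode == "static")
    snvStatStatic(df$ref_count, df$alt_count, seMethod)$statistic
  else
    snvStatIcd(df$alt_count_T, df$ref_count_T,
               df$alt_count_U, df$ref_count_U)$statistic
}

#' Gene-level test of static or condition-dependent ASE
#'
#' The full gene-level pipeline: optional dbSNP and depth pre-filters,
#' the >= `minVariants` pre-filter (default 2), per-variant statistics
#' (|effect| / se after pseudo-counts), Stouffer combination within
#' gene, empirical p-values against per-k resampled null distributions
#' drawn from the fitted variant null model, and BH adjustment within
#' each sample. One null distribution is built per distinct variant
#' count k (up to `kCap`; genes beyond the cap share one aggregated
#' null whose k is resampled from the observed over-cap counts) and is
#' reused across genes and samples. Null depths are drawn from the
#' pooled empirical depth distribution of all analysed variants (per
#' condition for icd).
#'
#' Randomness (the null resampling) uses R's global RNG; call
#' `set.seed()` for reproducibility.
#'
#' @param x An [AseCountTable-class].
#' @param null A [BetaBinomNull-class] fitted with [fitBetaBinomNull()]
#'   (or constructed directly for simulations).
#' @param nSamples Null-resampling size N (default 1e5).
#' @param minVariants Minimum dbSNP variants per gene (default 2; set 1
#'   to test single-variant genes).
#' @param kCap Largest k with its own null distribution (default 100).
#' @param dbsnpOnly Drop variants with `in_dbsnp = FALSE` (default
#'   `TRUE`).
#' @param minDepth Optional per-sample depth filter applied first.
#' @param minDepthSum Optional summed-conditions depth filter (icd).
#' @param seMethod Standard-error method for the static statistic:
#'   `"wilson"` (default) or `"delta"`.
#' @param ties Empirical p-value convention, `"random"` (exactly
#'   calibrated; default) or `"conservative"`; see [empiricalPValue()].
#' @return A [GeneAseResult-class], sorted by adjusted then nominal
#'   p-value and gene id.
#' @examples
#' set.seed(42)
#' sim <- simulateAseData(simScenario("icd", nGenes = 40, kPool = 2,
#'                                    depth = 50, effect = 8, rho = 0,
#'                                    nullFraction = 0.5))
#' res <- runGeneAse(sim$counts, BetaBinomNull(0.5, 0), nSamples = 2000)
#' head(geneResults(res))
#' @export
runGeneAse <- function(x, null, nSamples = 1e5, minVariants = 2L,
                       kCap = 100L, dbsnpOnly = TRUE, minDepth = NULL,
                       minDepthSum = NULL,
                       seMethod = c("wilson", "delta"),
                       ties = c("random", "conservative")) {
  stopifnot(is(x, "AseCountTable"))
  if (missing(null) || !is(null, "BetaBinomNull"))
    stop("a fitted BetaBinomNull is required")
  seMethod <- match.arg(seMethod)
  ties <- match.arg(ties)
  mode <- aseMode(x)
  if (!is.null(minDepth)) x <- filterByDepth(x, minDepth, "per_sample")
  if (!is.null(minDepthSum)) {
    if (mode != "icd") stop("minDepthSum applies to icd data only")
    x <- filterByDepth(x, minDepthSum, "summed_conditions")
  }
  df <- aseCounts(x)
  if (dbsnpOnly) df <- df[df$in_dbsnp, , drop = FALSE]
  if (!nrow(df)) stop("no variants left to analyse after filtering")

  key <- paste(df$sample_id, df$gene_id, sep = "\r")
  kByGene <- table(key)
  keep <- key %in% names(kByGene)[kByGene >= minVariants]
  df <- df[keep, , drop = FALSE]
  key <- key[keep]
  if (!nrow(df)) stop("no genes with >= ", minVariants, " variants")

  # observed gene statistics
  stat <- .snvStatistics(df, mode, seMethod)
  gStat <- rowsum(stat, key)
  genes <- rownames(gStat)
  kObs <- as.integer(table(key)[genes])
  gStat <- as.vector(gStat) / sqrt(kObs)

  # pooled empirical depth distributions
  if (mode == "static") {
    depthPool <- df$ref_count + df$alt_count
    depthPoolT <- NULL
  } else {
    depthPool <- df$ref_count_U + df$alt_count_U
    depthPoolT <- df$ref_count_T + df$alt_count_T
  }

  kEff <- ifelse(kObs > kCap, -1L, kObs)
  pval <- numeric(length(genes))
  for (kk in unique(kEff)) {
    idx <- kEff == kk
    kDraw <- if (kk == -1L) unique(kObs[idx]) else kk
    nd <- buildNullDistribution(kDraw, depthPool, null, N = nSamples,
                                mode = mode, depthPoolT = depthPoolT,
                                seMethod = seMethod)
    pval[idx] <- empiricalPValue(gStat[idx], nd, ties = ties)
  }

  parts <- strsplit(genes, "\r", fixed = TRUE)
  out <- data.frame(sample_id = vapply(parts, `[`, "", 1L),
                    gene_id = vapply(parts, `[`, "", 2L),
                    k = kObs, statistic = gStat, p_value = pval,
                    stringsAsFactors = FALSE)
  out$p_adjusted <- stats::ave(out$p_value, out$sample_id, FUN = bhAdjust)
  out <- out[order(out$p_adjusted, out$p_value, out$gene_id,
                   out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  new("GeneAseResult", results = out, aseMode = mode,
      nSamples = as.integer(nSamples))
}

#' Gate genes for condition-dependent analysis on weak static evidence
#'
#' Genes enter the condition-dependent analysis when they show at least
#' a weak indication of static ASE — a nominal (unadjusted) static
#' gene p-value <= `threshold` (inclusive) in either condition.
#'
#' @param staticU,staticT [GeneAseResult-class] objects (or their
#'   `data.frame`s) from static runs on the untreated and treated
#'   samples.
#' @param threshold Nominal p-value gate (default 0.2).
#' @return Character vector of eligible gene ids.
#' @export
cdGate <- function(staticU, staticT, threshold = 0.2) {
  get <- function(r) {
    df <- if (is(r, "GeneAseResult")) geneResults(r) else as.data.frame(r)
    df$gene_id[df$p_value <= threshold]
  }
  sort(unique(c(get(staticU), get(staticT))))
}
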