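.drawDepths <- function(n, depth) {
  depth <- as.integer(depth)
  if (length(depth) == 1L) rep.int(depth, n)
  else depth[sample.int(length(depth), n, replace = TRUE)]
}

#' Simulate DNA allele counts at heterozygous sites
#'
#' Per site: a depth drawn from the depth pool, an alternative-allele
#' count from \eqn{BB(depth, p_0, \rho)}, reference = depth - alt.
#' Serves as input for [fitBetaBinomNull()].
#'
#' @param nSites Number of sites.
#' @param depth Depth pool (scalar or vector, uniform draw per site).
#' @param p0 Mean allele fraction (default 0.5).
#' @param rho Overdispersion in [0, 1).
#' @return A `data.frame` with columns `ref_count`, `alt_count`.
#' @export
simulateDnaCounts <- function(nSites, depth = 50L, p0 = 0.5, rho = 0) {
  if (nSites < 1) stop("nSites must be >= 1")
  d <- .drawDepths(nSites, depth)
  alt <- rBetaBinom(nSites, d, p0, rho)
  data.frame(ref_count = d - alt, alt_count = alt)
}

#' Simulate the variants of one gene with static ASE
#'
#' A single gene-level sign \eqn{s \in \{-1, +1\}} is drawn (phase is
#' unknown, so the direction is arbitrary but shared within the gene);
#' each variant then draws a depth and an alternative count from
#' \eqn{BB(depth, p_0 + s\,e, \rho)}. `effect = 0` reduces exactly to
#' the null generator.
#'
#' @param k Number of variants.
#' @param depth Depth pool.
#' @param effect Allelic-fraction deviation e in [0, 0.5).
#' @param rho Overdispersion.
#' @param geneId,sampleId Identifiers for the emitted rows.
#' @param p0 Baseline allele fraction (default 0.5).
#' @return A `data.frame` of static-schema rows.
#' @export
simulateStaticGene <- function(k, depth, effect, rho, geneId = "g1",
                               sampleId = "s1", p0 = 0.5) {
  if (effect < 0 || effect >= 0.5) stop("static effect must lie in [0, 0.5)")
  s <- sample(c(-1, 1), 1L)
  p <- min(max(p0 + s * effect, 1e-6), 1 - 1e-6)
  d <- .drawDepths(k, depth)
  alt <- rBetaBinom(k, d, p, rho)
  data.frame(sample_id = sampleId,
             variant_id = paste0(geneId, "_v", seq_len(k)),
             gene_id = geneId, ref_count = d - alt, alt_count = alt,
             stringsAsFactors = FALSE)
}

#' Simulate the variants of one gene with condition-dependent ASE
#'
#' Each variant draws a latent baseline allele fraction
#' \eqn{\theta_U \sim Beta} centred at `p0` with overdispersion `rho`
#' (the variant's static imbalance, shared across conditions — the
#' paired design); the treated condition's latent odds are scaled by
#' the odds-ratio raised to a gene-level random sign,
#' \eqn{odds(\theta_T) = OR^s\, odds(\theta_U)}. Counts per condition
#' are binomial at the respective latent fraction. `oddsRatio = 1`
#' makes \eqn{\theta_T = \theta_U} exactly, the null of no *change* in
#' imbalance.
#'
#' @param k Number of variants.
#' @param depth Depth pool, applied per condition per variant.
#' @param oddsRatio Condition odds-ratio, >= 1 (direction comes from
#'   the random sign).
#' @param rho Overdispersion of the latent baseline fraction.
#' @param geneId,sampleId Identifiers for the emitted rows.
#' @param p0 Baseline allele fraction (default 0.5).
#' @return A `data.frame` of icd-schema rows.
#' @export
simulateIcdGene <- function(k, depth, oddsRatio, rho, geneId = "g1",
                            sampleId = "s1", p0 = 0.5) {
  if (oddsRatio < 1)
    stop("oddsRatio must be >= 1; direction is carried by the random sign")
  s <- sample(c(-1, 1), 1L)
  thetaU <- if (rho == 0) rep.int(p0, k) else {
    sh <- .bbShapes(p0, rho)
    pmin(pmax(stats::rbeta(k, sh[["alpha"]], sh[["beta"]]), 1e-9), 1 - 1e-9)
  }
  oddsT <- oddsRatio^s * thetaU / (1 - thetaU)
  thetaT <- oddsT / (1 + oddsT)
  dU <- .drawDepths(k, depth)
  dT <- .drawDepths(k, depth)
  altU <- stats::rbinom(k, dU, thetaU)
  altT <- stats::rbinom(k, dT, thetaT)
  data.frame(sample_id = sampleId,
             variant_id = paste0(geneId, "_v", seq_len(k)),
             gene_id = geneId,
             ref_count_U = dU - altU, alt_count_U = altU,
             ref_count_T = dT - altT, alt_count_T = altT,
             stringsAsFactors = FALSE)
}

#' @rdname simulateAseData
#' @export
setMethod("simulateAseData", "SimScenario", function(scenario) {
  mode <- scenario@aseMode
  n <- scenario@nGenes
  nNull <- round(scenario@nullFraction * n)
  isAse <- c(rep(FALSE, nNull), rep(TRUE, n - nNull))
  ids <- sprintf("gene%05d", seq_len(n))
  ks <- if (length(scenario@kPool) == 1L) rep.int(scenario@kPool, n)
        else scenario@kPool[sample.int(length(scenario@kPool), n,
                                       replace = TRUE)]
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    eff <- if (isAse[i]) scenario@effect else if (mode == "static") 0 else 1
    rows[[i]] <- if (mode == "static")
      simulateStaticGene(ks[i], scenario@depth, eff, scenario@rho,
                         geneId = ids[i], p0 = scenario@p0)
    else
      simulateIcdGene(ks[i], scenario@depth, eff, scenario@rho,
                      geneId = ids[i], p0 = scenario@p0)
  }
  counts <- AseCountTable(do.call(rbind, rows), mode)
  list(counts = counts,
       truth = data.frame(gene_id = ids, is_ase = isAse,
                          stringsAsFactors = FALSE))
})

#' Perturb counts with artificial reference-mapping bias
#'
#' Emulates reference-allele mapping bias by inflating reference counts
#' and deflating alternative counts uniformly:
#' `ref' = round(ref * (1 + bias))`,
#' `alt' = max(0, round(alt * (1 - bias)))` — applied to every variant
#' (and both conditions for icd data).
#'
#' @param x An [AseCountTable-class].
#' @param biasFraction Bias magnitude in [0, 1); 0 is the identity.
#' @return A perturbed [AseCountTable-class].
#' @export
perturbMappingBias <- function(x, biasFraction = 0.1) {
  stopifnot(is(x, "AseCountTable"))
  if (biasFraction < 0 || biasFraction >= 1)
    stop("biasFraction must lie in [0, 1)")
  df <- aseCounts(x)
  refCols <- grep("^ref_count", names(df), value = TRUE)
  altCols <- grep("^alt_count", names(df), value = TRUE)
  for (cc in refCols) df[[cc]] <- as.integer(round(df[[cc]] * (1 + biasFraction)))
  for (cc in altCols) df[[cc]] <- pmax(0L, as.integer(round(df[[cc]] * (1 - biasFraction))))
  AseCountTable(df, aseMode(x))
}
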