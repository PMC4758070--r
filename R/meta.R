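#' Fisher's method for combining p-values
#'
#' \eqn{\chi^2 = -2 \sum_{i=1}^m \ln p_i}, compared against a chi-square
#' distribution with `2m` degrees of freedom. With a single input the
#' combined p-value equals that input.
#'
#' @param p Numeric vector of m p-values in (0, 1]; m >= 1. (The
#'   add-one empirical p-value convention guarantees p > 0 upstream.)
#' @return A list with elements `chi2`, `df` and `p_meta`.
#' @examples
#' fisherMethod(c(0.05, 0.05))  # chi2 ~ 11.98, p ~ 0.0175
#' @export
fisherMethod <- function(p) {
  if (!length(p)) stop("need at least one p-value")
  if (any(p <= 0) || any(p > 1)) stop("p-values must lie in (0, 1]")
  chi2 <- -2 * sum(log(p))
  m <- length(p)
  list(chi2 = chi2, df = 2L * m,
       p_meta = stats::pchisq(chi2, df = 2 * m, lower.tail = FALSE))
}

#' Meta-analysis of gene ASE across individuals
#'
#' Treats the per-individual (or per-sample) gene-level results as
#' biological replicates: for each gene, the p-values from the samples
#' in which the gene was testable (genotypes differ between
#' individuals, so genes may be missing from some) are combined by
#' Fisher's method, followed by BH adjustment across genes. The
#' reported significant set is the union of meta-significant genes and
#' genes significant in any single sample, de-duplicated, with an
#' `evidence` flag (`"meta"`, `"individual"` or `"both"`).
#'
#' @param results A list of [GeneAseResult-class] objects (or
#'   `data.frame`s with `sample_id`, `gene_id`, `p_value`,
#'   `p_adjusted`), one per individual/sample.
#' @param fdr Significance level on adjusted p-values (default 0.05).
#' @return A list with `meta` (a `data.frame`: `gene_id`, `m`, `chi2`,
#'   `p_meta`, `p_meta_adjusted`, `evidence`, `sample_ids`) and
#'   `significant` (the union set of gene ids).
#' @export
metaAnalysis <- function(results, fdr = 0.05) {
  if (is(results, "GeneAseResult")) results <- list(results)
  dfs <- lapply(results, function(r)
    if (is(r, "GeneAseResult")) geneResults(r) else as.data.frame(r))
  all <- do.call(rbind, lapply(dfs, function(d)
    d[, c("sample_id", "gene_id", "p_value", "p_adjusted")]))
  if (!nrow(all)) stop("no gene results to combine")

  bySample <- split(all, all$gene_id)
  meta <- do.call(rbind, lapply(bySample, function(d) {
    fm <- fisherMethod(d$p_value)
    data.frame(gene_id = d$gene_id[1L], m = nrow(d), chi2 = fm$chi2,
               p_meta = fm$p_meta,
               sample_ids = paste(sort(unique(d$sample_id)), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  meta$p_meta_adjusted <- bhAdjust(meta$p_meta)

  indivSig <- unique(all$gene_id[all$p_adjusted <= fdr])
  metaSig <- meta$gene_id[meta$p_meta_adjusted <= fdr]
  meta$evidence <- ifelse(meta$gene_id %in% metaSig & meta$gene_id %in% indivSig,
                          "both",
                   ifelse(meta$gene_id %in% metaSig, "meta",
                   ifelse(meta$gene_id %in% indivSig, "individual", "none")))
  meta <- meta[order(meta$p_meta_adjusted, meta$gene_id), ,
               drop = FALSE]
  meta <- meta[, c("gene_id", "m", "chi2", "p_meta", "p_meta_adjusted",
                   "evidence", "sample_ids")]
  rownames(meta) <- NULL
  list(meta = meta, significant = sort(unique(c(metaSig, indivSig))))
}
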