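# Independent oracles used to check the package's statistics. These are
# deliberately naive (enumeration, quadrature, root-finding, loops) and
# share no code with the implementation paths they verify.

# Two-sided exact binomial p-value by minimum-likelihood enumeration:
# the sum of P(X = x) over all x whose likelihood does not exceed the
# observed one (with the customary relative tolerance for ties).
oracleBinomTwoSided <- function(alt, n, p) {
  d <- dbinom(0:n, n, p)
  sum(d[d <= d[alt + 1L] * (1 + 1e-7)])
}

# Two-sided Fisher's exact p-value by enumeration of the full
# hypergeometric support at fixed margins, minimum-likelihood rule.
# Table layout: rows = conditions (T, U), columns = (alt, ref).
oracleFisher2x2 <- function(altT, refT, altU, refU) {
  m <- altT + altU          # total alt
  nn <- refT + refU         # total ref
  kk <- altT + refT         # condition-T margin
  support <- max(0L, kk - nn):min(kk, m)
  d <- dhyper(support, m, nn, kk)
  sum(d[d <= dhyper(altT, m, nn, kk) * (1 + 1e-7)])
}

# Wilson score interval endpoints found by root-finding on the score
# equation |phat - p| = z * sqrt(p (1 - p) / n), then mapped to the
# log-odds scale; returns the half-width-based standard error.
oracleWilsonLogitSE <- function(alt, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  ph <- alt / n
  g <- function(p) (ph - p)^2 - z^2 * p * (1 - p) / n
  lo <- uniroot(g, c(1e-12, ph), tol = 1e-12)$root
  hi <- uniroot(g, c(ph, 1 - 1e-12), tol = 1e-12)$root
  (qlogis(hi) - qlogis(lo)) / (2 * z)
}

# Beta-binomial pmf by numerical integration of the binomial pmf
# against the Beta mixing density.
oracleBBQuadrature <- function(x, size, p0, rho) {
  a <- p0 * (1 - rho) / rho
  b <- (1 - p0) * (1 - rho) / rho
  integrate(function(th) dbinom(x, size, th) * dbeta(th, a, b),
            0, 1, rel.tol = 1e-12)$value
}

# Static per-variant statistic recomputed naively: pseudo-counts, log
# odds, Wilson-based se by root finding.
oracleStaticStat <- function(ref, alt) {
  if (ref == 0L || alt == 0L) { ref <- ref + 1L; alt <- alt + 1L }
  abs(log(alt / ref)) / oracleWilsonLogitSE(alt, alt + ref)
}

# Brute-force binomial-resampling implementation of the static
# gene-level pipeline for a fixed depth and binomial null (rho = 0):
# plain loops, independent statistic code, add-one empirical p.
oracleStaticGenePipeline <- function(countsDf, depth, p0, N) {
  ks <- sort(unique(table(countsDf$gene_id)))
  nulls <- list()
  for (k in ks) {
    vals <- numeric(N)
    for (i in seq_len(N)) {
      s <- 0
      for (j in seq_len(k)) {
        a <- rbinom(1L, depth, p0)
        s <- s + oracleStaticStat(depth - a, a)
      }
      vals[i] <- s / sqrt(k)
    }
    nulls[[as.character(k)]] <- vals
  }
  genes <- unique(countsDf$gene_id)
  p <- numeric(length(genes))
  for (gi in seq_along(genes)) {
    rows <- countsDf[countsDf$gene_id == genes[gi], ]
    stat <- sum(mapply(oracleStaticStat, rows$ref_count, rows$alt_count)) /
      sqrt(nrow(rows))
    nv <- nulls[[as.character(nrow(rows))]]
    p[gi] <- (1 + sum(nv >= stat)) / (N + 1)
  }
  data.frame(gene_id = genes, p_value = p, stringsAsFactors = FALSE)
}

# Small valid static count data.frame used across io tests.
makeStaticDf <- function(n = 3L, sample = "s1") {
  data.frame(sample_id = sample,
             variant_id = paste0("rs", seq_len(n)),
             gene_id = paste0("g", rep_len(1:2, n)),
             ref_count = seq_len(n) + 4L,
             alt_count = rev(seq_len(n) + 2L),
             stringsAsFactors = FALSE)
}

makeIcdDf <- function(n = 3L, sample = "s1") {
  data.frame(sample_id = sample,
             variant_id = paste0("rs", seq_len(n)),
             gene_id = paste0("g", rep_len(1:2, n)),
             ref_count_U = seq_len(n) + 10L,
             alt_count_U = seq_len(n) + 8L,
             ref_count_T = seq_len(n) + 20L,
             alt_count_T = seq_len(n) + 3L,
             stringsAsFactors = FALSE)
}
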