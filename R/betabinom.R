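.checkBBPar <- function(p0, rho) {
  if (length(p0) != 1L || !is.finite(p0) || p0 <= 0 || p0 >= 1)
    stop("p0 must lie strictly in (0, 1)")
  if (length(rho) != 1L || !is.finite(rho) || rho < 0 || rho >= 1)
    stop("rho must lie in [0, 1)")
}

# Intraclass-correlation parameterization: alpha + beta = (1 - rho) / rho,
# so rho -> 0 is the binomial limit.
.bbShapes <- function(p0, rho) {
  p0 <- unname(p0); rho <- unname(rho)
  s <- (1 - rho) / rho
  c(alpha = p0 * s, beta = (1 - p0) * s)
}

#' Beta-binomial probability mass function
#'
#' Density of the beta-binomial distribution parameterized by its mean
#' allele fraction `p0` and intraclass-correlation overdispersion `rho`
#' (shape parameters \eqn{\alpha = p_0(1-\rho)/\rho},
#' \eqn{\beta = (1-p_0)(1-\rho)/\rho}). `rho = 0` gives the ordinary
#' binomial pmf.
#'
#' @param x Number of successes (alternative-allele reads).
#' @param size Number of trials (total read depth). Recycled against `x`.
#' @param p0 Mean success probability in (0, 1).
#' @param rho Overdispersion in [0, 1).
#' @param log Return log-density?
#' @return Numeric vector of (log-)probabilities.
#' @examples
#' dBetaBinom(0:10, 10, 0.5, 0)    # == dbinom(0:10, 10, 0.5)
#' dBetaBinom(0:10, 10, 0.5, 0.22)
#' @export
dBetaBinom <- function(x, size, p0, rho, log = FALSE) {
  .checkBBPar(p0, rho)
  if (rho == 0) return(stats::dbinom(x, size, p0, log = log))
  sh <- .bbShapes(p0, rho)
  if (length(size) < length(x)) size <- rep_len(size, length(x))
  if (length(x) < length(size)) x <- rep_len(x, length(size))
  lp <- lchoose(size, x) + lbeta(x + sh[["alpha"]], size - x + sh[["beta"]]) -
    lbeta(sh[["alpha"]], sh[["beta"]])
  out <- x < 0 | x > size | x != round(x)
  lp[out] <- -Inf
  if (log) lp else exp(lp)
}

#' Draw beta-binomial allele counts
#'
#' Samples alternative-allele counts by drawing a per-observation success
#' probability \eqn{\theta \sim Beta(\alpha, \beta)} and then a count
#' \eqn{\sim Binomial(size, \theta)}; at `rho = 0` it reduces to direct
#' binomial sampling. Reproducible under `set.seed()`.
#'
#' @param n Number of draws.
#' @param size Read depth(s), recycled to length `n`; all must be >= 1.
#' @param p0 Mean success probability in (0, 1).
#' @param rho Overdispersion in [0, 1).
#' @return Integer vector of `n` counts in `[0, size]`.
#' @examples
#' set.seed(1)
#' rBetaBinom(5, 50, 0.5, 0.22)
#' @export
rBetaBinom <- function(n, size, p0, rho) {
  .checkBBPar(p0, rho)
  size <- rep_len(as.integer(size), n)
  if (any(size < 1)) stop("all depths must be >= 1")
  if (rho == 0) return(stats::rbinom(n, size, p0))
  sh <- .bbShapes(p0, rho)
  theta <- stats::rbeta(n, sh[["alpha"]], sh[["beta"]])
  stats::rbinom(n, size, theta)
}

#' Beta-binomial log-likelihood of DNA allele counts
#'
#' @param ref,alt Integer vectors of reference/alternative allele counts
#'   (paired).
#' @param p0 Mean allele fraction in (0, 1).
#' @param rho Overdispersion in [0, 1); `rho = 0` gives the exact
#'   binomial log-likelihood.
#' @return The summed log-likelihood.
#' @export
betaBinomLogLik <- function(ref, alt, p0, rho) {
  if (length(ref) != length(alt)) stop("ref and alt must have equal length")
  sum(dBetaBinom(alt, ref + alt, p0, rho, log = TRUE))
}

# Method-of-moments start for (p0, rho): plug-in from the spread of
# per-site allele fractions around the pooled mean.
.bbMoments <- function(ref, alt) {
  n <- ref + alt
  z <- alt / n
  p <- sum(alt) / sum(n)
  p <- min(max(p, 1e-4), 1 - 1e-4)
  w <- mean(1 / n)
  v <- stats::var(z)
  rho <- (v / (p * (1 - p)) - w) / (1 - w)
  if (!is.finite(rho)) rho <- 0.01
  rho <- min(max(rho, 1e-4), 0.9)
  c(p0 = p, rho = rho)
}

#' Fit the variant-level beta-binomial null model
#'
#' Maximum-likelihood fit of \eqn{BB(p^0, \rho^0)} to DNA allele counts
#' at heterozygous sites, on the logit scale for both parameters with a
#' method-of-moments start. Sites below `minDepth` total reads are
#' excluded before fitting. If the binomial boundary (\eqn{\rho = 0},
#' with \eqn{\hat p} the pooled fraction) attains at least the interior
#' optimum's likelihood, the boundary fit is returned.
#'
#' @param dna A `data.frame` with integer columns `ref_count` and
#'   `alt_count` (as from [readDnaCounts()] or [simulateDnaCounts()]),
#'   or a two-column matrix (ref, alt).
#' @param minDepth Minimum total depth per site (default 10).
#' @param minSites Minimum number of usable sites (default 50).
#' @return A [BetaBinomNull-class].
#' @examples
#' set.seed(7)
#' dna <- simulateDnaCounts(2000, depth = 50, p0 = 0.5, rho = 0.22)
#' fitBetaBinomNull(dna)
#' @export
fitBetaBinomNull <- function(dna, minDepth = 10, minSites = 50) {
  dna <- as.data.frame(dna)
  if (is.null(dna$ref_count)) names(dna)[1:2] <- c("ref_count", "alt_count")
  ref <- as.integer(dna$ref_count)
  alt <- as.integer(dna$alt_count)
  keep <- (ref + alt) >= minDepth
  ref <- ref[keep]; alt <- alt[keep]
  if (length(ref) < minSites)
    stop("need at least ", minSites, " DNA sites with depth >= ", minDepth,
         " to fit the null model (got ", length(ref), ")")
  start <- .bbMoments(ref, alt)
  startLL <- betaBinomLogLik(ref, alt, start[["p0"]], start[["rho"]])
  negll <- function(par) {
    p0 <- stats::plogis(par[1L])
    rho <- stats::plogis(par[2L])
    -betaBinomLogLik(ref, alt, p0, rho)
  }
  opt <- stats::optim(stats::qlogis(start), negll, method = "Nelder-Mead",
                      control = list(maxit = 500L))
  p0 <- stats::plogis(opt$par[1L])
  rho <- stats::plogis(opt$par[2L])
  ll <- -opt$value
  # binomial boundary: rho = 0 with the pooled MLE of p
  pBin <- min(max(sum(alt) / sum(ref + alt), 1e-6), 1 - 1e-6)
  llBin <- betaBinomLogLik(ref, alt, pBin, 0)
  if (llBin >= ll) {
    p0 <- pBin; rho <- 0; ll <- llBin
  }
  if (ll < startLL - 1e-6)
    stop("beta-binomial fit failed to improve on the moments start ",
         "(p0 = ", signif(start[["p0"]], 4), ", rho = ",
         signif(start[["rho"]], 4), ")")
  BetaBinomNull(p0, rho, nSites = length(ref), logLik = ll)
}
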