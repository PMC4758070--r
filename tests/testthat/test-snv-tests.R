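test_that("static effect size measures deviation from allelic balance", {
  expect_identical(staticEffectSize(5, 5), 0)
  expect_identical(staticEffectSize(0, 10), 0.5)
  expect_identical(staticEffectSize(1, 3), 0.25)
  expect_error(staticEffectSize(0, 0), "zero total depth")
})

test_that("static effect size is allele-swap symmetric and scale invariant", {
  set.seed(11)
  for (i in 1:50) {
    a <- sample(0:40, 1L); b <- sample(0:40, 1L)
    if (a + b == 0) a <- 1L
    expect_equal(staticEffectSize(a, b), staticEffectSize(b, a))
    m <- sample(2:5, 1L)
    expect_equal(staticEffectSize(m * a, m * b), staticEffectSize(a, b))
  }
})

test_that("icd effect size is the log2 odds-ratio between conditions", {
  expect_equal(icdEffectSize(4, 4, 7, 7), 0)
  expect_equal(icdEffectSize(8, 2, 2, 8), 4)
  # zero cell: pseudo-counts first, then log2(6/1 / 1) on T=(6,1), U=(6,6)
  expect_error(icdEffectSize(5, 0, 5, 5), "zero cell")
  aug <- addPseudocounts(5, 0, 5, 5)
  expect_equal(icdEffectSize(aug$altT, aug$refT, aug$altU, aug$refU),
               log2(6), tolerance = 1e-12)
})

test_that("modified binomial test matches exact enumeration and is symmetric", {
  expect_equal(modifiedBinomTest(5, 5), 1)
  expect_equal(modifiedBinomTest(10, 0), 2 * 0.5^10)
  expect_equal(modifiedBinomTest(2, 8, 0.8), 1)
  expect_error(modifiedBinomTest(0, 0), "zero total depth")

  for (n in c(3L, 10L, 17L)) {
    for (alt in 0:n) {
      for (b in c(0.3, 0.5, 0.8)) {
        expect_equal(modifiedBinomTest(n - alt, alt, b),
                     oracleBinomTwoSided(alt, n, b), tolerance = 1e-12)
      }
      expect_equal(modifiedBinomTest(n - alt, alt, 0.5),
                   modifiedBinomTest(alt, n - alt, 0.5))
    }
  }
})

test_that("Fisher's exact icd test matches hypergeometric enumeration", {
  expect_equal(fisherExactIcd(5, 5, 5, 5), 1)
  expect_equal(fisherExactIcd(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(fisherExactIcd(3, 1, 1, 3), 34 / 70, tolerance = 1e-12)
  expect_error(fisherExactIcd(0, 0, 5, 5), "degenerate margin")

  set.seed(21)
  for (i in 1:60) {
    cells <- as.integer(rmultinom(1, sample(4:30, 1L), rep(0.25, 4)))
    if (cells[1] + cells[2] == 0 || cells[3] + cells[4] == 0) next
    expect_equal(fisherExactIcd(cells[1], cells[2], cells[3], cells[4]),
                 oracleFisher2x2(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-9)
  }
})

test_that("BH adjustment is monotone, order-preserving and exceeds input", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bhAdjust(0.4), 0.4)
  expect_identical(bhAdjust(numeric(0)), numeric(0))
  set.seed(31)
  p <- runif(40)
  q <- bhAdjust(p)
  expect_true(all(q >= p))
  perm <- sample.int(40)
  expect_equal(bhAdjust(p[perm]), q[perm])
})

test_that("within-gene SNR flags consistent condition-dependent genes", {
  r <- geneSnr(c(2, 2, 2))
  expect_identical(r$snr, Inf)
  expect_true(r$consistent)
  r2 <- geneSnr(c(1, 3))
  expect_equal(r2$snr, 2 / sqrt(2), tolerance = 1e-12)
  expect_false(r2$consistent)
  expect_error(geneSnr(0.8), "at least two")
})

test_that("sustained effects require the threshold in two or more individuals", {
  eff <- data.frame(
    variant_id = c("v1", "v1", "v2", "v3", "v3"),
    sample_id  = c("i1", "i2", "i1", "i1", "i2"),
    delta_ase  = c(0.8, 0.8, 0.8, 0.3, 0.9))
  got <- sustainedEffectVariants(eff, threshold = 0.61)
  expect_identical(got$variants, "v1")  # v2 one individual, v3 once over

  # percentile-derived threshold: 90th of ten equally spaced values
  got2 <- sustainedEffectVariants(eff, percentileOf = seq(0.1, 1, by = 0.1))
  expect_equal(got2$threshold, 0.91, tolerance = 1e-12)
})

test_that("per-variant test runner adjusts within sample and honours null ratios", {
  df <- data.frame(sample_id = rep(c("s1", "s2"), each = 2L),
                   variant_id = c("v1", "v2", "v1", "v2"),
                   gene_id = "g",
                   ref_count = c(20L, 5L, 18L, 2L),
                   alt_count = c(2L, 6L, 2L, 18L),
                   null_ratio = c(0.5, 0.5, 0.1, 0.5))
  res <- snvAseTest(AseCountTable(df, "static"))
  expect_equal(res$p_value[3],
               oracleBinomTwoSided(2L, 20L, 0.1), tolerance = 1e-12)
  for (s in c("s1", "s2")) {
    idx <- res$sample_id == s
    expect_equal(res$p_adjusted[idx], bhAdjust(res$p_value[idx]))
  }

  icd <- makeIcdDf(3L)
  resIcd <- snvAseTest(AseCountTable(icd, "icd"))
  expect_equal(resIcd$p_value[1],
               oracleFisher2x2(icd$alt_count_T[1], icd$ref_count_T[1],
                               icd$alt_count_U[1], icd$ref_count_U[1]),
               tolerance = 1e-9)
})
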