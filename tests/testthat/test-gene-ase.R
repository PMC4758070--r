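test_that("pseudo-counts are added to every cell only when a zero is present", {
  expect_equal(addPseudocounts(5, 0, 3, 2),
               list(altT = 6, refT = 1, altU = 4, refU = 3))
  expect_equal(addPseudocounts(5, 2, 3, 2),
               list(altT = 5, refT = 2, altU = 3, refU = 2))
  expect_equal(addPseudocounts(0, 7), list(alt = 1, ref = 8))
  # vectorised: only the zero-bearing row is bumped
  got <- addPseudocounts(c(5, 5), c(0, 2))
  expect_equal(got$alt, c(6, 5))
  expect_equal(got$ref, c(1, 2))
})

test_that("static per-variant statistic is symmetric with a Wilson-based se", {
  expect_equal(snvStatStatic(5, 5)$statistic, 0)
  set.seed(51)
  for (i in 1:25) {
    a <- sample(1:60, 1L); b <- sample(1:60, 1L)
    expect_equal(snvStatStatic(a, b)$statistic, snvStatStatic(b, a)$statistic)
  }
  got <- snvStatStatic(2, 8)
  expect_equal(got$effect, log(4), tolerance = 1e-12)
  expect_equal(got$se, oracleWilsonLogitSE(8, 10), tolerance = 1e-9)
  expect_equal(got$statistic, log(4) / oracleWilsonLogitSE(8, 10),
               tolerance = 1e-9)
  # delta-method alternative
  expect_equal(snvStatStatic(2, 8, seMethod = "delta")$se,
               sqrt(1 / 8 + 1 / 2))
})

test_that("icd per-variant statistic uses Woolf's se on the log odds-ratio", {
  expect_equal(snvStatIcd(4, 4, 7, 7)$statistic, 0)
  got <- snvStatIcd(8, 2, 2, 8)
  expect_equal(got$effect, log(16), tolerance = 1e-12)
  expect_equal(got$se, sqrt(1 / 8 + 1 / 2 + 1 / 2 + 1 / 8), tolerance = 1e-12)
  expect_equal(got$statistic, 2.4800, tolerance = 1e-4)
  expect_equal(snvStatIcd(2, 8, 8, 2)$statistic, got$statistic)  # T/U swap
})

test_that("Stouffer combination scales by the root of the variant count", {
  expect_equal(stoufferCombine(1.7), 1.7)
  expect_equal(stoufferCombine(rep(2, 4)), 4)
  expect_equal(stoufferCombine(c(1, 3)), 4 / sqrt(2), tolerance = 1e-12)
  expect_error(stoufferCombine(numeric(0)), "empty")
  expect_error(stoufferCombine(c(1, Inf)), "finite")
})

test_that("resampled null distributions are reproducible and well-formed", {
  null <- BetaBinomNull(0.5, 0.22)
  set.seed(61); n1 <- buildNullDistribution(3, 50L, null, 2000, "icd")
  set.seed(61); n2 <- buildNullDistribution(3, 50L, null, 2000, "icd")
  expect_identical(n1@values, n2@values)
  expect_length(n1@values, 2000L)
  expect_true(all(n1@values >= 0))
  expect_error(buildNullDistribution(2, integer(0), null, 2000, "static"),
               "empty depth pool")
  expect_error(buildNullDistribution(2, 50L, null, 500, "static"),
               "at least 1000")
})

test_that("binomial-limit null matches a brute-force resampling oracle", {
  null <- BetaBinomNull(0.5, 0)
  set.seed(62)
  nd <- buildNullDistribution(1, 50L, null, 1e4, "static")
  set.seed(63)
  oracle <- vapply(rbinom(1e4, 50, 0.5), function(a)
    oracleStaticStat(50L - a, a), numeric(1))
  # both samples live on the same discrete atoms; round away float noise
  # (~1e-12) so the ECDFs are compared at matching atoms
  ks <- suppressWarnings(ks.test(round(nd@values, 8), round(oracle, 8)))
  expect_gt(ks$p.value, 0.01)
})

test_that("conservative empirical p-values follow the add-one convention", {
  expect_equal(empiricalPValue(2, c(0.5, 1, 3), ties = "conservative"), 0.5)
  nullv <- seq_len(9999) / 100
  cons <- function(o) empiricalPValue(o, nullv, ties = "conservative")
  expect_equal(cons(1e6), 1e-4)                         # above all
  expect_equal(cons(-1), 1)                             # below all
  expect_equal(cons(nullv[5000]), (1 + 5000) / 10000)   # tie counts as extreme
  set.seed(64)
  nv <- rexp(10000)
  obs <- c(0.2, 1, 4)
  expect_equal(empiricalPValue(obs, nv, ties = "conservative"),
               vapply(obs, function(o) (1 + sum(nv >= o)) / 10001, numeric(1)))
})

test_that("randomized empirical p-values are exactly uniform on a discrete statistic", {
  # observed and null drawn from the same coarse distribution: the
  # conservative rule is visibly sub-uniform, the randomized rule is not
  set.seed(65)
  nullv <- rbinom(10000, 8, 0.5)
  obs <- rbinom(2000, 8, 0.5)
  pc <- empiricalPValue(obs, nullv, ties = "conservative")
  pr <- empiricalPValue(obs, nullv, ties = "random")
  expect_lt(suppressWarnings(ks.test(pc, "punif"))$p.value, 0.01)
  expect_gt(suppressWarnings(ks.test(pr, "punif"))$p.value, 0.01)
  expect_true(all(pr > 0 & pr <= 1))
})

test_that("gene test enforces the minimum-variant pre-filter", {
  df <- rbind(makeStaticDf(4L),
              data.frame(sample_id = "s1", variant_id = "solo",
                         gene_id = "lonely", ref_count = 10L,
                         alt_count = 30L))
  x <- AseCountTable(df, "static")
  set.seed(71)
  res <- runGeneAse(x, BetaBinomNull(0.5, 0), nSamples = 1000)
  expect_false("lonely" %in% geneResults(res)$gene_id)
  set.seed(71)
  res1 <- runGeneAse(x, BetaBinomNull(0.5, 0), nSamples = 1000,
                     minVariants = 1)
  expect_true("lonely" %in% geneResults(res1)$gene_id)
  expect_error(runGeneAse(x, "not a null"), "BetaBinomNull")
})

test_that("single-variant gene p-value equals the variant-level empirical p", {
  df <- data.frame(sample_id = "s", variant_id = paste0("v", 1:3),
                   gene_id = paste0("g", 1:3),
                   ref_count = c(30L, 10L, 25L), alt_count = c(20L, 40L, 25L))
  x <- AseCountTable(df, "static")
  null <- BetaBinomNull(0.5, 0.1)
  set.seed(72)
  res <- geneResults(runGeneAse(x, null, nSamples = 2000, minVariants = 1,
                                ties = "conservative"))
  set.seed(72)
  nd <- buildNullDistribution(1, df$ref_count + df$alt_count, null,
                              2000, "static")
  stat <- snvStatStatic(df$ref_count, df$alt_count)$statistic
  expected <- empiricalPValue(stat, nd, ties = "conservative")
  got <- res$p_value[match(df$gene_id, res$gene_id)]
  expect_equal(got, expected)
})

test_that("genes beyond the k cap share an aggregated null", {
  set.seed(73)
  sim <- simulateAseData(simScenario("static", nGenes = 6, kPool = c(4L, 6L),
                                     depth = 40, effect = 0, rho = 0,
                                     nullFraction = 1))
  res <- runGeneAse(sim$counts, BetaBinomNull(0.5, 0), nSamples = 1000,
                    kCap = 3L)
  df <- geneResults(res)
  expect_true(all(df$k %in% c(4L, 6L)))
  expect_true(all(df$p_value > 0 & df$p_value <= 1))
})

test_that("BH adjustment is applied within each sample", {
  set.seed(74)
  one <- makeStaticDf(6L, sample = "s1")
  two <- makeStaticDf(6L, sample = "s2")
  two$alt_count <- two$alt_count + 20L
  x <- AseCountTable(rbind(one, two), "static")
  res <- geneResults(runGeneAse(x, BetaBinomNull(0.5, 0), nSamples = 1000))
  for (s in c("s1", "s2")) {
    idx <- res$sample_id == s
    expect_equal(res$p_adjusted[idx], bhAdjust(res$p_value[idx]))
  }
})

test_that("static gate admits genes with weak evidence in either condition", {
  u <- data.frame(sample_id = "sU", gene_id = c("g1", "g2", "g3"),
                  k = 2L, statistic = 1,
                  p_value = c(0.15, 0.25, 0.20), p_adjusted = 1)
  t <- data.frame(sample_id = "sT", gene_id = c("g1", "g2", "g3"),
                  k = 2L, statistic = 1,
                  p_value = c(0.90, 0.30, 0.90), p_adjusted = 1)
  expect_identical(cdGate(u, t), c("g1", "g3"))  # 0.2 inclusive, g2 out
})

test_that("gene-level power rises with effect size", {
  null <- BetaBinomNull(0.5, 0)
  powerAt <- function(effect, seed) {
    set.seed(seed)
    sim <- simulateAseData(simScenario("static", nGenes = 120, kPool = 2,
                                       depth = 50, effect = effect, rho = 0,
                                       nullFraction = 0))
    res <- geneResults(runGeneAse(sim$counts, null, nSamples = 2000))
    mean(res$p_value < 0.05)
  }
  p <- vapply(c(0, 0.15, 0.3), powerAt, numeric(1), seed = 75)
  expect_lt(p[1], 0.12)          # near the nominal level under the null
  expect_gt(p[2], p[1])          # monotone within simulation error
  expect_gt(p[3], 0.95)          # strong effects are essentially always seen
})
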