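test_that("DNA simulator round-trips through the null-model fit", {
  set.seed(91)
  dna <- simulateDnaCounts(3000, depth = 50, p0 = 0.5, rho = 0)
  expect_equal(mean(dna$alt_count / (dna$alt_count + dna$ref_count)), 0.5,
               tolerance = 0.01)
  set.seed(91); a <- simulateDnaCounts(100, 50, 0.5, 0.22)
  set.seed(91); b <- simulateDnaCounts(100, 50, 0.5, 0.22)
  expect_identical(a, b)
})

test_that("static gene generator shares one sign and hits the target mean", {
  set.seed(92)
  g <- simulateStaticGene(2000L, depth = 1000L, effect = 0.3, rho = 0)
  frac <- mean(g$alt_count / (g$alt_count + g$ref_count))
  expect_true(abs(frac - 0.8) < 0.01 || abs(frac - 0.2) < 0.01)
  expect_error(simulateStaticGene(5, 50, 0.5, 0), "\\[0, 0.5\\)")

  # at high depth every variant of a gene leans the same way
  set.seed(93)
  g2 <- simulateStaticGene(20L, depth = 500L, effect = 0.25, rho = 0)
  side <- g2$alt_count / (g2$alt_count + g2$ref_count) > 0.5
  expect_true(all(side) || all(!side))
})

test_that("icd generator applies the odds-ratio to the latent baseline", {
  set.seed(94)
  g <- simulateIcdGene(4000L, depth = 500L, oddsRatio = 16, rho = 0)
  pU <- mean(g$alt_count_U / (g$alt_count_U + g$ref_count_U))
  pT <- mean(g$alt_count_T / (g$alt_count_T + g$ref_count_T))
  expect_equal(pU, 0.5, tolerance = 0.01)
  expect_true(abs(pT - 16 / 17) < 0.01 || abs(pT - 1 / 17) < 0.01)
  expect_error(simulateIcdGene(5, 50, 0.5, 0), ">= 1")

  # OR = 1 leaves both conditions at the shared latent fraction
  set.seed(95)
  h <- simulateIcdGene(5000L, depth = 200L, oddsRatio = 1, rho = 0.22)
  dASE <- abs(log2((h$alt_count_T + 1) / (h$ref_count_T + 1)) -
              log2((h$alt_count_U + 1) / (h$ref_count_U + 1)))
  expect_lt(median(dASE), 0.5)
})

test_that("zero effect reduces the generators to the null distribution", {
  set.seed(96)
  nullG <- simulateAseData(simScenario("static", nGenes = 300, kPool = 1,
                                       depth = 80, effect = 0, rho = 0.1,
                                       nullFraction = 1))
  effG <- simulateAseData(simScenario("static", nGenes = 300, kPool = 1,
                                      depth = 80, effect = 0, rho = 0.1,
                                      nullFraction = 0))
  fN <- with(aseCounts(nullG$counts), alt_count / (alt_count + ref_count))
  fE <- with(aseCounts(effG$counts), alt_count / (alt_count + ref_count))
  expect_gt(suppressWarnings(ks.test(fN, fE))$p.value, 0.01)
  expect_true(all(!nullG$truth$is_ase))
})

test_that("mapping-bias perturbation shifts counts as documented", {
  df <- data.frame(sample_id = "s", variant_id = c("v1", "v2"),
                   gene_id = "g", ref_count = c(10L, 3L),
                   alt_count = c(10L, 1L))
  x <- AseCountTable(df, "static")
  same <- perturbMappingBias(x, 0)
  expect_identical(aseCounts(same)$ref_count, df$ref_count)
  pert <- aseCounts(perturbMappingBias(x, 0.1))
  expect_identical(pert$ref_count, c(11L, 3L))
  expect_identical(pert$alt_count, c(9L, 1L))
  expect_true(all(pert$alt_count >= 0L))
  expect_error(perturbMappingBias(x, 1), "biasFraction")
})

test_that("variant-level FDR experiment labels and reports correctly", {
  set.seed(97)
  r <- runSnvFdr("icd", depth = 100, effect = 8, rho = 0,
                 nNullVariants = 400, nAltVariants = 100)
  expect_true(r$nCalled > 0)
  expect_lt(r$fdr, 0.2)
  set.seed(97)
  r2 <- runSnvFdr("icd", depth = 100, effect = 8, rho = 0,
                  nNullVariants = 400, nAltVariants = 100)
  expect_identical(r, r2)  # deterministic under a fixed seed

  # an all-null mix with nothing called reports NA
  set.seed(98)
  rn <- runSnvFdr("static", depth = 20, effect = 0, rho = 0,
                  nNullVariants = 50, nAltVariants = 0)
  expect_true(is.na(rn$fdr) || rn$fdr == 1)
})

test_that("ROC separates signal from noise and degenerates at zero effect", {
  set.seed(99)
  roc <- runRoc("static", effects = c(0, 0.3), depth = 50, rho = 0,
                nGenesPerEffect = 100, k = 2, nSamples = 2000,
                null = BetaBinomNull(0.5, 0))
  expect_lt(abs(roc$auc_gene[1] - 0.5), 0.12)
  expect_gt(roc$auc_gene[2], 0.9)
  expect_gt(roc$auc_naive[2], 0.8)  # the comparator also sees strong signal
  expect_gt(roc$auc_gene[2], roc$auc_gene[1])
})
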