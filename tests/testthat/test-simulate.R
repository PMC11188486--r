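test_that("population mixing follows the convex-combination model", {
  t1 <- TemplateProfile(c("a", "b"), c(0.8, 0.2))
  t2 <- TemplateProfile(c("a", "b"), c(0.2, 0.8))
  # ep = 0: training population collapses onto the testing one
  mix0 <- mixPopulations(t1, t2, 0)
  expect_equal(mix0$v1, mix0$v2)
  # ep = 1: training population is template 1
  mix1 <- mixPopulations(t1, t2, 1)
  expect_equal(unname(mix1$v1), c(0.8, 0.2))
  # halfway mixture, hand-computed
  expect_equal(unname(mixPopulations(t1, t2, 0.5)$v1), c(0.5, 0.5))
  expect_error(mixPopulations(t1, t2, 1.2), "\\[0, 1\\]")
  # depth-weighted templates are normalized before mixing
  t1b <- TemplateProfile(c("a", "b"), c(80, 20))
  expect_equal(mixPopulations(t1b, t2, 1)$v1, mix1$v1)
})

test_that("Dirichlet draws are proper compositions calibrated to v", {
  v <- c(a = 0.3, b = 0.7)
  probs <- drawSampleProbs(v, c = 1e6, n = 5000, seed = 3)
  expect_true(all(abs(colSums(probs) - 1) < 1e-12))
  expect_true(all(abs(rowMeans(probs) - v) < 0.005))
  # huge concentration: essentially no sample-to-sample variation
  tight <- drawSampleProbs(v, c = 1e12, n = 10, seed = 4)
  expect_true(all(abs(tight - v) < 1e-4))
  # spread shrinks like 1/sqrt(c) between c = 1e3 and c = 1e6
  s3 <- sd(drawSampleProbs(v, 1e3, 2000, seed = 5)[1, ])
  s6 <- sd(drawSampleProbs(v, 1e6, 2000, seed = 6)[1, ])
  expect_equal(s3 / s6, sqrt(1e6 / 1e3), tolerance = 0.15)
  expect_error(drawSampleProbs(c(0.5, 0.5, 0), 1e6, 5), "floorZeros")
})

test_that("multinomial sampling conserves the library size exactly", {
  v <- floorZeros(c(a = 0.2, b = 0.3, c = 0.5, d = 0))
  probs <- drawSampleProbs(v, 1e6, 20, seed = 1)
  tab <- drawCounts(probs, librarySize = 1e6, seed = 2)
  expect_true(all(colSums(counts(tab)) == 1e6))

  # degenerate composition puts every read on taxon 1
  deg <- matrix(c(1, 0, 0), 3, 2, dimnames = list(letters[1:3], c("s1", "s2")))
  expect_equal(unname(counts(drawCounts(deg, 1000, seed = 1))[1, ]), c(1000, 1000))

  # binomial accuracy at library 1e6 over 500 samples
  half <- drawSampleProbs(c(x = 0.5, y = 0.5), 1e12, 500, seed = 3)
  cnt <- counts(drawCounts(half, 1e6, seed = 4))
  expect_true(all(abs(cnt[1, ] / 1e6 - 0.5) < 0.002))
  expect_error(drawCounts(deg, 0), "at least 1")
})

test_that("signature selection respects the coefficient bounds and is fixed by seed", {
  taxa <- paste0("t", 1:40)
  m1 <- selectSignature(taxa, "linear", seed = 11)
  m2 <- selectSignature(taxa, "linear", seed = 11)
  expect_identical(m1@signature, m2@signature)
  expect_identical(m1@beta, m2@beta)
  expect_true(all(m1@beta[1:5] >= 3 & m1@beta[1:5] <= 5))
  expect_true(all(m1@beta[6:10] >= -5 & m1@beta[6:10] <= -3))
  # forced choice when exactly 10 taxa are available
  expect_setequal(selectSignature(taxa[1:10], seed = 1)@signature, taxa[1:10])
  expect_error(selectSignature(taxa[1:9]), "at least 10")
})

test_that("the four phenotype links evaluate to their closed forms", {
  # abundances placed so that beta' x = 2 (positive half at 0.1, negative at 0)
  x <- matrix(c(rep(0.1, 5), rep(0, 5)), 10, 1)
  lin <- makeModel("linear", scale = 10)
  expect_equal(as.numeric(simulatePhenotype(x, lin)), 20)
  quad <- makeModel("quadratic", scale = 10)
  expect_equal(as.numeric(simulatePhenotype(x, quad)), 10 * 5 * 4 * 0.01)
  inv <- makeModel("inverse", scale = 10)
  expect_equal(as.numeric(simulatePhenotype(x, inv)), 5)
  # beta' x = 0 gives the logistic midpoint c4 / 2
  x0 <- matrix(0, 10, 1)
  logi <- makeModel("logistic", scale = 4)
  expect_equal(as.numeric(simulatePhenotype(x0, logi)), 2)
  # with noise off the phenotype is a deterministic function of x
  expect_equal(simulatePhenotype(x, lin, seed = 1),
               simulatePhenotype(x, lin, seed = 99))
})

test_that("scale calibration hits the target phenotype magnitude", {
  tpl <- baselineVector(synthesizeTemplate(60, 15, seed = 2))
  v <- floorZeros(profileAbundance(tpl) / sum(profileAbundance(tpl)))
  for (rel in c("linear", "quadratic", "inverse", "logistic")) {
    model <- selectSignature(names(v)[v > 1e-6], rel, seed = 3, noiseSD = 0)
    model <- calibrateScaleConstant(v, model, 1e6, seed = 4)
    probs <- drawSampleProbs(v, 1e6, 300, seed = 5)
    y <- simulatePhenotype(probs[model@signature, ], model, seed = 6)
    expect_equal(mean(abs(y)), 50, tolerance = 0.1)
  }
})

test_that("batch hyperparameters solve the moment-matching equations", {
  b2 <- solveBatchHyperparams(500, 2)
  expect_equal(b2@deltaAlpha, 402)
  expect_equal(b2@deltaBeta, 802)
  expect_equal(b2@gammaMu, 500)
  expect_equal(b2@gammaVar, 0.01)
  b1 <- solveBatchHyperparams(0, 1)
  expect_equal(b1@deltaAlpha, 102)
  expect_equal(b1@deltaBeta, 101)
  expect_error(solveBatchHyperparams(0, -1), "positive")

  # sampled moments recover the severity pair and the 0.01 hyperprior variance
  par <- sampleBatchParams(solveBatchHyperparams(1000, 2), 1e5, seed = 8)
  expect_equal(mean(par$gamma), 1000, tolerance = 0.01)
  expect_equal(var(par$gamma), 0.01, tolerance = 0.05)
  expect_equal(mean(par$delta), 2, tolerance = 0.01)
  expect_equal(var(par$delta), 0.01, tolerance = 0.05)
})

test_that("batch corruption implements the location-scale update", {
  tab <- PhenoCounts(makeCounts(100, 40, seed = 9, lambda = 200))
  # identity limit: no mean shift, unit variance inflation, vanishing spread
  ident <- solveBatchHyperparams(0, 1, hyperVar = 1e-12)
  out <- applyBatchEffects(tab, ident, seed = 1)
  expect_lte(max(abs(counts(out) - counts(tab))), 1)

  # a chosen taxon's transformed values match a loop oracle exactly
  spec <- solveBatchHyperparams(500, 2)
  par <- sampleBatchParams(spec, nrow(counts(tab)), seed = 21)
  out2 <- applyBatchEffects(tab, spec, seed = 21)
  i <- 7
  mi <- mean(counts(tab)[i, ])
  oracle <- vapply(seq_len(ncol(tab)), function(j) {
    round(max(0, (counts(tab)[i, j] - mi) * sqrt(par$delta[i]) + mi +
                par$gamma[i]))
  }, numeric(1))
  expect_equal(unname(counts(out2)[i, ]), oracle)

  # sev_var = 4 inflates per-taxon variances about fourfold (dense table so
  # the clip at zero stays inactive)
  dense <- PhenoCounts(makeCounts(100, 60, seed = 10, lambda = 500,
                                  zeroProb = 0))
  infl <- solveBatchHyperparams(0, 4)
  out4 <- applyBatchEffects(dense, infl, seed = 5)
  v0 <- apply(counts(dense), 1, var)
  v4 <- apply(counts(out4), 1, var)
  expect_equal(median(v4 / v0), 4, tolerance = 0.25)
})

test_that("scenario generators honour the study-pair contracts", {
  t1 <- baselineVector(synthesizeTemplate(50, 10, seed = 31))
  t2 <- baselineVector(synthesizeTemplate(60, 10, seed = 32))
  sp1 <- simulateScenario1(t1, t2, ep = 0.4, nSamples = 8, librarySize = 2e4,
                           seed = 1)
  expect_identical(rownames(trainData(sp1)), rownames(testData(sp1)))
  expect_true(all(colSums(counts(trainData(sp1))) == 2e4))
  expect_length(phenotype(testData(sp1)), 8)

  # scenario 2 corrupts the training counts only
  tpl <- baselineVector(synthesizeTemplate(50, 10, seed = 33))
  spB <- simulateScenario2(tpl, 1000, 1, nSamples = 8, librarySize = 2e4,
                           seed = 2)
  expect_false(all(colSums(counts(trainData(spB))) == 2e4))
  expect_true(all(colSums(counts(testData(spB))) == 2e4))

  # scenario 2 identity limit: vanishing hyperprior spread at severity (0, 1)
  # leaves the training counts unchanged up to rounding
  spId <- simulateScenario2(tpl, 0, 1, nSamples = 8, librarySize = 2e4,
                            seed = 2, hyperVar = 1e-12)
  expect_true(all(abs(colSums(counts(trainData(spId))) - 2e4) <=
                    nrow(trainData(spId))))

  # scenario 3: overlap grid honoured; full overlap means identical models
  sp3 <- simulateScenario3(tpl, overlap = 10, nSamples = 8, librarySize = 2e4,
                           seed = 3)
  expect_identical(truthModels(sp3)$train@signature,
                   truthModels(sp3)$test@signature)
  sp3b <- simulateScenario3(tpl, overlap = 4, nSamples = 8, librarySize = 2e4,
                            seed = 3)
  tr <- truthModels(sp3b)$train; te <- truthModels(sp3b)$test
  expect_length(intersect(tr@signature, te@signature), 4)
  expect_length(te@signature, 10)
  expect_error(simulateScenario3(tpl, overlap = 3), "2, 4, 6, 8, 10")
})
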