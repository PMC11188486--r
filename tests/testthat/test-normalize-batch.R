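logPair <- function(seedA = 1, seedB = 2, nTaxa = 60, nTr = 12, nTe = 9) {
  tr <- makeCounts(nTaxa, nTr, seed = seedA, lambda = 80)
  te <- makeCounts(nTaxa, nTe, seed = seedB, lambda = 80)
  colnames(te) <- paste0("u", seq_len(ncol(te)))
  logTssPreprocess(tr, te)
}

test_that("log-TSS preprocessing yields finite logs of proportions", {
  pre <- logPair()
  expect_true(all(is.finite(pre$train)) && all(is.finite(pre$test)))
  expect_true(all(pre$train <= 0)) # proportions never exceed 1
})

test_that("QN forces identical sorted value vectors and is idempotent", {
  pre <- logPair()
  out <- batchCorrect(pre$train, pre$test, "QN")
  tr <- normValues(out$train); te <- normValues(out$test)
  ref <- sort(tr[, 1])
  for (j in seq_len(ncol(tr))) expect_equal(sort(tr[, j]), ref)
  for (j in seq_len(ncol(te))) expect_equal(unname(sort(te[, j])), unname(ref))
  # idempotence
  out2 <- batchCorrect(tr, te, "QN")
  expect_equal(normValues(out2$train), tr)
  expect_equal(normValues(out2$test), te)
})

test_that("QN training pass agrees with limma's quantile normalization", {
  skip_if_not_installed("limma")
  set.seed(20)
  tr <- matrix(rnorm(200 * 6), 200, 6,
               dimnames = list(paste0("t", 1:200), paste0("s", 1:6)))
  out <- batchCorrect(tr, tr, "QN")
  ref <- limma::normalizeQuantiles(tr)
  expect_equal(unname(normValues(out$train)), unname(ref), tolerance = 1e-9)
})

test_that("FSQN matches each test taxon's distribution to the train taxon", {
  pre <- logPair(nTe = 12) # equal sizes: sorted vectors match exactly
  out <- batchCorrect(pre$train, pre$test, "FSQN")
  tr <- normValues(out$train); te <- normValues(out$test)
  expect_equal(tr, pre$train) # training data untouched
  for (i in seq_len(nrow(te)))
    expect_equal(unname(sort(te[i, ])), unname(sort(tr[i, ])))
})

test_that("BMC zeroes per-batch feature means", {
  pre <- logPair()
  out <- batchCorrect(pre$train, pre$test, "BMC")
  expect_true(all(abs(rowMeans(normValues(out$train))) < 1e-12))
  expect_true(all(abs(rowMeans(normValues(out$test))) < 1e-12))
})

test_that("linear-model correction equalizes batch means to the grand mean", {
  pre <- logPair()
  out <- batchCorrect(pre$train, pre$test, "Limma")
  tr <- normValues(out$train); te <- normValues(out$test)
  expect_true(all(abs(rowMeans(tr) - rowMeans(te)) < 1e-12))
  grand <- rowMeans(cbind(pre$train, pre$test))
  expect_equal(rowMeans(tr), grand)

  # agrees with limma::removeBatchEffect on the between-batch contrast
  skip_if_not_installed("limma")
  X <- cbind(pre$train, pre$test)
  batch <- rep(c("tr", "te"), c(ncol(pre$train), ncol(pre$test)))
  ref <- limma::removeBatchEffect(X, batch = batch)
  refDiff <- rowMeans(ref[, batch == "tr"]) - rowMeans(ref[, batch == "te"])
  expect_true(all(abs(refDiff) < 1e-9))
})

test_that("ComBat removes a planted location shift between batches", {
  set.seed(33)
  nTaxa <- 200
  tr <- matrix(rnorm(nTaxa * 25, mean = 0), nTaxa, 25,
               dimnames = list(paste0("t", 1:nTaxa), paste0("s", 1:25)))
  te <- matrix(rnorm(nTaxa * 25, mean = 0), nTaxa, 25,
               dimnames = list(paste0("t", 1:nTaxa), paste0("u", 1:25)))
  trShift <- tr + 3 # planted gamma = 3, scale 1, no biology
  before <- rowMeans(trShift) - rowMeans(te)
  expect_equal(mean(before), 3, tolerance = 0.1)
  out <- batchCorrect(trShift, te, "ComBat")
  after <- rowMeans(normValues(out$train)) - rowMeans(normValues(out$test))
  expect_lt(abs(mean(after)), 0.1)
  # the bulk of the per-taxon shift is gone too
  expect_lt(mean(abs(after)), 0.5 * mean(abs(before)))
})

test_that("ComBat tracks the reference empirical-Bayes implementation", {
  skip_if_not_installed("sva")
  set.seed(34)
  nTaxa <- 80
  tr <- matrix(rnorm(nTaxa * 15, 0, 1.3), nTaxa, 15,
               dimnames = list(paste0("t", 1:nTaxa), paste0("s", 1:15))) + 2
  te <- matrix(rnorm(nTaxa * 12), nTaxa, 12,
               dimnames = list(paste0("t", 1:nTaxa), paste0("u", 1:12)))
  out <- batchCorrect(tr, te, "ComBat")
  mine <- cbind(normValues(out$train), normValues(out$test))
  batch <- rep(1:2, c(15, 12))
  ref <- suppressMessages(sva::ComBat(cbind(tr, te), batch = batch))
  expect_gt(cor(as.numeric(mine), as.numeric(ref)), 0.99)
  expect_lt(mean(abs(mine - ref)), 0.15)
})
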