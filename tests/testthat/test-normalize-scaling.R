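test_that("the pseudo-count is 0.65 times the global minimum non-zero entry", {
  expect_equal(pseudoCount(matrix(c(0, 0.002, 1, 2), 2)), 0.0013)
  expect_equal(pseudoCount(matrix(c(0, 1, 5, 9), 2)), 0.65)
  m <- matrix(round(runif(1000, 0, 50)), 50, 20)
  m[1, 1] <- 3 # guarantee a non-zero
  lo <- Inf
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
    if (m[i, j] > 0 && m[i, j] < lo) lo <- m[i, j]
  expect_equal(pseudoCount(m), 0.65 * lo)
  expect_error(pseudoCount(matrix(0, 2, 2)), "all-zero")
})

test_that("simple scaling factors match their definitions", {
  m <- matrix(c(1, 3, 2, 4), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(unname(scalingFactors(m, "TSS")), c(4, 6))
  z <- matrix(c(0, 2, 6, 10, 1, 2, 3, 4), 4,
              dimnames = list(letters[1:4], c("s1", "s2")))
  expect_equal(unname(scalingFactors(z, "MED")), c(6, 2.5))
  expect_equal(unname(scalingFactors(z, "UQ")),
               c(quantile(c(2, 6, 10), 0.75)[[1]], 3.25))

  # multiplying one sample's counts by k multiplies its factor by k
  for (meth in c("TSS", "UQ", "MED")) {
    s0 <- scalingFactors(z, meth)
    z2 <- z; z2[, 2] <- z2[, 2] * 7
    expect_equal(unname(scalingFactors(z2, meth)[2]), unname(7 * s0[2]))
  }

  bad <- cbind(z, s3 = 0)
  expect_error(scalingFactors(bad, "TSS"), "s3")
})

test_that("applyScaling divides counts by per-sample factors and inverts", {
  m <- makeCounts(20, 6, seed = 3)
  s <- scalingFactors(m, "TSS")
  nm <- applyScaling(m, s, "TSS")
  expect_true(all(abs(colSums(normValues(nm)) - 1) < 1e-12))
  expect_equal(sweep(normValues(nm), 2, s, "*"), m)
  expect_equal(normValues(applyScaling(m, rep(1, 6))), m)
  expect_error(applyScaling(m, rep(0, 6)), "positive")
})

test_that("TMM and RLE factors are one on a table of identical samples", {
  col <- c(5, 20, 7, 100, 1)
  m <- matrix(col, 5, 4, dimnames = list(paste0("t", 1:5), paste0("s", 1:4)))
  expect_true(all(abs(scalingFactors(m, "TMM") - 1) < 1e-9))
  expect_true(all(abs(scalingFactors(m, "RLE") - 1) < 1e-9))
})

test_that("TMM matches edgeR on dense tables", {
  skip_if_not_installed("edgeR")
  set.seed(14)
  m <- matrix(rpois(200 * 8, 60) + 1, 200, 8,
              dimnames = list(paste0("t", 1:200), paste0("s", 1:8)))
  m[, 3] <- m[, 3] * 4 # unequal depth
  mine <- scalingFactors(m, "TMM")
  ref <- edgeR::calcNormFactors(m, method = "TMM")
  expect_equal(unname(mine), unname(ref), tolerance = 1e-6)
})

test_that("RLE matches DESeq2 on all-positive tables", {
  skip_if_not_installed("DESeq2")
  set.seed(15)
  m <- matrix(rpois(151 * 6, 40) + 1, 151, 6,
              dimnames = list(paste0("t", 1:151), paste0("s", 1:6)))
  mine <- scalingFactors(m, "RLE")
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  # odd taxon count keeps the median a single order statistic, so the two
  # median conventions coincide
  expect_equal(unname(mine), unname(ref), tolerance = 1e-8)
})

test_that("GMPR agrees with a nested-loop pairwise-median oracle", {
  # hand evaluation: sample 1 vs 2 ratios are 2/4 and 8/4, whose median is
  # 1.25; with a single partner the geometric mean is that median itself
  m0 <- matrix(c(2, 8, 4, 4), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(unname(scalingFactors(m0, "GMPR")), c(1.25, 1.25))

  gmprOracle <- function(m) {
    n <- ncol(m)
    s <- numeric(n)
    for (j in 1:n) {
      rs <- c()
      for (k in 1:n) {
        if (k == j) next
        ratios <- c()
        for (i in 1:nrow(m))
          if (m[i, j] > 0 && m[i, k] > 0) ratios <- c(ratios, m[i, j] / m[i, k])
        if (length(ratios)) rs <- c(rs, median(ratios))
      }
      s[j] <- exp(mean(log(rs)))
    }
    s
  }
  for (seed in 1:20) {
    m <- makeCounts(6, 4, seed = seed, lambda = 10, zeroProb = 0.4)
    expect_equal(unname(scalingFactors(m, "GMPR")), gmprOracle(m),
                 tolerance = 1e-12)
  }
})

test_that("CSS factors are cumulative sums up to the chosen quantile", {
  # smoothly varying non-zero counts: the quantile-median curve has relative
  # steps far below the 0.1 instability threshold, so the quantile stays at
  # the 0.5 fallback and the factor is the cumulative sum below the median
  set.seed(8)
  m <- matrix(sample(50:150, 80 * 10, replace = TRUE), 80, 10,
              dimnames = list(paste0("t", 1:80), paste0("s", 1:10)))
  s <- scalingFactors(m, "CSS")
  expect_true(all(s > 0))
  oracle <- vapply(seq_len(ncol(m)), function(j) {
    cj <- m[, j]
    sum(cj[cj <= quantile(cj[cj > 0], 0.5)]) / 1000
  }, numeric(1))
  expect_equal(unname(s), oracle)

  # sparse realistic table: factors stay positive and finite
  sp <- makeCounts(80, 10, seed = 9, lambda = 50)
  expect_true(all(is.finite(scalingFactors(sp, "CSS"))))
})
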