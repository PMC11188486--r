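tssOf <- function(m) sweep(m, 2, colSums(m), "/")

test_that("CLR is the centred log-ratio: zero column sums, closed forms", {
  u <- matrix(0.25, 4, 2)
  expect_equal(normValues(transformAbundance(u, "CLR")), matrix(0, 4, 2))
  x <- tssOf(makeCounts(50, 12, seed = 2))
  cl <- normValues(transformAbundance(x, "CLR"))
  expect_true(all(abs(colSums(cl)) < 1e-9))
  expect_true(all(is.finite(cl)))
})

test_that("AST maps into [0, pi/2] with the arcsine square-root form", {
  expect_equal(normValues(transformAbundance(matrix(0.25), "AST"))[1, 1],
               pi / 6)
  x <- tssOf(makeCounts(30, 8, seed = 3))
  a <- normValues(transformAbundance(x, "AST"))
  expect_true(all(a >= 0 & a <= pi / 2))
})

test_that("STD standardizes rows; constant rows become zero", {
  x <- tssOf(makeCounts(30, 10, seed = 4))
  x[5, ] <- 0.01 # constant row
  s <- normValues(transformAbundance(x, "STD"))
  vr <- apply(x, 1, sd) > 0
  expect_true(all(abs(rowMeans(s[vr, ])) < 1e-12))
  expect_true(all(abs(apply(s[vr, ], 1, sd) - 1) < 1e-12))
  expect_equal(s[5, ], setNames(rep(0, 10), colnames(x)))
})

test_that("rank-based transforms give strict ranks and normal scores", {
  x <- tssOf(makeCounts(40, 12, seed = 5))
  r <- normValues(transformAbundance(x, "Rank", seed = 7))
  expect_true(all(apply(r, 1, function(ri)
    identical(unname(sort(ri)), as.numeric(1:12)))))

  # printed Blom score for m = 3 samples, rank 2
  xb <- matrix(c(0.2, 0.5, 0.3), 1, 3)
  b <- normValues(transformAbundance(rbind(xb, 1 - xb), "Blom"))
  expect_equal(b[1, 3], qnorm((2 - 0.375) / 4), tolerance = 1e-9)

  # NPN truncation bounds the scores at qnorm(delta), qnorm(1 - delta)
  m <- 12
  delta <- 1 / (4 * m^0.25 * sqrt(pi * log(m)))
  np <- normValues(transformAbundance(x, "NPN", seed = 7))
  expect_lte(max(np), qnorm(1 - delta) + 1e-12)
  expect_gte(min(np), qnorm(delta) - 1e-12)
})

test_that("Blom and NPN rows are approximately standard normal at m = 50", {
  x <- tssOf(makeCounts(30, 50, seed = 6, zeroProb = 0.5))
  for (meth in c("Blom", "NPN")) {
    v <- normValues(transformAbundance(x, meth, seed = 8))
    ks <- apply(v, 1, function(row) {
      e <- ecdf(row)
      grid <- seq(-3, 3, length.out = 400)
      max(abs(e(grid) - pnorm(grid)))
    })
    expect_lt(max(ks), 0.2)
  }
})

test_that("logCPM is library-size-adjusted log2 abundance", {
  m <- makeCounts(20, 5, seed = 7, lambda = 100, zeroProb = 0.2)
  lc <- normValues(logCPM(m))
  # a count equal to 1e-6 of the library sits at ~0 log2 CPM
  lib <- colSums(m)
  i <- which(m[, 1] > 0)[1]
  expect_equal(lc[i, 1], unname(log2(m[i, 1] / lib[1] * 1e6)))
  # doubling a count raises its logCPM by about 1 (library shift negligible
  # when recomputed with the same library)
  pc <- 0.65 * min(m[m > 0])
  oracle <- log2(ifelse(m == 0, pc, m) %*% diag(1 / lib) * 1e6)
  expect_equal(unname(lc), unname(oracle), tolerance = 1e-12)
})

test_that("VST matches its closed form and stabilizes variance", {
  # dispersion override: value at count 3 with a = 1 is 2 * asinh(sqrt(3)),
  # agreeing with numerical quadrature of 1/sqrt(mu + a mu^2)
  m <- matrix(c(3, 5, 7, 11), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  v <- normValues(vstCounts(m, dispersion = 1))
  expect_equal(v[1, 1], 2 * asinh(sqrt(3)), tolerance = 1e-12)
  quad <- integrate(function(mu) 1 / sqrt(mu + mu^2), 0, 3)$value
  expect_equal(v[1, 1], quad, tolerance = 1e-6)

  # a -> 0 limit is the Poisson square-root transform 2 sqrt(c)
  v0 <- normValues(vstCounts(m, dispersion = 1e-12))
  expect_equal(v0[1, 1], 2 * sqrt(3), tolerance = 1e-5)

  # zero counts are transformed at the pseudo-counted value one
  mz <- matrix(c(0, 5, 7, 11), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  vz <- normValues(vstCounts(mz, dispersion = 1))
  expect_equal(vz[1, 1], 2 * asinh(sqrt(1)))

  # variance grows more slowly with the mean after transformation; checked on
  # negative-binomial data without zero inflation, the mean-variance model
  # the transform assumes (excess zeros re-inflate the variance)
  big <- counts(synthesizeTemplate(150, 30, zeroFraction = 0, seed = 9))
  raw <- big
  vs <- normValues(vstCounts(big))
  slope <- function(mat) {
    mu <- rowMeans(mat); s2 <- apply(mat, 1, var)
    keep <- mu > 0 & s2 > 0
    coef(lm(log(s2[keep]) ~ log(mu[keep])))[2]
  }
  expect_lt(abs(slope(vs)), abs(slope(raw)))
})

test_that("every transformation maps sparse inputs to finite outputs", {
  x <- tssOf(makeCounts(40, 15, seed = 10, zeroProb = 0.6))
  for (meth in c("CLR", "LOG", "AST", "STD", "Rank", "Blom", "NPN"))
    expect_true(all(is.finite(normValues(transformAbundance(x, meth)))),
                info = meth)
})
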