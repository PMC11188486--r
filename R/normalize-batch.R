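# Batch-correction methods. All operate on log-transformed TSS relative
# abundances (zeros replaced by the global pseudo-count of the combined
# table) with batch = dataset label (train vs test).

#' Log-TSS preprocessing for batch correction
#'
#' TSS-normalizes the training and testing count tables, replaces zeros by a
#' pseudo relative abundance of 0.65 times the minimum non-zero abundance
#' across the combined table, and takes natural logs.
#'
#' @param train,test [PhenoCounts-class] objects or count matrices on one
#'   taxon list.
#' @return List of two log-abundance matrices `train`, `test`.
#' @export
logTssPreprocess <- function(train, test) {
  mTr <- if (methods::is(train, "PhenoCounts")) counts(train) else as.matrix(train)
  mTe <- if (methods::is(test, "PhenoCounts")) counts(test) else as.matrix(test)
  .stopIfNot(identical(rownames(mTr), rownames(mTe)),
             "train and test must share one taxon list")
  relTr <- sweep(mTr, 2, colSums(mTr), "/")
  relTe <- sweep(mTe, 2, colSums(mTe), "/")
  pc <- pseudoCount(cbind(relTr, relTe))
  list(train = log(.zeroReplace(relTr, pc)), test = log(.zeroReplace(relTe, pc)))
}

#' Batch-correct a train/test pair of log-abundance matrices
#'
#' * `QN` (quantile normalization): the reference distribution is the mean of
#'   the training samples' order statistics; every training and testing
#'   sample is mapped onto it by rank (test samples of any size via linear
#'   interpolation between reference order statistics), so all sample-sorted
#'   value vectors become identical.
#' * `FSQN` (feature-specific quantile normalization): each test taxon's
#'   values are mapped onto the corresponding training taxon's distribution;
#'   training values are untouched.
#' * `BMC` (batch mean centring): each taxon's within-batch mean is
#'   subtracted, per batch.
#' * `Limma` (linear-model removal): the per-taxon batch coefficient of a
#'   least-squares fit is removed, equalizing batch means to the grand mean.
#' * `ComBat`: parametric empirical-Bayes location-scale adjustment -- batch
#'   means and variances are shrunk towards normal / inverse-gamma priors
#'   (method-of-moments hyperparameters, iteratively solved) and removed.
#'
#' @param train,test log-abundance matrices from [logTssPreprocess()].
#' @param method one of `"QN"`, `"FSQN"`, `"BMC"`, `"Limma"`, `"ComBat"`.
#' @return List of two [NormalizedMatrix-class] objects `train`, `test`.
#' @export
batchCorrect <- function(train, test,
                         method = c("QN", "FSQN", "BMC", "Limma", "ComBat")) {
  method <- match.arg(method)
  .stopIfNot(identical(rownames(train), rownames(test)),
             "train and test must share one taxon list")
  out <- switch(method,
                QN = .qnPair(train, test),
                FSQN = .fsqnPair(train, test),
                BMC = list(train = train - rowMeans(train),
                           test = test - rowMeans(test)),
                Limma = .limmaPair(train, test),
                ComBat = .combatPair(train, test))
  list(train = NormalizedMatrix(out$train, method, "combined-extract"),
       test = NormalizedMatrix(out$test, method, "combined-extract"))
}

# map the values of vector x onto reference order statistics by rank; exact
# assignment when lengths match, linear interpolation otherwise
.qnMap <- function(x, ref) {
  n <- length(x); nr <- length(ref)
  out <- numeric(n)
  if (n == nr) {
    out[order(x)] <- ref
  } else {
    probs <- (rank(x, ties.method = "first") - 0.5) / n
    out <- approx((seq_len(nr) - 0.5) / nr, ref, xout = probs, rule = 2)$y
  }
  out
}

.qnPair <- function(train, test) {
  ref <- rowMeans(apply(train, 2, sort))
  list(train = apply(train, 2, .qnMap, ref = ref),
       test = apply(test, 2, .qnMap, ref = ref))
}

.fsqnPair <- function(train, test) {
  adj <- t(vapply(seq_len(nrow(train)),
                  function(i) .qnMap(test[i, ], sort(train[i, ])),
                  numeric(ncol(test))))
  dimnames(adj) <- dimnames(test)
  list(train = train, test = adj)
}

.limmaPair <- function(train, test) {
  grand <- rowMeans(cbind(train, test))
  list(train = train - (rowMeans(train) - grand),
       test = test - (rowMeans(test) - grand))
}

# parametric empirical-Bayes ComBat for the two-batch, no-covariate design
.combatPair <- function(train, test, tol = 1e-4, maxIter = 100) {
  X <- cbind(train, test)
  nTr <- ncol(train); nTe <- ncol(test); N <- nTr + nTe
  batches <- list(seq_len(nTr), nTr + seq_len(nTe))
  nk <- c(nTr, nTe)
  batchMean <- vapply(batches, function(ix) rowMeans(X[, ix, drop = FALSE]),
                      numeric(nrow(X)))
  grand <- as.numeric(batchMean %*% (nk / N))
  varPooled <- rowSums((X - batchMean[, rep(1:2, nk)])^2) / N
  varPooled <- pmax(varPooled, 1e-12)
  Z <- (X - grand) / sqrt(varPooled)
  adjusted <- Z
  for (b in 1:2) {
    ix <- batches[[b]]
    Zb <- Z[, ix, drop = FALSE]
    gHat <- rowMeans(Zb)
    dHat <- if (nk[b] > 1) .rowVars(Zb) else rep(1, nrow(Zb))
    dHat <- pmax(dHat, 1e-12)
    gBar <- mean(gHat); t2 <- max(var(gHat), 1e-12)
    if (!is.finite(t2)) t2 <- 1e-12
    mD <- mean(dHat); s2D <- max(var(dHat), 1e-12)
    if (!is.finite(s2D)) s2D <- 1e-12
    aPr <- (2 * s2D + mD^2) / s2D
    bPr <- (mD * s2D + mD^3) / s2D
    gStar <- gHat; dStar <- dHat
    for (it in seq_len(maxIter)) {
      gNew <- (nk[b] * t2 * gHat + dStar * gBar) / (nk[b] * t2 + dStar)
      ss <- rowSums((Zb - gNew)^2)
      dNew <- (0.5 * ss + bPr) / (nk[b] / 2 + aPr - 1)
      change <- max(abs(gNew - gStar) / pmax(abs(gStar), 1e-12),
                    abs(dNew - dStar) / pmax(abs(dStar), 1e-12))
      gStar <- gNew; dStar <- dNew
      if (change < tol) break
    }
    adjusted[, ix] <- (Zb - gStar) / sqrt(pmax(dStar, 1e-12))
  }
  out <- adjusted * sqrt(varPooled) + grand
  list(train = out[, seq_len(nTr), drop = FALSE],
       test = out[, nTr + seq_len(nTe), drop = FALSE])
}
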