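# Random-forest regression stage: seeded fits with grid-searched mtry via
# cross-validation, RMSE scoring, and 1..K ranking of methods.

#' Root mean squared error
#'
#' @param pred,actual numeric vectors of equal length.
#' @return `sqrt(mean((pred - actual)^2))`.
#' @examples
#' rmse(c(0, 0), c(3, 4)) # sqrt(25 / 2)
#' @export
rmse <- function(pred, actual) {
  .stopIfNot(length(pred) == length(actual) && length(pred) >= 1,
             "pred and actual must be non-empty vectors of equal length")
  sqrt(mean((pred - actual)^2))
}

#' Fit a random-forest regressor and predict the test phenotype
#'
#' A random forest (1000 trees by default) is trained on the normalized
#' training matrix; the number of variables tried at each split (`mtry`) is
#' selected from the grid `{floor(sqrt(m)/2), floor(sqrt(m)), floor(2
#' sqrt(m))}` (clipped to `[1, m]`) by 10-fold cross-validated RMSE, with
#' folds stratified by phenotype quartile bins. Everything is deterministic
#' given the seed.
#'
#' @param trainX,testX [NormalizedMatrix-class] objects or numeric matrices
#'   (taxa as rows, samples as columns) on one taxon list.
#' @param trainY numeric phenotype vector, one value per training sample.
#' @param nTrees number of trees (default 1000).
#' @param cvFolds cross-validation folds (default 10; reduced with a warning
#'   when there are fewer samples than folds).
#' @param seed integer seed.
#' @return Numeric vector of predicted phenotypes for the test samples, with
#'   attributes `mtry` (selected value) and `cvRMSE` (named grid results).
#' @export
fitPredictRF <- function(trainX, trainY, testX, nTrees = 1000, cvFolds = 10,
                         seed = 1) {
  xTr <- if (methods::is(trainX, "NormalizedMatrix")) normValues(trainX) else as.matrix(trainX)
  xTe <- if (methods::is(testX, "NormalizedMatrix")) normValues(testX) else as.matrix(testX)
  .stopIfNot(identical(rownames(xTr), rownames(xTe)),
             "train and test matrices must share one taxon list")
  n <- ncol(xTr)
  .stopIfNot(length(trainY) == n, "trainY must have one value per training sample")
  m <- nrow(xTr)
  feat <- paste0("f", seq_len(m))
  dTr <- data.frame(t(xTr)); colnames(dTr) <- feat
  dTe <- data.frame(t(xTe)); colnames(dTe) <- feat
  dTr$.y <- trainY

  grid <- sort(unique(pmin(pmax(c(floor(sqrt(m) / 2), floor(sqrt(m)),
                                  floor(2 * sqrt(m))), 1), m)))
  if (cvFolds > n) {
    warning("reducing cvFolds from ", cvFolds, " to ", n)
    cvFolds <- n
  }
  folds <- .stratifiedFolds(trainY, cvFolds, seed)
  cvErr <- vapply(grid, function(mt) {
    errs <- vapply(seq_len(cvFolds), function(f) {
      hold <- folds == f
      if (!any(hold) || all(hold)) return(NA_real_)
      fit <- ranger::ranger(
        dependent.variable.name = ".y", data = dTr[!hold, , drop = FALSE],
        num.trees = nTrees, mtry = mt, num.threads = 1,
        seed = deriveSeed(seed, "cv", mt, f), verbose = FALSE)
      rmse(predict(fit, dTr[hold, , drop = FALSE])$predictions,
           trainY[hold])
    }, numeric(1))
    mean(errs, na.rm = TRUE)
  }, numeric(1))
  best <- grid[which.min(cvErr)]
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = dTr, num.trees = nTrees,
    mtry = best, num.threads = 1, seed = deriveSeed(seed, "final", best),
    verbose = FALSE)
  out <- predict(fit, dTe)$predictions
  attr(out, "mtry") <- best
  attr(out, "cvRMSE") <- setNames(cvErr, grid)
  out
}

# fold labels stratified by phenotype quartile bins (4 bins), seeded
.stratifiedFolds <- function(y, k, seed) {
  set.seed(deriveSeed(seed, "folds"))
  bins <- cut(rank(y, ties.method = "first"), breaks = 4, labels = FALSE)
  folds <- integer(length(y))
  for (b in unique(bins)) {
    ix <- which(bins == b)
    folds[ix] <- sample(rep_len(seq_len(k), length(ix)))
  }
  folds
}

#' Rank methods by median RMSE
#'
#' Medians are arranged in ascending order and assigned ranks 1..K (lower
#' RMSE = lower = better rank); ties receive average ranks.
#'
#' @param medianRmse named numeric vector of per-method median RMSE values
#'   (at least 2 methods).
#' @return A data.frame with columns `method`, `medianRMSE`, `rank`, ordered
#'   by rank.
#' @examples
#' rankMethods(c(A = 1, B = 2, C = 2))
#' @export
rankMethods <- function(medianRmse) {
  .stopIfNot(length(medianRmse) >= 2, "need at least 2 methods to rank")
  bad <- names(medianRmse)[!is.finite(medianRmse)]
  if (length(bad))
    stop("non-finite median RMSE for method(s): ", paste(bad, collapse = ", "))
  rk <- rank(medianRmse, ties.method = "average")
  out <- data.frame(method = names(medianRmse),
                    medianRMSE = as.numeric(medianRmse),
                    rank = as.numeric(rk), stringsAsFactors = FALSE)
  out[order(out$rank), , drop = FALSE]
}
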