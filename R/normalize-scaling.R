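# Scaling normalizations: per-sample factors s_j with x_ij = c_ij / s_j.
# All factors are implemented from their printed formulas; edgeR and DESeq2
# serve only as independent cross-checks in the test suite.

#' Global pseudo-count for zero replacement
#'
#' Returns 0.65 times the minimum non-zero entry of the whole table. Zero
#' cells are replaced by this value before any log-based transformation so
#' that every method maps finite inputs to finite outputs.
#'
#' @param m non-negative numeric matrix with at least one positive entry.
#' @return A single positive number.
#' @examples
#' pseudoCount(matrix(c(0, 1, 2, 4), 2))
#' @export
pseudoCount <- function(m) {
  pos <- m[m > 0]
  if (!length(pos)) stop("cannot derive a pseudo-count from an all-zero matrix")
  0.65 * min(pos)
}

# replace zeros by the global pseudo-count
.zeroReplace <- function(m, pc = pseudoCount(m)) {
  m[m == 0] <- pc
  m
}

#' Per-sample scaling factors
#'
#' Computes one positive scaling factor per sample for the seven scaling
#' methods:
#' * `TSS` -- total sample reads;
#' * `UQ` -- upper quartile of the non-zero counts;
#' * `MED` -- median of the non-zero counts;
#' * `CSS` -- cumulative sum of counts up to a data-determined quantile,
#'   divided by a fixed constant (`Ncss = 1000`);
#' * `TMM` -- doubly trimmed (30% on M-values, 5% on A-values), weighted mean
#'   of log-ratios against a reference sample; factors rescaled to geometric
#'   mean 1;
#' * `RLE` -- median fold change against the per-taxon geometric-mean
#'   reference (taxa positive in every sample; pseudo-counted fallback when
#'   none exist);
#' * `GMPR` -- geometric mean over the other samples of the median count
#'   ratio across shared non-zero taxa (zero-robust RLE variant).
#'
#' @param x a [PhenoCounts-class] or a non-negative count matrix (taxa as
#'   rows).
#' @param method one of `"TSS"`, `"UQ"`, `"MED"`, `"CSS"`, `"TMM"`, `"RLE"`,
#'   `"GMPR"`.
#' @return Named numeric vector of positive factors, one per sample.
#' @examples
#' m <- matrix(c(1, 3, 2, 4), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
#' scalingFactors(m, "TSS")
#' @export
scalingFactors <- function(x, method = c("TSS", "UQ", "MED", "CSS", "TMM",
                                         "RLE", "GMPR")) {
  method <- match.arg(method)
  m <- if (methods::is(x, "PhenoCounts")) counts(x) else as.matrix(x)
  empty <- colSums(m) == 0
  if (any(empty))
    stop("sample(s) with no non-zero counts: ",
         paste(colnames(m)[empty], collapse = ", "))
  s <- switch(method,
              TSS = colSums(m),
              UQ = apply(m, 2, function(cj) quantile(cj[cj > 0], 0.75)),
              MED = apply(m, 2, function(cj) median(cj[cj > 0])),
              CSS = .cssFactors(m),
              TMM = .tmmFactors(m),
              RLE = .rleFactors(m),
              GMPR = .gmprFactors(m))
  if (any(!is.finite(s) | s <= 0))
    stop(method, " produced a non-positive factor for sample(s): ",
         paste(colnames(m)[!is.finite(s) | s <= 0], collapse = ", "))
  setNames(as.numeric(s), colnames(m))
}

#' Divide counts by per-sample scaling factors
#'
#' @param x a [PhenoCounts-class] or count matrix.
#' @param s positive factor vector of length `ncol`.
#' @param method method label stored on the result.
#' @param provenance provenance label (see [NormalizedMatrix-class]).
#' @return A [NormalizedMatrix-class] with `values[i, j] = counts[i, j] / s[j]`.
#' @export
applyScaling <- function(x, s, method = "scaled", provenance = "train-only") {
  m <- if (methods::is(x, "PhenoCounts")) counts(x) else as.matrix(x)
  .stopIfNot(length(s) == ncol(m), "one factor per sample is required")
  if (any(s <= 0)) stop("scaling factors must be positive")
  NormalizedMatrix(sweep(m, 2, s, "/"), method, provenance)
}

# CSS: cumulative sum up to a data-determined quantile l-hat. The quantile is
# chosen by an instability criterion on the median per-sample quantile curve:
# scanning upward from 0.5, the first level where the relative step of the
# median quantile reaches 0.1 is taken; if the curve never destabilizes the
# fallback is 0.5. Ncss = 1000 keeps factors on a convenient scale.
.cssFactors <- function(m, Ncss = 1000, threshold = 0.1) {
  grid <- seq(0.5, 0.99, by = 0.01)
  qmat <- apply(m, 2, function(cj) quantile(cj[cj > 0], probs = grid))
  med <- apply(qmat, 1, median)
  lhat <- 0.5
  for (k in seq_along(grid)[-1]) {
    if (med[k - 1] > 0 && abs(med[k] - med[k - 1]) / med[k - 1] >= threshold) {
      lhat <- grid[k - 1]
      break
    }
  }
  vapply(seq_len(ncol(m)), function(j) {
    cj <- m[, j]
    q <- quantile(cj[cj > 0], probs = lhat)
    sum(cj[cj <= q]) / Ncss
  }, numeric(1))
}

# TMM: reference = sample whose 75th percentile of depth-scaled counts is
# closest to the mean; per sample, weighted mean of log2 relative-abundance
# ratios after trimming 30% of M-values and 5% of A-values from each tail,
# weights the usual inverse asymptotic variances; factors rescaled to
# geometric mean 1.
.tmmFactors <- function(m) {
  lib <- colSums(m)
  f75 <- vapply(seq_len(ncol(m)),
                function(j) quantile(m[, j] / lib[j], 0.75), numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(m)), function(j) {
    if (j == ref) return(1)
    .tmmPair(m[, j], m[, ref], lib[j], lib[ref])
  }, numeric(1))
  f / .geomMean(f)
}

.tmmPair <- function(obs, refc, nO, nR, logratioTrim = 0.3, sumTrim = 0.05) {
  keep <- obs > 0 & refc > 0
  obs <- obs[keep]; refc <- refc[keep]
  if (!length(obs)) return(1)
  M <- log2((obs / nO) / (refc / nR))
  A <- (log2(obs / nO) + log2(refc / nR)) / 2
  w <- (nO - obs) / (nO * obs) + (nR - refc) / (nR * refc)
  n <- length(M)
  loM <- floor(n * logratioTrim) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * sumTrim) + 1
  hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep2)) return(1)
  2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

# RLE: geometric-mean reference over taxa positive in every sample; fallback
# to pseudo-counted counts when no such taxon exists (the printed reference
# is zero whenever any sample has a zero).
.rleFactors <- function(m) {
  allPos <- rowSums(m > 0) == ncol(m)
  if (!any(allPos)) m <- .zeroReplace(m) else m <- m[allPos, , drop = FALSE]
  ref <- exp(rowMeans(log(m)))
  apply(m, 2, function(cj) median(cj / ref))
}

# GMPR: s_j = geometric mean over samples k != j of the median ratio
# c_ij / c_ik across taxa non-zero in both; pairs sharing no taxon are
# skipped, and a sample sharing none with anyone is an error.
.gmprFactors <- function(m) {
  n <- ncol(m)
  vapply(seq_len(n), function(j) {
    r <- vapply(seq_len(n), function(k) {
      if (k == j) return(NA_real_)
      both <- m[, j] > 0 & m[, k] > 0
      if (!any(both)) return(NA_real_)
      median(m[both, j] / m[both, k])
    }, numeric(1))
    r <- r[!is.na(r)]
    if (!length(r))
      stop("GMPR undefined: sample ", colnames(m)[j],
           " shares no non-zero taxon with any other sample")
    .geomMean(r)
  }, numeric(1))
}
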