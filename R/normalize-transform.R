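# Feature transformations applied to TSS relative abundances (CLR, LOG, AST,
# STD, Rank, Blom, NPN) and two count-level transforms (logCPM, VST).

#' Transform a relative-abundance matrix
#'
#' All seven transformations expect TSS-normalized relative abundances
#' (columns summing to 1):
#' * `CLR` -- centred log-ratio: per sample, log of each abundance over the
#'   sample geometric mean (columns sum to 0);
#' * `LOG` -- natural log (zeros replaced by the global pseudo-count first,
#'   as for CLR);
#' * `AST` -- arcsine square root, mapping into `[0, pi/2]`;
#' * `STD` -- per-taxon standardization to mean 0, SD 1 (constant rows are
#'   set to 0);
#' * `Rank` -- per-taxon ranks across samples;
#' * `Blom` -- per-taxon rank-based normal scores
#'   `qnorm((r - 3/8) / (m + 1))`;
#' * `NPN` -- truncated normal scores `qnorm(clamp(r/(m+1), delta, 1-delta))`
#'   with `delta = 1 / (4 m^{1/4} sqrt(pi log m))`.
#'
#' Ties in the rank-based transforms (Rank, Blom, NPN) -- ubiquitous at zero
#' abundance -- are broken by adding `N(0, 1e-10)` jitter before ranking, so
#' ranks are strict.
#'
#' @param x relative-abundance matrix (taxa as rows, columns sum to 1).
#' @param method one of `"CLR"`, `"LOG"`, `"AST"`, `"STD"`, `"Rank"`,
#'   `"Blom"`, `"NPN"`.
#' @param seed seed for the tie-breaking jitter of the rank-based methods.
#' @param pseudo optional pseudo-count overriding the table-wide default
#'   (used by the combined train/test protocol to share one value).
#' @return A [NormalizedMatrix-class].
#' @examples
#' x <- matrix(c(.25, .75, .5, .5), 2)
#' normValues(transformAbundance(x, "AST"))
#' @export
transformAbundance <- function(x, method = c("CLR", "LOG", "AST", "STD",
                                             "Rank", "Blom", "NPN"),
                               seed = 1, pseudo = NULL) {
  method <- match.arg(method)
  x <- as.matrix(x)
  .stopIfNot(all(x >= 0) && all(x <= 1 + 1e-9),
             "transformAbundance expects relative abundances in [0, 1]")
  vals <- switch(method,
                 CLR = {
                   z <- .zeroReplace(x, pseudo %||% pseudoCount(x))
                   lz <- log(z)
                   sweep(lz, 2, colMeans(lz), "-")
                 },
                 LOG = log(.zeroReplace(x, pseudo %||% pseudoCount(x))),
                 AST = asin(sqrt(pmin(x, 1))),
                 STD = {
                   mu <- rowMeans(x)
                   sdv <- apply(x, 1, sd)
                   out <- (x - mu) / ifelse(sdv > 0, sdv, 1)
                   out[sdv == 0, ] <- 0
                   out
                 },
                 Rank = .rowRanks(x, seed),
                 Blom = {
                   r <- .rowRanks(x, seed)
                   m <- ncol(x)
                   qnorm((r - 3 / 8) / (m + 1))
                 },
                 NPN = {
                   r <- .rowRanks(x, seed)
                   m <- ncol(x)
                   delta <- 1 / (4 * m^(1 / 4) * sqrt(pi * log(m)))
                   qnorm(pmin(pmax(r / (m + 1), delta), 1 - delta))
                 })
  dimnames(vals) <- dimnames(x)
  NormalizedMatrix(vals, method)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# strict per-row ranks after N(0, 1e-10) tie-breaking jitter
.rowRanks <- function(x, seed) {
  set.seed(seed)
  xj <- x + matrix(rnorm(length(x), 0, sqrt(1e-10)), nrow(x))
  t(apply(xj, 1, rank))
}

#' Log counts per million
#'
#' `log2` of counts per million reads: zeros are replaced by the global
#' pseudo-count (0.65 times the minimum non-zero count), each column is
#' divided by its raw library size and scaled by `1e6` before taking `log2`.
#'
#' @param x a [PhenoCounts-class] or count matrix.
#' @return A [NormalizedMatrix-class].
#' @export
logCPM <- function(x) {
  m <- if (methods::is(x, "PhenoCounts")) counts(x) else as.matrix(x)
  lib <- colSums(m)
  .stopIfNot(all(lib > 0), "every sample needs a positive library size")
  z <- .zeroReplace(m)
  NormalizedMatrix(log2(sweep(z, 2, lib, "/") * 1e6), "logCPM")
}

#' Variance-stabilizing transformation for counts
#'
#' Per taxon, the mean-variance relation is modelled as
#' `v(mu) = mu + a * mu^2`; the transform is the closed form of
#' `integral 1/sqrt(v(mu)) dmu`, namely `(2 / sqrt(a)) * asinh(sqrt(a * c))`
#' (tending to `2 * sqrt(c)` as `a -> 0`). Raw per-taxon dispersions are the
#' method-of-moments estimates `(s^2 - m) / m^2`, smoothed by a linear
#' regression of dispersion on mean abundance and floored at `1e-8`. A
#' pseudo-count of one replaces zero counts.
#'
#' @param x a [PhenoCounts-class] or count matrix with at least 2 samples.
#' @param dispersion optional per-taxon dispersion vector overriding the
#'   fitted trend (recycled; mainly for validation against the closed form).
#' @return A [NormalizedMatrix-class].
#' @export
vstCounts <- function(x, dispersion = NULL) {
  m <- if (methods::is(x, "PhenoCounts")) counts(x) else as.matrix(x)
  .stopIfNot(ncol(m) >= 2, "VST needs at least two samples")
  mu <- rowMeans(m)
  a <- if (!is.null(dispersion)) rep_len(dispersion, nrow(m)) else {
    s2 <- .rowVars(m)
    aRaw <- ifelse(mu > 0, (s2 - mu) / mu^2, NA_real_)
    ok <- is.finite(aRaw)
    if (sum(ok) >= 2) {
      fit <- lm(aRaw[ok] ~ mu[ok])
      coef(fit)[1] + coef(fit)[2] * mu
    } else aRaw
  }
  a[!is.finite(a)] <- 1e-8
  a <- pmax(a, 1e-8)
  z <- m
  z[z == 0] <- 1
  vals <- (2 / sqrt(a)) * asinh(sqrt(a * z))
  dimnames(vals) <- dimnames(m)
  NormalizedMatrix(vals, "VST")
}
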