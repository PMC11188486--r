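# Community-level heterogeneity audit: Shannon diversity, Bray-Curtis
# dissimilarity, PCoA, marginal PERMANOVA and Wilcoxon shift tests. The
# heavy lifting is delegated to vegan and base R; the wrappers pin down the
# contracts used throughout the package.

#' Shannon diversity of a composition
#'
#' Natural-log Shannon entropy `-sum(x * log(x))` (zero entries contribute
#' zero), computed with `vegan::diversity`.
#'
#' @param x relative-abundance vector, or a taxa-by-samples matrix (one index
#'   per column).
#' @return A single value, or a named vector for matrix input.
#' @examples
#' shannonIndex(rep(0.25, 4)) # log(4)
#' @export
shannonIndex <- function(x) {
  if (any(x < 0)) stop("abundances must be non-negative")
  if (is.matrix(x)) vegan::diversity(t(x), index = "shannon")
  else unname(vegan::diversity(x, index = "shannon"))
}

#' Bray-Curtis dissimilarity
#'
#' For two vectors, `sum(|a - b|) / sum(a + b)`; for a taxa-by-samples
#' matrix, the full pairwise distance matrix (via `vegan::vegdist`).
#'
#' @param a abundance vector or taxa-by-samples matrix.
#' @param b second abundance vector (vector mode only).
#' @return A single value in `[0, 1]`, or a symmetric distance matrix.
#' @examples
#' brayCurtis(c(1, 1), c(1, 0)) # 1/3
#' @export
brayCurtis <- function(a, b = NULL) {
  if (is.null(b)) {
    .stopIfNot(is.matrix(a), "matrix mode needs a taxa-by-samples matrix")
    if (any(colSums(a) == 0)) stop("all-zero sample(s) in the table")
    return(as.matrix(vegan::vegdist(t(a), method = "bray")))
  }
  .stopIfNot(length(a) == length(b), "vectors must have equal length")
  if (any(a < 0) || any(b < 0)) stop("abundances must be non-negative")
  if (sum(a) + sum(b) == 0) stop("Bray-Curtis undefined for two all-zero vectors")
  sum(abs(a - b)) / sum(a + b)
}

#' Principal coordinate analysis
#'
#' Classical metric scaling (double-centred Gower matrix eigendecomposition,
#' via `stats::cmdscale`) of a distance matrix; coordinates are ordered by
#' descending eigenvalue. When fewer than `k` positive eigenvalues exist the
#' result is truncated with a warning (an all-zero distance matrix yields
#' all-zero coordinates).
#'
#' @param d distance matrix (symmetric matrix or `dist`).
#' @param k number of coordinate axes (default 2).
#' @return `n x k` coordinate matrix (columns `Axis1`, `Axis2`, ...), with
#'   eigenvalues in attribute `eig`.
#' @export
pcoaCoords <- function(d, k = 2) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  .stopIfNot(k >= 1 && k <= n - 1, "k must lie in [1, n - 1]")
  if (all(dm == 0)) {
    coords <- matrix(0, n, k, dimnames = list(rownames(dm),
                                              paste0("Axis", seq_len(k))))
    attr(coords, "eig") <- rep(0, n)
    return(coords)
  }
  fit <- cmdscale(stats::as.dist(dm), k = k, eig = TRUE)
  pts <- fit$points
  if (ncol(pts) < k) {
    warning("only ", ncol(pts), " positive eigenvalue axes available; truncating")
    k <- ncol(pts)
  }
  coords <- pts[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_len(k))
  attr(coords, "eig") <- fit$eig
  coords
}

#' Marginal PERMANOVA of a distance matrix
#'
#' One-way permutational multivariate ANOVA: `R^2 = SS_between / SS_total`
#' from squared inter-point distances, with a free-permutation p-value using
#' the add-one convention `p = (1 + #{F* >= F}) / (1 + nPerm)`. Each factor
#' is tested alone (marginally): pass a data.frame to test several factors
#' one at a time.
#'
#' @param d distance matrix (symmetric matrix or `dist`).
#' @param labels factor vector (one label per sample), or a data.frame of
#'   factors tested marginally.
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed.
#' @return A data.frame with one row per factor: `factor`, `R2`, `F`, `p`.
#' @export
permanovaTest <- function(d, labels, nPerm = 1000, seed = 1) {
  dm <- as.matrix(d)
  if (!is.data.frame(labels)) labels <- data.frame(group = labels)
  out <- lapply(names(labels), function(nm) {
    g <- factor(labels[[nm]])
    if (nlevels(g) < 2)
      stop("factor '", nm, "' has a single level; PERMANOVA undefined")
    .stopIfNot(length(g) == nrow(dm), "one label per sample is required")
    set.seed(deriveSeed(seed, "permanova", nm))
    dat <- data.frame(g = g)
    fit <- vegan::adonis2(stats::as.dist(dm) ~ g, data = dat,
                          permutations = nPerm)
    data.frame(factor = nm, R2 = fit$R2[1], F = fit$F[1],
               p = fit$`Pr(>F)`[1], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Two-sided Wilcoxon rank-sum shift test
#'
#' @param x,y numeric vectors.
#' @return Two-sided p-value.
#' @export
wilcoxonShift <- function(x, y) {
  .stopIfNot(length(x) >= 1 && length(y) >= 1, "both vectors must be non-empty")
  suppressWarnings(wilcox.test(x, y, alternative = "two.sided")$p.value)
}

#' Community-level heterogeneity audit across datasets
#'
#' For a collection of count tables: per-sample Shannon indices with a
#' Wilcoxon comparison of each dataset against the rest, the Bray-Curtis
#' distance matrix of TSS abundances, PCoA coordinates, and a marginal
#' PERMANOVA of the dataset factor.
#'
#' @param tables named list of [PhenoCounts-class] objects on one taxon list
#'   (harmonize first if needed).
#' @param k PCoA axes (default 2).
#' @param nPerm PERMANOVA permutations (default 1000).
#' @param seed integer seed.
#' @return List with `shannon` (per-sample data.frame), `shannonTests`
#'   (per-dataset Wilcoxon p), `distance`, `pcoa`, `permanova`.
#' @export
communityAudit <- function(tables, k = 2, nPerm = 1000, seed = 1) {
  .stopIfNot(is.list(tables) && length(tables) >= 2 &&
               !is.null(names(tables)), "need a named list of >= 2 tables")
  taxa <- rownames(counts(tables[[1]]))
  for (tb in tables)
    .stopIfNot(identical(rownames(counts(tb)), taxa),
               "all tables must share one taxon list")
  rel <- do.call(cbind, lapply(tables, function(tb) {
    m <- counts(tb)
    sweep(m, 2, colSums(m), "/")
  }))
  dataset <- rep(names(tables), vapply(tables, ncol, integer(1)))
  colnames(rel) <- paste0(dataset, ".", unlist(lapply(tables, function(tb)
    colnames(counts(tb)))))
  sh <- shannonIndex(rel)
  shannonDf <- data.frame(sample = colnames(rel), dataset = dataset,
                          shannon = as.numeric(sh), stringsAsFactors = FALSE)
  tests <- vapply(names(tables), function(nm) {
    wilcoxonShift(sh[dataset == nm], sh[dataset != nm])
  }, numeric(1))
  dm <- brayCurtis(rel)
  list(shannon = shannonDf,
       shannonTests = data.frame(dataset = names(tables),
                                 p = as.numeric(tests),
                                 stringsAsFactors = FALSE),
       distance = dm,
       pcoa = pcoaCoords(dm, k = min(k, ncol(rel) - 1)),
       permanova = permanovaTest(dm, data.frame(dataset = dataset),
                                 nPerm = nPerm, seed = seed))
}
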