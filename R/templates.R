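# Reading, writing and synthesizing taxon-by-sample count tables.

#' Read a count table (TSV/CSV) into a PhenoCounts object
#'
#' The on-disk convention is taxa as rows: first column taxon identifiers,
#' header row sample identifiers. `dialect = "samples-as-rows"` reads the
#' transpose. An optional two-column phenotype file (sample id, value) is
#' joined by sample identifier.
#'
#' @param path path to a TSV (default) or CSV file (`.csv` extension switches
#'   the separator).
#' @param dialect `"taxa-as-rows"` (default) or `"samples-as-rows"`.
#' @param phenotypePath optional path to a two-column TSV of sample id and
#'   phenotype value.
#' @return A [PhenoCounts-class] object.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeCountTable(PhenoCounts(matrix(1:4, 2, 2)), tf)
#' readCountTable(tf)
#' @export
readCountTable <- function(path, dialect = c("taxa-as-rows", "samples-as-rows"),
                           phenotypePath = NULL) {
  dialect <- match.arg(dialect)
  .stopIfNot(file.exists(path), paste("file not found:", path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .stopIfNot(ncol(df) >= 2, "count table needs an identifier column and at least one data column")
  ids <- as.character(df[[1]])
  body <- df[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1]
      stop("parse error in ", basename(path), ", line ", bad + 1,
           ": non-numeric value '", col[bad], "' in column '",
           colnames(body)[j], "'")
    }
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  if (dialect == "samples-as-rows") m <- t(m)
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop("validation error: negative count for taxon '", rownames(m)[bad[1]],
         "', sample '", colnames(m)[bad[2]], "'")
  }
  if (any(abs(m - round(m)) > 1e-8))
    stop("validation error: non-integer counts in ", basename(path))
  ph <- NULL
  if (!is.null(phenotypePath)) {
    pdf <- read.delim(phenotypePath, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
    ph <- setNames(as.numeric(pdf[[2]]), as.character(pdf[[1]]))
    .stopIfNot(all(colnames(m) %in% names(ph)),
               "phenotype file is missing some samples")
    ph <- ph[colnames(m)]
  }
  PhenoCounts(m, phenotype = ph)
}

#' Write a PhenoCounts object to disk
#'
#' @param x a [PhenoCounts-class] object.
#' @param path output TSV/CSV path (extension selects the separator).
#' @param dialect orientation on disk; see [readCountTable()].
#' @param phenotypePath optional path for a two-column phenotype TSV.
#' @return Invisibly, `path`.
#' @export
writeCountTable <- function(x, path,
                            dialect = c("taxa-as-rows", "samples-as-rows"),
                            phenotypePath = NULL) {
  dialect <- match.arg(dialect)
  m <- counts(x)
  if (dialect == "samples-as-rows") m <- t(m)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  colnames(df)[1] <- if (dialect == "taxa-as-rows") "taxon" else "sample"
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(phenotypePath) && !is.null(phenotype(x))) {
    write.table(data.frame(sample = colnames(counts(x)),
                           phenotype = as.numeric(phenotype(x))),
                phenotypePath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Derive the baseline population abundance vector of a template
#'
#' Sums each taxon's counts across samples, yielding the population baseline
#' vector used to seed the Dirichlet-multinomial simulator.
#'
#' @param x a [PhenoCounts-class] object.
#' @return A [TemplateProfile-class].
#' @examples
#' baselineVector(PhenoCounts(matrix(1:4, 2, 2)))
#' @export
baselineVector <- function(x) {
  m <- counts(x)
  .stopIfNot(nrow(m) > 0 && ncol(m) > 0, "count table is empty")
  if (sum(m) == 0) stop("degenerate template: all counts are zero")
  TemplateProfile(rownames(m), rowSums(m))
}

#' Synthesize a realistic template count table
#'
#' Emulates the structure of real stool shotgun-sequencing cohorts without any
#' download: per-taxon mean abundances are long-tailed (log-normal), per-cell
#' counts are negative-binomial around the taxon mean, and sparsity is tuned
#' to a target zero fraction (excess zeros added by Bernoulli thinning; when
#' the negative-binomial draw is already sparser than requested, zero cells
#' are promoted to singletons). Every sample is guaranteed a positive total.
#'
#' @param nTaxa,nSamples table dimensions.
#' @param zeroFraction target fraction of zero cells in `[0, 1)`; the realized
#'   fraction lands within about 0.1 of the target.
#' @param logMean,logSD log-normal parameters of the per-taxon mean abundance.
#' @param dispersion negative-binomial size parameter (smaller = noisier).
#' @param seed integer seed; the output is deterministic given the seed.
#' @return A [PhenoCounts-class] object.
#' @examples
#' tpl <- synthesizeTemplate(50, 10, zeroFraction = 0.4, seed = 1)
#' mean(counts(tpl) == 0)
#' @export
synthesizeTemplate <- function(nTaxa, nSamples, zeroFraction = 0.6,
                               logMean = 4, logSD = 2, dispersion = 0.8,
                               seed = 1) {
  .stopIfNot(nTaxa >= 1 && nSamples >= 1, "nTaxa and nSamples must be positive")
  .stopIfNot(zeroFraction >= 0 && zeroFraction < 1,
             "zeroFraction must lie in [0, 1)")
  .stopIfNot(logSD > 0, "logSD must be positive")
  set.seed(seed)
  mu <- rlnorm(nTaxa, meanlog = logMean, sdlog = logSD)
  m <- matrix(rnbinom(nTaxa * nSamples, mu = rep(mu, nSamples),
                      size = dispersion),
              nrow = nTaxa, ncol = nSamples)
  zf0 <- mean(m == 0)
  ncell <- length(m)
  if (zf0 > zeroFraction) {
    # sparser than requested: promote randomly chosen zero cells to 1
    nFix <- round((zf0 - zeroFraction) * ncell)
    zeros <- which(m == 0)
    if (nFix > 0) m[sample(zeros, nFix)] <- 1
  } else if (zf0 < zeroFraction) {
    # thin nonzero cells to add the missing zeros
    pDrop <- (zeroFraction - zf0) / (1 - zf0)
    nz <- which(m > 0)
    m[nz[runif(length(nz)) < pDrop]] <- 0
  }
  # every sample must keep a positive total
  for (attempt in seq_len(10)) {
    empty <- which(colSums(m) == 0)
    if (!length(empty)) break
    for (j in empty) m[sample.int(nTaxa, 1), j] <- max(1, round(rnbinom(1, mu = mean(mu), size = dispersion)))
  }
  if (any(colSums(m) == 0))
    stop("failed to produce positive sample totals after bounded retries")
  rownames(m) <- paste0("taxon_", seq_len(nTaxa))
  colnames(m) <- paste0("sample_", seq_len(nSamples))
  PhenoCounts(m)
}
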