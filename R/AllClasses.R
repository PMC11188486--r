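#' @import methods
#' @importFrom stats approx lm median predict quantile rbinom rgamma rlnorm
#'   rmultinom rnbinom rnorm runif sd var qnorm cmdscale wilcox.test coef
#'   fitted setNames
#' @importFrom utils read.delim write.table head
NULL

#' PhenoCounts: a taxon-by-sample count table with optional phenotype
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] holding one
#' `counts` assay of non-negative integers (taxa as rows, samples as columns)
#' and, optionally, a numeric `phenotype` column in `colData`. This is the
#' universal input object of the package: templates, simulated studies and
#' real cohorts are all carried as `PhenoCounts`.
#'
#' @slot ... inherits all slots from `SummarizedExperiment`.
#' @export
setClass("PhenoCounts", contains = "SummarizedExperiment")

.validPhenoCounts <- function(object) {
  msg <- character(0)
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  m <- SummarizedExperiment::assay(object, "counts")
  if (anyNA(m)) msg <- c(msg, "counts contain NA")
  else {
    if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(abs(m - round(m)) > 1e-8)) msg <- c(msg, "counts must be integral")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "taxon identifiers must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample identifiers must be present and unique")
  if ("phenotype" %in% colnames(SummarizedExperiment::colData(object))) {
    ph <- SummarizedExperiment::colData(object)$phenotype
    if (!is.numeric(ph)) msg <- c(msg, "phenotype must be numeric")
  }
  if (length(msg)) msg else TRUE
}
setValidity("PhenoCounts", .validPhenoCounts)

#' Construct a PhenoCounts object
#'
#' @param counts numeric matrix of non-negative integers, taxa as rows and
#'   samples as columns. Dimnames are required; unnamed dimensions are given
#'   `taxon_i` / `sample_j` identifiers.
#' @param phenotype optional numeric vector of per-sample phenotype values
#'   (length `ncol(counts)`).
#' @return A [PhenoCounts-class] object.
#' @examples
#' pc <- PhenoCounts(matrix(1:4, 2, 2), phenotype = c(22.5, 31.0))
#' counts(pc)
#' phenotype(pc)
#' @export
PhenoCounts <- function(counts, phenotype = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("taxon_", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample_", seq_len(ncol(counts)))
  storage.mode(counts) <- "double"
  cd <- S4Vectors::DataFrame(row.names = colnames(counts))
  if (!is.null(phenotype)) {
    .stopIfNot(length(phenotype) == ncol(counts),
               "phenotype length must equal the number of samples")
    cd$phenotype <- as.numeric(phenotype)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
  methods::new("PhenoCounts", se)
}

#' TemplateProfile: baseline taxon abundance of a population
#'
#' Holds the per-taxon baseline abundance vector of a population, obtained by
#' summing a template count table across samples (or synthesized). Units are
#' arbitrary; mixing and simulation normalize to proportions internally.
#'
#' @slot taxa character vector of taxon identifiers.
#' @slot p numeric vector of non-negative baseline abundances.
#' @export
setClass("TemplateProfile",
         representation(taxa = "character", p = "numeric"))

setValidity("TemplateProfile", function(object) {
  msg <- character(0)
  if (length(object@taxa) != length(object@p))
    msg <- c(msg, "taxa and p must have equal length")
  if (anyDuplicated(object@taxa)) msg <- c(msg, "taxon identifiers must be unique")
  if (any(object@p < 0)) msg <- c(msg, "baseline abundances must be non-negative")
  if (length(object@p) && sum(object@p) <= 0)
    msg <- c(msg, "baseline abundances must have positive sum")
  if (length(msg)) msg else TRUE
})

#' @rdname TemplateProfile-class
#' @param taxa character vector of taxon identifiers.
#' @param p numeric vector of non-negative abundances, same length as `taxa`.
#' @export
TemplateProfile <- function(taxa, p) {
  methods::new("TemplateProfile", taxa = as.character(taxa), p = as.numeric(p))
}

#' PhenotypeModel: signature-taxa model linking abundance to phenotype
#'
#' Ten signature taxa drive a simulated quantitative phenotype through one of
#' four links. The first five coefficients are positive (enriched taxa,
#' uniform on `[3, 5]`), the last five negative (depleted taxa, uniform on
#' `[-5, -3]`). A scale constant keeps the phenotype in the dozens-to-hundreds
#' range; Gaussian noise is added on top.
#'
#' @slot signature character vector of 10 taxon identifiers.
#' @slot beta numeric vector of 10 coefficients.
#' @slot relationship one of `"linear"`, `"quadratic"`, `"inverse"`,
#'   `"logistic"`.
#' @slot scaleConstant positive scale constant (c1..c4 depending on the link).
#' @slot noiseSD standard deviation of the additive Gaussian noise.
#' @export
setClass("PhenotypeModel",
         representation(signature = "character", beta = "numeric",
                        relationship = "character", scaleConstant = "numeric",
                        noiseSD = "numeric"))

setValidity("PhenotypeModel", function(object) {
  msg <- character(0)
  if (length(object@signature) != 10 || anyDuplicated(object@signature))
    msg <- c(msg, "signature must contain 10 distinct taxa")
  if (length(object@beta) != 10) msg <- c(msg, "beta must have length 10")
  else {
    if (any(object@beta[1:5] < 3 - 1e-9 | object@beta[1:5] > 5 + 1e-9))
      msg <- c(msg, "beta[1..5] must lie in [3, 5]")
    if (any(object@beta[6:10] < -5 - 1e-9 | object@beta[6:10] > -3 + 1e-9))
      msg <- c(msg, "beta[6..10] must lie in [-5, -3]")
  }
  if (!object@relationship %in% c("linear", "quadratic", "inverse", "logistic"))
    msg <- c(msg, "relationship must be linear/quadratic/inverse/logistic")
  if (length(object@scaleConstant) != 1 ||
      (!is.na(object@scaleConstant) && object@scaleConstant <= 0))
    msg <- c(msg, "scaleConstant must be a single positive number (or NA before calibration)")
  if (length(object@noiseSD) != 1 || object@noiseSD < 0)
    msg <- c(msg, "noiseSD must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' @rdname PhenotypeModel-class
#' @param signature character vector of 10 taxon identifiers.
#' @param beta numeric vector of 10 coefficients (5 positive then 5 negative).
#' @param relationship link function name.
#' @param scaleConstant positive scale constant, or `NA` before calibration.
#' @param noiseSD noise standard deviation (default 1).
#' @export
PhenotypeModel <- function(signature, beta, relationship,
                           scaleConstant = NA_real_, noiseSD = 1) {
  methods::new("PhenotypeModel", signature = as.character(signature),
               beta = as.numeric(beta), relationship = relationship,
               scaleConstant = as.numeric(scaleConstant),
               noiseSD = as.numeric(noiseSD))
}

#' BatchEffectModel: severity-indexed hyperpriors for batch effects
#'
#' Per-taxon batch effects are an additive location shift `gamma_i` drawn from
#' `N(gammaMu, gammaVar)` and a multiplicative scale change `delta_i` drawn
#' from `InvGamma(deltaAlpha, deltaBeta)`. The hyperparameters are solved from
#' a severity pair: the normal mean equals `sevMean`, the inverse-gamma mean
#' equals `sevVar`, and both hyperpriors have variance `hyperVar` (0.01).
#'
#' @slot sevMean batch-mean severity (0, 500 or 1000 in the study grid).
#' @slot sevVar batch-variance severity (1, 2 or 4 in the study grid).
#' @slot gammaMu,gammaVar normal hyperprior for the location shift.
#' @slot deltaAlpha,deltaBeta inverse-gamma hyperprior for the scale change.
#' @export
setClass("BatchEffectModel",
         representation(sevMean = "numeric", sevVar = "numeric",
                        gammaMu = "numeric", gammaVar = "numeric",
                        deltaAlpha = "numeric", deltaBeta = "numeric"))

setValidity("BatchEffectModel", function(object) {
  msg <- character(0)
  a <- object@deltaAlpha; b <- object@deltaBeta
  if (a <= 2) msg <- c(msg, "deltaAlpha must exceed 2 for a finite variance")
  else {
    if (abs(b / (a - 1) - object@sevVar) > 1e-9)
      msg <- c(msg, "inverse-gamma mean must equal sevVar")
    if (abs(b^2 / ((a - 1)^2 * (a - 2)) - object@gammaVar) > 1e-9)
      msg <- c(msg, "inverse-gamma variance must equal the hyperprior variance")
  }
  if (abs(object@gammaMu - object@sevMean) > 1e-9)
    msg <- c(msg, "normal hyperprior mean must equal sevMean")
  if (length(msg)) msg else TRUE
})

#' StudyPair: a simulated training/testing study pair
#'
#' Training and testing count tables on one ordered taxon list, each carrying
#' simulated phenotypes, plus the true phenotype model(s) and the scenario
#' metadata (population effect, batch severity or signature overlap).
#'
#' @slot train,test [PhenoCounts-class] objects with phenotype.
#' @slot truth list of [PhenotypeModel-class] objects (`train`, `test`).
#' @slot scenario list of scenario metadata.
#' @export
setClass("StudyPair",
         representation(train = "PhenoCounts", test = "PhenoCounts",
                        truth = "list", scenario = "list"))

setValidity("StudyPair", function(object) {
  if (!identical(rownames(object@train), rownames(object@test)))
    "train and test must share an identical, ordered taxon list" else TRUE
})

#' NormalizedMatrix: output of a normalization method
#'
#' A real-valued taxa-by-samples matrix together with the method identifier
#' and the provenance of the statistics used (`train-only` when the table was
#' normalized on its own, `combined-extract` when the values were extracted
#' from a joint train+test normalization pass).
#'
#' @slot values numeric matrix (taxa as rows, samples as columns).
#' @slot method method identifier.
#' @slot provenance `"train-only"` or `"combined-extract"`.
#' @export
setClass("NormalizedMatrix",
         representation(values = "matrix", method = "character",
                        provenance = "character"))

setValidity("NormalizedMatrix", function(object) {
  msg <- character(0)
  if (!all(is.finite(object@values)))
    msg <- c(msg, "normalized values must be finite")
  if (!object@provenance %in% c("train-only", "combined-extract"))
    msg <- c(msg, "provenance must be 'train-only' or 'combined-extract'")
  if (length(msg)) msg else TRUE
})

NormalizedMatrix <- function(values, method, provenance = "train-only") {
  methods::new("NormalizedMatrix", values = as.matrix(values),
               method = method, provenance = provenance)
}
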