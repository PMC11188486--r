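#' @importFrom SummarizedExperiment assay assayNames colData
NULL

#' Access the count matrix of a PhenoCounts object
#'
#' @param object a [PhenoCounts-class] object.
#' @param ... ignored.
#' @return Numeric taxa-by-samples matrix.
#' @export
setGeneric("counts", function(object, ...) standardGeneric("counts"))

#' @rdname counts
#' @export
setMethod("counts", "PhenoCounts", function(object, ...) {
  SummarizedExperiment::assay(object, "counts")
})

#' Access or replace the per-sample phenotype of a PhenoCounts object
#'
#' @param object a [PhenoCounts-class] object.
#' @return Numeric vector (named by sample), or `NULL` when absent.
#' @export
setGeneric("phenotype", function(object) standardGeneric("phenotype"))

#' @rdname phenotype
#' @export
setMethod("phenotype", "PhenoCounts", function(object) {
  cd <- SummarizedExperiment::colData(object)
  if (!"phenotype" %in% colnames(cd)) return(NULL)
  setNames(cd$phenotype, rownames(cd))
})

#' @rdname phenotype
#' @param value numeric vector of length `ncol(object)`, or `NULL`.
#' @export
setGeneric("phenotype<-", function(object, value) standardGeneric("phenotype<-"))

#' @rdname phenotype
#' @export
setMethod("phenotype<-", "PhenoCounts", function(object, value) {
  if (!is.null(value))
    .stopIfNot(length(value) == ncol(object),
               "phenotype length must equal the number of samples")
  SummarizedExperiment::colData(object)$phenotype <-
    if (is.null(value)) NULL else as.numeric(value)
  methods::validObject(object)
  object
})

#' @rdname TemplateProfile-class
#' @param object,x a `TemplateProfile`.
#' @export
setMethod("length", "TemplateProfile", function(x) length(x@p))

#' Accessors for TemplateProfile
#'
#' `profileTaxa()` returns the taxon identifiers, `profileAbundance()` the
#' baseline abundance vector (named by taxon).
#'
#' @param object a [TemplateProfile-class].
#' @return Character or named numeric vector.
#' @export
setGeneric("profileTaxa", function(object) standardGeneric("profileTaxa"))

#' @rdname profileTaxa
#' @export
setMethod("profileTaxa", "TemplateProfile", function(object) object@taxa)

#' @rdname profileTaxa
#' @export
setGeneric("profileAbundance", function(object) standardGeneric("profileAbundance"))

#' @rdname profileTaxa
#' @export
setMethod("profileAbundance", "TemplateProfile", function(object) {
  setNames(object@p, object@taxa)
})

#' Accessors for StudyPair
#'
#' @param object a [StudyPair-class].
#' @return `trainData()`/`testData()` return [PhenoCounts-class];
#'   `truthModels()` the list of true [PhenotypeModel-class] objects;
#'   `scenarioInfo()` the scenario metadata list.
#' @export
setGeneric("trainData", function(object) standardGeneric("trainData"))
#' @rdname trainData
#' @export
setMethod("trainData", "StudyPair", function(object) object@train)
#' @rdname trainData
#' @export
setGeneric("testData", function(object) standardGeneric("testData"))
#' @rdname trainData
#' @export
setMethod("testData", "StudyPair", function(object) object@test)
#' @rdname trainData
#' @export
setGeneric("truthModels", function(object) standardGeneric("truthModels"))
#' @rdname trainData
#' @export
setMethod("truthModels", "StudyPair", function(object) object@truth)
#' @rdname trainData
#' @export
setGeneric("scenarioInfo", function(object) standardGeneric("scenarioInfo"))
#' @rdname trainData
#' @export
setMethod("scenarioInfo", "StudyPair", function(object) object@scenario)

#' Accessors for NormalizedMatrix
#'
#' @param object a [NormalizedMatrix-class].
#' @return `normValues()` the numeric matrix, `normMethod()` the method name,
#'   `normProvenance()` the provenance flag.
#' @export
setGeneric("normValues", function(object) standardGeneric("normValues"))
#' @rdname normValues
#' @export
setMethod("normValues", "NormalizedMatrix", function(object) object@values)
#' @rdname normValues
#' @export
setGeneric("normMethod", function(object) standardGeneric("normMethod"))
#' @rdname normValues
#' @export
setMethod("normMethod", "NormalizedMatrix", function(object) object@method)
#' @rdname normValues
#' @export
setGeneric("normProvenance", function(object) standardGeneric("normProvenance"))
#' @rdname normValues
#' @export
setMethod("normProvenance", "NormalizedMatrix", function(object) object@provenance)

# show methods ---------------------------------------------------------------

setMethod("show", "TemplateProfile", function(object) {
  cat("TemplateProfile with", length(object@taxa), "taxa;",
      sum(object@p > 0), "with positive baseline\n")
})

setMethod("show", "PhenotypeModel", function(object) {
  cat("PhenotypeModel:", object@relationship,
      "| scale =", format(object@scaleConstant, digits = 4),
      "| noise SD =", object@noiseSD, "\n")
  cat("  signature:", paste(head(object@signature, 4), collapse = ", "),
      "... (10 taxa, 5 enriched / 5 depleted)\n")
})

setMethod("show", "BatchEffectModel", function(object) {
  cat("BatchEffectModel: sev_mean =", object@sevMean,
      ", sev_var =", object@sevVar, "\n")
  cat("  gamma ~ N(", object@gammaMu, ",", object@gammaVar, ")",
      "  delta ~ InvGamma(", format(object@deltaAlpha, digits = 6), ",",
      format(object@deltaBeta, digits = 6), ")\n")
})

setMethod("show", "StudyPair", function(object) {
  info <- object@scenario
  cat("StudyPair (scenario", info$scenario, "):",
      nrow(object@train), "taxa;",
      ncol(object@train), "train /", ncol(object@test), "test samples\n")
  extra <- setdiff(names(info), "scenario")
  if (length(extra))
    cat("  ", paste(vapply(extra, function(k)
      paste0(k, " = ", paste(info[[k]], collapse = "/")), character(1)),
      collapse = ", "), "\n")
})

setMethod("show", "NormalizedMatrix", function(object) {
  cat("NormalizedMatrix:", object@method, "(", object@provenance, ")",
      nrow(object@values), "taxa x", ncol(object@values), "samples\n")
})
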