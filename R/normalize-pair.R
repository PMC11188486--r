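# The uniform train/test normalization protocol. Sample-wise methods
# normalize the two tables independently; reference- and distribution-based
# methods normalize the training table alone, then normalize the combined
# train+test table and extract the test columns; batch-correction methods
# operate on the pair jointly after log-TSS preprocessing.

#' Registry of implemented normalization methods
#'
#' @return A data.frame with columns `name`, `family` (scaling / coda /
#'   transformation / batch) and `needsCombined` (whether the test table is
#'   normalized through the combined train+test pass).
#' @examples
#' normMethods()
#' @export
normMethods <- function() {
  data.frame(
    name = c("TSS", "UQ", "MED", "CSS", "TMM", "RLE", "GMPR",
             "CLR",
             "LOG", "AST", "STD", "Rank", "Blom", "NPN", "logCPM", "VST",
             "QN", "FSQN", "BMC", "Limma", "ComBat"),
    family = c(rep("scaling", 7), "coda", rep("transformation", 8),
               rep("batch", 5)),
    needsCombined = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE,
                      FALSE,
                      FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE,
                      rep(TRUE, 5)),
    stringsAsFactors = FALSE)
}

#' Normalize a training/testing table pair by any implemented method
#'
#' Dispatches to the method families with the appropriate protocol:
#' * sample-wise methods (`TSS`, `UQ`, `MED`, `CSS`, `GMPR`, `CLR`, `LOG`,
#'   `AST`, `logCPM`) normalize train and test independently;
#' * combined-protocol methods (`TMM`, `RLE`, `STD`, `Rank`, `Blom`, `NPN`,
#'   `VST`) normalize the training table alone (that is what the model is fit
#'   on), then normalize the concatenated train+test table and extract the
#'   test columns from it;
#' * batch-correction methods (`QN`, `FSQN`, `BMC`, `Limma`, `ComBat`) run
#'   the log-TSS preprocess and correct with batch = dataset label;
#' * `ConQuR` is a reserved adapter slot and raises a not-implemented error.
#'
#' @param train,test [PhenoCounts-class] objects on one taxon list.
#' @param method a method name from [normMethods()].
#' @param seed seed for the tie-breaking jitter of rank-based transforms.
#' @return List of two [NormalizedMatrix-class] objects `train`, `test`.
#' @examples
#' tpl <- synthesizeTemplate(40, 8, seed = 1)
#' tp2 <- synthesizeTemplate(40, 6, seed = 2)
#' colSums(normValues(normalizePair(tpl, tp2, "TSS")$train))
#' @export
normalizePair <- function(train, test, method, seed = 1) {
  if (identical(method, "ConQuR"))
    stop("ConQuR adapter slot: not implemented (no algorithm reimplementation)")
  reg <- normMethods()
  if (!method %in% reg$name)
    stop("unknown method '", method, "'; valid methods: ",
         paste(reg$name, collapse = ", "))
  .stopIfNot(identical(rownames(train), rownames(test)),
             "train and test must share one taxon list")
  fam <- reg$family[reg$name == method]
  mTr <- counts(train); mTe <- counts(test)

  scalingOne <- function(m) applyScaling(m, scalingFactors(m, method), method)
  tssOf <- function(m) sweep(m, 2, colSums(m), "/")

  if (method %in% c("TSS", "UQ", "MED", "CSS", "GMPR")) {
    return(list(train = scalingOne(mTr), test = scalingOne(mTe)))
  }
  if (method %in% c("TMM", "RLE")) {
    trainOut <- scalingOne(mTr)
    comb <- cbind(mTr, mTe)
    sComb <- scalingFactors(comb, method)
    testOut <- applyScaling(mTe, sComb[ncol(mTr) + seq_len(ncol(mTe))],
                            method, "combined-extract")
    return(list(train = trainOut, test = testOut))
  }
  if (method %in% c("CLR", "LOG", "AST")) {
    return(list(train = transformAbundance(tssOf(mTr), method, seed = seed),
                test = transformAbundance(tssOf(mTe), method, seed = seed)))
  }
  if (method == "logCPM") {
    return(list(train = logCPM(mTr), test = logCPM(mTe)))
  }
  if (method %in% c("STD", "Rank", "Blom", "NPN")) {
    trainOut <- transformAbundance(tssOf(mTr), method, seed = seed)
    comb <- transformAbundance(cbind(tssOf(mTr), tssOf(mTe)), method,
                               seed = seed)
    testVals <- normValues(comb)[, ncol(mTr) + seq_len(ncol(mTe)), drop = FALSE]
    return(list(train = trainOut,
                test = NormalizedMatrix(testVals, method, "combined-extract")))
  }
  if (method == "VST") {
    trainOut <- vstCounts(mTr)
    comb <- vstCounts(cbind(mTr, mTe))
    testVals <- normValues(comb)[, ncol(mTr) + seq_len(ncol(mTe)), drop = FALSE]
    return(list(train = trainOut,
                test = NormalizedMatrix(testVals, "VST", "combined-extract")))
  }
  if (fam == "batch") {
    pre <- logTssPreprocess(mTr, mTe)
    return(batchCorrect(pre$train, pre$test, method))
  }
  stop("unhandled method '", method, "'")
}
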