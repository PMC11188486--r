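# Orchestration of the full benchmark: scenario grid x phenotype
# relationships x normalization methods x repetitions, seeded and resumable,
# with tidy records and rank summaries.

#' Build and validate a benchmark configuration
#'
#' @param scenario 1, 2 or 3.
#' @param cells scenario grid: numeric vector of population effects for
#'   scenario 1 (subset of `{0, 0.2, ..., 1}`), a list of
#'   `c(sevMean, sevVar)` pairs for scenario 2 (from `{0, 500, 1000} x
#'   {1, 2, 4}`), or a numeric vector of overlaps for scenario 3 (subset of
#'   `{2, 4, 6, 8, 10}`).
#' @param relationships subset of `c("linear", "quadratic", "inverse",
#'   "logistic")`.
#' @param methods subset of [normMethods()] names.
#' @param nReps repetitions per cell (study default 100).
#' @param nSamples samples per population (study default 100).
#' @param librarySize reads per sample (study default `1e6`).
#' @param concentration Dirichlet concentration (default `1e6`).
#' @param nTrees,cvFolds random-forest settings (study defaults 1000 / 10).
#' @param noiseSD phenotype noise SD (default 1).
#' @param masterSeed master seed from which all record seeds derive.
#' @param templates list of [TemplateProfile-class]: two for scenario 1
#'   (train-like, test-like), one for scenarios 2 and 3.
#' @return A validated config list of class `benchmarkConfig`.
#' @export
benchmarkConfig <- function(scenario, cells, relationships = "linear",
                            methods = normMethods()$name, nReps = 100,
                            nSamples = 100, librarySize = 1e6,
                            concentration = 1e6, nTrees = 1000, cvFolds = 10,
                            noiseSD = 1, masterSeed = 1, templates) {
  .stopIfNot(scenario %in% 1:3, "scenario must be 1, 2 or 3")
  .stopIfNot(nReps >= 1, "nReps must be at least 1")
  .stopIfNot(all(relationships %in%
                   c("linear", "quadratic", "inverse", "logistic")),
             "unknown relationship")
  .stopIfNot(all(methods %in% normMethods()$name),
             "unknown normalization method in config")
  if (scenario == 1) {
    .stopIfNot(is.numeric(cells) && all(cells >= 0 & cells <= 1),
               "scenario 1 cells are population effects in [0, 1]")
    .stopIfNot(length(templates) == 2, "scenario 1 needs two templates")
    cells <- as.list(cells)
  } else if (scenario == 2) {
    if (is.numeric(cells)) cells <- list(cells)
    ok <- vapply(cells, function(cl) length(cl) == 2 &&
                   cl[1] %in% c(0, 500, 1000) && cl[2] %in% c(1, 2, 4),
                 logical(1))
    .stopIfNot(all(ok),
               "scenario 2 cells are (sevMean, sevVar) pairs from {0,500,1000} x {1,2,4}")
    .stopIfNot(length(templates) == 1, "scenario 2 needs one template")
  } else {
    .stopIfNot(all(unlist(cells) %in% c(2, 4, 6, 8, 10)),
               "scenario 3 cells are overlaps in {2, 4, 6, 8, 10}")
    .stopIfNot(length(templates) == 1, "scenario 3 needs one template")
    cells <- as.list(cells)
  }
  structure(list(scenario = scenario, cells = cells,
                 relationships = relationships, methods = methods,
                 nReps = nReps, nSamples = nSamples,
                 librarySize = librarySize, concentration = concentration,
                 nTrees = nTrees, cvFolds = cvFolds, noiseSD = noiseSD,
                 masterSeed = masterSeed, templates = templates),
            class = "benchmarkConfig")
}

.cellLabel <- function(scenario, cell) {
  if (scenario == 2) paste0("m", cell[1], "_v", cell[2])
  else as.character(cell)
}

# simulate the StudyPair for one record (shared by all methods of the
# repetition: methods differ only in normalization)
.simulateCell <- function(cfg, cell, relationship, repSeed, signatureSeed) {
  if (cfg$scenario == 1) {
    simulateScenario1(cfg$templates[[1]], cfg$templates[[2]], ep = cell,
                      relationship = relationship, nSamples = cfg$nSamples,
                      librarySize = cfg$librarySize,
                      concentration = cfg$concentration,
                      noiseSD = cfg$noiseSD, seed = repSeed,
                      signatureSeed = signatureSeed)
  } else if (cfg$scenario == 2) {
    simulateScenario2(cfg$templates[[1]], sevMean = cell[1], sevVar = cell[2],
                      relationship = relationship, nSamples = cfg$nSamples,
                      librarySize = cfg$librarySize,
                      concentration = cfg$concentration,
                      noiseSD = cfg$noiseSD, seed = repSeed,
                      signatureSeed = signatureSeed)
  } else {
    simulateScenario3(cfg$templates[[1]], overlap = cell,
                      relationship = relationship, nSamples = cfg$nSamples,
                      librarySize = cfg$librarySize,
                      concentration = cfg$concentration,
                      noiseSD = cfg$noiseSD, seed = repSeed,
                      signatureSeed = signatureSeed)
  }
}

#' Run the benchmark over a configuration
#'
#' For every cell x relationship x repetition one study pair is simulated
#' (its seed derives from the master seed and the record labels, and excludes
#' the method, so all methods see identical data); every method then
#' normalizes the pair, a random forest is fit on the normalized training
#' data, and the test RMSE is recorded. Failed records are kept with
#' `NA` RMSE and an error message rather than aborting the run. Passing a
#' previous result resumes: completed records are copied over and skipped.
#'
#' @param cfg a [benchmarkConfig()].
#' @param previous optional records data.frame from an earlier (partial) run
#'   with the same config; matching records are not recomputed.
#' @param verbose print per-cell progress.
#' @return A tidy data.frame with one row per record: `scenario`, `cell`,
#'   `relationship`, `method`, `repetition`, `seed`, `rmse`, `error`.
#' @export
runBenchmark <- function(cfg, previous = NULL, verbose = FALSE) {
  .stopIfNot(inherits(cfg, "benchmarkConfig"), "cfg must be a benchmarkConfig")
  signatureSeed <- deriveSeed(cfg$masterSeed, "signature", cfg$scenario)
  rows <- list()
  for (cell in cfg$cells) {
    cl <- .cellLabel(cfg$scenario, cell)
    for (rel in cfg$relationships) {
      for (rep in seq_len(cfg$nReps)) {
        repSeed <- deriveSeed(cfg$masterSeed, cfg$scenario, cl, rel, rep)
        done <- if (is.null(previous)) NULL else
          previous[previous$cell == cl & previous$relationship == rel &
                     previous$repetition == rep, , drop = FALSE]
        pair <- NULL
        for (method in cfg$methods) {
          if (!is.null(done) && method %in% done$method[!is.na(done$rmse)]) {
            rows[[length(rows) + 1]] <-
              done[done$method == method, , drop = FALSE][1, ]
            next
          }
          if (is.null(pair))
            pair <- .simulateCell(cfg, cell, rel, repSeed, signatureSeed)
          rec <- data.frame(scenario = cfg$scenario, cell = cl,
                            relationship = rel, method = method,
                            repetition = rep, seed = repSeed,
                            rmse = NA_real_, error = NA_character_,
                            stringsAsFactors = FALSE)
          res <- tryCatch({
            np <- normalizePair(trainData(pair), testData(pair), method,
                                seed = repSeed)
            pred <- fitPredictRF(np$train, phenotype(trainData(pair)),
                                 np$test, nTrees = cfg$nTrees,
                                 cvFolds = cfg$cvFolds,
                                 seed = deriveSeed(repSeed, method))
            rmse(pred, phenotype(testData(pair)))
          }, error = function(e) e)
          if (inherits(res, "error")) rec$error <- conditionMessage(res)
          else rec$rmse <- res
          rows[[length(rows) + 1]] <- rec
        }
      }
      if (verbose)
        message("scenario ", cfg$scenario, " cell ", cl, " ", rel, " done")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize benchmark records into medians and rank distributions
#'
#' @param records tidy records from [runBenchmark()].
#' @return List with `medians` (one row per cell x relationship x method,
#'   column `medianRMSE`), `ranks` (per cell x relationship rank tables) and
#'   `rankDistribution` (per-method vector of ranks across cells).
#' @export
summarizeBenchmark <- function(records) {
  ok <- records[!is.na(records$rmse), , drop = FALSE]
  dropped <- unique(records$cell[is.na(records$rmse)])
  if (length(dropped))
    warning("records with failures in cell(s): ",
            paste(dropped, collapse = ", "))
  med <- stats::aggregate(rmse ~ scenario + cell + relationship + method,
                          data = ok, FUN = median)
  names(med)[names(med) == "rmse"] <- "medianRMSE"
  keys <- unique(med[, c("cell", "relationship"), drop = FALSE])
  ranks <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- med[med$cell == keys$cell[i] &
                 med$relationship == keys$relationship[i], , drop = FALSE]
    if (nrow(sub) < 2) return(NULL) # ranking needs >= 2 methods
    rk <- rankMethods(setNames(sub$medianRMSE, sub$method))
    cbind(cell = keys$cell[i], relationship = keys$relationship[i], rk)
  })
  ranks <- ranks[!vapply(ranks, is.null, logical(1))]
  ranksDf <- if (length(ranks)) do.call(rbind, ranks) else NULL
  rankDist <- if (is.null(ranksDf)) NULL else split(ranksDf$rank, ranksDf$method)
  list(medians = med, ranks = ranksDf, rankDistribution = rankDist)
}

#' Cross-study prediction matrix over real or synthetic cohorts
#'
#' Every ordered pair of datasets is used once as (training, testing); the
#' pair is normalized by the given method, a random forest predicts the test
#' phenotype, and the median RMSE over `nReps` seeded repetitions is
#' reported. Datasets are harmonized to the union of their taxa (zero fill).
#'
#' @param datasets named list of [PhenoCounts-class] objects with phenotype.
#' @param method a [normMethods()] name (default `"TSS"`).
#' @param nReps repetitions per pair (default 10).
#' @param nTrees,cvFolds random-forest settings.
#' @param seed master seed.
#' @return Square matrix of median RMSE values (rows = training dataset,
#'   columns = testing dataset, `NA` diagonal).
#' @export
crossPredict <- function(datasets, method = "TSS", nReps = 10, nTrees = 500,
                         cvFolds = 5, seed = 1) {
  .stopIfNot(is.list(datasets) && length(datasets) >= 2 &&
               !is.null(names(datasets)), "need a named list of >= 2 datasets")
  small <- names(datasets)[vapply(datasets, ncol, integer(1)) < 30]
  if (length(small))
    warning("dataset(s) below the 30-sample inclusion floor: ",
            paste(small, collapse = ", "))
  taxa <- sort(unique(unlist(lapply(datasets, rownames))))
  harm <- lapply(datasets, function(d) {
    m <- matrix(0, length(taxa), ncol(d), dimnames = list(taxa, colnames(d)))
    m[rownames(d), ] <- counts(d)
    PhenoCounts(m, phenotype = phenotype(d))
  })
  nms <- names(datasets)
  out <- matrix(NA_real_, length(nms), length(nms), dimnames = list(nms, nms))
  for (a in nms) for (b in nms) {
    if (a == b) next
    np <- normalizePair(harm[[a]], harm[[b]], method,
                        seed = deriveSeed(seed, a, b))
    errs <- vapply(seq_len(nReps), function(r) {
      pred <- fitPredictRF(np$train, phenotype(harm[[a]]), np$test,
                           nTrees = nTrees, cvFolds = cvFolds,
                           seed = deriveSeed(seed, a, b, r))
      rmse(pred, phenotype(harm[[b]]))
    }, numeric(1))
    out[a, b] <- median(errs)
  }
  out
}
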