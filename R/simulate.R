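# Dirichlet-multinomial simulator of heterogeneous training/testing study
# pairs: population effects, location-scale batch effects and divergent
# signature-taxa phenotype models.

#' Harmonize two templates onto the union of their taxa
#'
#' Prediction across studies needs a common feature space: the union of the
#' two taxon lists is taken, a taxon absent from one template getting baseline
#' zero there. The shared taxa (positive baseline in both) are also returned;
#' signature taxa may only be drawn from these.
#'
#' @param t1,t2 [TemplateProfile-class] objects.
#' @return List with harmonized `t1`, `t2` and the character vector `shared`.
#' @export
harmonizeTemplates <- function(t1, t2) {
  taxa <- union(t1@taxa, t2@taxa)
  p1 <- setNames(numeric(length(taxa)), taxa)
  p2 <- p1
  p1[t1@taxa] <- t1@p
  p2[t2@taxa] <- t2@p
  list(t1 = TemplateProfile(taxa, p1), t2 = TemplateProfile(taxa, p2),
       shared = taxa[p1 > 0 & p2 > 0])
}

#' Mix two population baselines by a population effect
#'
#' Builds the pseudo-population pair `v1 = ep * p1 + (1 - ep) * p2`,
#' `v2 = p2`, where `ep` in `[0, 1]` quantifies how far the training
#' population departs from the testing one (`ep = 0`: identical populations;
#' `ep = 1`: fully distinct). Templates are normalized to proportions before
#' mixing so sequencing depth does not weight the mixture.
#'
#' @param p1,p2 [TemplateProfile-class] objects on the same taxon list (see
#'   [harmonizeTemplates()]).
#' @param ep population effect in `[0, 1]`.
#' @return List of numeric proportion vectors `v1`, `v2` (named by taxon).
#' @examples
#' t1 <- TemplateProfile(c("a", "b"), c(8, 2))
#' t2 <- TemplateProfile(c("a", "b"), c(2, 8))
#' mixPopulations(t1, t2, 0.5)$v1
#' @export
mixPopulations <- function(p1, p2, ep) {
  .stopIfNot(ep >= 0 && ep <= 1, "population effect ep must lie in [0, 1]")
  .stopIfNot(identical(p1@taxa, p2@taxa),
             "templates must be harmonized to a common taxon list first")
  q1 <- p1@p / sum(p1@p)
  q2 <- p2@p / sum(p2@p)
  v1 <- ep * q1 + (1 - ep) * q2
  list(v1 = setNames(v1 / sum(v1), p1@taxa),
       v2 = setNames(q2, p2@taxa))
}

#' Floor zero entries of a proportion vector
#'
#' Dirichlet concentrations must be positive; zero baseline entries are
#' floored at a small constant and the vector renormalized.
#'
#' @param v proportion vector.
#' @param floor replacement for zero entries (default `1e-8`).
#' @return Renormalized positive proportion vector.
#' @export
floorZeros <- function(v, floor = 1e-8) {
  v[v <= 0] <- floor
  v / sum(v)
}

#' Draw per-sample taxon probability vectors from a Dirichlet distribution
#'
#' Sample compositions follow `Dir(c * v)`: large concentrations `c` keep the
#' per-sample composition close to the population baseline `v` while still
#' injecting sample-to-sample variability.
#'
#' @param v positive proportion vector (apply [floorZeros()] first).
#' @param c concentration (default `1e6`).
#' @param n number of samples.
#' @param seed integer seed.
#' @return Taxa-by-samples matrix; every column sums to 1.
#' @export
drawSampleProbs <- function(v, c = 1e6, n, seed = 1) {
  .stopIfNot(c > 0, "concentration must be positive")
  if (any(v <= 0))
    stop("v contains zero entries; floor the template with floorZeros() first")
  .stopIfNot(abs(sum(v) - 1) < 1e-6, "v must sum to 1")
  set.seed(seed)
  g <- matrix(rgamma(length(v) * n, shape = rep(c * v, n)),
              nrow = length(v), ncol = n)
  probs <- sweep(g, 2, colSums(g), "/")
  rownames(probs) <- names(v)
  colnames(probs) <- paste0("sample_", seq_len(n))
  probs
}

#' Draw multinomial read counts for each sample
#'
#' Each sample's reads follow `MN(librarySize, x_j)` with `x_j` its Dirichlet
#' composition, so every column total equals the library size exactly.
#'
#' @param probs taxa-by-samples probability matrix (columns sum to 1).
#' @param librarySize reads per sample (default `1e6`).
#' @param seed integer seed.
#' @return A [PhenoCounts-class] object.
#' @export
drawCounts <- function(probs, librarySize = 1e6, seed = 1) {
  .stopIfNot(librarySize >= 1, "librarySize must be at least 1")
  .stopIfNot(all(abs(colSums(probs) - 1) < 1e-6), "probability columns must sum to 1")
  set.seed(seed)
  m <- vapply(seq_len(ncol(probs)),
              function(j) rmultinom(1, size = librarySize, prob = probs[, j])[, 1],
              numeric(nrow(probs)))
  dimnames(m) <- dimnames(probs)
  PhenoCounts(m)
}

#' Randomly select a signature-taxa phenotype model
#'
#' Chooses 10 distinct taxa from the shared taxa of the two populations; the
#' first five are enriched (coefficients uniform on `[3, 5]`), the last five
#' depleted (uniform on `[-5, -3]`). The selection is deterministic given the
#' seed and is meant to be held fixed across simulation repetitions.
#'
#' @param sharedTaxa character vector of candidate taxa (at least 10).
#' @param relationship link name (`linear`, `quadratic`, `inverse`,
#'   `logistic`).
#' @param seed integer seed.
#' @param noiseSD noise standard deviation (default 1).
#' @return A [PhenotypeModel-class] with `scaleConstant = NA` (calibrate with
#'   [calibrateScaleConstant()]).
#' @export
selectSignature <- function(sharedTaxa, relationship = "linear", seed = 1,
                            noiseSD = 1) {
  if (length(sharedTaxa) < 10)
    stop("need at least 10 shared taxa to place a signature")
  set.seed(seed)
  sig <- if (length(sharedTaxa) == 10) sharedTaxa else sample(sharedTaxa, 10)
  beta <- c(runif(5, 3, 5), runif(5, -5, -3))
  PhenotypeModel(sig, beta, relationship, NA_real_, noiseSD)
}

# noise-free phenotype response g(x) before scaling; x is the 10 x n
# signature relative-abundance matrix
.signatureResponse <- function(x, model) {
  eta <- as.numeric(crossprod(model@beta, x))
  switch(model@relationship,
         linear = eta,
         quadratic = as.numeric(crossprod(model@beta, x^2)),
         inverse = 1 / pmax(eta, 1e-6),
         logistic = 1 / (1 + exp(eta)))
}

#' Calibrate the phenotype scale constant
#'
#' The scale constants c1..c4 keep simulated phenotypes in the
#' dozens-to-hundreds range. They are calibrated per (population,
#' relationship) from a pilot draw of noise-free samples so that the mean
#' absolute noise-free phenotype equals `targetAbs`.
#'
#' @param v positive proportion vector of the population baseline.
#' @param model [PhenotypeModel-class] (scale may be `NA`).
#' @param concentration Dirichlet concentration of the pilot draw.
#' @param nPilot pilot sample count (default 200).
#' @param targetAbs target mean absolute phenotype (default 50).
#' @param seed integer seed.
#' @return The model with `scaleConstant` filled in.
#' @export
calibrateScaleConstant <- function(v, model, concentration = 1e6,
                                   nPilot = 200, targetAbs = 50, seed = 1) {
  probs <- drawSampleProbs(v, concentration, nPilot, seed = seed)
  g <- .signatureResponse(probs[model@signature, , drop = FALSE], model)
  scale <- targetAbs / max(mean(abs(g)), 1e-12)
  methods::initialize(model, scaleConstant = scale)
}

#' Simulate phenotypes from signature relative abundances
#'
#' Applies the model's link to the signature relative abundances and adds
#' Gaussian noise: `y = scale * g(beta' x) + eps`, `eps ~ N(0, noiseSD^2)`.
#'
#' @param x relative-abundance matrix restricted to the 10 signature taxa
#'   (rows in model signature order, columns are samples), entries in
#'   `[0, 1]`.
#' @param model [PhenotypeModel-class] with a calibrated scale constant.
#' @param seed integer seed for the noise draw.
#' @return Numeric phenotype vector, one per sample.
#' @export
simulatePhenotype <- function(x, model, seed = 1) {
  .stopIfNot(!is.na(model@scaleConstant), "scaleConstant must be calibrated")
  .stopIfNot(nrow(x) == 10, "x must be restricted to the 10 signature taxa")
  g <- .signatureResponse(x, model)
  set.seed(seed)
  model@scaleConstant * g + rnorm(ncol(x), 0, model@noiseSD)
}

#' Solve batch-effect hyperparameters from a severity pair
#'
#' The additive location shift is `gamma ~ N(sevMean, hyperVar)`; the
#' multiplicative scale change is `delta ~ InvGamma(alpha, beta)` with mean
#' `sevVar` and variance `hyperVar`, giving the closed form
#' `alpha = 2 + sevVar^2 / hyperVar`, `beta = sevVar * (alpha - 1)`.
#'
#' @param sevMean batch-mean severity (study grid: 0, 500, 1000).
#' @param sevVar batch-variance severity (study grid: 1, 2, 4).
#' @param hyperVar variance of both hyperpriors (default 0.01).
#' @return A [BatchEffectModel-class].
#' @examples
#' solveBatchHyperparams(500, 2) # alpha = 402, beta = 802
#' @export
solveBatchHyperparams <- function(sevMean, sevVar, hyperVar = 0.01) {
  .stopIfNot(sevVar > 0, "sevVar must be positive")
  .stopIfNot(hyperVar > 0, "hyperVar must be positive")
  alpha <- 2 + sevVar^2 / hyperVar
  beta <- sevVar * (alpha - 1)
  methods::new("BatchEffectModel", sevMean = sevMean, sevVar = sevVar,
               gammaMu = sevMean, gammaVar = hyperVar,
               deltaAlpha = alpha, deltaBeta = beta)
}

#' Sample per-taxon batch parameters from a BatchEffectModel
#'
#' @param model a [BatchEffectModel-class].
#' @param nTaxa number of taxa.
#' @param seed integer seed.
#' @return List with numeric vectors `gamma` (additive) and `delta`
#'   (multiplicative).
#' @export
sampleBatchParams <- function(model, nTaxa, seed = 1) {
  set.seed(seed)
  gamma <- rnorm(nTaxa, model@gammaMu, sqrt(model@gammaVar))
  delta <- 1 / rgamma(nTaxa, shape = model@deltaAlpha, rate = model@deltaBeta)
  list(gamma = gamma, delta = delta)
}

#' Corrupt a training count table with batch effects
#'
#' Per taxon `i` with mean count `m_i`, each count is re-centred and
#' re-scaled: `c' = round(max(0, (c - m_i) * sqrt(delta_i) + m_i + gamma_i))`
#' -- the location-scale reading of the ComBat generative model. Batch
#' effects are technical, so they are applied to the counts only (phenotypes
#' are simulated from the uncorrupted abundances) and, in scenario 2, to the
#' training table only.
#'
#' @param x a [PhenoCounts-class] object (the training table).
#' @param model a [BatchEffectModel-class].
#' @param seed integer seed for the per-taxon parameter draws.
#' @return A [PhenoCounts-class] with corrupted counts (phenotype preserved).
#' @export
applyBatchEffects <- function(x, model, seed = 1) {
  m <- counts(x)
  par <- sampleBatchParams(model, nrow(m), seed = seed)
  mi <- rowMeans(m)
  out <- round(pmax((m - mi) * sqrt(par$delta) + mi + par$gamma, 0))
  dimnames(out) <- dimnames(m)
  PhenoCounts(out, phenotype = phenotype(x))
}

# internal: draw one population (counts + phenotype) from baseline v
.drawStudy <- function(v, model, nSamples, librarySize, concentration, seed) {
  probs <- drawSampleProbs(v, concentration, nSamples, seed = seed)
  tab <- drawCounts(probs, librarySize, seed = seed + 1L)
  rel <- sweep(counts(tab), 2, colSums(counts(tab)), "/")
  y <- simulatePhenotype(rel[model@signature, , drop = FALSE], model,
                         seed = seed + 2L)
  phenotype(tab) <- y
  tab
}

#' Scenario 1: different background taxon distributions
#'
#' Two populations are built by mixing two template baselines with population
#' effect `ep` (training population `v1`, testing population `v2 = p2`); a
#' single signature model on the shared taxa drives the phenotype in both.
#'
#' @param template1,template2 [TemplateProfile-class] objects (train-like and
#'   test-like populations).
#' @param ep population effect in `{0, 0.2, ..., 1}` (any value in `[0, 1]`
#'   is accepted).
#' @param relationship phenotype link.
#' @param nSamples samples per population (default 100).
#' @param librarySize reads per sample (default `1e6`).
#' @param concentration Dirichlet concentration (default `1e6`).
#' @param noiseSD phenotype noise SD (default 1).
#' @param seed per-repetition seed.
#' @param signatureSeed seed of the signature selection, held fixed across
#'   repetitions (default 1000).
#' @return A [StudyPair-class].
#' @export
simulateScenario1 <- function(template1, template2, ep,
                              relationship = "linear", nSamples = 100,
                              librarySize = 1e6, concentration = 1e6,
                              noiseSD = 1, seed = 1, signatureSeed = 1000) {
  h <- harmonizeTemplates(template1, template2)
  mix <- mixPopulations(h$t1, h$t2, ep)
  v1 <- floorZeros(mix$v1)
  v2 <- floorZeros(mix$v2)
  model <- selectSignature(h$shared, relationship, seed = signatureSeed,
                           noiseSD = noiseSD)
  model <- calibrateScaleConstant(v2, model, concentration,
                                  seed = signatureSeed + 1L)
  train <- .drawStudy(v1, model, nSamples, librarySize, concentration,
                      seed = seed)
  test <- .drawStudy(v2, model, nSamples, librarySize, concentration,
                     seed = seed + 7919L)
  methods::new("StudyPair", train = train, test = test,
               truth = list(train = model, test = model),
               scenario = list(scenario = 1, ep = ep,
                               relationship = relationship))
}

#' Scenario 2: batch effects between studies of one population
#'
#' Both studies are drawn from one template baseline; location-scale batch
#' effects of the given severity corrupt the training counts only (the
#' phenotype is computed from the pre-batch abundances).
#'
#' @param template a [TemplateProfile-class].
#' @param sevMean,sevVar batch severity (grids `{0, 500, 1000}` and
#'   `{1, 2, 4}`).
#' @param relationship phenotype link.
#' @inheritParams simulateScenario1
#' @param hyperVar hyperprior variance (default 0.01).
#' @return A [StudyPair-class].
#' @export
simulateScenario2 <- function(template, sevMean, sevVar,
                              relationship = "linear", nSamples = 100,
                              librarySize = 1e6, concentration = 1e6,
                              noiseSD = 1, hyperVar = 0.01, seed = 1,
                              signatureSeed = 1000) {
  v <- floorZeros(template@p / sum(template@p))
  names(v) <- template@taxa
  shared <- template@taxa[template@p > 0]
  model <- selectSignature(shared, relationship, seed = signatureSeed,
                           noiseSD = noiseSD)
  model <- calibrateScaleConstant(v, model, concentration,
                                  seed = signatureSeed + 1L)
  train <- .drawStudy(v, model, nSamples, librarySize, concentration,
                      seed = seed)
  test <- .drawStudy(v, model, nSamples, librarySize, concentration,
                     seed = seed + 7919L)
  batch <- solveBatchHyperparams(sevMean, sevVar, hyperVar)
  train <- applyBatchEffects(train, batch, seed = seed + 104729L)
  methods::new("StudyPair", train = train, test = test,
               truth = list(train = model, test = model),
               scenario = list(scenario = 2, sevMean = sevMean,
                               sevVar = sevVar, relationship = relationship))
}

#' Scenario 3: divergent phenotype models between studies
#'
#' Both studies share one population baseline and noise model, but the test
#' study keeps only `overlap` of the training signature taxa (balanced across
#' the enriched and depleted halves) and replaces the rest with fresh taxa
#' and coefficients, always totalling 10 signature taxa.
#'
#' @param template a [TemplateProfile-class].
#' @param overlap number of signature taxa shared by the two models
#'   (`{2, 4, 6, 8, 10}`).
#' @param relationship phenotype link.
#' @inheritParams simulateScenario1
#' @return A [StudyPair-class].
#' @export
simulateScenario3 <- function(template, overlap, relationship = "linear",
                              nSamples = 100, librarySize = 1e6,
                              concentration = 1e6, noiseSD = 1, seed = 1,
                              signatureSeed = 1000) {
  .stopIfNot(overlap %in% c(2, 4, 6, 8, 10),
             "overlap must be one of 2, 4, 6, 8, 10")
  v <- floorZeros(template@p / sum(template@p))
  names(v) <- template@taxa
  shared <- template@taxa[template@p > 0]
  trainModel <- selectSignature(shared, relationship, seed = signatureSeed,
                                noiseSD = noiseSD)
  testModel <- .overlapModel(trainModel, shared, overlap,
                             seed = signatureSeed + 13L)
  trainModel <- calibrateScaleConstant(v, trainModel, concentration,
                                       seed = signatureSeed + 1L)
  # one scale constant per (template, relationship): the test model reuses the
  # training constant so RMSE stays on one scale across the overlap grid
  testModel <- methods::initialize(testModel,
                                   scaleConstant = trainModel@scaleConstant)
  train <- .drawStudy(v, trainModel, nSamples, librarySize, concentration,
                      seed = seed)
  test <- .drawStudy(v, testModel, nSamples, librarySize, concentration,
                     seed = seed + 7919L)
  methods::new("StudyPair", train = train, test = test,
               truth = list(train = trainModel, test = testModel),
               scenario = list(scenario = 3, overlap = overlap,
                               relationship = relationship))
}

# build the test-study model sharing `overlap` taxa with the training model;
# keeps overlap/2 enriched and overlap/2 depleted taxa (with their
# coefficients) and fills the remaining slots with fresh taxa and
# coefficients
.overlapModel <- function(trainModel, sharedTaxa, overlap, seed = 1) {
  if (overlap == 10) return(trainModel)
  set.seed(seed)
  keepPos <- trainModel@signature[seq_len(overlap / 2)]
  keepNeg <- trainModel@signature[5 + seq_len(overlap / 2)]
  nNew <- (10 - overlap) / 2
  pool <- setdiff(sharedTaxa, trainModel@signature)
  .stopIfNot(length(pool) >= 2 * nNew,
             "not enough shared taxa to draw replacement signature taxa")
  fresh <- sample(pool, 2 * nNew)
  sig <- c(keepPos, fresh[seq_len(nNew)], keepNeg, fresh[nNew + seq_len(nNew)])
  beta <- c(trainModel@beta[seq_len(overlap / 2)], runif(nNew, 3, 5),
            trainModel@beta[5 + seq_len(overlap / 2)], runif(nNew, -5, -3))
  PhenotypeModel(sig, beta, trainModel@relationship, NA_real_,
                 trainModel@noiseSD)
}
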