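# Small in-code fixtures shared across the suite.

# random sparse Poisson count matrix with dimnames
makeCounts <- function(nTaxa, nSamples, seed = 1, lambda = 20,
                       zeroProb = 0.3) {
  set.seed(seed)
  m <- matrix(rpois(nTaxa * nSamples, lambda), nTaxa, nSamples)
  m[matrix(runif(nTaxa * nSamples) < zeroProb, nTaxa, nSamples)] <- 0
  # keep every sample non-empty
  for (j in which(colSums(m) == 0)) m[1, j] <- 1
  dimnames(m) <- list(paste0("t", seq_len(nTaxa)), paste0("s", seq_len(nSamples)))
  m
}

# a valid PhenotypeModel with controllable coefficients
makeModel <- function(relationship = "linear", scale = 10, noiseSD = 0,
                      beta = c(rep(4, 5), rep(-4, 5)),
                      taxa = paste0("t", 1:10)) {
  PhenotypeModel(taxa, beta, relationship, scale, noiseSD)
}

# quick small study pair (scenario 1) for protocol-level tests
makeStudyPair <- function(seed = 1, nSamples = 15, ep = 0.4) {
  t1 <- baselineVector(synthesizeTemplate(60, 12, zeroFraction = 0.5,
                                          seed = seed))
  t2 <- baselineVector(synthesizeTemplate(70, 12, zeroFraction = 0.5,
                                          seed = seed + 1))
  simulateScenario1(t1, t2, ep = ep, nSamples = nSamples, librarySize = 5e4,
                    seed = seed + 2, signatureSeed = 99)
}
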