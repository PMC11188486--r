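# MicrobiomeNormBench

Benchmarking normalization methods for **cross-study quantitative phenotype
prediction** from metagenomic count data.

Microbiome count tables are compositional, sparse and heterogeneous across
cohorts: differences in population background, technical batch effects and
divergent phenotype-taxon associations all degrade a model trained on one
study when it is applied to another. A long list of normalization methods
promises to remove part of that heterogeneity. This package asks the
operational question: *when a random-forest regressor is trained on one
study and scored on another, does the choice of normalization method change
the prediction error?*

It provides:

* **A heterogeneity simulator.** Study pairs are generated from
  Dirichlet-multinomial sampling around population baseline vectors
  `v = ep * p1 + (1 - ep) * p2` (population effect `ep`), with per-sample
  compositions `x_j ~ Dir(c * v)` and counts `MN(librarySize, x_j)`.
  Quantitative phenotypes follow one of four links on 10 signature taxa
  (coefficients uniform on `[3, 5]` and `[-5, -3]`):
  linear `y = c1 * b'x + e`, quadratic `y = c2 * b'x^2 + e`, inverse
  `y = c3 / (b'x) + e`, logistic `y = c4 / (1 + exp(b'x)) + e`,
  `e ~ N(0, 1)`. Batch effects are location-scale corruptions with
  per-taxon `gamma ~ N(sev_mean, 0.01)` and
  `delta ~ InvGamma(alpha, beta)` solved so that `E[delta] = sev_var` and
  `Var = 0.01`. A third scenario varies the *overlap* (2..10) between the
  training and testing signature-taxa models.
* **21 normalization methods implemented from their formulas** — scaling
  (TSS, UQ, MED, CSS, TMM, RLE, GMPR), compositional (CLR), transformations
  (LOG, AST, STD, Rank, Blom, NPN, logCPM, VST) and batch corrections (QN,
  FSQN, BMC, linear-model, ComBat) — behind one train/test protocol that
  keeps the test data out of the training-set normalization (reference- and
  distribution-based methods extract the test columns from a joint
  train+test pass).
* **A seeded prediction stage**: random-forest regression (`ranger`) with
  cross-validated `mtry`, RMSE scoring, and 1..K ranking of methods by
  median RMSE.
* **A community-statistics audit**: Shannon diversity, Bray-Curtis
  dissimilarity, PCoA, marginal PERMANOVA and Wilcoxon shift tests.

## Worked example

```r
library(MicrobiomeNormBench)

# two synthetic cohort templates (train-like and test-like populations)
t1 <- baselineVector(synthesizeTemplate(150, 30, zeroFraction = 0.6, seed = 101))
t2 <- baselineVector(synthesizeTemplate(180, 40, zeroFraction = 0.6, seed = 102))

# one simulated study pair at population effect 0.4
sp <- simulateScenario1(t1, t2, ep = 0.4, relationship = "linear",
                        nSamples = 50, librarySize = 1e5, seed = 3)
sp
#> StudyPair (scenario 1 ): 180 taxa; 50 train / 50 test samples
#>    ep = 0.4, relationship = linear

# normalize by TSS and score a random forest on the held-out study
np <- normalizePair(trainData(sp), testData(sp), "TSS")
pred <- fitPredictRF(np$train, phenotype(trainData(sp)), np$test,
                     nTrees = 200, cvFolds = 5, seed = 9)
rmse(pred, phenotype(testData(sp)))
#> [1] 6.922179

# a small benchmark over a method panel
cfg <- benchmarkConfig(1, cells = c(0.2, 1), relationships = "linear",
                       methods = c("TSS", "CLR", "TMM", "BMC"), nReps = 5,
                       nSamples = 50, librarySize = 1e5, nTrees = 200,
                       cvFolds = 5, masterSeed = 11, templates = list(t1, t2))
sm <- summarizeBenchmark(runBenchmark(cfg))
sm$medians
#>   scenario cell relationship method medianRMSE
#> 1        1  0.2       linear    BMC   12.52378
#> 2        1    1       linear    BMC   61.93906
#> 3        1  0.2       linear    CLR   12.09978
#> 4        1    1       linear    CLR   61.57113
#> 5        1  0.2       linear    TMM   12.26967
#> 6        1    1       linear    TMM   61.49386
#> 7        1  0.2       linear    TSS   12.40335
#> 8        1    1       linear    TSS   61.79904

# within a cell the methods sit within a few percent of one another, while
# moving ep from 0.2 to 1 multiplies the error fivefold: heterogeneity, not
# normalization, drives cross-study accuracy
```

The RMSE is in phenotype units (phenotypes are calibrated to a mean
absolute value of about 50, the body-mass-index-like "dozens" range). The
interesting quantity is the *spread* of median RMSE across methods within
one simulation cell: a small spread relative to its mean says the
normalization choice does not drive cross-study prediction accuracy.

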