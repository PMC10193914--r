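test_that("null phenotypes have the distributional signatures of their kind", {
  n <- 10000
  ph <- simulateNullPhenotype("normal", n, seed = 51)
  expect_lt(abs(mean(phenotypeValues(ph))), 0.05)
  expect_lt(abs(sd(phenotypeValues(ph)) - 1), 0.05)
  expect_identical(phenotypeKind(ph), "continuous")

  ph <- simulateNullPhenotype("chisq1", n, seed = 52)
  v <- phenotypeValues(ph)
  skew <- mean((v - mean(v))^3) / sd(v)^3
  expect_lt(abs(skew - sqrt(8)), 0.4)   # chi-squared(1) skewness = sqrt(8)

  ph <- simulateNullPhenotype("dichot25", n, seed = 53)
  expect_lt(abs(mean(phenotypeValues(ph)) - 0.25), 0.02)
  expect_identical(phenotypeKind(ph), "dichotomous")
  ph <- simulateNullPhenotype("dichot50", n, seed = 54)
  expect_lt(abs(mean(phenotypeValues(ph)) - 0.50), 0.02)
})

test_that("GFP machinery respects degenerate q thresholds and seeds", {
  ds <- smallDataset(nSubjects = 40, nRegions = 12, seed = 55)
  rs <- buildRegions(ds, verbose = FALSE)
  r1 <- estimateGFP(ds, rs, "normal", nReplicates = 10, baseSeed = 3,
                    qThreshold = 1.001)
  expect_equal(simRate(r1), 1)           # everything is "significant"
  r0 <- estimateGFP(ds, rs, "normal", nReplicates = 10, baseSeed = 3,
                    qThreshold = 0)
  expect_equal(simRate(r0), 0)
  # reproducibility: identical seeds give identical reports
  a <- estimateGFP(ds, rs, "normal", nReplicates = 15, baseSeed = 9)
  b <- estimateGFP(ds, rs, "normal", nReplicates = 15, baseSeed = 9)
  expect_identical(simFlags(a), simFlags(b))
  expect_equal(simMcSE(a), sqrt(simRate(a) * (1 - simRate(a)) / 15))
})

test_that("PCA caching does not change the replicate outcomes", {
  ds <- smallDataset(nSubjects = 40, nRegions = 10, seed = 56)
  rs <- buildRegions(ds, verbose = FALSE)
  cached <- estimateGFP(ds, rs, "normal", nReplicates = 8, baseSeed = 2,
                        cache = TRUE)
  fresh <- estimateGFP(ds, rs, "normal", nReplicates = 8, baseSeed = 2,
                       cache = FALSE)
  expect_identical(simFlags(cached), simFlags(fresh))
})

test_that("the fast replicate engine agrees with analyseRegions", {
  ds <- smallDataset(nSubjects = 45, nRegions = 12, seed = 57)
  rs <- buildRegions(ds, verbose = FALSE)
  for (kindSeed in list(c("normal", 11), c("dichot50", 12))) {
    ph <- simulateNullPhenotype(kindSeed[1], 45, colnames(ds),
                                seed = as.integer(kindSeed[2]))
    for (m in c("fisher", "stouffer", "joint")) {
      res <- analyseRegions(ds, rs, ph, method = m, verbose = FALSE)
      rep1 <- estimateGFP(ds, rs, kindSeed[1], nReplicates = 1,
                          baseSeed = as.integer(kindSeed[2]) - 1,
                          method = m, qThreshold = 0.05)
      expect_identical(simFlags(rep1), as.numeric(any(res$q_value < 0.05)))
    }
  }
})

test_that("subject resampling draws a fresh subset per replicate", {
  ds <- smallDataset(nSubjects = 50, nRegions = 8, seed = 58)
  rs <- buildRegions(ds, verbose = FALSE)
  rep <- estimateGFP(ds, rs, "normal", nReplicates = 4, baseSeed = 1,
                     resampleSubjects = TRUE, resampleN = 25)
  expect_equal(rep@nReplicates, 4L)
  expect_equal(rep@params$n, 25)
  # reproducible as well
  rep2 <- estimateGFP(ds, rs, "normal", nReplicates = 4, baseSeed = 1,
                      resampleSubjects = TRUE, resampleN = 25)
  expect_identical(simFlags(rep), simFlags(rep2))
})

test_that("signal phenotypes anchor at the maximal-loading causal probes", {
  set.seed(61)
  n <- 400
  p <- 8
  l1 <- c(rep(0.9, 4), rep(0.1, 4))
  l2 <- c(rep(0.1, 4), rep(0.6, 4))
  X <- generateTwoFactorRegion(p, l1, l2, n)
  colnames(X) <- paste0("cg", 1:p)
  rownames(X) <- paste0("S", 1:n)
  pca <- computeRegionPCA(asResiduals(X))
  cp <- causalProbes(pca)
  expect_true(cp["pc1"] %in% 1:4 || cp["pc1"] %in% 5:8)
  expect_true(cp["pc1"] != cp["pc2"])   # separated causal probes
  expect_true((cp["pc1"] <= 4) != (cp["pc2"] <= 4))

  # vanishing noise: phenotype converges to the causal probe's values
  ph <- simulateSignalPhenotype(pca, X, "cts_pc1", noiseSD = 1e-8,
                                seed = 2)
  expect_gt(cor(phenotypeValues(ph), X[, cp["pc1"]]), 0.999999)

  # median dichotomization gives a 50/50 split for even n
  ph <- simulateSignalPhenotype(pca, X, "dts_pc1", noiseSD = 1, seed = 3)
  expect_equal(mean(phenotypeValues(ph)), 0.5)
  expect_identical(phenotypeKind(ph), "dichotomous")

  # calibrated noise hits the target correlation on average
  sdN <- calibrateNoiseSD(X[, cp["pc1"]], targetCorr = 0.15)
  cors <- vapply(1:200, function(r) {
    ph <- simulateSignalPhenotype(pca, X, "cts_pc1", noiseSD = sdN,
                                  seed = 100 + r)
    cor(phenotypeValues(ph), X[, cp["pc1"]])
  }, numeric(1))
  expect_lt(abs(median(cors) - 0.15), 0.03)
})

test_that("the mixed signal is the mean of the standardized components", {
  set.seed(62)
  X <- generateTwoFactorRegion(6, c(rep(0.8, 3), rep(0.1, 3)),
                               c(rep(0.1, 3), rep(0.6, 3)), 100)
  colnames(X) <- paste0("cg", 1:6); rownames(X) <- paste0("S", 1:100)
  pca <- computeRegionPCA(asResiduals(X))
  cp <- causalProbes(pca)
  ph <- simulateSignalPhenotype(pca, X, "cts_pc1pc2", noiseSD = 2,
                                seed = 9)
  # reconstruct with the same seed and noise stream
  set.seed(9)
  c1 <- X[, cp["pc1"]] + rnorm(100, sd = 2)
  c2 <- X[, cp["pc2"]] + rnorm(100, sd = 2)
  expect_equal(unname(phenotypeValues(ph)),
               unname((as.numeric(scale(c1)) + as.numeric(scale(c2))) / 2),
               tolerance = 1e-12)
})

test_that("TP rate decreases with noise and vanishes at extreme noise", {
  ds <- smallDataset(nSubjects = 80, nRegions = 10, seed = 63)
  rs <- buildRegions(ds, verbose = FALSE)
  resid <- residualizeMethylation(ds)
  pcas <- precomputeRegionPCA(resid, rs)
  macs <- vapply(pcas, function(p) p@mac, numeric(1))
  rid <- names(which.max(macs))   # a strongly correlated region
  mC <- t(mValues(ds))[, regionProbes(rs)[[rid]], drop = FALSE]
  sd0 <- sd(mC[, causalProbes(pcas[[rid]])["pc1"]])

  rates <- vapply(c(0.5, 2, 8) * sd0, function(s)
    simRate(estimateTP(ds, rs, rid, "cts_pc1", noiseSD = s,
                       nReplicates = 120, baseSeed = 40,
                       pcaCache = pcas)), numeric(1))
  expect_true(all(diff(rates) <= 0))
  expect_gt(rates[1], rates[3])

  # absurd noise degenerates to the null rejection rate
  nullish <- simRate(estimateTP(ds, rs, rid, "cts_pc1",
                                noiseSD = 1e6 * sd0, nReplicates = 200,
                                baseSeed = 41, pcaCache = pcas))
  expect_lt(abs(nullish - 0.05), 3 * sqrt(0.05 * 0.95 / 200) + 1e-9)
})
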