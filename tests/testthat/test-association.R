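# brute-force oracles, independent of the implementation paths
fisherOracle <- function(p) pchisq(-2 * sum(log(p)), 2 * length(p),
                                   lower.tail = FALSE)
stoufferOracle <- function(p) pnorm(sum(qnorm(1 - p)) / sqrt(length(p)),
                                    lower.tail = FALSE)
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- numeric(m)
  run <- 1
  for (idx in seq_len(m)) {
    i <- o[idx]
    rank <- m - idx + 1
    run <- min(run, p[i] * m / rank)
    adj[i] <- run
  }
  pmin(adj, 1)
}

test_that("Fisher combination matches its closed form and the k=1 identity", {
  # closed form for 4 df: exp(-X/2) * (1 + X/2)
  X <- -2 * 2 * log(0.5)
  expect_equal(fisherCombine(c(0.5, 0.5)), exp(-X / 2) * (1 + X / 2),
               tolerance = 1e-10)
  expect_equal(fisherCombine(c(0.5, 0.5)), 0.59657, tolerance = 1e-4)
  expect_identical(fisherCombine(0.05), 0.05)        # k = 1: no meta-analysis
  expect_equal(fisherCombine(c(1, 1)), 1)
  expect_error(fisherCombine(c(0.5, 0)), "\\(0, 1\\]")
  set.seed(31)
  for (i in 1:200) {
    p <- runif(sample(2:8, 1))
    expect_equal(fisherCombine(p), fisherOracle(p), tolerance = 1e-6)
  }
})

test_that("Stouffer combination matches the normal-sum oracle", {
  expect_equal(stoufferCombine(c(0.5, 0.5)), 0.5, tolerance = 1e-12)
  expect_identical(stoufferCombine(0.05), 0.05)
  expect_equal(stoufferCombine(c(0.05, 0.05)),
               pnorm(2 * qnorm(0.95) / sqrt(2), lower.tail = FALSE),
               tolerance = 1e-10)
  expect_lt(abs(stoufferCombine(c(0.05, 0.05)) - 0.01001), 1e-4)
  expect_warning(p <- stoufferCombine(c(1, 0.2)), "clamped")
  expect_true(p > 0 && p < 1)
  set.seed(32)
  for (i in 1:200) {
    p <- runif(sample(2:8, 1), 0.001, 0.999)
    expect_equal(stoufferCombine(p), stoufferOracle(p), tolerance = 1e-6)
  }
})

test_that("BH q-values agree with a brute-force step-up on random vectors", {
  expect_equal(bhFDR(0.03), 0.03)
  expect_equal(bhFDR(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bhFDR(rep(0.05, 7)), rep(0.05, 7))
  set.seed(33)
  for (i in 1:1000) {
    p <- runif(sample(1:50, 1))
    expect_equal(bhFDR(p), bhOracle(p), tolerance = 1e-12)
  }
})

test_that("per-PC p-value equals lm in both regression directions", {
  set.seed(34)
  n <- 80
  y <- rnorm(n)
  s <- 0.3 * y + rnorm(n)
  p <- pcPhenotypePValue(s, y)
  lmP <- function(f, d) summary(lm(f, d))$coefficients[2, 4]
  d <- data.frame(s = s, y = y)
  expect_equal(p, lmP(s ~ y, d), tolerance = 1e-12)
  expect_equal(p, lmP(y ~ s, d), tolerance = 1e-12)   # direction-free
  expect_equal(pcPhenotypePValue(-s, y), p, tolerance = 1e-12)  # sign flip
  # binary predictor: identical to the pooled-variance two-sample t-test
  g <- rbinom(n, 1, 0.4)
  expect_equal(pcPhenotypePValue(s, g),
               t.test(s ~ g, var.equal = TRUE)$p.value, tolerance = 1e-12)
  # perfect fit
  expect_lt(pcPhenotypePValue(y, y), 1e-12)
  expect_error(pcPhenotypePValue(s, rep(1, n)), "constant")
})

test_that("per-PC p-values are uniform under the null", {
  set.seed(35)
  n <- 100
  s <- rnorm(n)
  ps <- replicate(1000, pcPhenotypePValue(s, rnorm(n)))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the joint F-test matches lm and reduces to t^2 at k=1", {
  set.seed(36)
  n <- 60
  S <- matrix(rnorm(n * 3), n)
  y <- rnorm(n) + 0.2 * S[, 1]
  p <- jointPCPValue(y, S, kind = "continuous")
  f <- summary(lm(y ~ S))$fstatistic
  expect_equal(p, pf(f[1], f[2], f[3], lower.tail = FALSE),
               ignore_attr = TRUE, tolerance = 1e-12)
  # k = 1: F = t^2, so the p-values coincide exactly
  expect_equal(jointPCPValue(y, S[, 1, drop = FALSE], kind = "continuous"),
               pcPhenotypePValue(S[, 1], y), tolerance = 1e-12)
})

test_that("the joint F-test has exact size under the null", {
  set.seed(37)
  n <- 200
  S <- matrix(rnorm(n * 3), n)
  rej <- mean(replicate(2000, jointPCPValue(rnorm(n), S,
                                            kind = "continuous") < 0.05))
  expect_lt(abs(rej - 0.05), 0.015)
})

test_that("the logistic joint test is inflated at small n with many PCs", {
  set.seed(38)
  n <- 100
  S <- matrix(rnorm(n * 10), n)
  rej <- mean(replicate(400, {
    y <- rbinom(n, 1, 0.25)
    while (length(unique(y)) < 2) y <- rbinom(n, 1, 0.25)
    as.numeric(jointPCPValue(y, S, kind = "dichotomous")) < 0.05
  }))
  expect_gt(rej, 0.05)   # small-sample likelihood-ratio inflation
})

test_that("analyseRegions produces consistent, sign-invariant results", {
  ds <- smallDataset(nSubjects = 50, nRegions = 20, seed = 41)
  rs <- buildRegions(ds, verbose = FALSE)
  ph <- simulateNullPhenotype("normal", 50, colnames(ds), seed = 5)

  res <- analyseRegions(ds, rs, ph, verbose = FALSE)
  expect_true(all(res$p_region > 0 & res$p_region <= 1))
  expect_true(all(res$q_value > 0 & res$q_value <= 1))
  expect_equal(res$q_value, bhFDR(res$p_region))
  expect_true(all(res$mac >= 0.3))
  expect_true(all(res$k >= 1 & res$k <= 10))

  # deterministic: identical inputs give identical output
  res2 <- analyseRegions(ds, rs, ph, verbose = FALSE)
  expect_identical(as.data.frame(res), as.data.frame(res2))

  # region p-values are invariant to PC score sign flips
  resid <- residualizeMethylation(ds)
  pcas <- precomputeRegionPCA(resid, rs)
  flipped <- lapply(pcas, function(p) {
    p@scores <- -p@scores
    p@loadings <- -p@loadings
    p
  })
  for (m in c("fisher", "stouffer", "joint")) {
    a <- analyseRegions(ds, rs, ph, method = m, pcaCache = pcas,
                        verbose = FALSE)
    b <- analyseRegions(ds, rs, ph, method = m, pcaCache = flipped,
                        verbose = FALSE)
    expect_equal(a$p_region, b$p_region, tolerance = 1e-10)
  }
})

test_that("k=1 makes all meta variants equal the PC1 regression p-value", {
  ds <- smallDataset(nSubjects = 50, nRegions = 15, seed = 43)
  rs <- buildRegions(ds, verbose = FALSE)
  ph <- simulateNullPhenotype("normal", 50, colnames(ds), seed = 7)
  resid <- residualizeMethylation(ds)
  pcas <- precomputeRegionPCA(resid, rs)

  fis <- analyseRegions(ds, rs, ph, method = "fisher", firstPCOnly = TRUE,
                        pcaCache = pcas, verbose = FALSE)
  sto <- analyseRegions(ds, rs, ph, method = "stouffer",
                        firstPCOnly = TRUE, pcaCache = pcas,
                        verbose = FALSE)
  expect_identical(fis$p_region, sto$p_region)
  direct <- vapply(fis$region_id, function(id)
    pcPhenotypePValue(pcaScores(pcas[[id]])[, 1],
                      unname(phenotypeValues(ph)[colnames(ds)])),
    numeric(1))
  expect_equal(fis$p_region, unname(direct), tolerance = 1e-12)
  expect_true(all(fis$k == 1L))
  # joint at k=1 with a continuous phenotype: F = t^2, same p
  joi <- analyseRegions(ds, rs, ph, method = "joint", firstPCOnly = TRUE,
                        pcaCache = pcas, verbose = FALSE)
  expect_equal(joi$p_region, fis$p_region, tolerance = 1e-10)
})

test_that("Fisher regional p-value is monotone in any per-PC p-value", {
  base <- c(0.2, 0.5, 0.8)
  for (j in 1:3) {
    lowered <- base; lowered[j] <- base[j] / 4
    expect_lt(fisherCombine(lowered), fisherCombine(base))
  }
})

test_that("the phenotype must not be among the covariates", {
  ds <- smallDataset(nSubjects = 30, nRegions = 8, seed = 44)
  rs <- buildRegions(ds, verbose = FALSE)
  ph <- Phenotype(setNames(rnorm(30), colnames(ds)), name = "age")
  expect_error(analyseRegions(ds, rs, ph, verbose = FALSE),
               "must not be part of the covariate set")
})

test_that("an empty retained set yields an empty result with a warning", {
  ds <- smallDataset(nSubjects = 30, nRegions = 8, seed = 45)
  rs <- buildRegions(ds, verbose = FALSE)
  ph <- simulateNullPhenotype("normal", 30, colnames(ds), seed = 1)
  expect_warning(res <- analyseRegions(ds, rs, ph, macMin = 1.01,
                                       verbose = FALSE),
                 "no regions pass")
  expect_equal(nrow(res), 0L)
})
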