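#' Draw a null phenotype, independent of all methylation data
#'
#' Four phenotype types are supported: a standard-normal continuous
#' phenotype (`"normal"`), a skewed continuous phenotype from the
#' chi-squared distribution with 1 df (`"chisq1"`), and dichotomous
#' phenotypes with expected case fractions 50% (`"dichot50"`) and 25%
#' (`"dichot25"`), drawn as independent Bernoulli variables.
#'
#' @param kind one of `"normal"`, `"chisq1"`, `"dichot50"`, `"dichot25"`.
#' @param n number of subjects.
#' @param subjectIds optional ids used to name the values.
#' @param seed optional seed; when `NULL` the current RNG stream is used
#'   (callers such as [estimateGFP()] seed per replicate).
#' @return a [Phenotype-class] named `"null_<kind>"`.
#' @export
simulateNullPhenotype <- function(kind = c("normal", "chisq1", "dichot50",
                                           "dichot25"),
                                  n, subjectIds = NULL, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  if (n < 2L) stop("need n >= 2")
  v <- switch(kind,
    normal = stats::rnorm(n),
    chisq1 = stats::rchisq(n, df = 1),
    dichot50 = .bernoulliBothClasses(n, 0.5),
    dichot25 = .bernoulliBothClasses(n, 0.25))
  Phenotype(v, kind = if (startsWith(kind, "dichot")) "dichotomous"
                      else "continuous",
            name = paste0("null_", kind),
            subjectIds = if (is.null(subjectIds)) as.character(seq_len(n))
                         else subjectIds)
}

.bernoulliBothClasses <- function(n, prob) {
  for (i in 1:100) {
    v <- stats::rbinom(n, 1L, prob)
    if (length(unique(v)) == 2L) return(v)
  }
  stop("failed to draw a dichotomous phenotype with both classes")
}

.simReport <- function(label, params, flags) {
  rate <- mean(flags)
  new("SimulationReport", label = label, params = params,
      nReplicates = length(flags), rate = rate,
      mcSE = sqrt(rate * (1 - rate) / length(flags)),
      flags = as.numeric(flags))
}

#' @describeIn SimulationReport-class brief summary
#' @param object a `SimulationReport`
#' @export
setMethod("show", "SimulationReport", function(object) {
  cat(sprintf("SimulationReport: %s\n  rate = %.4f (MC SE %.4f, %d replicates)\n",
              object@label, object@rate, object@mcSE, object@nReplicates))
})

#' @rdname SimulationReport-class
#' @param x a `SimulationReport`
#' @export
simRate <- function(x) x@rate

#' @rdname SimulationReport-class
#' @export
simMcSE <- function(x) x@mcSE

#' @rdname SimulationReport-class
#' @export
simFlags <- function(x) x@flags

# Precompute everything phenotype-independent for fast replicate evaluation:
# residuals, per-region PCA, MAC filter, k selection, and the concatenated
# score matrix with its region grouping.
.nullEngine <- function(dataset, regionSet, varThreshold, kMax, firstPCOnly,
                        macMin, covariates, pcaCache = NULL,
                        verbose = FALSE) {
  if (is.null(pcaCache)) {
    resid <- residualizeMethylation(dataset, covariates = covariates)
    pcaCache <- precomputeRegionPCA(resid, regionSet)
  }
  kept <- filterRegions(regionSet, pcaCache, macMin = macMin,
                        verbose = verbose)
  ids <- regionIds(kept)
  kVec <- vapply(ids, function(id)
    selectK(pcaCache[[id]]@varianceFractions, varThreshold, kMax,
            firstPCOnly), integer(1L))
  S <- do.call(cbind, lapply(ids, function(id)
    pcaCache[[id]]@scores[, seq_len(kVec[[id]]), drop = FALSE]))
  list(ids = ids, kVec = unname(kVec), S = S,
       group = rep(seq_along(ids), kVec), cache = pcaCache, kept = kept)
}

# per-region p-values for one phenotype draw, using the precomputed engine
.enginePValues <- function(eng, y, method, kind) {
  n <- length(y)
  if (method %in% c("fisher", "stouffer")) {
    p <- .corPValues(eng$S, y)
    if (method == "fisher") {
      X <- rowsum(-2 * log(pmax(p, 1e-300)), eng$group)[, 1L]
      pReg <- stats::pchisq(X, df = 2 * eng$kVec, lower.tail = FALSE)
    } else {
      Z <- rowsum(stats::qnorm(pmin(pmax(p, 1e-300), 1 - 1e-16),
                               lower.tail = FALSE), eng$group)[, 1L] /
        sqrt(eng$kVec)
      pReg <- stats::pnorm(Z, lower.tail = FALSE)
    }
    # k = 1: the PC1 regression p-value is the regional significance
    one <- eng$kVec == 1L
    if (any(one)) {
      firstCol <- cumsum(c(1L, eng$kVec))[seq_along(eng$kVec)]
      pReg[one] <- p[firstCol[one]]
    }
    return(pmax(pReg, 1e-300))
  }
  if (kind == "continuous") {
    r <- drop(stats::cor(eng$S, y))
    R2 <- rowsum(r^2, eng$group)[, 1L]
    R2 <- pmin(R2, 1 - 1e-12)
    k <- eng$kVec
    Fstat <- (R2 / k) / ((1 - R2) / (n - k - 1))
    return(pmax(stats::pf(Fstat, k, n - k - 1, lower.tail = FALSE), 1e-300))
  }
  firstCol <- cumsum(c(1L, eng$kVec))[seq_along(eng$kVec)]
  vapply(seq_along(eng$kVec), function(i) {
    S <- eng$S[, firstCol[i] + seq_len(eng$kVec[i]) - 1L, drop = FALSE]
    as.numeric(jointPCPValue(y, S, kind = "dichotomous"))
  }, numeric(1L))
}

#' Estimate the genome-wide false-positive (GFP) rate
#'
#' Monte-Carlo estimate of the probability that a genome-wide analysis of a
#' phenotype simulated independently of the methylation data yields at
#' least one FDR-significant region (`min q < qThreshold`). Per replicate r
#' the seed `baseSeed + r` is set, a null phenotype is drawn, and the full
#' region analysis is evaluated. Because the null phenotype is never part
#' of the covariate set, residuals and per-region PCA do not change across
#' replicates; they are computed once and reused (`cache = TRUE`). With
#' `resampleSubjects = TRUE`, each replicate first draws a random subject
#' subset (residuals and PCA are then recomputed per replicate).
#'
#' @param dataset a [MethylationDataset-class].
#' @param regionSet a [CpGRegionSet-class].
#' @param phenoKind null phenotype type, see [simulateNullPhenotype()].
#' @param nReplicates number of Monte-Carlo replicates. Default 200.
#' @param baseSeed replicate r uses seed `baseSeed + r`, so any replicate
#'   can be reproduced in isolation.
#' @param resampleSubjects draw a fresh subject subset per replicate.
#' @param resampleN subset size when resampling. Default 100.
#' @param cache reuse residuals/PCA across replicates (ignored — always
#'   recomputed — when `resampleSubjects = TRUE`).
#' @param verbose log progress.
#' @inheritParams analyseRegions
#' @return a [SimulationReport-class]; `simRate()` is the GFP estimate.
#' @export
estimateGFP <- function(dataset, regionSet,
                        phenoKind = c("normal", "chisq1", "dichot50",
                                      "dichot25"),
                        nReplicates = 200L, baseSeed = 0L,
                        method = c("fisher", "stouffer", "joint"),
                        firstPCOnly = FALSE, varThreshold = 0.80,
                        kMax = 10L, macMin = 0.3, qThreshold = 0.05,
                        covariates = NULL, resampleSubjects = FALSE,
                        resampleN = 100L, cache = TRUE, verbose = FALSE) {
  phenoKind <- match.arg(phenoKind)
  method <- match.arg(method)
  kind <- if (startsWith(phenoKind, "dichot")) "dichotomous"
          else "continuous"
  flags <- logical(nReplicates)

  if (resampleSubjects) {
    for (r in seq_len(nReplicates)) {
      set.seed(baseSeed + r)
      idx <- sample(colnames(dataset), resampleN)
      sub <- dataset[, idx]
      eng <- .nullEngine(sub, regionSet, varThreshold, kMax, firstPCOnly,
                         macMin, covariates)
      y <- phenotypeValues(
        simulateNullPhenotype(phenoKind, length(idx), idx))
      q <- bhFDR(.enginePValues(eng, unname(y), method, kind))
      flags[r] <- any(q < qThreshold)
      if (verbose && r %% 50L == 0L) message("replicate ", r)
    }
  } else {
    eng <- .nullEngine(dataset, regionSet, varThreshold, kMax, firstPCOnly,
                       macMin, covariates, verbose = verbose)
    n <- ncol(dataset)
    for (r in seq_len(nReplicates)) {
      if (!cache)
        eng <- .nullEngine(dataset, regionSet, varThreshold, kMax,
                           firstPCOnly, macMin, covariates)
      set.seed(baseSeed + r)
      y <- phenotypeValues(
        simulateNullPhenotype(phenoKind, n, colnames(dataset)))
      q <- bhFDR(.enginePValues(eng, unname(y), method, kind))
      flags[r] <- any(q < qThreshold)
      if (verbose && r %% 50L == 0L) message("replicate ", r)
    }
  }
  .simReport(
    sprintf("GFP, %s phenotype, %s", phenoKind,
            .methodLabel(method, firstPCOnly)),
    list(phenoKind = phenoKind, method = method, firstPCOnly = firstPCOnly,
         varThreshold = varThreshold, kMax = kMax, macMin = macMin,
         qThreshold = qThreshold, baseSeed = baseSeed,
         resampleSubjects = resampleSubjects,
         n = if (resampleSubjects) resampleN else ncol(dataset)),
    flags)
}

#' The causal probes of a fitted region
#'
#' The probe with the largest absolute loading on PC1 (and on PC2, when
#' present). Ties are broken towards the lower probe index.
#'
#' @param pca a [RegionPCA-class]
#' @return named integer vector with elements `pc1` and (if available)
#'   `pc2`, giving column indices into the region's probe block.
#' @export
causalProbes <- function(pca) {
  out <- c(pc1 = unname(which.max(abs(pca@loadings[, 1L]))))
  if (ncol(pca@loadings) >= 2L)
    out <- c(out, pc2 = unname(which.max(abs(pca@loadings[, 2L]))))
  out
}

#' Simulate a component-anchored "true signal" phenotype
#'
#' Builds a phenotype carrying a known signal for power simulation. The
#' continuous variants are the M-value of a causal probe plus independent
#' normal noise: `cts_pc1` anchors at the probe with the largest absolute
#' PC1 loading, `cts_pc2` at the PC2-loading maximizer, and `cts_pc1pc2`
#' is the mean of the standardized (mean 0, SD 1) `cts_pc1` and `cts_pc2`
#' draws. The dichotomous variants (`dts_*`) split the corresponding
#' continuous value at its median.
#'
#' @param pca the region's fitted [RegionPCA-class].
#' @param mBlock subjects-by-probes matrix of M-values for the region's
#'   probes (same column order as the PCA loadings).
#' @param signal one of `"cts_pc1"`, `"cts_pc2"`, `"cts_pc1pc2"`,
#'   `"dts_pc1"`, `"dts_pc2"`, `"dts_pc1pc2"`.
#' @param noiseSD standard deviation of the added normal noise, in M-value
#'   units; a length-2 vector gives separate SDs for the PC1- and
#'   PC2-anchored components.
#' @param seed optional seed (callers usually seed per replicate).
#' @return a [Phenotype-class].
#' @seealso [calibrateNoiseSD()] to target a phenotype/causal-probe
#'   correlation.
#' @export
simulateSignalPhenotype <- function(pca, mBlock,
                                    signal = c("cts_pc1", "cts_pc2",
                                               "cts_pc1pc2", "dts_pc1",
                                               "dts_pc2", "dts_pc1pc2"),
                                    noiseSD, seed = NULL) {
  signal <- match.arg(signal)
  if (!is.null(seed)) set.seed(seed)
  if (any(noiseSD <= 0)) stop("noiseSD must be positive")
  noiseSD <- rep_len(noiseSD, 2L)
  mBlock <- as.matrix(mBlock)
  n <- nrow(mBlock)
  cp <- causalProbes(pca)
  needPC2 <- grepl("pc2", signal, fixed = TRUE)
  if (needPC2 && is.na(cp["pc2"]))
    stop("region has no second component")

  cts1 <- mBlock[, cp["pc1"]] + stats::rnorm(n, sd = noiseSD[1L])
  v <- switch(sub("^dts", "cts", signal),
    cts_pc1 = cts1,
    cts_pc2 = mBlock[, cp["pc2"]] + stats::rnorm(n, sd = noiseSD[2L]),
    cts_pc1pc2 = {
      cts2 <- mBlock[, cp["pc2"]] + stats::rnorm(n, sd = noiseSD[2L])
      (as.numeric(scale(cts1)) + as.numeric(scale(cts2))) / 2
    })
  dichot <- startsWith(signal, "dts")
  if (dichot) v <- as.numeric(v > stats::median(v))
  Phenotype(v, kind = if (dichot) "dichotomous" else "continuous",
            name = signal,
            subjectIds = if (!is.null(rownames(mBlock))) rownames(mBlock)
                         else as.character(seq_len(n)))
}

#' Noise SD that targets a phenotype/causal-probe correlation
#'
#' For a phenotype `M + e`, `e ~ N(0, sd^2)` independent of the causal
#' probe's M-values, `cor(phenotype, M) = sd(M) / sqrt(sd(M)^2 + sd^2)`;
#' inverting gives `sd = sd(M) * sqrt(1 / r^2 - 1)`. Power simulations
#' add substantial noise so detection is neither certain nor hopeless —
#' target correlations around 0.13-0.16 are the regime studied.
#'
#' @param mCausal M-values of the causal probe.
#' @param targetCorr desired correlation between phenotype and probe.
#' @return noise standard deviation in M-value units.
#' @export
calibrateNoiseSD <- function(mCausal, targetCorr = 0.15) {
  if (targetCorr <= 0 || targetCorr >= 1)
    stop("targetCorr must lie in (0, 1)")
  stats::sd(mCausal) * sqrt(1 / targetCorr^2 - 1)
}

#' Estimate the true-positive (TP) rate for one region
#'
#' Per replicate r (seed `baseSeed + r`) a fresh signal phenotype is drawn
#' with [simulateSignalPhenotype()] and the region's uncorrected p-value is
#' computed; a p-value below `alpha` counts as a true positive.
#'
#' @param dataset a [MethylationDataset-class].
#' @param regionSet a [CpGRegionSet-class] containing `regionId`.
#' @param regionId the region carrying the simulated signal.
#' @param signal,noiseSD passed to [simulateSignalPhenotype()].
#' @param nReplicates Monte-Carlo replicates. Default 500.
#' @param baseSeed seed offset, as in [estimateGFP()].
#' @param alpha uncorrected significance threshold. Default 0.05.
#' @inheritParams analyseRegions
#' @return a [SimulationReport-class]; `simRate()` is the TP estimate.
#' @export
estimateTP <- function(dataset, regionSet, regionId, signal, noiseSD,
                       nReplicates = 500L, baseSeed = 0L,
                       method = c("fisher", "stouffer", "joint"),
                       firstPCOnly = FALSE, varThreshold = 0.80,
                       kMax = 10L, alpha = 0.05, covariates = NULL,
                       pcaCache = NULL) {
  method <- match.arg(method)
  if (!regionId %in% regionIds(regionSet)) stop("unknown region id")
  probes <- regionProbes(regionSet)[[regionId]]
  if (is.null(pcaCache)) {
    resid <- residualizeMethylation(dataset, covariates = covariates)
    pca <- computeRegionPCA(resid, probes, regionId)
  } else {
    pca <- pcaCache[[regionId]]
  }
  k <- selectK(pca@varianceFractions, varThreshold, kMax, firstPCOnly)
  S <- pca@scores[, seq_len(k), drop = FALSE]
  mBlock <- t(mValues(dataset))[, probes, drop = FALSE]
  kind <- if (startsWith(signal, "dts")) "dichotomous" else "continuous"

  flags <- logical(nReplicates)
  for (r in seq_len(nReplicates)) {
    set.seed(baseSeed + r)
    y <- phenotypeValues(simulateSignalPhenotype(pca, mBlock, signal,
                                                 noiseSD))
    flags[r] <- .regionPValue(unname(y), S, method, kind)$p < alpha
  }
  .simReport(
    sprintf("TP, region %s, signal %s, %s", regionId, signal,
            .methodLabel(method, firstPCOnly)),
    list(regionId = regionId, signal = signal, noiseSD = noiseSD,
         method = method, firstPCOnly = firstPCOnly,
         varThreshold = varThreshold, kMax = kMax, alpha = alpha,
         k = k, baseSeed = baseSeed, n = ncol(dataset)),
    flags)
}
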