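#' P-value for the association of one PC with the phenotype
#'
#' Simple linear regression with the component scores as outcome and the
#' phenotype as the sole predictor (`PC ~ phenotype`); returns the two-sided
#' t-test p-value for the slope. For simple regression this p-value is
#' identical whichever variable is taken as outcome, and for a 0/1 phenotype
#' it equals the pooled-variance two-sample t-test, so the same formula
#' serves continuous and dichotomous phenotypes.
#'
#' @param scores numeric vector (or single-column matrix) of PC scores.
#' @param phenotype a [Phenotype-class] or numeric vector aligned with
#'   `scores`.
#' @return two-sided p-value in (0, 1].
#' @export
pcPhenotypePValue <- function(scores, phenotype) {
  y <- if (is(phenotype, "Phenotype")) phenotype@values else phenotype
  s <- as.numeric(scores)
  n <- length(s)
  if (n < 4L) stop("need at least 4 subjects")
  if (length(y) != n) stop("scores and phenotype lengths differ")
  if (stats::sd(y) == 0) stop("phenotype is constant")
  drop(.corPValues(matrix(s, ncol = 1L), y))
}

# two-sided slope p-values for regressions of each column of S on y,
# via the correlation/t identity t = r * sqrt((n-2) / (1 - r^2))
.corPValues <- function(S, y) {
  n <- length(y)
  r <- drop(stats::cor(S, y))
  r2 <- pmin(r^2, 1)
  tstat <- abs(r) * sqrt((n - 2) / pmax(1 - r2, .Machine$double.xmin))
  p <- 2 * stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  pmax(p, 1e-300)
}

#' Combine per-PC p-values by Fisher's method
#'
#' `X = -2 * sum(log(p_i))` is referred to a chi-squared distribution with
#' `2k` degrees of freedom. With a single p-value (k = 1) the input is
#' returned unchanged: the meta-analysis is skipped and the PC1 regression
#' p-value is the regional significance. P-values are floored at 1e-300
#' before taking logs.
#'
#' @param pvals p-values in (0, 1].
#' @return combined p-value.
#' @examples
#' fisherCombine(c(0.5, 0.5))   # 0.59657...
#' fisherCombine(0.05)          # 0.05 (k = 1 identity)
#' @export
fisherCombine <- function(pvals) {
  if (!length(pvals)) stop("no p-values to combine")
  if (any(pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]")
  if (length(pvals) == 1L) return(pvals)
  X <- -2 * sum(log(pmax(pvals, 1e-300)))
  max(stats::pchisq(X, df = 2 * length(pvals), lower.tail = FALSE), 1e-300)
}

#' Combine per-PC p-values by Stouffer's method
#'
#' Each p-value is transformed to a z-score `z_i = qnorm(1 - p_i)`; the
#' combined statistic `Z = sum(z_i) / sqrt(k)` is referred to the standard
#' normal upper tail. As for Fisher, k = 1 returns the input unchanged.
#' P-values at 0 or 1 are clamped into (1e-300, 1 - 1e-16) with a warning.
#'
#' @param pvals p-values in (0, 1).
#' @return combined p-value.
#' @examples
#' stoufferCombine(c(0.5, 0.5))    # 0.5
#' stoufferCombine(c(0.05, 0.05))  # 0.01001...
#' @export
stoufferCombine <- function(pvals) {
  if (!length(pvals)) stop("no p-values to combine")
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  if (any(pvals <= 0 | pvals >= 1)) {
    warning("p-values at 0 or 1 clamped before the z transform")
    pvals <- pmin(pmax(pvals, 1e-300), 1 - 1e-16)
  }
  if (length(pvals) == 1L) return(pvals)
  Z <- sum(stats::qnorm(pvals, lower.tail = FALSE)) / sqrt(length(pvals))
  max(stats::pnorm(Z, lower.tail = FALSE), 1e-300)
}

#' Joint nested-model test of the top k PCs
#'
#' Regresses the phenotype on all selected component scores in one model
#' (`phenotype ~ PC1 + ... + PCk`) and compares it to the intercept-only
#' model. Continuous phenotypes use the overall F-test of the linear model
#' (`F(k, n-k-1)`); dichotomous phenotypes use the likelihood-ratio
#' chi-squared test (k df) from logistic regression. If the logistic fit
#' does not converge or separates, the deviance drop is capped at the null
#' deviance and the result is flagged via attribute `"warning"`.
#'
#' @param phenotype a [Phenotype-class] or numeric vector.
#' @param scores n-by-k matrix of component scores.
#' @param kind phenotype kind; inferred from a `Phenotype` object.
#' @return p-value, possibly with attribute `warning = TRUE`.
#' @export
jointPCPValue <- function(phenotype, scores,
                          kind = c("continuous", "dichotomous")) {
  if (is(phenotype, "Phenotype")) {
    y <- phenotype@values
    kind <- phenotype@kind
  } else {
    y <- as.numeric(phenotype)
    kind <- match.arg(kind)
  }
  S <- as.matrix(scores)
  n <- length(y)
  k <- ncol(S)
  if (n <= k + 2L) stop("need n > k + 2 subjects")
  if (kind == "continuous") {
    fit <- stats::lm.fit(cbind(1, S), y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    Fstat <- ((tss - rss) / k) / (rss / (n - k - 1))
    p <- stats::pf(Fstat, k, n - k - 1, lower.tail = FALSE)
    return(max(p, 1e-300))
  }
  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(1, S), y, family = stats::binomial()),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  stat <- fit$null.deviance - fit$deviance
  if (!fit$converged || any(fit$fitted.values < 1e-10) ||
      any(fit$fitted.values > 1 - 1e-10)) {
    warned <- TRUE
    stat <- min(stat, fit$null.deviance)
  }
  p <- max(stats::pchisq(stat, df = k, lower.tail = FALSE), 1e-300)
  if (warned) attr(p, "warning") <- TRUE
  p
}

#' Benjamini-Hochberg FDR-adjusted p-values (q-values)
#'
#' Step-up adjusted p-values with monotonicity enforcement, order-preserving
#' with respect to the input. A thin wrapper over
#' `stats::p.adjust(method = "BH")`.
#'
#' @param pvals numeric vector of p-values.
#' @return vector of q-values, same length and order.
#' @export
bhFDR <- function(pvals) {
  if (!length(pvals)) stop("no p-values")
  stats::p.adjust(pvals, method = "BH")
}

# regional p-value given selected scores; dispatches on method
.regionPValue <- function(y, S, method, kind) {
  S <- as.matrix(S)
  if (method %in% c("fisher", "stouffer")) {
    p <- .corPValues(S, y)
    if (length(p) == 1L) return(list(p = p, pcs = p, warn = FALSE))
    comb <- if (method == "fisher") fisherCombine(p) else stoufferCombine(p)
    return(list(p = comb, pcs = p, warn = FALSE))
  }
  p <- jointPCPValue(y, S, kind = kind)
  list(p = as.numeric(p), pcs = as.numeric(p),
       warn = isTRUE(attr(p, "warning")))
}

#' Region-level differential-methylation analysis
#'
#' The full per-region procedure: covariate residualization, per-region PCA
#' of the standardized residuals, MAC filtering, selection of the number of
#' components from the cumulative-variance threshold, per-region p-values
#' (per-PC regressions combined by Fisher or Stouffer, or a joint
#' nested-model test), and Benjamini-Hochberg q-values across all retained
#' regions. Regions with `q < qThreshold` are flagged as DMRs.
#'
#' @param dataset a [MethylationDataset-class].
#' @param regionSet a [CpGRegionSet-class].
#' @param phenotype a [Phenotype-class]; aligned to the dataset's subjects
#'   by id. Its name must not appear among the covariates used.
#' @param method `"fisher"` (default), `"stouffer"` (per-PC regressions
#'   meta-analysed) or `"joint"` (nested-model F / likelihood-ratio test).
#' @param firstPCOnly test only the first component (k = 1).
#' @param varThreshold cumulative variance threshold for [selectK()].
#' @param kMax cap on the number of components. Default 10.
#' @param macMin minimum MAC for a region to be analysed. Default 0.3.
#' @param qThreshold q-value cut-off defining a DMR. Default 0.05.
#' @param covariates covariate selection passed to
#'   [residualizeMethylation()].
#' @param pcaCache optional precomputed list from [precomputeRegionPCA()]
#'   (must match the dataset's current subjects); residualization and PCA
#'   are skipped when provided.
#' @param binaryPerPC how dichotomous phenotypes are handled in the per-PC
#'   regressions: `"linear"` (default; the slope t-test, equivalent to a
#'   two-sample t-test) or `"logistic"` (per-PC logistic Wald test).
#' @param verbose log stage counts.
#' @return a [S4Vectors::DataFrame] with one row per analysed region:
#'   `region_id, chrom, start, end, context, n_probes, mac, k, p_region,
#'   q_value, is_dmr, pc_pvalues` (comma-joined), `method, n_used, warning`.
#'   Analysis settings are stored in `metadata()`.
#' @export
analyseRegions <- function(dataset, regionSet, phenotype,
                           method = c("fisher", "stouffer", "joint"),
                           firstPCOnly = FALSE, varThreshold = 0.80,
                           kMax = 10L, macMin = 0.3, qThreshold = 0.05,
                           covariates = NULL, pcaCache = NULL,
                           binaryPerPC = c("linear", "logistic"),
                           verbose = TRUE) {
  method <- match.arg(method)
  binaryPerPC <- match.arg(binaryPerPC)
  stopifnot(is(dataset, "MethylationDataset"), is(regionSet, "CpGRegionSet"),
            is(phenotype, "Phenotype"))

  usedCovars <- if (is.character(covariates)) covariates
                else colnames(covariateTable(dataset))
  if (phenotype@name %in% usedCovars)
    stop("phenotype '", phenotype@name,
         "' must not be part of the covariate set")

  subjects <- colnames(dataset)
  if (!all(subjects %in% names(phenotype@values)))
    stop("phenotype is missing values for some subjects")
  y <- unname(phenotype@values[subjects])

  if (is.null(pcaCache)) {
    resid <- residualizeMethylation(dataset, covariates = covariates)
    pcaCache <- precomputeRegionPCA(resid, regionSet)
  } else if (!all(regionIds(regionSet) %in% names(pcaCache))) {
    stop("pcaCache is missing some regions")
  }
  pcaCache <- pcaCache[regionIds(regionSet)]

  kept <- filterRegions(regionSet, pcaCache, macMin = macMin,
                        verbose = verbose)
  if (!length(kept)) {
    warning("no regions pass the MAC filter")
    res <- S4Vectors::DataFrame(region_id = character(),
      chrom = character(), start = integer(), end = integer(),
      context = character(), n_probes = integer(), mac = numeric(),
      k = integer(), p_region = numeric(), q_value = numeric(),
      is_dmr = logical(), pc_pvalues = character(), method = character(),
      n_used = integer(), warning = logical())
    metadata(res) <- .analysisParams(method, firstPCOnly, varThreshold,
                                     kMax, macMin, qThreshold, usedCovars)
    return(res)
  }

  gr <- regionRanges(kept)
  m <- mcols(gr)
  R <- length(kept)
  pRegion <- numeric(R)
  kUsed <- integer(R)
  macs <- numeric(R)
  pcP <- character(R)
  warns <- logical(R)
  binKind <- if (phenotype@kind == "dichotomous" &&
                 method %in% c("fisher", "stouffer") &&
                 binaryPerPC == "logistic") "logistic" else "default"

  for (i in seq_len(R)) {
    pca <- pcaCache[[m$region_id[i]]]
    k <- selectK(pca@varianceFractions, varThreshold, kMax, firstPCOnly)
    S <- pca@scores[, seq_len(k), drop = FALSE]
    if (binKind == "logistic" && method %in% c("fisher", "stouffer")) {
      pc <- vapply(seq_len(k), function(j)
        .logisticWaldP(y, S[, j]), numeric(1L))
      p <- if (k == 1L) pc[1L]
           else if (method == "fisher") fisherCombine(pc)
           else stoufferCombine(pc)
      ans <- list(p = p, pcs = pc, warn = FALSE)
    } else {
      ans <- .regionPValue(y, S, method, phenotype@kind)
    }
    pRegion[i] <- ans$p
    kUsed[i] <- k
    macs[i] <- pca@mac
    pcP[i] <- paste(signif(ans$pcs, 6), collapse = ",")
    warns[i] <- ans$warn
  }

  q <- bhFDR(pRegion)
  res <- S4Vectors::DataFrame(
    region_id = m$region_id,
    chrom = as.character(seqnames(gr)),
    start = start(gr), end = end(gr),
    context = m$context, n_probes = m$n_probes,
    mac = macs, k = kUsed, p_region = pRegion, q_value = q,
    is_dmr = q < qThreshold, pc_pvalues = pcP,
    method = .methodLabel(method, firstPCOnly),
    n_used = length(y), warning = warns)
  metadata(res) <- .analysisParams(method, firstPCOnly, varThreshold, kMax,
                                   macMin, qThreshold, usedCovars)
  if (verbose)
    message(R, " region(s) analysed; ", sum(res$is_dmr), " DMR(s) at q < ",
            qThreshold)
  res
}

.logisticWaldP <- function(y, s) {
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, s), y, family = stats::binomial()))
  # Wald test on the score coefficient
  X <- cbind(1, s)
  w <- fit$weights
  V <- tryCatch(solve(crossprod(X * sqrt(w))), error = function(e) NULL)
  if (is.null(V)) return(1)
  z <- fit$coefficients[2L] / sqrt(V[2L, 2L])
  max(2 * stats::pnorm(abs(z), lower.tail = FALSE), 1e-300)
}

.methodLabel <- function(method, firstPCOnly) {
  if (firstPCOnly)
    if (method == "joint") "joint_pc1" else paste0(method, "_pc1")
  else method
}

.analysisParams <- function(method, firstPCOnly, varThreshold, kMax, macMin,
                            qThreshold, covariates) {
  list(method = method, firstPCOnly = firstPCOnly,
       varThreshold = varThreshold, kMax = kMax, macMin = macMin,
       qThreshold = qThreshold, covariates = covariates)
}

#' Write an analysis result table as TSV
#'
#' @param result the `DataFrame` returned by [analyseRegions()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeResultsTSV <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
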