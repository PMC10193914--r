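#' Principal components of one region's standardized residuals
#'
#' Runs PCA (via [stats::prcomp]) on the subjects-by-probes block of
#' standardized residuals belonging to one region; this is equivalent to an
#' eigen-decomposition of the probes' correlation matrix. Variance fractions
#' are reported for all p probes (padded with zeros beyond the block's
#' rank). PC signs are arbitrary, so a fixed convention is applied: the
#' largest-magnitude loading of each component is made positive. The
#' region's MAC (maximum absolute pairwise Pearson correlation between
#' probes) is computed on the same block.
#'
#' @param resid a [MethResiduals-class] (or a subjects-by-probes numeric
#'   matrix of standardized residuals).
#' @param probeIds probe ids of the region, in positional order.
#' @param regionId identifier stored in the result.
#' @return a [RegionPCA-class] with `kSelected` unset (`NA`).
#' @export
computeRegionPCA <- function(resid, probeIds = NULL, regionId = "region") {
  V <- if (is(resid, "MethResiduals")) resid@values else as.matrix(resid)
  if (!is.null(probeIds)) {
    missing <- setdiff(probeIds, colnames(V))
    if (length(missing))
      stop("region probes absent from residual matrix: ",
           paste(missing, collapse = ", "))
    V <- V[, probeIds, drop = FALSE]
  }
  n <- nrow(V)
  p <- ncol(V)
  if (p < 2L) stop("a region needs at least 2 probes for PCA")
  if (n < 2L || nrow(unique(V)) < 2L)
    stop("need at least 2 distinct subjects")

  pr <- stats::prcomp(V, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  vf <- numeric(p)
  vf[seq_along(ev)] <- ev / sum(ev)
  ncomp <- ncol(pr$rotation)

  # sign convention: largest-|loading| entry of each PC made positive
  flip <- vapply(seq_len(ncomp), function(j) {
    l <- pr$rotation[, j]
    l[which.max(abs(l))] < 0
  }, logical(1L))
  pr$rotation[, flip] <- -pr$rotation[, flip, drop = FALSE]
  pr$x[, flip] <- -pr$x[, flip, drop = FALSE]
  rownames(pr$x) <- rownames(V)

  new("RegionPCA", regionId = regionId, loadings = pr$rotation,
      scores = pr$x, varianceFractions = vf, kSelected = NA_integer_,
      mac = computeMAC(V))
}

#' Maximum absolute pairwise correlation (MAC) of a probe block
#'
#' The largest absolute Pearson correlation over all probe pairs in the
#' block. Because correlation is scale-free, the MAC is identical whether
#' computed on raw or standardized residuals. It is the package's
#' region-inclusion statistic: regions whose probes share no minimal level
#' of co-methylation are better served by single-CpG analysis.
#'
#' @param block subjects-by-probes numeric matrix with at least 2 columns.
#' @return a value in \[0, 1\].
#' @export
computeMAC <- function(block) {
  block <- as.matrix(block)
  if (ncol(block) < 2L) stop("MAC needs at least 2 probes")
  C <- stats::cor(block)
  max(abs(C[upper.tri(C)]))
}

#' Choose the number of components to test
#'
#' Returns the smallest k whose cumulative variance fraction reaches
#' `threshold`, capped at `kMax` (default 10, to prevent overfitting and
#' numerical instability) and at the number of components with nonzero
#' variance. With `firstPCOnly = TRUE` the first component alone is used
#' (k = 1), regardless of the threshold.
#'
#' @param varianceFractions non-increasing fractions summing to 1 (e.g.
#'   from a [RegionPCA-class]).
#' @param threshold cumulative variance target; the values studied are
#'   0.80, 0.90, 0.95 and 0.99, with 0.80 the recommended default.
#' @param kMax upper limit on k. Default 10.
#' @param firstPCOnly analyse only the first component.
#' @return an integer k in `[1, min(kMax, #nonzero components)]`.
#' @examples
#' selectK(c(0.85, 0.10, 0.05), 0.80)            # 1
#' selectK(c(0.50, 0.25, 0.15, 0.10), 0.80)      # 3
#' selectK(rep(0.05, 20), 0.80)                  # capped at 10
#' @export
selectK <- function(varianceFractions, threshold = 0.80, kMax = 10L,
                    firstPCOnly = FALSE) {
  nz <- sum(varianceFractions > 1e-12)
  if (nz < 1L) stop("no component has nonzero variance")
  if (firstPCOnly) return(1L)
  cum <- cumsum(varianceFractions)
  hit <- which(cum >= threshold - 1e-9)
  k <- if (length(hit)) hit[1L] else as.integer(kMax)
  as.integer(min(k, kMax, nz))
}

#' Apply the selected k to a fitted RegionPCA
#'
#' @param pca a [RegionPCA-class]
#' @inheritParams selectK
#' @return the `RegionPCA` with `kSelected` filled in.
#' @export
applySelectK <- function(pca, threshold = 0.80, kMax = 10L,
                         firstPCOnly = FALSE) {
  pca@kSelected <- selectK(pca@varianceFractions, threshold, kMax,
                           firstPCOnly)
  pca
}

#' Fit PCA for every region of a set
#'
#' Convenience wrapper: one [computeRegionPCA()] per region, returned as a
#' named list. PCA depends only on the residuals (never on the phenotype),
#' so the result can be cached and reused across simulation replicates that
#' vary only the phenotype.
#'
#' @param resid a [MethResiduals-class]
#' @param regionSet a [CpGRegionSet-class]
#' @return named list of [RegionPCA-class], one per region.
#' @export
precomputeRegionPCA <- function(resid, regionSet) {
  probes <- regionProbes(regionSet)
  out <- vector("list", length(probes))
  names(out) <- names(probes)
  for (i in seq_along(probes))
    out[[i]] <- computeRegionPCA(resid, probes[[i]], names(probes)[i])
  out
}

#' Filter regions by minimum MAC
#'
#' Retains regions whose MAC is at least `macMin` (inclusive). A cut-off of
#' 0.3 is the recommended default: it requires some minimal co-methylation
#' in the region without noticeably inflating false-positive rates, and it
#' reduces the multiple-testing burden. Sweeping `macMin` over
#' 0, 0.1, ..., 0.5 is supported by simply calling this repeatedly.
#'
#' @param regionSet a [CpGRegionSet-class]
#' @param x per-region MAC values: a named numeric vector, a list of
#'   [RegionPCA-class] (as from [precomputeRegionPCA()]), or a
#'   [MethResiduals-class] from which MACs are computed.
#' @param macMin minimum MAC, inclusive. Default 0.3.
#' @param verbose log retained/dropped counts.
#' @return the filtered [CpGRegionSet-class].
#' @export
filterRegions <- function(regionSet, x, macMin = 0.3, verbose = TRUE) {
  macs <- regionMACs(regionSet, x)
  keep <- macs >= macMin
  if (verbose)
    message(sum(keep), " region(s) retained, ", sum(!keep),
            " dropped at MAC >= ", macMin)
  regionSet[keep]
}

#' @rdname filterRegions
#' @export
regionMACs <- function(regionSet, x) {
  ids <- regionIds(regionSet)
  if (is.numeric(x)) {
    if (!all(ids %in% names(x))) stop("MAC vector is missing regions")
    return(unname(x[ids]))
  }
  if (is.list(x)) {
    if (!all(ids %in% names(x))) stop("PCA list is missing regions")
    return(vapply(x[ids], function(p) p@mac, numeric(1L)))
  }
  probes <- regionProbes(regionSet)
  vapply(probes, function(pr) computeMAC(residValues(x)[, pr, drop = FALSE]),
         numeric(1L))
}

#' @describeIn RegionPCA-class brief summary
#' @param object a `RegionPCA`
#' @export
setMethod("show", "RegionPCA", function(object) {
  p <- length(object@varianceFractions)
  cat(sprintf("RegionPCA '%s': p = %d probes, n = %d subjects\n",
              object@regionId, p, nrow(object@scores)))
  cat(sprintf("  MAC = %.3f; PC1 variance fraction = %.3f; k selected = %s\n",
              object@mac, object@varianceFractions[1L],
              ifelse(is.na(object@kSelected), "(unset)",
                     object@kSelected)))
})

#' @rdname methylation-accessors
#' @export
pcaLoadings <- function(x) x@loadings

#' @rdname methylation-accessors
#' @export
pcaScores <- function(x) x@scores

#' @rdname methylation-accessors
#' @export
varianceFractions <- function(x) x@varianceFractions
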