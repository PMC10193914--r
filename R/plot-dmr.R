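#' High-weight probes of one component
#'
#' Probes whose absolute loading on the given component exceeds the median
#' absolute loading across *all* probes and selected components of the
#' region (strict inequality; loading signs are arbitrary in PCA and are
#' ignored).
#'
#' @param pca a [RegionPCA-class] with `kSelected` set (or supply `k`).
#' @param pcIndex which component.
#' @param k number of components over which the median is taken; defaults
#'   to `pca@kSelected`.
#' @return character vector of probe ids (may be empty).
#' @export
selectHighWeightProbes <- function(pca, pcIndex, k = pca@kSelected) {
  if (is.na(k)) stop("kSelected is unset; pass k or use applySelectK()")
  if (pcIndex > k) stop("pcIndex exceeds the number of selected components")
  L <- abs(pca@loadings[, seq_len(k), drop = FALSE])
  thr <- stats::median(L)
  rownames(pca@loadings)[L[, pcIndex] > thr]
}

#' Data behind a DMR plot
#'
#' Assembles, for each plottable component of a region, the per-probe
#' group-mean beta-values that [plotDMR()] draws. A component is plottable
#' when its association p-value is below `pcPThreshold` and it has at least
#' `minHighWeightProbes` high-weight probes. The two display groups come
#' from the phenotype: the two classes of a dichotomous phenotype, or a
#' split of a continuous phenotype at `groupQuantile`.
#'
#' @param dataset a [MethylationDataset-class].
#' @param regionSet a [CpGRegionSet-class] containing the region.
#' @param regionId region to plot.
#' @param pca the region's [RegionPCA-class] with `kSelected` set.
#' @param phenotype a [Phenotype-class].
#' @param pcPValues per-component association p-values (length
#'   `pca@kSelected`); computed with [pcPhenotypePValue()] if omitted.
#' @param pcPThreshold nominal p-value cut-off for a component to be shown.
#' @param minHighWeightProbes minimum high-weight probes per shown
#'   component. Default 2.
#' @param groupQuantile split point for continuous phenotypes. Default 0.5.
#' @return a list with elements `pcs` (data.frame: pc, pvalue, plotted,
#'   reason) and `panels` (one data.frame per plotted component: probe,
#'   pos, mean beta per group, high-weight flag), plus `groups` (subject
#'   group labels).
#' @export
dmrPlotData <- function(dataset, regionSet, regionId, pca, phenotype,
                        pcPValues = NULL, pcPThreshold = 0.05,
                        minHighWeightProbes = 2L, groupQuantile = 0.5) {
  probes <- regionProbes(regionSet)[[regionId]]
  if (is.null(probes)) stop("unknown region id")
  k <- pca@kSelected
  if (is.na(k)) stop("kSelected is unset; use applySelectK()")
  subjects <- colnames(dataset)
  y <- phenotype@values[subjects]
  if (is.null(pcPValues))
    pcPValues <- vapply(seq_len(k), function(j)
      pcPhenotypePValue(pca@scores[subjects, j], unname(y)), numeric(1L))

  groups <- if (phenotype@kind == "dichotomous") {
    factor(ifelse(y == 1, "group1", "group0"),
           levels = c("group0", "group1"))
  } else {
    cut <- stats::quantile(y, groupQuantile)
    factor(ifelse(y > cut, "high", "low"), levels = c("low", "high"))
  }

  beta <- t(betaValues(dataset))[subjects, probes, drop = FALSE]
  pos <- start(probeAnnotation(dataset)[probes])

  pcs <- data.frame(pc = seq_len(k), pvalue = pcPValues,
                    plotted = FALSE, reason = "")
  panels <- list()
  for (j in seq_len(k)) {
    hw <- selectHighWeightProbes(pca, j, k)
    if (pcPValues[j] >= pcPThreshold) {
      pcs$reason[j] <- "not trait-associated"
    } else if (length(hw) < minHighWeightProbes) {
      pcs$reason[j] <- "fewer than the required high-weight probes"
    } else {
      pcs$plotted[j] <- TRUE
      gm <- vapply(levels(groups), function(g)
        colMeans(beta[groups == g, , drop = FALSE]), numeric(length(probes)))
      panels[[paste0("PC", j)]] <- data.frame(
        probe = probes, pos = pos, gm,
        high_weight = probes %in% hw, check.names = FALSE)
    }
  }
  list(pcs = pcs, panels = panels, groups = groups)
}

#' Plot a DMR's group-mean methylation by component
#'
#' One panel per plottable component: per-probe mean beta-values for the
#' two phenotype groups against genomic position, with high-weight probes
#' marked. Components failing the display criteria are skipped with a
#' logged note. Writes PNG or SVG depending on the file extension.
#'
#' @inheritParams dmrPlotData
#' @param outPath output image path ending in `.png` or `.svg`.
#' @param qValue optional q-value shown in the title.
#' @param width,height device size in inches.
#' @return invisibly, `outPath`, or `NULL` when no component is plottable
#'   (no file is written).
#' @export
plotDMR <- function(dataset, regionSet, regionId, pca, phenotype, outPath,
                    pcPValues = NULL, pcPThreshold = 0.05,
                    minHighWeightProbes = 2L, groupQuantile = 0.5,
                    qValue = NA_real_, width = 7, height = 4) {
  pd <- dmrPlotData(dataset, regionSet, regionId, pca, phenotype,
                    pcPValues, pcPThreshold, minHighWeightProbes,
                    groupQuantile)
  skipped <- pd$pcs[!pd$pcs$plotted, ]
  for (i in seq_len(nrow(skipped)))
    message("PC", skipped$pc[i], " not plotted: ", skipped$reason[i])
  if (!length(pd$panels)) {
    message("no component meets the display criteria; nothing plotted")
    return(invisible(NULL))
  }
  ext <- tolower(sub(".*\\.", "", outPath))
  switch(ext,
    png = grDevices::png(outPath, width = width, height = height,
                         units = "in", res = 150),
    svg = grDevices::svg(outPath, width = width, height = height),
    stop("outPath must end in .png or .svg"))
  on.exit(grDevices::dev.off())
  np <- length(pd$panels)
  graphics::par(mfrow = c(1, np), mar = c(4, 4, 3, 1))
  grpNames <- levels(pd$groups)
  cols <- c("#1b6ca8", "#d1495b")
  for (nm in names(pd$panels)) {
    df <- pd$panels[[nm]]
    graphics::matplot(df$pos, as.matrix(df[, grpNames]), type = "b",
                      pch = ifelse(df$high_weight, 19, 1),
                      lty = 1, col = cols, ylim = c(0, 1),
                      xlab = "position (bp)", ylab = "mean beta",
                      main = sprintf("%s %s%s", regionId, nm,
                                     if (is.na(qValue)) "" else
                                       sprintf(" (q = %.2g)", qValue)))
    graphics::legend("topright", legend = grpNames, col = cols, lty = 1,
                     bty = "n", cex = 0.8)
  }
  invisible(outPath)
}
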