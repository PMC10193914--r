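#' Generate an EPIC-like synthetic methylation dataset
#'
#' Builds a complete dataset — beta-value matrix, probe annotation and
#' covariate table — with a known region structure, so every analysis stage
#' can be exercised without cohort data. Probes are laid out in clusters
#' that satisfy the region-building rules (within-cluster gaps at most
#' 200 bp, clusters separated by much more), alternating genic and
#' intergenic context across chromosomes 1-22. Within each region the
#' M-values follow a latent-factor model on the standardized scale:
#' equicorrelated regions share a single factor (`Z = sqrt(rho) f +
#' sqrt(1-rho) e`), two-factor regions load two orthogonal factors on
#' complementary probe subsets so that the PC1- and PC2-anchored causal
#' probes differ. Per-probe baselines are drawn from a bimodal mixture
#' (mostly-methylated and mostly-unmethylated probes, as on real arrays),
#' covariate effects (age, sex, a cell-proportion analogue and a
#' smoking-score analogue) are added on the M-value scale, and the result
#' is mapped to beta-values by the inverse logit, so all betas are strictly
#' inside (0,1).
#'
#' @param nSubjects number of subjects. Default 100.
#' @param nRegions number of probe clusters. Default 2000.
#' @param probesPerRegion inclusive integer range of probes per region.
#'   Default `c(3, 40)`.
#' @param intraGap inclusive bp range for gaps between neighbouring probes
#'   within a cluster; must stay within the region-building `maxGap`.
#' @param interGap bp separation between consecutive clusters on a
#'   chromosome; must exceed `maxGap`. Default 5000.
#' @param fracTwoFactor fraction of regions with two-factor structure (the
#'   rest are equicorrelated). Default 0.4.
#' @param rhoRange range of the equicorrelation parameter. Default
#'   `c(0.05, 0.95)`, giving a genome that mixes regions well below and
#'   well above the MAC = 0.3 analysis cut-off.
#' @param fracIntergenic fraction of regions without gene annotation.
#' @param probeSDRange range of per-probe M-value standard deviations.
#' @param covariateEffects named list of per-covariate effect-size SDs on
#'   the M-value scale; each probe's effect is drawn from
#'   `N(0, sd^2)`. Covariates generated: `age` (years), `sex` (0/1),
#'   `cellprop` (a white-blood-cell proportion analogue), `smokescore`.
#' @param seed RNG seed; the generator is fully deterministic given it.
#' @return a [MethylationDataset-class] (beta scale) whose
#'   `metadata()$trueRegions` records the generated cluster layout
#'   (data.frame: region_id, chrom, start, end, context, n_probes,
#'   structure, rho).
#' @export
simulateMethylationDataset <- function(nSubjects = 100L, nRegions = 2000L,
                                       probesPerRegion = c(3L, 40L),
                                       intraGap = c(20L, 150L),
                                       interGap = 5000L,
                                       fracTwoFactor = 0.4,
                                       rhoRange = c(0.05, 0.95),
                                       fracIntergenic = 0.2,
                                       probeSDRange = c(0.25, 1),
                                       covariateEffects = list(
                                         age = 0.004, sex = 0.05,
                                         cellprop = 0.5, smokescore = 0.02),
                                       seed = 1L) {
  set.seed(seed)
  n <- as.integer(nSubjects)

  covars <- data.frame(
    age = round(stats::runif(n, 25, 75), 1),
    sex = stats::rbinom(n, 1L, 0.5),
    cellprop = pmin(pmax(stats::rnorm(n, 0.12, 0.03), 0.01), 0.4),
    smokescore = stats::rnorm(n),
    row.names = sprintf("S%04d", seq_len(n)))
  if (n >= 2L && length(unique(covars$sex)) == 1L)
    covars$sex[1:2] <- c(0L, 1L)
  Xc <- scale(as.matrix(covars), center = TRUE, scale = FALSE)

  pLo <- probesPerRegion[1L]; pHi <- probesPerRegion[2L]
  pVec <- .sampleRange(pLo, pHi, nRegions)
  twoFac <- stats::runif(nRegions) < fracTwoFactor
  rho <- stats::runif(nRegions, rhoRange[1L], rhoRange[2L])
  intergenic <- stats::runif(nRegions) < fracIntergenic
  chrom <- paste0("chr", rep_len(1:22, nRegions))

  cursor <- integer(22L)
  names(cursor) <- paste0("chr", 1:22)
  cursor[] <- 10000L
  probeOffset <- cumsum(c(0L, pVec))

  blocks <- vector("list", nRegions)
  annot <- vector("list", nRegions)
  truth <- vector("list", nRegions)
  geneCounter <- 0L

  for (i in seq_len(nRegions)) {
    p <- pVec[i]
    Z <- if (twoFac[i])
      .twoFactorBlock(n, p, rho[i])
    else
      .equicorrelatedBlock(n, p, rho[i])
    mu <- ifelse(stats::runif(p) < 0.5, stats::rnorm(p, -2.5, 0.4),
                 stats::rnorm(p, 2.5, 0.4))
    sdv <- stats::runif(p, probeSDRange[1L], probeSDRange[2L])
    G <- vapply(names(covariateEffects), function(cv)
      stats::rnorm(p, 0, covariateEffects[[cv]]), numeric(p))
    M <- sweep(Z, 2L, sdv, `*`)
    M <- sweep(M, 2L, mu, `+`)
    M <- M + Xc[, names(covariateEffects), drop = FALSE] %*% t(G)

    gaps <- .sampleRange(intraGap[1L], intraGap[2L], p - 1L)
    start <- cursor[chrom[i]] + interGap
    pos <- start + c(0L, cumsum(gaps))
    cursor[chrom[i]] <- pos[p]

    probeIds <- sprintf("cg%08d", probeOffset[i] + seq_len(p))
    colnames(M) <- probeIds
    blocks[[i]] <- M
    gene <- if (intergenic[i]) "" else {
      geneCounter <- geneCounter + 1L
      sprintf("GENE%05d", geneCounter)
    }
    annot[[i]] <- data.frame(probe_id = probeIds, chrom = chrom[i],
                             pos = pos, genes = gene)
    truth[[i]] <- data.frame(
      region_id = sprintf("%s:%d-%d", chrom[i], pos[1L], pos[p]),
      chrom = chrom[i], start = pos[1L], end = pos[p],
      context = if (intergenic[i]) "intergenic" else "genic",
      n_probes = p,
      structure = if (twoFac[i]) "two_factor" else "equicorrelated",
      rho = rho[i])
  }

  M <- do.call(cbind, blocks)
  rownames(M) <- rownames(covars)
  beta <- mToBeta(M)
  ds <- MethylationDataset(beta, do.call(rbind, annot), covars,
                           scale = "beta", verbose = FALSE)
  metadata(ds)$trueRegions <- do.call(rbind, truth)
  metadata(ds)$seed <- seed
  ds
}

# sample() treats a scalar first argument as 1:x; guard the degenerate range
.sampleRange <- function(lo, hi, n) {
  if (lo == hi) rep(as.integer(lo), n)
  else sample(lo:hi, n, replace = TRUE)
}

# single-factor equicorrelated block on the standardized scale
.equicorrelatedBlock <- function(n, p, rho) {
  f <- stats::rnorm(n)
  sqrt(rho) * matrix(f, n, p) +
    sqrt(1 - rho) * matrix(stats::rnorm(n * p), n, p)
}

# two orthogonal factors loading complementary probe halves; `rho` scales
# the leading loadings so the block's MAC tracks the equicorrelated case.
# The second factor is deliberately weaker so that PC1 aligns with factor 1
# and the PC1/PC2 causal probes fall in different halves.
.twoFactorBlock <- function(n, p, rho) {
  half <- ceiling(p / 2)
  l1 <- c(stats::runif(half, 0.8, 0.95),
          stats::runif(p - half, 0.05, 0.2)) * sqrt(rho)
  l2 <- c(stats::runif(half, 0.05, 0.2),
          stats::runif(p - half, 0.5, 0.65)) * sqrt(rho)
  generateTwoFactorRegion(p, l1, l2, n)
}

#' Generate a two-factor correlated region block
#'
#' Draws an n-by-p matrix on the standardized M-value scale from
#' `Z = f1 * load1' + f2 * load2' + E * diag(sqrt(1 - load1^2 - load2^2))`
#' with independent standard-normal factors `f1`, `f2` and noise `E`. The
#' implied probe correlation matrix is
#' `load1 load1' + load2 load2' + diag(uniqueness)`; the per-probe
#' uniqueness must stay positive, i.e. `load1^2 + load2^2 < 1` everywhere.
#' Choosing `load1` concentrated on one probe subset and `load2` on the
#' complement separates the PC1 and PC2 causal probes, which is what the
#' power simulations need.
#'
#' @param p number of probes.
#' @param load1,load2 length-p factor loadings.
#' @param n number of subjects.
#' @param seed optional seed.
#' @return n-by-p numeric matrix (mean 0, unit variance per probe, in
#'   expectation).
#' @export
generateTwoFactorRegion <- function(p, load1, load2, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(load1) != p || length(load2) != p)
    stop("loadings must have length p")
  uniq <- 1 - load1^2 - load2^2
  if (any(uniq <= 0))
    stop("degenerate loadings: load1^2 + load2^2 must stay below 1")
  f1 <- stats::rnorm(n)
  f2 <- stats::rnorm(n)
  tcrossprod(f1, load1) + tcrossprod(f2, load2) +
    matrix(stats::rnorm(n * p), n, p) %*% diag(sqrt(uniq), p, p)
}
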