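#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<- Rle
#' @importFrom IRanges IRanges CharacterList
#' @importFrom GenomicRanges GRanges seqnames start end granges
#' @importFrom GenomeInfoDb seqnames seqlevels
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges
#'   colData rowData
NULL

#' MethylationDataset: methylation values with probe annotation and covariates
#'
#' A container for subjects-by-probes methylation data, stored in the
#' Bioconductor orientation (probes as rows, subjects as columns) as a
#' [SummarizedExperiment::RangedSummarizedExperiment]. The single assay
#' `"meth"` holds either beta-values (proportions, strictly inside (0,1)) or
#' M-values (`log2(beta/(1-beta))`); which one is recorded in
#' `metadata(x)$scale`. Probe genomic positions and gene context live in
#' `rowRanges`, subject covariates in `colData`.
#'
#' @slot ... inherits all slots from `RangedSummarizedExperiment`.
#' @seealso [MethylationDataset()], [betaToM()], [loadDataset()]
#' @export
setClass("MethylationDataset", contains = "RangedSummarizedExperiment")

setValidity("MethylationDataset", function(object) {
  msg <- character()
  if (!"meth" %in% names(assays(object)))
    msg <- c(msg, "assay 'meth' is required")
  sc <- metadata(object)$scale
  if (is.null(sc) || !sc %in% c("beta", "mvalue"))
    msg <- c(msg, "metadata(x)$scale must be 'beta' or 'mvalue'")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "probe ids must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "subject ids must be unique")
  if ("meth" %in% names(assays(object))) {
    v <- assay(object, "meth")
    if (anyNA(v))
      msg <- c(msg, "methylation values must not contain missing values")
    else if (identical(sc, "beta") && (any(v <= 0) || any(v >= 1)))
      msg <- c(msg, "beta-values must lie strictly in (0,1)")
  }
  if (!is.null(rowRanges(object)) && length(object) &&
      any(start(rowRanges(object)) < 1))
    msg <- c(msg, "probe positions must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Phenotype: a per-subject trait to be tested against methylation
#'
#' Holds a numeric phenotype keyed by subject id, with an explicit kind.
#' Continuous phenotypes are analysed with linear models; dichotomous
#' phenotypes are coded 0/1 (both classes must be present) and use a
#' logistic likelihood only in the joint nested-model test.
#'
#' @slot values named numeric vector, names are subject ids.
#' @slot kind `"continuous"` or `"dichotomous"`.
#' @slot name phenotype label; used to guard against accidentally
#'   residualizing the phenotype away (it must not appear among covariates).
#' @seealso [Phenotype()], [analyseRegions()]
#' @export
setClass("Phenotype",
  representation(values = "numeric", kind = "character", name = "character"))

setValidity("Phenotype", function(object) {
  msg <- character()
  v <- object@values
  if (is.null(names(v)) || anyDuplicated(names(v)))
    msg <- c(msg, "values must be named by unique subject ids")
  if (anyNA(v)) msg <- c(msg, "phenotype values must not be missing")
  if (!object@kind %in% c("continuous", "dichotomous"))
    msg <- c(msg, "kind must be 'continuous' or 'dichotomous'")
  if (identical(object@kind, "dichotomous")) {
    if (!all(v %in% c(0, 1)))
      msg <- c(msg, "dichotomous phenotypes must be coded 0/1")
    else if (length(unique(v)) < 2)
      msg <- c(msg, "dichotomous phenotypes need both classes present")
  }
  if (length(msg)) msg else TRUE
})

#' CpGRegionSet: candidate regions of clustered CpG probes
#'
#' The result of [buildRegions()]: a set of genomic regions, each covering at
#' least `minProbes` CpG probes with consecutive gaps no larger than `maxGap`
#' base pairs, stratified into genic (per annotated gene) and intergenic
#' (per chromosome) clusters. Regions are stored as a
#' [GenomicRanges::GRanges] whose metadata columns carry the region id,
#' context, gene (NA for intergenic) and the ordered probe ids.
#'
#' @slot regions `GRanges` with mcols `region_id`, `context`, `gene`,
#'   `probes` (a `CharacterList`, probes ordered by position), `n_probes`.
#' @slot maxGap maximum within-region gap between consecutive probes (bp).
#' @slot minProbes minimum number of probes per retained region.
#' @seealso [buildRegions()], [filterRegions()]
#' @export
setClass("CpGRegionSet",
  representation(regions = "GRanges", maxGap = "integer", minProbes = "integer"))

setValidity("CpGRegionSet", function(object) {
  msg <- character()
  m <- mcols(object@regions)
  need <- c("region_id", "context", "gene", "probes", "n_probes")
  if (!all(need %in% colnames(m)))
    return(paste("regions must carry mcols:", paste(need, collapse = ", ")))
  if (anyDuplicated(m$region_id)) msg <- c(msg, "region ids must be unique")
  if (length(object@regions) && any(m$n_probes < object@minProbes))
    msg <- c(msg, "all regions must satisfy the minimum probe count")
  if (!all(m$context %in% c("genic", "intergenic")))
    msg <- c(msg, "context must be 'genic' or 'intergenic'")
  if (length(msg)) msg else TRUE
})

#' MethResiduals: standardized covariate-adjusted methylation residuals
#'
#' Per-probe ordinary-least-squares residuals of M-values on the covariate
#' design, standardized column-wise to mean 0 and (n-1)-denominator standard
#' deviation 1. Stored subjects-by-probes because downstream PCA treats
#' subjects as observations.
#'
#' @slot values numeric matrix, subjects x probes, dimnames set.
#' @slot covariateNames covariate columns that were regressed out.
#' @seealso [residualizeMethylation()]
#' @export
setClass("MethResiduals",
  representation(values = "matrix", covariateNames = "character"))

#' RegionPCA: the fitted principal components of one region
#'
#' @slot regionId region identifier.
#' @slot loadings p x ncomp orthonormal probe-loading matrix; each column's
#'   largest-magnitude entry is made positive (PC signs are otherwise
#'   arbitrary).
#' @slot scores n x ncomp matrix of subject scores (rownames = subject ids).
#' @slot varianceFractions length-p vector of variance fractions, padded with
#'   zeros when the block is rank-deficient; non-increasing, sums to 1.
#' @slot kSelected number of components retained for testing (NA until
#'   [selectK()] has been applied).
#' @slot mac maximum absolute pairwise Pearson correlation among the
#'   region's probes.
#' @seealso [computeRegionPCA()], [selectK()], [computeMAC()]
#' @export
setClass("RegionPCA",
  representation(regionId = "character", loadings = "matrix",
    scores = "matrix", varianceFractions = "numeric",
    kSelected = "integer", mac = "numeric"))

#' SimulationReport: a Monte-Carlo false-positive or true-positive rate
#'
#' @slot label human-readable description of the estimated quantity.
#' @slot params the simulation settings used.
#' @slot nReplicates number of Monte-Carlo replicates.
#' @slot rate estimated rate (mean of the per-replicate 0/1 flags).
#' @slot mcSE binomial Monte-Carlo standard error
#'   `sqrt(rate * (1 - rate) / nReplicates)`.
#' @slot flags per-replicate 0/1 outcomes.
#' @seealso [estimateGFP()], [estimateTP()]
#' @export
setClass("SimulationReport",
  representation(label = "character", params = "list",
    nReplicates = "integer", rate = "numeric", mcSE = "numeric",
    flags = "numeric"))
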