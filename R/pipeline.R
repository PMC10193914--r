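#' Assemble and validate a run configuration
#'
#' Collects every knob of the end-to-end analysis with the recommended
#' defaults: per-PC regressions combined with Fisher's method, components
#' covering at least 80% of the residual variance (at most 10), regions
#' with MAC of at least 0.3, DMRs called at q < 0.05. The phenotype must
#' not appear in the covariate list — otherwise its signal would be
#' regressed out before testing.
#'
#' @param methPath,annotPath,covarPath input files (see [loadDataset()]);
#'   omit them when calling [runDMRAnalysis()] with an in-memory dataset.
#' @param scale scale of the stored methylation values.
#' @param covariateNames covariates to residualize on (default: all).
#' @param phenotypeName,phenotypeKind which covariate-table column holds
#'   the phenotype and how to treat it.
#' @param method,firstPCOnly,varThreshold,kMax,macMin,qThreshold see
#'   [analyseRegions()].
#' @param maxGap,minProbes see [buildRegions()].
#' @param seed RNG seed for the run (degeneracy jitter).
#' @param outDir output directory for [runDMRAnalysis()].
#' @return a validated named list of class `dmrRunConfig`.
#' @export
dmrRunConfig <- function(methPath = NULL, annotPath = NULL,
                         covarPath = NULL, scale = "beta",
                         covariateNames = NULL, phenotypeName = "phenotype",
                         phenotypeKind = "continuous",
                         method = "fisher", firstPCOnly = FALSE,
                         varThreshold = 0.80, kMax = 10L, macMin = 0.3,
                         qThreshold = 0.05, maxGap = 200L, minProbes = 3L,
                         seed = 1L, outDir = ".") {
  cfg <- list(methPath = methPath, annotPath = annotPath,
              covarPath = covarPath, scale = scale,
              covariateNames = covariateNames,
              phenotypeName = phenotypeName,
              phenotypeKind = phenotypeKind, method = method,
              firstPCOnly = firstPCOnly, varThreshold = varThreshold,
              kMax = as.integer(kMax), macMin = macMin,
              qThreshold = qThreshold, maxGap = as.integer(maxGap),
              minProbes = as.integer(minProbes), seed = as.integer(seed),
              outDir = outDir)
  if (!is.null(cfg$covariateNames) &&
      cfg$phenotypeName %in% cfg$covariateNames)
    stop("phenotype '", cfg$phenotypeName,
         "' must not be in the covariate list")
  if (!cfg$method %in% c("fisher", "stouffer", "joint"))
    stop("method must be fisher, stouffer or joint")
  if (!cfg$varThreshold %in% c(0.80, 0.90, 0.95, 0.99))
    warning("varThreshold outside the studied grid (0.80/0.90/0.95/0.99)")
  class(cfg) <- "dmrRunConfig"
  cfg
}

#' Read / write a run configuration as YAML
#'
#' The round trip is lossless: `readRunConfig(writeRunConfig(cfg, f))`
#' reproduces `cfg`.
#'
#' @param cfg a config from [dmrRunConfig()].
#' @param path YAML file path.
#' @return `writeRunConfig` invisibly returns `path`; `readRunConfig`
#'   returns the config.
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  do.call(dmrRunConfig, yaml::read_yaml(path))
}

#' Run the end-to-end DMR analysis
#'
#' Load (or accept) the dataset, build regions, residualize, fit per-region
#' PCA, filter by MAC, test each region against the phenotype, adjust by
#' Benjamini-Hochberg, and write `results.tsv`, `summary.txt` and the
#' resolved `config.yaml` to the configured output directory. The run is
#' deterministic given the config's seed.
#'
#' @param config a [dmrRunConfig()] (or a YAML path to one).
#' @param dataset optional in-memory [MethylationDataset-class]; when
#'   supplied the config's input paths are ignored.
#' @param phenotype optional [Phenotype-class]; by default the
#'   `phenotypeName` column is taken from the dataset's covariate table
#'   (and excluded from the covariates used for residualization).
#' @param regionSet optional precomputed [CpGRegionSet-class].
#' @param verbose log per-stage counts.
#' @return the result `DataFrame` from [analyseRegions()], invisibly.
#' @export
runDMRAnalysis <- function(config, dataset = NULL, phenotype = NULL,
                           regionSet = NULL, verbose = TRUE) {
  if (is.character(config)) config <- readRunConfig(config)
  stopifnot(inherits(config, "dmrRunConfig"))
  set.seed(config$seed)

  if (is.null(dataset))
    dataset <- loadDataset(config$methPath, config$annotPath,
                           config$covarPath, scale = config$scale,
                           verbose = verbose)
  covarNames <- config$covariateNames
  if (is.null(covarNames))
    covarNames <- colnames(covariateTable(dataset))
  if (is.null(phenotype)) {
    if (!config$phenotypeName %in% colnames(covariateTable(dataset)))
      stop("phenotype column '", config$phenotypeName,
           "' not found in the covariate table")
    phenotype <- Phenotype(
      stats::setNames(covariateTable(dataset)[[config$phenotypeName]],
                      colnames(dataset)),
      kind = config$phenotypeKind, name = config$phenotypeName)
  }
  covarNames <- setdiff(covarNames, phenotype@name)

  if (is.null(regionSet))
    regionSet <- buildRegions(dataset, maxGap = config$maxGap,
                              minProbes = config$minProbes,
                              verbose = verbose)

  res <- analyseRegions(dataset, regionSet, phenotype,
                        method = config$method,
                        firstPCOnly = config$firstPCOnly,
                        varThreshold = config$varThreshold,
                        kMax = config$kMax, macMin = config$macMin,
                        qThreshold = config$qThreshold,
                        covariates = covarNames, verbose = verbose)

  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  writeResultsTSV(res, file.path(config$outDir, "results.tsv"))
  writeRunConfig(config, file.path(config$outDir, "config.yaml"))
  writeLines(c(
    sprintf("regions built: %d", length(regionSet)),
    sprintf("regions analysed (MAC >= %.2f): %d", config$macMin, nrow(res)),
    sprintf("DMRs at q < %.2f: %d", config$qThreshold, sum(res$is_dmr)),
    sprintf("subjects used: %d",
            if (nrow(res)) res$n_used[1L] else ncol(dataset))),
    file.path(config$outDir, "summary.txt"))
  invisible(res)
}

#' Run a null- or power-simulation study over the parameter grid
#'
#' Sweeps the studied parameter grid and returns one row per setting.
#' `"null_small_n"` resamples a subject subset per replicate before drawing
#' the null phenotype; `"null_full_n"` uses all subjects with residuals and
#' PCA computed once and reused; `"power"` estimates true-positive rates
#' for a component-anchored signal in one region.
#'
#' @param dataset a [MethylationDataset-class].
#' @param regionSet a [CpGRegionSet-class].
#' @param study `"null_small_n"`, `"null_full_n"` or `"power"`.
#' @param phenoKinds null phenotype types to sweep (null studies).
#' @param methods,varThresholds,macMins grid axes; defaults give the full
#'   studied grid for null studies.
#' @param firstPCOnly also include the PC1-only variants.
#' @param nReplicates Monte-Carlo replicates per cell.
#' @param baseSeed seed offset per replicate.
#' @param resampleN subject subset size for `"null_small_n"`.
#' @param regionId,signal,noiseSD power-study settings (see
#'   [estimateTP()]).
#' @param verbose log progress.
#' @return data.frame with columns `study, method, var_threshold, mac_min,
#'   phenotype, n, n_replicates, rate, mc_se, seed`.
#' @export
runSimulationStudy <- function(dataset, regionSet,
                               study = c("null_small_n", "null_full_n",
                                         "power"),
                               phenoKinds = c("normal", "chisq1",
                                              "dichot50", "dichot25"),
                               methods = c("fisher", "stouffer", "joint"),
                               varThresholds = c(0.80, 0.90, 0.95, 0.99),
                               macMins = seq(0, 0.5, by = 0.1),
                               firstPCOnly = FALSE,
                               nReplicates = 200L, baseSeed = 0L,
                               resampleN = 100L, regionId = NULL,
                               signal = "cts_pc1", noiseSD = NULL,
                               verbose = FALSE) {
  study <- match.arg(study)
  rows <- list()
  if (study %in% c("null_small_n", "null_full_n")) {
    grid <- expand.grid(kind = phenoKinds, method = methods,
                        vt = varThresholds, mm = macMins,
                        stringsAsFactors = FALSE)
    for (i in seq_len(nrow(grid))) {
      rep <- estimateGFP(dataset, regionSet,
                         phenoKind = grid$kind[i],
                         nReplicates = nReplicates, baseSeed = baseSeed,
                         method = grid$method[i],
                         firstPCOnly = firstPCOnly,
                         varThreshold = grid$vt[i], macMin = grid$mm[i],
                         resampleSubjects = study == "null_small_n",
                         resampleN = resampleN, verbose = verbose)
      rows[[i]] <- data.frame(
        study = study, method = .methodLabel(grid$method[i], firstPCOnly),
        var_threshold = grid$vt[i], mac_min = grid$mm[i],
        phenotype = grid$kind[i], n = rep@params$n,
        n_replicates = nReplicates, rate = simRate(rep),
        mc_se = simMcSE(rep), seed = baseSeed)
    }
  } else {
    if (is.null(regionId)) stop("power study needs a regionId")
    for (i in seq_along(varThresholds)) {
      for (m in methods) {
        rep <- estimateTP(dataset, regionSet, regionId, signal, noiseSD,
                          nReplicates = nReplicates, baseSeed = baseSeed,
                          method = m, firstPCOnly = firstPCOnly,
                          varThreshold = varThresholds[i])
        rows[[length(rows) + 1L]] <- data.frame(
          study = study, method = .methodLabel(m, firstPCOnly),
          var_threshold = varThresholds[i], mac_min = NA_real_,
          phenotype = signal, n = ncol(dataset),
          n_replicates = nReplicates, rate = simRate(rep),
          mc_se = simMcSE(rep), seed = baseSeed)
      }
    }
  }
  do.call(rbind, rows)
}
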