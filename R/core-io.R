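#' Construct a MethylationDataset
#'
#' @param values numeric matrix of methylation values. Accepted in the file
#'   orientation (subjects as rows, probe ids as column names); it is stored
#'   internally probes-by-subjects.
#' @param annotation probe annotation: either a `GRanges` with a `genes`
#'   `CharacterList` metadata column, or a data.frame with columns
#'   `probe_id`, `chrom`, `pos` (1-based) and `genes` (semicolon-separated
#'   gene symbols, empty string for intergenic probes).
#' @param covariates optional data.frame of subject covariates; subjects are
#'   matched by a `subject_id` column or by rownames. Categorical covariates
#'   must be numerically encoded.
#' @param scale `"beta"` or `"mvalue"`.
#' @param verbose log counts of dropped probes/subjects.
#' @return a [MethylationDataset-class].
#' @details Subjects present in both the methylation matrix and the covariate
#'   table are retained (in methylation-matrix order); probes missing from
#'   the annotation are dropped; subjects with any missing covariate value
#'   are dropped. All drops are logged. Alignment is always by id, never by
#'   row order.
#' @export
MethylationDataset <- function(values, annotation, covariates = NULL,
                               scale = c("beta", "mvalue"), verbose = TRUE) {
  scale <- match.arg(scale)
  if (is.null(colnames(values)))
    stop("methylation matrix must have probe ids as column names")
  if (is.null(rownames(values)))
    stop("methylation matrix must have subject ids as row names")
  if (anyDuplicated(rownames(values))) stop("duplicated subject ids")
  if (anyDuplicated(colnames(values))) stop("duplicated probe ids")
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing methylation value at subject '%s', probe '%s'",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]))
  }

  gr <- .asProbeGRanges(annotation)

  keepProbes <- intersect(colnames(values), names(gr))
  nDropProbe <- ncol(values) - length(keepProbes)
  if (nDropProbe > 0 && verbose)
    message(nDropProbe, " probe(s) dropped: missing from the annotation")
  if (!length(keepProbes)) stop("no probes overlap the annotation")
  values <- values[, keepProbes, drop = FALSE]
  gr <- gr[keepProbes]

  subjects <- rownames(values)
  cd <- S4Vectors::DataFrame(row.names = subjects)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if ("subject_id" %in% colnames(covariates)) {
      if (anyDuplicated(covariates$subject_id))
        stop("duplicated subject ids in covariate table")
      rownames(covariates) <- covariates$subject_id
      covariates$subject_id <- NULL
    }
    ok <- stats::complete.cases(covariates)
    if (any(!ok) && verbose)
      message(sum(!ok), " subject(s) dropped due to missing covariates")
    covariates <- covariates[ok, , drop = FALSE]
    subjects <- intersect(rownames(values), rownames(covariates))
    nDropSubj <- nrow(values) - length(subjects)
    if (!length(subjects))
      stop("no overlapping subjects between methylation and covariates")
    if (nDropSubj > 0 && verbose)
      message(nDropSubj,
              " subject(s) dropped: absent from the covariate table")
    values <- values[subjects, , drop = FALSE]
    cd <- S4Vectors::DataFrame(covariates[subjects, , drop = FALSE])
    for (cn in colnames(cd))
      if (length(subjects) > 1L && length(unique(cd[[cn]])) == 1L)
        warning("covariate '", cn, "' is constant across subjects")
  }

  se <- SummarizedExperiment(assays = list(meth = t(values)),
                             rowRanges = gr, colData = cd)
  metadata(se)$scale <- scale
  new("MethylationDataset", se)
}

.asProbeGRanges <- function(annotation) {
  if (is(annotation, "GRanges")) {
    gr <- annotation
    if (is.null(names(gr))) stop("annotation GRanges must be named by probe id")
    if (is.null(mcols(gr)$genes))
      mcols(gr)$genes <- IRanges::CharacterList(vector("list", length(gr)))
    return(gr)
  }
  annotation <- as.data.frame(annotation)
  need <- c("probe_id", "chrom", "pos")
  if (!all(need %in% colnames(annotation)))
    stop("annotation needs columns: probe_id, chrom, pos[, genes]")
  if (anyDuplicated(annotation$probe_id))
    stop("duplicated probe ids in annotation")
  if (any(annotation$pos < 1)) stop("probe positions must be >= 1")
  genes <- if ("genes" %in% colnames(annotation)) {
    g <- strsplit(ifelse(is.na(annotation$genes), "", annotation$genes), ";",
                  fixed = TRUE)
    IRanges::CharacterList(lapply(g, function(x) x[nzchar(x)]))
  } else IRanges::CharacterList(vector("list", nrow(annotation)))
  gr <- GRanges(annotation$chrom,
                IRanges(annotation$pos, width = 1L),
                genes = genes)
  names(gr) <- annotation$probe_id
  gr
}

#' @describeIn MethylationDataset-class number of probes and subjects
#' @param object a `MethylationDataset`
#' @export
setMethod("show", "MethylationDataset", function(object) {
  cat("MethylationDataset:", nrow(object), "probes x", ncol(object),
      "subjects\n")
  cat("  scale:", metadata(object)$scale, "\n")
  cat("  covariates:", if (ncol(colData(object)))
    paste(colnames(colData(object)), collapse = ", ") else "(none)", "\n")
})

#' Accessors for MethylationDataset
#'
#' `methScale()` returns `"beta"` or `"mvalue"`; `betaValues()` and
#' `mValues()` return the probes-by-subjects matrix on the requested scale,
#' converting if necessary; `probeAnnotation()` returns the probe `GRanges`;
#' `covariateTable()` the subject covariates.
#'
#' @param x a [MethylationDataset-class]
#' @name methylation-accessors
NULL

#' @rdname methylation-accessors
#' @export
methScale <- function(x) metadata(x)$scale

#' @rdname methylation-accessors
#' @export
betaValues <- function(x) {
  v <- assay(x, "meth")
  if (identical(methScale(x), "beta")) v else mToBeta(v)
}

#' @rdname methylation-accessors
#' @export
mValues <- function(x) {
  v <- assay(x, "meth")
  if (identical(methScale(x), "mvalue")) v else betaToM(v)
}

#' @rdname methylation-accessors
#' @export
probeAnnotation <- function(x) rowRanges(x)

#' @rdname methylation-accessors
#' @export
covariateTable <- function(x) colData(x)

#' Convert beta-values to M-values and back
#'
#' M-values are base-2 logit-transformed beta-values:
#' `M = log2(beta / (1 - beta))`; the inverse map is
#' `beta = 2^M / (1 + 2^M)`. Beta-values are proportions and suit
#' interpretation; M-values are unbounded and suit linear modelling.
#'
#' @param beta numeric vector/matrix of beta-values, strictly in (0,1).
#' @param m numeric vector/matrix of finite M-values.
#' @return numeric of the same shape on the other scale. For a
#'   [MethylationDataset-class], a dataset with the assay converted and the
#'   scale tag updated.
#' @examples
#' betaToM(0.8)        # log2(4) = 2
#' mToBeta(0)          # 0.5
#' @export
betaToM <- function(beta) {
  if (is(beta, "MethylationDataset")) {
    if (identical(methScale(beta), "mvalue")) return(beta)
    out <- beta
    SummarizedExperiment::assay(out, "meth") <- betaToM(assay(beta, "meth"))
    metadata(out)$scale <- "mvalue"
    return(out)
  }
  bad <- !is.na(beta) & (beta <= 0 | beta >= 1)
  if (any(bad)) stop(.describeBad(beta, bad, "beta-value outside (0,1)"))
  v <- log2(beta / (1 - beta))
  v
}

#' @rdname betaToM
#' @export
mToBeta <- function(m) {
  if (is(m, "MethylationDataset")) {
    if (identical(methScale(m), "beta")) return(m)
    out <- m
    SummarizedExperiment::assay(out, "meth") <- mToBeta(assay(m, "meth"))
    metadata(out)$scale <- "beta"
    return(out)
  }
  bad <- !is.finite(m)
  if (any(bad)) stop(.describeBad(m, bad, "non-finite M-value"))
  # stable inverse logit on the log2 scale
  ifelse(m > 0, 1 / (1 + 2^(-m)), 2^m / (1 + 2^m))
}

.describeBad <- function(x, bad, what) {
  i <- which(bad)[1L]
  if (is.matrix(x)) {
    rc <- arrayInd(i, dim(x))
    sprintf("%s at row '%s', column '%s'", what,
            if (!is.null(rownames(x))) rownames(x)[rc[1L]] else rc[1L],
            if (!is.null(colnames(x))) colnames(x)[rc[2L]] else rc[2L])
  } else {
    sprintf("%s at position %d", what, i)
  }
}

.readTable <- function(path) {
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr, fixed = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
}

#' Load a methylation dataset from tabular files
#'
#' Reads three CSV/TSV files (the delimiter is sniffed from the header line):
#' the methylation matrix (first column = subject id, remaining header =
#' probe ids), the probe annotation (`probe_id, chrom, pos, genes` with a
#' semicolon-separated gene list, empty for intergenic) and the covariate
#' table (keyed by `subject_id`). Subjects present in both tables are kept;
#' probes absent from the annotation and subjects with missing covariates
#' are dropped with logged counts.
#'
#' @param methPath,annotPath,covarPath file paths; `covarPath` may be `NULL`.
#' @param scale scale of the stored methylation values.
#' @param verbose log drop counts.
#' @return a [MethylationDataset-class].
#' @seealso [writeDataset()] for the inverse operation.
#' @export
loadDataset <- function(methPath, annotPath, covarPath = NULL,
                        scale = c("beta", "mvalue"), verbose = TRUE) {
  scale <- match.arg(scale)
  meth <- .readTable(methPath)
  rownames(meth) <- as.character(meth[[1L]])
  meth <- as.matrix(meth[, -1L, drop = FALSE])
  storage.mode(meth) <- "double"
  annot <- .readTable(annotPath)
  covars <- if (!is.null(covarPath)) .readTable(covarPath) else NULL
  MethylationDataset(meth, annot, covars, scale = scale, verbose = verbose)
}

#' Write a methylation dataset to its tabular file formats
#'
#' Writes `methylation.csv`, `annotation.csv` and (when covariates are
#' present) `covariates.csv` under `dir`, in the formats read by
#' [loadDataset()]. Reloading the written files reproduces the dataset.
#'
#' @param x a [MethylationDataset-class]
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written.
#' @export
writeDataset <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  methPath <- file.path(dir, "methylation.csv")
  v <- t(assay(x, "meth"))
  utils::write.csv(data.frame(subject_id = rownames(v), v,
                              check.names = FALSE, row.names = NULL),
                   methPath, row.names = FALSE, quote = FALSE)
  gr <- rowRanges(x)
  annotPath <- file.path(dir, "annotation.csv")
  utils::write.csv(data.frame(
    probe_id = names(gr),
    chrom = as.character(seqnames(gr)),
    pos = start(gr),
    genes = vapply(mcols(gr)$genes, paste, "", collapse = ";")),
    annotPath, row.names = FALSE, quote = FALSE)
  paths <- c(methPath, annotPath)
  if (ncol(colData(x))) {
    covarPath <- file.path(dir, "covariates.csv")
    utils::write.csv(data.frame(subject_id = colnames(x),
                                as.data.frame(colData(x)),
                                check.names = FALSE, row.names = NULL),
                     covarPath, row.names = FALSE, quote = FALSE)
    paths <- c(paths, covarPath)
  }
  invisible(paths)
}

#' Construct a Phenotype
#'
#' @param values numeric vector named by subject id (or supply `subjectIds`).
#' @param kind `"continuous"` or `"dichotomous"` (0/1 coding, both classes
#'   required). If omitted, a vector containing only 0s and 1s is taken as
#'   dichotomous.
#' @param name phenotype label; must not collide with a covariate name used
#'   during residualization.
#' @param subjectIds optional ids when `values` is unnamed.
#' @return a [Phenotype-class].
#' @export
Phenotype <- function(values, kind = NULL, name = "phenotype",
                      subjectIds = NULL) {
  if (!is.null(subjectIds)) names(values) <- subjectIds
  if (is.null(kind))
    kind <- if (all(values %in% c(0, 1)) && length(unique(values)) == 2L)
      "dichotomous" else "continuous"
  new("Phenotype", values = values, kind = kind, name = name)
}

#' @describeIn Phenotype-class brief summary
#' @param object a `Phenotype`
#' @export
setMethod("show", "Phenotype", function(object) {
  cat(sprintf("Phenotype '%s' (%s), n = %d\n", object@name, object@kind,
              length(object@values)))
})

#' @rdname methylation-accessors
#' @export
phenotypeValues <- function(x) x@values

#' @rdname methylation-accessors
#' @export
phenotypeKind <- function(x) x@kind
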