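#' Remove covariate effects from M-values and standardize
#'
#' For every probe j the M-values are regressed on the covariate design by
#' ordinary least squares (`M_j ~ covariates`, with intercept); the
#' residuals `M_j - fitted_j` are then standardized column-wise to mean 0
#' and standard deviation 1 (n-1 denominator). All probes share one QR
#' factorization of the design matrix, which is numerically identical to
#' probe-by-probe fitting. A probe whose M-values have zero variance is
#' given a tiny uniform perturbation (drawn from the current RNG stream)
#' before fitting so that the standardization is defined; the same
#' perturb-and-refit is attempted once if a *residual* column degenerates.
#'
#' @param x a [MethylationDataset-class] (converted to M-values internally)
#'   or a subjects-by-probes numeric M-value matrix.
#' @param covariates covariate values: by default all columns of
#'   `covariateTable(x)`; alternatively a character vector naming a subset
#'   of those columns, or a numeric data.frame/matrix aligned by subject id.
#'   Categorical covariates must already be numerically encoded.
#' @param jitterFactor relative magnitude of the degeneracy perturbation:
#'   uniform on `c(-a, a)` with `a = jitterFactor * max(1, |column mean|)`.
#' @return a [MethResiduals-class] (subjects x probes).
#' @details Residuals are specific to the subject set they were computed on;
#'   recompute them per analysis rather than subsetting a cached matrix.
#'   The phenotype under test must never be part of the covariate set
#'   ([analyseRegions()] enforces this by name).
#' @export
residualizeMethylation <- function(x, covariates = NULL,
                                   jitterFactor = 1e-6) {
  if (is(x, "MethylationDataset")) {
    M <- t(mValues(x))
    covarData <- as.data.frame(covariateTable(x))
    if (is.null(covariates)) {
      covariates <- covarData
    } else if (is.character(covariates)) {
      missing <- setdiff(covariates, colnames(covarData))
      if (length(missing))
        stop("unknown covariate(s): ", paste(missing, collapse = ", "))
      covariates <- covarData[, covariates, drop = FALSE]
    }
  } else {
    M <- as.matrix(x)
  }
  n <- nrow(M)
  covNames <- character()
  if (is.null(covariates) || NCOL(covariates) == 0L ||
      NROW(covariates) == 0L) {
    X <- matrix(1, n, 1L)
  } else {
    covariates <- as.data.frame(covariates)
    if (!is.null(rownames(M)) && !is.null(rownames(covariates)) &&
        !all(rownames(M) %in% rownames(covariates)))
      stop("covariate table is missing some subjects")
    if (!is.null(rownames(M)) && all(rownames(M) %in% rownames(covariates)))
      covariates <- covariates[rownames(M), , drop = FALSE]
    if (nrow(covariates) != n)
      stop("covariates and methylation have different subject counts")
    covNames <- colnames(covariates)
    X <- cbind(`(Intercept)` = 1, as.matrix(covariates))
    storage.mode(X) <- "double"
  }
  m <- ncol(X) - 1L
  if (n <= m + 2L)
    stop("need more subjects than covariates + 2 (n = ", n, ", m = ", m, ")")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    stop("covariate design is rank-deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }

  M <- .jitterConstantColumns(M, jitterFactor)
  R <- .olsResiduals(qrX, M)
  sds <- .colSdsN1(R)
  if (any(sds == 0)) {
    # one perturb-and-refit pass on residual degeneracy
    deg <- sds == 0
    M[, deg] <- .jitterMatrix(M[, deg, drop = FALSE], jitterFactor)
    R[, deg] <- .olsResiduals(qrX, M[, deg, drop = FALSE])
    sds <- .colSdsN1(R)
    if (any(sds == 0))
      stop("residuals have zero variance for probe(s): ",
           paste(colnames(M)[sds == 0], collapse = ", "))
  }
  R <- scale(R, center = TRUE, scale = sds)
  attr(R, "scaled:center") <- NULL
  attr(R, "scaled:scale") <- NULL
  dimnames(R) <- dimnames(M)
  new("MethResiduals", values = R, covariateNames = covNames)
}

.olsResiduals <- function(qrX, M) {
  M - qr.fitted(qrX, M)
}

.colSdsN1 <- function(R) {
  n <- nrow(R)
  mu <- colMeans(R)
  sqrt(pmax(colSums(R^2) - n * mu^2, 0) / (n - 1L))
}

.jitterConstantColumns <- function(M, jitterFactor) {
  sds <- .colSdsN1(M)
  if (any(sds == 0))
    M[, sds == 0] <- .jitterMatrix(M[, sds == 0, drop = FALSE], jitterFactor)
  M
}

.jitterMatrix <- function(M, jitterFactor) {
  a <- jitterFactor * pmax(1, abs(colMeans(M)))
  M + matrix(stats::runif(length(M), -1, 1), nrow(M), ncol(M)) *
    rep(a, each = nrow(M))
}

#' @describeIn MethResiduals-class brief summary
#' @param object a `MethResiduals`
#' @export
setMethod("show", "MethResiduals", function(object) {
  cat(sprintf("MethResiduals: %d subjects x %d probes\n",
              nrow(object@values), ncol(object@values)))
  cat("  covariates removed:", if (length(object@covariateNames))
    paste(object@covariateNames, collapse = ", ") else "(intercept only)",
    "\n")
})

#' @rdname methylation-accessors
#' @export
residValues <- function(x) x@values
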