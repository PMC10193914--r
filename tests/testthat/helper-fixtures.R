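# Shared fixture builders; everything is generated in code at test time.

# A small synthetic genome reused across tests.
smallDataset <- function(nSubjects = 60, nRegions = 30, seed = 42, ...) {
  simulateMethylationDataset(nSubjects = nSubjects, nRegions = nRegions,
                             seed = seed, ...)
}

# A data matrix whose *sample* correlation matrix equals Sigma exactly:
# whiten the empirical covariance, then colour by chol(Sigma).
exactCorrelationData <- function(n, Sigma, seed = 1) {
  set.seed(seed)
  p <- ncol(Sigma)
  Z <- matrix(rnorm(n * p), n, p)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  W <- solve(chol(crossprod(Z) / (n - 1)))
  X <- (Z %*% W) %*% chol(Sigma)
  scale(X, center = TRUE, scale = apply(X, 2, sd))
}

# Standardized residual matrix wrapper around an arbitrary numeric block.
asResiduals <- function(X, probeIds = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- if (is.null(probeIds))
      paste0("cg", seq_len(ncol(X))) else probeIds
  if (is.null(rownames(X))) rownames(X) <- paste0("S", seq_len(nrow(X)))
  X <- scale(X)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  new("MethResiduals", values = X, covariateNames = character())
}

# Write a tiny three-file dataset to a temp dir; returns the paths.
writeToyFiles <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                          subjects = c("A", "B", "C"),
                          probes = c("cg1", "cg2", "cg3"),
                          covarSubjects = subjects) {
  set.seed(99)
  meth <- matrix(runif(length(subjects) * length(probes), 0.2, 0.8),
                 length(subjects), length(probes),
                 dimnames = list(subjects, probes))
  methPath <- file.path(dir, "meth.csv")
  write.csv(data.frame(subject_id = subjects, meth, check.names = FALSE),
            methPath, row.names = FALSE, quote = FALSE)
  annotPath <- file.path(dir, "annot.csv")
  write.csv(data.frame(probe_id = probes, chrom = "chr1",
                       pos = c(100L, 200L, 350L), genes = "GENE1"),
            annotPath, row.names = FALSE, quote = FALSE)
  covarPath <- file.path(dir, "covar.csv")
  write.csv(data.frame(subject_id = covarSubjects,
                       age = seq(30, by = 5,
                                 length.out = length(covarSubjects)),
                       sex = rep_len(c(0, 1), length(covarSubjects))),
            covarPath, row.names = FALSE, quote = FALSE)
  list(meth = methPath, annot = annotPath, covar = covarPath, dir = dir)
}
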