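#' Encode 0/1/2 dosages into additive and dominance incidence codings
#'
#' Builds a \code{\link{GenotypeMatrix}} from a matrix of reference-allele
#' counts. The additive coding is \code{Z = dosage - 1} (so homozygotes map
#' to -1 and 1 and heterozygotes to 0) and the dominance coding \code{W} is
#' the heterozygote indicator. With \code{center = TRUE} each column of
#' \code{Z} and \code{W} is centered within the population; centering is
#' off by default because it can make individual-level covariance matrices
#' singular.
#'
#' @param dosage integer matrix (individuals x SNPs) with entries in
#'   \{0, 1, 2\}; dimnames, when present, provide individual ids and SNP
#'   names.
#' @param ids,snps optional character vectors overriding the dimnames.
#' @param center logical; subtract column means from Z and W (per
#'   population). Default \code{FALSE}.
#' @return a \code{GenotypeMatrix}.
#' @examples
#' g <- encodeGenotypes(rbind(c(0, 1, 2), c(1, 1, 1)))
#' addCoding(g)   # -1/0/1 coding
#' domCoding(g)   # heterozygote indicator
#' @export
encodeGenotypes <- function(dosage, ids = NULL, snps = NULL, center = FALSE) {
  dosage <- as.matrix(dosage)
  if (is.null(ids)) ids <- rownames(dosage)
  if (is.null(ids)) ids <- sprintf("ind%d", seq_len(nrow(dosage)))
  if (is.null(snps)) snps <- colnames(dosage)
  if (is.null(snps)) snps <- sprintf("snp%d", seq_len(ncol(dosage)))
  bad <- which(!(dosage %in% c(0, 1, 2)) | is.na(dosage))
  if (length(bad) > 0) {
    rc <- arrayInd(bad[1], dim(dosage))
    mpStop(sprintf(
      "invalid genotype coding: entry at row %d ('%s'), column %d ('%s') is %s; dosages must be 0, 1 or 2 with no missing values",
      rc[1], ids[rc[1]], rc[2], snps[rc[2]],
      ifelse(is.na(dosage[bad[1]]), "missing", format(dosage[bad[1]]))),
      class = "mp_validation_error")
  }
  storage.mode(dosage) <- "integer"
  dimnames(dosage) <- list(ids, snps)
  Z <- dosage - 1
  W <- (dosage == 1) + 0
  storage.mode(Z) <- "double"; storage.mode(W) <- "double"
  if (center && nrow(dosage) > 0) {
    Z <- sweep(Z, 2, colMeans(Z))
    W <- sweep(W, 2, colMeans(W))
  }
  new("GenotypeMatrix", ids = ids, snps = snps, dosage = dosage,
      Z = Z, W = W, centered = center)
}

#' Genomic inbreeding of each individual
#'
#' Observed homozygosity \code{F_q = 1 - het_q / m}, where \code{het_q} is
#' the number of heterozygous SNPs of individual \code{q} and \code{m} the
#' SNP count. Bounded in [0, 1]; used as the inbreeding-depression
#' covariate of the fixed-effect design.
#'
#' @param g a \code{\link{GenotypeMatrix}}.
#' @return named numeric vector of length \code{nRecords(g)}.
#' @export
inbreedingCovariate <- function(g) {
  stopifnot(is(g, "GenotypeMatrix"))
  m <- ncol(g@dosage)
  if (m == 0)
    mpStop("cannot compute genomic inbreeding with zero SNPs",
           class = "mp_validation_error")
  setNames(1 - rowSums(g@dosage == 1L) / m, g@ids)
}

#' Build a population's fixed-effect design matrix
#'
#' The design is [intercept | genomic inbreeding (optional) | user
#' covariates]. Full column rank is verified; collinear columns (e.g. a
#' constant inbreeding covariate in a fully homozygous population) raise a
#' validation error naming the offending columns.
#'
#' @param genotypes a \code{\link{GenotypeMatrix}}.
#' @param covariates optional numeric matrix or data.frame of user
#'   covariates (one row per individual).
#' @param includeInbreeding logical; append the genomic-inbreeding column.
#'   Default \code{TRUE}, matching the model in which dominance effects
#'   have zero prior mean because inbreeding depression is absorbed as a
#'   covariate.
#' @return numeric design matrix with named columns.
#' @export
buildDesign <- function(genotypes, covariates = NULL, includeInbreeding = TRUE) {
  stopifnot(is(genotypes, "GenotypeMatrix"))
  n <- nrow(genotypes@dosage)
  X <- matrix(1, n, 1, dimnames = list(genotypes@ids, "intercept"))
  if (includeInbreeding)
    X <- cbind(X, inbreeding = inbreedingCovariate(genotypes))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n)
      mpStop("covariates must have one row per individual",
             class = "mp_validation_error")
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    X <- cbind(X, covariates)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    mpStop(sprintf("fixed-effect design is rank deficient; collinear column(s): %s",
                   paste(dropped, collapse = ", ")),
           class = "mp_validation_error")
  }
  X
}

#' Assemble a PopulationData object
#'
#' @param label population label.
#' @param y numeric phenotypes.
#' @param genotypes a \code{\link{GenotypeMatrix}} with rows aligned to
#'   \code{y}.
#' @param covariates,includeInbreeding passed to \code{\link{buildDesign}};
#'   alternatively supply a ready design via \code{X}.
#' @param X optional explicit design matrix (must contain an intercept).
#' @return a \code{PopulationData}.
#' @export
populationData <- function(label, y, genotypes, covariates = NULL,
                           includeInbreeding = TRUE, X = NULL) {
  if (length(y) != nrow(genotypes@dosage))
    mpStop(sprintf("population '%s': %d phenotypes but %d genotyped individuals",
                   label, length(y), nrow(genotypes@dosage)),
           class = "mp_validation_error")
  if (is.null(X))
    X <- buildDesign(genotypes, covariates, includeInbreeding)
  new("PopulationData", label = as.character(label), y = as.numeric(y),
      X = X, genotypes = genotypes)
}

#' Assemble a MultiPopDataset
#'
#' @param populations list of \code{PopulationData}, in population order.
#' @return a \code{MultiPopDataset}.
#' @export
multiPopDataset <- function(populations) {
  new("MultiPopDataset", populations = populations)
}

#' Construct variance components
#'
#' @param g0a,g0d P x P symmetric covariance matrices of additive and
#'   dominance SNP effects across populations.
#' @param sigmaE2 length-P vector of residual variances.
#' @return a \code{VarianceComponents}.
#' @export
varianceComponents <- function(g0a, g0d, sigmaE2) {
  new("VarianceComponents", g0a = as.matrix(g0a), g0d = as.matrix(g0d),
      sigmaE2 = as.numeric(sigmaE2))
}

#' Validate a dataset against variance components
#'
#' Collects (rather than throws) every consistency failure: shared SNP set,
#' matching population counts, positive-definiteness of G0a and G0d
#' (checked by Cholesky), and positive residual variances.
#'
#' @param ds a \code{\link{MultiPopDataset}}.
#' @param vc a \code{\link{VarianceComponents}}.
#' @return character vector of failure messages; empty when consistent.
#' @export
validateDataset <- function(ds, vc) {
  failures <- character(0)
  P <- nPopulations(ds)
  if (length(vc@sigmaE2) != P)
    failures <- c(failures, sprintf(
      "dimension mismatch: dataset has P = %d populations but variance components have P = %d",
      P, length(vc@sigmaE2)))
  if (!isPosDef(vc@g0a))
    failures <- c(failures, "G0a is not positive definite (Cholesky failed); not a valid covariance matrix")
  if (!isPosDef(vc@g0d))
    failures <- c(failures, "G0d is not positive definite (Cholesky failed); not a valid covariance matrix")
  if (any(vc@sigmaE2 <= 0))
    failures <- c(failures, "residual variances must be strictly positive")
  ms <- vapply(ds@populations, function(p) ncol(p@genotypes@dosage), integer(1))
  if (length(unique(ms)) > 1)
    failures <- c(failures, "populations disagree on SNP count m")
  failures
}
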