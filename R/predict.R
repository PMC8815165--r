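#' Indirect prediction of newly genotyped individuals
#'
#' Predicts genetic values of individuals with no phenotype as the sum of
#' estimated SNP effects weighted by gene content: \code{uA = Z_new
#' aHat_target} and \code{uD = W_new dHat_target}, where target is the
#' population whose effect estimates are used. SNPs are matched by name
#' and reordered to the training panel; any missing SNP is an error.
#'
#' @param solution a \code{\link{SolutionSet}} carrying marker effects, or
#'   a list with elements \code{aHat}, \code{dHat}.
#' @param newGenotypes a \code{\link{GenotypeMatrix}} for the individuals
#'   to predict.
#' @param targetPop integer index (row of aHat) of the population whose
#'   marker effects are applied.
#' @return data.frame with columns id, uA, uD, total.
#' @export
indirectPredict <- function(solution, newGenotypes, targetPop = 1L) {
  if (is(solution, "SolutionSet")) {
    aHat <- solution@aHat; dHat <- solution@dHat
  } else {
    aHat <- solution$aHat; dHat <- solution$dHat
  }
  if (is.null(aHat) || nrow(aHat) == 0)
    mpStop("the solution carries no marker effects; indirect prediction needs a marker-level solve (snp_blup, gls_si, or backsolved compact GBLUP)",
           class = "mp_validation_error")
  if (targetPop < 1 || targetPop > nrow(aHat))
    mpStop(sprintf("targetPop must be in 1..%d", nrow(aHat)),
           class = "mp_validation_error")
  trainSnps <- colnames(aHat)
  if (!is.null(trainSnps)) {
    missing <- setdiff(trainSnps, newGenotypes@snps)
    if (length(missing) > 0)
      mpStop(sprintf("new genotypes are missing %d training SNP(s): %s%s",
                     length(missing),
                     paste(utils::head(missing, 5), collapse = ", "),
                     if (length(missing) > 5) ", ..." else ""),
             class = "mp_validation_error")
    ord <- match(trainSnps, newGenotypes@snps)
  } else ord <- seq_len(ncol(aHat))
  Z <- newGenotypes@Z[, ord, drop = FALSE]
  W <- newGenotypes@W[, ord, drop = FALSE]
  uA <- drop(Z %*% aHat[targetPop, ])
  uD <- drop(W %*% dHat[targetPop, ])
  data.frame(id = newGenotypes@ids, uA = uA, uD = uD, total = uA + uD,
             row.names = NULL)
}

#' Cross-method equivalence check
#'
#' Compares fixed effects, marker effects (where produced) and genetic
#' values pairwise across \code{\link{SolutionSet}}s from the same
#' dataset, on the relative scale \code{|x - y| / max(|x|, 1)}. All four
#' exact strategies are equivalent estimators, so discrepancies beyond
#' numerical tolerance indicate an implementation or conditioning problem.
#'
#' @param solutions list of \code{\link{SolutionSet}}s computed on the
#'   same dataset.
#' @param tol pass tolerance on the maximum relative discrepancy
#'   (default 1e-6).
#' @return an \code{\link{EquivalenceReport}}.
#' @export
checkEquivalence <- function(solutions, tol = 1e-6) {
  stopifnot(length(solutions) >= 2,
            all(vapply(solutions, is, logical(1), "SolutionSet")))
  fps <- vapply(solutions, function(s) s@fingerprint, character(1))
  if (length(unique(fps)) > 1)
    mpStop("solutions were computed on different datasets; refusing to compare",
           class = "mp_validation_error")
  quantities <- c("beta", "aHat", "dHat", "uA", "uD")
  rows <- list()
  for (iA in seq_along(solutions)) for (iB in seq_along(solutions)) {
    if (iB <= iA) next
    sA <- solutions[[iA]]; sB <- solutions[[iB]]
    for (qt in quantities) {
      xA <- slot(sA, qt); xB <- slot(sB, qt)
      hasA <- length(xA) > 0; hasB <- length(xB) > 0
      compared <- hasA && hasB
      rows[[length(rows) + 1]] <- data.frame(
        methodA = sA@method, methodB = sB@method, quantity = qt,
        maxRelDiff = if (compared) relDiff(xA, xB) else NA_real_,
        compared = compared)
    }
  }
  tab <- do.call(rbind, rows)
  pass <- all(tab$maxRelDiff[tab$compared] <= tol)
  sizes <- lapply(solutions, function(s) s@sizes)
  names(sizes) <- vapply(solutions, function(s) s@method, character(1))
  new("EquivalenceReport", table = tab, pass = pass, tol = tol,
      sizes = sizes)
}
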