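# SNP-BLUP: Henderson's mixed-model equations parameterized in marker
# effects across populations. The LHS is assembled block by block in the
# displayed dense/sparse/zero pattern: dense Z_i'Z_i sigma_e^-2 + I g0a^ii
# diagonal blocks, sparse I g0a^ij cross-population blocks, Z_i'W_i
# additive-by-dominance couplings within population, zero across
# populations. Stored dense throughout: the sparse I-blocks destroy the
# payoff of sparse solvers here.

#' Number of random-effect equations of the SNP-BLUP system
#'
#' \code{|effects| * P * m}: with additive and dominance effects for P
#' populations, 2Pm marker equations (e.g. 6m for three populations, hence
#' 300,000 equations at a 50K SNP panel).
#'
#' @param P population count.
#' @param m SNP count.
#' @param effects character subset of \code{c("additive", "dominance")}.
#' @return integer equation count (random part only).
#' @examples
#' systemSize(3, 50000)  # 300000
#' @export
systemSize <- function(P, m, effects = c("additive", "dominance")) {
  if (length(effects) == 0)
    mpStop("at least one effect class is required", class = "mp_validation_error")
  effects <- match.arg(effects, c("additive", "dominance"), several.ok = TRUE)
  if (P < 1 || m < 1)
    mpStop("P and m must be >= 1", class = "mp_validation_error")
  as.integer(length(unique(effects)) * P * m)
}

# Layout: [beta_1..beta_P | a_1..a_P | d_1..d_P], each a_i/d_i of length m.
snpBlupLayout <- function(ds) {
  P <- nPopulations(ds); m <- nSnps(ds)
  pSizes <- vapply(ds@populations, function(p) ncol(p@X), integer(1))
  pTotal <- sum(pSizes)
  list(P = P, m = m, pSizes = pSizes, pTotal = pTotal,
       betaOffsets = cumsum(c(0, pSizes))[seq_len(P)],
       aOffset = pTotal, dOffset = pTotal + P * m,
       size = pTotal + 2L * P * m)
}

#' Assemble the SNP-BLUP mixed-model equations
#'
#' Builds the full LHS and RHS with equation order [beta; a_1..a_P;
#' d_1..d_P]. Marker blocks follow the dense/sparse/zero pattern: diagonal
#' additive block (i,i) = Z_i'Z_i / sigmaE2_i + I g0a^ii, off-diagonal
#' additive block (i,j) = I g0a^ij, additive x dominance coupling
#' Z_i'W_i / sigmaE2_i within population and zero across. Fixed-effect
#' rows carry the standard couplings X_i'X_i, X_i'Z_i, X_i'W_i scaled by
#' 1/sigmaE2_i, block-diagonal across populations.
#'
#' @param ds a \code{\link{MultiPopDataset}}.
#' @param vc a \code{\link{VarianceComponents}}.
#' @return an unsolved \code{\link{SnpBlupSystem}}.
#' @export
buildSnpBlupSystem <- function(ds, vc) {
  fails <- validateDataset(ds, vc)
  if (length(fails) > 0)
    mpStop(paste("invalid inputs:", paste(fails, collapse = "; ")),
           class = "mp_validation_error")
  lay <- snpBlupLayout(ds)
  P <- lay$P; m <- lay$m
  g0aInv <- chol2inv(mpChol(vc@g0a, "G0a"))
  g0dInv <- chol2inv(mpChol(vc@g0d, "G0d"))
  N <- lay$size
  lhs <- matrix(0, N, N)
  rhs <- numeric(N)
  aIdx <- function(i) lay$aOffset + (i - 1L) * m + seq_len(m)
  dIdx <- function(i) lay$dOffset + (i - 1L) * m + seq_len(m)
  bIdx <- function(i) lay$betaOffsets[i] + seq_len(lay$pSizes[i])
  for (i in seq_len(P)) {
    p <- ds@populations[[i]]
    w <- 1 / vc@sigmaE2[i]
    Z <- p@genotypes@Z; W <- p@genotypes@W; X <- p@X
    bi <- bIdx(i); ai <- aIdx(i); di <- dIdx(i)
    lhs[bi, bi] <- crossprod(X) * w
    lhs[bi, ai] <- crossprod(X, Z) * w; lhs[ai, bi] <- t(lhs[bi, ai])
    lhs[bi, di] <- crossprod(X, W) * w; lhs[di, bi] <- t(lhs[bi, di])
    lhs[ai, ai] <- crossprod(Z) * w
    lhs[di, di] <- crossprod(W) * w
    lhs[ai, di] <- crossprod(Z, W) * w; lhs[di, ai] <- t(lhs[ai, di])
    rhs[bi] <- crossprod(X, p@y) * w
    rhs[ai] <- crossprod(Z, p@y) * w
    rhs[di] <- crossprod(W, p@y) * w
  }
  # prior precision: sparse I g^ij blocks, added on top of the data part
  for (i in seq_len(P)) for (j in seq_len(P)) {
    idx <- cbind(aIdx(i), aIdx(j))
    lhs[idx] <- lhs[idx] + g0aInv[i, j]
    idx <- cbind(dIdx(i), dIdx(j))
    lhs[idx] <- lhs[idx] + g0dInv[i, j]
  }
  new("SnpBlupSystem", lhs = lhs, rhs = rhs, layout = lay,
      solution = numeric(0), solved = FALSE)
}

#' Solve an assembled system by Cholesky factorization
#'
#' @param system a \code{\link{SnpBlupSystem}} or \code{\link{GblupSystem}}.
#' @param ... unused.
#' @return the system with \code{solution} and the cached Cholesky factor
#'   filled in.
#' @name solveSystem
NULL

#' @rdname solveSystem
setMethod("solveSystem", "SnpBlupSystem", function(system, ...) {
  R <- mpChol(system@lhs, what = "the SNP-BLUP left-hand side",
              advice = "check that G0a and G0d are positive definite and X has full rank")
  system@solution <- drop(cholSolve(R, system@rhs))
  system@cholFactor <- R
  system@solved <- TRUE
  system
})

# shared: build a SolutionSet from marker-effect estimates
markerSolutionSet <- function(method, ds, beta, aHat, dHat, sizes) {
  P <- nPopulations(ds); m <- nSnps(ds)
  ids <- unlist(lapply(ds@populations, function(p) p@genotypes@ids))
  uA <- unlist(lapply(seq_len(P), function(i)
    drop(ds@populations[[i]]@genotypes@Z %*% aHat[i, ])))
  uD <- unlist(lapply(seq_len(P), function(i)
    drop(ds@populations[[i]]@genotypes@W %*% dHat[i, ])))
  names(uA) <- ids; names(uD) <- ids
  rownames(aHat) <- popLabels(ds); colnames(aHat) <- ds@populations[[1]]@genotypes@snps
  dimnames(dHat) <- dimnames(aHat)
  new("SolutionSet", method = method, beta = beta, aHat = aHat, dHat = dHat,
      uA = uA, uD = uD, fingerprint = datasetFingerprint(ds), sizes = sizes)
}

betaNames <- function(ds) {
  unlist(lapply(ds@populations, function(p)
    paste(p@label, colnames(p@X), sep = ":")))
}

#' Extract a SolutionSet from a solved system
#'
#' @param system a solved system object.
#' @param ds the dataset the system was built from.
#' @param vc the variance components used.
#' @param ... unused.
#' @return a \code{\link{SolutionSet}}.
#' @name solutionSet
NULL

#' @rdname solutionSet
setMethod("solutionSet", "SnpBlupSystem", function(system, ds, vc, ...) {
  if (!system@solved)
    mpStop("solve the system before extracting solutions",
           class = "mp_validation_error")
  lay <- system@layout
  P <- lay$P; m <- lay$m
  sol <- system@solution
  beta <- setNames(sol[seq_len(lay$pTotal)], betaNames(ds))
  aHat <- matrix(sol[lay$aOffset + seq_len(P * m)], P, m, byrow = TRUE)
  dHat <- matrix(sol[lay$dOffset + seq_len(P * m)], P, m, byrow = TRUE)
  sizes <- list(equations = lay$size,
                randomEquations = 2L * P * m,
                largestDense = lay$size)
  markerSolutionSet("snp_blup", ds, beta, aHat, dHat, sizes)
})

#' Marker prediction-error variances from the inverse SNP-BLUP LHS
#'
#' PEV of each marker-effect estimate is the corresponding diagonal of the
#' inverse LHS; reliability is 1 - PEV / priorVar clipped to [0, 1], with
#' priorVar the population's diagonal of G0a (G0d).
#'
#' @param system a solved \code{\link{SnpBlupSystem}}.
#' @param vc the \code{\link{VarianceComponents}} used to build it.
#' @param ... unused.
#' @return a \code{\link{PevReport}} with target \code{"markers"}.
#' @name markerPev
NULL

#' @rdname markerPev
setMethod("markerPev", "SnpBlupSystem", function(system, vc, ...) {
  if (!system@solved)
    mpStop("solve the system before requesting prediction-error variances",
           class = "mp_validation_error")
  lay <- system@layout
  P <- lay$P; m <- lay$m
  dInv <- diag(chol2inv(system@cholFactor))
  pevA <- matrix(dInv[lay$aOffset + seq_len(P * m)], P, m, byrow = TRUE)
  pevD <- matrix(dInv[lay$dOffset + seq_len(P * m)], P, m, byrow = TRUE)
  priorA <- matrix(diag(vc@g0a), P, m)
  priorD <- matrix(diag(vc@g0d), P, m)
  relA <- pmin(pmax(1 - pevA / priorA, 0), 1)
  relD <- pmin(pmax(1 - pevD / priorD, 0), 1)
  new("PevReport", target = "markers", pevA = pevA, pevD = pevD,
      relA = relA, relD = relD, priorA = priorA, priorD = priorD)
})

#' One-call SNP-BLUP solve
#'
#' @param ds a \code{\link{MultiPopDataset}}.
#' @param vc a \code{\link{VarianceComponents}}.
#' @return a \code{\link{SolutionSet}} tagged \code{snp_blup}.
#' @export
solveSnpBlup <- function(ds, vc) {
  sys <- buildSnpBlupSystem(ds, vc)
  sys <- solveSystem(sys)
  solutionSet(sys, ds, vc)
}
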