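# Individual-level GBLUP in two formulations. The standard multiple-trait
# formulation carries P additive and P dominance "trait" values per
# individual (2Pn random equations) and uses an arbitrarily scaled
# cross-population matrix G* per effect, with all scaling entering through
# the inverse marker-effect covariances. The compact formulation carries
# only each individual's own-population genetic values (2n random
# equations) and uses the inverses of the true covariance matrices G_A and
# G_D directly.

popOffsets <- function(ds) {
  as.integer(cumsum(c(0L, vapply(ds@populations, function(p)
    length(p@y), integer(1)))))
}

#' Unscaled cross-population Gram matrix G*
#'
#' Block (i, j) = \code{Z_i Z_j'} (additive) or \code{W_i W_j'}
#' (dominance); no variance scaling is applied.
#'
#' @param ds a \code{\link{MultiPopDataset}}.
#' @param flavor \code{"additive"} or \code{"dominance"}.
#' @return a \code{\link{CrossPopGramMatrix}}.
#' @export
buildGram <- function(ds, flavor = c("additive", "dominance")) {
  flavor <- match.arg(flavor)
  S <- do.call(rbind, lapply(ds@populations, function(p)
    if (flavor == "additive") p@genotypes@Z else p@genotypes@W))
  new("CrossPopGramMatrix", values = tcrossprod(S), flavor = flavor,
      offsets = popOffsets(ds))
}

#' Scaled individual-level covariance matrix G_A or G_D
#'
#' Block (i, j) = \code{Z_i sigma_a_ij Z_j'} (additive flavor; dominance
#' analogous with W and the dominance covariances). This is the covariance
#' matrix of the stacked own-population genetic values.
#'
#' @param ds a \code{\link{MultiPopDataset}}.
#' @param vc a \code{\link{VarianceComponents}}.
#' @param flavor \code{"additive"} or \code{"dominance"}.
#' @param blendEpsilon relative ridge to apply (default 0).
#' @return a \code{\link{ScaledCovMatrix}}.
#' @export
buildScaledCov <- function(ds, vc, flavor = c("additive", "dominance"),
                           blendEpsilon = 0) {
  flavor <- match.arg(flavor)
  G0 <- if (flavor == "additive") vc@g0a else vc@g0d
  P <- nPopulations(ds)
  off <- popOffsets(ds)
  n <- off[P + 1L]
  M <- matrix(0, n, n)
  cod <- lapply(ds@populations, function(p)
    if (flavor == "additive") p@genotypes@Z else p@genotypes@W)
  for (i in seq_len(P)) for (j in seq_len(i)) {
    blk <- tcrossprod(cod[[i]], cod[[j]]) * G0[i, j]
    M[(off[i] + 1):off[i + 1], (off[j] + 1):off[j + 1]] <- blk
    if (i != j)
      M[(off[j] + 1):off[j + 1], (off[i] + 1):off[i + 1]] <- t(blk)
  }
  if (blendEpsilon > 0) M <- blend(M, blendEpsilon)
  new("ScaledCovMatrix", values = M, flavor = flavor,
      blendEpsilon = blendEpsilon, offsets = off)
}

#' Blend a symmetric PSD matrix with a relative ridge
#'
#' Returns \code{M + epsilon * s * I}, where \code{s} is the mean diagonal
#' of M (1 when the mean diagonal is zero), so \code{epsilon} is
#' dimensionless. For PSD input and \code{epsilon > 0} the result is
#' positive definite with smallest eigenvalue at least \code{epsilon * s}.
#'
#' @param M symmetric matrix (or \code{\link{ScaledCovMatrix}}).
#' @param epsilon non-negative relative ridge.
#' @return matrix of the same class as the input.
#' @export
blend <- function(M, epsilon) {
  if (epsilon < 0)
    mpStop("blending epsilon must be non-negative", class = "mp_validation_error")
  if (is(M, "ScaledCovMatrix")) {
    M@values <- blend(M@values, epsilon)
    M@blendEpsilon <- M@blendEpsilon + epsilon
    return(M)
  }
  s <- mean(diag(M))
  if (s == 0) s <- 1
  M + diag(epsilon * s, nrow(M))
}

gblupBetaBlocks <- function(ds, vc, lhs, rhs, bIdx) {
  for (i in seq_len(nPopulations(ds))) {
    p <- ds@populations[[i]]
    w <- 1 / vc@sigmaE2[i]
    bi <- bIdx(i)
    lhs[bi, bi] <- crossprod(p@X) * w
    rhs[bi] <- crossprod(p@X, p@y) * w
  }
  list(lhs = lhs, rhs = rhs)
}

#' Assemble the standard multiple-trait GBLUP system
#'
#' The effect vector holds P additive "trait" copies of all n individuals
#' (trait-major: all individuals for trait 1, then trait 2, ...) followed
#' by P dominance copies. The prior precision of the additive part is
#' \code{G0a^-1 (x) (G*_A)^-1}, realized blockwise as
#' \code{G*^(ij) g0a^kl}; each record contributes data only to its own
#' population's trait copy, including the additive x dominance coupling
#' \code{I / sigmaE2_i} on matched records.
#'
#' @param ds a \code{\link{MultiPopDataset}}.
#' @param vc a \code{\link{VarianceComponents}}.
#' @param blendEpsilon relative ridge applied to G*_A and G*_D before
#'   inversion (default 0).
#' @return an unsolved \code{\link{GblupSystem}} (formulation
#'   \code{"standard"}).
#' @export
buildStandardGblup <- function(ds, vc, blendEpsilon = 0) {
  fails <- validateDataset(ds, vc)
  if (length(fails) > 0)
    mpStop(paste("invalid inputs:", paste(fails, collapse = "; ")),
           class = "mp_validation_error")
  P <- nPopulations(ds)
  off <- popOffsets(ds)
  n <- off[P + 1L]
  pSizes <- vapply(ds@populations, function(p) ncol(p@X), integer(1))
  pTotal <- sum(pSizes)
  g0aInv <- chol2inv(mpChol(vc@g0a, "G0a"))
  g0dInv <- chol2inv(mpChol(vc@g0d, "G0d"))
  GsA <- buildGram(ds, "additive")@values
  GsD <- buildGram(ds, "dominance")@values
  if (blendEpsilon > 0) {
    GsA <- blend(GsA, blendEpsilon); GsD <- blend(GsD, blendEpsilon)
  }
  GsAinv <- chol2inv(rankCheckedChol(GsA, "G*_A (additive cross-product matrix)",
    advice = "blend it with a small epsilon"))
  GsDinv <- chol2inv(rankCheckedChol(GsD, "G*_D (dominance cross-product matrix)",
    advice = "blend it with a small epsilon"))

  N <- pTotal + 2L * P * n
  lhs <- matrix(0, N, N)
  rhs <- numeric(N)
  bIdx <- function(i) cumsum(c(0L, pSizes))[i] + seq_len(pSizes[i])
  aCol <- function(k, q) pTotal + (k - 1L) * n + q        # trait k, individual q
  dCol <- function(k, q) pTotal + P * n + (k - 1L) * n + q

  # prior precisions: Kronecker products, trait-major
  aAll <- pTotal + seq_len(P * n)
  dAll <- pTotal + P * n + seq_len(P * n)
  lhs[aAll, aAll] <- kronecker(g0aInv, GsAinv)
  lhs[dAll, dAll] <- kronecker(g0dInv, GsDinv)

  # data part: each record informs its own population's trait copy
  for (i in seq_len(P)) {
    p <- ds@populations[[i]]
    w <- 1 / vc@sigmaE2[i]
    q <- (off[i] + 1):off[i + 1]
    ac <- aCol(i, q); dc <- dCol(i, q)
    idx <- cbind(ac, ac); lhs[idx] <- lhs[idx] + w
    idx <- cbind(dc, dc); lhs[idx] <- lhs[idx] + w
    idx <- cbind(ac, dc); lhs[idx] <- lhs[idx] + w
    idx <- cbind(dc, ac); lhs[idx] <- lhs[idx] + w
    bi <- bIdx(i)
    lhs[bi, ac] <- t(p@X) * w; lhs[ac, bi] <- t(lhs[bi, ac])
    lhs[bi, dc] <- t(p@X) * w; lhs[dc, bi] <- t(lhs[bi, dc])
    rhs[ac] <- p@y * w
    rhs[dc] <- p@y * w
  }
  bb <- gblupBetaBlocks(ds, vc, lhs, rhs, bIdx)
  lay <- list(P = P, n = n, pSizes = pSizes, pTotal = pTotal,
              offsets = off, size = N, randomEquations = 2L * P * n)
  new("GblupSystem", formulation = "standard", lhs = bb$lhs, rhs = bb$rhs,
      layout = lay, solution = numeric(0), solved = FALSE,
      blendEpsilon = blendEpsilon, covFactors = list())
}

#' Assemble the compact GBLUP system
#'
#' The effect vector is (u_a, u_d), each of length n: every individual's
#' own-population additive and dominance genetic value. The LHS adds the
#' inverses of the true covariance matrices G_A and G_D to diagonal and
#' additive x dominance residual couplings \code{I / sigmaE2_i}; the whole
#' random part has order 2n.
#'
#' @param ds a \code{\link{MultiPopDataset}}.
#' @param vc a \code{\link{VarianceComponents}}.
#' @param blendEpsilon relative ridge applied to G_A and G_D before
#'   inversion (default 0). Blending makes the system solvable when clones
#'   or n > m make the covariances singular, at the price of an
#'   approximate prior.
#' @return an unsolved \code{\link{GblupSystem}} (formulation
#'   \code{"compact"}).
#' @export
buildCompactGblup <- function(ds, vc, blendEpsilon = 0) {
  fails <- validateDataset(ds, vc)
  if (length(fails) > 0)
    mpStop(paste("invalid inputs:", paste(fails, collapse = "; ")),
           class = "mp_validation_error")
  P <- nPopulations(ds)
  off <- popOffsets(ds)
  n <- off[P + 1L]
  pSizes <- vapply(ds@populations, function(p) ncol(p@X), integer(1))
  pTotal <- sum(pSizes)
  GA <- buildScaledCov(ds, vc, "additive", blendEpsilon)
  GD <- buildScaledCov(ds, vc, "dominance", blendEpsilon)
  RGA <- rankCheckedChol(GA@values, "G_A (additive covariance of genetic values)",
    advice = "rank deficiency arises from clones, centering, or n > m; blend it with a small epsilon")
  RGD <- rankCheckedChol(GD@values, "G_D (dominance covariance of genetic values)",
    advice = "rank deficiency arises from clones, centering, or n > m; blend it with a small epsilon")
  GAinv <- chol2inv(RGA)
  GDinv <- chol2inv(RGD)
  wRec <- rep(1 / vc@sigmaE2, times = diff(off))
  N <- pTotal + 2L * n
  lhs <- matrix(0, N, N)
  rhs <- numeric(N)
  aAll <- pTotal + seq_len(n)
  dAll <- pTotal + n + seq_len(n)
  lhs[aAll, aAll] <- GAinv; idx <- cbind(aAll, aAll)
  lhs[idx] <- lhs[idx] + wRec
  lhs[dAll, dAll] <- GDinv; idx <- cbind(dAll, dAll)
  lhs[idx] <- lhs[idx] + wRec
  idx <- cbind(aAll, dAll); lhs[idx] <- lhs[idx] + wRec
  idx <- cbind(dAll, aAll); lhs[idx] <- lhs[idx] + wRec
  bIdx <- function(i) cumsum(c(0L, pSizes))[i] + seq_len(pSizes[i])
  y <- phenotypes(ds)
  for (i in seq_len(P)) {
    p <- ds@populations[[i]]
    w <- 1 / vc@sigmaE2[i]
    q <- (off[i] + 1):off[i + 1]
    bi <- bIdx(i)
    lhs[bi, pTotal + q] <- t(p@X) * w
    lhs[pTotal + q, bi] <- t(lhs[bi, pTotal + q])
    lhs[bi, pTotal + n + q] <- t(p@X) * w
    lhs[pTotal + n + q, bi] <- t(lhs[bi, pTotal + n + q])
  }
  rhs[aAll] <- y * wRec
  rhs[dAll] <- y * wRec
  bb <- gblupBetaBlocks(ds, vc, lhs, rhs, bIdx)
  lay <- list(P = P, n = n, pSizes = pSizes, pTotal = pTotal,
              offsets = off, size = N, randomEquations = 2L * n)
  new("GblupSystem", formulation = "compact", lhs = bb$lhs, rhs = bb$rhs,
      layout = lay, solution = numeric(0), solved = FALSE,
      blendEpsilon = blendEpsilon,
      covFactors = list(cholGA = RGA, cholGD = RGD))
}

#' @rdname solveSystem
setMethod("solveSystem", "GblupSystem", function(system, ...) {
  R <- mpChol(system@lhs,
              what = sprintf("the %s GBLUP left-hand side", system@formulation),
              advice = "the covariance matrices may be singular; consider blending")
  system@solution <- drop(cholSolve(R, system@rhs))
  system@cholFactor <- R
  system@solved <- TRUE
  system
})

#' @rdname solutionSet
setMethod("solutionSet", "GblupSystem", function(system, ds, vc, ...) {
  if (!system@solved)
    mpStop("solve the system before extracting solutions",
           class = "mp_validation_error")
  lay <- system@layout
  P <- lay$P; n <- lay$n; pTotal <- lay$pTotal
  sol <- system@solution
  beta <- setNames(sol[seq_len(pTotal)], betaNames(ds))
  ids <- unlist(lapply(ds@populations, function(p) p@genotypes@ids))
  popOf <- rep(seq_len(P), times = diff(lay$offsets))
  if (system@formulation == "standard") {
    q <- seq_len(n)
    uA <- sol[pTotal + (popOf - 1L) * n + q]
    uD <- sol[pTotal + P * n + (popOf - 1L) * n + q]
    method <- "gblup_standard"
  } else {
    uA <- sol[pTotal + seq_len(n)]
    uD <- sol[pTotal + n + seq_len(n)]
    method <- "gblup_compact"
  }
  names(uA) <- ids; names(uD) <- ids
  sizes <- list(equations = lay$size, randomEquations = lay$randomEquations,
                largestDense = lay$size)
  new("SolutionSet", method = method, beta = beta,
      aHat = matrix(0, 0, 0), dHat = matrix(0, 0, 0),
      uA = uA, uD = uD, fingerprint = datasetFingerprint(ds), sizes = sizes)
})

#' Backsolve marker effects from a solved compact GBLUP system
#'
#' Uses the selection-index identity \code{a_hat = C_au G_A^-1 u_hat_a},
#' where block (k, j) of \code{C_au} is \code{sigma_a_kj Z_j'}; dominance
#' analogous. Only exact for the unblended compact formulation: with a
#' blended prior the identity is inconsistent and the call is refused.
#'
#' @param system a solved compact \code{\link{GblupSystem}} with
#'   \code{blendEpsilon = 0}.
#' @param ds,vc the dataset and variance components used to build it.
#' @return list with \code{aHat}, \code{dHat} (P x m matrices).
#' @export
backsolveMarkers <- function(system, ds, vc) {
  if (!is(system, "GblupSystem") || system@formulation != "compact")
    mpStop("marker backsolving is only supported for the compact GBLUP formulation",
           class = "mp_validation_error")
  if (!system@solved)
    mpStop("solve the system before backsolving markers",
           class = "mp_validation_error")
  if (system@blendEpsilon > 0)
    mpStop("marker backsolving from a blended system is ill-posed; re-solve with blendEpsilon = 0",
           class = "mp_validation_error")
  lay <- system@layout
  P <- lay$P; n <- lay$n; m <- nSnps(ds)
  off <- lay$offsets
  uA <- system@solution[lay$pTotal + seq_len(n)]
  uD <- system@solution[lay$pTotal + n + seq_len(n)]
  wA <- cholSolve(system@covFactors$cholGA, uA)
  wD <- cholSolve(system@covFactors$cholGD, uD)
  aHat <- matrix(0, P, m); dHat <- matrix(0, P, m)
  for (j in seq_len(P)) {
    q <- (off[j] + 1):off[j + 1]
    Zw <- crossprod(ds@populations[[j]]@genotypes@Z, wA[q])
    Ww <- crossprod(ds@populations[[j]]@genotypes@W, wD[q])
    for (k in seq_len(P)) {
      aHat[k, ] <- aHat[k, ] + vc@g0a[k, j] * drop(Zw)
      dHat[k, ] <- dHat[k, ] + vc@g0d[k, j] * drop(Ww)
    }
  }
  rownames(aHat) <- popLabels(ds)
  colnames(aHat) <- ds@populations[[1]]@genotypes@snps
  dimnames(dHat) <- dimnames(aHat)
  list(aHat = aHat, dHat = dHat)
}

#' One-call GBLUP solves
#'
#' \code{solveGblupStandard} runs the multiple-trait formulation;
#' \code{solveGblupCompact} runs the compact formulation and, when
#' unblended, attaches backsolved marker effects to the returned
#' \code{\link{SolutionSet}}.
#'
#' @param ds a \code{\link{MultiPopDataset}}.
#' @param vc a \code{\link{VarianceComponents}}.
#' @param blendEpsilon relative ridge (default 0).
#' @param backsolve logical; backsolve marker effects (compact, unblended
#'   only).
#' @return a \code{\link{SolutionSet}}.
#' @export
solveGblupStandard <- function(ds, vc, blendEpsilon = 0) {
  sys <- buildStandardGblup(ds, vc, blendEpsilon)
  sys <- solveSystem(sys)
  solutionSet(sys, ds, vc)
}

#' @rdname solveGblupStandard
#' @export
solveGblupCompact <- function(ds, vc, blendEpsilon = 0,
                              backsolve = blendEpsilon == 0) {
  sys <- buildCompactGblup(ds, vc, blendEpsilon)
  sys <- solveSystem(sys)
  sol <- solutionSet(sys, ds, vc)
  if (backsolve) {
    bk <- backsolveMarkers(sys, ds, vc)
    sol@aHat <- bk$aHat
    sol@dHat <- bk$dHat
  }
  sol
}
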