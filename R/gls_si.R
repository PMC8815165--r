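# GLS + selection index: build the phenotypic covariance
# V = G_A + G_D + R once (order n, invertible by construction whenever the
# residual variances are positive), estimate fixed effects by GLS, then
# backsolve marker effects through their covariances with the data. This
# is the most compact of the exact strategies when m > n, and the only one
# that never needs blending.

#' Build the phenotypic covariance V = G_A + G_D + R
#'
#' @param ds a \code{\link{MultiPopDataset}}.
#' @param vc a \code{\link{VarianceComponents}}.
#' @return a \code{\link{PhenotypicCovariance}} with cached Cholesky
#'   factor.
#' @export
buildV <- function(ds, vc) {
  fails <- validateDataset(ds, vc)
  if (length(fails) > 0)
    mpStop(paste("invalid inputs:", paste(fails, collapse = "; ")),
           class = "mp_validation_error")
  off <- popOffsets(ds)
  V <- buildScaledCov(ds, vc, "additive")@values +
       buildScaledCov(ds, vc, "dominance")@values
  wRec <- rep(vc@sigmaE2, times = diff(off))
  diag(V) <- diag(V) + wRec
  R <- mpChol(V, "V = G_A + G_D + R",
              advice = "this should not happen with positive residual variances")
  new("PhenotypicCovariance", V = V, cholFactor = R)
}

# stacked block-diagonal fixed-effect design of the whole dataset
stackedDesign <- function(ds) {
  X <- blockDiag(lapply(ds@populations, function(p) p@X))
  colnames(X) <- betaNames(ds)
  X
}

#' Estimate fixed effects by generalized least squares
#'
#' \code{betaHat = (X' V^-1 X)^-1 X' V^-1 y} over the stacked dataset
#' (block-diagonal X across populations), together with the adjusted data
#' \code{yc = V^-1 (y - X betaHat)} shared by every selection-index
#' backsolve.
#'
#' @param V a \code{\link{PhenotypicCovariance}}.
#' @param ds the \code{\link{MultiPopDataset}} it was built from.
#' @return a \code{\link{GlsFit}}.
#' @export
glsFixedEffects <- function(V, ds) {
  stopifnot(is(V, "PhenotypicCovariance"))
  X <- stackedDesign(ds)
  y <- phenotypes(ds)
  if (qr(X)$rank < ncol(X))
    mpStop("stacked fixed-effect design is rank deficient",
           class = "mp_validation_error")
  R <- V@cholFactor
  ViX <- cholSolve(R, X)
  Viy <- cholSolve(R, y)
  XtViX <- crossprod(X, ViX)
  betaCov <- chol2inv(mpChol(XtViX, "X' V^-1 X"))
  betaHat <- drop(betaCov %*% crossprod(X, Viy))
  names(betaHat) <- colnames(X)
  residual <- y - drop(X %*% betaHat)
  yc <- drop(cholSolve(R, residual))
  new("GlsFit", betaHat = betaHat, betaCov = betaCov, yc = yc,
      residual = residual, vcov = V)
}

#' Backsolve marker effects by selection index
#'
#' Implements the stepwise algorithm: per population,
#' \code{v_i = Z_i' yc_i}; then \code{aHat_k = sum_j sigma_a_kj v_j}
#' (dominance analogous with W and the dominance covariances). The
#' covariance matrix C_a is never materialized; everything is done
#' population block by population block.
#'
#' @param fit a \code{\link{GlsFit}} computed on \code{ds}.
#' @param ds a \code{\link{MultiPopDataset}}.
#' @param vc a \code{\link{VarianceComponents}}.
#' @return a \code{\link{SiBacksolve}}.
#' @export
siBacksolve <- function(fit, ds, vc) {
  stopifnot(is(fit, "GlsFit"))
  off <- popOffsets(ds)
  P <- nPopulations(ds); m <- nSnps(ds)
  if (length(fit@yc) != off[P + 1L])
    mpStop("fit and dataset disagree on the number of records",
           class = "mp_validation_error")
  vA <- matrix(0, m, P); vD <- matrix(0, m, P)
  for (i in seq_len(P)) {
    q <- (off[i] + 1):off[i + 1]
    vA[, i] <- crossprod(ds@populations[[i]]@genotypes@Z, fit@yc[q])
    vD[, i] <- crossprod(ds@populations[[i]]@genotypes@W, fit@yc[q])
  }
  aHat <- t(vA %*% t(vc@g0a))   # row k = sum_j sigma_a_kj v_j
  dHat <- t(vD %*% t(vc@g0d))
  rownames(aHat) <- popLabels(ds)
  colnames(aHat) <- ds@populations[[1]]@genotypes@snps
  dimnames(dHat) <- dimnames(aHat)
  new("SiBacksolve", v = vA, aHat = aHat, dHat = dHat)
}

#' Prediction-error variances from the GLS projection
#'
#' Uses \code{PEV(t) = PriorVar(t) - C_t' P C_t} with the projection
#' \code{P = V^-1 - V^-1 X (X' V^-1 X)^-1 X' V^-1}, which accounts for the
#' estimation of the fixed effects. Targets are either the marker effects
#' (C_a columns are the covariances of the data with each population's
#' effect at each SNP) or the own-population genetic values (C_u = G_A,
#' resp. G_D).
#'
#' @param fit a \code{\link{GlsFit}}.
#' @param ds a \code{\link{MultiPopDataset}}.
#' @param vc a \code{\link{VarianceComponents}}.
#' @param target \code{"markers"} or \code{"genetic_values"}.
#' @return a \code{\link{PevReport}}.
#' @export
pevSi <- function(fit, ds, vc, target = c("markers", "genetic_values")) {
  target <- match.arg(target)
  stopifnot(is(fit, "GlsFit"))
  V <- fit@vcov
  R <- V@cholFactor
  n <- nrow(V@V)
  Vinv <- chol2inv(R)
  X <- stackedDesign(ds)
  M <- Vinv %*% X
  Pmat <- Vinv - M %*% fit@betaCov %*% t(M)
  off <- popOffsets(ds)
  P <- nPopulations(ds); m <- nSnps(ds)
  if (target == "markers") {
    pevA <- matrix(0, P, m); pevD <- matrix(0, P, m)
    for (k in seq_len(P)) {
      # C column for (pop k, all snps): rows of pop j are Z_j sigma_a_jk
      Ca <- matrix(0, n, m); Cd <- matrix(0, n, m)
      for (j in seq_len(P)) {
        q <- (off[j] + 1):off[j + 1]
        Ca[q, ] <- ds@populations[[j]]@genotypes@Z * vc@g0a[j, k]
        Cd[q, ] <- ds@populations[[j]]@genotypes@W * vc@g0d[j, k]
      }
      pevA[k, ] <- vc@g0a[k, k] - colSums(Ca * (Pmat %*% Ca))
      pevD[k, ] <- vc@g0d[k, k] - colSums(Cd * (Pmat %*% Cd))
    }
    priorA <- matrix(diag(vc@g0a), P, m)
    priorD <- matrix(diag(vc@g0d), P, m)
  } else {
    GA <- buildScaledCov(ds, vc, "additive")@values
    GD <- buildScaledCov(ds, vc, "dominance")@values
    pevA <- matrix(diag(GA) - colSums(GA * (Pmat %*% GA)), 1, n)
    pevD <- matrix(diag(GD) - colSums(GD * (Pmat %*% GD)), 1, n)
    priorA <- matrix(diag(GA), 1, n)
    priorD <- matrix(diag(GD), 1, n)
    ids <- unlist(lapply(ds@populations, function(p) p@genotypes@ids))
    colnames(pevA) <- ids; colnames(pevD) <- ids
  }
  zeroA <- priorA == 0; zeroD <- priorD == 0
  if (any(zeroA) || any(zeroD))
    warning("zero prior variance for some targets; their reliability is reported as 0")
  relA <- ifelse(zeroA, 0, pmin(pmax(1 - pevA / ifelse(zeroA, 1, priorA), 0), 1))
  relD <- ifelse(zeroD, 0, pmin(pmax(1 - pevD / ifelse(zeroD, 1, priorD), 0), 1))
  new("PevReport", target = target, pevA = pevA, pevD = pevD,
      relA = relA, relD = relD, priorA = priorA, priorD = priorD)
}

#' One-call GLS + selection-index solve
#'
#' Builds V once, fits the fixed effects by GLS, backsolves marker effects
#' by selection index, and returns everything as a
#' \code{\link{SolutionSet}}. The largest dense matrix factorized has
#' order n.
#'
#' @param ds a \code{\link{MultiPopDataset}}.
#' @param vc a \code{\link{VarianceComponents}}.
#' @return a \code{\link{SolutionSet}} tagged \code{gls_si}.
#' @export
solveGlsSi <- function(ds, vc) {
  V <- buildV(ds, vc)
  fit <- glsFixedEffects(V, ds)
  bk <- siBacksolve(fit, ds, vc)
  pTotal <- length(fit@betaHat)
  n <- length(fit@yc)
  sizes <- list(equations = pTotal + n, randomEquations = n,
                largestDense = n)
  markerSolutionSet("gls_si", ds, fit@betaHat, bk@aHat, bk@dHat, sizes)
}

## ---- matrix-free variant ----------------------------------------------

# V as an operator: x -> (G_A + G_D + R) x, population block by block,
# never forming V.
applyV <- function(ds, vc, x) {
  off <- popOffsets(ds)
  P <- nPopulations(ds)
  wRec <- rep(vc@sigmaE2, times = diff(off))
  out <- x * wRec
  tZ <- vector("list", P); tW <- vector("list", P)
  for (j in seq_len(P)) {
    q <- (off[j] + 1):off[j + 1]
    tZ[[j]] <- crossprod(ds@populations[[j]]@genotypes@Z, x[q])
    tW[[j]] <- crossprod(ds@populations[[j]]@genotypes@W, x[q])
  }
  for (i in seq_len(P)) {
    q <- (off[i] + 1):off[i + 1]
    accA <- 0; accD <- 0
    for (j in seq_len(P)) {
      accA <- accA + vc@g0a[i, j] * tZ[[j]]
      accD <- accD + vc@g0d[i, j] * tW[[j]]
    }
    out[q] <- out[q] + drop(ds@populations[[i]]@genotypes@Z %*% accA) +
                       drop(ds@populations[[i]]@genotypes@W %*% accD)
  }
  out
}

# Conjugate gradients for the symmetric PD operator A, relative-residual
# tolerance, iteration cap.
cgSolve <- function(A, b, tol = 1e-10, maxit = NULL) {
  n <- length(b)
  if (is.null(maxit)) maxit <- 10L * n
  x <- numeric(n)
  r <- b
  p <- r
  rs <- sum(r * r)
  b2 <- sqrt(sum(b * b))
  if (b2 == 0) return(x)
  for (it in seq_len(maxit)) {
    Ap <- A(p)
    alpha <- rs / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs2 <- sum(r * r)
    if (sqrt(rs2) <= tol * b2) return(x)
    p <- r + (rs2 / rs) * p
    rs <- rs2
  }
  mpStop(sprintf(
    "conjugate-gradient solve did not converge within %d iterations (relative residual %.3e > tol %.1e)",
    maxit, sqrt(rs) / b2, tol), class = "mp_numerical_error")
}

#' Inversion-free GLS + selection index
#'
#' Solves \code{V Theta = y} and \code{V M = X} by conjugate gradients
#' with V applied as an operator (three products per population block,
#' never forming the n x n matrix), then
#' \code{(X'M) betaHat = X'Theta} and \code{yc = Theta - M betaHat},
#' followed by the same selection-index backsolve as the direct path.
#'
#' @param ds a \code{\link{MultiPopDataset}}.
#' @param vc a \code{\link{VarianceComponents}}.
#' @param tol relative-residual tolerance of the iterative solves
#'   (default 1e-10).
#' @return list with \code{fit} (a \code{\link{GlsFit}} whose
#'   \code{vcov} slot holds an empty placeholder), \code{backsolve} (a
#'   \code{\link{SiBacksolve}}) and \code{solution} (a
#'   \code{\link{SolutionSet}} tagged \code{gls_si}).
#' @export
solveMatrixFree <- function(ds, vc, tol = 1e-10) {
  fails <- validateDataset(ds, vc)
  if (length(fails) > 0)
    mpStop(paste("invalid inputs:", paste(fails, collapse = "; ")),
           class = "mp_validation_error")
  X <- stackedDesign(ds)
  y <- phenotypes(ds)
  A <- function(x) applyV(ds, vc, x)
  Theta <- cgSolve(A, y, tol = tol)
  M <- apply(X, 2, function(col) cgSolve(A, col, tol = tol))
  XtM <- crossprod(X, M)
  betaCov <- chol2inv(mpChol(XtM, "X' V^-1 X"))
  betaHat <- drop(betaCov %*% crossprod(X, Theta))
  names(betaHat) <- colnames(X)
  residual <- y - drop(X %*% betaHat)
  yc <- drop(Theta - M %*% betaHat)
  emptyV <- new("PhenotypicCovariance", V = matrix(0, 0, 0),
                cholFactor = matrix(0, 0, 0))
  fit <- new("GlsFit", betaHat = betaHat, betaCov = betaCov, yc = yc,
             residual = residual, vcov = emptyV)
  bk <- siBacksolve(fit, ds, vc)
  pTotal <- length(betaHat)
  n <- length(y)
  sizes <- list(equations = pTotal + n, randomEquations = n,
                largestDense = pTotal)  # only X'M is ever factorized
  sol <- markerSolutionSet("gls_si", ds, betaHat, bk@aHat, bk@dHat, sizes)
  list(fit = fit, backsolve = bk, solution = sol)
}
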