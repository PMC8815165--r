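#' @import methods
#' @importFrom stats rnorm rbinom rbeta setNames coef lm var cor sd
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' GenotypeMatrix: SNP dosages with additive and dominance codings
#'
#' Holds the 0/1/2 reference-allele dosages of one population together with
#' the two codings used throughout the package: the additive coding
#' \code{Z = dosage - 1} (values -1/0/1) and the dominance (heterozygote
#' indicator) coding \code{W} (1 at heterozygous genotypes, 0 elsewhere).
#' Column-constant shifts of \code{Z} and \code{W} around these canonical
#' codings are tolerated by the validity method, so that per-population
#' column centering (see \code{\link{encodeGenotypes}}) produces a valid
#' object.
#'
#' @slot ids character, individual identifiers (rows).
#' @slot snps character, SNP names (columns).
#' @slot dosage integer matrix, counts of the reference allele in 0/1/2.
#' @slot Z numeric matrix, additive coding.
#' @slot W numeric matrix, dominance coding.
#' @slot centered logical, whether per-population column centering was
#'   applied to \code{Z} and \code{W}.
#' @export
setClass("GenotypeMatrix",
  representation(ids = "character", snps = "character",
                 dosage = "matrix", Z = "matrix", W = "matrix",
                 centered = "logical"),
  prototype(centered = FALSE))

setValidity("GenotypeMatrix", function(object) {
  msgs <- character(0)
  d <- object@dosage
  if (!all(dim(object@Z) == dim(d)) || !all(dim(object@W) == dim(d)))
    msgs <- c(msgs, "Z, W and dosage must have identical dimensions")
  if (nrow(d) != length(object@ids))
    msgs <- c(msgs, "length(ids) must equal nrow(dosage)")
  if (ncol(d) != length(object@snps))
    msgs <- c(msgs, "length(snps) must equal ncol(dosage)")
  bad <- which(!(d %in% c(0, 1, 2)) | is.na(d))
  if (length(bad) > 0) {
    rc <- arrayInd(bad[1], dim(d))
    msgs <- c(msgs, sprintf(
      "dosage values must be 0, 1 or 2 with no missing entries (first offence: row %d ['%s'], column %d ['%s'])",
      rc[1], object@ids[rc[1]], rc[2], object@snps[rc[2]]))
  }
  if (length(msgs) == 0 && nrow(d) > 0 && ncol(d) > 0) {
    # Z/W may be shifted by a per-column constant (centering); the shift
    # must be constant within each column.
    devZ <- object@Z - (d - 1)
    devW <- object@W - (d == 1)
    rngZ <- apply(devZ, 2, function(x) diff(range(x)))
    rngW <- apply(devW, 2, function(x) diff(range(x)))
    if (any(rngZ > 1e-10) || any(rngW > 1e-10))
      msgs <- c(msgs,
        "Z (W) must equal dosage - 1 (heterozygote indicator) up to a per-column constant shift")
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' PopulationData: one population's phenotypes, design and genotypes
#'
#' @slot label character population label.
#' @slot y numeric phenotype vector (trait units).
#' @slot X numeric fixed-effect design matrix; must contain an all-ones
#'   intercept column and be of full column rank.
#' @slot genotypes a \code{GenotypeMatrix}, rows aligned with \code{y}.
#' @export
setClass("PopulationData",
  representation(label = "character", y = "numeric", X = "matrix",
                 genotypes = "GenotypeMatrix"))

setValidity("PopulationData", function(object) {
  msgs <- character(0)
  n <- length(object@y)
  if (nrow(object@X) != n)
    msgs <- c(msgs, "nrow(X) must equal length(y)")
  if (nrow(object@genotypes@dosage) != n)
    msgs <- c(msgs, "genotype rows must equal length(y)")
  if (n > 0) {
    if (!any(apply(object@X, 2, function(x) all(x == 1))))
      msgs <- c(msgs, "X must contain an all-ones intercept column")
    if (qr(object@X)$rank < ncol(object@X))
      msgs <- c(msgs, "X must have full column rank")
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' MultiPopDataset: aligned data for P populations
#'
#' @slot populations list of \code{PopulationData}, one per population, in
#'   evaluation order (population index 1..P).
#' @export
setClass("MultiPopDataset", representation(populations = "list"))

setValidity("MultiPopDataset", function(object) {
  msgs <- character(0)
  pops <- object@populations
  if (length(pops) < 1)
    msgs <- c(msgs, "at least one population is required")
  if (!all(vapply(pops, is, logical(1), "PopulationData")))
    return("all elements of 'populations' must be PopulationData objects")
  ms <- vapply(pops, function(p) ncol(p@genotypes@dosage), integer(1))
  if (length(unique(ms)) > 1)
    msgs <- c(msgs, "all populations must share the same SNP count m")
  snpsets <- lapply(pops, function(p) p@genotypes@snps)
  if (length(unique(snpsets)) > 1)
    msgs <- c(msgs, "all populations must share the same SNP names in the same order")
  ids <- unlist(lapply(pops, function(p) p@genotypes@ids))
  if (anyDuplicated(ids))
    msgs <- c(msgs, sprintf("individual ids must be unique across populations (duplicated: %s)",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  labels <- vapply(pops, function(p) p@label, character(1))
  if (anyDuplicated(labels))
    msgs <- c(msgs, "population labels must be unique")
  if (length(msgs) == 0) TRUE else msgs
})

#' VarianceComponents: across-population marker-effect covariances
#'
#' \code{g0a} and \code{g0d} are the P x P covariance matrices of,
#' respectively, additive and dominance effects of one SNP across the P
#' populations; \code{sigmaE2} holds the per-population residual variances.
#' Symmetry and dimensions are enforced at construction; positive
#' definiteness is checked where inverses are required (and reported by
#' \code{\link{validateDataset}}), so that deliberately degenerate inputs
#' can still be represented and diagnosed.
#'
#' @slot g0a numeric P x P symmetric matrix (additive, effect-variance units).
#' @slot g0d numeric P x P symmetric matrix (dominance).
#' @slot sigmaE2 numeric length-P vector of residual variances.
#' @export
setClass("VarianceComponents",
  representation(g0a = "matrix", g0d = "matrix", sigmaE2 = "numeric"))

setValidity("VarianceComponents", function(object) {
  msgs <- character(0)
  P <- length(object@sigmaE2)
  for (nm in c("g0a", "g0d")) {
    M <- slot(object, nm)
    if (!all(dim(M) == c(P, P)))
      msgs <- c(msgs, sprintf("%s must be %d x %d to match sigmaE2", nm, P, P))
    else if (max(abs(M - t(M))) > 1e-8 * max(abs(M), 1))
      msgs <- c(msgs, sprintf("%s must be symmetric", nm))
  }
  if (any(!is.finite(object@sigmaE2)) || any(object@sigmaE2 <= 0))
    msgs <- c(msgs, "sigmaE2 must be strictly positive")
  if (length(msgs) == 0) TRUE else msgs
})

#' SolutionSet: estimates from one solving strategy
#'
#' @slot method one of \code{"snp_blup"}, \code{"gblup_standard"},
#'   \code{"gblup_compact"}, \code{"gls_si"}.
#' @slot beta named numeric vector of fixed-effect estimates, concatenated
#'   population by population (names \code{<pop>:<term>}).
#' @slot aHat P x m matrix of additive marker-effect estimates (0 x 0 when
#'   the method does not produce marker effects).
#' @slot dHat P x m matrix of dominance marker-effect estimates.
#' @slot uA named numeric length-n vector of own-population additive
#'   genetic values, \code{Z_i a_i} rowwise.
#' @slot uD named numeric length-n vector of dominance genetic values.
#' @slot fingerprint character checksum of the dataset the solution was
#'   computed from (guards \code{\link{checkEquivalence}}).
#' @slot sizes list of system-size metadata: \code{equations} (full system
#'   order), \code{randomEquations}, and \code{largestDense} (order of the
#'   largest dense matrix factorized by the strategy).
#' @export
setClass("SolutionSet",
  representation(method = "character", beta = "numeric",
                 aHat = "matrix", dHat = "matrix",
                 uA = "numeric", uD = "numeric",
                 fingerprint = "character", sizes = "list"))

setValidity("SolutionSet", function(object) {
  ok <- object@method %in% c("snp_blup", "gblup_standard", "gblup_compact", "gls_si")
  if (!ok) return("unknown method tag")
  if (length(object@uA) != length(object@uD))
    return("uA and uD must have equal length")
  TRUE
})

#' SnpBlupSystem: Henderson's MME in marker effects
#'
#' Equation order is fixed as [beta; a_1..a_P; d_1..d_P] so that diagonal
#' elements of the inverse LHS map unambiguously to effects.
#'
#' @slot lhs symmetric coefficient matrix of order p_total + 2Pm.
#' @slot rhs right-hand side.
#' @slot layout list of block offsets (\code{betaOffsets}, \code{aOffset},
#'   \code{dOffset}, \code{P}, \code{m}, \code{pTotal}).
#' @slot solution numeric, filled by \code{\link{solveSystem}}.
#' @slot cholFactor upper-triangular Cholesky factor, cached after solve.
#' @slot solved logical.
#' @export
setClass("SnpBlupSystem",
  representation(lhs = "matrix", rhs = "numeric", layout = "list",
                 solution = "numeric", cholFactor = "matrixOrNULL",
                 solved = "logical"),
  prototype(solved = FALSE, cholFactor = NULL))

#' GblupSystem: individual-level MME (standard or compact formulation)
#'
#' @slot formulation \code{"standard"} (multiple-trait, 2Pn random
#'   equations) or \code{"compact"} (2n random equations).
#' @slot lhs,rhs,layout,solution,cholFactor,solved as for
#'   \code{SnpBlupSystem}.
#' @slot blendEpsilon relative ridge applied to the covariance matrices
#'   before inversion (0 = none).
#' @slot covFactors list of cached Cholesky factors of the (blended)
#'   covariance matrices, used by \code{\link{backsolveMarkers}}.
#' @export
setClass("GblupSystem",
  representation(formulation = "character", lhs = "matrix", rhs = "numeric",
                 layout = "list", solution = "numeric",
                 cholFactor = "matrixOrNULL", solved = "logical",
                 blendEpsilon = "numeric", covFactors = "list"),
  prototype(solved = FALSE, cholFactor = NULL, blendEpsilon = 0))

#' CrossPopGramMatrix: unscaled cross-population coding cross products
#'
#' Block (i, j) is \code{Z_i Z_j'} (additive flavor) or \code{W_i W_j'}
#' (dominance flavor); the whole matrix is \code{S S'} for the row-stacked
#' coding matrix S, hence symmetric PSD with rank at most min(n, m). The
#' scale is arbitrary: covariances between individuals only arise after
#' multiplication by the SNP-effect (co)variances, so these values are not
#' "relationships".
#'
#' @slot values the n x n matrix.
#' @slot flavor \code{"additive"} or \code{"dominance"}.
#' @slot offsets integer vector of population block offsets (length P + 1).
#' @export
setClass("CrossPopGramMatrix",
  representation(values = "matrix", flavor = "character",
                 offsets = "integer"))

#' ScaledCovMatrix: true individual-level covariance of genetic values
#'
#' Block (i, j) is \code{Z_i sigma_a_ij Z_j'} (additive) or
#' \code{W_i sigma_d_ij W_j'} (dominance): the covariance matrix G_A (G_D)
#' of the stacked genetic values. PSD by construction; positive definite
#' only when full rank, which blending with a relative ridge can enforce.
#'
#' @slot values the n x n matrix.
#' @slot flavor \code{"additive"} or \code{"dominance"}.
#' @slot blendEpsilon relative ridge already applied (0 = none).
#' @slot offsets integer vector of population block offsets (length P + 1).
#' @export
setClass("ScaledCovMatrix",
  representation(values = "matrix", flavor = "character",
                 blendEpsilon = "numeric", offsets = "integer"),
  prototype(blendEpsilon = 0))

#' PhenotypicCovariance: V = G_A + G_D + R and its Cholesky factor
#'
#' @slot V the n x n phenotypic covariance matrix.
#' @slot cholFactor upper-triangular Cholesky factor of V.
#' @export
setClass("PhenotypicCovariance",
  representation(V = "matrix", cholFactor = "matrix"))

#' GlsFit: generalized least squares fit of the fixed effects
#'
#' @slot betaHat named fixed-effect estimates.
#' @slot betaCov (X' V^-1 X)^-1.
#' @slot yc adjusted data V^-1 (y - X betaHat), the vector all
#'   selection-index backsolves share.
#' @slot residual y - X betaHat.
#' @slot vcov the \code{PhenotypicCovariance} the fit was computed with.
#' @export
setClass("GlsFit",
  representation(betaHat = "numeric", betaCov = "matrix", yc = "numeric",
                 residual = "numeric", vcov = "PhenotypicCovariance"))

#' SiBacksolve: marker effects recovered by selection index
#'
#' @slot v m x P matrix of per-population cross products Z_i' y^c_i
#'   (column i = population i).
#' @slot aHat,dHat P x m marker-effect estimates.
#' @export
setClass("SiBacksolve",
  representation(v = "matrix", aHat = "matrix", dHat = "matrix"))

#' PevReport: prediction-error variances and reliabilities
#'
#' @slot target \code{"markers"} or \code{"genetic_values"}.
#' @slot pevA,pevD prediction-error variances (P x m matrices for markers;
#'   1 x n for genetic values).
#' @slot relA,relD reliabilities 1 - PEV/priorVar, clipped to [0, 1].
#' @slot priorA,priorD prior variances on the same layout.
#' @export
setClass("PevReport",
  representation(target = "character", pevA = "matrix", pevD = "matrix",
                 relA = "matrix", relD = "matrix",
                 priorA = "matrix", priorD = "matrix"))

#' SimulationConfig: parameters of the multi-population simulator
#'
#' @slot P integer population count.
#' @slot nPerPop integer vector of record counts per population.
#' @slot m integer SNP count.
#' @slot fst divergence of population allele frequencies in [0, 1);
#'   0 means all populations share the base frequencies.
#' @slot vc \code{VarianceComponents} used both to draw effects and to
#'   solve.
#' @slot betaTrue P x 2 matrix of true fixed effects per population
#'   (column 1 = mean, column 2 = inbreeding-depression slope).
#' @slot seed integer master seed; all randomness derives from it.
#' @slot crossbredPairs list of integer pairs (sirePop, damPop); population
#'   k is crossbred when \code{crossbredPairs[[k]]} is non-NULL.
#' @export
setClass("SimulationConfig",
  representation(P = "integer", nPerPop = "integer", m = "integer",
                 fst = "numeric", vc = "VarianceComponents",
                 betaTrue = "matrix", seed = "integer",
                 crossbredPairs = "list"))

setValidity("SimulationConfig", function(object) {
  msgs <- character(0)
  if (object@P < 1L) msgs <- c(msgs, "P must be >= 1")
  if (length(object@nPerPop) != object@P || any(object@nPerPop < 1L))
    msgs <- c(msgs, "nPerPop must hold one positive count per population")
  if (object@m < 1L) msgs <- c(msgs, "m must be >= 1")
  if (object@fst < 0 || object@fst >= 1)
    msgs <- c(msgs, "fst must lie in [0, 1)")
  if (length(object@vc@sigmaE2) != object@P)
    msgs <- c(msgs, "variance components must have dimension P")
  if (!all(dim(object@betaTrue) == c(object@P, 2)))
    msgs <- c(msgs, "betaTrue must be P x 2 (mean, inbreeding slope)")
  if (length(object@crossbredPairs) != object@P)
    msgs <- c(msgs, "crossbredPairs must have length P (NULL entries for purebreds)")
  if (length(msgs) == 0) TRUE else msgs
})

#' EquivalenceReport: pairwise discrepancies between solving strategies
#'
#' @slot table data.frame with columns methodA, methodB, quantity,
#'   maxRelDiff, compared.
#' @slot pass logical, TRUE when every compared discrepancy is <= tol.
#' @slot tol tolerance used.
#' @slot sizes named list of system-size metadata per method.
#' @export
setClass("EquivalenceReport",
  representation(table = "data.frame", pass = "logical", tol = "numeric",
                 sizes = "list"))
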