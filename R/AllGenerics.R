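#' @rdname accessors
#' @export
setGeneric("nPopulations", function(x) standardGeneric("nPopulations"))

#' @rdname accessors
#' @export
setGeneric("nRecords", function(x) standardGeneric("nRecords"))

#' @rdname accessors
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname accessors
#' @export
setGeneric("popLabels", function(x) standardGeneric("popLabels"))

#' @rdname accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname accessors
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @rdname accessors
#' @export
setGeneric("addCoding", function(x) standardGeneric("addCoding"))

#' @rdname accessors
#' @export
setGeneric("domCoding", function(x) standardGeneric("domCoding"))

#' @rdname accessors
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname solveSystem
#' @export
setGeneric("solveSystem", function(system, ...) standardGeneric("solveSystem"))

#' @rdname solutionSet
#' @export
setGeneric("solutionSet", function(system, ds, vc, ...) standardGeneric("solutionSet"))

#' @rdname markerPev
#' @export
setGeneric("markerPev", function(system, vc, ...) standardGeneric("markerPev"))

## ---- accessor methods -------------------------------------------------

#' Accessors for mpblup data classes
#'
#' \code{nPopulations}, \code{nRecords}, \code{nSnps}, \code{popLabels},
#' \code{populations}, \code{phenotypes}, \code{dosage}, \code{addCoding}
#' and \code{domCoding} extract the obvious components of
#' \code{\link{MultiPopDataset}}, \code{\link{PopulationData}} and
#' \code{\link{GenotypeMatrix}} objects without touching slots directly.
#'
#' @param x the object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
setMethod("nPopulations", "MultiPopDataset", function(x) length(x@populations))

#' @rdname accessors
setMethod("nRecords", "MultiPopDataset",
  function(x) sum(vapply(x@populations, function(p) length(p@y), integer(1))))

#' @rdname accessors
setMethod("nSnps", "MultiPopDataset",
  function(x) ncol(x@populations[[1]]@genotypes@dosage))

#' @rdname accessors
setMethod("nSnps", "GenotypeMatrix", function(x) ncol(x@dosage))

#' @rdname accessors
setMethod("nRecords", "GenotypeMatrix", function(x) nrow(x@dosage))

#' @rdname accessors
setMethod("popLabels", "MultiPopDataset",
  function(x) vapply(x@populations, function(p) p@label, character(1)))

#' @rdname accessors
setMethod("populations", "MultiPopDataset", function(x) x@populations)

#' @rdname accessors
setMethod("phenotypes", "MultiPopDataset",
  function(x) unlist(lapply(x@populations, function(p) p@y)))

#' @rdname accessors
setMethod("phenotypes", "PopulationData", function(x) x@y)

#' @rdname accessors
setMethod("addCoding", "GenotypeMatrix", function(x) x@Z)

#' @rdname accessors
setMethod("domCoding", "GenotypeMatrix", function(x) x@W)

#' @rdname accessors
setMethod("dosage", "GenotypeMatrix", function(x) x@dosage)

#' @rdname accessors
setMethod("addCoding", "PopulationData", function(x) x@genotypes@Z)

#' @rdname accessors
setMethod("domCoding", "PopulationData", function(x) x@genotypes@W)

## ---- show methods -----------------------------------------------------

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d individuals x %d SNPs%s\n",
              nrow(object@dosage), ncol(object@dosage),
              if (isTRUE(object@centered)) " (column-centered codings)" else ""))
})

setMethod("show", "MultiPopDataset", function(object) {
  ns <- vapply(object@populations, function(p) length(p@y), integer(1))
  cat(sprintf("MultiPopDataset: %d population(s), n = %d records, m = %d SNPs\n",
              length(ns), sum(ns), nSnps(object)))
  for (i in seq_along(ns))
    cat(sprintf("  [%d] %-12s n_i = %d, p_i = %d fixed effects\n",
                i, object@populations[[i]]@label, ns[i],
                ncol(object@populations[[i]]@X)))
})

setMethod("show", "VarianceComponents", function(object) {
  P <- length(object@sigmaE2)
  cat(sprintf("VarianceComponents for P = %d populations\n", P))
  cat("  additive  diag(G0a):", signif(diag(object@g0a), 4), "\n")
  cat("  dominance diag(G0d):", signif(diag(object@g0d), 4), "\n")
  cat("  residual  sigmaE2  :", signif(object@sigmaE2, 4), "\n")
})

setMethod("show", "SolutionSet", function(object) {
  cat(sprintf("SolutionSet [%s]: %d fixed effects, %s, %d genetic values\n",
              object@method, length(object@beta),
              if (nrow(object@aHat) > 0)
                sprintf("%d x %d marker effects", nrow(object@aHat), ncol(object@aHat))
              else "no marker effects",
              length(object@uA)))
  cat(sprintf("  system: %d equations (%d random), largest dense matrix order %d\n",
              object@sizes$equations, object@sizes$randomEquations,
              object@sizes$largestDense))
})

setMethod("show", "SnpBlupSystem", function(object) {
  cat(sprintf("SnpBlupSystem: %d equations (%d marker equations), %s\n",
              nrow(object@lhs), 2L * object@layout$P * object@layout$m,
              if (object@solved) "solved" else "not solved"))
})

setMethod("show", "GblupSystem", function(object) {
  cat(sprintf("GblupSystem (%s): %d equations, blend epsilon = %g, %s\n",
              object@formulation, nrow(object@lhs), object@blendEpsilon,
              if (object@solved) "solved" else "not solved"))
})

setMethod("show", "PhenotypicCovariance", function(object) {
  cat(sprintf("PhenotypicCovariance: V of order %d (Cholesky cached)\n",
              nrow(object@V)))
})

setMethod("show", "GlsFit", function(object) {
  cat(sprintf("GlsFit: %d fixed effects over %d records\n",
              length(object@betaHat), length(object@yc)))
})

setMethod("show", "PevReport", function(object) {
  cat(sprintf("PevReport (%s): mean reliability additive %.3f, dominance %.3f\n",
              object@target, mean(object@relA), mean(object@relD)))
})

setMethod("show", "EquivalenceReport", function(object) {
  cat(sprintf("EquivalenceReport: %s at tol %g\n",
              if (object@pass) "PASS" else "FAIL", object@tol))
  print(object@table)
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: P = %d, n = (%s), m = %d, fst = %g, seed = %d\n",
              object@P, paste(object@nPerPop, collapse = ", "), object@m,
              object@fst, object@seed))
})
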