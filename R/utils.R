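# Internal helpers shared across solvers.

# Classed errors so the CLI can map failures to exit codes:
#   mp_validation_error -> 2, mp_numerical_error -> 3, mp_equivalence_error -> 4
mpStop <- function(msg, class = "mp_error", call. = FALSE) {
  stop(structure(class = c(class, "mp_error", "error", "condition"),
                 list(message = msg, call = if (call.) sys.call(-1) else NULL)))
}

# Cholesky that fails with a classed, actionable error.
mpChol <- function(M, what = "matrix", advice = NULL) {
  R <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(R))
    mpStop(paste0("Cholesky factorization of ", what, " failed (matrix is ",
                  "singular or not positive definite)",
                  if (!is.null(advice)) paste0("; ", advice) else ""),
           class = "mp_numerical_error")
  R
}

# Solve M x = b given the upper Cholesky factor of M.
cholSolve <- function(R, b) backsolve(R, backsolve(R, b, transpose = TRUE))

# Cholesky with an explicit numerical-rank check: exact singularity (e.g.
# duplicated genotype rows) can slip through chol() by rounding, so the
# smallest eigenvalue is tested against 1e-10 x mean diagonal first.
rankCheckedChol <- function(M, what = "matrix", advice = NULL) {
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10 * mean(diag(M)))
    mpStop(paste0(what, " is numerically singular (smallest eigenvalue ",
                  format(min(ev), digits = 3), " below 1e-10 of the mean diagonal)",
                  if (!is.null(advice)) paste0("; ", advice) else ""),
           class = "mp_numerical_error")
  mpChol(M, what = what, advice = advice)
}

isPosDef <- function(M) {
  !is.null(tryCatch(chol(M), error = function(e) NULL))
}

# Relative discrepancy on the scale max(|x|, 1), elementwise max.
relDiff <- function(x, y) {
  if (length(x) == 0 && length(y) == 0) return(0)
  max(abs(x - y) / pmax(abs(x), 1))
}

# Block-diagonal stack of a list of matrices.
blockDiag <- function(mats) {
  nr <- vapply(mats, nrow, integer(1))
  nc <- vapply(mats, ncol, integer(1))
  out <- matrix(0, sum(nr), sum(nc))
  r0 <- c(0, cumsum(nr)); c0 <- c(0, cumsum(nc))
  for (i in seq_along(mats))
    out[(r0[i] + 1):r0[i + 1], (c0[i] + 1):c0[i + 1]] <- mats[[i]]
  out
}

# Cheap order-insensitive checksum of the data entering a solve, used to
# refuse equivalence comparisons across different datasets.
datasetFingerprint <- function(ds) {
  parts <- vapply(ds@populations, function(p) {
    sprintf("%s:%d:%.10e:%.10e:%.10e", p@label, length(p@y),
            sum(p@y), sum(p@genotypes@Z * seq_len(ncol(p@genotypes@Z))[col(p@genotypes@Z)]),
            sum(p@X))
  }, character(1))
  paste(parts, collapse = "|")
}

# Deterministic per-stage seeds derived from one master seed, so that e.g.
# enlarging m does not reshuffle the phenotype noise stream.
stageSeed <- function(seed, stage) {
  offsets <- c(freq = 11L, geno = 23L, effects_a = 37L, effects_d = 41L,
               noise = 53L, redraw = 67L)
  as.integer((as.numeric(seed) * 48271 + offsets[[stage]] * 9973) %% 2147483629)
}
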