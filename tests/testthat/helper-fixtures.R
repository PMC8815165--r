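# Shared fixtures (memoized: presets are deterministic, so building each
# once per run is safe) and independent oracles.

.fixtureCache <- new.env(parent = emptyenv())

getFixture <- function(name) {
  key <- gsub("-", "_", name)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- makeFixture(name)
  .fixtureCache[[key]]
}

# Brute-force normal-equations oracle for the SNP-BLUP system:
# T' R^-1 T + blockdiag(0, G0a^-1 (x) I_m, G0d^-1 (x) I_m) with
# T = [blockdiag(X_i) | blockdiag(Z_i) | blockdiag(W_i)].
oracleSnpBlup <- function(ds, vc) {
  pops <- populations(ds)
  bdiag <- function(mats) {
    nr <- vapply(mats, nrow, integer(1)); nc <- vapply(mats, ncol, integer(1))
    out <- matrix(0, sum(nr), sum(nc))
    r0 <- c(0, cumsum(nr)); c0 <- c(0, cumsum(nc))
    for (i in seq_along(mats))
      out[(r0[i] + 1):r0[i + 1], (c0[i] + 1):c0[i + 1]] <- mats[[i]]
    out
  }
  Tmat <- cbind(bdiag(lapply(pops, function(p) p@X)),
                bdiag(lapply(pops, function(p) addCoding(p))),
                bdiag(lapply(pops, function(p) domCoding(p))))
  rinv <- rep(1 / vc@sigmaE2,
              times = vapply(pops, function(p) length(p@y), integer(1)))
  m <- nSnps(ds)
  pTotal <- sum(vapply(pops, function(p) ncol(p@X), integer(1)))
  prior <- matrix(0, ncol(Tmat), ncol(Tmat))
  idx <- pTotal + seq_len(nPopulations(ds) * m)
  prior[idx, idx] <- kronecker(solve(vc@g0a), diag(m))
  idx2 <- max(idx) + seq_len(nPopulations(ds) * m)
  prior[idx2, idx2] <- kronecker(solve(vc@g0d), diag(m))
  y <- phenotypes(ds)
  list(lhs = crossprod(Tmat, Tmat * rinv) + prior,
       rhs = drop(crossprod(Tmat, y * rinv)))
}

# Independent assembly of G_A (or G_D) via the Kronecker route:
# blockdiag(Z_i) (G0 (x) I_m) blockdiag(Z_i)'.
oracleScaledCov <- function(ds, vc, flavor) {
  pops <- populations(ds)
  cod <- lapply(pops, function(p)
    if (flavor == "additive") addCoding(p) else domCoding(p))
  G0 <- if (flavor == "additive") vc@g0a else vc@g0d
  m <- nSnps(ds)
  nr <- vapply(cod, nrow, integer(1))
  S <- matrix(0, sum(nr), length(pops) * m)
  r0 <- c(0, cumsum(nr))
  for (i in seq_along(cod))
    S[(r0[i] + 1):r0[i + 1], (i - 1) * m + seq_len(m)] <- cod[[i]]
  S %*% kronecker(G0, diag(m)) %*% t(S)
}

# fitted values X_i beta_i + u_a + u_d per record, in dataset order
fittedValues <- function(sol, ds) {
  off <- 0
  out <- numeric(0)
  for (p in populations(ds)) {
    b <- sol@beta[(off + 1):(off + ncol(p@X))]
    off <- off + ncol(p@X)
    out <- c(out, drop(p@X %*% b) + sol@uA[p@genotypes@ids] +
               sol@uD[p@genotypes@ids])
  }
  out
}

# true own-population additive genetic values of a simulation bundle
trueOwnU <- function(bundle) {
  unlist(lapply(seq_len(nPopulations(bundle$ds)), function(i)
    drop(addCoding(populations(bundle$ds)[[i]]) %*% bundle$truth$aTrue[i, ])))
}

# re-encode every population with column-centered codings, keeping y and X
centerDataset <- function(ds) {
  multiPopDataset(lapply(populations(ds), function(p)
    populationData(p@label, p@y,
      encodeGenotypes(dosage(p@genotypes), ids = p@genotypes@ids,
                      snps = p@genotypes@snps, center = TRUE),
      X = p@X)))
}

maxRelDiff <- function(x, y) max(abs(x - y) / pmax(abs(x), 1))
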