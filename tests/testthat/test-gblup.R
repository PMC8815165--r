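test_that("the Gram matrix is the raw cross product of stacked codings", {
  # dosage chosen so the additive coding is the 2 x 2 identity
  g <- encodeGenotypes(rbind(c(2, 1), c(1, 2)))
  ds <- multiPopDataset(list(populationData("p1", c(0, 0), g,
    X = matrix(1, 2, 1, dimnames = list(NULL, "intercept")))))
  expect_equal(unname(buildGram(ds, "additive")@values), diag(2))
  # oracle: stack the codings and take the product directly
  fx <- getFixture("tiny-2pop")
  S <- do.call(rbind, lapply(populations(fx$ds), addCoding))
  expect_equal(buildGram(fx$ds, "additive")@values, S %*% t(S),
               tolerance = 1e-12)
  # duplicated genotype rows give duplicated Gram rows
  sc <- getFixture("singular-clones")
  Gs <- buildGram(sc$ds, "additive")@values
  expect_equal(Gs[1, ], Gs[2, ], tolerance = 1e-12)
})

test_that("the scaled covariance matrices carry the marker-effect variances blockwise", {
  # single population, single SNP, Z = (1, -1)': G_A = sigma_a^2 Z Z'
  g <- encodeGenotypes(matrix(c(2L, 0L), 2, 1))
  ds <- multiPopDataset(list(populationData("p1", c(0, 0), g,
    X = matrix(1, 2, 1, dimnames = list(NULL, "intercept")))))
  vc <- varianceComponents(matrix(2), matrix(1), 1)
  GA <- buildScaledCov(ds, vc, "additive")@values
  expect_equal(unname(GA), rbind(c(2, -2), c(-2, 2)))
  # zero cross-population covariance zeroes the off-diagonal blocks
  fx <- getFixture("tiny-2pop")
  vc0 <- varianceComponents(diag(diag(fx$vc@g0a)), fx$vc@g0d, fx$vc@sigmaE2)
  GA0 <- buildScaledCov(fx$ds, vc0, "additive")
  n1 <- length(populations(fx$ds)[[1]]@y)
  expect_equal(max(abs(GA0@values[seq_len(n1), -seq_len(n1)])), 0)
  # Kronecker-route oracle
  eq <- getFixture("equiv-3pop")
  expect_equal(buildScaledCov(eq$ds, eq$vc, "additive")@values,
               oracleScaledCov(eq$ds, eq$vc, "additive"), tolerance = 1e-12)
  expect_equal(buildScaledCov(eq$ds, eq$vc, "dominance")@values,
               oracleScaledCov(eq$ds, eq$vc, "dominance"), tolerance = 1e-12)
})

test_that("blending adds a relative ridge and restores positive definiteness", {
  expect_equal(blend(matrix(0, 2, 2), 0.01), diag(0.01, 2))
  expect_equal(blend(diag(2), 0.01), diag(1.01, 2))
  expect_error(blend(diag(2), -1e-3), class = "mp_validation_error")
  sc <- getFixture("singular-clones")
  GA <- buildScaledCov(sc$ds, sc$vc, "additive")@values
  evRaw <- eigen(GA, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(min(evRaw), 1e-10 * mean(diag(GA)))   # numerically singular
  blended <- blend(GA, 1e-6)
  expect_silent(chol(blended))
  # monotonicity: smallest eigenvalue >= epsilon * mean diagonal
  evMin <- min(eigen(blended, symmetric = TRUE, only.values = TRUE)$values)
  expect_gte(evMin, 1e-6 * mean(diag(GA)) * (1 - 1e-8))
})

test_that("the standard formulation reproduces the displayed block pattern", {
  fx <- getFixture("equiv-3pop")
  sys <- buildStandardGblup(fx$ds, fx$vc)
  lay <- sys@layout
  expect_equal(lay$randomEquations, 2L * 3L * nRecords(fx$ds))
  GsAinv <- chol2inv(chol(buildGram(fx$ds, "additive")@values))
  g0aInv <- solve(fx$vc@g0a)
  n <- lay$n; off <- lay$offsets
  # off-diagonal trait pair (k, l): pure prior block G*^(ij) g0a^kl
  set.seed(41)
  for (draw in 1:6) {
    k <- 1; l <- sample(2:3, 1)
    i <- sample(3, 1); j <- sample(3, 1)
    rows <- lay$pTotal + (k - 1) * n + (off[i] + 1):off[i + 1]
    cols <- lay$pTotal + (l - 1) * n + (off[j] + 1):off[j + 1]
    expected <- GsAinv[(off[i] + 1):off[i + 1], (off[j] + 1):off[j + 1]] *
      g0aInv[k, l]
    expect_equal(unname(sys@lhs[rows, cols]), unname(expected),
                 tolerance = 1e-12)
  }
  # diagonal trait, matching population: prior plus I / sigmaE2
  i <- 2
  rows <- lay$pTotal + (i - 1) * n + (off[i] + 1):off[i + 1]
  expected <- GsAinv[(off[i] + 1):off[i + 1], (off[i] + 1):off[i + 1]] *
    g0aInv[i, i] + diag(1 / fx$vc@sigmaE2[i], off[i + 1] - off[i])
  expect_equal(unname(sys@lhs[rows, rows]), unname(expected),
               tolerance = 1e-12)
})

test_that("compact and standard formulations have the advertised sizes", {
  fx <- getFixture("equiv-3pop")
  n <- nRecords(fx$ds)
  expect_equal(buildCompactGblup(fx$ds, fx$vc)@layout$randomEquations, 2L * n)
  expect_equal(buildStandardGblup(fx$ds, fx$vc)@layout$randomEquations,
               2L * 3L * n)
})

test_that("zero phenotypes give zero compact-GBLUP solutions and zero backsolved markers", {
  fx <- getFixture("equiv-3pop")
  ds0 <- multiPopDataset(lapply(populations(fx$ds), function(p)
    populationData(p@label, rep(0, length(p@y)), p@genotypes, X = p@X)))
  sys <- solveSystem(buildCompactGblup(ds0, fx$vc))
  sol <- solutionSet(sys, ds0, fx$vc)
  expect_equal(max(abs(c(sol@beta, sol@uA, sol@uD))), 0)
  bk <- backsolveMarkers(sys, ds0, fx$vc)
  expect_equal(max(abs(bk$aHat)), 0)
})

test_that("marker backsolving reproduces the direct selection-index solution", {
  # two individuals, two SNPs, full-rank G_A and G_D: compare against an
  # explicit small-matrix selection-index computation
  g <- encodeGenotypes(rbind(c(1, 2), c(2, 1)))
  y <- c(1.3, -0.4)
  ds <- multiPopDataset(list(populationData("p1", y, g,
    X = matrix(1, 2, 1, dimnames = list(NULL, "intercept")))))
  vc <- varianceComponents(matrix(0.5), matrix(0.25), 1)
  sys <- solveSystem(buildCompactGblup(ds, vc))
  bk <- backsolveMarkers(sys, ds, vc)
  # explicit oracle: V, GLS beta, a_hat = Ca' V^-1 (y - X b)
  Z <- addCoding(g); W <- domCoding(g)
  V <- 0.5 * Z %*% t(Z) + 0.25 * W %*% t(W) + diag(2)
  X <- matrix(1, 2, 1)
  b <- solve(t(X) %*% solve(V) %*% X, t(X) %*% solve(V) %*% y)
  aOracle <- drop(0.5 * t(Z) %*% solve(V, y - drop(X %*% b)))
  dOracle <- drop(0.25 * t(W) %*% solve(V, y - drop(X %*% b)))
  expect_equal(unname(bk$aHat[1, ]), unname(aOracle), tolerance = 1e-9)
  expect_equal(unname(bk$dHat[1, ]), unname(dOracle), tolerance = 1e-9)
})

test_that("backsolving is refused for blended systems and the standard formulation", {
  fx <- getFixture("equiv-3pop")
  sysB <- solveSystem(buildCompactGblup(fx$ds, fx$vc, blendEpsilon = 1e-6))
  expect_error(backsolveMarkers(sysB, fx$ds, fx$vc),
               class = "mp_validation_error")
  sysS <- buildStandardGblup(fx$ds, fx$vc)
  expect_error(backsolveMarkers(sysS, fx$ds, fx$vc),
               class = "mp_validation_error")
})

test_that("unblended compact GBLUP fails on clones while blending rescues it", {
  sc <- getFixture("singular-clones")
  err <- expect_error(buildCompactGblup(sc$ds, sc$vc),
                      class = "mp_numerical_error")
  expect_match(conditionMessage(err), "blend")
  sol <- solveGblupCompact(sc$ds, sc$vc, blendEpsilon = 1e-6,
                           backsolve = FALSE)
  expect_true(all(is.finite(sol@uA)))
})
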