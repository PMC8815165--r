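test_that("V is the sum of the scaled covariances and the residual diagonal", {
  # scalar case: one record, dosage 2 -> Z = 1, W = 0; V = sigma_a^2 + sigma_e^2
  g <- encodeGenotypes(matrix(2L, 1, 1))
  ds <- multiPopDataset(list(populationData("p1", 0.7, g,
    X = matrix(1, 1, 1, dimnames = list(NULL, "intercept")))))
  vc <- varianceComponents(matrix(2), matrix(1), 1)
  expect_equal(unname(buildV(ds, vc)@V), matrix(3))
  # vanishing genetic variances: V collapses to R
  fx <- getFixture("tiny-2pop")
  vcR <- varianceComponents(diag(2) * 1e-14, diag(2) * 1e-14, fx$vc@sigmaE2)
  V <- buildV(fx$ds, vcR)@V
  expect_equal(V, diag(rep(fx$vc@sigmaE2, each = 8)), tolerance = 1e-9)
  # oracle assembly on the large fixture
  eq <- getFixture("equiv-3pop")
  off <- cumsum(c(0, vapply(populations(eq$ds), function(p) length(p@y),
                            integer(1))))
  Vora <- oracleScaledCov(eq$ds, eq$vc, "additive") +
    oracleScaledCov(eq$ds, eq$vc, "dominance") +
    diag(rep(eq$vc@sigmaE2, times = diff(off)))
  expect_equal(buildV(eq$ds, eq$vc)@V, Vora, tolerance = 1e-12)
})

test_that("GLS reduces to ordinary and weighted means in the identity-V cases", {
  g <- encodeGenotypes(rbind(c(0L, 1L), c(2L, 1L)))
  ds <- multiPopDataset(list(populationData("p1", c(1, 3), g,
    X = matrix(1, 2, 1, dimnames = list(NULL, "intercept")))))
  VI <- new("PhenotypicCovariance", V = diag(2), cholFactor = chol(diag(2)))
  expect_equal(unname(glsFixedEffects(VI, ds)@betaHat), 2)
  ds2 <- multiPopDataset(list(populationData("p1", c(0, 5), g,
    X = matrix(1, 2, 1, dimnames = list(NULL, "intercept")))))
  VW <- new("PhenotypicCovariance", V = diag(c(1, 4)),
            cholFactor = chol(diag(c(1, 4))))
  expect_equal(unname(glsFixedEffects(VW, ds2)@betaHat), 1)
})

test_that("GLS satisfies its normal equations: X' yc = 0", {
  for (name in c("tiny-2pop", "crossbred-3pop", "singular-clones")) {
    fx <- getFixture(name)
    fit <- glsFixedEffects(buildV(fx$ds, fx$vc), fx$ds)
    X <- mpblup:::stackedDesign(fx$ds)
    scale <- max(abs(phenotypes(fx$ds)), 1)
    expect_lt(max(abs(crossprod(X, fit@yc))), 1e-8 * scale)
  }
})

test_that("the scalar selection-index chain gives a_hat = residual / 2", {
  # one record, Z = 1, W = 0, sigma_a^2 = 1, sigma_e^2 = 1 -> V = 2,
  # yc = c / 2, a_hat = c / 2
  g <- encodeGenotypes(matrix(2L, 1, 1))
  ds <- multiPopDataset(list(populationData("p1", 0, g,
    X = matrix(1, 1, 1, dimnames = list(NULL, "intercept")))))
  vc <- varianceComponents(matrix(1), matrix(1), 1)
  V <- buildV(ds, vc)
  expect_equal(unname(V@V), matrix(2))
  for (cres in c(-1.5, 0.3, 2)) {
    fit <- new("GlsFit", betaHat = c(`p1:intercept` = 0),
               betaCov = matrix(2), yc = cres / 2, residual = cres, vcov = V)
    bk <- siBacksolve(fit, ds, vc)
    expect_equal(unname(bk@aHat[1, 1]), cres / 2)
    expect_equal(unname(bk@dHat[1, 1]), 0)   # W = 0: no dominance signal
  }
  # zero residual -> zero marker estimates
  fit0 <- glsFixedEffects(V, ds)
  expect_equal(max(abs(siBacksolve(fit0, ds, vc)@aHat)), 0, tolerance = 1e-12)
})

test_that("GLS + SI agrees with SNP-BLUP on fixtures including rank-deficient ones", {
  for (name in c("tiny-2pop", "singular-clones")) {
    fx <- getFixture(name)
    sSnp <- solveSnpBlup(fx$ds, fx$vc)
    sGls <- solveGlsSi(fx$ds, fx$vc)
    expect_lt(maxRelDiff(sSnp@beta, sGls@beta), 1e-8)
    expect_lt(maxRelDiff(sSnp@aHat, sGls@aHat), 1e-8)
    expect_lt(maxRelDiff(sSnp@dHat, sGls@dHat), 1e-8)
  }
})

test_that("projection-formula PEVs are bounded and lose all information as noise explodes", {
  fx <- getFixture("tiny-2pop")
  fit <- glsFixedEffects(buildV(fx$ds, fx$vc), fx$ds)
  for (target in c("markers", "genetic_values")) {
    pev <- pevSi(fit, fx$ds, fx$vc, target)
    expect_true(all(pev@pevA >= -1e-10))
    expect_true(all(pev@pevA <= pev@priorA + 1e-10))
    expect_true(all(pev@pevD >= -1e-10))
    expect_true(all(pev@pevD <= pev@priorD + 1e-10))
    expect_true(all(pev@relA >= 0 & pev@relA <= 1))
  }
  # sigma_e -> infinity: reliabilities vanish
  vcNoisy <- varianceComponents(fx$vc@g0a, fx$vc@g0d, fx$vc@sigmaE2 * 1e8)
  fitN <- glsFixedEffects(buildV(fx$ds, vcNoisy), fx$ds)
  pevN <- pevSi(fitN, fx$ds, vcNoisy, "markers")
  expect_lt(max(pevN@relA), 1e-4)
  expect_lt(max(pevN@relD), 1e-4)
})

test_that("the matrix-free operator and solves match the explicit path", {
  fx <- getFixture("tiny-2pop")
  V <- buildV(fx$ds, fx$vc)@V
  set.seed(51)
  for (draw in 1:5) {
    x <- rnorm(nrow(V))
    expect_equal(mpblup:::applyV(fx$ds, fx$vc, x), drop(V %*% x),
                 tolerance = 1e-10)
  }
  # near-identity V: the CG solves reduce to the inputs, so the fit is OLS
  vcTiny <- varianceComponents(diag(2) * 1e-14, diag(2) * 1e-14, c(1, 1))
  mf <- solveMatrixFree(fx$ds, vcTiny, tol = 1e-12)
  y <- phenotypes(fx$ds)
  X <- mpblup:::stackedDesign(fx$ds)
  bOls <- drop(solve(crossprod(X), crossprod(X, y)))
  expect_equal(unname(mf$fit@betaHat), unname(bOls), tolerance = 1e-6)
  expect_equal(mf$fit@yc, y - drop(X %*% mf$fit@betaHat), tolerance = 1e-6)
  # full consistency with the direct path
  direct <- solveGlsSi(fx$ds, fx$vc)
  viaCg <- solveMatrixFree(fx$ds, fx$vc, tol = 1e-12)$solution
  expect_lt(maxRelDiff(direct@beta, viaCg@beta), 1e-8)
  expect_lt(maxRelDiff(direct@aHat, viaCg@aHat), 1e-8)
})

test_that("conjugate gradients reports non-convergence with a classed error", {
  A <- function(x) c(x[1] + 0.9 * x[2], 0.9 * x[1] + x[2])
  expect_error(mpblup:::cgSolve(A, c(1, 2), tol = 1e-14, maxit = 1),
               class = "mp_numerical_error")
})

test_that("the strategies' dense-matrix footprints order as expected when m > n", {
  fx <- getFixture("equiv-3pop")
  sGls <- solveGlsSi(fx$ds, fx$vc)
  sCom <- solveGblupCompact(fx$ds, fx$vc, backsolve = FALSE)
  sStd <- solveGblupStandard(fx$ds, fx$vc)
  sSnp <- solveSnpBlup(fx$ds, fx$vc)
  sizes <- c(gls = sGls@sizes$largestDense, compact = sCom@sizes$largestDense,
             standard = sStd@sizes$largestDense, snp = sSnp@sizes$largestDense)
  expect_true(sizes["gls"] < sizes["compact"])
  expect_true(sizes["compact"] < sizes["standard"])
  expect_true(sizes["standard"] < sizes["snp"])
  expect_equal(unname(sizes["gls"]), nRecords(fx$ds))
})
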