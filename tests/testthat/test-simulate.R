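test_that("the simulator is a pure function of its configuration", {
  cfg <- simConfig(P = 2, nPerPop = 10, m = 30, fst = 0.1, seed = 7)
  b1 <- simulateDataset(cfg)
  b2 <- simulateDataset(cfg)
  expect_identical(dosage(populations(b1$ds)[[1]]@genotypes),
                   dosage(populations(b2$ds)[[1]]@genotypes))
  expect_identical(phenotypes(b1$ds), phenotypes(b2$ds))
  expect_identical(b1$truth$aTrue, b2$truth$aTrue)
  # same preset twice: identical bundles
  expect_identical(makeFixture("tiny-2pop")$truth, getFixture("tiny-2pop")$truth)
})

test_that("fst = 0 gives every population the same allele frequencies", {
  g <- simulateGenotypes(simConfig(P = 3, nPerPop = 5, m = 50, fst = 0, seed = 3))
  expect_equal(g$freq[, 1], g$freq[, 2])
  expect_equal(g$freq[, 1], g$freq[, 3])
})

test_that("divergence reduces mean within-population heterozygosity", {
  c0 <- simConfig(P = 2, nPerPop = 500, m = 2000, fst = 0, seed = 11)
  c2 <- simConfig(P = 2, nPerPop = 500, m = 2000, fst = 0.2, seed = 11)
  hetOf <- function(cfg) {
    g <- simulateGenotypes(cfg)
    mean(vapply(g$genotypes, function(gm) mean(dosage(gm) == 1L), numeric(1)))
  }
  expect_lt(hetOf(c2), hetOf(c0))
})

test_that("per-SNP effect vectors reproduce the configured cross-population structure", {
  # diagonal G0a: cross-population correlation ~ 0 within 3/sqrt(m)
  m <- 5000
  vcDiag <- varianceComponents(diag(2) * 0.01, diag(2) * 0.01, c(1, 1))
  eff <- simulateEffects(simConfig(P = 2, nPerPop = 5, m = m, vc = vcDiag, seed = 5))
  expect_lt(abs(cor(eff$aTrue[1, ], eff$aTrue[2, ])), 3 / sqrt(m))
  # empirical covariance converges to G0a elementwise
  vc <- simConfig(P = 2, m = m, seed = 5)@vc
  eff2 <- simulateEffects(simConfig(P = 2, nPerPop = 5, m = m, vc = vc, seed = 5))
  emp <- tcrossprod(eff2$aTrue) / m
  expect_lt(max(abs(emp - vc@g0a)) / max(vc@g0a), 5 / sqrt(m) * sqrt(2))
  # degenerate (all-zero) covariance is refused
  vc0 <- varianceComponents(diag(2), matrix(0, 2, 2), c(1, 1))
  expect_error(simulateEffects(simConfig(P = 2, m = 10, vc = vc0, seed = 1)),
               class = "mp_numerical_error")
})

test_that("phenotypes follow the additive + dominance linear model", {
  # noise-free limit: y minus the model part vanishes
  vcTiny <- varianceComponents(diag(2) * 0.01, diag(2) * 0.01, rep(1e-12, 2))
  cfg <- simConfig(P = 2, nPerPop = 20, m = 40, vc = vcTiny, seed = 9)
  b <- simulateDataset(cfg)
  for (i in 1:2) {
    p <- populations(b$ds)[[i]]
    model <- drop(p@X %*% cfg@betaTrue[i, ] +
                  addCoding(p) %*% b$truth$aTrue[i, ] +
                  domCoding(p) %*% b$truth$dTrue[i, ])
    expect_lt(max(abs(p@y - model)), 1e-5)
  }
  # mean recovery: effects ~ 0, noise 1 -> sample mean near the true mean
  vcNull <- varianceComponents(diag(2) * 1e-12, diag(2) * 1e-12, c(1, 1))
  cfgNull <- simConfig(P = 2, nPerPop = 200, m = 40, vc = vcNull, seed = 13,
                       betaTrue = cbind(rep(10, 2), rep(0, 2)))
  bNull <- simulateDataset(cfgNull)
  for (i in 1:2)
    expect_lt(abs(mean(phenotypes(populations(bNull$ds)[[i]])) - 10),
              4 / sqrt(200))
})

test_that("realized additive variance matches the aggregate of simulated draws", {
  cfg <- simConfig(P = 1, nPerPop = 300, m = 100, fst = 0, seed = 17)
  b <- simulateDataset(cfg)
  p <- populations(b$ds)[[1]]
  empirical <- var(drop(addCoding(p) %*% b$truth$aTrue[1, ]))
  # independent aggregation: sum over SNPs of coding variance (~ 2pq)
  # times the per-SNP additive effect variance
  expected <- sum(apply(addCoding(p), 2, var)) * cfg@vc@g0a[1, 1]
  expect_lt(abs(empirical - expected) / expected, 0.4)
})

test_that("crossbred genotypes mix the parental allele frequencies", {
  cfg <- simConfig(P = 3, nPerPop = 400, m = 200, fst = 0.3, seed = 19,
                   crossbredPairs = list(NULL, NULL, c(1L, 2L)))
  g <- simulateGenotypes(cfg)
  freqObs <- vapply(g$genotypes, function(gm) colMeans(dosage(gm)) / 2,
                    numeric(cfg@m))
  expected <- (g$freq[, 1] + g$freq[, 2]) / 2
  expect_lt(mean(abs(freqObs[, 3] - expected)), 0.03)
})

test_that("fixture presets honour their contracts", {
  fx <- getFixture("tiny-2pop")
  expect_equal(nPopulations(fx$ds), 2)
  expect_equal(nRecords(fx$ds), 16)
  expect_equal(nSnps(fx$ds), 12)
  eq <- getFixture("equiv-3pop")
  expect_gt(nSnps(eq$ds), nRecords(eq$ds))  # m > n: full-rank G matrices
  sc <- getFixture("singular-clones")
  GA <- buildScaledCov(sc$ds, sc$vc, "additive")@values
  ev <- eigen(GA, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(min(ev), 1e-8 * mean(diag(GA)))
  err <- expect_error(makeFixture("nope"), class = "mp_validation_error")
  expect_match(conditionMessage(err), "tiny-2pop")
})

test_that("every simulated SNP is polymorphic in at least one population", {
  g <- simulateGenotypes(simConfig(P = 2, nPerPop = 4, m = 300, fst = 0.4,
                                   seed = 23))
  allv <- rbind(dosage(g$genotypes[[1]]), dosage(g$genotypes[[2]]))
  expect_true(all(apply(allv, 2, function(x) length(unique(x)) > 1)))
})
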