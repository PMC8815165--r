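#' Build a simulation configuration
#'
#' Defaults describe a polygenic trait with additive effects strongly
#' correlated across populations (0.8), moderately correlated dominance
#' (0.5), per-SNP variances scaled so total additive variance is of order
#' one against a unit residual variance, moderate allele-frequency
#' divergence (fst = 0.15), a population mean of 10 and an inbreeding
#' depression of -2 trait units per unit of homozygosity.
#'
#' @param P population count.
#' @param nPerPop record counts (recycled to length P).
#' @param m SNP count.
#' @param fst Balding-Nichols divergence parameter in [0, 1).
#' @param vc optional \code{\link{VarianceComponents}}; when NULL a default
#'   set is built: additive per-SNP variance 2/m with cross-population
#'   correlation 0.8, dominance variance 0.8/m with correlation 0.5,
#'   residual variance 1.
#' @param betaTrue P x 2 matrix (mean, inbreeding slope); default
#'   mean 10, slope -2 for every population.
#' @param seed master seed; every stage of the simulation derives its own
#'   stream from it.
#' @param crossbredPairs list of length P; entry k either NULL (purebred)
#'   or c(sirePop, damPop), making population k's genotypes one gamete
#'   drawn at each parental population's allele frequency.
#' @return a \code{\link{SimulationConfig}}.
#' @export
simConfig <- function(P = 3L, nPerPop = 60L, m = 400L, fst = 0.15,
                      vc = NULL, betaTrue = NULL, seed = 1L,
                      crossbredPairs = NULL) {
  P <- as.integer(P)
  nPerPop <- as.integer(rep_len(nPerPop, P))
  m <- as.integer(m)
  if (is.null(vc)) {
    corA <- matrix(0.8, P, P); diag(corA) <- 1
    corD <- matrix(0.5, P, P); diag(corD) <- 1
    vc <- varianceComponents(g0a = corA * (2 / m), g0d = corD * (0.8 / m),
                             sigmaE2 = rep(1, P))
  }
  if (is.null(betaTrue))
    betaTrue <- cbind(mean = rep(10, P), inbreeding = rep(-2, P))
  if (is.null(crossbredPairs))
    crossbredPairs <- rep(list(NULL), P)
  new("SimulationConfig", P = P, nPerPop = nPerPop, m = m, fst = fst,
      vc = vc, betaTrue = as.matrix(betaTrue), seed = as.integer(seed),
      crossbredPairs = crossbredPairs)
}

#' Simulate multi-population genotypes
#'
#' Base allele frequencies are drawn from Beta(2, 2). With \code{fst > 0},
#' population-specific frequencies follow the Balding-Nichols model,
#' Beta(p(1-fst)/fst, (1-p)(1-fst)/fst), so populations diverge around the
#' base frequency; with \code{fst = 0} all populations share the base
#' frequencies. Purebred dosages are Binomial(2, p_pop); crossbred
#' populations receive one Bernoulli gamete at each parental population's
#' frequency. SNPs monomorphic in every population are redrawn (up to 50
#' attempts) so each SNP is polymorphic somewhere.
#'
#' @param cfg a \code{\link{SimulationConfig}}.
#' @return list with \code{genotypes} (list of P
#'   \code{\link{GenotypeMatrix}}) and \code{freq} (m x P matrix of
#'   population allele frequencies used).
#' @export
simulateGenotypes <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  P <- cfg@P; m <- cfg@m
  set.seed(stageSeed(cfg@seed, "freq"))
  base <- rbeta(m, 2, 2)
  freq <- matrix(0, m, P)
  for (i in seq_len(P)) {
    if (cfg@fst > 0) {
      k <- (1 - cfg@fst) / cfg@fst
      freq[, i] <- rbeta(m, base * k, (1 - base) * k)
    } else freq[, i] <- base
  }
  # numerical guard: Balding-Nichols can hit 0/1 exactly at strong drift
  freq <- pmin(pmax(freq, 1e-6), 1 - 1e-6)

  drawPop <- function(i, fr) {
    ni <- cfg@nPerPop[i]
    pair <- cfg@crossbredPairs[[i]]
    if (is.null(pair)) {
      matrix(rbinom(ni * m, 2, rep(fr[, i], each = ni)), ni, m)
    } else {
      g1 <- matrix(rbinom(ni * m, 1, rep(fr[, pair[1]], each = ni)), ni, m)
      g2 <- matrix(rbinom(ni * m, 1, rep(fr[, pair[2]], each = ni)), ni, m)
      g1 + g2
    }
  }

  set.seed(stageSeed(cfg@seed, "geno"))
  dos <- lapply(seq_len(P), drawPop, fr = freq)

  # redraw SNPs that are monomorphic in every population
  set.seed(stageSeed(cfg@seed, "redraw"))
  for (attempt in seq_len(50)) {
    allvals <- do.call(rbind, dos)
    mono <- which(apply(allvals, 2, function(x) length(unique(x)) == 1L))
    if (length(mono) == 0) break
    if (attempt == 50)
      mpStop(paste0("could not obtain polymorphism at ", length(mono),
                    " SNP(s) after 50 redraws; increase n_per_pop or reduce fst"),
             class = "mp_validation_error")
    base2 <- rbeta(length(mono), 2, 2)
    for (i in seq_len(P)) {
      if (cfg@fst > 0) {
        k <- (1 - cfg@fst) / cfg@fst
        freq[mono, i] <- pmin(pmax(rbeta(length(mono), base2 * k,
                                         (1 - base2) * k), 1e-6), 1 - 1e-6)
      } else freq[mono, i] <- base2
    }
    for (i in seq_len(P)) {
      ni <- cfg@nPerPop[i]
      pair <- cfg@crossbredPairs[[i]]
      sub <- if (is.null(pair)) {
        matrix(rbinom(ni * length(mono), 2, rep(freq[mono, i], each = ni)),
               ni, length(mono))
      } else {
        matrix(rbinom(ni * length(mono), 1, rep(freq[mono, pair[1]], each = ni)),
               ni, length(mono)) +
          matrix(rbinom(ni * length(mono), 1, rep(freq[mono, pair[2]], each = ni)),
                 ni, length(mono))
      }
      dos[[i]][, mono] <- sub
    }
  }

  snps <- sprintf("snp%04d", seq_len(m))
  genos <- lapply(seq_len(P), function(i) {
    ids <- sprintf("p%d_i%04d", i, seq_len(cfg@nPerPop[i]))
    encodeGenotypes(dos[[i]], ids = ids, snps = snps)
  })
  list(genotypes = genos, freq = freq)
}

#' Simulate correlated marker effects
#'
#' For each SNP independently, the P-vector of additive effects is drawn
#' from MVN(0, G0a) and the P-vector of dominance effects from
#' MVN(0, G0d), independent of each other and across SNPs.
#'
#' @param cfg a \code{\link{SimulationConfig}}.
#' @return list with \code{aTrue}, \code{dTrue} (P x m matrices).
#' @export
simulateEffects <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  P <- cfg@P; m <- cfg@m
  La <- t(mpChol(cfg@vc@g0a, what = "G0a",
                 advice = "marker-effect covariances must be positive definite to simulate effects"))
  Ld <- t(mpChol(cfg@vc@g0d, what = "G0d",
                 advice = "marker-effect covariances must be positive definite to simulate effects"))
  set.seed(stageSeed(cfg@seed, "effects_a"))
  aTrue <- La %*% matrix(rnorm(P * m), P, m)
  set.seed(stageSeed(cfg@seed, "effects_d"))
  dTrue <- Ld %*% matrix(rnorm(P * m), P, m)
  list(aTrue = aTrue, dTrue = dTrue)
}

#' Simulate phenotypes under the additive + dominance model
#'
#' \code{y_i = X_i beta_i + Z_i a_i + W_i d_i + e_i}, with
#' \code{e_i ~ N(0, sigmaE2_i I)} and \code{X_i} the intercept +
#' genomic-inbreeding design from \code{\link{buildDesign}}.
#'
#' @param genotypes list of P \code{\link{GenotypeMatrix}}.
#' @param aTrue,dTrue P x m matrices of true SNP effects.
#' @param cfg a \code{\link{SimulationConfig}}.
#' @return a \code{\link{MultiPopDataset}}.
#' @export
simulatePhenotypes <- function(genotypes, aTrue, dTrue, cfg) {
  P <- cfg@P
  if (length(genotypes) != P || nrow(aTrue) != P || ncol(aTrue) != cfg@m ||
      !all(dim(dTrue) == dim(aTrue)))
    mpStop("genotypes/effects shapes inconsistent with the configuration",
           class = "mp_validation_error")
  set.seed(stageSeed(cfg@seed, "noise"))
  pops <- vector("list", P)
  for (i in seq_len(P)) {
    g <- genotypes[[i]]
    ni <- nrow(g@dosage)
    X <- buildDesign(g, includeInbreeding = TRUE)
    e <- rnorm(ni, sd = sqrt(cfg@vc@sigmaE2[i]))
    y <- drop(X %*% cfg@betaTrue[i, ] + g@Z %*% aTrue[i, ] +
              g@W %*% dTrue[i, ] + e)
    pops[[i]] <- populationData(label = paste0("pop", i), y = y,
                                genotypes = g, X = X)
  }
  multiPopDataset(pops)
}

#' Simulate a complete dataset plus the generating truth
#'
#' @param cfg a \code{\link{SimulationConfig}}.
#' @return list with \code{ds} (\code{MultiPopDataset}), \code{vc}, and
#'   \code{truth} (list aTrue, dTrue, betaTrue, freq).
#' @export
simulateDataset <- function(cfg) {
  g <- simulateGenotypes(cfg)
  eff <- simulateEffects(cfg)
  ds <- simulatePhenotypes(g$genotypes, eff$aTrue, eff$dTrue, cfg)
  list(ds = ds, vc = cfg@vc,
       truth = list(aTrue = eff$aTrue, dTrue = eff$dTrue,
                    betaTrue = cfg@betaTrue, freq = g$freq))
}

#' Named fixture datasets used throughout the test suite and examples
#'
#' Presets (all fully deterministic):
#' \describe{
#'   \item{tiny-2pop}{P = 2, n = (8, 8), m = 12. Small enough for
#'     hand-checkable and brute-force oracle comparisons.}
#'   \item{equiv-3pop}{P = 3, n = (60, 60, 60), m = 400. m > n guarantees
#'     full-rank individual-level covariance matrices, so all four solving
#'     strategies run unblended and can be compared.}
#'   \item{crossbred-3pop}{P = 3, n = (40, 40, 40), m = 120; population 3
#'     is a cross of populations 1 and 2.}
#'   \item{singular-clones}{P = 2, n = (10, 10), m = 60, with individual 2
#'     of population 1 an exact genotype clone of individual 1, forcing
#'     the individual-level additive covariance matrix to be singular.}
#' }
#'
#' @param name preset name.
#' @return list with \code{ds}, \code{vc}, \code{truth}, \code{cfg}.
#' @export
makeFixture <- function(name) {
  presets <- c("tiny-2pop", "equiv-3pop", "crossbred-3pop", "singular-clones")
  if (!name %in% presets)
    mpStop(sprintf("unknown fixture '%s'; available presets: %s",
                   name, paste(presets, collapse = ", ")),
           class = "mp_validation_error")
  cfg <- switch(name,
    "tiny-2pop" = simConfig(P = 2, nPerPop = 8, m = 12, fst = 0.1, seed = 20101L),
    "equiv-3pop" = simConfig(P = 3, nPerPop = 60, m = 400, fst = 0.15, seed = 20202L),
    "crossbred-3pop" = simConfig(P = 3, nPerPop = 40, m = 120, fst = 0.15,
                                 seed = 20303L,
                                 crossbredPairs = list(NULL, NULL, c(1L, 2L))),
    "singular-clones" = simConfig(P = 2, nPerPop = 10, m = 60, fst = 0.1,
                                  seed = 20404L))
  if (name != "singular-clones") {
    out <- simulateDataset(cfg)
  } else {
    g <- simulateGenotypes(cfg)
    # clone individual 1 of population 1 into slot 2: duplicated rows in
    # Z and W make G_A and G_D rank deficient
    d1 <- g$genotypes[[1]]@dosage
    d1[2, ] <- d1[1, ]
    g$genotypes[[1]] <- encodeGenotypes(d1, ids = g$genotypes[[1]]@ids,
                                        snps = g$genotypes[[1]]@snps)
    eff <- simulateEffects(cfg)
    ds <- simulatePhenotypes(g$genotypes, eff$aTrue, eff$dTrue, cfg)
    out <- list(ds = ds, vc = cfg@vc,
                truth = list(aTrue = eff$aTrue, dTrue = eff$dTrue,
                             betaTrue = cfg@betaTrue, freq = g$freq))
  }
  out$cfg <- cfg
  out
}
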