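# Plain-text input/output: genotype and phenotype CSV/TSV, variance
# components in YAML or JSON, solution CSVs and a JSON run log.

#' @importFrom utils read.csv write.csv head
NULL

readDelimAuto <- function(path) {
  if (grepl("\\.tsv$", path, ignore.case = TRUE))
    read.csv(path, sep = "\t", check.names = FALSE, stringsAsFactors = FALSE)
  else
    read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a genotype file
#'
#' CSV/TSV with a header of SNP names, first column the individual id,
#' remaining columns 0/1/2 dosages.
#'
#' @param path file path.
#' @param center logical, passed to \code{\link{encodeGenotypes}}.
#' @return a \code{\link{GenotypeMatrix}}.
#' @export
readGenotypes <- function(path, center = FALSE) {
  df <- readDelimAuto(path)
  ids <- as.character(df[[1]])
  dos <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(dos) <- "integer"
  encodeGenotypes(dos, ids = ids, snps = colnames(df)[-1], center = center)
}

#' Read a phenotype file
#'
#' CSV with columns id, population, y, then optional covariate columns.
#' Population labels are mapped to indices 1..P in first-appearance order
#' unless \code{popOrder} fixes an explicit ordering.
#'
#' @param path file path.
#' @param popOrder optional character vector of population labels in
#'   evaluation order.
#' @return data.frame with attribute \code{"popOrder"}.
#' @export
readPhenotypes <- function(path, popOrder = NULL) {
  df <- readDelimAuto(path)
  need <- c("id", "population", "y")
  if (!all(need %in% colnames(df)))
    mpStop(sprintf("phenotype file must have columns %s",
                   paste(need, collapse = ", ")),
           class = "mp_validation_error")
  df$id <- as.character(df$id)
  df$population <- as.character(df$population)
  if (is.null(popOrder)) popOrder <- unique(df$population)
  if (!setequal(popOrder, unique(df$population)))
    mpStop("popOrder does not match the population labels in the file",
           class = "mp_validation_error")
  attr(df, "popOrder") <- popOrder
  df
}

#' Read variance components from YAML or JSON
#'
#' Expected keys: \code{g0a} (P x P), \code{g0d} (P x P), \code{sigma_e2}
#' (length P). Format chosen by file extension.
#'
#' @param path file path ending in .yaml, .yml or .json.
#' @return a \code{\link{VarianceComponents}}.
#' @export
readVarianceComponents <- function(path) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path)
  else
    yaml::read_yaml(path)
  for (key in c("g0a", "g0d", "sigma_e2"))
    if (is.null(obj[[key]]))
      mpStop(sprintf("variance-component file is missing key '%s'", key),
             class = "mp_validation_error")
  toMat <- function(x) {
    if (is.matrix(x)) return(x)
    do.call(rbind, lapply(x, as.numeric))
  }
  varianceComponents(toMat(obj$g0a), toMat(obj$g0d), as.numeric(obj$sigma_e2))
}

#' Write variance components to YAML
#'
#' @param vc a \code{\link{VarianceComponents}}.
#' @param path output path.
#' @export
writeVarianceComponents <- function(vc, path) {
  obj <- list(g0a = apply(vc@g0a, 1, as.numeric, simplify = FALSE),
              g0d = apply(vc@g0d, 1, as.numeric, simplify = FALSE),
              sigma_e2 = as.numeric(vc@sigmaE2))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Assemble a dataset from genotype and phenotype files
#'
#' @param genotypePath genotype CSV/TSV covering all individuals.
#' @param phenotypePath phenotype CSV (id, population, y, covariates...).
#' @param popOrder optional explicit population ordering.
#' @param includeInbreeding logical, passed to \code{\link{buildDesign}}.
#' @param center logical, center codings per population.
#' @return a \code{\link{MultiPopDataset}}.
#' @export
readDataset <- function(genotypePath, phenotypePath, popOrder = NULL,
                        includeInbreeding = TRUE, center = FALSE) {
  g <- readGenotypes(genotypePath)
  ph <- readPhenotypes(phenotypePath, popOrder)
  popOrder <- attr(ph, "popOrder")
  missing <- setdiff(ph$id, g@ids)
  if (length(missing) > 0)
    mpStop(sprintf("%d phenotyped individual(s) have no genotype: %s%s",
                   length(missing), paste(head(missing, 5), collapse = ", "),
                   if (length(missing) > 5) ", ..." else ""),
           class = "mp_validation_error")
  covCols <- setdiff(colnames(ph), c("id", "population", "y"))
  pops <- lapply(popOrder, function(lab) {
    sub <- ph[ph$population == lab, , drop = FALSE]
    idx <- match(sub$id, g@ids)
    gm <- encodeGenotypes(g@dosage[idx, , drop = FALSE], ids = sub$id,
                          snps = g@snps, center = center)
    covs <- if (length(covCols) > 0)
      as.matrix(sub[, covCols, drop = FALSE]) else NULL
    populationData(label = lab, y = sub$y, genotypes = gm,
                   covariates = covs, includeInbreeding = includeInbreeding)
  })
  multiPopDataset(pops)
}

#' Write a dataset to genotype/phenotype CSV files
#'
#' @param ds a \code{\link{MultiPopDataset}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeDataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gpath <- file.path(dir, "genotypes.csv")
  ppath <- file.path(dir, "phenotypes.csv")
  dos <- do.call(rbind, lapply(ds@populations, function(p) p@genotypes@dosage))
  gdf <- data.frame(id = rownames(dos), dos, check.names = FALSE,
                    row.names = NULL)
  write.csv(gdf, gpath, row.names = FALSE, quote = FALSE)
  pdf <- do.call(rbind, lapply(ds@populations, function(p)
    data.frame(id = p@genotypes@ids, population = p@label, y = p@y,
               row.names = NULL)))
  write.csv(pdf, ppath, row.names = FALSE, quote = FALSE)
  invisible(c(genotypes = gpath, phenotypes = ppath))
}

#' Write a SolutionSet to CSV files plus a JSON run log
#'
#' Writes \code{fixed_effects.csv} (population, name, estimate),
#' \code{markers.csv} (snp, population, a_hat, d_hat and, when a
#' \code{\link{PevReport}} is given, pev_a, pev_d, rel_a, rel_d) and
#' \code{genetic_values.csv} (id, population, u_a, u_d), plus
#' \code{run_log.json} recording method, sizes and tolerances.
#'
#' @param sol a \code{\link{SolutionSet}}.
#' @param ds the dataset it came from.
#' @param dir output directory.
#' @param pev optional marker \code{\link{PevReport}}.
#' @param log optional named list merged into the run log.
#' @return invisibly, the directory.
#' @export
writeSolutionSet <- function(sol, ds, dir, pev = NULL, log = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labels <- popLabels(ds)
  fx <- data.frame(
    population = sub(":.*$", "", names(sol@beta)),
    name = sub("^[^:]*:", "", names(sol@beta)),
    estimate = unname(sol@beta))
  write.csv(fx, file.path(dir, "fixed_effects.csv"), row.names = FALSE,
            quote = FALSE)
  if (nrow(sol@aHat) > 0) {
    mk <- do.call(rbind, lapply(seq_len(nrow(sol@aHat)), function(k)
      data.frame(snp = colnames(sol@aHat), population = labels[k],
                 a_hat = sol@aHat[k, ], d_hat = sol@dHat[k, ],
                 row.names = NULL)))
    if (!is.null(pev) && pev@target == "markers") {
      mk$pev_a <- as.vector(t(pev@pevA)); mk$pev_d <- as.vector(t(pev@pevD))
      mk$rel_a <- as.vector(t(pev@relA)); mk$rel_d <- as.vector(t(pev@relD))
    }
    write.csv(mk, file.path(dir, "markers.csv"), row.names = FALSE,
              quote = FALSE)
  }
  popOf <- rep(labels, times = vapply(ds@populations, function(p)
    length(p@y), integer(1)))
  gv <- data.frame(id = names(sol@uA), population = popOf,
                   u_a = unname(sol@uA), u_d = unname(sol@uD))
  write.csv(gv, file.path(dir, "genetic_values.csv"), row.names = FALSE,
            quote = FALSE)
  log <- c(list(method = sol@method, sizes = sol@sizes,
                fingerprint = sol@fingerprint), log)
  jsonlite::write_json(log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read back a SolutionSet written by \code{\link{writeSolutionSet}}
#'
#' @param dir directory holding the CSVs and run log.
#' @return a \code{\link{SolutionSet}}.
#' @export
readSolutionSet <- function(dir) {
  log <- jsonlite::fromJSON(file.path(dir, "run_log.json"))
  fx <- read.csv(file.path(dir, "fixed_effects.csv"),
                 stringsAsFactors = FALSE)
  beta <- setNames(fx$estimate, paste(fx$population, fx$name, sep = ":"))
  gv <- read.csv(file.path(dir, "genetic_values.csv"),
                 stringsAsFactors = FALSE)
  uA <- setNames(gv$u_a, gv$id); uD <- setNames(gv$u_d, gv$id)
  mpath <- file.path(dir, "markers.csv")
  if (file.exists(mpath)) {
    mk <- read.csv(mpath, stringsAsFactors = FALSE)
    pops <- unique(mk$population)
    snps <- unique(mk$snp)
    aHat <- matrix(mk$a_hat, length(pops), length(snps), byrow = TRUE,
                   dimnames = list(pops, snps))
    dHat <- matrix(mk$d_hat, length(pops), length(snps), byrow = TRUE,
                   dimnames = list(pops, snps))
  } else {
    aHat <- matrix(0, 0, 0); dHat <- matrix(0, 0, 0)
  }
  new("SolutionSet", method = log$method, beta = beta, aHat = aHat,
      dHat = dHat, uA = uA, uD = uD, fingerprint = log$fingerprint,
      sizes = lapply(log$sizes, as.integer))
}
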