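#' Build a validated simulation configuration
#'
#' Defaults reproduce the study conditions the pipeline is designed for: a
#' three-cohort blood study of 1026 samples (cohorts of 454, 381 and 191)
#' with 43.5% T2D cases, older cases than controls in the two EWAS cohorts, a
#' genotyping-batch split of roughly 703/323 for meQTL discovery/replication
#' and a two-batch metabolomics split of roughly 364/344. Feature-space sizes
#' are scaled down to 1000 CpGs, 5000 SNPs and 150 metabolites so that a full
#' synthetic run is feasible on a laptop; see the package vignette.
#'
#' Planted effects default to a small standard set (six SNP-to-CpG pairs of
#' which two are trans, five T2D-shifted CpGs, four T2D-shifted metabolites
#' and three CpG-to-metabolite links). Pass empty data.frames (or
#' `effects = "none"`) for a global-null panel.
#'
#' @param nSamples,nCpgs,nSnps,nMetabolites cohort and feature-space sizes.
#' @param caseFraction fraction of T2D cases.
#' @param nFamilies,familySize number of sibships and siblings each; the
#'   remaining samples are unrelated.
#' @param mafRange minor-allele-frequency interval, within (0, 0.5].
#' @param effects `"default"` for the standard planted set, `"none"` for a
#'   global null, or a list with any of `snpCpg`, `t2dCpg`, `t2dMetabolite`,
#'   `cpgMetabolite` data.frames (see \linkS4class{SimulationConfig}).
#' @param ggmEdgeDensity,ggmPartialCor density and magnitude of the planted
#'   metabolite partial-correlation graph.
#' @param methNoiseSd residual SD on the logit-methylation scale.
#' @param metaboliteLogSd SD of log metabolite abundance.
#' @param covariateEffectScale multiplier on the random covariate loadings of
#'   every CpG (0 switches all covariate structure off).
#' @param missingRate random missingness rate of the raw metabolite matrix.
#' @param ancestryFst divergence of the two simulated ancestry components.
#' @param ageCollinearT2d `TRUE` (default) reproduces the study design in
#'   which cases are substantially older than controls in the two EWAS
#'   cohorts; `FALSE` draws age independently of disease status, the
#'   appropriate global-null condition.
#' @param seed integer master seed.
#' @return a \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(nSamples = 200, nCpgs = 50, nSnps = 300,
#'                         nMetabolites = 20, seed = 7)
#' cfg
#' @export
simulationConfig <- function(nSamples = 1026L, nCpgs = 1000L, nSnps = 5000L,
                             nMetabolites = 150L, caseFraction = 0.435,
                             nFamilies = 50L, familySize = 2L,
                             mafRange = c(0.05, 0.5), effects = "default",
                             ggmEdgeDensity = 0.05, ggmPartialCor = 0.3,
                             methNoiseSd = 0.5, metaboliteLogSd = 0.4,
                             covariateEffectScale = 1, missingRate = 0.01,
                             ancestryFst = 0.02, ageCollinearT2d = TRUE,
                             seed = 1L) {
  cpgId <- function(i) sprintf("cg%07d", i)
  metId <- function(i) sprintf("met%04d", i)
  snpId <- function(i) sprintf("rs_sim_%04d", i)
  eff <- list(snpCpg = data.frame(snp = character(), cpg = character(),
                                  beta = numeric()),
              t2dCpg = data.frame(cpg = character(), beta = numeric()),
              t2dMetabolite = data.frame(metabolite = character(),
                                         beta = numeric()),
              cpgMetabolite = data.frame(cpg = character(),
                                         metabolite = character(),
                                         beta = numeric()))
  if (identical(effects, "default")) {
    eff$snpCpg <- data.frame(
      snp = snpId(1:6), cpg = cpgId(1:6),
      beta = c(0.6, -0.5, 0.5, -0.6, 0.45, 0.5))
    eff$t2dCpg <- data.frame(cpg = cpgId(11:15),
                             beta = c(0.35, -0.3, 0.3, 0.4, -0.35))
    eff$t2dMetabolite <- data.frame(metabolite = metId(1:4),
                                    beta = c(0.5, -0.5, 0.4, 0.6))
    eff$cpgMetabolite <- data.frame(cpg = cpgId(c(11, 12, 14)),
                                    metabolite = metId(5:7),
                                    beta = c(0.3, -0.3, 0.25))
  } else if (is.list(effects)) {
    for (nm in names(effects)) {
      if (!nm %in% names(eff)) stop("unknown effect table: ", nm)
      eff[[nm]] <- effects[[nm]]
    }
  } else if (!identical(effects, "none")) {
    stop("effects must be \"default\", \"none\" or a list of tables")
  }
  new("SimulationConfig",
      nSamples = as.integer(nSamples), nCpgs = as.integer(nCpgs),
      nSnps = as.integer(nSnps), nMetabolites = as.integer(nMetabolites),
      caseFraction = caseFraction, nFamilies = as.integer(nFamilies),
      familySize = as.integer(familySize), mafRange = as.numeric(mafRange),
      snpCpg = eff$snpCpg, t2dCpg = eff$t2dCpg,
      t2dMetabolite = eff$t2dMetabolite, cpgMetabolite = eff$cpgMetabolite,
      ggmEdgeDensity = ggmEdgeDensity, ggmPartialCor = ggmPartialCor,
      methNoiseSd = methNoiseSd, metaboliteLogSd = metaboliteLogSd,
      covariateEffectScale = covariateEffectScale, missingRate = missingRate,
      ancestryFst = ancestryFst, ageCollinearT2d = isTRUE(ageCollinearT2d),
      seed = as.integer(seed))
}

#' Apply the T2D case definition
#'
#' A sample is a case if it self-reports a diabetes diagnosis or has
#' HbA1c >= 6.5, provided the self-reported age of onset is above 30 years or
#' missing.
#'
#' @param samples data.frame with columns `selfReport` (logical), `hba1c`
#'   (percent) and `onsetAge` (years, NA allowed).
#' @return logical case indicator.
#' @export
classifyDiabetes <- function(samples) {
  stopifnot(all(c("selfReport", "hba1c", "onsetAge") %in% names(samples)))
  (samples$selfReport | samples$hba1c >= 6.5) &
    (is.na(samples$onsetAge) | samples$onsetAge > 30)
}

## Per-sample phenotype/covariate skeleton shared by all layer generators.
.simulateSamples <- function(config) {
  set.seed(.deriveSeed(config@seed, 11L))
  n <- config@nSamples
  ids <- sprintf("S%04d", seq_len(n))
  nFam <- config@nFamilies * config@familySize
  family <- rep(NA_character_, n)
  if (nFam > 0)
    family[seq_len(nFam)] <- rep(sprintf("F%03d", seq_len(config@nFamilies)),
                                 each = config@familySize)
  pop <- ifelse(stats::runif(n) < 0.5, "A", "B")
  if (nFam > 0) {                       # family members share ancestry
    famPop <- stats::setNames(pop[match(unique(stats::na.omit(family)),
                                        family)],
                              unique(stats::na.omit(family)))
    pop[!is.na(family)] <- famPop[family[!is.na(family)]]
  }
  n1 <- round(n * 454 / 1026); n2 <- round(n * 381 / 1026)
  cohort <- sample(rep(1:3, times = c(n1, n2, n - n1 - n2)))
  t2d <- stats::rbinom(n, 1, config@caseFraction)
  age <- if (config@ageCollinearT2d) {
    ifelse(cohort %in% c(1, 2),
           ifelse(t2d == 1, stats::rnorm(n, 53, 9),
                  stats::rnorm(n, 36, 11)),
           ifelse(t2d == 1, stats::rnorm(n, 53, 9.5),
                  stats::rnorm(n, 55, 12)))
  } else {
    ifelse(cohort %in% c(1, 2), stats::rnorm(n, 44, 12),
           stats::rnorm(n, 54, 11))
  }
  age <- pmin(pmax(age, 20), 80)
  sex <- ifelse(stats::runif(n) < 0.5, "F", "M")
  bmi <- ifelse(cohort == 1 & t2d == 1, stats::rnorm(n, 32.4, 6),
         ifelse(cohort == 1, stats::rnorm(n, 26.6, 6),
                stats::rnorm(n, 30.7, 5.4)))
  bmi <- pmax(bmi, 16)
  hba1c <- ifelse(t2d == 1, stats::rnorm(n, 7.8, 1.2),
                  pmin(stats::rnorm(n, 5.4, 0.35), 6.4))
  hba1c <- pmax(hba1c, 4)
  selfReport <- t2d == 1 & (stats::runif(n) < 0.85 | hba1c < 6.5)
  onsetAge <- ifelse(selfReport, pmax(stats::rnorm(n, 45, 8), 31), NA)
  smoking <- stats::rbinom(n, 1, 0.25) * stats::rnorm(n, 1, 0.2)
  ## five leukocyte proportions from a Dirichlet
  alpha <- c(neutrophils = 33, basophils = 0.5, eosinophils = 2,
             monocytes = 5, lymphocytes = 18)
  g <- vapply(alpha, function(a) stats::rgamma(n, shape = a), numeric(n))
  cells <- g / rowSums(g)
  colnames(cells) <- names(alpha)
  plate <- ave(seq_len(n), cohort,
               FUN = function(i) ceiling(seq_along(i) / 96))
  plate <- sprintf("P%d_%02d", cohort, plate)
  well <- rep_len(LETTERS[1:8], n)
  genoBatch <- ifelse(stats::runif(n) < 703 / 1026, 1L, 2L)
  metBatch <- ifelse(stats::runif(n) < 364 / 708, 1L, 2L)
  out <- S4Vectors::DataFrame(
    sample = ids, cohort = cohort, t2d = t2d, age = age, sex = sex,
    bmi = bmi, hba1c = hba1c, selfReport = selfReport, onsetAge = onsetAge,
    smoking = smoking, family = family, pop = pop,
    plate = plate, well = well, batch = paste0("B", cohort),
    genoBatch = genoBatch, metBatch = metBatch,
    row.names = ids)
  cbind(out, S4Vectors::DataFrame(cells))
}

#' Simulate genotype dosages with explicit family structure
#'
#' Unrelated samples draw two alleles per SNP from their ancestry-specific
#' allele frequency (a Balding-Nichols perturbation of the panel frequency);
#' sibships draw four parental haplotypes and each sibling inherits one
#' maternal and one paternal allele per SNP, so the expected kinship between
#' siblings is 0.25 (0.5 on the genomic-relationship scale). SNPs are placed
#' on chromosomes 1 and 2 across 250 Mb each, so cis and trans labels are
#' both exercised downstream.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param samples optional sample skeleton (internal use); generated from
#'   `config` when missing.
#' @return list with `genotypes` (SummarizedExperiment, SNPs x samples, assay
#'   `"dosage"`, rowData chr/pos/maf) and `kinship` (the expected
#'   genomic-relationship matrix: unit diagonal, 0.5 for siblings).
#' @export
simulateGenotypes <- function(config, samples = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  if (is.null(samples)) samples <- .simulateSamples(config)
  set.seed(.deriveSeed(config@seed, 23L))
  n <- nrow(samples); m <- config@nSnps
  maf <- stats::runif(m, config@mafRange[1], config@mafRange[2])
  Fst <- config@ancestryFst
  popFreq <- cbind(
    A = pmin(pmax(maf + stats::rnorm(m, 0, sqrt(Fst * maf * (1 - maf))),
                  0.01), 0.99),
    B = pmin(pmax(maf + stats::rnorm(m, 0, sqrt(Fst * maf * (1 - maf))),
                  0.01), 0.99))
  G <- matrix(0L, m, n, dimnames = list(NULL, rownames(samples)))
  unrel <- is.na(samples$family)
  for (p in c("A", "B")) {
    idx <- which(unrel & samples$pop == p)
    if (length(idx))
      G[, idx] <- matrix(stats::rbinom(m * length(idx), 2,
                                       rep(popFreq[, p], length(idx))),
                         m, length(idx))
  }
  for (fam in unique(stats::na.omit(samples$family))) {
    idx <- which(samples$family == fam)
    p <- popFreq[, samples$pop[idx[1]]]
    hap <- matrix(stats::rbinom(4 * m, 1, rep(p, 4)), m, 4)  # M1 M2 F1 F2
    for (i in idx) {
      mat <- ifelse(stats::runif(m) < 0.5, hap[, 1], hap[, 2])
      pat <- ifelse(stats::runif(m) < 0.5, hap[, 3], hap[, 4])
      G[, i] <- mat + pat
    }
  }
  ## coordinates: planted-pair SNPs at fixed positions, the rest uniform
  chr <- sample(1:2, m, replace = TRUE)
  pos <- as.integer(stats::runif(m, 1e6, 250e6))
  snpNames <- sprintf("rs_sim_%04d", seq_len(m))
  planted <- match(config@snpCpg$snp, snpNames)
  if (any(!is.na(planted))) {
    k <- which(!is.na(planted))
    chr[planted[k]] <- 1L
    pos[planted[k]] <- as.integer(10e6 * k)
  }
  rd <- S4Vectors::DataFrame(chr = chr, pos = pos, ref = "A", alt = "G",
                             maf = maf, row.names = snpNames)
  rownames(G) <- snpNames
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = G), rowData = rd,
    colData = samples)
  kin <- diag(1, n)
  dimnames(kin) <- list(rownames(samples), rownames(samples))
  for (fam in unique(stats::na.omit(samples$family))) {
    idx <- which(samples$family == fam)
    kin[idx, idx] <- 0.5
    diag(kin)[idx] <- 1
  }
  list(genotypes = se, kinship = kin)
}

#' Simulate methylation beta values
#'
#' Each CpG's logit-methylation is a linear predictor (intercept, age, sex,
#' batch, batch-by-sex interaction, plate, well row, cell-count composition,
#' planted SNP and T2D effects, Gaussian noise) pushed through the inverse
#' logit, so beta values are strictly inside (0,1). One designated CpG,
#' `cg05575921`, is driven by the latent smoking variable and serves as the
#' smoking surrogate covariate downstream.
#'
#' @param genotypes SummarizedExperiment of dosages (from
#'   [simulateGenotypes()]).
#' @param samples sample table (DataFrame or data.frame) with the covariate
#'   columns produced by the generator.
#' @param truth list with effect tables `snpCpg` and `t2dCpg`, scalar
#'   `methNoiseSd` and `covariateEffectScale`, and `nCpgs`.
#' @param seed integer seed.
#' @return SummarizedExperiment, CpGs x samples, assay `"beta"`, rowData
#'   chr/pos.
#' @export
simulateMethylation <- function(genotypes, samples, truth, seed) {
  set.seed(as.integer(seed))
  n <- nrow(samples)
  m <- truth$nCpgs
  cpgNames <- sprintf("cg%07d", seq_len(m))
  smokeCpg <- "cg05575921"
  cpgNames[m] <- smokeCpg                # last row is the smoking surrogate
  if (nrow(truth$snpCpg) &&
      !all(truth$snpCpg$cpg %in% cpgNames))
    stop("planted snpCpg effects reference CpGs outside the panel")
  if (nrow(truth$t2dCpg) && !all(truth$t2dCpg$cpg %in% cpgNames))
    stop("planted t2dCpg effects reference CpGs outside the panel")
  s <- truth$covariateEffectScale
  intercept <- .logit(stats::runif(m, 0.15, 0.85))
  eta <- matrix(intercept, m, n)
  ageC <- samples$age - mean(samples$age)
  male <- as.numeric(samples$sex == "M")
  eta <- eta + (s * stats::rnorm(m, 0, 0.004)) %o% ageC
  eta <- eta + (s * stats::rnorm(m, 0, 0.05)) %o% male
  for (b in unique(samples$batch)) {
    ind <- as.numeric(samples$batch == b)
    eta <- eta + (s * stats::rnorm(m, 0, 0.08)) %o% ind
    eta <- eta + (s * stats::rnorm(m, 0, 0.04)) %o% (ind * male)
  }
  plates <- unique(samples$plate)
  plateEff <- matrix(s * stats::rnorm(m * length(plates), 0, 0.03),
                     m, length(plates), dimnames = list(NULL, plates))
  eta <- eta + plateEff[, samples$plate]
  wells <- unique(samples$well)
  wellEff <- matrix(s * stats::rnorm(m * length(wells), 0, 0.02),
                    m, length(wells), dimnames = list(NULL, wells))
  eta <- eta + wellEff[, samples$well]
  cells <- as.matrix(as.data.frame(samples[, c("neutrophils", "basophils",
                                               "eosinophils", "monocytes",
                                               "lymphocytes")]))
  cellsC <- scale(cells, scale = FALSE)
  cellLoad <- matrix(s * stats::rnorm(m * 5, 0, 0.3), m, 5)
  eta <- eta + cellLoad %*% t(cellsC)
  eta[m, ] <- eta[m, ] - 1.2 * samples$smoking      # smoking surrogate
  G <- SummarizedExperiment::assay(genotypes, "dosage")
  if (nrow(truth$snpCpg)) {
    for (k in seq_len(nrow(truth$snpCpg))) {
      i <- match(truth$snpCpg$cpg[k], cpgNames)
      eta[i, ] <- eta[i, ] + truth$snpCpg$beta[k] * G[truth$snpCpg$snp[k], ]
    }
  }
  if (nrow(truth$t2dCpg)) {
    for (k in seq_len(nrow(truth$t2dCpg))) {
      i <- match(truth$t2dCpg$cpg[k], cpgNames)
      eta[i, ] <- eta[i, ] + truth$t2dCpg$beta[k] * samples$t2d
    }
  }
  eta <- eta + matrix(stats::rnorm(m * n, 0, truth$methNoiseSd), m, n)
  beta <- stats::plogis(eta)
  ## CpG coordinates: planted pairs sit 30 kb from their SNP (cis) except
  ## pairs flagged trans, which move to the other chromosome
  chr <- sample(1:2, m, replace = TRUE)
  pos <- as.integer(stats::runif(m, 1e6, 250e6))
  if (nrow(truth$snpCpg)) {
    grd <- SummarizedExperiment::rowData(genotypes)
    for (k in seq_len(nrow(truth$snpCpg))) {
      i <- match(truth$snpCpg$cpg[k], cpgNames)
      j <- match(truth$snpCpg$snp[k], rownames(genotypes))
      if (isTRUE(truth$snpCpg$trans[k])) {
        chr[i] <- ifelse(grd$chr[j] == 1L, 2L, 1L)
      } else {
        chr[i] <- grd$chr[j]
        pos[i] <- grd$pos[j] + 30000L
      }
    }
  }
  dimnames(beta) <- list(cpgNames, rownames(samples))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(beta = beta),
    rowData = S4Vectors::DataFrame(chr = chr, pos = pos,
                                   row.names = cpgNames),
    colData = S4Vectors::DataFrame(samples))
}

## Sparse precision matrix with unit diagonal whose off-diagonal pattern IS
## the planted partial-correlation graph: P = I - Pc, pcor_ij = Pc_ij.
## Rescales Pc towards zero until P is safely positive definite.
.makePrecision <- function(p, density, rho) {
  Pc <- matrix(0, p, p)
  pairs <- which(upper.tri(Pc))
  on <- pairs[stats::runif(length(pairs)) < density]
  Pc[on] <- rho * sample(c(-1, 1), length(on), replace = TRUE)
  Pc <- Pc + t(Pc)
  P <- diag(p) - Pc
  while (min(eigen(P, symmetric = TRUE, only.values = TRUE)$values) < 0.05) {
    Pc <- 0.9 * Pc
    P <- diag(p) - Pc
  }
  list(precision = P, partialCor = Pc)
}

#' Simulate a metabolite panel with a Gaussian-graphical dependence structure
#'
#' Latent z-scores are drawn from a multivariate normal whose correlation
#' matrix is the (standardized) inverse of a sparse precision matrix, then
#' shifted by the planted T2D and CpG effects and exponentiated to a positive
#' raw scale, so the downstream log/outlier/z-score QC is meaningful.
#'
#' @param samples sample table with a `t2d` column.
#' @param methylation SummarizedExperiment of beta values (needed when
#'   `truth$cpgMetabolite` is non-empty), or `NULL`.
#' @param truth list with `precision` (positive definite, unit diagonal; or
#'   `NULL` to draw one from `ggmEdgeDensity`/`ggmPartialCor`), effect tables
#'   `t2dMetabolite` and `cpgMetabolite`, and scalars `metaboliteLogSd`,
#'   `missingRate`, `nMetabolites`.
#' @param seed integer seed.
#' @return SummarizedExperiment, metabolites x samples, assay `"abundance"`
#'   (raw positive scale), rowData pathway/subpathway; the precision and
#'   partial-correlation matrices used are stored in `metadata()`.
#' @export
simulateMetabolites <- function(samples, methylation, truth, seed) {
  set.seed(as.integer(seed))
  n <- nrow(samples)
  p <- truth$nMetabolites
  if (is.null(truth$precision)) {
    pr <- .makePrecision(p, truth$ggmEdgeDensity, truth$ggmPartialCor)
  } else {
    P <- truth$precision
    ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop("precision matrix must be positive definite")
    pc <- -P / sqrt(diag(P) %o% diag(P)); diag(pc) <- 0
    pr <- list(precision = P, partialCor = pc)
  }
  R <- stats::cov2cor(solve(pr$precision))
  z <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = R)
  metNames <- sprintf("met%04d", seq_len(p))
  colnames(z) <- metNames
  if (nrow(truth$t2dMetabolite)) {
    for (k in seq_len(nrow(truth$t2dMetabolite))) {
      j <- match(truth$t2dMetabolite$metabolite[k], metNames)
      z[, j] <- z[, j] + truth$t2dMetabolite$beta[k] * samples$t2d
    }
  }
  if (nrow(truth$cpgMetabolite)) {
    stopifnot(!is.null(methylation))
    B <- SummarizedExperiment::assay(methylation, "beta")
    for (k in seq_len(nrow(truth$cpgMetabolite))) {
      j <- match(truth$cpgMetabolite$metabolite[k], metNames)
      x <- as.numeric(scale(.logit(B[truth$cpgMetabolite$cpg[k], ])))
      z[, j] <- z[, j] + truth$cpgMetabolite$beta[k] * x
    }
  }
  raw <- exp(2 + truth$metaboliteLogSd * t(z))   # metabolites x samples
  if (truth$missingRate > 0)
    raw[stats::runif(length(raw)) < truth$missingRate] <- NA
  pathways <- c("Amino Acid", "Carbohydrate", "Lipid", "Xenobiotics",
                "Nucleotide")
  pw <- sample(pathways, p, replace = TRUE)
  rd <- S4Vectors::DataFrame(
    pathway = pw,
    subpathway = paste0(pw, " subclass ", sample(1:3, p, replace = TRUE)),
    row.names = metNames)
  dimnames(raw) <- list(metNames, rownames(samples))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = raw), rowData = rd,
    colData = S4Vectors::DataFrame(samples))
  S4Vectors::metadata(se)$precision <- pr$precision
  S4Vectors::metadata(se)$partialCor <- pr$partialCor
  se
}

#' Simulate a complete multi-omics cohort with recorded ground truth
#'
#' Orchestrates [simulateGenotypes()], [simulateMethylation()] and
#' [simulateMetabolites()] under one master seed. The result is a
#' deterministic function of the configuration: the same config yields
#' byte-identical matrices.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return a \linkS4class{MultiOmicsStudy}; `groundTruth()` holds the planted
#'   effect tables, the expected kinship matrix, the metabolite precision /
#'   partial-correlation matrices and the latent smoking vector.
#' @examples
#' cfg <- simulationConfig(nSamples = 120, nCpgs = 40, nSnps = 200,
#'                         nMetabolites = 15, nFamilies = 10, seed = 42)
#' study <- simulateCohort(cfg)
#' study
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  samples <- .simulateSamples(config)
  geno <- simulateGenotypes(config, samples)
  truth <- list(
    snpCpg = config@snpCpg, t2dCpg = config@t2dCpg,
    t2dMetabolite = config@t2dMetabolite,
    cpgMetabolite = config@cpgMetabolite,
    nCpgs = config@nCpgs, nMetabolites = config@nMetabolites,
    methNoiseSd = config@methNoiseSd,
    metaboliteLogSd = config@metaboliteLogSd,
    covariateEffectScale = config@covariateEffectScale,
    missingRate = config@missingRate,
    ggmEdgeDensity = config@ggmEdgeDensity,
    ggmPartialCor = config@ggmPartialCor,
    precision = NULL)
  ## mark default planted pairs 5 and 6 as trans for cis/trans exercise
  if (nrow(truth$snpCpg) && is.null(truth$snpCpg$trans))
    truth$snpCpg$trans <- seq_len(nrow(truth$snpCpg)) %in%
      utils::tail(seq_len(nrow(truth$snpCpg)), 2)
  meth <- simulateMethylation(geno$genotypes, samples, truth,
                              .deriveSeed(config@seed, 37L))
  mets <- simulateMetabolites(samples, meth, truth,
                              .deriveSeed(config@seed, 53L))
  truth$kinship <- geno$kinship
  truth$precision <- S4Vectors::metadata(mets)$precision
  truth$partialCor <- S4Vectors::metadata(mets)$partialCor
  truth$smoking <- samples$smoking
  truth$smokingCpg <- "cg05575921"
  new("MultiOmicsStudy", samples = samples, methylation = meth,
      genotypes = geno$genotypes, metabolites = mets, groundTruth = truth)
}
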