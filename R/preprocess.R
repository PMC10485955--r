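#' Metabolite quality control: log, 3-SD outlier removal, z-scoring
#'
#' Per metabolite: natural-log transform (optional), set values more than
#' three standard deviations from the mean over all samples to missing
#' (single pass), then re-standardize the non-missing values to mean 0 and
#' SD 1. Metabolites with zero variance, or with missingness above
#' `maxMissing` after the outlier pass, are dropped. Non-positive raw values
#' cannot be log-transformed; they are recorded, set missing, and a warning
#' is raised.
#'
#' @param raw numeric matrix, metabolites x samples; missing values allowed.
#' @param log apply the natural-log transform first (set `FALSE` when the
#'   input is already on a transformed scale).
#' @param maxMissing per-metabolite missingness ceiling (default 20%).
#' @return z-scored matrix (retained metabolites x samples) with attribute
#'   `"qcReport"`: a data.frame with one row per input metabolite
#'   (`metabolite`, `nNonPositive`, `nOutliers`, `missingFrac`, `dropped`,
#'   `reason`).
#' @export
metaboliteQC <- function(raw, log = TRUE, maxMissing = 0.2) {
  stopifnot(is.matrix(raw))
  m <- nrow(raw)
  nNonPos <- integer(m); nOut <- integer(m)
  if (log) {
    bad <- !is.na(raw) & raw <= 0
    nNonPos <- rowSums(bad)
    if (any(bad)) {
      warning(sum(bad), " non-positive raw value(s) set to missing")
      raw[bad] <- NA
    }
    raw <- base::log(raw)
  }
  mu <- rowMeans(raw, na.rm = TRUE)
  sd0 <- apply(raw, 1, stats::sd, na.rm = TRUE)
  out <- abs(raw - mu) > 3 * sd0
  out[is.na(out)] <- FALSE
  nOut <- rowSums(out)
  raw[out] <- NA
  missFrac <- rowMeans(is.na(raw))
  mu2 <- rowMeans(raw, na.rm = TRUE)
  sd2 <- apply(raw, 1, stats::sd, na.rm = TRUE)
  zeroVar <- is.na(sd2) | sd2 == 0
  drop <- zeroVar | missFrac > maxMissing
  reason <- ifelse(zeroVar, "zero variance",
                   ifelse(missFrac > maxMissing, "missingness", ""))
  z <- (raw - mu2) / sd2
  report <- data.frame(metabolite = rownames(raw) %||% as.character(seq_len(m)),
                       nNonPositive = nNonPos, nOutliers = nOut,
                       missingFrac = missFrac, dropped = drop,
                       reason = reason, row.names = NULL)
  z <- z[!drop, , drop = FALSE]
  attr(z, "qcReport") <- report
  z
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the per-CpG age model in controls
#'
#' Ordinary least squares of each CpG on age, using control samples only.
#' The resulting intercept/slope pairs are later used by [ageResidualize()]
#' to adjust all samples (cases included), avoiding the collinearity of age
#' with disease status in age-imbalanced cohorts.
#'
#' @param cpgValues numeric matrix (CpGs x samples) or vector.
#' @param age numeric vector of ages.
#' @param controlMask logical vector: `TRUE` for control samples.
#' @return data.frame with columns `cpg`, `beta0`, `beta1`, of class
#'   `"ageAdjustModel"`.
#' @export
fitAgeModel <- function(cpgValues, age, controlMask) {
  if (is.null(dim(cpgValues)))
    cpgValues <- matrix(cpgValues, nrow = 1, dimnames = list(
      "cpg", names(cpgValues)))
  stopifnot(length(age) == ncol(cpgValues),
            length(controlMask) == ncol(cpgValues))
  use <- controlMask & !is.na(age)
  if (sum(use) < 3) stop("need at least 3 controls with non-missing age")
  a <- age[use]
  if (stats::var(a) == 0) stop("degenerate fit: all controls have the same age")
  Y <- cpgValues[, use, drop = FALSE]
  aC <- a - mean(a)
  beta1 <- as.vector(Y %*% aC) / sum(aC^2)
  beta0 <- rowMeans(Y) - beta1 * mean(a)
  ids <- rownames(cpgValues) %||% paste0("cpg", seq_len(nrow(cpgValues)))
  structure(data.frame(cpg = ids, beta0 = beta0,
                       beta1 = beta1, row.names = NULL),
            class = c("ageAdjustModel", "data.frame"),
            nControls = sum(use))
}

#' Remove the control-estimated age trend from all samples
#'
#' `adjusted = cpg - (beta0 + beta1 * age)`, applied to cases and controls
#' alike with the coefficients fitted by [fitAgeModel()]. Samples with
#' missing age are excluded with a warning.
#'
#' @param cpgValues matrix (CpGs x samples) or vector, same CpG order as the
#'   model.
#' @param age numeric vector of ages.
#' @param model an `"ageAdjustModel"` from [fitAgeModel()].
#' @return adjusted matrix; columns with missing age are dropped.
#' @export
ageResidualize <- function(cpgValues, age, model) {
  stopifnot(inherits(model, "ageAdjustModel"))
  if (is.null(dim(cpgValues)))
    cpgValues <- matrix(cpgValues, nrow = 1, dimnames = list(
      model$cpg[1], names(cpgValues)))
  stopifnot(nrow(cpgValues) == nrow(model))
  if (anyNA(age)) {
    warning(sum(is.na(age)), " sample(s) with missing age excluded")
    cpgValues <- cpgValues[, !is.na(age), drop = FALSE]
    age <- age[!is.na(age)]
  }
  cpgValues - (model$beta0 + outer(model$beta1, age))
}

#' Principal components of the genotype matrix
#'
#' Top eigenvectors of the genomic relationship matrix (equivalently, left
#' singular vectors of the centered, allele-frequency-scaled dosages), used
#' to correct association models for population stratification and
#' relatedness.
#'
#' @param study a \linkS4class{MultiOmicsStudy} (or a dosage matrix,
#'   SNPs x samples).
#' @param nPCs number of components.
#' @return samples x nPCs matrix of unit-norm eigenvectors.
#' @export
computeGenomicPCs <- function(study, nPCs = 3) {
  G <- if (is(study, "MultiOmicsStudy")) dosages(study) else study
  p <- rowMeans(G, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1
  if (sum(poly) < 100)
    stop("need at least 100 polymorphic SNPs for genomic PCs")
  G <- G[poly, , drop = FALSE]; p <- p[poly]
  Z <- (G - 2 * p) / sqrt(2 * p * (1 - p))
  ## right singular vectors of Z are the GRM eigenvectors
  sv <- svd(Z, nu = 0, nv = nPCs)
  pcs <- sv$v
  dimnames(pcs) <- list(colnames(G), paste0("gPC", seq_len(nPCs)))
  pcs
}

#' Attach analysis covariates and QC'd metabolites to a study
#'
#' Computes the three genomic principal components, the first two principal
#' components of the five measured cell counts, and the QC'd metabolite
#' z-score assay, storing them on the study object so that the association
#' stages can share them.
#'
#' @param study a \linkS4class{MultiOmicsStudy}.
#' @param maxMissing passed to [metaboliteQC()].
#' @return the augmented study: sample table gains `gPC1..gPC3`,
#'   `cellPC1..cellPC2`; the metabolite layer gains assay `"z"` (dropped
#'   metabolites removed) and a `qcReport` in its metadata.
#' @export
preprocessStudy <- function(study, maxMissing = 0.2) {
  stopifnot(is(study, "MultiOmicsStudy"))
  st <- study@samples
  if (ncol(study@genotypes) > 0) {
    gpc <- computeGenomicPCs(study)
    st[, colnames(gpc)] <- gpc
  }
  cells <- as.matrix(as.data.frame(
    st[, c("neutrophils", "basophils", "eosinophils", "monocytes",
           "lymphocytes")]))
  cpc <- stats::prcomp(cells, center = TRUE, scale. = TRUE)$x[, 1:2]
  st$cellPC1 <- cpc[, 1]; st$cellPC2 <- cpc[, 2]
  study@samples <- st
  ## keep layer colData in sync with the sample table
  for (layer in c("methylation", "genotypes", "metabolites")) {
    se <- slot(study, layer)
    if (ncol(se) > 0) {
      SummarizedExperiment::colData(se) <- st
      slot(study, layer) <- se
    }
  }
  if (nrow(study@metabolites) > 0) {
    z <- metaboliteQC(abundances(study), log = TRUE, maxMissing = maxMissing)
    keep <- rownames(z)
    se <- study@metabolites[keep, ]
    SummarizedExperiment::assay(se, "z") <- z
    S4Vectors::metadata(se)$qcReport <- attr(z, "qcReport")
    study@metabolites <- se
  }
  validObject(study)
  study
}

## Named covariate models.  Age handled by residualization (not a design
## column) in the EWAS-style models; included as a column where noted.
.covariateTags <- c("ewas_noBMI", "ewas_BMI", "meqtl", "cpg_metabolite",
                    "mwas", "cpg_hba1c")

#' Build the design matrix for a named analysis model
#'
#' Models:
#' \describe{
#'   \item{ewas_noBMI / ewas_BMI}{sex, two cell-count PCs, plate, batch,
#'     batch-by-sex interaction, well position, smoking-surrogate CpG value
#'     and three genomic PCs (plus BMI in the `_BMI` variant); age is handled
#'     by residualization, flagged in the return value.}
#'   \item{meqtl}{the EWAS covariates plus age, BMI and T2D status as
#'     columns (the kinship random effect is added by the mixed model).}
#'   \item{cpg_metabolite}{the EWAS covariates excluding BMI.}
#'   \item{mwas}{age, sex, BMI and three genomic PCs only.}
#'   \item{cpg_hba1c}{the EWAS covariates without T2D (which the EWAS models
#'     never contain as a covariate, T2D being their predictor).}
#' }
#' Factors that are constant on the analysed subset (e.g. batch inside a
#' single-batch cohort) are omitted, as are interactions involving them;
#' any remaining collinearity raises an error naming the offending columns.
#'
#' @param study a preprocessed \linkS4class{MultiOmicsStudy} (see
#'   [preprocessStudy()]; the genomic and cell-count PCs are computed on the
#'   fly if absent).
#' @param modelTag one of the model names above.
#' @param samples optional character vector of sample ids (default: all).
#' @return list with `design` (samples x k numeric matrix, no intercept,
#'   full rank), `ageResidualize` (logical), `age`, `controls` (logical,
#'   t2d == 0), `samples` and `tag`.
#' @export
buildCovariates <- function(study, modelTag, samples = NULL) {
  modelTag <- match.arg(modelTag, .covariateTags)
  st <- study@samples
  if (!"gPC1" %in% colnames(st) || !"cellPC1" %in% colnames(st)) {
    study <- preprocessStudy(study)
    st <- study@samples
  }
  if (is.null(samples)) samples <- rownames(st)
  st <- st[samples, ]
  df <- as.data.frame(st)
  df$sex <- factor(df$sex)
  for (f in c("plate", "batch", "well")) df[[f]] <- droplevels(factor(df[[f]]))
  smokeCpg <- "cg05575921"
  hasSmoke <- smokeCpg %in% rownames(study@methylation)
  if (hasSmoke)
    df$smokeSurrogate <- betaValues(study)[smokeCpg, samples]
  nlev <- function(f) nlevels(df[[f]])
  terms <- character()
  if (modelTag == "mwas") {
    terms <- c("age", "sex", "bmi", "gPC1", "gPC2", "gPC3")
  } else {
    terms <- c("sex", "cellPC1", "cellPC2")
    ## plates are typically nested in batches; the batch main effect is then
    ## absorbed by the plate indicators and must not enter twice
    batchNested <- nlev("plate") >= nlev("batch") &&
      all(rowSums(table(df$plate, df$batch) > 0) == 1)
    for (f in c("plate", "batch", "well"))
      if (nlev(f) >= 2 && !(f == "batch" && batchNested))
        terms <- c(terms, f)
    if (nlev("batch") >= 2 && nlev("sex") >= 2) {
      ## reference-coded batch-by-sex interaction, built explicitly so the
      ## batch margin (absorbed by plate) is not re-introduced
      male <- as.numeric(df$sex == levels(df$sex)[2])
      for (b in levels(df$batch)[-1]) {
        cn <- paste0("sex", levels(df$sex)[2], ".batch", b)
        df[[cn]] <- male * as.numeric(df$batch == b)
        terms <- c(terms, cn)
      }
    }
    if (hasSmoke) terms <- c(terms, "smokeSurrogate")
    terms <- c(terms, "gPC1", "gPC2", "gPC3")
    if (modelTag == "ewas_BMI") terms <- c(terms, "bmi")
    if (modelTag == "meqtl") terms <- c(terms, "age", "bmi", "t2d")
  }
  terms <- terms[vapply(terms, function(tm) {
    v <- strsplit(tm, ":", fixed = TRUE)[[1]][1]
    v %in% names(df)
  }, logical(1))]
  X <- stats::model.matrix(stats::reformulate(terms), data = df)
  X <- .pruneDesign(X)
  design <- X[, -1, drop = FALSE]
  rownames(design) <- samples
  list(design = design,
       ageResidualize = modelTag %in% c("ewas_noBMI", "ewas_BMI",
                                        "cpg_metabolite", "cpg_hba1c"),
       age = st$age, controls = st$t2d == 0,
       samples = samples, tag = modelTag)
}
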