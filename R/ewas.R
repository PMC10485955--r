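#' Linear association of one response with one predictor
#'
#' Ordinary least squares of `y` on `x` with covariates partialled by
#' inclusion in the design; returns the effect, SE, t and two-sided p for
#' the predictor of interest. This is the regression atom used by every
#' fixed-effect association stage.
#'
#' @param y numeric response vector.
#' @param x numeric predictor vector.
#' @param covariates optional numeric matrix (samples x k), no intercept.
#' @param xname label recorded for the predictor.
#' @return one-row data.frame: `feature`, `predictor`, `beta`, `se`, `t`,
#'   `p`, `df`, `n`.
#' @examples
#' set.seed(1)
#' x <- rnorm(50); y <- 0.5 * x + rnorm(50)
#' fitLinearAssoc(y, x)
#' @export
fitLinearAssoc <- function(y, x, covariates = NULL, xname = "x") {
  stopifnot(length(y) == length(x))
  if (stats::var(y, na.rm = TRUE) == 0) stop("response has zero variance")
  Y <- matrix(y, nrow = 1, dimnames = list("y", NULL))
  .fastAssoc(Y, x, covariates, xname = xname)
}

#' Epigenome-wide association of methylation with T2D in one cohort
#'
#' Fits, per CpG, the linear model `CpG ~ T2D + covariates` with the named
#' covariate model, after removing the control-estimated age trend from all
#' samples ([fitAgeModel()] in the cohort's controls, [ageResidualize()]
#' everywhere) — age is deliberately not a design column because it is
#' collinear with disease status in age-imbalanced cohorts.
#'
#' @param study a preprocessed \linkS4class{MultiOmicsStudy}.
#' @param cohort cohort label (matched against the `cohort` sample column),
#'   or `NULL` for all samples.
#' @param modelTag `"ewas_noBMI"` (default) or `"ewas_BMI"`.
#' @param transform `"beta"` analyses beta values (default); `"logit"`
#'   analyses logit-transformed methylation, the scale on which synthetic
#'   effects are planted.
#' @param cpgs optional CpG subset.
#' @return data.frame with one row per CpG: `cpg`, `chr`, `pos`, `cohort`,
#'   `model`, `beta`, `se`, `t`, `p`, `df`, `n`.
#' @export
runEwas <- function(study, cohort, modelTag = "ewas_noBMI",
                    transform = c("beta", "logit"), cpgs = NULL) {
  transform <- match.arg(transform)
  st <- study@samples
  ids <- if (is.null(cohort)) rownames(st) else
    rownames(st)[st$cohort == cohort]
  if (length(ids) == 0) stop("empty cohort: ", cohort)
  if (length(ids) < 10) stop("cohort too small for association testing")
  cov <- buildCovariates(study, modelTag, samples = ids)
  Y <- betaValues(study)[, ids, drop = FALSE]
  if (!is.null(cpgs)) Y <- Y[cpgs, , drop = FALSE]
  if (transform == "logit") Y <- .logit(Y)
  if (cov$ageResidualize) {
    am <- fitAgeModel(Y, cov$age, cov$controls)
    Y <- ageResidualize(Y, cov$age, am)
  }
  t2d <- st[ids, "t2d"]
  res <- .fastAssoc(Y, t2d, cov$design, xname = "t2d")
  rd <- SummarizedExperiment::rowData(study@methylation)[rownames(Y), ]
  data.frame(cpg = res$feature, chr = rd$chr, pos = rd$pos,
             cohort = if (is.null(cohort)) NA else cohort,
             model = modelTag,
             res[, c("beta", "se", "t", "p", "df", "n")],
             row.names = NULL)
}

#' Two-way discovery/replication selection
#'
#' Pass 1: CpGs with `p < alphaDisc` in table A are kept if their p-value in
#' table B is below `0.05 / k_A`, where `k_A` is the number of CpGs passing
#' the discovery threshold in A. Pass 2 swaps the roles. The output is the
#' union, each CpG tagged with its discovery cohort (ties broken towards the
#' more significant discovery).
#'
#' @param tableA,tableB association tables from [runEwas()] over the same
#'   CpG universe (columns `cpg`, `beta`, `p`).
#' @param alphaDisc discovery threshold (default 5.8e-8, the epigenome-wide
#'   significance level for the 850K array).
#' @return data.frame: `cpg`, `discoveryCohort` (1 = A, 2 = B),
#'   `discoveryP`, `replicationP`, `replicationThreshold`.
#' @export
twoWayDiscoveryReplication <- function(tableA, tableB, alphaDisc = 5.8e-8) {
  stopifnot(setequal(tableA$cpg, tableB$cpg))
  tableB <- tableB[match(tableA$cpg, tableB$cpg), ]
  onePass <- function(disc, rep, label) {
    k <- sum(disc$p < alphaDisc, na.rm = TRUE)
    if (k == 0) return(NULL)
    thr <- 0.05 / k
    sel <- which(disc$p < alphaDisc & rep$p < thr)
    if (!length(sel)) return(NULL)
    data.frame(cpg = disc$cpg[sel], discoveryCohort = label,
               discoveryP = disc$p[sel], replicationP = rep$p[sel],
               replicationThreshold = thr, row.names = NULL)
  }
  out <- rbind(onePass(tableA, tableB, 1L), onePass(tableB, tableA, 2L))
  if (is.null(out))
    return(data.frame(cpg = character(), discoveryCohort = integer(),
                      discoveryP = numeric(), replicationP = numeric(),
                      replicationThreshold = numeric()))
  ## a CpG discovered in both passes is tagged by its more significant one
  out <- out[order(out$discoveryP), ]
  out[!duplicated(out$cpg), , drop = FALSE]
}

#' Combine BMI-adjusted and unadjusted selections with a direction filter
#'
#' Union of the two model selections, then restriction to CpGs whose effect
#' has the same sign in both cohorts under the model that discovered them
#' (the direction-consistency step that takes the published funnel from 74
#' to 66 CpGs). Each retained CpG records which model(s) selected it.
#'
#' @param selectionNoBmi,selectionBmi outputs of
#'   [twoWayDiscoveryReplication()] for the two models.
#' @param tablesNoBmi,tablesBmi each a list of the two cohort association
#'   tables (`list(tableA, tableB)`) for the respective model.
#' @return data.frame: `cpg`, `models` (`"noBMI"`, `"BMI"` or `"both"`),
#'   `discoveryCohort`, `betaCohort1`, `betaCohort2`, `directionConsistent`;
#'   only direction-consistent CpGs are returned. The pre-filter union size
#'   is stored in attribute `"nUnion"`.
#' @export
combineModels <- function(selectionNoBmi, selectionBmi,
                          tablesNoBmi, tablesBmi) {
  all_cpgs <- union(selectionNoBmi$cpg, selectionBmi$cpg)
  if (!length(all_cpgs))
    return(structure(data.frame(cpg = character(), models = character(),
                                discoveryCohort = integer(),
                                betaCohort1 = numeric(),
                                betaCohort2 = numeric(),
                                directionConsistent = logical()),
                     nUnion = 0L))
  rows <- lapply(all_cpgs, function(cg) {
    inNo <- cg %in% selectionNoBmi$cpg
    inB <- cg %in% selectionBmi$cpg
    model <- if (inNo && inB) "both" else if (inNo) "noBMI" else "BMI"
    ## sign check uses the model that discovered the CpG (noBMI if both)
    tabs <- if (inNo) tablesNoBmi else tablesBmi
    sel <- if (inNo) selectionNoBmi else selectionBmi
    b1 <- tabs[[1]]$beta[match(cg, tabs[[1]]$cpg)]
    b2 <- tabs[[2]]$beta[match(cg, tabs[[2]]$cpg)]
    data.frame(cpg = cg, models = model,
               discoveryCohort = sel$discoveryCohort[match(cg, sel$cpg)],
               betaCohort1 = b1, betaCohort2 = b2,
               directionConsistent = sign(b1) == sign(b2))
  })
  out <- do.call(rbind, rows)
  structure(out[out$directionConsistent, , drop = FALSE],
            nUnion = length(all_cpgs))
}
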