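#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Simulation configuration for a synthetic multi-omics cohort
#'
#' Holds the sizes, rates, planted effects and noise scales that
#' [simulateCohort()] turns into a study object with recorded ground truth.
#' Use the [simulationConfig()] constructor, which supplies the default study
#' conditions (a three-cohort design of 1026 samples with 43.5% cases) and
#' validates every field.
#'
#' @slot nSamples,nCpgs,nSnps,nMetabolites positive integer sizes.
#' @slot caseFraction proportion of T2D cases in (0,1).
#' @slot nFamilies,familySize number of sibships and siblings per sibship;
#'   remaining samples are unrelated.
#' @slot mafRange minor-allele-frequency interval within (0, 0.5].
#' @slot snpCpg data.frame (snp, cpg, beta): additive dosage effects on the
#'   logit-methylation scale.
#' @slot t2dCpg data.frame (cpg, beta): case/control shifts on the
#'   logit-methylation scale.
#' @slot t2dMetabolite data.frame (metabolite, beta): case/control shifts in
#'   SD units of the log-metabolite.
#' @slot cpgMetabolite data.frame (cpg, metabolite, beta): metabolite shift in
#'   SD units per SD of the CpG's logit value.
#' @slot ggmEdgeDensity edge density of the metabolite partial-correlation
#'   graph, in (0,1).
#' @slot ggmPartialCor magnitude of planted partial correlations.
#' @slot methNoiseSd residual SD of logit methylation.
#' @slot metaboliteLogSd SD of log-scale metabolite abundance.
#' @slot covariateEffectScale multiplier on the random covariate loadings
#'   (age, sex, batch, plate, well, cell composition) of every CpG; set 0 for
#'   a global-null panel.
#' @slot missingRate random missingness rate of the raw metabolite matrix.
#' @slot ancestryFst Balding-Nichols divergence of the two simulated ancestry
#'   components.
#' @slot ageCollinearT2d make cases older than controls in the two EWAS
#'   cohorts (the study design the age-residual adjustment exists for); set
#'   `FALSE` for a global-null cohort in which age is exchangeable with
#'   disease status.
#' @slot seed integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#' @seealso [simulationConfig()], [simulateCohort()]
#' @export
setClass("SimulationConfig", representation(
  nSamples = "integer", nCpgs = "integer", nSnps = "integer",
  nMetabolites = "integer", caseFraction = "numeric", nFamilies = "integer",
  familySize = "integer", mafRange = "numeric",
  snpCpg = "data.frame", t2dCpg = "data.frame",
  t2dMetabolite = "data.frame", cpgMetabolite = "data.frame",
  ggmEdgeDensity = "numeric", ggmPartialCor = "numeric",
  methNoiseSd = "numeric", metaboliteLogSd = "numeric",
  covariateEffectScale = "numeric", missingRate = "numeric",
  ancestryFst = "numeric", ageCollinearT2d = "logical", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  counts <- c(nSamples = object@nSamples, nCpgs = object@nCpgs,
              nSnps = object@nSnps, nMetabolites = object@nMetabolites)
  if (any(is.na(counts)) || any(counts <= 0L))
    msg <- c(msg, "all counts (nSamples, nCpgs, nSnps, nMetabolites) must be > 0")
  if (!is.na(object@caseFraction) &&
      (object@caseFraction <= 0 || object@caseFraction >= 1))
    msg <- c(msg, "caseFraction must lie in (0,1)")
  mr <- object@mafRange
  if (length(mr) != 2 || any(is.na(mr)) || mr[1] <= 0 || mr[2] > 0.5 ||
      mr[1] > mr[2])
    msg <- c(msg, "mafRange must be an interval within (0, 0.5]")
  if (object@ggmEdgeDensity <= 0 || object@ggmEdgeDensity >= 1)
    msg <- c(msg, "ggmEdgeDensity must lie in (0,1)")
  if (object@nFamilies < 0L || object@familySize < 0L)
    msg <- c(msg, "nFamilies and familySize must be >= 0")
  if (object@nFamilies * object@familySize > object@nSamples)
    msg <- c(msg, "family samples exceed nSamples")
  if (object@methNoiseSd <= 0 || object@metaboliteLogSd <= 0)
    msg <- c(msg, "noise SDs must be positive")
  if (length(msg)) msg else TRUE
})

#' Container for a multi-omics study
#'
#' Bundles the per-sample phenotype table with up to three
#' \linkS4class{SummarizedExperiment} layers (methylation beta values,
#' genotype dosages, metabolite abundances) sharing one sample universe.
#' Synthetic studies additionally carry the generator's ground truth (planted
#' effect tables, the expected kinship matrix and the metabolite precision
#' matrix) for recovery testing.
#'
#' @slot samples `DataFrame` of per-sample phenotypes and technical
#'   covariates (t2d, age, sex, bmi, hba1c, five cell counts, plate, well,
#'   batch, cohort, genoBatch, metBatch, ...).
#' @slot methylation SummarizedExperiment, CpGs x samples, assay `"beta"`,
#'   rowData chr/pos.
#' @slot genotypes SummarizedExperiment, SNPs x samples, assay `"dosage"`,
#'   rowData chr/pos/ref/alt.
#' @slot metabolites SummarizedExperiment, metabolites x samples, assay
#'   `"abundance"`, rowData pathway/subpathway.
#' @slot groundTruth list; empty for real data.
#' @export
setClass("MultiOmicsStudy", representation(
  samples = "DataFrame",
  methylation = "SummarizedExperiment",
  genotypes = "SummarizedExperiment",
  metabolites = "SummarizedExperiment",
  groundTruth = "list"))

setValidity("MultiOmicsStudy", function(object) {
  ids <- rownames(object@samples)
  if (is.null(ids)) return("samples must have rownames (sample ids)")
  for (layer in c("methylation", "genotypes", "metabolites")) {
    se <- slot(object, layer)
    if (ncol(se) == 0L) next
    if (!identical(colnames(se), ids))
      return(sprintf("column names of %s do not match the sample table", layer))
  }
  TRUE
})

#' Per-SNP summary statistics for two-sample Mendelian randomization
#'
#' One row per instrument: the SNP's effect on the exposure (a CpG's
#' methylation) and on the outcome (e.g. HbA1c), each with its standard error.
#'
#' @slot snps character SNP identifiers.
#' @slot bx,bxse SNP-to-exposure effects and standard errors.
#' @slot by,byse SNP-to-outcome effects and standard errors.
#' @seealso [mrInput()], [mlSingleSnp()], [ivwEstimate()]
#' @export
setClass("MRInput", representation(
  snps = "character", bx = "numeric", bxse = "numeric",
  by = "numeric", byse = "numeric"))

setValidity("MRInput", function(object) {
  n <- length(object@bx)
  if (!all(lengths(list(object@snps, object@bxse, object@by,
                        object@byse)) == n))
    return("all summary-statistic vectors must have equal length")
  if (any(object@bxse <= 0) || any(object@byse <= 0))
    return("standard errors must be strictly positive")
  TRUE
})

#' Result of a Mendelian randomization estimator
#'
#' @slot estimate causal estimate, outcome units per exposure unit.
#' @slot se standard error of the estimate.
#' @slot ci 95% confidence interval, `estimate +/- 1.96 se`.
#' @slot p two-sided normal p-value.
#' @slot method one of `"wald"`, `"maxlik"`, `"ivw"`.
#' @slot nSnps number of instruments combined.
#' @slot Q,Qp,I2 Cochran's Q across instruments, its chi-square p-value and
#'   the I-squared percentage (`NA` for single-SNP methods).
#' @export
setClass("MRResult", representation(
  estimate = "numeric", se = "numeric", ci = "numeric", p = "numeric",
  method = "character", nSnps = "integer",
  Q = "numeric", Qp = "numeric", I2 = "numeric"))

#' Tripartite multi-omics network
#'
#' Typed graph over SNP, CpG and metabolite nodes whose edges are meQTL
#' associations (`meqtl`), CpG-metabolite meta-analysis associations
#' (`cpg_met`) and metabolite partial correlations (`met_met`).
#'
#' @slot nodes data.frame with columns `id`, `layer` (snp/cpg/metabolite).
#' @slot edges data.frame with columns `from`, `to`, `type`, `weight`, `p`.
#' @seealso [assembleNetwork()], [componentStats()], [exportSif()]
#' @export
setClass("OmicsNetwork", representation(
  nodes = "data.frame", edges = "data.frame"))

setValidity("OmicsNetwork", function(object) {
  nd <- object@nodes; ed <- object@edges
  if (!all(c("id", "layer") %in% names(nd)))
    return("nodes need columns id, layer")
  if (!all(c("from", "to", "type", "weight", "p") %in% names(ed)))
    return("edges need columns from, to, type, weight, p")
  if (anyDuplicated(nd$id)) return("duplicate node ids")
  if (nrow(ed)) {
    if (!all(c(ed$from, ed$to) %in% nd$id))
      return("edge endpoints missing from node table")
    if (any(ed$from == ed$to)) return("self-edges are not allowed")
    lay <- stats::setNames(nd$layer, nd$id)
    type_ok <- c(meqtl_from = "snp", meqtl_to = "cpg",
                 cpg_met_from = "cpg", cpg_met_to = "metabolite",
                 met_met_from = "metabolite", met_met_to = "metabolite")
    for (ty in unique(ed$type)) {
      sel <- ed$type == ty
      f <- type_ok[paste0(ty, "_from")]; t <- type_ok[paste0(ty, "_to")]
      if (is.na(f)) return(sprintf("unknown edge type '%s'", ty))
      if (!all(lay[ed$from[sel]] == f) || !all(lay[ed$to[sel]] == t))
        return(sprintf("edge type '%s' joins wrong layers", ty))
    }
  }
  TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nSamples, "samples,",
      object@nCpgs, "CpGs,", object@nSnps, "SNPs,",
      object@nMetabolites, "metabolites\n")
  cat("  case fraction", object@caseFraction, "| families",
      object@nFamilies, "x", object@familySize, "| seed", object@seed, "\n")
  cat("  planted effects: snp->cpg", nrow(object@snpCpg),
      "| t2d->cpg", nrow(object@t2dCpg),
      "| t2d->met", nrow(object@t2dMetabolite),
      "| cpg->met", nrow(object@cpgMetabolite), "\n")
})

setMethod("show", "MultiOmicsStudy", function(object) {
  cat("MultiOmicsStudy with", nrow(object@samples), "samples\n")
  cat("  methylation:", nrow(object@methylation), "CpGs\n")
  cat("  genotypes:  ", nrow(object@genotypes), "SNPs\n")
  cat("  metabolites:", nrow(object@metabolites), "metabolites\n")
  if (length(object@groundTruth))
    cat("  synthetic study with recorded ground truth\n")
})

setMethod("show", "MRInput", function(object) {
  cat("MRInput with", length(object@bx), "instrument(s):",
      paste(object@snps, collapse = ", "), "\n")
})

setMethod("show", "MRResult", function(object) {
  cat(sprintf("MRResult [%s, %d SNP(s)]: estimate %.4g (SE %.3g), CI [%.4g, %.4g], p = %.3g\n",
              object@method, object@nSnps, object@estimate, object@se,
              object@ci[1], object@ci[2], object@p))
  if (!is.na(object@Q))
    cat(sprintf("  heterogeneity: Q = %.4g (p = %.3g), I2 = %.1f%%\n",
                object@Q, object@Qp, object@I2))
})

setMethod("show", "OmicsNetwork", function(object) {
  cat("OmicsNetwork:", nrow(object@nodes), "nodes,",
      nrow(object@edges), "edges\n")
  if (nrow(object@nodes))
    print(table(object@nodes$layer))
})
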