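#' Pipeline configuration
#'
#' Assembles (and validates) the configuration consumed by
#' [runPipeline()]: either a simulation block (turned into a
#' \linkS4class{SimulationConfig}) or a `studyDir` previously written by
#' [writeStudy()], plus the stage thresholds.
#'
#' @param simulate list of arguments for [simulationConfig()], or `NULL`
#'   when `studyDir` is given.
#' @param studyDir directory of input tables (alternative to `simulate`).
#' @param alphaDisc EWAS discovery threshold (default 5.8e-8).
#' @param alphaMeqtl meQTL discovery threshold (default 8.7e-10).
#' @param locusWindow meQTL locus-replication window in bp (default 5e5).
#' @param mwasSplit MWAS discovery fraction (default 0.7).
#' @param transform methylation scale used by the association stages.
#' @param seed master seed for the stage-level randomness (cohort splits).
#' @return a validated configuration list of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(simulate = list(), studyDir = NULL,
                           alphaDisc = 5.8e-8, alphaMeqtl = 8.7e-10,
                           locusWindow = 5e5, mwasSplit = 0.7,
                           transform = "beta", seed = 1L) {
  thresholds <- c(alphaDisc = alphaDisc, alphaMeqtl = alphaMeqtl,
                  mwasSplit = mwasSplit)
  if (any(thresholds <= 0 | thresholds > 1))
    stop("thresholds must lie in (0, 1]")
  if (locusWindow <= 0) stop("locusWindow must be positive")
  if (!is.null(studyDir) && !dir.exists(studyDir))
    stop("studyDir does not exist: ", studyDir)
  structure(list(simulate = simulate, studyDir = studyDir,
                 alphaDisc = alphaDisc, alphaMeqtl = alphaMeqtl,
                 locusWindow = locusWindow, mwasSplit = mwasSplit,
                 transform = transform, seed = as.integer(seed)),
            class = "pipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are the arguments of
#'   [pipelineConfig()].
#' @return a `"pipelineConfig"`.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(pipelineConfig, yaml::read_yaml(path))
}

.writeStageManifest <- function(dir, stage, seed, thresholds, counts,
                                files) {
  files <- files[file.exists(files)]
  md5 <- tools::md5sum(files)
  names(md5) <- basename(files)
  manifest <- list(stage = stage, seed = seed, thresholds = thresholds,
                   counts = counts, files = as.list(md5))
  jsonlite::write_json(manifest,
                       file.path(dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, na = "null")
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full multi-omics pipeline
#'
#' Executes simulate (or load) -> preprocess -> EWAS (both BMI models,
#' two-way discovery/replication, direction filter) -> meQTL (kinship mixed
#' model on the genotyping-batch split, locus-window replication) -> MWAS ->
#' CpG-metabolite two-batch meta-analysis with heterogeneity exclusion ->
#' two-sample MR of the top meQTL CpG against HbA1c -> network assembly.
#' Every stage writes its result TSV plus a JSON manifest (seed, thresholds,
#' counts, output md5 sums) into `outDir`; a rerun with the same
#' configuration reproduces identical outputs.
#'
#' @param config a `"pipelineConfig"` (see [pipelineConfig()]).
#' @param outDir output directory.
#' @return invisibly, a list with the stage results.
#' @export
runPipeline <- function(config, outDir) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  res <- list()
  tryCatch({
    ## ---- simulate / load -------------------------------------------------
    if (!is.null(config$studyDir)) {
      study <- readStudy(config$studyDir)
    } else {
      simArgs <- config$simulate
      simCfg <- do.call(simulationConfig, simArgs)
      study <- simulateCohort(simCfg)
      writeStudy(study, file.path(outDir, "study"))
    }
    .writeStageManifest(outDir, "simulate", config$seed, list(),
                        list(nSamples = nrow(study@samples),
                             nCpgs = nrow(study@methylation),
                             nSnps = nrow(study@genotypes),
                             nMetabolites = nrow(study@metabolites)),
                        list.files(file.path(outDir, "study"),
                                   full.names = TRUE))
    ## ---- preprocess ------------------------------------------------------
    stage <- "preprocess"
    study <- preprocessStudy(study)
    qc <- S4Vectors::metadata(study@metabolites)$qcReport
    f <- .writeTsv(qc, file.path(outDir, "metabolite_qc.tsv"))
    .writeStageManifest(outDir, "preprocess", config$seed, list(),
                        list(metabolitesKept = sum(!qc$dropped)), f)
    res$study <- study
    ## ---- ewas ------------------------------------------------------------
    stage <- "ewas"
    tabs <- list()
    for (model in c("ewas_noBMI", "ewas_BMI"))
      for (coh in 1:2)
        tabs[[paste(model, coh, sep = ".")]] <-
          runEwas(study, cohort = coh, modelTag = model,
                  transform = config$transform)
    selNo <- twoWayDiscoveryReplication(tabs$ewas_noBMI.1, tabs$ewas_noBMI.2,
                                        alphaDisc = config$alphaDisc)
    selB <- twoWayDiscoveryReplication(tabs$ewas_BMI.1, tabs$ewas_BMI.2,
                                       alphaDisc = config$alphaDisc)
    final <- combineModels(selNo, selB,
                           list(tabs$ewas_noBMI.1, tabs$ewas_noBMI.2),
                           list(tabs$ewas_BMI.1, tabs$ewas_BMI.2))
    ewasAll <- do.call(rbind, tabs)
    f <- c(.writeTsv(ewasAll, file.path(outDir, "ewas_associations.tsv")),
           .writeTsv(final, file.path(outDir, "ewas_selected.tsv")))
    .writeStageManifest(outDir, "ewas", config$seed,
                        list(alphaDisc = config$alphaDisc),
                        list(selectedNoBmi = nrow(selNo),
                             selectedBmi = nrow(selB),
                             union = attr(final, "nUnion"),
                             directionConsistent = nrow(final)), f)
    res$ewas <- list(tables = tabs, selection = final)
    ## ---- meqtl -----------------------------------------------------------
    stage <- "meqtl"
    st <- sampleTable(study)
    discIds <- rownames(st)[st$genoBatch == 1]
    repIds <- rownames(st)[st$genoBatch == 2]
    cpgSet <- final$cpg
    pairs <- runMeqtl(study, cpgSet, samples = discIds,
                      alpha = config$alphaMeqtl,
                      transform = config$transform)
    repPairs <- runMeqtl(study, cpgSet, samples = repIds, alpha = 1,
                         transform = config$transform)
    if (nrow(pairs))
      pairs <- locusReplicate(pairs, repPairs, window = config$locusWindow)
    f <- .writeTsv(pairs, file.path(outDir, "meqtl_pairs.tsv"))
    .writeStageManifest(outDir, "meqtl", config$seed,
                        list(alphaMeqtl = config$alphaMeqtl,
                             locusWindow = config$locusWindow),
                        list(pairs = nrow(pairs),
                             replicated = sum(pairs$replicated %||% logical()),
                             cis = sum(pairs$label == "cis")), f)
    res$meqtl <- pairs
    ## ---- metabolome ------------------------------------------------------
    stage <- "metabolome"
    mwas <- runMwas(study, splitFraction = config$mwasSplit,
                    seed = .deriveSeed(config$seed, 71L))
    cm <- meta <- sel <- NULL
    if (length(mwas$significant) && nrow(final)) {
      cm1 <- cpgMetaboliteBatch(study, final$cpg, mwas$significant,
                                batch = 1, transform = config$transform)
      cm2 <- cpgMetaboliteBatch(study, final$cpg, mwas$significant,
                                batch = 2, transform = config$transform)
      meta <- inverseVarianceMeta(cm1, cm2)
      sel <- selectCpgMetabolite(meta, nrow(final),
                                 length(mwas$significant))
    }
    f <- c(.writeTsv(mwas$discovery, file.path(outDir, "mwas_discovery.tsv")),
           .writeTsv(mwas$replication,
                     file.path(outDir, "mwas_replication.tsv")))
    if (!is.null(meta))
      f <- c(f, .writeTsv(meta, file.path(outDir, "cpg_metabolite_meta.tsv")))
    .writeStageManifest(outDir, "metabolome", config$seed,
                        list(mwasSplit = config$mwasSplit),
                        list(mwas = as.list(mwas$counts),
                             cpgMetPre = sel$nPreFilter %||% 0L,
                             cpgMetFinal = sel$nFinal %||% 0L), f)
    res$mwas <- mwas; res$cpgMetabolite <- sel
    ## ---- mr --------------------------------------------------------------
    stage <- "mr"
    mrTab <- NULL
    if (nrow(pairs)) {
      topCpg <- pairs$cpg[which.min(pairs$p)]
      inst <- utils::head(pairs[pairs$cpg == topCpg, ][
        order(pairs$p[pairs$cpg == topCpg]), ], 3)
      G <- dosages(study)[inst$snp, , drop = FALSE]
      cov <- buildCovariates(study, "mwas")
      outc <- lapply(inst$snp, function(s)
        fitLinearAssoc(st$hba1c, G[s, ], cov$design, xname = s))
      outc <- do.call(rbind, outc)
      mri <- mrInput(inst$snp, bx = inst$beta, bxse = inst$se,
                     by = outc$beta, byse = outc$se)
      fits <- lapply(seq_along(inst$snp), function(j)
        mlSingleSnp(inst$beta[j], inst$se[j], outc$beta[j], outc$se[j]))
      mrTab <- data.frame(
        cpg = topCpg, snp = inst$snp, method = "maxlik",
        estimate = vapply(fits, slot, numeric(1), "estimate"),
        se = vapply(fits, slot, numeric(1), "se"),
        p = vapply(fits, slot, numeric(1), "p"))
      if (length(inst$snp) >= 2) {
        iv <- ivwEstimate(mri)
        mrTab <- rbind(mrTab, data.frame(
          cpg = topCpg, snp = paste(inst$snp, collapse = ","),
          method = "ivw", estimate = iv@estimate, se = iv@se, p = iv@p))
      }
      f <- .writeTsv(mrTab, file.path(outDir, "mr_results.tsv"))
      .writeStageManifest(outDir, "mr", config$seed, list(),
                          list(instruments = nrow(inst)), f)
    }
    res$mr <- mrTab
    ## ---- network ---------------------------------------------------------
    stage <- "network"
    metSel <- if (!is.null(sel) && nrow(sel$selected))
      unique(sel$selected$metabolite) else character()
    net <- NULL
    if (length(metSel) >= 2 || nrow(pairs) || !is.null(sel)) {
      Z <- SummarizedExperiment::assay(study@metabolites, "z")
      cov <- buildCovariates(study, "mwas")
      resid <- residualizeMetabolites(Z, cov$design)
      mm <- partialCorrelationNetwork(resid, naAction = "meanImpute")
      mm <- mm[mm$met1 %in% metSel | mm$met2 %in% metSel, , drop = FALSE]
      net <- assembleNetwork(
        meqtlPairs = if (nrow(pairs)) pairs else NULL,
        cpgMetPairs = if (!is.null(sel) && nrow(sel$selected))
          sel$selected else NULL,
        metMetEdges = if (nrow(mm)) mm else NULL)
      comp <- componentStats(net)
      exportSif(net, file.path(outDir, "network.sif"))
      exportGraphML(net, file.path(outDir, "network.graphml"))
      exportNetworkTables(net, file.path(outDir, "network"))
      f <- .writeTsv(comp, file.path(outDir, "network_components.tsv"))
      .writeStageManifest(outDir, "network", config$seed, list(),
                          list(nodes = nrow(net@nodes),
                               edges = nrow(net@edges),
                               components = nrow(comp)), f)
    }
    res$network <- net
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
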