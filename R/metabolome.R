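#' Metabolome-wide association with T2D, with Bonferroni
#' discovery/replication
#'
#' Samples are split at random into discovery and replication fractions.
#' Each QC'd metabolite is regressed on T2D status with the `mwas` covariate
#' set (age, sex, BMI, three genomic PCs). Discovery keeps metabolites at
#' `p < 0.05 / m_total`; replication keeps those at `p < 0.05 / m_sig` with
#' the same effect sign.
#'
#' @param study a preprocessed \linkS4class{MultiOmicsStudy} (metabolite
#'   layer must carry the QC'd `"z"` assay).
#' @param splitFraction discovery fraction (default 0.7).
#' @param seed seed for the random split.
#' @return list: `discovery` and `replication` association tables,
#'   `significant` (replicated metabolite ids), `counts`
#'   (`tested`/`discovered`/`replicated`), `thresholds`.
#' @export
runMwas <- function(study, splitFraction = 0.7, seed = 1L) {
  se <- study@metabolites
  if (!"z" %in% SummarizedExperiment::assayNames(se))
    stop("metabolite layer has no QC'd assay; run preprocessStudy() first")
  Z <- SummarizedExperiment::assay(se, "z")
  st <- study@samples
  ids <- rownames(st)
  set.seed(as.integer(seed))
  nd <- round(length(ids) * splitFraction)
  if (nd == 0 || nd == length(ids))
    stop("split produces an empty cohort")
  disc <- sample(ids, nd)
  repl <- setdiff(ids, disc)
  fitHalf <- function(sub) {
    cov <- buildCovariates(study, "mwas", samples = sub)
    res <- .fastAssoc(Z[, sub, drop = FALSE], st[sub, "t2d"],
                      cov$design, xname = "t2d")
    names(res)[names(res) == "feature"] <- "metabolite"
    res
  }
  dTab <- fitHalf(disc)
  rTab <- fitHalf(repl)
  m <- nrow(Z)
  thrD <- 0.05 / m
  sig <- dTab$metabolite[dTab$p < thrD]
  thrR <- if (length(sig)) 0.05 / length(sig) else NA
  replicated <- character()
  if (length(sig)) {
    rSub <- rTab[match(sig, rTab$metabolite), ]
    dSub <- dTab[match(sig, dTab$metabolite), ]
    keep <- rSub$p < thrR & sign(rSub$beta) == sign(dSub$beta)
    replicated <- sig[keep]
  }
  list(discovery = dTab, replication = rTab, significant = replicated,
       counts = c(tested = m, discovered = length(sig),
                  replicated = length(replicated)),
       thresholds = c(discovery = thrD, replication = thrR))
}

#' CpG-metabolite associations within one metabolomics batch
#'
#' For every (CpG, metabolite) combination, fits the linear model with the
#' CpG as dependent variable and the metabolite as predictor, using the
#' EWAS covariates excluding BMI and the control-fitted age residualization
#' — the T2D EWAS model with the metabolite in place of disease status.
#'
#' @param study a preprocessed \linkS4class{MultiOmicsStudy}.
#' @param cpgs CpG ids to test.
#' @param metaboliteIds metabolite ids to test (must be in the QC'd assay).
#' @param batch metabolomics batch label, matched against the `metBatch`
#'   sample column (`NULL` for all samples).
#' @param transform methylation scale, `"beta"` or `"logit"`.
#' @return data.frame: `cpg`, `metabolite`, `batch`, `beta`, `se`, `t`, `p`,
#'   `df`, `n`.
#' @export
cpgMetaboliteBatch <- function(study, cpgs, metaboliteIds, batch = NULL,
                               transform = c("beta", "logit")) {
  transform <- match.arg(transform)
  st <- study@samples
  ids <- if (is.null(batch)) rownames(st) else
    rownames(st)[st$metBatch == batch]
  if (!length(ids)) stop("no samples in metabolomics batch ", batch)
  se <- study@metabolites
  if (!"z" %in% SummarizedExperiment::assayNames(se))
    stop("metabolite layer has no QC'd assay; run preprocessStudy() first")
  Z <- SummarizedExperiment::assay(se, "z")[metaboliteIds, ids, drop = FALSE]
  cov <- buildCovariates(study, "cpg_metabolite", samples = ids)
  Y <- betaValues(study)[cpgs, ids, drop = FALSE]
  if (transform == "logit") Y <- .logit(Y)
  am <- fitAgeModel(Y, cov$age, cov$controls)
  Y <- ageResidualize(Y, cov$age, am)
  out <- lapply(metaboliteIds, function(met) {
    res <- .fastAssoc(Y, Z[met, ], cov$design, xname = met)
    data.frame(cpg = res$feature, metabolite = met,
               batch = if (is.null(batch)) NA else batch,
               res[, c("beta", "se", "t", "p", "df", "n")],
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Fixed-effect inverse-variance meta-analysis of two batches
#'
#' STDERR-scheme weights `w_i = 1 / SE_i^2`; meta effect
#' `sum(w b) / sum(w)`, meta SE `sqrt(1 / sum(w))`, two-sided normal
#' p-value; Cochran's `Q = sum(w (b - b_meta)^2)` with a chi-square p-value
#' on `n_batches - 1` df and `I2 = max(0, (Q - df) / Q) * 100`. Pairs with
#' heterogeneity `Qp < 0.05` are flagged `excluded` (with two batches this
#' is exactly equivalent to `I2 > 73.96`).
#'
#' @param recordsBatch1,recordsBatch2 association tables sharing key columns
#'   `cpg` and `metabolite` (or a single `feature`/`metabolite` key) and
#'   stat columns `beta`, `se`.
#' @return data.frame with per-batch stats, `beta` (meta), `se`, `z`, `p`,
#'   `Q`, `Qp`, `I2`, `excluded`.
#' @export
inverseVarianceMeta <- function(recordsBatch1, recordsBatch2) {
  keys <- intersect(c("cpg", "metabolite", "feature"),
                    intersect(names(recordsBatch1), names(recordsBatch2)))
  if (!length(keys)) stop("no shared key columns between batches")
  k1 <- do.call(paste, c(recordsBatch1[keys], sep = "\r"))
  k2 <- do.call(paste, c(recordsBatch2[keys], sep = "\r"))
  common <- intersect(k1, k2)
  if (!length(common)) stop("no matching pairs across batches")
  i1 <- match(common, k1); i2 <- match(common, k2)
  b <- cbind(recordsBatch1$beta[i1], recordsBatch2$beta[i2])
  s <- cbind(recordsBatch1$se[i1], recordsBatch2$se[i2])
  if (any(s <= 0)) stop("standard errors must be strictly positive")
  w <- 1 / s^2
  sw <- rowSums(w)
  bMeta <- rowSums(w * b) / sw
  seMeta <- sqrt(1 / sw)
  z <- bMeta / seMeta
  Q <- rowSums(w * (b - bMeta)^2)
  dfQ <- ncol(b) - 1
  Qp <- stats::pchisq(Q, df = dfQ, lower.tail = FALSE)
  I2 <- pmax(0, (Q - dfQ) / Q) * 100
  I2[Q == 0] <- 0
  out <- recordsBatch1[i1, keys, drop = FALSE]
  out$beta1 <- b[, 1]; out$se1 <- s[, 1]
  out$beta2 <- b[, 2]; out$se2 <- s[, 2]
  out$beta <- bMeta; out$se <- seMeta; out$z <- z
  out$p <- 2 * stats::pnorm(-abs(z))
  out$Q <- Q; out$Qp <- Qp; out$I2 <- I2
  out$excluded <- Qp < 0.05
  rownames(out) <- NULL
  out
}

#' Select significant CpG-metabolite pairs from the meta-analysis
#'
#' Keeps pairs with meta p-value below `0.05 / (nCpgs * nMetabolites)`, then
#' drops pairs flagged for heterogeneity; both counts are reported.
#'
#' @param metaTable output of [inverseVarianceMeta()].
#' @param nCpgs,nMetabolites Bonferroni denominator factors (numbers of
#'   CpGs and metabolites tested).
#' @return list: `selected` (final table), `nPreFilter`,
#'   `nHeterogeneityExcluded`, `nFinal`, `threshold`.
#' @export
selectCpgMetabolite <- function(metaTable, nCpgs, nMetabolites) {
  thr <- 0.05 / (nCpgs * nMetabolites)
  pre <- metaTable[!is.na(metaTable$p) & metaTable$p < thr, , drop = FALSE]
  final <- pre[!pre$excluded, , drop = FALSE]
  list(selected = final, nPreFilter = nrow(pre),
       nHeterogeneityExcluded = nrow(pre) - nrow(final),
       nFinal = nrow(final), threshold = thr)
}
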