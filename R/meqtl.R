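#' Genomic relationship matrix from dosages
#'
#' Centered, allele-frequency-scaled genotypes averaged over SNPs:
#' `K = Z'Z / m` with `Z[i,j] = (g[i,j] - 2 p_i) / sqrt(2 p_i (1 - p_i))`.
#' The diagonal is approximately 1 plus the inbreeding coefficient; sibling
#' pairs sit near 0.5. Negative eigenvalues (possible when samples outnumber
#' SNPs) are bent to 1e-6.
#'
#' @param genotypes dosage matrix (SNPs x samples), a genotype
#'   SummarizedExperiment, or a \linkS4class{MultiOmicsStudy}.
#' @return symmetric positive semi-definite samples x samples matrix.
#' @export
estimateKinship <- function(genotypes) {
  G <- if (is(genotypes, "MultiOmicsStudy")) dosages(genotypes)
       else if (is(genotypes, "SummarizedExperiment"))
         SummarizedExperiment::assay(genotypes, "dosage")
       else genotypes
  p <- rowMeans(G, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all SNPs are monomorphic")
  if (sum(poly) < 100)
    stop("need at least 100 polymorphic SNPs to estimate kinship")
  G <- G[poly, , drop = FALSE]; p <- p[poly]
  Z <- (G - 2 * p) / sqrt(2 * p * (1 - p))
  K <- crossprod(Z) / nrow(Z)
  pd <- tryCatch({ chol(K); TRUE }, error = function(e) FALSE)
  if (!pd) {
    ev <- eigen(K, symmetric = TRUE)
    if (min(ev$values) < 0) {
      ev$values[ev$values < 1e-6] <- 1e-6
      K <- ev$vectors %*% (ev$values * t(ev$vectors))
      dimnames(K) <- list(colnames(Z), colnames(Z))
    }
  }
  K
}

#' Fit the polygenic mixed model by profile maximum likelihood
#'
#' Maximizes the Gaussian log-likelihood of
#' `y ~ N(X b, s2g * 2K + s2e * I)` over the heritability ratio
#' `h2 = s2g / (s2g + s2e)` on the spectral decomposition of `2K`: for each
#' `h2` the GLS coefficients and the profiled total variance are closed
#' form, so the search is one-dimensional. When the likelihood is flat in
#' `h2` (e.g. `K = I`), the smallest maximizing `h2` is returned, which
#' reduces the fit to OLS.
#'
#' @param y numeric response vector.
#' @param covariates numeric covariate matrix (samples x k, no intercept),
#'   or `NULL` for intercept only.
#' @param K kinship matrix from [estimateKinship()].
#' @param eig optional pre-computed `eigen(2 * K, symmetric = TRUE)`, reused
#'   across responses sharing one kinship matrix.
#' @return object of class `"polygenicFit"`: list with `coef`, `s2g`, `s2e`,
#'   `h2`, `residuals`, `logLik`, `n`, and the rotated quantities needed by
#'   [mmscoreTest()].
#' @export
fitPolygenic <- function(y, covariates = NULL, K, eig = NULL) {
  X <- cbind("(Intercept)" = rep(1, length(y)), covariates)
  stopifnot(nrow(K) == length(y))
  if (is.null(eig)) eig <- eigen(2 * K, symmetric = TRUE)
  if (min(eig$values) < -1e-8)
    stop("kinship matrix is not positive semi-definite after bending")
  lam <- pmax(eig$values, 0)
  U <- eig$vectors
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)
  n <- length(y)
  profile <- function(h2) {
    d <- h2 * lam + (1 - h2)
    w <- 1 / d
    XtWX <- crossprod(Xt * w, Xt)
    XtWy <- crossprod(Xt * w, yt)
    b <- solve(XtWX, XtWy)
    r <- yt - Xt %*% b
    s2 <- sum(w * r^2) / n
    ll <- -0.5 * (n * log(2 * pi * s2) + sum(log(d)) + n)
    list(ll = ll, b = b, s2 = s2)
  }
  opt <- stats::optimize(function(h2) -profile(h2)$ll,
                         interval = c(0, 0.99), tol = 1e-6)
  cand <- c(0, opt$minimum, 0.99)
  lls <- vapply(cand, function(h) profile(h)$ll, numeric(1))
  ## prefer the smallest h2 among near-ties (flat likelihood)
  best <- cand[which(lls > max(lls) - 1e-6)][1]
  pf <- profile(best)
  b <- drop(pf$b)
  names(b) <- colnames(X)
  resid <- drop(y - X %*% pf$b)
  s2g <- best * pf$s2; s2e <- (1 - best) * pf$s2
  structure(list(coef = b, s2g = s2g, s2e = s2e, h2 = best,
                 residuals = resid, logLik = pf$ll, n = n,
                 U = U, Xt = Xt, dV = pf$s2 * (best * lam + (1 - best)),
                 utr = drop(crossprod(U, resid))),
            class = "polygenicFit")
}

#' @export
print.polygenicFit <- function(x, ...) {
  cat(sprintf("polygenic fit: n = %d, h2 = %.3f (s2g = %.4g, s2e = %.4g), logLik = %.2f\n",
              x$n, x$h2, x$s2g, x$s2e, x$logLik))
  invisible(x)
}

## Vectorized score tests for many SNPs against one polygenic fit.
## G: SNPs x samples.  The genotype is projected off the fixed effects in
## the V-metric (the efficient score); since the GLS residuals already
## satisfy X' V^-1 r = 0, only the quadratic form in the denominator is
## affected.  Returns beta, se, chi2, p per SNP.
.mmscoreMatrix <- function(fit, G) {
  Gc <- G - rowMeans(G)
  W <- crossprod(fit$U, t(Gc))          # n x m, rotated centered genotypes
  Wd <- W / fit$dV
  gVr <- drop(crossprod(Wd, fit$utr))
  XtWX <- crossprod(fit$Xt / fit$dV, fit$Xt)
  A <- crossprod(fit$Xt, Wd)            # k x m: X' V^-1 g
  gPg <- colSums(W * Wd) - colSums(A * solve(XtWX, A))
  gPg[gPg < 0] <- 0
  beta <- ifelse(gPg > 0, gVr / gPg, NA)
  se <- ifelse(gPg > 0, 1 / sqrt(gPg), NA)
  chi2 <- ifelse(gPg > 0, gVr^2 / gPg, NA)
  snps <- rownames(G) %||% paste0("snp", seq_len(nrow(G)))
  data.frame(snp = snps, beta = beta, se = se, chi2 = chi2,
             p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
             row.names = NULL)
}

#' Mixed-model score test for one variant
#'
#' Efficient score statistic `T = (g~' V^-1 r)^2 / (g~' V^-1 g~)` with `g~`
#' the genotype centered and projected off the fixed-effect design in the
#' V-metric, `r` the polygenic-model residuals and `V` the fitted covariance
#' `s2g * 2K + s2e * I`; p-value from the 1-df chi-square. The reported
#' effect is `b = (g~' V^-1 r) / (g~' V^-1 g~)` with
#' `SE = (g~' V^-1 g~)^-1/2`, which is free of the attenuation a merely
#' centered genotype suffers when it correlates with the covariates.
#' Monomorphic variants are skipped with a message.
#'
#' @param fit a `"polygenicFit"` from [fitPolygenic()].
#' @param g genotype dosage vector.
#' @param snp label for the output row.
#' @return one-row data.frame `snp`, `beta`, `se`, `chi2`, `p`, or `NULL`
#'   for a monomorphic variant.
#' @export
mmscoreTest <- function(fit, g, snp = "snp") {
  stopifnot(length(g) == fit$n)
  if (stats::var(g) == 0) {
    message("monomorphic variant skipped: ", snp)
    return(NULL)
  }
  .mmscoreMatrix(fit, matrix(g, nrow = 1, dimnames = list(snp, NULL)))
}

#' Label a SNP-CpG pair cis or trans
#'
#' Cis: same chromosome and distance strictly below `cisWindow` (1 Mb);
#' everything else, including same-chromosome pairs beyond the window, is
#' trans. Pairs with missing coordinates are left unlabeled with a warning.
#'
#' @param pairs data.frame with columns `snpChr`, `snpPos`, `cpgChr`,
#'   `cpgPos`.
#' @param cisWindow cis distance bound in bp (default 1e6, exclusive).
#' @return `pairs` with columns `distance` (bp, same-chromosome only) and
#'   `label` (`"cis"`/`"trans"`/NA) added.
#' @export
classifyCisTrans <- function(pairs, cisWindow = 1e6) {
  need <- c("snpChr", "snpPos", "cpgChr", "cpgPos")
  stopifnot(all(need %in% names(pairs)))
  miss <- !stats::complete.cases(pairs[, need])
  if (any(miss)) warning(sum(miss), " pair(s) with missing coordinates left unlabeled")
  sameChr <- pairs$snpChr == pairs$cpgChr
  dist <- ifelse(sameChr, abs(pairs$snpPos - pairs$cpgPos), NA)
  pairs$distance <- dist
  pairs$label <- ifelse(miss, NA,
                        ifelse(sameChr & dist < cisWindow, "cis", "trans"))
  pairs
}

#' Kinship-aware meQTL scan for a CpG set
#'
#' For each CpG, fits the polygenic mixed model with the `meqtl` covariate
#' set (age, sex, T2D, BMI, cell-count PCs, plate, batch, well, smoking
#' surrogate, genomic PCs, kinship random effect) and score-tests every
#' variant with MAF above `mafMin`. Pairs below `alpha` are retained and
#' labeled cis/trans.
#'
#' @param study a preprocessed \linkS4class{MultiOmicsStudy}.
#' @param cpgs character vector of CpG ids (empty input gives an empty
#'   table).
#' @param samples optional sample-id subset (e.g. a genotyping batch for the
#'   discovery/replication split).
#' @param alpha retention threshold (default 8.7e-10).
#' @param mafMin minor-allele-frequency filter (default 0.01).
#' @param transform `"beta"` or `"logit"` methylation scale.
#' @return data.frame of retained pairs: `snp`, `snpChr`, `snpPos`, `cpg`,
#'   `cpgChr`, `cpgPos`, `beta`, `se`, `chi2`, `p`, `distance`, `label`;
#'   attribute `"nTests"` records the number of tests performed.
#' @export
runMeqtl <- function(study, cpgs, samples = NULL, alpha = 8.7e-10,
                     mafMin = 0.01, transform = c("beta", "logit")) {
  transform <- match.arg(transform)
  empty <- data.frame(snp = character(), snpChr = integer(),
                      snpPos = integer(), cpg = character(),
                      cpgChr = integer(), cpgPos = integer(),
                      beta = numeric(), se = numeric(), chi2 = numeric(),
                      p = numeric(), distance = numeric(),
                      label = character())
  if (!length(cpgs)) return(structure(empty, nTests = 0L))
  if (is.null(samples)) samples <- rownames(study@samples)
  cov <- buildCovariates(study, "meqtl", samples = samples)
  G <- dosages(study)[, samples, drop = FALSE]
  p <- rowMeans(G) / 2
  maf <- pmin(p, 1 - p)
  G <- G[maf > mafMin, , drop = FALSE]
  K <- estimateKinship(dosages(study)[, samples, drop = FALSE])
  eig <- eigen(2 * K, symmetric = TRUE)
  B <- betaValues(study)[cpgs, samples, drop = FALSE]
  if (transform == "logit") B <- .logit(B)
  grd <- SummarizedExperiment::rowData(study@genotypes)
  crd <- SummarizedExperiment::rowData(study@methylation)
  res <- lapply(cpgs, function(cg) {
    fit <- fitPolygenic(B[cg, ], cov$design, K, eig = eig)
    tab <- .mmscoreMatrix(fit, G)
    tab <- tab[!is.na(tab$p) & tab$p < alpha, , drop = FALSE]
    if (!nrow(tab)) return(NULL)
    data.frame(snp = tab$snp,
               snpChr = grd[tab$snp, "chr"], snpPos = grd[tab$snp, "pos"],
               cpg = cg, cpgChr = crd[cg, "chr"], cpgPos = crd[cg, "pos"],
               beta = tab$beta, se = tab$se, chi2 = tab$chi2, p = tab$p,
               row.names = NULL)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) return(structure(empty, nTests = nrow(G) * length(cpgs)))
  structure(classifyCisTrans(out), nTests = nrow(G) * length(cpgs))
}

#' Locus-window replication of discovery meQTL pairs
#'
#' A discovery pair replicates if the replication table contains the same
#' CpG either with the identical SNP or with any SNP on the same chromosome
#' within `window` bp of the discovery SNP, at a replication p-value below
#' `alphaRep`.
#'
#' @param discoveryPairs,replicationPairs meQTL pair tables (see
#'   [runMeqtl()]; the replication table should be unthresholded, i.e. run
#'   with `alpha = 1` on the candidate pairs, or at the replication
#'   threshold).
#' @param window locus window in bp (default 500 kb).
#' @param alphaRep replication threshold; defaults to
#'   `0.05 / nrow(discoveryPairs)`.
#' @return `discoveryPairs` with a logical `replicated` column.
#' @export
locusReplicate <- function(discoveryPairs, replicationPairs,
                           window = 5e5, alphaRep = NULL) {
  if (is.null(alphaRep))
    alphaRep <- if (nrow(discoveryPairs)) 0.05 / nrow(discoveryPairs) else 0.05
  rep <- replicationPairs[replicationPairs$p < alphaRep, , drop = FALSE]
  discoveryPairs$replicated <- vapply(seq_len(nrow(discoveryPairs)),
    function(i) {
      d <- discoveryPairs[i, ]
      cand <- rep[rep$cpg == d$cpg, , drop = FALSE]
      if (!nrow(cand)) return(FALSE)
      any(cand$snp == d$snp |
            (cand$snpChr == d$snpChr & abs(cand$snpPos - d$snpPos) <= window))
    }, logical(1))
  discoveryPairs
}
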