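#' Construct a two-sample MR input
#'
#' @param snps SNP identifiers.
#' @param bx,bxse per-SNP effect on the exposure (CpG methylation) and SE.
#' @param by,byse per-SNP effect on the outcome and SE.
#' @return an \linkS4class{MRInput}.
#' @examples
#' mrInput("rs1", bx = -100.2, bxse = 16.1, by = 0.08, byse = 0.0022)
#' @export
mrInput <- function(snps, bx, bxse, by, byse) {
  new("MRInput", snps = as.character(snps), bx = as.numeric(bx),
      bxse = as.numeric(bxse), by = as.numeric(by), byse = as.numeric(byse))
}

#' Wald ratio
#'
#' Single-variant causal estimate: outcome effect divided by exposure
#' effect, `by / bx`.
#'
#' @param bx,by numeric vectors of exposure and outcome effects.
#' @return `by / bx`.
#' @export
waldRatio <- function(bx, by) {
  if (any(bx == 0)) stop("Wald ratio undefined for bx = 0")
  by / bx
}

.mrResult <- function(estimate, se, method, nSnps, Q = NA_real_,
                      Qp = NA_real_, I2 = NA_real_) {
  new("MRResult", estimate = estimate, se = se,
      ci = estimate + c(-1, 1) * 1.96 * se,
      p = 2 * stats::pnorm(-abs(estimate / se)),
      method = method, nSnps = as.integer(nSnps),
      Q = Q, Qp = Qp, I2 = I2)
}

#' Single-SNP maximum-likelihood MR estimate
#'
#' Maximizes the bivariate normal likelihood `bx ~ N(xi, bxse^2)`,
#' `by ~ N(theta * xi, byse^2)` over the true exposure effect `xi` and the
#' causal effect `theta`. The point estimate coincides with the Wald ratio;
#' the SE comes from the observed Fisher information at the optimum (which
#' matches the closed-form delta expression
#' `sqrt((byse/bx)^2 + (by * bxse / bx^2)^2)`).
#'
#' @param input an \linkS4class{MRInput} with exactly one SNP, or the `bx`
#'   value when the four summary statistics are passed individually.
#' @param bxse,by,byse individual summary statistics (when `input` is
#'   numeric).
#' @return an \linkS4class{MRResult} with `method = "maxlik"`.
#' @examples
#' mlSingleSnp(mrInput("rs7909192", -100.2, 16.1, 0.08, 0.0022))
#' @export
mlSingleSnp <- function(input, bxse = NULL, by = NULL, byse = NULL) {
  if (is.numeric(input))
    input <- mrInput("snp", input, bxse, by, byse)
  stopifnot(is(input, "MRInput"))
  validObject(input)
  if (length(input@bx) != 1)
    stop("mlSingleSnp() takes exactly one SNP; use ivwEstimate() for several")
  bx <- input@bx; sx <- input@bxse; byv <- input@by; sy <- input@byse
  if (bx == 0) stop("exposure effect bx = 0: ratio estimate undefined")
  nll <- function(par) {
    xi <- par[1]; theta <- par[2]
    0.5 * ((bx - xi)^2 / sx^2 + (byv - theta * xi)^2 / sy^2)
  }
  opt <- stats::optim(c(bx, byv / bx), nll, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
  if (opt$convergence != 0)
    stop("single-SNP ML did not converge (code ", opt$convergence,
         "); inputs: bx=", bx, " by=", byv)
  hess <- stats::optimHess(opt$par, nll)
  vc <- solve(hess)
  .mrResult(opt$par[2], sqrt(vc[2, 2]), "maxlik", 1L)
}

#' Inverse-variance-weighted MR estimate
#'
#' Combines per-SNP Wald ratios `b_j = by_j / bx_j` with first-order weights
#' `s_j = byse_j / |bx_j|`: fixed-effect estimate
#' `sum(b_j / s_j^2) / sum(1 / s_j^2)`, SE `sqrt(1 / sum(1 / s_j^2))`,
#' Cochran's `Q = sum((b_j - b)^2 / s_j^2)` on `J - 1` df and the I-squared
#' percentage.
#'
#' @param input an \linkS4class{MRInput} with at least two SNPs.
#' @return an \linkS4class{MRResult} with `method = "ivw"`.
#' @examples
#' hk1 <- mrInput(c("rs7909192", "rs75743765", "rs11596193"),
#'                bx = c(-100.2, -73.5, -86.6), bxse = c(16.1, 9.8, 11.3),
#'                by = c(0.08, 0.0456, 0.0277),
#'                byse = c(0.0022, 0.0036, 0.004))
#' ivwEstimate(hk1)
#' @export
ivwEstimate <- function(input) {
  stopifnot(is(input, "MRInput"))
  validObject(input)
  J <- length(input@bx)
  if (J < 2)
    stop("ivwEstimate() needs at least 2 SNPs; use mlSingleSnp() or waldRatio()")
  if (any(input@bx == 0)) stop("exposure effect bx = 0 for some SNP")
  b <- waldRatio(input@bx, input@by)
  s <- input@byse / abs(input@bx)
  w <- 1 / s^2
  est <- sum(w * b) / sum(w)
  se <- sqrt(1 / sum(w))
  Q <- sum(w * (b - est)^2)
  Qp <- stats::pchisq(Q, df = J - 1, lower.tail = FALSE)
  I2 <- if (Q > 0) max(0, (Q - (J - 1)) / Q) * 100 else 0
  .mrResult(est, se, "ivw", J, Q = Q, Qp = Qp, I2 = I2)
}

#' CpG associations with a continuous outcome
#'
#' Linear regression of each CpG on the outcome (e.g. HbA1c) with the EWAS
#' covariates minus T2D and the control-fitted age residualization; used to
#' confirm exposure-outcome associations before Mendelian randomization.
#'
#' @param study a preprocessed \linkS4class{MultiOmicsStudy}.
#' @param cpgs CpG ids to test.
#' @param outcome name of a numeric sample column (default `"hba1c"`), or a
#'   numeric vector aligned with the analysed samples.
#' @param cohort cohort label or `NULL` for all samples.
#' @param transform methylation scale, `"beta"` or `"logit"`.
#' @return data.frame: `cpg`, `cohort`, `beta`, `se`, `t`, `p`, `df`, `n`.
#' @export
cpgOutcomeAssoc <- function(study, cpgs, outcome = "hba1c", cohort = NULL,
                            transform = c("beta", "logit")) {
  transform <- match.arg(transform)
  st <- study@samples
  ids <- if (is.null(cohort)) rownames(st) else
    rownames(st)[st$cohort == cohort]
  cov <- buildCovariates(study, "cpg_hba1c", samples = ids)
  y <- if (is.character(outcome)) st[ids, outcome] else outcome
  if (stats::var(y, na.rm = TRUE) == 0) stop("outcome has zero variance")
  Y <- betaValues(study)[cpgs, ids, drop = FALSE]
  if (transform == "logit") Y <- .logit(Y)
  am <- fitAgeModel(Y, cov$age, cov$controls)
  Y <- ageResidualize(Y, cov$age, am)
  res <- .fastAssoc(Y, y, cov$design, xname = "outcome")
  data.frame(cpg = res$feature, cohort = if (is.null(cohort)) NA else cohort,
             res[, c("beta", "se", "t", "p", "df", "n")], row.names = NULL)
}
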