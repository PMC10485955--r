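## Internal linear-algebra helpers shared by the association stages.

## Drop design columns that are constant on the analysed samples (e.g. a
## batch factor inside a single-batch cohort); error, naming columns, if the
## remainder is still rank deficient.  Intercept is assumed present in `X`.
.pruneDesign <- function(X) {
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2,
                        function(col) stats::var(col) > 0))
  X <- X[, keep, drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  X
}

## One predictor, many response rows.  Y: features x samples; x: predictor
## vector; Z: covariate matrix (samples x k) WITHOUT intercept.  Returns a
## data.frame with one row per feature.  Complete cases on (x, Z) are used;
## rows of Y with missing values fall back to a per-feature fit.
.fastAssoc <- function(Y, x, Z = NULL, xname = "x") {
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1,
                                   dimnames = list("y", names(Y)))
  X <- cbind("(Intercept)" = 1, x = as.numeric(x))
  if (!is.null(Z) && ncol(Z) > 0) X <- cbind(X, Z)
  cc <- stats::complete.cases(X)
  if (stats::var(as.numeric(x)[cc]) == 0)
    stop("predictor has zero variance")
  X <- .pruneDesign(X[cc, , drop = FALSE])
  Yc <- Y[, cc, drop = FALSE]
  n <- nrow(X); rk <- ncol(X); df <- n - rk
  if (df < 2L) stop("fewer complete cases than rank(design)+2")
  XtXi <- chol2inv(chol(crossprod(X)))
  H <- XtXi %*% t(X)                      # rk x n
  miss <- rowSums(is.na(Yc)) > 0
  beta <- se <- sigma2 <- nused <- dfout <- numeric(nrow(Yc))
  ok <- !miss
  if (any(ok)) {
    B <- H %*% t(Yc[ok, , drop = FALSE])  # rk x features
    res <- t(Yc[ok, , drop = FALSE]) - X %*% B
    s2 <- colSums(res^2) / df
    beta[ok] <- B[2, ]
    se[ok] <- sqrt(s2 * XtXi[2, 2])
    sigma2[ok] <- s2; nused[ok] <- n; dfout[ok] <- df
  }
  for (i in which(miss)) {
    yi <- Yc[i, ]
    use <- !is.na(yi)
    Xi <- .pruneDesign(X[use, , drop = FALSE])
    XtXi_i <- chol2inv(chol(crossprod(Xi)))
    b <- XtXi_i %*% crossprod(Xi, yi[use])
    r <- yi[use] - Xi %*% b
    dfi <- sum(use) - ncol(Xi)
    if (dfi < 2L) stop("fewer complete cases than rank(design)+2")
    s2 <- sum(r^2) / dfi
    j <- match("x", colnames(Xi))
    beta[i] <- b[j]; se[i] <- sqrt(s2 * XtXi_i[j, j])
    sigma2[i] <- s2; nused[i] <- sum(use); dfout[i] <- dfi
  }
  tval <- beta / se
  data.frame(feature = rownames(Y), predictor = xname,
             beta = beta, se = se, t = tval,
             p = 2 * stats::pt(-abs(tval), dfout),
             df = dfout, n = nused, row.names = NULL,
             stringsAsFactors = FALSE)
}

## Genomic inflation factor from two-sided p-values.
.lambdaGC <- function(p) {
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1, lower.tail = FALSE)
}

.logit <- function(b) stats::qlogis(b)

## Stage-specific seeds derived from one master seed, kept below 2^31.
.deriveSeed <- function(seed, offset) {
  (as.integer(seed) + 1664525L * as.integer(offset)) %% 2147483647L
}
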