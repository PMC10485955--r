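## Shared synthetic cohorts, built once per test run.

.cache <- new.env(parent = emptyenv())

## mid-size cohort with the default planted effects and sibships
testStudy <- function() {
  if (is.null(.cache$study)) {
    cfg <- simulationConfig(nSamples = 400, nCpgs = 60, nSnps = 800,
                            nMetabolites = 30, nFamilies = 30, seed = 9)
    .cache$study <- preprocessStudy(simulateCohort(cfg))
  }
  .cache$study
}

## global-null cohort: no planted effects, no covariate loadings
nullStudy <- function() {
  if (is.null(.cache$null)) {
    cfg <- simulationConfig(nSamples = 300, nCpgs = 500, nSnps = 300,
                            nMetabolites = 40, nFamilies = 0,
                            effects = "none", covariateEffectScale = 0,
                            ageCollinearT2d = FALSE,
                            missingRate = 0, seed = 17)
    .cache$null <- preprocessStudy(simulateCohort(cfg))
  }
  .cache$null
}

## minimal sample table for layer-level generators
minimalSamples <- function(n, t2d = rep(0L, n), seed = 1) {
  set.seed(seed)
  S4Vectors::DataFrame(sample = sprintf("S%04d", seq_len(n)), t2d = t2d,
                       row.names = sprintf("S%04d", seq_len(n)))
}

## brute-force OLS oracle: normal equations by hand
olsOracle <- function(y, X) {
  XtXi <- solve(t(X) %*% X)
  b <- XtXi %*% t(X) %*% y
  r <- y - X %*% b
  df <- length(y) - ncol(X)
  s2 <- sum(r^2) / df
  list(beta = unname(drop(b)), se = unname(sqrt(s2 * diag(XtXi))),
       df = df, sigma2 = s2)
}

## union-find connected-components oracle
unionFindComponents <- function(ids, from, to) {
  parent <- stats::setNames(seq_along(ids), ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_along(from)) {
    a <- find(from[k]); b <- find(to[k])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(ids, function(i) find(i), numeric(1))
  as.integer(table(factor(roots, levels = unique(roots))))
}
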