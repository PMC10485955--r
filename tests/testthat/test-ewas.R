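test_that("fitLinearAssoc matches hand-computed normal equations", {
  ## 6-point hand dataset
  x <- c(0, 1, 2, 3, 4, 5)
  y <- c(0.2, 0.5, 0.9, 1.4, 1.6, 2.2)
  fit <- fitLinearAssoc(y, x)
  or <- olsOracle(y, cbind(1, x))
  expect_lt(abs(fit$beta - or$beta[2]), 1e-12)
  expect_lt(abs(fit$se - or$se[2]), 1e-12)
  expect_equal(fit$df, or$df)
  ## y = x exactly: slope 1, zero residual
  fit2 <- fitLinearAssoc(x + 0.5, x)
  expect_equal(fit2$beta, 1, tolerance = 1e-12)
  expect_lt(fit2$se, 1e-10)
  ## independent y at large n: |beta| < 3 SE
  set.seed(10)
  xx <- rnorm(1e4); yy <- rnorm(1e4)
  f3 <- fitLinearAssoc(yy, xx)
  expect_lt(abs(f3$beta), 3 * f3$se)
  ## degenerate inputs
  expect_error(fitLinearAssoc(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(fitLinearAssoc(rnorm(10), rep(2, 10)), "zero variance")
})

test_that("fitLinearAssoc agrees with lm on random small instances", {
  set.seed(11)
  for (rep in 1:30) {
    n <- sample(8:20, 1)
    X <- cbind(z1 = rnorm(n), z2 = rnorm(n))
    x <- rnorm(n)
    y <- 0.3 * x + X %*% c(0.5, -0.2) + rnorm(n)
    fit <- fitLinearAssoc(drop(y), x, covariates = X)
    lmf <- summary(lm(y ~ x + X))$coefficients
    expect_equal(fit$beta, lmf["x", 1], tolerance = 1e-10)
    expect_equal(fit$se, lmf["x", 2], tolerance = 1e-10)
    expect_equal(fit$p, lmf["x", 4], tolerance = 1e-8)
    or <- olsOracle(drop(y), cbind(1, x, X))
    expect_equal(fit$beta, or$beta[2], tolerance = 1e-12)
  }
})

test_that("EWAS is calibrated under the global null", {
  tab <- runEwas(nullStudy(), cohort = NULL)
  lambda <- median(qchisq(tab$p, 1, lower.tail = FALSE)) / qchisq(0.5, 1)
  ## the sampling SD of a median-based lambda over 500 tests is ~0.087, so
  ## the band here is ~1.7 SD; the tight [0.9, 1.1] check runs at 2000 tests
  expect_gt(lambda, 0.85)
  expect_lt(lambda, 1.15)
  ## and the two-way selection keeps nothing
  t1 <- runEwas(nullStudy(), cohort = 1)
  t2 <- runEwas(nullStudy(), cohort = 2)
  sel <- twoWayDiscoveryReplication(t1, t2)
  expect_equal(nrow(sel), 0)
})

test_that("EWAS recovers planted T2D shifts on the scale they were planted", {
  study <- testStudy()
  tr <- groundTruth(study)$t2dCpg
  tab <- runEwas(study, cohort = NULL, transform = "logit")
  idx <- match(tr$cpg, tab$cpg)
  z <- (tab$beta[idx] - tr$beta) / tab$se[idx]
  expect_lt(max(abs(z)), 2.5)
  expect_true(all(sign(tab$beta[idx]) == sign(tr$beta)))
})

test_that("detection power matches the analytic noncentrality prediction", {
  ## the EWAS regression atom at cohort scale: planted mean shift, power
  ## at the discovery threshold vs the normal approximation
  set.seed(12)
  n <- 450; b <- 0.02; sdE <- 0.04; alpha <- 5.8e-8
  t2d <- rbinom(n, 1, 0.4)
  sePred <- sdE / sqrt(n * var(t2d) * (n - 1) / n)
  zcrit <- qnorm(1 - alpha / 2)
  predPower <- pnorm(b / sePred - zcrit) + pnorm(-b / sePred - zcrit)
  R <- 200
  hits <- vapply(seq_len(R), function(i) {
    y <- b * t2d + rnorm(n, 0, sdE)
    fitLinearAssoc(y, t2d)$p < alpha
  }, logical(1))
  expect_lt(abs(mean(hits) - predPower),
            max(0.1, 3 * sqrt(predPower * (1 - predPower) / R)))
})

test_that("degenerate cohorts are rejected", {
  study <- testStudy()
  expect_error(runEwas(study, cohort = 99), "empty cohort")
})

test_that("two-way discovery/replication implements the pass logic", {
  mkTab <- function(cpgs, p, beta = rep(0.1, length(cpgs)))
    data.frame(cpg = cpgs, beta = beta, p = p)
  cpgs <- paste0("cg", 1:6)
  ## A discovers 3 CpGs; their B p-values are 0.01, 0.02, 0.5;
  ## threshold 0.05/3 = 0.0167 so exactly one replicates from pass 1
  tabA <- mkTab(cpgs, c(1e-9, 2e-8, 5e-8, 0.3, 0.4, 0.5))
  tabB <- mkTab(cpgs, c(0.01, 0.02, 0.5, 0.6, 0.7, 0.8))
  sel <- twoWayDiscoveryReplication(tabA, tabB)
  expect_equal(nrow(sel), 1)
  expect_equal(sel$cpg, "cg1")
  expect_equal(sel$discoveryCohort, 1L)
  expect_equal(sel$replicationThreshold, 0.05 / 3)
  ## symmetric pass: discovery in B replicates in A
  sel2 <- twoWayDiscoveryReplication(tabB, tabA)
  expect_equal(sel2$cpg, "cg1")
  expect_equal(sel2$discoveryCohort, 2L)
  ## no discoveries anywhere: empty, not an error
  null <- mkTab(cpgs, rep(0.5, 6))
  expect_equal(nrow(twoWayDiscoveryReplication(null, null)), 0)
  ## discovered in both cohorts: tagged once, by the stronger discovery
  tabC <- mkTab(cpgs, c(1e-12, rep(0.9, 5)))
  tabD <- mkTab(cpgs, c(1e-9, rep(0.9, 5)))
  sel3 <- twoWayDiscoveryReplication(tabC, tabD)
  expect_equal(nrow(sel3), 1)
  expect_equal(sel3$discoveryCohort, 1L)
})

test_that("model combination applies the direction-consistency filter", {
  mkTab <- function(beta) data.frame(cpg = paste0("cg", seq_along(beta)),
                                     beta = beta, p = 1e-9)
  mkSel <- function(cpgs) {
    k <- length(cpgs)
    data.frame(cpg = cpgs, discoveryCohort = rep(1L, k),
               discoveryP = rep(1e-9, k), replicationP = rep(1e-3, k),
               replicationThreshold = rep(0.01, k))
  }
  betasA <- c(0.02, -0.01, 0.03, 0.02, -0.02, 0.01)
  betasB <- c(0.01, -0.02, 0.01, -0.01, -0.01, 0.02)  # cg4 flips sign
  tabs <- list(mkTab(betasA), mkTab(betasB))
  ## disjoint selections of sizes 3 and 2, all sign-consistent -> 5
  selNo <- mkSel(paste0("cg", 1:3))
  selB <- mkSel(paste0("cg", 5:6))
  out <- combineModels(selNo, selB, tabs, tabs)
  expect_equal(nrow(out), 5)
  expect_equal(attr(out, "nUnion"), 5L)
  ## sign flip excluded
  out2 <- combineModels(mkSel(paste0("cg", 1:4)), mkSel(character()),
                        tabs, tabs)
  expect_equal(nrow(out2), 3)
  expect_false("cg4" %in% out2$cpg)
  ## overlapping selections count once and carry the both-models flag
  out3 <- combineModels(mkSel(c("cg1", "cg2")), mkSel(c("cg2", "cg3")),
                        tabs, tabs)
  expect_equal(nrow(out3), 3)
  expect_equal(out3$models[out3$cpg == "cg2"], "both")
  expect_equal(sum(out3$cpg == "cg2"), 1)
})
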