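test_that("metabolite QC removes outliers and restandardizes", {
  set.seed(2)
  n <- 200
  raw <- matrix(exp(rnorm(5 * n)), 5, n,
                dimnames = list(paste0("m", 1:5), NULL))
  ## plant one value 4 SD above the mean of metabolite 1 (log scale)
  lx <- log(raw[1, ])
  raw[1, 7] <- exp(mean(lx) + 4 * sd(lx))
  z <- metaboliteQC(raw)
  rep <- attr(z, "qcReport")
  expect_true(is.na(z[1, 7]))
  expect_gte(rep$nOutliers[1], 1)
  for (i in 1:5) {
    v <- z[i, !is.na(z[i, ])]
    expect_lt(abs(mean(v)), 1e-12)
    expect_lt(abs(sd(v) - 1), 1e-12)
  }
})

test_that("metabolite QC drops degenerate rows and keeps clean panels intact", {
  raw <- matrix(exp(rnorm(300)), 15, 20,
                dimnames = list(sprintf("m%02d", 1:15), NULL))
  rawC <- rbind(raw, const = rep(2.5, 20))
  z <- metaboliteQC(rawC)
  expect_equal(nrow(z), 15)            # the constant metabolite is dropped
  expect_equal(attr(z, "qcReport")$reason[16], "zero variance")
  ## nothing dropped in a clean panel: all metabolites come through
  expect_equal(nrow(metaboliteQC(raw)), 15)
})

test_that("metabolite QC flags non-positive values and is stable on bounded data", {
  raw <- matrix(exp(rnorm(60)), 3, 20)
  raw[2, 5] <- -1
  expect_warning(z <- metaboliteQC(raw), "non-positive")
  expect_true(is.na(z[2, 5]))
  expect_equal(attr(z, "qcReport")$nNonPositive[2], 1L)
  ## a panel bounded well inside 3 SD is a fixed point of the QC
  q <- qnorm(seq(0.015, 0.985, length.out = 80))   # bounded at 2.17 SD
  bounded <- rbind(a = sample(q), b = sample(q))
  z1 <- metaboliteQC(exp(bounded))
  z2 <- metaboliteQC(z1, log = FALSE)
  expect_lt(max(abs(z2 - z1)), 1e-12)
})

test_that("age model matches the normal-equations oracle and exact lines", {
  set.seed(4)
  n <- 120
  age <- runif(n, 20, 70)
  ctrl <- rep(c(TRUE, FALSE), length.out = n)
  ## exact line in controls
  y <- 0.01 * age + 0.2
  m <- fitAgeModel(y, age, ctrl)
  expect_lt(abs(m$beta1 - 0.01), 1e-10)
  expect_lt(abs(m$beta0 - 0.2), 1e-10)
  ## noisy CpG against the hand-coded oracle
  Y <- matrix(0.3 + 0.005 * age + rnorm(n, 0, 0.05), 1, n)
  m2 <- fitAgeModel(Y, age, ctrl)
  or <- olsOracle(Y[1, ctrl], cbind(1, age[ctrl]))
  expect_lt(abs(m2$beta0 - or$beta[1]), 1e-10)
  expect_lt(abs(m2$beta1 - or$beta[2]), 1e-10)
  ## age-independent CpG: slope within noise
  Y0 <- matrix(rnorm(n, 0.5, 0.02), 1, n)
  m0 <- fitAgeModel(Y0, age, ctrl)
  se1 <- olsOracle(Y0[1, ctrl], cbind(1, age[ctrl]))$se[2]
  expect_lt(abs(m0$beta1), 3 * se1)
  ## degenerate inputs
  expect_error(fitAgeModel(y, age, c(TRUE, TRUE, rep(FALSE, n - 2))),
               "at least 3 controls")
  expect_error(fitAgeModel(y, rep(50, n), ctrl), "same age")
})

test_that("age model never sees case samples", {
  set.seed(5)
  n <- 100
  age <- runif(n, 20, 70)
  ctrl <- seq_len(n) <= 60
  y <- 0.002 * age + rnorm(n, 0, 0.01)
  yPoisoned <- y
  yPoisoned[!ctrl] <- 99           # absurd case values must not matter
  m1 <- fitAgeModel(y[ctrl], age[ctrl], rep(TRUE, 60))
  m2 <- fitAgeModel(yPoisoned, age, ctrl)
  expect_equal(m1$beta1, m2$beta1, tolerance = 1e-12)
  expect_equal(m1$beta0, m2$beta0, tolerance = 1e-12)
})

test_that("age residualization adjusts all samples with control coefficients", {
  set.seed(6)
  n <- 150
  age <- runif(n, 20, 70)
  ctrl <- rep(c(TRUE, FALSE), length.out = n)
  y <- 0.3 + 0.004 * age          # exact fit in everyone
  m <- fitAgeModel(y, age, ctrl)
  adj <- ageResidualize(y, age, m)
  expect_lt(max(abs(adj)), 1e-10)
  ## beta1 = 0: adjustment is a constant shift
  m0 <- structure(data.frame(cpg = "cpg", beta0 = 0.3, beta1 = 0),
                  class = c("ageAdjustModel", "data.frame"))
  expect_equal(drop(ageResidualize(y, age, m0)), y - 0.3)
  ## missing age excludes the sample with a warning
  age2 <- age; age2[3] <- NA
  expect_warning(adj2 <- ageResidualize(y, age2, m), "missing age")
  expect_equal(ncol(adj2), n - 1)
  ## a case-only slope deviation survives adjustment (simulation oracle):
  ## cases get slope 0.008, controls 0.004; the control model removes only
  ## the control trend, so case residuals still trend with age
  y2 <- y + ifelse(ctrl, 0, 0.004 * age)
  adj3 <- ageResidualize(y2, age, fitAgeModel(y2, age, ctrl))
  caseCor <- cor(adj3[1, !ctrl], age[!ctrl])
  expect_gt(caseCor, 0.99)
})

test_that("covariate designs match their model definitions", {
  study <- testStudy()
  mw <- buildCovariates(study, "mwas")
  expect_setequal(colnames(mw$design),
                  c("age", "sexM", "bmi", "gPC1", "gPC2", "gPC3"))
  expect_false(mw$ageResidualize)
  noB <- buildCovariates(study, "ewas_noBMI")
  wiB <- buildCovariates(study, "ewas_BMI")
  expect_setequal(setdiff(colnames(wiB$design), colnames(noB$design)), "bmi")
  expect_true(noB$ageResidualize)
  expect_false("age" %in% colnames(noB$design))
  expect_false("t2d" %in% colnames(noB$design))
  expect_true(all(c("age", "bmi", "t2d") %in%
                    colnames(buildCovariates(study, "meqtl")$design)))
  expect_true("smokeSurrogate" %in% colnames(noB$design))
  ## genomic PCs are orthonormal
  pcs <- computeGenomicPCs(study)
  expect_lt(max(abs(crossprod(pcs) - diag(3))), 1e-8)
  ## full-rank design even within a single batch/cohort
  ids <- rownames(sampleTable(study))[sampleTable(study)$cohort == 1]
  d1 <- buildCovariates(study, "ewas_noBMI", samples = ids)
  expect_equal(qr(cbind(1, d1$design))$rank, ncol(d1$design) + 1)
})

test_that("genuine collinearity is reported with column names", {
  set.seed(7)
  z <- rnorm(40)
  expect_error(fitLinearAssoc(rnorm(40), rnorm(40),
                              covariates = cbind(c1 = z, c2 = z)),
               "c2")
})
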