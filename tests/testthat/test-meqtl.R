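test_that("kinship estimates behave for duplicates, sibs and unrelateds", {
  set.seed(20)
  ## n large enough that the -1/n allele-frequency estimation bias on the
  ## duplicate-pair entry is negligible against the 0.05 bound
  m <- 5000; n <- 200
  p <- runif(m, 0.2, 0.5)   # moderate frequencies keep the z^2 kurtosis low
  G <- matrix(rbinom(m * n, 2, rep(p, n)), m, n)
  G <- cbind(G, G[, 1])                # duplicate the first sample
  colnames(G) <- paste0("S", seq_len(n + 1))
  K <- estimateKinship(G)
  expect_lt(abs(K[1, n + 1] - 1), 0.05)
  off <- K[upper.tri(K)]
  off <- off[off < 0.5]                # drop the planted duplicate pair
  expect_lt(abs(mean(off)), 3 / sqrt(m))
  expect_true(all(diag(K) > 0.8 & diag(K) < 1.3))
  expect_error(estimateKinship(matrix(2, 200, 10)), "monomorphic")
  expect_error(estimateKinship(G[1:50, ]), "at least 100")
})

test_that("polygenic fit reduces to OLS when kinship is uninformative", {
  set.seed(21)
  n <- 150
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- drop(X %*% c(0.4, -0.3)) + rnorm(n)
  fit <- fitPolygenic(y, X, diag(n))
  expect_equal(fit$h2, 0)
  ols <- lm(y ~ X)
  expect_lt(max(abs(fit$residuals - residuals(ols))), 1e-8)
  expect_lt(max(abs(fit$coef - coef(ols))), 1e-8)
})

test_that("profile likelihood is maximized and heritability is recovered", {
  set.seed(22)
  cfg <- simulationConfig(nSamples = 800, nCpgs = 5, nSnps = 600,
                          nMetabolites = 5, nFamilies = 200, familySize = 2,
                          effects = "none", seed = 33)
  g <- simulateGenotypes(cfg)
  K <- estimateKinship(SummarizedExperiment::assay(g$genotypes, "dosage"))
  eig <- eigen(2 * K, symmetric = TRUE)
  h2 <- 0.5
  lam <- pmax(eig$values, 0)
  y <- drop(eig$vectors %*% (sqrt(h2 * lam + (1 - h2)) * rnorm(800)))
  fit <- fitPolygenic(y, NULL, K, eig = eig)
  expect_gt(fit$h2, 0.35)
  expect_lt(fit$h2, 0.65)
  ## optimum beats the grid ends
  endLL <- vapply(c(1e-4, 0.99), function(h) {
    d <- h * lam + (1 - h)
    yt <- crossprod(eig$vectors, y)
    b <- sum(yt / d) / sum(1 / d)
    s2 <- sum((yt - crossprod(eig$vectors, rep(1, 800)) * b)^2 / d) / 800
    -0.5 * (800 * log(2 * pi * s2) + sum(log(d)) + 800)
  }, numeric(1))
  expect_gte(fit$logLik, max(endLL) - 1e-6)
})

test_that("the score test matches OLS when V is proportional to identity", {
  set.seed(23)
  n <- 500
  X <- cbind(c1 = rnorm(n))
  g <- rbinom(n, 2, 0.3)
  y <- 0.1 * g + drop(X) * 0.3 + rnorm(n)
  fit <- fitPolygenic(y, X, diag(n))
  sc <- mmscoreTest(fit, g)
  wald <- summary(lm(y ~ g + X))$coefficients["g", ]
  expect_lt(abs(sc$chi2 / wald[3]^2 - 1), 0.05)
  expect_equal(sc$beta, unname(wald[1]), tolerance = 0.01)
  ## genotype orthogonal to the residuals: exactly zero statistic
  fit2 <- fitPolygenic(y, NULL, diag(n))
  g3 <- residuals(lm(rnorm(n) ~ fit2$residuals))
  sc3 <- mmscoreTest(fit2, g3 - mean(g3))
  expect_lt(sc3$chi2, 1e-12)
  expect_equal(sc3$p, 1, tolerance = 1e-9)
  ## monomorphic variant is skipped
  expect_message(expect_null(mmscoreTest(fit, rep(1, n))), "monomorphic")
})

test_that("score and Wald chi-squares agree to first order on small instances", {
  set.seed(24)
  rel <- replicate(200, {
    n <- sample(30:50, 1)
    X <- cbind(rnorm(n))
    g <- rbinom(n, 2, runif(1, 0.2, 0.5))
    if (var(g) == 0) return(NA)
    y <- drop(X) * 0.5 + rnorm(n)
    fit <- fitPolygenic(y, X, diag(n))
    sc <- mmscoreTest(fit, g)
    ## exact GLS (= OLS here) Wald statistic with the same ML variance
    ## convention as the profile-likelihood fit
    XX <- cbind(1, g, X)
    b <- solve(crossprod(XX), crossprod(XX, y))
    rss <- sum((y - XX %*% b)^2)
    vb <- (rss / n) * solve(crossprod(XX))[2, 2]
    wald <- b[2]^2 / vb
    abs(sc$chi2 - wald) / max(wald, 1e-12)
  })
  rel <- rel[!is.na(rel)]
  expect_lt(mean(rel), 0.05)
  expect_lt(median(rel), 0.05)
})

test_that("score statistics are nonnegative and p decreases in the score", {
  set.seed(25)
  n <- 200
  y <- rnorm(n)
  fit <- fitPolygenic(y, NULL, diag(n))
  G <- matrix(rbinom(20 * n, 2, 0.3), 20, n)
  tab <- triomics:::.mmscoreMatrix(fit, G)
  expect_true(all(tab$chi2 >= 0))
  expect_equal(order(tab$chi2), order(tab$p, decreasing = TRUE))
})

test_that("null meQTL scans are calibrated under family structure", {
  set.seed(26)
  cfg <- simulationConfig(nSamples = 400, nCpgs = 5, nSnps = 800,
                          nMetabolites = 5, nFamilies = 100, familySize = 2,
                          effects = "none", covariateEffectScale = 0,
                          seed = 44)
  g <- simulateGenotypes(cfg)
  G <- SummarizedExperiment::assay(g$genotypes, "dosage")
  K <- estimateKinship(G)
  eig <- eigen(2 * K, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  ## polygenic null trait consistent with the kinship
  y <- drop(eig$vectors %*% (sqrt(0.4 * lam + 0.6) * rnorm(400)))
  fit <- fitPolygenic(y, NULL, K, eig = eig)
  tab <- triomics:::.mmscoreMatrix(fit, G)
  lambdaGC <- median(tab$chi2, na.rm = TRUE) / qchisq(0.5, 1)
  expect_gt(lambdaGC, 0.9)
  expect_lt(lambdaGC, 1.1)
})

test_that("cis/trans labels follow the 1 Mb rule", {
  pairs <- data.frame(
    snpChr = c(1, 1, 1, 2, 1),
    snpPos = c(1000000, 43409364, 5e6, 5e6, NA),
    cpgChr = c(1, 1, 1, 1, 1),
    cpgPos = c(1032000, 145441552, 5e6, 5e6, 1e6))
  expect_warning(lab <- classifyCisTrans(pairs), "missing coordinates")
  expect_equal(lab$label[1], "cis")        # 32 kb apart
  expect_equal(lab$label[2], "trans")      # ~102 Mb apart, same chromosome
  expect_equal(lab$distance[2], 145441552 - 43409364)
  expect_equal(lab$label[3], "cis")        # distance zero
  expect_equal(lab$label[4], "trans")      # different chromosome
  expect_true(is.na(lab$label[5]))
  ## labels partition all labeled pairs
  labeled <- lab$label[!is.na(lab$label)]
  expect_true(all(labeled %in% c("cis", "trans")))
  ## boundary: exactly 1 Mb is trans (exclusive rule)
  b <- classifyCisTrans(data.frame(snpChr = 1, snpPos = 1, cpgChr = 1,
                                   cpgPos = 1000001))
  expect_equal(b$label, "trans")
})

test_that("locus replication honours the 500 kb window", {
  disc <- data.frame(snp = c("s1", "s2", "s3"), snpChr = c(1, 1, 2),
                     snpPos = c(1e6, 2e6, 3e6),
                     cpg = c("cgA", "cgB", "cgC"), p = c(1e-12, 1e-12, 1e-12))
  rep <- data.frame(snp = c("s1", "sX", "sY"), snpChr = c(1, 1, 2),
                    snpPos = c(1e6, 2.4e6, 3.6e6),
                    cpg = c("cgA", "cgB", "cgC"), p = c(1e-6, 1e-6, 1e-6))
  out <- locusReplicate(disc, rep, window = 5e5, alphaRep = 1e-3)
  expect_true(out$replicated[1])       # exact SNP match
  expect_true(out$replicated[2])       # 400 kb away
  expect_false(out$replicated[3])      # 600 kb away
  ## empty replication table: nothing replicates
  out2 <- locusReplicate(disc, rep[0, ], window = 5e5, alphaRep = 1e-3)
  expect_false(any(out2$replicated))
})

test_that("the meQTL scan recovers planted effects and respects alpha", {
  study <- testStudy()
  tr <- groundTruth(study)$snpCpg
  pairs <- runMeqtl(study, tr$cpg, alpha = 1e-5, transform = "logit")
  hit <- merge(tr, pairs, by = c("snp", "cpg"))
  expect_equal(nrow(hit), nrow(tr))    # all planted pairs detected
  z <- (hit$beta.y - hit$beta.x) / hit$se
  expect_lt(max(abs(z)), 2)
  expect_equal(hit$label[hit$trans], rep("trans", sum(hit$trans)))
  expect_equal(hit$label[!hit$trans], rep("cis", sum(!hit$trans)))
  ## empty CpG set and alpha = 1 behavior
  expect_equal(nrow(runMeqtl(study, character())), 0)
  one <- runMeqtl(study, tr$cpg[1], alpha = 1)
  expect_equal(nrow(one), attr(one, "nTests"))
})
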