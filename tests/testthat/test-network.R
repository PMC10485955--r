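test_that("metabolite residualization is an orthogonal projection", {
  set.seed(50)
  n <- 200
  Z <- cbind(a = rnorm(n), b = rnorm(n))
  M <- matrix(rnorm(5 * n), 5, n, dimnames = list(paste0("m", 1:5), NULL))
  R <- residualizeMetabolites(M, Z)
  for (i in 1:5) for (j in 1:2)
    expect_lt(abs(cor(R[i, ], Z[, j])), 1e-10)
  ## exact linear combination of covariates vanishes
  M2 <- matrix(2 + 0.5 * Z[, 1] - Z[, 2], 1, n)
  expect_lt(max(abs(residualizeMetabolites(M2, Z))), 1e-8)
  ## covariates orthogonal to the metabolite: residuals = centered values
  Zorth <- qr.Q(qr(cbind(1, Z)))[, 2:3]
  y <- residuals(lm(rnorm(n) ~ Zorth))
  ry <- residualizeMetabolites(matrix(y, 1, n), Zorth)
  expect_lt(max(abs(ry - (y - mean(y)))), 1e-10)
  expect_error(residualizeMetabolites(M, cbind(Z, Z)), "rank deficient")
})

test_that("shrinkage partial correlations match the exact inverse at large n", {
  set.seed(51)
  ## the analytic intensity decays like p^2 / (n * sum r^2), so the
  ## vanishing-shrinkage regime needs substantial correlation mass, not
  ## just large n
  n <- 4000; p <- 10
  Sig <- matrix(0.5, p, p); diag(Sig) <- 1
  X <- MASS::mvrnorm(n, rep(0, p), Sig)
  res <- t(X)
  rownames(res) <- paste0("m", 1:p)
  edges <- partialCorrelationNetwork(res)
  expect_lt(attr(edges, "lambda"), 0.01)
  pcorHat <- attr(edges, "pcor")
  Om <- solve(cor(X))
  exact <- -Om / sqrt(diag(Om) %o% diag(Om)); diag(exact) <- 1
  expect_lt(max(abs(pcorHat - exact)), 1e-3)
})

test_that("a chain graph is recovered without the spurious transitive edge", {
  set.seed(52)
  n <- 800; p <- 6
  pc <- matrix(0, p, p)
  pc[1, 2] <- pc[2, 1] <- 0.4
  pc[2, 3] <- pc[3, 2] <- 0.4
  Sig <- solve(diag(p) - pc)
  res <- t(MASS::mvrnorm(n, rep(0, p), Sig))
  rownames(res) <- paste0("m", 1:p)
  edges <- partialCorrelationNetwork(res)
  key <- paste(edges$met1, edges$met2)
  expect_true("m1 m2" %in% key)
  expect_true("m2 m3" %in% key)
  expect_false("m1 m3" %in% key)
})

test_that("independent panels produce (almost) no edges at Bonferroni", {
  set.seed(53)
  res <- matrix(rnorm(20 * 500), 20, 500,
                dimnames = list(paste0("m", 1:20), NULL))
  edges <- partialCorrelationNetwork(res)
  expect_lte(nrow(edges), 1)
})

test_that("the edge set is invariant under metabolite permutation", {
  set.seed(54)
  n <- 400; p <- 8
  pc <- matrix(0, p, p); pc[1, 5] <- pc[5, 1] <- 0.45
  res <- t(MASS::mvrnorm(n, rep(0, p), solve(diag(p) - pc)))
  rownames(res) <- paste0("m", 1:p)
  e1 <- partialCorrelationNetwork(res)
  perm <- sample(p)
  e2 <- partialCorrelationNetwork(res[perm, ])
  canon <- function(e) sort(paste(pmin(e$met1, e$met2),
                                  pmax(e$met1, e$met2)))
  expect_identical(canon(e1), canon(e2))
})

test_that("network assembly types nodes, drops duplicates, rejects conflicts", {
  meqtl <- data.frame(snp = "rs1", cpg = "cgA", beta = 2.1, p = 1e-12)
  cpgMet <- data.frame(cpg = "cgA", metabolite = "metX", beta = 0.02,
                       p = 1e-7)
  metMet <- data.frame(met1 = "metX", met2 = "metY", pcor = 0.3, p = 1e-9)
  net <- assembleNetwork(meqtl, cpgMet, metMet)
  expect_equal(nrow(net@nodes), 4)
  expect_equal(nrow(net@edges), 3)
  expect_equal(sort(unique(net@nodes$layer)), c("cpg", "metabolite", "snp"))
  comp <- componentStats(net)
  expect_equal(nrow(comp), 1)
  expect_equal(comp$nNodes, 4)
  expect_equal(comp$nEdges, 3)
  ## empty inputs: empty graph
  e <- assembleNetwork()
  expect_equal(nrow(e@nodes), 0)
  expect_equal(nrow(e@edges), 0)
  ## duplicate edges collapse keeping the smaller p
  dup <- rbind(metMet, data.frame(met1 = "metY", met2 = "metX",
                                  pcor = 0.2, p = 1e-3))
  net2 <- assembleNetwork(metMetEdges = dup)
  expect_equal(nrow(net2@edges), 1)
  expect_equal(net2@edges$p, 1e-9)
  ## an id in two layers is a hard error
  badMet <- data.frame(cpg = "rs1", metabolite = "metX", beta = 1, p = 0.01)
  expect_error(assembleNetwork(meqtl, badMet, NULL), "conflicting layer")
})

test_that("component statistics match a union-find oracle", {
  ## two disjoint triangles
  tri <- data.frame(
    met1 = c("a", "b", "c", "x", "y", "z"),
    met2 = c("b", "c", "a", "y", "z", "x"),
    pcor = 0.5, p = 1e-9)
  net <- assembleNetwork(metMetEdges = tri)
  comp <- componentStats(net)
  expect_equal(comp$nNodes, c(3, 3))
  expect_equal(comp$nEdges, c(3, 3))
  ## star with k leaves
  k <- 7
  star <- data.frame(met1 = "hub", met2 = paste0("leaf", 1:k),
                     pcor = 0.5, p = 1e-9)
  compS <- componentStats(assembleNetwork(metMetEdges = star))
  expect_equal(compS$nNodes, k + 1)
  expect_equal(compS$nEdges, k)
  ## random graph vs union-find
  set.seed(55)
  ids <- paste0("n", 1:30)
  from <- sample(ids, 25, replace = TRUE)
  to <- sample(ids, 25, replace = TRUE)
  keep <- from != to
  ed <- unique(data.frame(met1 = pmin(from[keep], to[keep]),
                          met2 = pmax(from[keep], to[keep]),
                          pcor = 0.1, p = 1e-9))
  netR <- assembleNetwork(metMetEdges = ed)
  compR <- componentStats(netR)
  oracle <- sort(unionFindComponents(unique(c(ed$met1, ed$met2)),
                                     ed$met1, ed$met2), decreasing = TRUE)
  expect_equal(compR$nNodes, oracle)
  expect_equal(sum(compR$nNodes), nrow(netR@nodes))
  expect_equal(sum(compR$nEdges), nrow(netR@edges))
})

test_that("exports produce readable SIF, GraphML and TSV files", {
  net <- assembleNetwork(
    data.frame(snp = "rs1", cpg = "cgA", beta = 2, p = 1e-10),
    data.frame(cpg = "cgA", metabolite = "metX", beta = 0.01, p = 1e-6),
    NULL)
  d <- withr::local_tempdir()
  exportSif(net, file.path(d, "net.sif"))
  sif <- readLines(file.path(d, "net.sif"))
  expect_equal(sort(sif), sort(c("rs1 meqtl cgA", "cgA cpg_met metX")))
  exportGraphML(net, file.path(d, "net.graphml"))
  g <- igraph::read_graph(file.path(d, "net.graphml"), format = "graphml")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  exportNetworkTables(net, file.path(d, "tabs"))
  nd <- read.delim(file.path(d, "tabs", "nodes.tsv"))
  expect_equal(nrow(nd), 3)
})
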