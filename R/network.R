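#' Residualize metabolites against a covariate design
#'
#' Per-metabolite OLS residuals against the full covariate set (with
#' intercept); the residuals feed the partial-correlation analysis.
#'
#' @param metabolites numeric matrix, metabolites x samples (QC'd z-scores).
#' @param covariates numeric design matrix (samples x k, no intercept).
#' @return residual matrix, metabolites x samples.
#' @export
residualizeMetabolites <- function(metabolites, covariates) {
  stopifnot(is.matrix(metabolites))
  X <- cbind(1, covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("covariate design is rank deficient")
  if (!anyNA(metabolites))
    return(t(qr.resid(qrX, t(metabolites))))
  ## per-metabolite complete-case residuals; missing cells stay missing
  out <- metabolites
  for (i in seq_len(nrow(metabolites))) {
    y <- metabolites[i, ]
    ok <- !is.na(y)
    qi <- qr(X[ok, , drop = FALSE])
    out[i, ok] <- qr.resid(qi, y[ok])
  }
  out
}

## Schafer-Strimmer analytic shrinkage of the correlation matrix towards the
## identity: lambda* = sum_{i<j} Var-hat(r_ij) / sum_{i<j} r_ij^2.
.shrinkCorrelation <- function(X) {
  n <- nrow(X); p <- ncol(X)
  Xs <- scale(X)
  r <- stats::cor(X)
  S2 <- crossprod(Xs^2)                 # sum_k (x_ki x_kj)^2
  wbar <- (n - 1) / n * r
  varR <- n / (n - 1)^3 * (S2 - n * wbar^2)
  off <- upper.tri(r)
  lambda <- sum(varR[off]) / sum(r[off]^2)
  if (lambda < 0 || lambda > 1) {
    warning("shrinkage intensity ", signif(lambda, 3), " clipped to [0,1]")
    lambda <- min(max(lambda, 0), 1)
  }
  Rs <- (1 - lambda) * r
  diag(Rs) <- 1
  list(R = Rs, lambda = lambda)
}

#' Metabolite partial-correlation network
#'
#' Estimates the metabolite Gaussian graphical model from covariate
#' residuals: the sample correlation matrix is shrunk towards the identity
#' with the analytic intensity estimator, partial correlations are computed
#' from its inverse (`pcor_ij = -P_ij / sqrt(P_ii P_jj)`), and each pair is
#' tested with the Fisher z transform at effective sample size
#' `n - p - 1` (the degrees of freedom left after conditioning on the other
#' `p - 2` metabolites). Pairs below the Bonferroni threshold over all
#' `p (p - 1) / 2` pairs are returned as edges.
#'
#' @param residuals matrix, metabolites x samples (see
#'   [residualizeMetabolites()]).
#' @param alpha per-pair threshold; default `0.05 / (p (p - 1) / 2)`.
#' @param naAction `"error"` (default) or `"meanImpute"`: replace missing
#'   residuals by the metabolite's mean before estimating the GGM.
#' @return data.frame of edges (`met1`, `met2`, `pcor`, `p`), with
#'   attributes `"lambda"` (shrinkage intensity used) and `"pcor"` (the full
#'   partial-correlation matrix).
#' @export
partialCorrelationNetwork <- function(residuals, alpha = NULL,
                                      naAction = c("error", "meanImpute")) {
  naAction <- match.arg(naAction)
  if (anyNA(residuals)) {
    if (naAction == "error")
      stop("residual matrix contains missing values; ",
           "use naAction = \"meanImpute\" or complete the data")
    mu <- rowMeans(residuals, na.rm = TRUE)
    idx <- which(is.na(residuals), arr.ind = TRUE)
    residuals[idx] <- mu[idx[, 1]]
  }
  X <- t(residuals)                     # samples x metabolites
  n <- nrow(X); p <- ncol(X)
  if (n <= 3) stop("need more than 3 samples")
  if (n - p - 1 < 3)
    stop("too few samples for ", p, " metabolites (need n > p + 4)")
  if (is.null(alpha)) alpha <- 0.05 / (p * (p - 1) / 2)
  sh <- .shrinkCorrelation(X)
  P <- solve(sh$R)
  pcor <- -P / sqrt(diag(P) %o% diag(P))
  diag(pcor) <- 1
  dimnames(pcor) <- list(rownames(residuals), rownames(residuals))
  z <- atanh(pcor[upper.tri(pcor)])
  pv <- 2 * stats::pnorm(-abs(z) * sqrt(n - p - 1))
  idx <- which(upper.tri(pcor), arr.ind = TRUE)
  keep <- pv < alpha
  edges <- data.frame(met1 = rownames(pcor)[idx[keep, 1]],
                      met2 = rownames(pcor)[idx[keep, 2]],
                      pcor = pcor[upper.tri(pcor)][keep],
                      p = pv[keep], row.names = NULL)
  attr(edges, "lambda") <- sh$lambda
  attr(edges, "pcor") <- pcor
  edges
}

#' Assemble the tripartite multi-omics network
#'
#' Union of meQTL (SNP-CpG), CpG-metabolite and metabolite-metabolite edge
#' tables into one typed graph. Node layers are inferred from the edge
#' types; an identifier appearing in conflicting layers raises an error.
#' Duplicate edges (same endpoints and type) collapse to the one with the
#' smaller p-value.
#'
#' @param meqtlPairs data.frame with `snp`, `cpg`, `beta`, `p` (or `NULL`).
#' @param cpgMetPairs data.frame with `cpg`, `metabolite`, `beta`, `p` (or
#'   `NULL`).
#' @param metMetEdges data.frame with `met1`, `met2`, `pcor`, `p` (or
#'   `NULL`).
#' @return an \linkS4class{OmicsNetwork}.
#' @export
assembleNetwork <- function(meqtlPairs = NULL, cpgMetPairs = NULL,
                            metMetEdges = NULL) {
  edges <- list()
  if (!is.null(meqtlPairs) && nrow(meqtlPairs))
    edges$meqtl <- data.frame(from = meqtlPairs$snp, to = meqtlPairs$cpg,
                              type = "meqtl", weight = meqtlPairs$beta,
                              p = meqtlPairs$p)
  if (!is.null(cpgMetPairs) && nrow(cpgMetPairs))
    edges$cpg_met <- data.frame(from = cpgMetPairs$cpg,
                                to = cpgMetPairs$metabolite,
                                type = "cpg_met", weight = cpgMetPairs$beta,
                                p = cpgMetPairs$p)
  if (!is.null(metMetEdges) && nrow(metMetEdges))
    edges$met_met <- data.frame(from = metMetEdges$met1,
                                to = metMetEdges$met2,
                                type = "met_met", weight = metMetEdges$pcor,
                                p = metMetEdges$p)
  ed <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(), type = character(),
               weight = numeric(), p = numeric())
  rownames(ed) <- NULL
  if (nrow(ed)) {
    ## collapse duplicates (unordered endpoints within a type) keeping min p
    a <- pmin(ed$from, ed$to); b <- pmax(ed$from, ed$to)
    key <- paste(ed$type, a, b, sep = "\r")
    ed <- ed[order(key, ed$p), ]
    ed <- ed[!duplicated(paste(ed$type, pmin(ed$from, ed$to),
                               pmax(ed$from, ed$to), sep = "\r")), ]
    rownames(ed) <- NULL
  }
  layerOf <- rbind(
    if (!is.null(ed) && nrow(ed)) data.frame(
      id = c(ed$from[ed$type == "meqtl"], ed$to[ed$type == "meqtl"],
             ed$from[ed$type == "cpg_met"], ed$to[ed$type == "cpg_met"],
             ed$from[ed$type == "met_met"], ed$to[ed$type == "met_met"]),
      layer = c(rep("snp", sum(ed$type == "meqtl")),
                rep("cpg", sum(ed$type == "meqtl")),
                rep("cpg", sum(ed$type == "cpg_met")),
                rep("metabolite", sum(ed$type == "cpg_met")),
                rep("metabolite", 2 * sum(ed$type == "met_met")))))
  nodes <- unique(layerOf)
  if (anyDuplicated(nodes$id)) {
    bad <- nodes$id[duplicated(nodes$id)]
    stop("conflicting layer assignment for: ",
         paste(unique(bad), collapse = ", "))
  }
  if (is.null(nodes))
    nodes <- data.frame(id = character(), layer = character())
  rownames(nodes) <- NULL
  new("OmicsNetwork", nodes = nodes, edges = ed)
}

#' Connected-component summary of an omics network
#'
#' @param network an \linkS4class{OmicsNetwork}.
#' @return data.frame sorted by decreasing size: `component`, `nNodes`,
#'   `nEdges`.
#' @export
componentStats <- function(network) {
  stopifnot(is(network, "OmicsNetwork"))
  if (!nrow(network@nodes))
    return(data.frame(component = integer(), nNodes = integer(),
                      nEdges = integer()))
  g <- .asIgraph(network)
  comp <- igraph::components(g)
  memb <- comp$membership
  eFrom <- memb[network@edges$from]
  sizes <- as.integer(comp$csize)
  nE <- vapply(seq_along(sizes), function(k) sum(eFrom == k), integer(1))
  out <- data.frame(component = seq_along(sizes), nNodes = sizes,
                    nEdges = nE)
  out <- out[order(-out$nNodes), ]
  out$component <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

.asIgraph <- function(network) {
  igraph::graph_from_data_frame(
    network@edges[, c("from", "to", "type", "weight", "p")],
    directed = FALSE, vertices = network@nodes)
}

#' Export an omics network
#'
#' `exportSif()` writes the simple-interaction format
#' (`node1 edgetype node2`); `exportGraphML()` writes GraphML with layer,
#' weight and p attributes; `exportNetworkTables()` writes Cytoscape-ready
#' node and edge TSVs.
#'
#' @param network an \linkS4class{OmicsNetwork}.
#' @param path output file (or directory for `exportNetworkTables`).
#' @return the path(s) written, invisibly.
#' @export
exportSif <- function(network, path) {
  ed <- network@edges
  writeLines(paste(ed$from, ed$type, ed$to), path)
  invisible(path)
}

#' @rdname exportSif
#' @export
exportGraphML <- function(network, path) {
  igraph::write_graph(.asIgraph(network), path, format = "graphml")
  invisible(path)
}

#' @rdname exportSif
#' @export
exportNetworkTables <- function(network, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  nf <- file.path(path, "nodes.tsv"); ef <- file.path(path, "edges.tsv")
  utils::write.table(network@nodes, nf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(network@edges, ef, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(nf, ef))
}
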