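#' Read genotype dosages from a minimal VCF
#'
#' Uses the `DS` FORMAT field when present, otherwise counts alternate
#' alleles in `GT` (`0/1` -> 1, `1/1` -> 2, `.` -> NA). Multiallelic records
#' are skipped (with a message) or raise an error, per `multiallelic`.
#' Positions are kept 1-based as in the file.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param multiallelic `"skip"` (default) or `"error"`.
#' @return SummarizedExperiment, SNPs x samples, assay `"dosage"`, rowData
#'   `chr`, `pos`, `ref`, `alt`.
#' @export
readVcfDosages <- function(path, multiallelic = c("skip", "error")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm)))              # single-record files drop to a vector
    fixm <- matrix(fixm, nrow = 1, dimnames = list(NULL, names(fixm)))
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    if (multiallelic == "error")
      stop("multiallelic record(s) at line(s): ",
           paste(which(multi), collapse = ", "))
    message("skipping ", sum(multi), " multiallelic record(s)")
  }
  keep <- !multi
  fmt <- v@gt[, 1]
  hasDS <- all(grepl("DS", fmt))
  if (hasDS) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    cnt <- function(x) {
      ifelse(is.na(x) | x %in% c(".", "./.", ".|."), NA,
             vapply(strsplit(gsub("\\|", "/", x), "/"),
                    function(a) sum(a == "1"), numeric(1)))
    }
    ds <- apply(gt, 2, cnt)
    dimnames(ds) <- dimnames(gt)
  }
  ds <- ds[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID)
  rownames(ds) <- ids
  SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = ds),
    rowData = S4Vectors::DataFrame(chr = fix$CHROM,
                                   pos = as.integer(fix$POS),
                                   ref = fix$REF, alt = fix$ALT,
                                   row.names = ids))
}

#' Write genotype dosages as a minimal VCF
#'
#' @param genotypes genotype SummarizedExperiment (assay `"dosage"`, rowData
#'   chr/pos/ref/alt).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeVcfDosages <- function(genotypes, path) {
  G <- SummarizedExperiment::assay(genotypes, "dosage")
  rd <- SummarizedExperiment::rowData(genotypes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(G)), collapse = "\t")),
             con)
  body <- cbind(rd$chr, rd$pos, rownames(G), rd$ref, rd$alt, ".", "PASS",
                ".", "DS",
                matrix(format(G, trim = TRUE, digits = 10), nrow(G)))
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write feature-by-sample matrices with annotation columns
#'
#' TSV layout: `id` column, any annotation columns, then one column per
#' sample. Values round-trip at full double precision.
#'
#' @param x SummarizedExperiment (any first assay) or numeric matrix.
#' @param path TSV path.
#' @param annotation data.frame of per-feature annotation (taken from
#'   `rowData` for a SummarizedExperiment).
#' @return `readOmicsMatrix`: list with `matrix` and `annotation`.
#' @export
writeOmicsMatrix <- function(x, path, annotation = NULL) {
  if (is(x, "SummarizedExperiment")) {
    annotation <- as.data.frame(SummarizedExperiment::rowData(x))
    x <- SummarizedExperiment::assays(x)[[1]]
  }
  df <- data.frame(id = rownames(x), annotation,
                   as.data.frame(format(x, trim = TRUE, digits = 17)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeOmicsMatrix
#' @param annotationCols names of annotation columns in the file.
#' @export
readOmicsMatrix <- function(path, annotationCols = character()) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  anno <- df[, annotationCols, drop = FALSE]
  rownames(anno) <- df$id
  mat <- as.matrix(df[, setdiff(names(df), c("id", annotationCols)),
                      drop = FALSE])
  mat <- apply(mat, 2, as.numeric)
  rownames(mat) <- df$id
  list(matrix = mat, annotation = anno)
}

#' Write a synthetic study to a directory of plain-text files
#'
#' Sample sheet TSV, methylation TSV (id, chr, pos, per-sample beta),
#' genotypes as minimal VCF, metabolite TSV with pathway annotation, and a
#' ground-truth JSON holding the planted effect tables plus sparse encodings
#' of the expected kinship and metabolite precision matrices.
#'
#' @param study a \linkS4class{MultiOmicsStudy}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  st <- as.data.frame(study@samples)
  utils::write.table(st, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeOmicsMatrix(study@methylation, file.path(dir, "methylation.tsv"))
  writeVcfDosages(study@genotypes, file.path(dir, "genotypes.vcf"))
  writeOmicsMatrix(study@metabolites, file.path(dir, "metabolites.tsv"))
  tr <- study@groundTruth
  if (length(tr)) {
    sparse <- function(M) {
      ix <- which(upper.tri(M) & M != 0, arr.ind = TRUE)
      data.frame(i = ix[, 1], j = ix[, 2], value = M[ix])
    }
    json <- list(
      snpCpg = tr$snpCpg, t2dCpg = tr$t2dCpg,
      t2dMetabolite = tr$t2dMetabolite, cpgMetabolite = tr$cpgMetabolite,
      smokingCpg = tr$smokingCpg,
      kinshipOffDiagonal = sparse(tr$kinship - diag(nrow(tr$kinship))),
      precisionOffDiagonal = sparse(tr$precision))
    jsonlite::write_json(json, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(dir)
}

#' Read a study directory written by [writeStudy()]
#'
#' @param dir directory containing `samples.tsv`, `methylation.tsv`,
#'   `genotypes.vcf`, `metabolites.tsv` (and optionally `truth.json`).
#' @return a \linkS4class{MultiOmicsStudy} (ground truth restricted to the
#'   effect tables stored in the JSON).
#' @export
readStudy <- function(dir) {
  st <- utils::read.delim(file.path(dir, "samples.tsv"),
                          stringsAsFactors = FALSE)
  samples <- S4Vectors::DataFrame(st, row.names = st$sample)
  meth <- readOmicsMatrix(file.path(dir, "methylation.tsv"),
                          annotationCols = c("chr", "pos"))
  geno <- readVcfDosages(file.path(dir, "genotypes.vcf"))
  mets <- readOmicsMatrix(file.path(dir, "metabolites.tsv"),
                          annotationCols = c("pathway", "subpathway"))
  truthFile <- file.path(dir, "truth.json")
  truth <- if (file.exists(truthFile)) {
    j <- jsonlite::read_json(truthFile, simplifyVector = TRUE)
    j[c("snpCpg", "t2dCpg", "t2dMetabolite", "cpgMetabolite", "smokingCpg")]
  } else list()
  mkSE <- function(lst, assayName) {
    SummarizedExperiment::SummarizedExperiment(
      assays = stats::setNames(list(lst$matrix), assayName),
      rowData = S4Vectors::DataFrame(lst$annotation),
      colData = samples)
  }
  SummarizedExperiment::colData(geno) <- samples
  new("MultiOmicsStudy", samples = samples,
      methylation = mkSE(meth, "beta"),
      genotypes = geno,
      metabolites = mkSE(mets, "abundance"),
      groundTruth = if (is.null(truth)) list() else truth)
}
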