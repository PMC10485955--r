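#' Accessors for MultiOmicsStudy layers
#'
#' `sampleTable()` returns the per-sample phenotype/covariate table as a
#' `data.frame`; `methylation()`, `genotypes()` and `metabolites()` return the
#' layer `SummarizedExperiment`s; `betaValues()`, `dosages()` and
#' `abundances()` return the bare assay matrices (features x samples);
#' `groundTruth()` returns the generator's truth list (empty for real data).
#'
#' @param x a \linkS4class{MultiOmicsStudy}.
#' @return see Description.
#' @name study-accessors
#' @aliases sampleTable methylation genotypes metabolites betaValues dosages
#'   abundances groundTruth
NULL

#' @rdname study-accessors
#' @export
setGeneric("sampleTable", function(x) standardGeneric("sampleTable"))
#' @rdname study-accessors
#' @export
setGeneric("methylation", function(x) standardGeneric("methylation"))
#' @rdname study-accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname study-accessors
#' @export
setGeneric("metabolites", function(x) standardGeneric("metabolites"))
#' @rdname study-accessors
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))
#' @rdname study-accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname study-accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))
#' @rdname study-accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname study-accessors
setMethod("sampleTable", "MultiOmicsStudy", function(x)
  as.data.frame(x@samples))
#' @rdname study-accessors
setMethod("methylation", "MultiOmicsStudy", function(x) x@methylation)
#' @rdname study-accessors
setMethod("genotypes", "MultiOmicsStudy", function(x) x@genotypes)
#' @rdname study-accessors
setMethod("metabolites", "MultiOmicsStudy", function(x) x@metabolites)
#' @rdname study-accessors
setMethod("betaValues", "MultiOmicsStudy", function(x)
  SummarizedExperiment::assay(x@methylation, "beta"))
#' @rdname study-accessors
setMethod("dosages", "MultiOmicsStudy", function(x)
  SummarizedExperiment::assay(x@genotypes, "dosage"))
#' @rdname study-accessors
setMethod("abundances", "MultiOmicsStudy", function(x)
  SummarizedExperiment::assay(x@metabolites, "abundance"))
#' @rdname study-accessors
setMethod("groundTruth", "MultiOmicsStudy", function(x) x@groundTruth)
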