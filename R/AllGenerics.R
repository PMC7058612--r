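#' Accessors for mitolandscape containers
#'
#' `genotypeCalls()` returns the samples x variants call matrix,
#' `sampleIds()` the sample identifiers, `variantInfo()` the variant
#' annotation table, `variantPositions()` the 1-based coordinates,
#' `altFreqs()` per-variant alternative-allele frequencies over
#' non-missing calls, and `mtLength()` the circular reference length.
#'
#' @param x a container object.
#' @return See the individual descriptions above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))
#' @rdname accessors
#' @export
setGeneric("variantPositions",
           function(x) standardGeneric("variantPositions"))
#' @rdname accessors
#' @export
setGeneric("altFreqs", function(x) standardGeneric("altFreqs"))
#' @rdname accessors
#' @export
setGeneric("mtLength", function(x) standardGeneric("mtLength"))
#' @rdname accessors
#' @export
setGeneric("panelHaplotypes",
           function(x) standardGeneric("panelHaplotypes"))
#' @rdname accessors
#' @export
setGeneric("dosageMatrix", function(x) standardGeneric("dosageMatrix"))
#' @rdname accessors
#' @export
setGeneric("infoScores", function(x) standardGeneric("infoScores"))
#' @rdname accessors
#' @export
setGeneric("imputedFlags", function(x) standardGeneric("imputedFlags"))
#' @rdname accessors
#' @export
setGeneric("treeNodes", function(x) standardGeneric("treeNodes"))

#' @rdname accessors
#' @export
setMethod("genotypeCalls", "HaploidGenotypeMatrix", function(x) x@calls)
#' @rdname accessors
#' @export
setMethod("sampleIds", "HaploidGenotypeMatrix",
          function(x) rownames(x@calls))
#' @rdname accessors
#' @export
setMethod("variantInfo", "HaploidGenotypeMatrix", function(x) x@variants)
#' @rdname accessors
#' @export
setMethod("variantPositions", "HaploidGenotypeMatrix",
          function(x) x@variants$position)
#' @rdname accessors
#' @export
setMethod("mtLength", "HaploidGenotypeMatrix", function(x) x@mtLength)
#' @rdname accessors
#' @export
setMethod("altFreqs", "HaploidGenotypeMatrix",
          function(x) colMeans(x@calls, na.rm = TRUE))

#' @rdname accessors
#' @export
setMethod("panelHaplotypes", "HaplotypePanel", function(x) x@haplotypes)
#' @rdname accessors
#' @export
setMethod("variantPositions", "HaplotypePanel", function(x) x@positions)
#' @rdname accessors
#' @export
setMethod("altFreqs", "HaplotypePanel",
          function(x) colMeans(x@haplotypes))

#' @rdname accessors
#' @export
setMethod("dosageMatrix", "ImputedDosage", function(x) x@doses)
#' @rdname accessors
#' @export
setMethod("infoScores", "ImputedDosage", function(x) x@info)
#' @rdname accessors
#' @export
setMethod("imputedFlags", "ImputedDosage", function(x) x@imputed)
#' @rdname accessors
#' @export
setMethod("variantInfo", "ImputedDosage", function(x) x@variants)
#' @rdname accessors
#' @export
setMethod("sampleIds", "ImputedDosage", function(x) rownames(x@doses))

#' @rdname accessors
#' @export
setMethod("treeNodes", "Haplotree",
          function(x) c(x@root, x@edges$child))

#' @describeIn HaploidGenotypeMatrix-class dimensions
#'   (samples, variants).
#' @param x a HaploidGenotypeMatrix.
#' @export
setMethod("dim", "HaploidGenotypeMatrix", function(x) dim(x@calls))

setMethod("show", "HaploidGenotypeMatrix", function(object) {
  cat(sprintf(
    "HaploidGenotypeMatrix: %d samples x %d variants (contig %s, %d bp)\n",
    nrow(object@calls), ncol(object@calls),
    paste(unique(object@variants$contig), collapse = ","),
    as.integer(object@mtLength)))
  miss <- mean(is.na(object@calls))
  cat(sprintf("  missingness: %.2f%%\n", 100 * miss))
})

setMethod("show", "HaplotypePanel", function(object) {
  cat(sprintf("HaplotypePanel: %d phased haplotypes x %d variants\n",
              nrow(object@haplotypes), ncol(object@haplotypes)))
  cat(sprintf("  positions %g-%g bp\n", min(object@positions),
              max(object@positions)))
})

setMethod("show", "Haplotree", function(object) {
  cat(sprintf("Haplotree: %d nodes (root '%s'), %d edges\n",
              length(treeNodes(object)), object@root,
              nrow(object@edges)))
})

setMethod("show", "ImputedDosage", function(object) {
  cat(sprintf(
    "ImputedDosage: %d samples x %d variants (%d typed, %d imputed)\n",
    nrow(object@doses), ncol(object@doses), sum(!object@imputed),
    sum(object@imputed)))
})

setMethod("show", "RegionAnnotation", function(object) {
  cat(sprintf("RegionAnnotation '%s': %s\n", object@name,
              paste(sprintf("%d-%d", object@intervals$start,
                            object@intervals$end), collapse = ", ")))
})
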