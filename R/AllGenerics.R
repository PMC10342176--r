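#' @rdname BulkVariants-class
#' @param x,object a \code{BulkVariants} object.
#' @export
setGeneric("bulkLabel", function(x) standardGeneric("bulkLabel"))

#' @rdname BulkVariants-class
#' @export
setGeneric("variantKeys", function(x) standardGeneric("variantKeys"))

#' @rdname BulkVariants-class
#' @export
setGeneric("altFraction", function(x) standardGeneric("altFraction"))

#' @rdname GeneModels-class
#' @param x,object a \code{GeneModels} object.
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname GeneModels-class
#' @export
setGeneric("cdsByGene", function(x) standardGeneric("cdsByGene"))

#' @rdname BulkVariants-class
setMethod("bulkLabel", "BulkVariants", function(x) x@bulk)

#' @rdname BulkVariants-class
setMethod("variantKeys", "BulkVariants", function(x) {
    paste(as.character(seqnames(x)), start(x), mcols(x)$ref, mcols(x)$alt,
          sep = ":")
})

#' @rdname BulkVariants-class
setMethod("altFraction", "BulkVariants", function(x) {
    m <- mcols(x)
    tot <- m$adRef + m$adAlt
    ifelse(is.na(tot) | tot == 0, NA_real_, m$adAlt / tot)
})

#' @rdname GeneModels-class
setMethod("geneRanges", "GeneModels", function(x) x@genes)

#' @rdname GeneModels-class
setMethod("cdsByGene", "GeneModels", function(x) x@cds)

#' @rdname BulkVariants-class
setMethod("show", "BulkVariants", function(object) {
    cat(sprintf("BulkVariants: %d record(s) from bulk '%s'\n",
                length(object), object@bulk))
    callNextMethod()
})

#' @rdname BulkDesign-class
#' @param object a \code{BulkDesign}.
setMethod("show", "BulkDesign", function(object) {
    het <- if (is.na(object@hetCount)) "unknown" else object@hetCount
    cat(sprintf(
        "BulkDesign: %s bulk of %d plants (heterozygous: %s), %s / %s\n",
        object@role, object@nPlants, het, object@inheritance, object@family))
})

#' @rdname FilterThresholds-class
#' @param object a \code{FilterThresholds}.
setMethod("show", "FilterThresholds", function(object) {
    cat(sprintf(
        "FilterThresholds: minAB=%g minDP=%g minGQ=%g minQD=%g\n",
        object@minAB, object@minDP, object@minGQ, object@minQD))
})

#' @rdname GeneModels-class
setMethod("show", "GeneModels", function(object) {
    cat(sprintf("GeneModels: %d gene(s), CDS models for %d\n",
                length(object@genes), length(object@cds)))
})

#' @rdname SimScenario-class
#' @param object a \code{SimScenario}.
setMethod("show", "SimScenario", function(object) {
    cat(sprintf(paste0(
        "SimScenario: seed=%d, %g bp genome, %d genes, %d background ",
        "variants (%.0f%% shared)\n  bulks %d mutant / %d wildtype ",
        "(het: %s), depth %gx, error %g\n"),
        object@seed, object@genomeLength, object@nGenes, object@nBackground,
        100 * object@sharedFraction, object@bulkMutantN, object@bulkWtN,
        if (is.na(object@wtHetCount)) "random" else object@wtHetCount,
        object@meanDepth, object@errorRate))
    if (length(object@deletion))
        cat(sprintf("  planted deletion: %g-%g (0-based half-open)\n",
                    object@deletion[1], object@deletion[2]))
})
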