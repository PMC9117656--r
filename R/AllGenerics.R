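#' Accessors for package classes
#'
#' Small accessor generics so user code never reaches into slots.
#'
#' @param x an object of one of the package classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("genomeSequence", function(x) standardGeneric("genomeSequence"))
#' @rdname accessors
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))
#' @rdname accessors
#' @export
setGeneric("features", function(x) standardGeneric("features"))
#' @rdname accessors
#' @export
setGeneric("isCircular", function(x) standardGeneric("isCircular"))
#' @rdname accessors
#' @export
setGeneric("subgenus", function(x) standardGeneric("subgenus"))
#' @rdname accessors
#' @export
setGeneric("alignmentRows", function(x) standardGeneric("alignmentRows"))
#' @rdname accessors
#' @export
setGeneric("referenceId", function(x) standardGeneric("referenceId"))
#' @rdname accessors
#' @export
setGeneric("regionLengths", function(x) standardGeneric("regionLengths"))
#' @rdname accessors
#' @export
setGeneric("classTally", function(x) standardGeneric("classTally"))
#' @rdname accessors
#' @export
setGeneric("variantSites", function(x) standardGeneric("variantSites"))
#' @rdname accessors
#' @export
setGeneric("consensusSequence", function(x) standardGeneric("consensusSequence"))

#' @rdname accessors
#' @export
setMethod("sampleId", "AnnotatedGenome", function(x) x@sampleId)
#' @rdname accessors
#' @export
setMethod("genomeSequence", "AnnotatedGenome", function(x) x@sequence)
#' @rdname accessors
#' @export
setMethod("genomeLength", "AnnotatedGenome", function(x) nchar(x@sequence))
#' @rdname accessors
#' @export
setMethod("features", "AnnotatedGenome", function(x) x@features)
#' @rdname accessors
#' @export
setMethod("isCircular", "AnnotatedGenome", function(x) x@circular)
#' @rdname accessors
#' @export
setMethod("subgenus", "AnnotatedGenome", function(x) x@subgenus)

#' @rdname accessors
#' @export
setMethod("alignmentRows", "PlastomeAlignment", function(x) x@seqs)
#' @rdname accessors
#' @export
setMethod("referenceId", "PlastomeAlignment", function(x) x@referenceId)
#' @rdname accessors
#' @export
setMethod("sampleId", "PlastomeAlignment", function(x) names(x@seqs))

#' @rdname accessors
#' @export
setMethod("regionLengths", "QuadripartiteStructure", function(x) {
  c(total = x@totalLength, lsc = x@lscLength, ssc = x@sscLength,
    ir = x@irLength)
})

#' @rdname accessors
#' @export
setMethod("classTally", "VariantTable", function(x) x@classTally)
#' @rdname accessors
#' @export
setMethod("variantSites", "VariantTable", function(x) x@sites)
#' @rdname accessors
#' @export
setMethod("consensusSequence", "VariantTable", function(x) x@consensus)
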