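#' Transcript accessors
#'
#' `txLength()` returns summed exon widths (nt), `exonCount()` the number of
#' exons, `txSpan()` the genomic span (one `GRanges` entry per transcript),
#' `txExons()` the exon `GRangesList`, and `txData()` the per-transcript
#' metadata `DataFrame`.
#'
#' @param x A [TranscriptSet-class].
#' @return Named integer vector, `GRanges`, `GRangesList` or `DataFrame`.
#' @examples
#' ts <- simulateAnnotation(simConfig(seed = 1))$transcripts
#' head(txLength(ts))
#' @name transcript-accessors
NULL

#' @rdname transcript-accessors
#' @export
setGeneric("txLength", function(x) standardGeneric("txLength"))

#' @rdname transcript-accessors
#' @export
setGeneric("exonCount", function(x) standardGeneric("exonCount"))

#' @rdname transcript-accessors
#' @export
setGeneric("txSpan", function(x) standardGeneric("txSpan"))

#' @rdname transcript-accessors
#' @export
setGeneric("txExons", function(x) standardGeneric("txExons"))

#' @rdname transcript-accessors
#' @export
setGeneric("txData", function(x) standardGeneric("txData"))

#' @rdname transcript-accessors
#' @export
setMethod("txLength", "TranscriptSet", function(x)
  setNames(as.integer(sum(width(x@exons))), names(x@exons)))

#' @rdname transcript-accessors
#' @export
setMethod("exonCount", "TranscriptSet", function(x)
  setNames(elementNROWS(x@exons), names(x@exons)))

#' @rdname transcript-accessors
#' @export
setMethod("txSpan", "TranscriptSet", function(x) {
  sp <- unlist(range(x@exons))
  mcols(sp)$transcript_id <- names(sp)
  mcols(sp)$gene_id <- x@txData$gene_id
  sp
})

#' @rdname transcript-accessors
#' @export
setMethod("txExons", "TranscriptSet", function(x) x@exons)

#' @rdname transcript-accessors
#' @export
setMethod("txData", "TranscriptSet", function(x) x@txData)

#' @export
setMethod("length", "TranscriptSet", function(x) length(x@exons))

#' @export
setMethod("names", "TranscriptSet", function(x) names(x@exons))

#' Subset a TranscriptSet by index, name or logical
#'
#' @param x A [TranscriptSet-class].
#' @param i Index vector.
#' @param j,drop,... Ignored.
#' @return A [TranscriptSet-class].
#' @export
setMethod("[", "TranscriptSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@exons))
  new("TranscriptSet", exons = x@exons[i], txData = x@txData[i, , drop = FALSE])
})

#' Expression accessors
#'
#' `abundance()` returns the abundance assay matrix, `stages()` the
#' per-sample stage labels, `layerType()` the RNA layer.
#'
#' @param x An [ExpressionMatrix-class].
#' @return Matrix, character vector, or scalar string.
#' @name expression-accessors
NULL

#' @rdname expression-accessors
#' @export
setGeneric("abundance", function(x) standardGeneric("abundance"))

#' @rdname expression-accessors
#' @export
setGeneric("stages", function(x) standardGeneric("stages"))

#' @rdname expression-accessors
#' @export
setGeneric("layerType", function(x) standardGeneric("layerType"))

#' @rdname expression-accessors
#' @export
setMethod("abundance", "ExpressionMatrix", function(x)
  SummarizedExperiment::assay(x, "abundance"))

#' @rdname expression-accessors
#' @export
setMethod("stages", "ExpressionMatrix", function(x)
  setNames(as.character(colData(x)$stage), colnames(x)))

#' @rdname expression-accessors
#' @export
setMethod("layerType", "ExpressionMatrix", function(x) metadata(x)$layer)

#' Network accessors
#'
#' `triads()` returns the triad table of a [CernaNetwork-class];
#' `networkEdges()` the typed edge table.
#'
#' @param x A [CernaNetwork-class].
#' @return A `DataFrame`.
#' @name network-accessors
NULL

#' @rdname network-accessors
#' @export
setGeneric("triads", function(x) standardGeneric("triads"))

#' @rdname network-accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname network-accessors
#' @export
setMethod("triads", "CernaNetwork", function(x) x@triads)

#' @rdname network-accessors
#' @export
setMethod("networkEdges", "CernaNetwork", function(x) x@edges)
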