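#' @include AllClasses.R
NULL

#' Accessors for TranscriptSet
#'
#' \code{transcriptIds} returns the transcript identifiers; \code{geneIds}
#' the parent gene ids; \code{txCategory} the annotation category;
#' \code{txExons} the underlying \code{GRangesList} of exons;
#' \code{txLengths} the spliced transcript lengths (sum of exon widths, bp);
#' \code{txSpans} one \code{GRanges} per transcript covering first exon
#' start to last exon end.  Spans (not exon unions) are the substrate for
#' all positional comparisons in this package.
#'
#' @param x A \linkS4class{TranscriptSet}.
#' @return See individual descriptions.
#' @name TranscriptSet-accessors
NULL

#' @rdname TranscriptSet-accessors
#' @export
setGeneric("transcriptIds", function(x) standardGeneric("transcriptIds"))
#' @rdname TranscriptSet-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname TranscriptSet-accessors
#' @export
setGeneric("txCategory", function(x) standardGeneric("txCategory"))
#' @rdname TranscriptSet-accessors
#' @export
setGeneric("txExons", function(x) standardGeneric("txExons"))
#' @rdname TranscriptSet-accessors
#' @export
setGeneric("txLengths", function(x) standardGeneric("txLengths"))
#' @rdname TranscriptSet-accessors
#' @export
setGeneric("txSpans", function(x) standardGeneric("txSpans"))

#' @rdname TranscriptSet-accessors
setMethod("transcriptIds", "TranscriptSet", function(x) names(x@exons))

#' @rdname TranscriptSet-accessors
setMethod("geneIds", "TranscriptSet", function(x) {
  stats::setNames(x@txData$gene_id, rownames(x@txData))
})

#' @rdname TranscriptSet-accessors
setMethod("txCategory", "TranscriptSet", function(x) {
  stats::setNames(x@txData$category, rownames(x@txData))
})

#' @rdname TranscriptSet-accessors
setMethod("txExons", "TranscriptSet", function(x) x@exons)

#' @rdname TranscriptSet-accessors
setMethod("txLengths", "TranscriptSet", function(x) {
  stats::setNames(sum(width(x@exons)), names(x@exons))
})

#' @rdname TranscriptSet-accessors
setMethod("txSpans", "TranscriptSet", function(x) {
  sp <- unlist(range(x@exons), use.names = TRUE)
  mcols(sp)$gene_id <- x@txData$gene_id
  mcols(sp)$category <- x@txData$category
  sp
})
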