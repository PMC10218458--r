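#' Accessors for scarsig S4 classes
#'
#' Small accessor generics so user code never touches slots directly:
#' `sampleId()` returns sample identifiers, `scheme()` the channel scheme,
#' `channelCounts()` a catalog's named count vector, `nUnclassified()` the
#' number of records a catalog could not classify, `signatureNames()` the
#' signature identifiers of a [SignatureSet-class] or [SignatureFit-class],
#' `signatureProbs()` the signatures-by-channels probability matrix, and
#' `exposures()` the refitted weight vector of a [SignatureFit-class].
#'
#' @param x a scarsig object.
#' @return the corresponding slot value (see details above).
#' @name accessors
#' @aliases sampleId scheme channelCounts nUnclassified signatureNames
#'   signatureProbs exposures
#' @examples
#' sigs <- bundledSignatures("SBS96")
#' signatureNames(sigs)
NULL

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("scheme", function(x) standardGeneric("scheme"))
#' @rdname accessors
#' @export
setGeneric("channelCounts", function(x) standardGeneric("channelCounts"))
#' @rdname accessors
#' @export
setGeneric("nUnclassified", function(x) standardGeneric("nUnclassified"))
#' @rdname accessors
#' @export
setGeneric("signatureNames", function(x) standardGeneric("signatureNames"))
#' @rdname accessors
#' @export
setGeneric("signatureProbs", function(x) standardGeneric("signatureProbs"))
#' @rdname accessors
#' @export
setGeneric("exposures", function(x) standardGeneric("exposures"))

#' @rdname accessors
#' @export
setMethod("sampleId", "MutationCatalog", function(x) x@sampleId)
#' @rdname accessors
#' @export
setMethod("sampleId", "SignatureFit", function(x) x@sampleId)
#' @rdname accessors
#' @export
setMethod("sampleId", "ScarScores", function(x) x@sampleId)
#' @rdname accessors
#' @export
setMethod("scheme", "MutationCatalog", function(x) x@scheme)
#' @rdname accessors
#' @export
setMethod("scheme", "SignatureSet", function(x) x@scheme)
#' @rdname accessors
#' @export
setMethod("channelCounts", "MutationCatalog", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("nUnclassified", "MutationCatalog", function(x) x@nUnclassified)
#' @rdname accessors
#' @export
setMethod("signatureNames", "SignatureSet", function(x) rownames(x@probs))
#' @rdname accessors
#' @export
setMethod("signatureNames", "SignatureFit", function(x) names(x@weights))
#' @rdname accessors
#' @export
setMethod("signatureProbs", "SignatureSet", function(x) x@probs)
#' @rdname accessors
#' @export
setMethod("exposures", "SignatureFit", function(x) x@weights)

setMethod("show", "MutationCatalog", function(object) {
    cat(sprintf("MutationCatalog (%s) sample '%s': %d mutations over %d channels",
                object@scheme, object@sampleId, sum(object@counts),
                length(object@counts)))
    if (object@nUnclassified > 0L)
        cat(sprintf(" (+%d unclassified)", object@nUnclassified))
    cat("\n")
    nz <- sort(object@counts[object@counts > 0L], decreasing = TRUE)
    if (length(nz))
        cat("  top channels:",
            paste(sprintf("%s=%d", names(head(nz, 5L)), head(nz, 5L)),
                  collapse = ", "), "\n")
})

setMethod("show", "SignatureSet", function(object) {
    cat(sprintf("SignatureSet (%s): %d signatures x %d channels\n",
                object@scheme, nrow(object@probs), ncol(object@probs)))
    cat("  signatures:", paste(rownames(object@probs), collapse = ", "), "\n")
})

setMethod("show", "SignatureFit", function(object) {
    cat(sprintf("SignatureFit sample '%s': n = %d, loglik = %.3f, %s in %d iters\n",
                object@sampleId, object@nMutations, object@loglik,
                if (object@converged) "converged" else "NOT converged",
                object@nIter))
    w <- sort(object@weights, decreasing = TRUE)
    cat("  weights:", paste(sprintf("%s=%.3f", names(w), w), collapse = ", "),
        "\n")
})

setMethod("show", "GenomeLayout", function(object) {
    cat(sprintf("GenomeLayout: %d chromosomes, %.1f Mb total\n",
                length(object@chrom), sum(object@length) / 1e6))
})

setMethod("show", "ScarScores", function(object) {
    cat(sprintf("ScarScores (%d sample%s, HRD threshold %g):\n",
                length(object@sampleId),
                if (length(object@sampleId) == 1L) "" else "s",
                object@threshold))
    print(as.data.frame(object))
})

#' @describeIn scarScores coerce scar scores to a data.frame (one row per
#'   sample, columns sample_id, loh, lst, ntai, hrd_sum, hrd_high).
#' @param x a [ScarScores-class] object.
#' @param row.names,optional,... passed on as in [base::as.data.frame()].
#' @export
as.data.frame.ScarScores <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
    data.frame(sample_id = x@sampleId, loh = x@loh, lst = x@lst,
               ntai = x@ntai, hrd_sum = x@hrdSum, hrd_high = x@hrdHigh,
               stringsAsFactors = FALSE)
}

#' @rdname accessors
#' @export
setGeneric("hrdSum", function(x) standardGeneric("hrdSum"))
#' @rdname accessors
#' @export
setMethod("hrdSum", "ScarScores", function(x) setNames(x@hrdSum, x@sampleId))
#' @rdname accessors
#' @export
setGeneric("hrdHigh", function(x) standardGeneric("hrdHigh"))
#' @rdname accessors
#' @export
setMethod("hrdHigh", "ScarScores", function(x) setNames(x@hrdHigh, x@sampleId))
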