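#' @import methods
#' @importFrom stats cor rmultinom rnorm runif sd setNames rbinom rpois
#' @importFrom utils read.delim write.table head
NULL

#' MutationCatalog: per-sample channel counts
#'
#' Holds the mutation counts of one sample over a fixed channel universe,
#' either the 96 single-base-substitution trinucleotide channels (SBS96) or
#' the 83 COSMIC indel channels (ID83), in canonical channel order.
#'
#' @slot sampleId single character, sample identifier.
#' @slot scheme `"SBS96"` or `"ID83"`.
#' @slot counts named non-negative integer vector, one entry per channel in
#'   canonical order (see [sbsChannels()], [idChannels()]).
#' @slot nUnclassified number of submitted records that could not be assigned
#'   a channel (reference mismatch, contig edge); reported, never dropped
#'   silently.
#'
#' @seealso [buildCatalog()], [emRefit()]
#' @export
setClass("MutationCatalog",
    representation(
        sampleId      = "character",
        scheme        = "character",
        counts        = "integer",
        nUnclassified = "integer"
    )
)

setValidity("MutationCatalog", function(object) {
    msg <- NULL
    if (length(object@sampleId) != 1L)
        msg <- c(msg, "sampleId must be a single string")
    if (!object@scheme %in% c("SBS96", "ID83"))
        msg <- c(msg, "scheme must be 'SBS96' or 'ID83'")
    universe <- channelUniverse(object@scheme)
    if (length(object@counts) != length(universe))
        msg <- c(msg, sprintf("counts must have length %d for scheme %s",
                              length(universe), object@scheme))
    else if (!identical(names(object@counts), universe))
        msg <- c(msg, "counts must be named by the canonical channel universe")
    if (any(is.na(object@counts)) || any(object@counts < 0L))
        msg <- c(msg, "counts must be non-negative and non-missing")
    if (length(object@nUnclassified) != 1L || is.na(object@nUnclassified) ||
        object@nUnclassified < 0L)
        msg <- c(msg, "nUnclassified must be a single non-negative integer")
    if (is.null(msg)) TRUE else msg
})

#' SignatureSet: reference signature probability matrix
#'
#' A set of fixed reference mutational signatures (COSMIC-style) over one
#' channel scheme. Rows are signatures, columns are channels in canonical
#' order; each row is a probability distribution over channels.
#'
#' @slot scheme `"SBS96"` or `"ID83"`.
#' @slot probs numeric matrix, signatures x channels; every row sums to 1
#'   (within 1e-6 after load-time renormalization), all entries >= 0.
#'
#' @seealso [readSignatureSet()], [emRefit()]
#' @export
setClass("SignatureSet",
    representation(
        scheme = "character",
        probs  = "matrix"
    )
)

setValidity("SignatureSet", function(object) {
    msg <- NULL
    if (!object@scheme %in% c("SBS96", "ID83"))
        msg <- c(msg, "scheme must be 'SBS96' or 'ID83'")
    universe <- channelUniverse(object@scheme)
    p <- object@probs
    if (!is.numeric(p))
        msg <- c(msg, "probs must be a numeric matrix")
    else {
        if (ncol(p) != length(universe) ||
            !identical(colnames(p), universe))
            msg <- c(msg, "probs columns must be the canonical channel universe")
        if (is.null(rownames(p)) || anyDuplicated(rownames(p)))
            msg <- c(msg, "probs rows must carry unique signature names")
        if (any(p < 0))
            msg <- c(msg, "signature probabilities must be non-negative")
        rs <- rowSums(p)
        if (any(abs(rs - 1) > 1e-6))
            msg <- c(msg, "every signature row must sum to 1 (+/- 1e-6)")
    }
    if (is.null(msg)) TRUE else msg
})

#' SignatureFit: EM-refitted signature exposures of one sample
#'
#' @slot sampleId sample identifier.
#' @slot weights named non-negative numeric vector over signatures, summing
#'   to 1 (within 1e-9).
#' @slot nMutations total mutation count of the fitted catalog.
#' @slot loglik multinomial mixture log-likelihood at the returned weights.
#' @slot nIter number of EM iterations performed.
#' @slot converged whether the weight-change tolerance was reached before
#'   `maxIter`.
#'
#' @seealso [emRefit()]
#' @export
setClass("SignatureFit",
    representation(
        sampleId   = "character",
        weights    = "numeric",
        nMutations = "integer",
        loglik     = "numeric",
        nIter      = "integer",
        converged  = "logical"
    )
)

setValidity("SignatureFit", function(object) {
    msg <- NULL
    w <- object@weights
    if (is.null(names(w)))
        msg <- c(msg, "weights must be named by signature")
    if (any(w < -1e-12))
        msg <- c(msg, "weights must be non-negative")
    if (length(w) && abs(sum(w) - 1) > 1e-9)
        msg <- c(msg, "weights must sum to 1 (+/- 1e-9)")
    if (is.null(msg)) TRUE else msg
})

#' GenomeLayout: chromosome lengths and centromere intervals
#'
#' Minimal genome geometry needed by the telomere/centromere-anchored scar
#' definitions: per chromosome its length and the centromere interval
#' (1-based, bp).
#'
#' @slot chrom character vector of chromosome names (unique).
#' @slot length integer-valued numeric vector of chromosome lengths (bp).
#' @slot centromereStart,centromereEnd centromere interval, with
#'   0 < centromereStart < centromereEnd < length.
#'
#' @seealso [readGenomeLayout()], [scarScores()]
#' @export
setClass("GenomeLayout",
    representation(
        chrom           = "character",
        length          = "numeric",
        centromereStart = "numeric",
        centromereEnd   = "numeric"
    )
)

setValidity("GenomeLayout", function(object) {
    msg <- NULL
    n <- length(object@chrom)
    if (anyDuplicated(object@chrom))
        msg <- c(msg, "chromosome names must be unique")
    if (length(object@length) != n || length(object@centromereStart) != n ||
        length(object@centromereEnd) != n)
        msg <- c(msg, "all slots must have one entry per chromosome")
    else {
        bad <- !(object@centromereStart > 0 &
                 object@centromereStart < object@centromereEnd &
                 object@centromereEnd < object@length)
        if (any(bad))
            msg <- c(msg, paste0("invalid centromere geometry for: ",
                                 paste(object@chrom[bad], collapse = ", ")))
    }
    if (is.null(msg)) TRUE else msg
})

#' ScarScores: genomic scar scores and HRD call
#'
#' The three genomic scar scores of one or more samples — HRD-LOH, number of
#' large-scale transitions (LST), and number of telomeric allelic imbalances
#' (ntAI) — their sum, and the binary HRD-high call at a configurable
#' threshold (default 42, sum >= threshold is "high").
#'
#' @slot sampleId character vector of sample identifiers.
#' @slot loh,lst,ntai integer score vectors, parallel to `sampleId`.
#' @slot hrdSum integer vector, `loh + lst + ntai`.
#' @slot hrdHigh logical vector, `hrdSum >= threshold`.
#' @slot threshold the single threshold used for the call.
#'
#' @seealso [scarScores()], [hrdClassify()]
#' @export
setClass("ScarScores",
    representation(
        sampleId  = "character",
        loh       = "integer",
        lst       = "integer",
        ntai      = "integer",
        hrdSum    = "integer",
        hrdHigh   = "logical",
        threshold = "numeric"
    )
)

setValidity("ScarScores", function(object) {
    msg <- NULL
    n <- length(object@sampleId)
    lens <- c(length(object@loh), length(object@lst), length(object@ntai),
              length(object@hrdSum), length(object@hrdHigh))
    if (any(lens != n))
        msg <- c(msg, "all score vectors must be parallel to sampleId")
    if (any(object@loh < 0L) || any(object@lst < 0L) || any(object@ntai < 0L))
        msg <- c(msg, "scores must be non-negative")
    if (!identical(object@hrdSum, object@loh + object@lst + object@ntai))
        msg <- c(msg, "hrdSum must equal loh + lst + ntai")
    if (length(object@threshold) != 1L || is.na(object@threshold))
        msg <- c(msg, "threshold must be a single number")
    else if (!identical(object@hrdHigh, object@hrdSum >= object@threshold))
        msg <- c(msg, "hrdHigh must equal hrdSum >= threshold")
    if (is.null(msg)) TRUE else msg
})
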