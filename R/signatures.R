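## Reference signature sets and EM refitting of mutation catalogs.
##
## The model: a sample's catalog counts m_c are multinomial over channels
## with channel probability p_c = sum_k pi_k S_kc, where S is the fixed
## signature matrix and pi the unknown mixture weights. EM with uniform
## initialization maximizes the multinomial log-likelihood
## l(pi) = sum_c m_c log(sum_k pi_k S_kc).

#' Construct a SignatureSet from a probability matrix
#'
#' @param probs numeric matrix, one row per signature (rownames = signature
#'   names), one column per channel. Columns are matched to the canonical
#'   channel order by name; rows are renormalized to sum to 1.
#' @param scheme `"SBS96"` or `"ID83"`.
#' @return a [SignatureSet-class].
#' @export
signatureSet <- function(probs, scheme = c("SBS96", "ID83")) {
    scheme <- match.arg(scheme)
    universe <- channelUniverse(scheme)
    if (is.null(colnames(probs)))
        stop("probs must carry channel labels as column names")
    unknown <- setdiff(colnames(probs), universe)
    if (length(unknown))
        stop("unknown channel label(s): ",
             paste(head(unknown, 5L), collapse = ", "))
    absent <- setdiff(universe, colnames(probs))
    if (length(absent))
        stop("missing channel(s): ", paste(head(absent, 10L), collapse = ", "))
    probs <- probs[, universe, drop = FALSE]
    rs <- rowSums(probs)
    if (any(rs <= 0)) stop("a signature row sums to zero")
    probs <- probs / rs
    new("SignatureSet", scheme = scheme, probs = probs)
}

#' Read a COSMIC-format signature file
#'
#' Tab-separated, channel labels in the first column (any header name), one
#' column per signature — the orientation of the COSMIC download files. Rows
#' are reordered to the canonical channel order; each signature is
#' renormalized to sum to 1, with a warning when it was off by more than
#' 1e-4.
#'
#' @param path TSV path.
#' @param scheme `"SBS96"` or `"ID83"`.
#' @return a [SignatureSet-class].
#' @export
readSignatureSet <- function(path, scheme = c("SBS96", "ID83")) {
    scheme <- match.arg(scheme)
    df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (ncol(df) < 2L)
        stop("signature file needs a channel column plus >= 1 signature column")
    labels <- as.character(df[[1]])
    universe <- channelUniverse(scheme)
    unknown <- setdiff(labels, universe)
    if (length(unknown))
        stop("unknown channel label(s) in ", path, ": ",
             paste(head(unknown, 5L), collapse = ", "))
    absent <- setdiff(universe, labels)
    if (length(absent))
        stop("signature file is missing channel(s): ",
             paste(head(absent, 10L), collapse = ", "))
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- labels
    m <- t(m[universe, , drop = FALSE])  # signatures x channels
    cs <- rowSums(m)
    if (any(abs(cs - 1) > 1e-4))
        warning("signature(s) renormalized (column sums off by > 1e-4): ",
                paste(rownames(m)[abs(cs - 1) > 1e-4], collapse = ", "))
    signatureSet(m, scheme)
}

#' Bundled synthetic reference signatures
#'
#' Loads the small COSMIC-like signature sets shipped with the package: five
#' SBS96 signatures (clock-like CpG C>T, APOBEC-like TpC C>T and C>G, a flat
#' HRD-like signature, and an oxidative-damage-like C>A signature) and five
#' ID83 signatures (homopolymer 1-bp insertion/deletion processes, two
#' long-deletion processes — one microhomology-biased, one repeat-free — and
#' a mixed background). These are synthetic stand-ins shaped like their
#' COSMIC namesakes, intended for tests and simulations; real analyses
#' should load a downloaded COSMIC file via [readSignatureSet()].
#'
#' @param scheme `"SBS96"` or `"ID83"`.
#' @return a [SignatureSet-class].
#' @export
bundledSignatures <- function(scheme = c("SBS96", "ID83")) {
    scheme <- match.arg(scheme)
    fn <- if (scheme == "SBS96") "signatures_sbs96_synthetic.tsv"
          else "signatures_id83_synthetic.tsv"
    path <- system.file("extdata", fn, package = "scarsig", mustWork = TRUE)
    readSignatureSet(path, scheme)
}

#' Multinomial mixture log-likelihood of a catalog under fixed weights
#'
#' `sum_c m_c log(sum_k pi_k S_kc)`. If any channel with a positive count
#' has zero probability under the mixture the likelihood is minus infinity;
#' this is raised as an error naming the channel rather than returned as a
#' sentinel value.
#'
#' @param catalog a [MutationCatalog-class].
#' @param sigs a [SignatureSet-class] of the same scheme.
#' @param weights non-negative weights over signatures summing to 1.
#' @return the log-likelihood.
#' @export
catalogLoglik <- function(catalog, sigs, weights) {
    if (scheme(catalog) != scheme(sigs))
        stop("catalog and signature set use different schemes")
    S <- signatureProbs(sigs)
    if (length(weights) != nrow(S))
        stop("need one weight per signature")
    m <- channelCounts(catalog)
    p <- as.numeric(weights %*% S)
    bad <- m > 0 & p <= 0
    if (any(bad))
        stop("channel(s) with observed mutations but zero mixture ",
             "probability: ", paste(head(names(m)[bad], 5L), collapse = ", "))
    sum(m[m > 0] * log(p[m > 0]))
}

#' Refit a catalog against fixed reference signatures by EM
#'
#' Estimates non-negative mixture weights over the supplied signatures that
#' maximize the multinomial mixture log-likelihood of the catalog.
#' Initialization is uniform (1/K), so the fit is deterministic and needs no
#' seed; iteration stops when the largest absolute weight change drops below
#' `tol` or after `maxIter` iterations. The per-iteration log-likelihood is
#' non-decreasing (standard EM guarantee) and can be returned for
#' inspection.
#'
#' Channels with positive counts that no signature can generate make the
#' model unable to explain the data and raise an error naming the channel.
#'
#' @param catalog a [MutationCatalog-class] with at least one mutation.
#' @param sigs a [SignatureSet-class] of the same scheme.
#' @param tol convergence tolerance on the max absolute weight change
#'   (default 1e-8).
#' @param maxIter iteration cap (default 10000).
#' @param prune zero out converged weights below this value and renormalize
#'   (default 0, i.e. off).
#' @param trace if `TRUE`, attach the per-iteration log-likelihood
#'   trajectory as attribute `"loglikTrace"` of the result.
#' @return a [SignatureFit-class].
#' @export
#' @examples
#' sigs <- bundledSignatures("SBS96")
#' m <- rmultinom(1, 5000, 0.6 * signatureProbs(sigs)[1, ] +
#'                          0.4 * signatureProbs(sigs)[4, ])[, 1]
#' fit <- emRefit(catalogFromCounts(m, "SBS96", "toy"), sigs)
#' round(exposures(fit), 2)
emRefit <- function(catalog, sigs, tol = 1e-8, maxIter = 10000L,
                    prune = 0, trace = FALSE) {
    if (scheme(catalog) != scheme(sigs))
        stop("catalog and signature set use different schemes")
    m <- channelCounts(catalog)
    n <- sum(m)
    if (n == 0L) stop("cannot refit an empty catalog")
    S <- signatureProbs(sigs)
    K <- nrow(S)
    reachable <- colSums(S) > 0
    bad <- m > 0 & !reachable
    if (any(bad))
        stop("channel(s) with observed mutations but zero probability ",
             "under every signature: ",
             paste(head(names(m)[bad], 5L), collapse = ", "))
    obs <- m > 0
    Sobs <- S[, obs, drop = FALSE]
    mobs <- m[obs]
    pi <- rep(1 / K, K)
    ll <- numeric(if (trace) maxIter else 0L)
    iter <- 0L
    converged <- FALSE
    repeat {
        iter <- iter + 1L
        mix <- as.numeric(pi %*% Sobs)          # mixture prob per channel
        ## E+M in one step: pi_k <- pi_k * sum_c m_c S_kc / mix_c / n
        piNew <- pi * as.numeric(Sobs %*% (mobs / mix)) / n
        if (trace) ll[iter] <- sum(mobs * log(mix))
        delta <- max(abs(piNew - pi))
        pi <- piNew
        if (delta < tol) { converged <- TRUE; break }
        if (iter >= maxIter) break
    }
    if (prune > 0) {
        pi[pi < prune] <- 0
        pi <- pi / sum(pi)
    }
    pi <- pi / sum(pi)  # guard against drift
    names(pi) <- rownames(S)
    finalLL <- sum(mobs * log(as.numeric(pi %*% Sobs)))
    fit <- new("SignatureFit", sampleId = sampleId(catalog), weights = pi,
               nMutations = as.integer(n), loglik = finalLL,
               nIter = iter, converged = converged)
    if (trace) attr(fit, "loglikTrace") <- ll[seq_len(iter)]
    fit
}

#' Refit many catalogs and tabulate the exposures
#'
#' @param catalogs list of [MutationCatalog-class] objects.
#' @param sigs a [SignatureSet-class].
#' @param ... passed to [emRefit()].
#' @return data.frame: `sample_id`, one column per signature weight,
#'   `n_mutations`, `loglik`, `converged`.
#' @export
fitExposures <- function(catalogs, sigs, ...) {
    rows <- lapply(catalogs, function(cat) {
        fit <- emRefit(cat, sigs, ...)
        w <- as.list(exposures(fit))
        cbind(data.frame(sample_id = sampleId(fit), stringsAsFactors = FALSE),
              as.data.frame(w, check.names = FALSE),
              data.frame(n_mutations = fit@nMutations, loglik = fit@loglik,
                         converged = fit@converged))
    })
    do.call(rbind, rows)
}
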