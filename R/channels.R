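## Channel universes for the two COSMIC classification schemes.
## Both are generated once at load time and cached; every catalog, signature
## matrix and simulation indexes channels in exactly this order, so row order
## in files on disk never matters (loaders reorder to this canon).

.channelCache <- new.env(parent = emptyenv())

#' Canonical SBS96 channel labels
#'
#' The 96 pyrimidine-centric trinucleotide substitution channels in COSMIC
#' plotting order: substitution-major (C>A, C>G, C>T, T>A, T>C, T>G), within
#' each substitution the 16 flank combinations with the 5' base varying
#' slowest (A, C, G, T).
#'
#' @return character vector of 96 labels such as `"A[C>T]G"`.
#' @export
#' @examples
#' head(sbsChannels())
sbsChannels <- function() {
    if (!is.null(.channelCache$sbs)) return(.channelCache$sbs)
    subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
    bases <- c("A", "C", "G", "T")
    out <- character(0)
    for (s in subs)
        for (f in bases)
            for (t in bases)
                out <- c(out, paste0(f, "[", s, "]", t))
    .channelCache$sbs <- out
    out
}

#' Canonical ID83 channel labels
#'
#' The 83 COSMIC indel channels in COSMIC file order, labelled
#' `length:type:subtype:count` as in SigProfilerMatrixGenerator:
#' 1-bp deletions and insertions in C/T homopolymer context (count field
#' 0..5 = number of additional identical bases in the reference, i.e. "5"
#' means 6+ total copies for deletions and 5+ reference copies for
#' insertions), longer indels at tandem repeats (`R`, length field capped at
#' "5" meaning 5+), and repeat-free deletions with flanking microhomology
#' (`M`).
#'
#' @return character vector of 83 labels such as `"1:Del:T:4"` or
#'   `"5:Del:M:2"`.
#' @export
#' @examples
#' length(idChannels())
idChannels <- function() {
    if (!is.null(.channelCache$id)) return(.channelCache$id)
    out <- character(0)
    for (b in c("C", "T"))
        out <- c(out, paste0("1:Del:", b, ":", 0:5))
    for (b in c("C", "T"))
        out <- c(out, paste0("1:Ins:", b, ":", 0:5))
    for (L in 2:5)
        out <- c(out, paste0(L, ":Del:R:", 0:5))
    for (L in 2:5)
        out <- c(out, paste0(L, ":Ins:R:", 0:5))
    mh <- list(`2` = 1L, `3` = 1:2, `4` = 1:3, `5` = 1:5)
    for (L in names(mh))
        out <- c(out, paste0(L, ":Del:M:", mh[[L]]))
    .channelCache$id <- out
    out
}

#' Channel universe for a scheme
#'
#' @param scheme `"SBS96"` or `"ID83"`.
#' @return the canonical channel label vector for the scheme.
#' @export
channelUniverse <- function(scheme) {
    switch(match.arg(scheme, c("SBS96", "ID83")),
           SBS96 = sbsChannels(),
           ID83  = idChannels())
}

## reverse complement for plain character vectors of single bases
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.revcomp <- function(x) {
    vapply(x, function(s) {
        paste(rev(.COMPLEMENT[strsplit(s, "")[[1]]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
}
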