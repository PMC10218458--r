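## SBS96 / ID83 channel classification and per-sample catalog construction.
##
## The genome is supplied as a Biostrings::DNAStringSet (or a named character
## vector); classification works on plain character strings internally.

.genomeStrings <- function(genome) {
    if (isTRUE(attr(genome, "scarsigNormalized"))) return(genome)
    if (is(genome, "DNAStringSet")) {
        s <- as.character(genome)
        names(s) <- names(genome)
    } else if (is.character(genome) && !is.null(names(genome))) {
        s <- toupper(genome)
    } else {
        stop("genome must be a named DNAStringSet or named character vector")
    }
    attr(s, "scarsigNormalized") <- TRUE
    s
}

.chromSeq <- function(genomeStr, chrom) {
    if (!chrom %in% names(genomeStr))
        stop("chromosome '", chrom, "' not present in the genome")
    genomeStr[[chrom]]
}

#' SBS96 trinucleotide channel of a single-base substitution
#'
#' Returns the pyrimidine-centric trinucleotide channel of an SNV. When the
#' reference base is a purine (A or G) the variant and its flanks are
#' reverse-complemented, so a variant and its opposite-strand description map
#' to the same channel.
#'
#' @param chrom,pos locus (1-based).
#' @param ref,alt single reference/alternate bases.
#' @param genome named `DNAStringSet` or named character vector.
#' @return the channel label, e.g. `"A[C>T]A"`.
#' @export
#' @examples
#' g <- c(chr1 = "GACAG")
#' sbsContext("chr1", 3, "C", "T", g)  # "A[C>T]A"
sbsContext <- function(chrom, pos, ref, alt, genome) {
    gs <- .genomeStrings(genome)
    seq <- .chromSeq(gs, chrom)
    if (nchar(ref) != 1L || nchar(alt) != 1L)
        stop("sbsContext requires single-base ref and alt alleles")
    if (pos < 2L || pos > nchar(seq) - 1L)
        stop("position ", pos, " on ", chrom,
             " lacks a flanking base (contig edge)")
    tri <- substr(seq, pos - 1L, pos + 1L)
    if (substr(tri, 2L, 2L) != ref)
        stop("reference allele mismatch at ", chrom, ":", pos,
             " (genome has ", substr(tri, 2L, 2L), ", record says ", ref, ")")
    if (ref %in% c("A", "G")) {
        tri <- .revcomp(tri)
        ref <- .COMPLEMENT[[ref]]
        alt <- .COMPLEMENT[[alt]]
    }
    paste0(substr(tri, 1L, 1L), "[", ref, ">", alt, "]", substr(tri, 3L, 3L))
}

## Left-align a deletion: deleting seq[pos..pos+L-1] is equivalent to
## deleting seq[(pos-1)..(pos+L-2)] whenever seq[pos-1] == seq[pos+L-1].
## Returns the left-most equivalent start position.
.leftAlignDel <- function(seq, pos, L) {
    while (pos > 1L &&
           substr(seq, pos - 1L, pos - 1L) == substr(seq, pos + L - 1L,
                                                     pos + L - 1L))
        pos <- pos - 1L
    pos
}

## Left-align an insertion placed between seq[pos] and seq[pos+1]: shifting
## one left is valid when seq[pos] equals the last base of the inserted
## sequence (which is then rotated). Returns list(pos, s).
.leftAlignIns <- function(seq, pos, s) {
    L <- nchar(s)
    while (pos >= 1L &&
           substr(seq, pos, pos) == substr(s, L, L)) {
        s <- paste0(substr(s, L, L), substr(s, 1L, L - 1L))
        pos <- pos - 1L
    }
    list(pos = pos, s = s)
}

## number of tandem copies of s immediately 3' of `from` (1-based, first base
## after the event locus)
.tandemCopies3p <- function(seq, from, s) {
    L <- nchar(s)
    n <- 0L
    while (from + L - 1L <= nchar(seq) &&
           substr(seq, from, from + L - 1L) == s) {
        n <- n + 1L
        from <- from + L
    }
    n
}

## longest common prefix length of two strings
.lcp <- function(a, b) {
    n <- min(nchar(a), nchar(b))
    i <- 0L
    while (i < n && substr(a, i + 1L, i + 1L) == substr(b, i + 1L, i + 1L))
        i <- i + 1L
    i
}

#' ID83 channel of an insertion or deletion
#'
#' Classifies an indel into its COSMIC ID83 channel. The event is first
#' left-aligned against the genome; 1-bp events are assigned to
#' pyrimidine-represented homopolymer channels, longer events to
#' tandem-repeat channels when at least one additional copy of the
#' inserted/deleted sequence follows the locus (or the event is an
#' insertion), and repeat-free deletions of 2+ bp to microhomology channels
#' using the longer of the common prefix with the 3' flank and the common
#' suffix with the 5' flank, capped at length - 1. Microhomology 0 falls in
#' the zero-repeat deletion channel.
#'
#' @param chrom,pos locus (1-based; deletions: first deleted base;
#'   insertions: base immediately 5' of the insertion point, MAF convention).
#' @param ref,alt MAF-convention alleles (`"-"` for the empty side).
#' @param genome named `DNAStringSet` or named character vector.
#' @return the channel label, e.g. `"1:Del:T:4"`.
#' @export
classifyIndel <- function(chrom, pos, ref, alt, genome) {
    gs <- .genomeStrings(genome)
    seq <- .chromSeq(gs, chrom)
    isDel <- alt == "-" || alt == ""
    isIns <- ref == "-" || ref == ""
    if (isDel == isIns)
        stop("classifyIndel requires a MAF-convention INS or DEL record")
    if (isDel) {
        s <- ref
        L <- nchar(s)
        if (pos + L - 1L > nchar(seq) ||
            substr(seq, pos, pos + L - 1L) != s)
            stop("deleted allele '", s, "' not found in genome at ",
                 chrom, ":", pos)
        pos <- .leftAlignDel(seq, pos, L)
        s <- substr(seq, pos, pos + L - 1L)
        R <- .tandemCopies3p(seq, pos + L, s)
        if (L == 1L) {
            base <- if (s %in% c("A", "G")) .COMPLEMENT[[s]] else s
            return(paste0("1:Del:", base, ":", min(R, 5L)))
        }
        if (R >= 1L)
            return(paste0(min(L, 5L), ":Del:R:", min(R, 5L)))
        flank3 <- substr(seq, pos + L, min(nchar(seq), pos + 2L * L - 1L))
        flank5 <- substr(seq, max(1L, pos - L), pos - 1L)
        revstr <- function(x) paste(rev(strsplit(x, "")[[1]]), collapse = "")
        mh <- max(.lcp(s, flank3), .lcp(revstr(s), revstr(flank5)))
        mh <- min(mh, L - 1L, 5L)
        if (mh == 0L)
            return(paste0(min(L, 5L), ":Del:R:0"))
        paste0(min(L, 5L), ":Del:M:", mh)
    } else {
        s <- alt
        L <- nchar(s)
        if (pos < 0L || pos > nchar(seq))
            stop("insertion point ", pos, " outside ", chrom)
        al <- .leftAlignIns(seq, pos, s)
        pos <- al$pos
        s <- al$s
        R <- .tandemCopies3p(seq, pos + 1L, s)
        if (L == 1L) {
            base <- if (s %in% c("A", "G")) .COMPLEMENT[[s]] else s
            return(paste0("1:Ins:", base, ":", min(R, 5L)))
        }
        paste0(min(L, 5L), ":Ins:R:", min(R, 5L))
    }
}

#' ID83/SBS96 channel of one variant record row
#'
#' Dispatches a variant record to [sbsContext()] or [classifyIndel()]
#' according to its `Variant_Type`.
#'
#' @param row one-row variant data.frame.
#' @param genome named `DNAStringSet` or named character vector.
#' @return channel label.
#' @export
classifyVariant <- function(row, genome) {
    if (row$Variant_Type == "SNP")
        sbsContext(row$Chromosome, row$Start_Position, row$Reference_Allele,
                   row$Tumor_Seq_Allele2, genome)
    else
        classifyIndel(row$Chromosome, row$Start_Position,
                      row$Reference_Allele, row$Tumor_Seq_Allele2, genome)
}

#' Build a per-sample mutation catalog
#'
#' Classifies all of one sample's somatic mutations of the scheme's type
#' (SNPs for SBS96, insertions/deletions for ID83) into channels and counts
#' them. The catalog deliberately uses all somatic mutations, not the
#' protein-impact-filtered subset. Records that cannot be classified
#' (reference mismatch, contig edge) are counted in the `nUnclassified`
#' slot, never silently dropped.
#'
#' @param variants one sample's variant data.frame.
#' @param genome named `DNAStringSet` or named character vector.
#' @param scheme `"SBS96"` or `"ID83"`.
#' @param sampleId sample identifier for the catalog (defaults to the one
#'   `Tumor_Sample_Barcode` present, or `"sample"` for an empty table).
#' @return a [MutationCatalog-class].
#' @export
buildCatalog <- function(variants, genome, scheme = c("SBS96", "ID83"),
                         sampleId = NULL) {
    scheme <- match.arg(scheme)
    gs <- .genomeStrings(genome)
    universe <- channelUniverse(scheme)
    counts <- setNames(integer(length(universe)), universe)
    wanted <- if (scheme == "SBS96") "SNP" else c("INS", "DEL")
    v <- variants[variants$Variant_Type %in% wanted, , drop = FALSE]
    if (is.null(sampleId)) {
        sampleId <- unique(as.character(variants$Tumor_Sample_Barcode))
        if (length(sampleId) > 1L)
            stop("variants contain multiple samples; supply sampleId or split")
        if (!length(sampleId)) sampleId <- "sample"
    }
    nUnc <- 0L
    if (nrow(v)) {
        for (i in seq_len(nrow(v))) {
            ch <- tryCatch(
                if (scheme == "SBS96")
                    sbsContext(v$Chromosome[i], v$Start_Position[i],
                               v$Reference_Allele[i], v$Tumor_Seq_Allele2[i],
                               gs)
                else
                    classifyIndel(v$Chromosome[i], v$Start_Position[i],
                                  v$Reference_Allele[i],
                                  v$Tumor_Seq_Allele2[i], gs),
                error = function(e) NA_character_)
            if (is.na(ch)) nUnc <- nUnc + 1L
            else counts[[ch]] <- counts[[ch]] + 1L
        }
    }
    new("MutationCatalog", sampleId = sampleId, scheme = scheme,
        counts = counts, nUnclassified = nUnc)
}

#' Construct a catalog directly from channel counts
#'
#' Convenience constructor used by simulations and file import; counts are
#' matched to the canonical channel order by name.
#'
#' @param counts named numeric/integer vector of channel counts; channels
#'   not mentioned are 0.
#' @param scheme `"SBS96"` or `"ID83"`.
#' @param sampleId sample identifier.
#' @return a [MutationCatalog-class].
#' @export
catalogFromCounts <- function(counts, scheme = c("SBS96", "ID83"),
                              sampleId = "sample") {
    scheme <- match.arg(scheme)
    universe <- channelUniverse(scheme)
    unknown <- setdiff(names(counts), universe)
    if (length(unknown))
        stop("unknown channel label(s): ", paste(head(unknown, 5L),
                                                 collapse = ", "))
    full <- setNames(integer(length(universe)), universe)
    full[names(counts)] <- as.integer(round(counts))
    new("MutationCatalog", sampleId = sampleId, scheme = scheme,
        counts = full, nUnclassified = 0L)
}

#' Write catalogs as a channels-by-samples matrix (COSMIC orientation)
#'
#' @param catalogs list of [MutationCatalog-class] objects sharing a scheme.
#' @param path output TSV path; first column `MutationType`, one column per
#'   sample.
#' @return `path`, invisibly.
#' @export
writeCatalogs <- function(catalogs, path) {
    schemes <- unique(vapply(catalogs, scheme, character(1)))
    if (length(schemes) != 1L)
        stop("all catalogs must share one scheme")
    m <- vapply(catalogs, channelCounts,
                integer(length(channelUniverse(schemes))))
    colnames(m) <- vapply(catalogs, sampleId, character(1))
    df <- data.frame(MutationType = channelUniverse(schemes), m,
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
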