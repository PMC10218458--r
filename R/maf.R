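## MAF-dialect variant table input/output and the study's class filters.
##
## Variants are kept as plain data.frames with GDC MAF column names; one row
## is one (sample, locus, allele) record. Coordinates are 1-based inclusive
## throughout; indels use the MAF allele convention (deletions: ref = deleted
## bases, alt = "-", pos = first deleted base; insertions: ref = "-",
## alt = inserted bases, pos = base immediately 5' of the insertion point).

#' MAF Variant_Classification vocabulary
#'
#' The closed vocabulary accepted in the `Variant_Classification` column.
#' @return character vector of the 15 accepted classification labels.
#' @export
mafClassifications <- function() {
    c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation", "Silent",
      "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
      "Splice_Region", "Splice_Site", "Translation_Start_Site", "Intron",
      "RNA", "3'UTR", "5'UTR")
}

## classification categories discarded from the germline analysis
.GERMLINE_DISCARD <- c("Intron", "RNA", "Splice_Region", "Splice_Site",
                       "3'UTR", "5'UTR", "Silent")

## protein-impact categories kept for the somatic gene analysis; the same
## keep-set defines which mutations count toward TMB
.SOMATIC_KEEP <- c("Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del",
                   "In_Frame_Ins", "Missense_Mutation", "Nonsense_Mutation",
                   "Nonstop_Mutation", "Splice_Region", "Splice_Site",
                   "Translation_Start_Site")

.MAF_REQUIRED <- c("Tumor_Sample_Barcode", "Chromosome", "Start_Position",
                   "Reference_Allele", "Tumor_Seq_Allele2",
                   "Variant_Classification", "Variant_Type", "Hugo_Symbol")

.CLINVAR_LEVELS <- c("benign", "likely_benign", "uncertain",
                     "likely_pathogenic", "pathogenic", "conflicting",
                     "not_reviewed")
.SIFT_LEVELS <- c("tolerated", "deleterious")
.POLYPHEN_LEVELS <- c("benign", "possibly_damaging", "probably_damaging")

#' Validate a variant table
#'
#' Checks the structural invariants of a MAF-dialect variant data.frame:
#' required columns present, positions >= 1, classification vocabulary
#' closed, variant type consistent with allele lengths, no multi-allelic
#' rows (comma in the alternate allele), and read counts with
#' `alt_depth <= total_depth` where depth columns are present.
#'
#' @param variants data.frame with GDC MAF column names (see
#'   [readMaf()]).
#' @return the input, invisibly, if valid; otherwise an error.
#' @export
validateVariants <- function(variants) {
    missing <- setdiff(.MAF_REQUIRED, names(variants))
    if (length(missing))
        stop("variant table is missing mandatory column(s): ",
             paste(missing, collapse = ", "))
    pos <- variants$Start_Position
    if (!is.numeric(pos) || any(is.na(pos)))
        stop("Start_Position must be numeric and non-missing; offending row(s): ",
             paste(head(which(is.na(pos) | !is.finite(pos)), 5L),
                   collapse = ", "))
    if (any(pos < 1))
        stop("Start_Position must be >= 1 (1-based coordinates); row(s): ",
             paste(head(which(pos < 1), 5L), collapse = ", "))
    bad <- !variants$Variant_Classification %in% mafClassifications()
    if (any(bad))
        stop("unknown Variant_Classification value(s): ",
             paste(unique(variants$Variant_Classification[bad]), collapse = ", "))
    if (any(grepl(",", variants$Tumor_Seq_Allele2, fixed = TRUE)))
        stop("multi-allelic rows (comma-separated alternate alleles) must ",
             "be pre-split; row(s): ",
             paste(head(grep(",", variants$Tumor_Seq_Allele2, fixed = TRUE), 5L),
                   collapse = ", "))
    if (!all(variants$Variant_Type %in% c("SNP", "INS", "DEL")))
        stop("Variant_Type must be one of SNP, INS, DEL")
    rl <- ifelse(variants$Reference_Allele == "-", 0L,
                 nchar(variants$Reference_Allele))
    al <- ifelse(variants$Tumor_Seq_Allele2 == "-", 0L,
                 nchar(variants$Tumor_Seq_Allele2))
    expect <- ifelse(rl == al & rl == 1L, "SNP",
              ifelse(rl > al, "DEL", ifelse(al > rl, "INS", NA)))
    bad <- is.na(expect) | expect != variants$Variant_Type
    if (any(bad))
        stop("Variant_Type inconsistent with allele lengths in row(s): ",
             paste(head(which(bad), 5L), collapse = ", "))
    if (all(c("t_alt_count", "t_depth") %in% names(variants))) {
        bad <- !is.na(variants$t_alt_count) & !is.na(variants$t_depth) &
            variants$t_alt_count > variants$t_depth
        if (any(bad))
            stop("t_alt_count exceeds t_depth in row(s): ",
                 paste(head(which(bad), 5L), collapse = ", "))
    }
    for (col in c("CLIN_SIG", "SIFT", "PolyPhen")) {
        if (!col %in% names(variants)) next
        lev <- switch(col, CLIN_SIG = .CLINVAR_LEVELS, SIFT = .SIFT_LEVELS,
                      PolyPhen = .POLYPHEN_LEVELS)
        v <- variants[[col]]
        bad <- !is.na(v) & v != "" & !v %in% lev
        if (any(bad))
            stop("unknown ", col, " value(s): ",
                 paste(unique(v[bad]), collapse = ", "))
    }
    invisible(variants)
}

#' Read a MAF-dialect variant table
#'
#' Reads a tab-separated variant table using GDC MAF column names
#' (`Hugo_Symbol`, `Chromosome`, `Start_Position`, `Reference_Allele`,
#' `Tumor_Seq_Allele2`, `Variant_Classification`, `Variant_Type`,
#' `Tumor_Sample_Barcode`; optional `t_alt_count`, `t_depth`, `CLIN_SIG`,
#' `SIFT`, `PolyPhen`). Extra columns are passed through untouched; column
#' order is immaterial; lines starting with `#` are ignored. The
#' classification vocabulary is closed: unknown strings are an error, not a
#' warning.
#'
#' @param path path to a tab-separated file with a header row.
#' @return data.frame, one row per variant record.
#' @seealso [writeMaf()], [validateVariants()]
#' @export
readMaf <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                     check.names = FALSE, colClasses = NA)
    if (!nrow(df)) {
        missing <- setdiff(.MAF_REQUIRED, names(df))
        if (length(missing))
            stop("variant table is missing mandatory column(s): ",
                 paste(missing, collapse = ", "))
        return(df)
    }
    df$Start_Position <- suppressWarnings(as.numeric(df$Start_Position))
    if (any(is.na(df$Start_Position)))
        stop("unparsable Start_Position at data line(s): ",
             paste(head(which(is.na(df$Start_Position)), 5L), collapse = ", "))
    validateVariants(df)
    df
}

#' Write a MAF-dialect variant table
#'
#' @param variants variant data.frame (see [readMaf()]).
#' @param path output path; written tab-separated with header, no quotes.
#' @return `path`, invisibly.
#' @export
writeMaf <- function(variants, path) {
    write.table(variants, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "")
    invisible(path)
}

#' Germline variant-class filter
#'
#' Discards germline records in any of the seven non-protein-affecting
#' classification categories (`Intron`, `RNA`, `Splice_Region`,
#' `Splice_Site`, `3'UTR`, `5'UTR`, `Silent`), keeping everything else in
#' input order.
#'
#' @param variants variant data.frame.
#' @return the retained rows.
#' @export
filterGermlineClasses <- function(variants) {
    variants[!variants$Variant_Classification %in% .GERMLINE_DISCARD, ,
             drop = FALSE]
}

#' Somatic protein-impact class filter
#'
#' Keeps exactly the ten protein-impact classes used for the somatic gene
#' analysis and for TMB counting: `Frame_Shift_Del`, `Frame_Shift_Ins`,
#' `In_Frame_Del`, `In_Frame_Ins`, `Missense_Mutation`, `Nonsense_Mutation`,
#' `Nonstop_Mutation`, `Splice_Region`, `Splice_Site`,
#' `Translation_Start_Site`. Note `Splice_Region` is discarded by the
#' germline filter but kept here.
#'
#' @param variants variant data.frame.
#' @return the retained rows, input order preserved.
#' @export
filterSomaticImpactClasses <- function(variants) {
    variants[variants$Variant_Classification %in% .SOMATIC_KEEP, ,
             drop = FALSE]
}

#' Pathogenicity flag from ClinVar / SIFT / PolyPhen annotations
#'
#' A record is flagged (likely) pathogenic when ClinVar classifies it as
#' `pathogenic` or `likely_pathogenic`, or SIFT calls it `deleterious`, or
#' PolyPhen calls it `possibly_damaging` or `probably_damaging`. ClinVar
#' `conflicting` and `not_reviewed` are treated as non-pathogenic; absent
#' annotations contribute nothing, and a record with no annotations at all is
#' not flagged.
#'
#' @param variants variant data.frame with optional `CLIN_SIG`, `SIFT`,
#'   `PolyPhen` columns.
#' @return logical vector, one flag per row.
#' @export
flagPathogenic <- function(variants) {
    n <- nrow(variants)
    get <- function(col) {
        if (col %in% names(variants)) {
            v <- as.character(variants[[col]])
            v[is.na(v)] <- ""
            v
        } else rep("", n)
    }
    clin <- get("CLIN_SIG")
    sift <- get("SIFT")
    poly <- get("PolyPhen")
    clin %in% c("pathogenic", "likely_pathogenic") |
        sift == "deleterious" |
        poly %in% c("possibly_damaging", "probably_damaging")
}

#' Read a gene list (one symbol per line)
#'
#' Plain-text gene list, e.g. a targeted-panel gene set; blank lines and
#' `#` comments ignored.
#'
#' @param path path to the text file.
#' @return character vector of gene symbols.
#' @export
readGeneList <- function(path) {
    x <- readLines(path)
    x <- trimws(sub("#.*", "", x))
    x[nzchar(x)]
}
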