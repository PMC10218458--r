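## Genomic scar scores from allele-specific copy-number segments.
##
## Segments are data.frames with columns chrom, start, end (1-based
## inclusive, bp), major_cn, minor_cn (and optionally sample_id). All three
## scores operate on one sample's segments after preprocessing
## (merge + 3 Mb smoothing).

#' Construct a GenomeLayout
#'
#' @param chrom chromosome names.
#' @param length chromosome lengths (bp).
#' @param centromereStart,centromereEnd centromere interval (bp, 1-based).
#' @return a [GenomeLayout-class].
#' @export
genomeLayout <- function(chrom, length, centromereStart, centromereEnd) {
    new("GenomeLayout", chrom = as.character(chrom),
        length = as.numeric(length),
        centromereStart = as.numeric(centromereStart),
        centromereEnd = as.numeric(centromereEnd))
}

#' Read a genome layout table
#'
#' TSV with columns `chrom`, `length`, `centromere_start`, `centromere_end`.
#'
#' @param path file path.
#' @return a [GenomeLayout-class].
#' @export
readGenomeLayout <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "length", "centromere_start", "centromere_end")
    missing <- setdiff(need, names(df))
    if (length(missing))
        stop("layout table missing column(s): ",
             paste(missing, collapse = ", "))
    genomeLayout(df$chrom, df$length, df$centromere_start, df$centromere_end)
}

#' Write a genome layout table
#' @param layout a [GenomeLayout-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeGenomeLayout <- function(layout, path) {
    df <- data.frame(chrom = layout@chrom, length = layout@length,
                     centromere_start = layout@centromereStart,
                     centromere_end = layout@centromereEnd)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

.layoutRow <- function(layout, chrom) {
    i <- match(chrom, layout@chrom)
    if (is.na(i)) stop("chromosome '", chrom, "' not in layout")
    list(length = layout@length[i], cenStart = layout@centromereStart[i],
         cenEnd = layout@centromereEnd[i])
}

#' Read an allele-specific copy-number segment table
#'
#' Accepts either the Sequenza `*_segments.txt` dialect (columns
#' `chromosome`, `start.pos`, `end.pos`, `A`, `B`) or a generic dialect
#' (`chrom`, `start`, `end`, `major_cn`, `minor_cn`); an optional
#' `sample_id` column is carried through.
#'
#' @param path TSV path.
#' @return data.frame with columns `chrom`, `start`, `end`, `major_cn`,
#'   `minor_cn` (+ `sample_id` if present).
#' @export
readSegments <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (all(c("chromosome", "start.pos", "end.pos", "A", "B") %in% names(df))) {
        out <- data.frame(chrom = df$chromosome, start = df$`start.pos`,
                          end = df$`end.pos`, major_cn = df$A,
                          minor_cn = df$B, stringsAsFactors = FALSE)
    } else if (all(c("chrom", "start", "end", "major_cn", "minor_cn") %in%
                   names(df))) {
        out <- df[, c("chrom", "start", "end", "major_cn", "minor_cn")]
    } else {
        stop("unrecognized segment table dialect: need Sequenza columns ",
             "(chromosome, start.pos, end.pos, A, B) or generic columns ",
             "(chrom, start, end, major_cn, minor_cn)")
    }
    if ("sample_id" %in% names(df)) out$sample_id <- df$sample_id
    out
}

.checkSegments <- function(segments) {
    if (!nrow(segments)) return(segments)
    if (any(segments$start > segments$end))
        stop("segment with start > end")
    if (any(segments$major_cn < segments$minor_cn))
        stop("segment with major_cn < minor_cn")
    if (any(segments$major_cn < 0 | segments$minor_cn < 0))
        stop("negative copy number")
    segments <- segments[order(segments$chrom, segments$start), , drop = FALSE]
    for (chr in unique(segments$chrom)) {
        s <- segments[segments$chrom == chr, , drop = FALSE]
        if (nrow(s) > 1L && any(s$start[-1L] <= s$end[-nrow(s)]))
            stop("overlapping segments on ", chr)
    }
    segments
}

#' Merge and smooth a segment profile
#'
#' Preprocessing applied before scoring: (i) adjacent segments with
#' identical (major, minor) state are merged (the intervening gap, if any,
#' is absorbed); (ii) segments shorter than `minSegBp` are removed
#' iteratively, shortest first — when the removed segment's neighbors share
#' a state they are merged across the gap, otherwise each neighbor extends
#' to the gap midpoint so adjacency is preserved.
#'
#' @param segments one sample's segment data.frame.
#' @param minSegBp smoothing threshold in bp (default 3e6); segments at
#'   least this long are kept.
#' @return the smoothed segment data.frame, sorted by (chrom, start).
#' @export
preprocessSegments <- function(segments, minSegBp = 3e6) {
    segments <- .checkSegments(segments)
    if (!nrow(segments)) return(segments)
    out <- lapply(split(segments, segments$chrom), function(s) {
        s <- s[order(s$start), , drop = FALSE]
        repeat {
            ## merge identical adjacent states
            if (nrow(s) > 1L) {
                same <- s$major_cn[-1L] == s$major_cn[-nrow(s)] &
                        s$minor_cn[-1L] == s$minor_cn[-nrow(s)]
                if (any(same)) {
                    i <- which(same)[1L]
                    s$end[i] <- s$end[i + 1L]
                    s <- s[-(i + 1L), , drop = FALSE]
                    next
                }
            }
            ## drop the shortest sub-threshold segment
            len <- s$end - s$start + 1
            short <- which(len < minSegBp)
            if (!length(short)) break
            i <- short[which.min(len[short])]
            if (nrow(s) == 1L) { s <- s[0, , drop = FALSE]; break }
            if (i == 1L) {
                s$start[2L] <- s$start[1L]
                s <- s[-1L, , drop = FALSE]
            } else if (i == nrow(s)) {
                s$end[i - 1L] <- s$end[i]
                s <- s[-i, , drop = FALSE]
            } else if (s$major_cn[i - 1L] == s$major_cn[i + 1L] &&
                       s$minor_cn[i - 1L] == s$minor_cn[i + 1L]) {
                s$end[i - 1L] <- s$end[i + 1L]
                s <- s[-c(i, i + 1L), , drop = FALSE]
            } else {
                mid <- floor((s$start[i] + s$end[i]) / 2)
                s$end[i - 1L] <- mid
                s$start[i + 1L] <- mid + 1
                s <- s[-i, , drop = FALSE]
            }
        }
        s
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res[order(res$chrom, res$start), , drop = FALSE]
}

## contiguous runs of a logical state over a sorted per-chromosome segment
## table; two consecutive segments belong to one run when both are in the
## state (gaps between covered segments do not break a run of the same
## state, matching run-total-length scoring on possibly incompletely
## covered chromosomes)
.stateRuns <- function(s, state) {
    runs <- list()
    i <- 1L
    n <- nrow(s)
    while (i <= n) {
        if (state[i]) {
            j <- i
            while (j < n && state[j + 1L]) j <- j + 1L
            runs[[length(runs) + 1L]] <-
                c(start = s$start[i], end = s$end[j],
                  bp = sum(s$end[i:j] - s$start[i:j] + 1))
            i <- j + 1L
        } else i <- i + 1L
    }
    runs
}

#' HRD-LOH score
#'
#' Number of loss-of-heterozygosity regions (minor copy number 0 with at
#' least one remaining copy) whose total length exceeds `minBp` (default
#' 15 Mb, strict) but which do not span the entire chromosome. Whether a
#' run spans the whole chromosome is judged against the layout length, not
#' the observed segment extent, so uncovered telomeric gaps do not turn a
#' whole-chromosome event into a countable one.
#'
#' @param segments one sample's preprocessed segments.
#' @param layout a [GenomeLayout-class].
#' @param minBp minimum run length in bp, exclusive (default 15e6).
#' @return integer score.
#' @export
lohScore <- function(segments, layout, minBp = 15e6) {
    score <- 0L
    for (chr in unique(segments$chrom)) {
        s <- segments[segments$chrom == chr, , drop = FALSE]
        s <- s[order(s$start), , drop = FALSE]
        geo <- .layoutRow(layout, chr)
        runs <- .stateRuns(s, s$minor_cn == 0 & s$major_cn >= 1)
        for (r in runs) {
            whole <- r[["start"]] <= 1 && r[["end"]] >= geo$length
            if (!whole && r[["bp"]] > minBp) score <- score + 1L
        }
    }
    score
}

#' Number of telomeric allelic imbalances (ntAI)
#'
#' Counts allelic-imbalance segments (major != minor copy number) that
#' reach a chromosome end — start within `telomereMargin` bp of position 1,
#' or end within `telomereMargin` bp of the layout chromosome length — and
#' do not cross the centromere interval (i.e. do not extend from before
#' `centromere_start` to beyond `centromere_end`).
#'
#' @param segments one sample's preprocessed segments.
#' @param layout a [GenomeLayout-class].
#' @param telomereMargin slack in bp for "reaches the chromosome end"
#'   (default 0: the segment must abut the recorded end).
#' @return integer score.
#' @export
ntaiScore <- function(segments, layout, telomereMargin = 0) {
    score <- 0L
    for (i in seq_len(nrow(segments))) {
        seg <- segments[i, ]
        if (seg$major_cn == seg$minor_cn) next
        geo <- .layoutRow(layout, seg$chrom)
        telomeric <- seg$start <= 1 + telomereMargin ||
                     seg$end >= geo$length - telomereMargin
        crosses <- seg$start < geo$cenStart && seg$end > geo$cenEnd
        if (telomeric && !crosses) score <- score + 1L
    }
    score
}

#' Large-scale transition (LST) score
#'
#' After smoothing variation shorter than 3 Mb (see
#' [preprocessSegments()]), counts, per chromosome arm, breakpoints between
#' adjacent segments in different copy-number states where both segments
#' are at least `minSegBp` (default 10 Mb) long. Segments are split at the
#' centromere first, so arm membership and arm-internal lengths are
#' well-defined (p arm: before `centromere_start`; q arm: after
#' `centromere_end`).
#'
#' @param segments one sample's segments, preprocessed with a 3 Mb
#'   smoothing window.
#' @param layout a [GenomeLayout-class].
#' @param minSegBp minimum flanking-segment length in bp, inclusive
#'   (default 10e6).
#' @return integer score.
#' @export
lstScore <- function(segments, layout, minSegBp = 10e6) {
    score <- 0L
    for (chr in unique(segments$chrom)) {
        s <- segments[segments$chrom == chr, , drop = FALSE]
        s <- s[order(s$start), , drop = FALSE]
        geo <- .layoutRow(layout, chr)
        arms <- list(c(1, geo$cenStart - 1), c(geo$cenEnd + 1, geo$length))
        for (arm in arms) {
            a <- s[s$end >= arm[1] & s$start <= arm[2], , drop = FALSE]
            if (nrow(a) < 2L) next
            a$start <- pmax(a$start, arm[1])
            a$end <- pmin(a$end, arm[2])
            len <- a$end - a$start + 1
            for (i in seq_len(nrow(a) - 1L)) {
                diffState <- a$major_cn[i] != a$major_cn[i + 1L] ||
                             a$minor_cn[i] != a$minor_cn[i + 1L]
                if (diffState && len[i] >= minSegBp && len[i + 1L] >= minSegBp)
                    score <- score + 1L
            }
        }
    }
    score
}

#' Combine scar scores into an HRD call
#'
#' @param loh,lst,ntai non-negative integer scores (vectors allowed).
#' @param threshold HRD-high threshold on the sum; the literature value 42
#'   is the default and the call is inclusive (sum >= threshold is "high").
#' @param sampleId sample identifiers.
#' @return a [ScarScores-class].
#' @export
hrdClassify <- function(loh, lst, ntai, threshold = 42,
                        sampleId = paste0("sample", seq_along(loh))) {
    if (any(loh < 0) || any(lst < 0) || any(ntai < 0))
        stop("scar scores must be non-negative")
    loh <- as.integer(loh); lst <- as.integer(lst); ntai <- as.integer(ntai)
    hs <- loh + lst + ntai
    new("ScarScores", sampleId = as.character(sampleId), loh = loh,
        lst = lst, ntai = ntai, hrdSum = hs, hrdHigh = hs >= threshold,
        threshold = threshold)
}

#' Genomic scar scores of one sample
#'
#' Convenience wrapper: preprocesses the segment profile (3 Mb smoothing)
#' and computes HRD-LOH, LST and ntAI plus the HRD call.
#'
#' @param segments one sample's raw segment data.frame.
#' @param layout a [GenomeLayout-class].
#' @param threshold HRD-high threshold (default 42).
#' @param minSegBp smoothing window (default 3e6).
#' @param lohMinBp,lstMinSegBp,telomereMargin score parameters, see
#'   [lohScore()], [lstScore()], [ntaiScore()].
#' @param sampleId sample identifier (defaults to the `sample_id` column if
#'   present).
#' @return a [ScarScores-class] with one sample.
#' @export
scarScores <- function(segments, layout, threshold = 42, minSegBp = 3e6,
                       lohMinBp = 15e6, lstMinSegBp = 10e6,
                       telomereMargin = 0, sampleId = NULL) {
    if (is.null(sampleId))
        sampleId <- if ("sample_id" %in% names(segments) && nrow(segments))
            as.character(segments$sample_id[1]) else "sample"
    pre <- preprocessSegments(segments, minSegBp)
    hrdClassify(lohScore(pre, layout, lohMinBp),
                lstScore(pre, layout, lstMinSegBp),
                ntaiScore(pre, layout, telomereMargin),
                threshold = threshold, sampleId = sampleId)
}
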