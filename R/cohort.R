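## Cohort-level statistics: aggregated allele frequencies vs reference
## populations, panel-vs-WGS concordance, HRD-vs-signature correlation and
## clinicopathological summary tables.

#' Aggregated cohort allele frequency at one site
#'
#' The cohort alternate-allele frequency of a germline variant is the ratio
#' of the total number of alternate alleles observed in the mutated samples
#' to the total sequencing depth, where non-mutated samples are assumed to
#' carry exactly zero alternate alleles at the position and to have the
#' mean sequencing depth of the mutated samples:
#' `AF = sum(alt) / (sum(depth) + (nCohort - nMutated) * mean(depth))`.
#'
#' @param altCounts alternate-allele read counts of the mutated samples.
#' @param depths total read depths of the mutated samples (parallel).
#' @param nCohort total number of cohort samples (>= number of mutated
#'   samples).
#' @return the aggregated allele frequency in `[0, 1]`.
#' @export
#' @examples
#' cohortAggregateAf(c(10, 20), c(40, 60), nCohort = 5)  # 0.12
cohortAggregateAf <- function(altCounts, depths, nCohort) {
    k <- length(altCounts)
    if (length(depths) != k)
        stop("altCounts and depths must be parallel")
    if (k < 1L) stop("at least one mutated sample is required")
    if (nCohort < k)
        stop("nCohort (", nCohort, ") is smaller than the number of mutated ",
             "samples (", k, ")")
    if (any(altCounts > depths)) stop("alt count exceeds depth")
    denom <- sum(depths) + (nCohort - k) * mean(depths)
    if (denom <= 0) stop("zero total depth")
    sum(altCounts) / denom
}

#' Aggregate cohort AFs for every variant in a table
#'
#' Groups a germline variant table by variant key (chrom, pos, ref, alt) and
#' applies [cohortAggregateAf()] per site.
#'
#' @param variants variant data.frame with `t_alt_count` and `t_depth`.
#' @param nCohort number of samples in the cohort.
#' @return data.frame: variant key columns, `n_mutated`, `cohort_af`.
#' @export
aggregateCohortAf <- function(variants, nCohort) {
    if (!all(c("t_alt_count", "t_depth") %in% names(variants)))
        stop("variants need t_alt_count and t_depth columns")
    key <- paste(variants$Chromosome, variants$Start_Position,
                 variants$Reference_Allele, variants$Tumor_Seq_Allele2,
                 sep = ":")
    rows <- lapply(split(seq_len(nrow(variants)), key), function(i) {
        v <- variants[i, ]
        data.frame(Chromosome = v$Chromosome[1],
                   Start_Position = v$Start_Position[1],
                   Reference_Allele = v$Reference_Allele[1],
                   Tumor_Seq_Allele2 = v$Tumor_Seq_Allele2[1],
                   n_mutated = length(i),
                   cohort_af = cohortAggregateAf(v$t_alt_count, v$t_depth,
                                                 nCohort),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Join cohort AFs with reference-population AFs
#'
#' Joins per-variant cohort allele frequencies against one or more
#' reference-population AF tables (e.g. gnomAD and 1000 Genomes Europeans).
#' When several references report the variant, `ref_af_used` is their mean;
#' when only one does, that single value is used; variants present in no
#' reference are flagged (`in_reference = FALSE`) and kept with
#' `ref_af_used = NA`, never dropped.
#'
#' @param cohortAf data.frame from [aggregateCohortAf()] (key columns +
#'   `cohort_af`).
#' @param refTables named list of data.frames, each with the four key
#'   columns (`Chromosome`, `Start_Position`, `Reference_Allele`,
#'   `Tumor_Seq_Allele2`) and an `af` column.
#' @return `cohortAf` with one `af_<source>` column per reference plus
#'   `ref_af_used` and `in_reference`.
#' @export
compareToReference <- function(cohortAf, refTables) {
    key <- function(d) paste(d$Chromosome, d$Start_Position,
                             d$Reference_Allele, d$Tumor_Seq_Allele2,
                             sep = ":")
    ck <- key(cohortAf)
    afCols <- matrix(NA_real_, nrow(cohortAf), length(refTables),
                     dimnames = list(NULL, paste0("af_", names(refTables))))
    for (j in seq_along(refTables)) {
        rt <- refTables[[j]]
        afCols[, j] <- rt$af[match(ck, key(rt))]
    }
    used <- rowMeans(afCols, na.rm = TRUE)
    used[is.nan(used)] <- NA_real_
    out <- cbind(cohortAf, as.data.frame(afCols),
                 data.frame(ref_af_used = used,
                            in_reference = rowSums(!is.na(afCols)) > 0))
    rownames(out) <- NULL
    out
}

#' WGS-versus-panel variant concordance
#'
#' Matches two call sets of the same sample on the (chrom, pos, ref, alt)
#' key and counts variants found by both, by WGS only, and by the panel
#' only. Before matching, WGS calls are restricted to the panel's gene list
#' and, optionally, to exonic classes (everything except `Intron`, `RNA`,
#' `3'UTR`, `5'UTR`; splice categories are retained), since introns are
#' shallowly covered in targeted assays.
#'
#' @param wgs,panel variant data.frames of one sample.
#' @param geneList character vector of panel genes, or `NULL` for no gene
#'   filter.
#' @param exonicOnly apply the exonic class filter to the WGS calls
#'   (default `TRUE`).
#' @return list with `n_both`, `n_wgs_only`, `n_panel_only` and
#'   `overlap_frac` = n_both / (n_both + n_panel_only) (NA when the panel
#'   found nothing).
#' @export
matchVariants <- function(wgs, panel, geneList = NULL, exonicOnly = TRUE) {
    if (!is.null(geneList))
        wgs <- wgs[wgs$Hugo_Symbol %in% geneList, , drop = FALSE]
    if (exonicOnly)
        wgs <- wgs[!wgs$Variant_Classification %in%
                       c("Intron", "RNA", "3'UTR", "5'UTR"), , drop = FALSE]
    key <- function(d) paste(d$Chromosome, d$Start_Position,
                             d$Reference_Allele, d$Tumor_Seq_Allele2,
                             sep = ":")
    wk <- unique(key(wgs))
    pk <- unique(key(panel))
    nBoth <- length(intersect(wk, pk))
    res <- list(n_both = nBoth,
                n_wgs_only = length(setdiff(wk, pk)),
                n_panel_only = length(setdiff(pk, wk)))
    res$overlap_frac <- if (nBoth + res$n_panel_only > 0)
        nBoth / (nBoth + res$n_panel_only) else NA_real_
    res
}

#' Correlate HRD sums with signature exposures
#'
#' Pearson (or Spearman) correlation between per-sample HRD scar sums and
#' the exposure weights of selected signatures — by default the three
#' HRD-linked processes SBS3, ID6 and ID8. Samples are matched by
#' identifier; at least three shared samples are required. A constant input
#' yields `NA` (undefined), never 0.
#'
#' @param scores a [ScarScores-class] covering the cohort.
#' @param exposureTable data.frame from [fitExposures()] (possibly from two
#'   schemes rbound column-wise by the caller), with `sample_id` and one
#'   column per signature.
#' @param keys signature column names to correlate against (default
#'   `c("SBS3", "ID6", "ID8")`, intersected with available columns).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return named numeric vector of correlations, one per key.
#' @export
correlateScars <- function(scores, exposureTable,
                           keys = c("SBS3", "ID6", "ID8"),
                           method = c("pearson", "spearman")) {
    method <- match.arg(method)
    keys <- intersect(keys, names(exposureTable))
    if (!length(keys)) stop("none of the requested signatures are present")
    shared <- intersect(sampleId(scores), exposureTable$sample_id)
    if (length(shared) < 3L)
        stop("need at least 3 shared samples, have ", length(shared))
    hs <- hrdSum(scores)[shared]
    ex <- exposureTable[match(shared, exposureTable$sample_id), , drop = FALSE]
    vapply(keys, function(k) {
        x <- ex[[k]]
        if (sd(hs) == 0 || sd(x) == 0) return(NA_real_)
        cor(hs, x, method = method)
    }, numeric(1))
}

## round half away from zero, to `digits` decimals
.roundHalfUp <- function(x, digits = 0) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Clinicopathological cohort summary table
#'
#' Per-group summaries in the style of a clinical "Table 1": for each
#' categorical variable the count and integer-rounded percentage of every
#' category (denominator = group size; `NA` becomes its own `"NA"` category
#' when present; rounding is half away from zero, optionally to one
#' decimal), and for each numeric variable the mean, standard deviation,
#' minimum and maximum over non-missing values.
#'
#' @param metadata data.frame, one row per patient.
#' @param group name of the grouping column (e.g. treatment cohort).
#' @param categorical,numeric character vectors naming the variables to
#'   summarize.
#' @param digits decimals for percentages (default 0).
#' @return list with `categorical` (data.frame: variable, category, group,
#'   count, percent) and `numeric` (data.frame: variable, group, mean, sd,
#'   min, max, n_na).
#' @export
summarizeCohort <- function(metadata, group, categorical = character(0),
                            numeric = character(0), digits = 0) {
    if (!group %in% names(metadata))
        stop("unknown group variable: ", group)
    missingVars <- setdiff(c(categorical, numeric), names(metadata))
    if (length(missingVars))
        stop("unknown variable(s): ", paste(missingVars, collapse = ", "))
    groups <- unique(as.character(metadata[[group]]))
    catRows <- list()
    for (v in categorical) {
        vals <- as.character(metadata[[v]])
        vals[is.na(vals)] <- "NA"
        cats <- unique(vals)
        for (g in groups) {
            inG <- as.character(metadata[[group]]) == g
            denom <- sum(inG)
            for (cc in cats) {
                cnt <- sum(inG & vals == cc)
                catRows[[length(catRows) + 1L]] <- data.frame(
                    variable = v, category = cc, group = g, count = cnt,
                    percent = .roundHalfUp(100 * cnt / denom, digits),
                    stringsAsFactors = FALSE)
            }
        }
    }
    numRows <- list()
    for (v in numeric) {
        for (g in groups) {
            x <- metadata[[v]][as.character(metadata[[group]]) == g]
            nNA <- sum(is.na(x))
            x <- x[!is.na(x)]
            numRows[[length(numRows) + 1L]] <- data.frame(
                variable = v, group = g, mean = mean(x), sd = sd(x),
                min = min(x), max = max(x), n_na = nNA,
                stringsAsFactors = FALSE)
        }
    }
    list(categorical = if (length(catRows)) do.call(rbind, catRows)
             else data.frame(),
         numeric = if (length(numRows)) do.call(rbind, numRows)
             else data.frame())
}

#' Look up one percentage in a cohort summary
#'
#' @param summary result of [summarizeCohort()].
#' @param variable,category,group the cell to extract.
#' @return the percentage (single number).
#' @export
summaryPercent <- function(summary, variable, category, group) {
    d <- summary$categorical
    hit <- d$variable == variable & d$category == category & d$group == group
    if (sum(hit) != 1L)
        stop("no unique cell for ", variable, "/", category, "/", group)
    d$percent[hit]
}
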