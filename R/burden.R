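## Tumor mutational burden and mutation-type composition.

#' Tumor mutational burden (TMB)
#'
#' TMB is the number of protein-impact somatic mutations per megabase of
#' coding genome. The counted categories are exactly those of
#' [filterSomaticImpactClasses()]: frame-shift and in-frame indels,
#' missense, nonsense, nonstop, splice region, splice site and translation
#' start site mutations.
#'
#' @param variants one sample's somatic variant data.frame.
#' @param codingMb size of the coding territory in Mbp; no universal value
#'   exists, so it is an explicit parameter (default 35).
#' @return mutations per coding Mbp.
#' @export
#' @examples
#' maf <- data.frame(Variant_Classification =
#'     rep(c("Missense_Mutation", "Silent"), c(30, 12)))
#' computeTmb(maf, codingMb = 30)  # 1.0
computeTmb <- function(variants, codingMb = 35) {
    if (!is.numeric(codingMb) || length(codingMb) != 1L || codingMb <= 0)
        stop("codingMb must be a single positive number")
    nrow(filterSomaticImpactClasses(variants)) / codingMb
}

#' Somatic mutational prevalence
#'
#' All somatic mutations of a sample per megabase of genome, regardless of
#' their consequence. For breast cancer this typically falls in 0-10 /Mbp.
#'
#' @param variants one sample's full somatic variant data.frame, unfiltered.
#' @param genomeMb genome size in Mbp (default 3000; for synthetic genomes
#'   use the layout's total length).
#' @return mutations per genomic Mbp.
#' @export
computePrevalence <- function(variants, genomeMb = 3000) {
    if (!is.numeric(genomeMb) || length(genomeMb) != 1L || genomeMb <= 0)
        stop("genomeMb must be a single positive number")
    nrow(variants) / genomeMb
}

#' Mutation-type fractions
#'
#' Fractions of SNPs, deletions and insertions among a sample's records.
#'
#' @param variants nonempty variant data.frame with a `Variant_Type` column.
#' @return named numeric vector `c(frac_snp=, frac_del=, frac_ins=)`,
#'   summing to 1.
#' @export
variantTypeFractions <- function(variants) {
    if (!nrow(variants))
        stop("variant type fractions are undefined for an empty record set")
    n <- nrow(variants)
    c(frac_snp = sum(variants$Variant_Type == "SNP") / n,
      frac_del = sum(variants$Variant_Type == "DEL") / n,
      frac_ins = sum(variants$Variant_Type == "INS") / n)
}

#' Per-sample burden summary table
#'
#' Computes TMB, somatic mutational prevalence, mutation-type counts and
#' fractions for every sample in a multi-sample variant table.
#'
#' @param variants somatic variant data.frame with `Tumor_Sample_Barcode`.
#' @param codingMb,genomeMb denominators, see [computeTmb()] and
#'   [computePrevalence()].
#' @return data.frame with one row per sample: `sample_id`, `tmb`,
#'   `prevalence`, `n_snp`, `n_del`, `n_ins`, `frac_snp`, `frac_del`,
#'   `frac_ins`.
#' @export
burdenSummary <- function(variants, codingMb = 35, genomeMb = 3000) {
    samples <- unique(variants$Tumor_Sample_Barcode)
    rows <- lapply(samples, function(s) {
        v <- variants[variants$Tumor_Sample_Barcode == s, , drop = FALSE]
        fr <- variantTypeFractions(v)
        data.frame(sample_id = s,
                   tmb = computeTmb(v, codingMb),
                   prevalence = computePrevalence(v, genomeMb),
                   n_snp = sum(v$Variant_Type == "SNP"),
                   n_del = sum(v$Variant_Type == "DEL"),
                   n_ins = sum(v$Variant_Type == "INS"),
                   frac_snp = fr[["frac_snp"]],
                   frac_del = fr[["frac_del"]],
                   frac_ins = fr[["frac_ins"]],
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
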