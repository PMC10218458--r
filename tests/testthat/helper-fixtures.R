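## Fixture builders shared across test files.

## a valid MAF-dialect data.frame of random records
randomVariantTable <- function(n, seed = 1, samples = c("S1", "S2")) {
    set.seed(seed)
    classes <- mafClassifications()
    bases <- c("A", "C", "G", "T")
    type <- sample(c("SNP", "DEL", "INS"), n, replace = TRUE,
                   prob = c(0.86, 0.08, 0.06))
    ref <- alt <- character(n)
    for (i in seq_len(n)) {
        if (type[i] == "SNP") {
            ref[i] <- sample(bases, 1)
            alt[i] <- sample(setdiff(bases, ref[i]), 1)
        } else if (type[i] == "DEL") {
            ref[i] <- paste(sample(bases, sample(1:6, 1), replace = TRUE),
                            collapse = "")
            alt[i] <- "-"
        } else {
            ref[i] <- "-"
            alt[i] <- paste(sample(bases, sample(1:6, 1), replace = TRUE),
                            collapse = "")
        }
    }
    depth <- sample(20:120, n, replace = TRUE)
    data.frame(
        Hugo_Symbol = sample(c("TP53", "PIK3CA", "KMT2C", "MUC4", "BRCA1"),
                             n, replace = TRUE),
        Chromosome = sample(c("chr1", "chr2"), n, replace = TRUE),
        Start_Position = sample.int(1e6, n),
        Reference_Allele = ref,
        Tumor_Seq_Allele2 = alt,
        Variant_Classification = sample(classes, n, replace = TRUE),
        Variant_Type = type,
        Tumor_Sample_Barcode = sample(samples, n, replace = TRUE),
        t_depth = depth,
        t_alt_count = pmin(depth, sample(1:60, n, replace = TRUE)),
        stringsAsFactors = FALSE)
}

## minimal variant table from a classification vector
classTable <- function(classes, type = "SNP") {
    n <- length(classes)
    data.frame(
        Hugo_Symbol = rep("TP53", n), Chromosome = rep("chr1", n),
        Start_Position = seq_len(n) * 10,
        Reference_Allele = rep(if (type == "SNP") "C" else "CA", n),
        Tumor_Seq_Allele2 = rep(if (type == "SNP") "T" else "-", n),
        Variant_Classification = classes,
        Variant_Type = rep(if (type == "SNP") "SNP" else "DEL", n),
        Tumor_Sample_Barcode = rep("S1", n), stringsAsFactors = FALSE)
}

## a tiny layout whose arms fit all planted-event geometry
testScarLayout <- function(nChrom = 8) defaultScarLayout(nChrom)

## a disjoint-support toy signature pair over SBS96 for exact EM checks
disjointSigs <- function() {
    ch <- sbsChannels()
    a <- stats::setNames(rep(0, 96), ch)
    b <- a
    a[1:8] <- 1 / 8        # C>A block
    b[89:96] <- 1 / 8      # T>G block
    signatureSet(rbind(A = a, B = b), "SBS96")
}
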