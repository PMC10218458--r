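## End-to-end orchestration: write a simulated toy study to disk, and run
## the full downstream analysis flow over a study directory. The function
## interface (rather than a shell wrapper) is the package's entry point;
## every stage is also callable on its own.

#' Write a complete simulated toy study directory
#'
#' Generates and writes everything the analysis consumes: a genome FASTA
#' with layout table, a multi-sample somatic MAF (with per-variant channel
#' truth), per-sample segment tables with planted scar counts, the
#' synthetic clinicopathological metadata, and the bundled signature
#' matrices. Sample mixtures follow the HRD-graded cohort design of
#' [simHrdCohort()]: a latent HRD intensity drives SBS3/ID6/ID8 weights and
#' planted scar counts jointly.
#'
#' @param dir output directory (created; must not exist or be empty).
#' @param nSamples number of tumor samples (default 4).
#' @param nSnv,nIndel mutations per sample (defaults 300 / 60; genome-placed,
#'   so kept modest).
#' @param seed RNG seed.
#' @return `dir`, invisibly; files: `genome.fa`, `layout.tsv`,
#'   `somatic.maf`, `truth_channels.tsv`, `truth_exposures.tsv`,
#'   `segments.tsv`, `truth_scars.tsv`, `metadata.tsv`.
#' @export
simStudy <- function(dir, nSamples = 4, nSnv = 300, nIndel = 60, seed = 1) {
    if (dir.exists(dir) && length(list.files(dir)))
        stop("directory exists and is not empty: ", dir)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    set.seed(seed)
    g <- simGenome(nChrom = 2, chromLength = 1.5e6, seed = seed)
    writeXStringSet(g$genome, file.path(dir, "genome.fa"))
    writeGenomeLayout(g$layout, file.path(dir, "layout.tsv"))
    scarLayout <- defaultScarLayout()
    writeGenomeLayout(scarLayout, file.path(dir, "scar_layout.tsv"))
    sbs <- bundledSignatures("SBS96")
    id <- bundledSignatures("ID83")
    ids <- sprintf("S%02d", seq_len(nSamples))
    h <- runif(nSamples)
    seeds <- sample.int(1e6, 2L * nSamples)
    mafs <- list(); chTruth <- list(); expTruth <- list(); segs <- list()
    scarTruth <- list()
    for (i in seq_len(nSamples)) {
        sbsW <- c(SBS3 = 0.05 + 0.60 * h[i])
        rest <- 1 - sbsW[["SBS3"]]
        sbsW <- c(sbsW, SBS1 = 0.40 * rest, SBS2 = 0.20 * rest,
                  SBS13 = 0.20 * rest, SBS18 = 0.20 * rest)
        idW <- c(ID6 = 0.05 + 0.45 * h[i], ID8 = 0.03 + 0.25 * h[i])
        restI <- 1 - sum(idW)
        idW <- c(idW, ID1 = 0.40 * restI, ID2 = 0.35 * restI,
                 ID4 = 0.25 * restI)
        sim <- simMutations(g$genome, sbs, id, sbsW, idW, nSnv = nSnv,
                            nIndel = nIndel, sampleId = ids[i],
                            seed = seeds[i])
        mafs[[i]] <- sim$maf
        chTruth[[i]] <- data.frame(sample_id = ids[i], sim$truth)
        expTruth[[i]] <- data.frame(sample_id = ids[i],
                                    signature = c(names(sbsW), names(idW)),
                                    weight = c(sbsW, idW))
        plant <- c(loh = round(5 + 25 * h[i]), lst = round(3 + 20 * h[i]),
                   ntai = round(2 + 14 * h[i]))
        ss <- simSegments(scarLayout, plant[["loh"]], plant[["lst"]],
                          plant[["ntai"]], sampleId = ids[i],
                          seed = seeds[nSamples + i])
        segs[[i]] <- ss$segments
        scarTruth[[i]] <- data.frame(sample_id = ids[i], t(plant))
    }
    writeMaf(do.call(rbind, mafs), file.path(dir, "somatic.maf"))
    write.table(do.call(rbind, chTruth), file.path(dir, "truth_channels.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(do.call(rbind, expTruth),
                file.path(dir, "truth_exposures.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(do.call(rbind, segs), file.path(dir, "segments.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(do.call(rbind, scarTruth), file.path(dir, "truth_scars.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    meta <- system.file("extdata", "cohort_metadata_synthetic.tsv",
                        package = "scarsig", mustWork = TRUE)
    file.copy(meta, file.path(dir, "metadata.tsv"))
    invisible(dir)
}

#' Run the full downstream analysis over a study directory
#'
#' Orders the stages as in the study flow: somatic class filtering and
#' pathogenicity flagging, per-sample burden, SBS96/ID83 catalogs, EM
#' signature refitting, scar scores with HRD calls, HRD-versus-signature
#' correlation, and the cohort metadata summary. All outputs are TSV files
#' in `outDir` plus a machine-readable JSON run log recording parameters.
#' Any missing input path is a startup error before any output is written.
#'
#' @param studyDir directory from [simStudy()] (or with the same file
#'   names).
#' @param outDir output directory.
#' @param codingMb,genomeMb burden denominators; `genomeMb` defaults to the
#'   layout total.
#' @param hrdThreshold HRD-high threshold (default 42).
#' @param tol,maxIter EM settings.
#' @return invisibly, a list of the in-memory stage results.
#' @export
runStudy <- function(studyDir, outDir, codingMb = 35, genomeMb = NULL,
                     hrdThreshold = 42, tol = 1e-8, maxIter = 10000L) {
    need <- c("genome.fa", "layout.tsv", "scar_layout.tsv", "somatic.maf",
              "segments.tsv", "metadata.tsv")
    paths <- file.path(studyDir, need)
    missing <- need[!file.exists(paths)]
    if (length(missing))
        stop("study directory is missing input file(s): ",
             paste(missing, collapse = ", "))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    genome <- readDNAStringSet(file.path(studyDir, "genome.fa"))
    names(genome) <- sub("\\s.*", "", names(genome))
    layout <- readGenomeLayout(file.path(studyDir, "layout.tsv"))
    scarLayout <- readGenomeLayout(file.path(studyDir, "scar_layout.tsv"))
    maf <- readMaf(file.path(studyDir, "somatic.maf"))
    segments <- readSegments(file.path(studyDir, "segments.tsv"))
    meta <- read.delim(file.path(studyDir, "metadata.tsv"),
                       stringsAsFactors = FALSE)
    if (is.null(genomeMb)) genomeMb <- sum(layout@length) / 1e6

    impact <- filterSomaticImpactClasses(maf)
    impact$pathogenic <- flagPathogenic(impact)
    writeMaf(impact, file.path(outDir, "somatic_impact_filtered.maf"))

    burden <- burdenSummary(maf, codingMb = codingMb, genomeMb = genomeMb)
    write.table(burden, file.path(outDir, "burden.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    samples <- unique(maf$Tumor_Sample_Barcode)
    sbsSigs <- bundledSignatures("SBS96")
    idSigs <- bundledSignatures("ID83")
    sbsCats <- lapply(samples, function(s)
        buildCatalog(maf[maf$Tumor_Sample_Barcode == s, ], genome, "SBS96",
                     sampleId = s))
    idCats <- lapply(samples, function(s)
        buildCatalog(maf[maf$Tumor_Sample_Barcode == s, ], genome, "ID83",
                     sampleId = s))
    writeCatalogs(sbsCats, file.path(outDir, "catalog_sbs96.tsv"))
    writeCatalogs(idCats, file.path(outDir, "catalog_id83.tsv"))

    sbsExp <- fitExposures(sbsCats, sbsSigs, tol = tol, maxIter = maxIter)
    idExp <- fitExposures(idCats, idSigs, tol = tol, maxIter = maxIter)
    write.table(sbsExp, file.path(outDir, "exposures_sbs96.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(idExp, file.path(outDir, "exposures_id83.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    scoreList <- lapply(samples, function(s)
        scarScores(segments[segments$sample_id == s, ], scarLayout,
                   threshold = hrdThreshold, sampleId = s))
    scores <- hrdClassify(vapply(scoreList, function(x) x@loh, integer(1)),
                          vapply(scoreList, function(x) x@lst, integer(1)),
                          vapply(scoreList, function(x) x@ntai, integer(1)),
                          threshold = hrdThreshold, sampleId = samples)
    write.table(as.data.frame(scores), file.path(outDir, "scar_scores.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

    expo <- merge(sbsExp[, c("sample_id", "SBS3")],
                  idExp[, c("sample_id", "ID6", "ID8")], by = "sample_id")
    correlations <- if (length(samples) >= 3L)
        correlateScars(scores, expo) else NULL
    if (!is.null(correlations))
        write.table(data.frame(signature = names(correlations),
                               pearson_r = correlations),
                    file.path(outDir, "hrd_signature_correlation.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)

    summary <- summarizeCohort(meta, "cohort",
        categorical = c("er_status", "pr_status", "her2_status",
                        "ihc_subtype", "pt_stage", "pn_stage"),
        numeric = "age")
    write.table(summary$categorical,
                file.path(outDir, "cohort_summary_categorical.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(summary$numeric,
                file.path(outDir, "cohort_summary_numeric.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

    log <- list(package = "scarsig",
                version = as.character(utils::packageVersion("scarsig")),
                parameters = list(codingMb = codingMb, genomeMb = genomeMb,
                                  hrdThreshold = hrdThreshold, tol = tol,
                                  maxIter = maxIter),
                samples = samples,
                inputs = as.list(setNames(paths, need)))
    jsonlite::write_json(log, file.path(outDir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(list(burden = burden, sbsExposures = sbsExp,
                   idExposures = idExp, scores = scores,
                   correlations = correlations, summary = summary))
}
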