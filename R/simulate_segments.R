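## Segment-profile simulation with planted scar events, paired WGS/panel
## call sets, and an HRD-graded cohort generator.

#' Default genome layout for segment simulations
#'
#' A human-like layout: `nChrom` chromosomes of `chromLength` bp with the
#' centromere at 45-50% of the length. Used by the scar-score simulations,
#' where only geometry matters, not sequence.
#'
#' @param nChrom number of chromosomes (default 22).
#' @param chromLength chromosome length in bp (default 150e6).
#' @return a [GenomeLayout-class].
#' @export
defaultScarLayout <- function(nChrom = 22, chromLength = 150e6) {
    genomeLayout(paste0("chr", seq_len(nChrom)),
                 rep(chromLength, nChrom),
                 rep(floor(chromLength * 0.45), nChrom),
                 rep(floor(chromLength * 0.50), nChrom))
}

## Geometry constants for planted events (bp). Chosen so that no plant
## induces a score of another kind: telomeric AI segments are 8 Mb (< 10 Mb,
## so never an LST partner), LST blocks are balanced 12 Mb telomeric
## segments, LOH runs are interior 16 Mb (2,0) blocks insulated by 4 Mb
## (3,2) spacers (too short for LST, interior so never telomeric AI).
.NTAI_LEN <- 8e6
.LST_LEN <- 12e6
.LOH_LEN <- 16e6
.SPACER <- 4e6
.LOH_OFFSET <- 26e6   # block start offset from the arm's outer end

#' Simulate an allele-specific copy-number profile with planted scars
#'
#' Builds a baseline (2,2) profile over the layout and plants exactly
#' `loh` interior >15 Mb loss-of-heterozygosity runs, `lst` qualifying
#' large-scale-transition breakpoints, and `ntai` telomeric
#' allelic-imbalance segments, at non-interacting positions (each event
#' contributes to exactly one score). Telomeric slots (two per chromosome)
#' host ntAI and LST plants; interior arm slots host LOH plants. Requesting
#' more events than there are slots, or a layout whose arms are too short,
#' is an error.
#'
#' @param layout a [GenomeLayout-class] (default [defaultScarLayout()]).
#' @param loh,lst,ntai planted event counts.
#' @param sampleId sample identifier attached to the segments.
#' @param seed RNG seed (slot order is shuffled; geometry is fixed).
#' @return list with `segments` (data.frame) and `truth`
#'   (`c(loh=, lst=, ntai=)`).
#' @export
simSegments <- function(layout = defaultScarLayout(), loh = 0, lst = 0,
                        ntai = 0, sampleId = "S1", seed = 1) {
    set.seed(seed)
    chroms <- layout@chrom
    nC <- length(chroms)
    armLen <- min(layout@centromereStart - 1,
                  layout@length - layout@centromereEnd)
    if (any(armLen < .LOH_OFFSET + .LOH_LEN + 2 * .SPACER + 3e6))
        stop("layout arms too short for planted events")
    telSlots <- data.frame(chrom = rep(chroms, 2),
                           arm = rep(c("p", "q"), each = nC),
                           stringsAsFactors = FALSE)
    intSlots <- telSlots
    if (ntai + lst > nrow(telSlots))
        stop("infeasible plant: ", ntai + lst, " telomeric events but only ",
             nrow(telSlots), " chromosome ends")
    if (loh > nrow(intSlots))
        stop("infeasible plant: ", loh, " LOH events but only ",
             nrow(intSlots), " interior arm slots")
    telSlots <- telSlots[sample.int(nrow(telSlots)), , drop = FALSE]
    intSlots <- intSlots[sample.int(nrow(intSlots)), , drop = FALSE]

    events <- list()
    addEvent <- function(chrom, start, end, major, minor) {
        events[[length(events) + 1L]] <<- data.frame(
            chrom = chrom, start = start, end = end, major_cn = major,
            minor_cn = minor, stringsAsFactors = FALSE)
    }
    telUsed <- 0L
    for (k in seq_len(ntai)) {
        telUsed <- telUsed + 1L
        sl <- telSlots[telUsed, ]
        len <- layout@length[match(sl$chrom, chroms)]
        if (sl$arm == "p") addEvent(sl$chrom, 1, .NTAI_LEN, 2, 1)
        else addEvent(sl$chrom, len - .NTAI_LEN + 1, len, 2, 1)
    }
    for (k in seq_len(lst)) {
        telUsed <- telUsed + 1L
        sl <- telSlots[telUsed, ]
        len <- layout@length[match(sl$chrom, chroms)]
        if (sl$arm == "p") addEvent(sl$chrom, 1, .LST_LEN, 3, 3)
        else addEvent(sl$chrom, len - .LST_LEN + 1, len, 3, 3)
    }
    for (k in seq_len(loh)) {
        sl <- intSlots[k, ]
        len <- layout@length[match(sl$chrom, chroms)]
        if (sl$arm == "p") {
            a <- .LOH_OFFSET
            addEvent(sl$chrom, a, a + .SPACER - 1, 3, 2)
            addEvent(sl$chrom, a + .SPACER, a + .SPACER + .LOH_LEN - 1, 2, 0)
            addEvent(sl$chrom, a + .SPACER + .LOH_LEN,
                     a + 2 * .SPACER + .LOH_LEN - 1, 3, 2)
        } else {
            b <- len - .LOH_OFFSET + 1
            addEvent(sl$chrom, b - 2 * .SPACER - .LOH_LEN + 1,
                     b - .SPACER - .LOH_LEN, 3, 2)
            addEvent(sl$chrom, b - .SPACER - .LOH_LEN + 1, b - .SPACER, 2, 0)
            addEvent(sl$chrom, b - .SPACER + 1, b, 3, 2)
        }
    }
    ev <- if (length(events)) do.call(rbind, events) else
        data.frame(chrom = character(0), start = numeric(0),
                   end = numeric(0), major_cn = numeric(0),
                   minor_cn = numeric(0))
    ## fill baseline (2,2) around events per chromosome
    segs <- list()
    for (chrom in chroms) {
        len <- layout@length[match(chrom, chroms)]
        e <- ev[ev$chrom == chrom, , drop = FALSE]
        e <- e[order(e$start), , drop = FALSE]
        cursor <- 1
        for (i in seq_len(nrow(e))) {
            if (e$start[i] > cursor)
                segs[[length(segs) + 1L]] <- data.frame(
                    chrom = chrom, start = cursor, end = e$start[i] - 1,
                    major_cn = 2, minor_cn = 2, stringsAsFactors = FALSE)
            segs[[length(segs) + 1L]] <- e[i, ]
            cursor <- e$end[i] + 1
        }
        if (cursor <= len)
            segs[[length(segs) + 1L]] <- data.frame(
                chrom = chrom, start = cursor, end = len, major_cn = 2,
                minor_cn = 2, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, segs)
    out$sample_id <- sampleId
    rownames(out) <- NULL
    list(segments = out, truth = c(loh = loh, lst = lst, ntai = ntai))
}

#' Random (unplanted) segment profile
#'
#' Generates an arbitrary valid segment profile by cutting each chromosome
#' at random breakpoints and assigning random allele-specific states —
#' used to compare score implementations against brute-force oracles, with
#' no planted truth.
#'
#' @param layout a [GenomeLayout-class].
#' @param meanSegs mean number of segments per chromosome (default 8).
#' @param sampleId sample identifier.
#' @param seed RNG seed.
#' @return segment data.frame.
#' @export
simRandomSegments <- function(layout, meanSegs = 8, sampleId = "S1",
                              seed = 1) {
    set.seed(seed)
    segs <- list()
    states <- rbind(c(2, 2), c(2, 1), c(2, 0), c(3, 1), c(3, 3), c(1, 1),
                    c(1, 0), c(4, 2), c(3, 0), c(3, 2))
    for (i in seq_along(layout@chrom)) {
        len <- layout@length[i]
        k <- max(1L, rpois(1L, meanSegs))
        cuts <- sort(sample.int(len - 1L, min(k - 1L, len - 2L)))
        bounds <- c(0, cuts, len)
        si <- sample.int(nrow(states), length(bounds) - 1L, replace = TRUE)
        segs[[i]] <- data.frame(chrom = layout@chrom[i],
                                start = bounds[-length(bounds)] + 1,
                                end = bounds[-1],
                                major_cn = states[si, 1],
                                minor_cn = states[si, 2],
                                stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, segs)
    out$sample_id <- sampleId
    rownames(out) <- NULL
    out
}

#' Simulate a paired panel call set from a WGS call set
#'
#' Emulates the asymmetry of targeted-panel versus WGS calling: each WGS
#' variant is retained on the panel independently with probability
#' `sharing`, and panel-only false positives are added at rate `fpRate`
#' (relative to the WGS count) at loci absent from the WGS set.
#'
#' @param wgs variant data.frame (one sample).
#' @param sharing per-variant retention probability (default 0.9).
#' @param fpRate panel-only false-positive rate (default 0.05).
#' @param seed RNG seed.
#' @return variant data.frame of the simulated panel calls.
#' @export
simPanelPair <- function(wgs, sharing = 0.9, fpRate = 0.05, seed = 1) {
    set.seed(seed)
    keep <- runif(nrow(wgs)) < sharing
    panel <- wgs[keep, , drop = FALSE]
    nFp <- rbinom(1L, nrow(wgs), fpRate)
    if (nFp > 0 && nrow(wgs)) {
        fp <- wgs[sample.int(nrow(wgs), nFp, replace = TRUE), , drop = FALSE]
        fp$Start_Position <- fp$Start_Position + sample(137:997, nFp,
                                                        replace = TRUE)
        panel <- rbind(panel, fp)
    }
    rownames(panel) <- NULL
    panel
}

#' Simulate an HRD-graded cohort
#'
#' Generates a cohort in which each sample carries a latent HRD intensity
#' `h` in [0, 1] driving, jointly, its planted scar counts and the weights
#' of the HRD-linked signatures (SBS3 for substitutions, ID6 and ID8 for
#' indels) in its catalog mixtures — the structure in which scar sums and
#' refitted HRD-signature exposures should correlate strongly. Catalogs are
#' drawn at the channel level ([simCatalog()]); segments come from
#' [simSegments()].
#'
#' @param nSamples cohort size (default 29).
#' @param nSnv,nIndel mutations per sample catalog (defaults 5000 / 800).
#' @param layout layout for segment plants (default [defaultScarLayout()]).
#' @param seed RNG seed.
#' @return list with `samples` (data.frame of per-sample h and true
#'   exposures), `sbsCatalogs`, `idCatalogs` (lists of catalogs),
#'   `segmentSets` (list of segment data.frames), and `truthScars`
#'   (data.frame of planted counts).
#' @export
simHrdCohort <- function(nSamples = 29, nSnv = 5000, nIndel = 800,
                         layout = defaultScarLayout(), seed = 1) {
    set.seed(seed)
    sbs <- bundledSignatures("SBS96")
    id <- bundledSignatures("ID83")
    ids <- sprintf("S%02d", seq_len(nSamples))
    h <- runif(nSamples)
    sampleSeeds <- sample.int(1e6, nSamples * 2L)
    sbsCatalogs <- idCatalogs <- segmentSets <- vector("list", nSamples)
    truth <- vector("list", nSamples)
    sampleRows <- vector("list", nSamples)
    for (i in seq_len(nSamples)) {
        sbsW <- c(SBS3 = 0.05 + 0.60 * h[i])
        rest <- 1 - sbsW[["SBS3"]]
        sbsW <- c(sbsW, SBS1 = 0.40 * rest, SBS2 = 0.20 * rest,
                  SBS13 = 0.20 * rest, SBS18 = 0.20 * rest)
        idW <- c(ID6 = 0.05 + 0.45 * h[i], ID8 = 0.03 + 0.25 * h[i])
        restI <- 1 - sum(idW)
        idW <- c(idW, ID1 = 0.40 * restI, ID2 = 0.35 * restI,
                 ID4 = 0.25 * restI)
        sbsCatalogs[[i]] <- simCatalog(sbs, sbsW, nSnv, ids[i])
        idCatalogs[[i]] <- simCatalog(id, idW, nIndel, ids[i])
        plant <- c(loh = round(5 + 25 * h[i]), lst = round(3 + 20 * h[i]),
                   ntai = round(2 + 14 * h[i]))
        sim <- simSegments(layout, plant[["loh"]], plant[["lst"]],
                           plant[["ntai"]], sampleId = ids[i],
                           seed = sampleSeeds[i])
        segmentSets[[i]] <- sim$segments
        truth[[i]] <- data.frame(sample_id = ids[i], t(plant))
        sampleRows[[i]] <- data.frame(sample_id = ids[i], h = h[i],
                                      true_SBS3 = sbsW[["SBS3"]],
                                      true_ID6 = idW[["ID6"]],
                                      true_ID8 = idW[["ID8"]])
    }
    list(samples = do.call(rbind, sampleRows),
         sbsCatalogs = sbsCatalogs, idCatalogs = idCatalogs,
         segmentSets = segmentSets, truthScars = do.call(rbind, truth))
}
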