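## Synthetic-data generators: genomes with controlled repeat content,
## per-sample mutation sets drawn from known signature mixtures, and
## allele-specific copy-number profiles with planted scar events. Every
## generator is deterministic under its `seed` argument, and the ground
## truth (true exposures, per-variant channels, planted scar counts) is
## returned alongside the data so downstream stages can be checked exactly.
##
## Exposure ground truth is defined at the channel-sampling level: channels
## are drawn i.i.d. from the mixture distribution, then genomic loci
## realizing each channel are found. Recovery error of the EM refit is
## therefore attributable to multinomial sampling noise plus the optimizer,
## never to placement artifacts.

#' @importFrom Biostrings DNAStringSet writeXStringSet readDNAStringSet
NULL

#' Simulate a genome and its layout
#'
#' Generates random chromosome sequences at a target GC content. So that
#' every ID83 channel is realizable, short tandem-repeat cassettes (unit
#' lengths 2-5, 2-7 copies, random units) are embedded at regular spacing;
#' homopolymers of all needed lengths arise naturally in random sequence.
#' Centromeres are placed at 45-50% of each chromosome.
#'
#' @param nChrom number of chromosomes (default 2).
#' @param chromLength chromosome length in bp (default 1.5e6; recycled).
#' @param gc target GC fraction (default 0.41, human-like).
#' @param cassetteSpacing distance between repeat cassettes in bp
#'   (default 2000).
#' @param seed RNG seed.
#' @return list with `genome` (a named `DNAStringSet`) and `layout`
#'   (a [GenomeLayout-class]).
#' @export
simGenome <- function(nChrom = 2, chromLength = 1.5e6, gc = 0.41,
                      cassetteSpacing = 2000, seed = 1) {
    if (any(chromLength < 1000)) stop("chromosome lengths must be >= 1 kb")
    set.seed(seed)
    chromLength <- rep(chromLength, length.out = nChrom)
    bases <- c("A", "C", "G", "T")
    probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    cassettes <- expand.grid(L = 2:5, copies = 2:7)
    seqs <- character(nChrom)
    for (ci in seq_len(nChrom)) {
        n <- chromLength[ci]
        chars <- sample(bases, n, replace = TRUE, prob = probs)
        ## overwrite windows with tandem-repeat cassettes, cycling combos
        starts <- seq(500, n - 60, by = cassetteSpacing)
        for (k in seq_along(starts)) {
            cs <- cassettes[((k - 1) %% nrow(cassettes)) + 1L, ]
            unit <- sample(bases, cs$L, replace = TRUE, prob = probs)
            block <- rep(unit, cs$copies)
            chars[starts[k]:(starts[k] + length(block) - 1L)] <- block
        }
        seqs[ci] <- paste(chars, collapse = "")
    }
    names(seqs) <- paste0("chr", seq_len(nChrom))
    cenStart <- floor(chromLength * 0.45)
    cenEnd <- floor(chromLength * 0.50)
    list(genome = DNAStringSet(seqs),
         layout = genomeLayout(names(seqs), chromLength, cenStart, cenEnd))
}

## ---- per-chromosome search index for channel-directed placement --------

.buildChromIndex <- function(seqStr) {
    chars <- strsplit(seqStr, "")[[1]]
    n <- length(chars)
    idx <- list(chars = chars, n = n)
    ## homopolymer runs
    r <- rle(chars)
    idx$hom <- data.frame(start = cumsum(c(1L, r$lengths[-length(r$lengths)])),
                          len = r$lengths, base = r$values,
                          stringsAsFactors = FALSE)
    ## lag-L equality vectors and their maximal TRUE runs
    idx$eqRuns <- list()
    for (L in 2:6) {
        eq <- chars[seq_len(n - L)] == chars[(L + 1L):n]
        rr <- rle(eq)
        st <- cumsum(c(1L, rr$lengths[-length(rr$lengths)]))
        keep <- rr$values
        idx$eqRuns[[as.character(L)]] <-
            data.frame(start = st[keep], len = rr$lengths[keep])
    }
    ## pyrimidine-centric trinucleotide context of every interior position
    f <- chars[seq_len(n - 2L)]
    c0 <- chars[2:(n - 1L)]
    t0 <- chars[3:n]
    pur <- c0 %in% c("A", "G")
    tri <- character(n - 2L)
    tri[!pur] <- paste0(f[!pur], c0[!pur], t0[!pur])
    tri[pur] <- paste0(.COMPLEMENT[t0[pur]], .COMPLEMENT[c0[pur]],
                       .COMPLEMENT[f[pur]])
    idx$triPools <- split(2:(n - 1L), tri)
    idx
}

.parseIdChannel <- function(channel) {
    p <- strsplit(channel, ":", fixed = TRUE)[[1]]
    list(L = as.integer(p[1]), type = p[2], sub = p[3],
         count = as.integer(p[4]))
}

## Find a genomic site realizing an ID83 channel; `usedEnv$used[[chrom]]` is
## a logical mask of blocked positions. Returns list(chrom,pos,ref,alt) or
## NULL when the channel cannot be placed.
.findIndelSite <- function(channel, genomeStr, indexes, usedEnv,
                           maxTries = 400L) {
    spec <- .parseIdChannel(channel)
    chroms <- sample(names(indexes))
    if (is.null(usedEnv$cache)) usedEnv$cache <- list()
    ## random-position channels are re-drawn fresh; structural candidates
    ## (homopolymer/repeat/microhomology anchored) are enumerated once per
    ## (chromosome, channel) and cached
    randomStyle <- (spec$type == "Ins" && spec$count == 0L) ||
        (spec$type == "Del" && spec$L >= 2L && spec$sub == "R" &&
         spec$count == 0L)
    for (chrom in chroms) {
        idx <- indexes[[chrom]]
        used <- usedEnv$used[[chrom]]
        ckey <- paste0(chrom, "|", channel)
        if (!randomStyle && !is.null(usedEnv$cache[[ckey]])) {
            cands <- usedEnv$cache[[ckey]]
        } else {
            cands <- .indelCandidates(spec, idx)
            if (!randomStyle) usedEnv$cache[[ckey]] <-
                if (is.null(cands)) data.frame() else cands
        }
        if (is.null(cands) || !nrow(cands)) next
        cands <- cands[sample.int(nrow(cands), min(nrow(cands), maxTries)), ,
                       drop = FALSE]
        for (i in seq_len(nrow(cands))) {
            pos <- cands$pos[i]
            ref <- cands$ref[i]
            alt <- cands$alt[i]
            L <- max(nchar(ref), nchar(alt))
            win <- max(1L, pos - 2L * L - 6L):min(idx$n, pos + 3L * L + 6L)
            if (any(used[win])) next
            ok <- tryCatch(
                classifyIndel(chrom, pos, ref, alt, genomeStr) == channel,
                error = function(e) FALSE)
            if (!ok) next
            usedEnv$used[[chrom]][win] <- TRUE
            return(list(chrom = chrom, pos = pos, ref = ref, alt = alt))
        }
    }
    NULL
}

## Enumerate candidate (pos, ref, alt) for an ID83 channel on one chromosome
.indelCandidates <- function(spec, idx) {
    chars <- idx$chars
    n <- idx$n
    seqAt <- function(a, b) paste(chars[a:b], collapse = "")
    if (spec$L == 1L && spec$type == "Del") {
        wantLen <- spec$count + 1L
        h <- idx$hom
        sel <- h$base %in% c(spec$sub, .COMPLEMENT[[spec$sub]]) &
            (if (spec$count < 5L) h$len == wantLen else h$len >= 6L) &
            h$start >= 3L & (h$start + h$len) <= n - 2L
        if (!any(sel)) return(NULL)
        h <- h[sel, , drop = FALSE]
        return(data.frame(pos = h$start, ref = h$base, alt = "-",
                          stringsAsFactors = FALSE))
    }
    if (spec$L == 1L && spec$type == "Ins") {
        targets <- c(spec$sub, .COMPLEMENT[[spec$sub]])
        if (spec$count == 0L) {
            p <- sample.int(n - 3L, 300L, replace = TRUE) + 1L
            x <- sample(targets, length(p), replace = TRUE)
            keep <- chars[p] != x & chars[p + 1L] != x
            if (!any(keep)) return(NULL)
            return(data.frame(pos = p[keep], ref = "-", alt = x[keep],
                              stringsAsFactors = FALSE))
        }
        h <- idx$hom
        sel <- h$base %in% targets &
            (if (spec$count < 5L) h$len == spec$count else h$len >= 5L) &
            h$start >= 3L & (h$start + h$len) <= n - 2L
        if (!any(sel)) return(NULL)
        h <- h[sel, , drop = FALSE]
        return(data.frame(pos = h$start - 1L, ref = "-", alt = h$base,
                          stringsAsFactors = FALSE))
    }
    L <- spec$L           # 2..5; label 5 realized with unit length 5
    if (spec$type == "Ins") {
        if (spec$count == 0L) {
            p <- sample.int(n - 2L * L - 8L, 200L, replace = TRUE) + 4L
            alt <- vapply(seq_along(p), function(i)
                paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                      collapse = ""), character(1))
            return(data.frame(pos = p, ref = "-", alt = alt,
                              stringsAsFactors = FALSE))
        }
        er <- idx$eqRuns[[as.character(L)]]
        copies <- floor(er$len / L) + 1L
        sel <- (if (spec$count < 5L) copies == spec$count
                else copies >= 5L) &
            er$start >= L + 2L & (er$start + er$len + L) <= n - 2L
        if (!any(sel)) return(NULL)
        er <- er[sel, , drop = FALSE]
        if (nrow(er) > 1000L)
            er <- er[sample.int(nrow(er), 1000L), , drop = FALSE]
        return(data.frame(pos = er$start - 1L,
                          ref = "-",
                          alt = vapply(er$start, function(a)
                              seqAt(a, a + L - 1L), character(1)),
                          stringsAsFactors = FALSE))
    }
    ## deletions of length >= 2
    if (spec$sub == "R" && spec$count >= 1L) {
        er <- idx$eqRuns[[as.character(L)]]
        copies <- floor(er$len / L) + 1L
        sel <- (if (spec$count < 5L) copies == spec$count + 1L
                else copies >= 6L) &
            er$start >= L + 2L & (er$start + er$len + L) <= n - 2L
        if (!any(sel)) return(NULL)
        er <- er[sel, , drop = FALSE]
        if (nrow(er) > 1000L)
            er <- er[sample.int(nrow(er), 1000L), , drop = FALSE]
        return(data.frame(pos = er$start,
                          ref = vapply(er$start, function(a)
                              seqAt(a, a + L - 1L), character(1)),
                          alt = "-", stringsAsFactors = FALSE))
    }
    if (spec$sub == "R" && spec$count == 0L) {
        p <- sample.int(n - 2L * L - 8L, 300L, replace = TRUE) + 4L
        return(data.frame(pos = p,
                          ref = vapply(p, function(a)
                              seqAt(a, a + L - 1L), character(1)),
                          alt = "-", stringsAsFactors = FALSE))
    }
    ## microhomology deletion: need exact 3' microhomology of length `count`
    m <- spec$count
    delLen <- if (m >= L) m + 1L else L   # label length 5 means 5+, so
    er <- idx$eqRuns[[as.character(delLen)]]  # MH 5 uses a 6 bp deletion
    sel <- er$len == m &
        er$start >= delLen + 2L & (er$start + er$len + delLen) <= n - 2L
    if (!any(sel)) return(NULL)
    er <- er[sel, , drop = FALSE]
    if (nrow(er) > 1000L)
        er <- er[sample.int(nrow(er), 1000L), , drop = FALSE]
    data.frame(pos = er$start,
               ref = vapply(er$start, function(a)
                   seqAt(a, a + delLen - 1L), character(1)),
               alt = "-", stringsAsFactors = FALSE)
}

## default classification distributions (loosely: genome-wide somatic calls
## are dominated by intronic/non-coding events)
.SNP_CLASS_PROBS <- c(Intron = 0.40, Missense_Mutation = 0.25, Silent = 0.12,
                      "3'UTR" = 0.06, "5'UTR" = 0.04, RNA = 0.04,
                      Splice_Region = 0.03, Splice_Site = 0.01,
                      Nonsense_Mutation = 0.035, Nonstop_Mutation = 0.005,
                      Translation_Start_Site = 0.01)
.INDEL_REGION_PROBS <- c(Intron = 0.45, UTR = 0.10, coding = 0.45)

.GENE_POOL <- c("TP53", "PIK3CA", "KMT2C", "MUC4", "MUC12", "MUC17", "TTN",
                "CHEK2", "ATM", "BRCA1", "BRCA2", "PALB2", "GATA3", "MAP3K1",
                "NBN", "RAD51C", "BRIP1", "CDH1", "FGFR4", "AR", "NTRK1",
                sprintf("GENE%03d", 1:40))

#' Simulate one sample's somatic mutation set from signature mixtures
#'
#' Draws SBS96 channels i.i.d. from `sbsExposure` over `sbsSigs` (and ID83
#' channels from `idExposure` over `idSigs`), then finds genomic loci
#' realizing each sampled channel: SNVs by trinucleotide-context lookup,
#' indels by homopolymer/tandem-repeat/microhomology search with
#' classification verification. Variant classifications, gene symbols and
#' read counts are attached so the burden and filter stages are exercised.
#'
#' @param genome named `DNAStringSet` or named character vector from
#'   [simGenome()].
#' @param sbsSigs,idSigs [SignatureSet-class] objects (either may be
#'   `NULL` when the corresponding count is 0).
#' @param sbsExposure,idExposure named true mixture weights over the
#'   signatures (sum to 1).
#' @param nSnv,nIndel number of SNVs / indels to place.
#' @param sampleId sample identifier.
#' @param seed RNG seed.
#' @param snpClassProbs named probability vector over SNP classification
#'   labels.
#' @param indelRegionProbs probabilities for `Intron` / `UTR` / `coding`
#'   indel context; coding indels become frame-shift or in-frame according
#'   to length mod 3.
#' @param meanDepth mean simulated sequencing depth (default 60).
#' @return list with `maf` (variant data.frame) and `truth` (data.frame of
#'   each variant's channel plus attributes `sbsExposure`, `idExposure`).
#' @export
simMutations <- function(genome, sbsSigs = NULL, idSigs = NULL,
                         sbsExposure = NULL, idExposure = NULL,
                         nSnv = 0, nIndel = 0, sampleId = "S1", seed = 1,
                         snpClassProbs = .SNP_CLASS_PROBS,
                         indelRegionProbs = .INDEL_REGION_PROBS,
                         meanDepth = 60) {
    set.seed(seed)
    gs <- .genomeStrings(genome)
    indexes <- lapply(gs, .buildChromIndex)
    usedEnv <- new.env()
    usedEnv$used <- lapply(indexes, function(ix) logical(ix$n))

    sampleChannels <- function(sigs, exposure, n) {
        S <- signatureProbs(sigs)
        if (is.null(names(exposure)) ||
            !setequal(names(exposure), rownames(S)))
            stop("exposure must be named by the signature set's signatures")
        exposure <- exposure[rownames(S)]
        p <- as.numeric(exposure %*% S)
        sample(colnames(S), n, replace = TRUE, prob = p)
    }

    nTot <- nIndel + nSnv
    vChrom <- vPos <- vRef <- vAlt <- vClass <- vType <- vCh <-
        character(nTot)
    vPos <- numeric(nTot)
    k <- 0L

    if (nIndel > 0) {
        idCh <- sampleChannels(idSigs, idExposure, nIndel)
        regions <- sample(names(indelRegionProbs), nIndel, replace = TRUE,
                          prob = indelRegionProbs)
        for (j in seq_len(nIndel)) {
            ch <- idCh[j]
            site <- .findIndelSite(ch, gs, indexes, usedEnv)
            if (is.null(site))
                stop("context exhaustion: no unused locus realizes ID83 ",
                     "channel ", ch, "; simulate a longer genome")
            L <- max(nchar(site$ref), nchar(site$alt))
            type <- if (site$alt == "-") "DEL" else "INS"
            klass <- switch(regions[j],
                Intron = "Intron",
                UTR = "3'UTR",
                coding = if (L %% 3L == 0L)
                    paste0("In_Frame_", if (type == "DEL") "Del" else "Ins")
                else
                    paste0("Frame_Shift_", if (type == "DEL") "Del" else "Ins"))
            k <- k + 1L
            vChrom[k] <- site$chrom; vPos[k] <- site$pos
            vRef[k] <- site$ref; vAlt[k] <- site$alt
            vClass[k] <- klass; vType[k] <- type; vCh[k] <- ch
        }
    }

    if (nSnv > 0) {
        sbsCh <- sampleChannels(sbsSigs, sbsExposure, nSnv)
        snvClasses <- sample(names(snpClassProbs), nSnv, replace = TRUE,
                             prob = snpClassProbs)
        perChannel <- table(sbsCh)
        chromNames <- names(indexes)
        ## sample loci channel-wise from the pooled free positions
        for (ch in names(perChannel)) {
            nc <- perChannel[[ch]]
            key <- paste0(substr(ch, 1L, 1L), substr(ch, 3L, 3L),
                          substr(ch, 7L, 7L))
            alt <- substr(ch, 5L, 5L)
            poolChrom <- integer(0)
            poolPos <- integer(0)
            for (ci in seq_along(chromNames)) {
                pool <- indexes[[ci]]$triPools[[key]]
                if (is.null(pool)) next
                free <- pool[!usedEnv$used[[ci]][pool]]
                poolChrom <- c(poolChrom, rep(ci, length(free)))
                poolPos <- c(poolPos, free)
            }
            if (length(poolPos) < nc)
                stop("context exhaustion: only ", length(poolPos),
                     " unused loci have context ", key, " but ", nc,
                     " are needed; simulate a longer genome")
            pick <- if (length(poolPos) == 1L) 1L
                    else sample.int(length(poolPos), nc)
            for (p in pick) {
                ci <- poolChrom[p]
                pos <- poolPos[p]
                refBase <- indexes[[ci]]$chars[pos]
                altP <- if (refBase %in% c("A", "G")) .COMPLEMENT[[alt]]
                        else alt
                usedEnv$used[[ci]][pos] <- TRUE
                k <- k + 1L
                vChrom[k] <- chromNames[ci]; vPos[k] <- pos
                vRef[k] <- refBase; vAlt[k] <- altP
                vType[k] <- "SNP"; vCh[k] <- ch
            }
        }
        ## classifications are i.i.d., so assign them to the SNV block as
        ## drawn (channel grouping above does not bias them)
        vClass[(k - nSnv + 1L):k] <- snvClasses
    }

    maf <- data.frame(Hugo_Symbol = sample(.GENE_POOL, k, replace = TRUE),
                      Chromosome = vChrom[seq_len(k)],
                      Start_Position = vPos[seq_len(k)],
                      Reference_Allele = vRef[seq_len(k)],
                      Tumor_Seq_Allele2 = vAlt[seq_len(k)],
                      Variant_Classification = vClass[seq_len(k)],
                      Variant_Type = vType[seq_len(k)],
                      Tumor_Sample_Barcode = rep(sampleId, k),
                      stringsAsFactors = FALSE)
    truth <- as.list(vCh[seq_len(k)])
    if (nrow(maf)) {
        depth <- pmax(8L, as.integer(rnorm(nrow(maf), meanDepth,
                                           meanDepth / 5)))
        vaf <- runif(nrow(maf), 0.15, 0.6)
        maf$t_depth <- depth
        maf$t_alt_count <- pmin(depth,
                                vapply(seq_len(nrow(maf)), function(i)
                                    max(1L, rbinom(1L, depth[i], vaf[i])),
                                    integer(1)))
        rownames(maf) <- NULL
    }
    truthDf <- data.frame(channel = unlist(truth),
                          stringsAsFactors = FALSE)
    attr(truthDf, "sbsExposure") <- sbsExposure
    attr(truthDf, "idExposure") <- idExposure
    list(maf = maf, truth = truthDf)
}

#' Simulate a catalog directly by multinomial channel sampling
#'
#' Draws `n` mutations from the channel distribution implied by a signature
#' mixture — the channel-level ground-truth generator used when genomic
#' placement is irrelevant (e.g. large EM-recovery experiments).
#'
#' @param sigs a [SignatureSet-class].
#' @param exposure named true weights over the signatures (sum to 1).
#' @param n number of mutations.
#' @param sampleId sample identifier.
#' @param seed RNG seed (set it yourself beforehand and pass `NULL` to
#'   draw within an existing stream).
#' @return a [MutationCatalog-class].
#' @export
simCatalog <- function(sigs, exposure, n, sampleId = "S1", seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    S <- signatureProbs(sigs)
    exposure <- exposure[rownames(S)]
    p <- as.numeric(exposure %*% S)
    counts <- rmultinom(1L, n, p)[, 1]
    names(counts) <- colnames(S)
    catalogFromCounts(counts, scheme(sigs), sampleId)
}
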