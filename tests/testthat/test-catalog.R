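test_that("channel universes have the canonical sizes and members", {
    expect_length(sbsChannels(), 96)
    expect_length(idChannels(), 83)
    expect_true("A[C>T]G" %in% sbsChannels())
    expect_true(all(c("1:Del:T:5", "5:Del:M:5", "2:Ins:R:0") %in%
                    idChannels()))
    expect_false(anyDuplicated(idChannels()) > 0)
})

test_that("SBS context is pyrimidine-centric and strand-symmetric", {
    g <- c(chr1 = "GACAGTGCAT")
    expect_equal(sbsContext("chr1", 3, "C", "T", g), "A[C>T]A")
    ## G>A at a TGC context maps through reverse complement
    expect_equal(sbsContext("chr1", 7, "G", "A", g), "G[C>T]A")
    ## the same physical event described on either strand is one channel
    gFwd <- c(chr1 = "TTACGTT")
    gRev <- c(chr1 = as.character(
        Biostrings::reverseComplement(Biostrings::DNAString("TTACGTT"))))
    expect_equal(sbsContext("chr1", 4, "C", "A", gFwd),
                 sbsContext("chr1", 4, "G", "T", gRev))
    expect_error(sbsContext("chr1", 1, "G", "A", g), "edge")
    expect_error(sbsContext("chr1", 3, "G", "A", g), "mismatch")
})

test_that("indel classification matches hand-derived channels", {
    g <- c(chr1 = "GACAGTGCATTTTTACTCTCTGAA")
    ## one T deleted from the TTTTT run: homopolymer of five
    expect_equal(classifyIndel("chr1", 11, "T", "-", g), "1:Del:T:4")
    ## CT deleted from CTCTCT (three copies): 2 bp deletion at repeats
    expect_equal(classifyIndel("chr1", 16, "CT", "-", g), "2:Del:R:2")
    ## equivalent right-shifted description left-aligns to the same channel
    expect_equal(classifyIndel("chr1", 18, "CT", "-", g), "2:Del:R:2")
    ## 5 bp deletion, no tandem copy, 3' flank starts GC -> microhomology 2
    g2 <- c(chr1 = "AAAACCGGGCATTGCTTAGGACCA")
    expect_equal(classifyIndel("chr1", 9, "GCATT", "-", g2), "5:Del:M:2")
    ## T inserted next to four Ts
    expect_equal(classifyIndel("chr1", 10, "-", "T", g), "1:Ins:T:5")
    expect_error(classifyIndel("chr1", 3, "GG", "-", g), "not found")
})

test_that("catalogs count every record or report it unclassifiable", {
    g <- simGenome(nChrom = 2, chromLength = 2e5, seed = 5)
    empty <- buildCatalog(classTable(character(0)), g$genome, "SBS96",
                          sampleId = "E")
    expect_equal(sum(channelCounts(empty)), 0L)

    sbs <- bundledSignatures("SBS96")
    id <- bundledSignatures("ID83")
    w <- c(SBS1 = .2, SBS2 = .2, SBS3 = .2, SBS13 = .2, SBS18 = .2)
    wi <- c(ID1 = .25, ID2 = .25, ID4 = .3, ID6 = .1, ID8 = .1)
    sim <- simMutations(g$genome, sbs, id, w, wi, nSnv = 120, nIndel = 40,
                        seed = 6)
    catS <- buildCatalog(sim$maf, g$genome, "SBS96")
    catI <- buildCatalog(sim$maf, g$genome, "ID83")
    expect_equal(sum(channelCounts(catS)) + nUnclassified(catS), 120L)
    expect_equal(sum(channelCounts(catI)) + nUnclassified(catI), 40L)

    ## a reference-mismatching record is reported, not dropped or fatal
    bad <- sim$maf[sim$maf$Variant_Type == "SNP", ][1:3, ]
    bad$Reference_Allele <- "N"
    catBad <- buildCatalog(bad, g$genome, "SBS96", sampleId = "B")
    expect_equal(nUnclassified(catBad), 3L)
})

test_that("catalogs are additive over disjoint record sets", {
    g <- simGenome(nChrom = 2, chromLength = 2e5, seed = 7)
    sbs <- bundledSignatures("SBS96")
    w <- c(SBS1 = .2, SBS2 = .2, SBS3 = .2, SBS13 = .2, SBS18 = .2)
    sim <- simMutations(g$genome, sbs, NULL, w, NULL, nSnv = 100, seed = 8)
    a <- sim$maf[1:40, ]
    b <- sim$maf[41:100, ]
    catAll <- buildCatalog(sim$maf, g$genome, "SBS96", sampleId = "x")
    catA <- buildCatalog(a, g$genome, "SBS96", sampleId = "x")
    catB <- buildCatalog(b, g$genome, "SBS96", sampleId = "x")
    expect_equal(channelCounts(catAll),
                 channelCounts(catA) + channelCounts(catB))
})

test_that("planted events agree with the brute-force oracle", {
    g <- simGenome(nChrom = 2, chromLength = 8e5, seed = 11)
    gs <- stats::setNames(as.character(g$genome), names(g$genome))
    sbs <- bundledSignatures("SBS96")
    id <- bundledSignatures("ID83")
    w <- c(SBS1 = .2, SBS2 = .2, SBS3 = .2, SBS13 = .2, SBS18 = .2)
    wi <- c(ID1 = .2, ID2 = .2, ID4 = .2, ID6 = .2, ID8 = .2)
    sim <- simMutations(g$genome, sbs, id, w, wi, nSnv = 250, nIndel = 250,
                        seed = 12)
    for (i in seq_len(nrow(sim$maf))) {
        r <- sim$maf[i, ]
        oracle <- if (r$Variant_Type == "SNP")
            oracleSbs(r$Chromosome, r$Start_Position, r$Reference_Allele,
                      r$Tumor_Seq_Allele2, gs)
        else
            oracleIndel(r$Chromosome, r$Start_Position, r$Reference_Allele,
                        r$Tumor_Seq_Allele2, gs)
        expect_equal(classifyVariant(r, g$genome), oracle)
        expect_equal(oracle, sim$truth$channel[i])
    }
})

test_that("catalog construction from named counts round-trips", {
    counts <- c("A[C>T]G" = 5, "T[C>G]T" = 2)
    cat0 <- catalogFromCounts(counts, "SBS96", "s")
    expect_equal(sum(channelCounts(cat0)), 7L)
    expect_equal(channelCounts(cat0)[["A[C>T]G"]], 5L)
    expect_error(catalogFromCounts(c(bogus = 1), "SBS96"), "unknown")
})
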