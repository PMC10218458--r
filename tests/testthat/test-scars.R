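segRow <- function(chrom, start, end, major, minor, sample = "S1") {
    data.frame(chrom = chrom, start = start, end = end, major_cn = major,
               minor_cn = minor, sample_id = sample,
               stringsAsFactors = FALSE)
}

test_that("preprocessing merges identical neighbors and smooths slivers", {
    segs <- rbind(segRow("chr1", 1, 10e6, 2, 1),
                  segRow("chr1", 10e6 + 1, 30e6, 2, 1))
    pre <- preprocessSegments(segs)
    expect_equal(nrow(pre), 1L)
    expect_equal(pre$end, 30e6)

    ## a 2 Mb sliver of a different state vanishes into matching neighbors
    segs2 <- rbind(segRow("chr1", 1, 20e6, 2, 1),
                   segRow("chr1", 20e6 + 1, 22e6, 2, 0),
                   segRow("chr1", 22e6 + 1, 40e6, 2, 1))
    pre2 <- preprocessSegments(segs2, minSegBp = 3e6)
    expect_equal(nrow(pre2), 1L)
    expect_equal(c(pre2$start, pre2$end, pre2$major_cn, pre2$minor_cn),
                 c(1, 40e6, 2, 1))

    expect_equal(nrow(preprocessSegments(segs2[0, ])), 0L)
    expect_error(preprocessSegments(rbind(segRow("chr1", 1, 5e6, 2, 1),
                                          segRow("chr1", 4e6, 9e6, 2, 1))),
                 "overlap")
})

test_that("LOH score follows its length and whole-chromosome rules", {
    lay <- genomeLayout("chr1", 100e6, 45e6, 50e6)
    whole <- segRow("chr1", 1, 100e6, 2, 0)
    expect_equal(lohScore(whole, lay), 0L)
    interior <- rbind(segRow("chr1", 1, 30e6, 2, 1),
                      segRow("chr1", 30e6 + 1, 50e6, 2, 0),
                      segRow("chr1", 50e6 + 1, 100e6, 2, 1))
    expect_equal(lohScore(interior, lay), 1L)
    short <- rbind(segRow("chr1", 1, 30e6, 2, 1),
                   segRow("chr1", 30e6 + 1, 44e6, 2, 0),
                   segRow("chr1", 44e6 + 1, 100e6, 2, 1))
    expect_equal(lohScore(short, lay), 0L)   # 14 Mb, needs > 15 Mb
})

test_that("ntAI requires telomere contact without crossing the centromere", {
    lay <- genomeLayout("chr1", 100e6, 50e6, 55e6)
    expect_equal(ntaiScore(segRow("chr1", 1, 30e6, 2, 1), lay), 1L)
    ## spans the centromere to the q telomere
    expect_equal(ntaiScore(segRow("chr1", 40e6, 100e6, 2, 1), lay), 0L)
    ## balanced telomeric segment
    expect_equal(ntaiScore(segRow("chr1", 1, 30e6, 2, 2), lay), 0L)
    ## interior AI segment
    expect_equal(ntaiScore(segRow("chr1", 10e6, 30e6, 2, 1), lay), 0L)
})

test_that("LST counts long-flank breakpoints per arm after smoothing", {
    lay <- genomeLayout("chr1", 100e6, 45e6, 50e6)
    pair <- rbind(segRow("chr1", 1, 12e6, 2, 1),
                  segRow("chr1", 12e6 + 1, 27e6, 3, 1))
    expect_equal(lstScore(pair, lay), 1L)
    ## a 2 Mb sliver between them disappears during preprocessing
    sliver <- rbind(segRow("chr1", 1, 12e6, 2, 1),
                    segRow("chr1", 12e6 + 1, 14e6, 9, 1),
                    segRow("chr1", 14e6 + 1, 29e6, 3, 1))
    expect_equal(lstScore(preprocessSegments(sliver, 3e6), lay), 1L)
    shortFlank <- rbind(segRow("chr1", 1, 8e6, 2, 1),
                        segRow("chr1", 8e6 + 1, 44e6, 3, 1))
    expect_equal(lstScore(shortFlank, lay), 0L)
})

test_that("HRD classification sums scores with an inclusive threshold", {
    s <- hrdClassify(10, 15, 20, sampleId = "a")
    expect_equal(hrdSum(s)[["a"]], 45L)
    expect_true(hrdHigh(s)[["a"]])
    expect_false(hrdHigh(hrdClassify(0, 0, 0))[[1]])
    expect_true(hrdHigh(hrdClassify(14, 14, 14))[[1]])   # exactly 42
    expect_false(hrdHigh(hrdClassify(14, 14, 13))[[1]])
    expect_error(hrdClassify(-1, 0, 0), "non-negative")
})

test_that("scores equal the brute-force oracles on random profiles", {
    lay <- testScarLayout(6)
    for (seed in 1:60) {
        segs <- simRandomSegments(lay, meanSegs = 7, seed = seed)
        pre <- preprocessSegments(segs)
        expect_equal(lohScore(pre, lay), oracleLoh(pre, lay))
        expect_equal(lstScore(pre, lay), oracleLst(pre, lay))
        expect_equal(ntaiScore(pre, lay), oracleNtai(pre, lay))
    }
})

test_that("planted scar events are recovered exactly", {
    lay <- testScarLayout(8)
    set.seed(77)
    for (i in 1:25) {
        plant <- c(loh = sample(0:10, 1), lst = sample(0:8, 1),
                   ntai = sample(0:8, 1))
        sim <- simSegments(lay, plant[["loh"]], plant[["lst"]],
                           plant[["ntai"]], seed = 1000 + i)
        sc <- scarScores(sim$segments, lay)
        expect_equal(sc@loh, plant[["loh"]])
        expect_equal(sc@lst, plant[["lst"]])
        expect_equal(sc@ntai, plant[["ntai"]])
    }
    sc0 <- scarScores(simSegments(lay, 0, 0, 0, seed = 4)$segments, lay)
    expect_equal(hrdSum(sc0)[[1]], 0L)
})

test_that("scores are invariant under splitting a segment in two", {
    lay <- testScarLayout(4)
    segs <- simSegments(lay, 3, 2, 2, seed = 31)$segments
    i <- which(segs$end - segs$start > 2e6)[1]
    mid <- floor((segs$start[i] + segs$end[i]) / 2)
    split1 <- segs[i, ]; split1$end <- mid
    split2 <- segs[i, ]; split2$start <- mid + 1
    segsSplit <- rbind(segs[-i, ], split1, split2)
    a <- scarScores(segs, lay)
    b <- scarScores(segsSplit, lay)
    expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("segment tables read from both supported dialects", {
    segs <- simSegments(testScarLayout(2), 1, 1, 1, seed = 9)$segments
    generic <- withr::local_tempfile(fileext = ".tsv")
    write.table(segs, generic, sep = "\t", quote = FALSE, row.names = FALSE)
    backG <- readSegments(generic)
    expect_equal(backG$major_cn, segs$major_cn)

    sequenza <- withr::local_tempfile(fileext = ".tsv")
    sq <- data.frame(chromosome = segs$chrom, `start.pos` = segs$start,
                     `end.pos` = segs$end, A = segs$major_cn,
                     B = segs$minor_cn, check.names = FALSE)
    write.table(sq, sequenza, sep = "\t", quote = FALSE, row.names = FALSE)
    backS <- readSegments(sequenza)
    expect_equal(backS[, c("chrom", "start", "end", "major_cn", "minor_cn")],
                 backG[, c("chrom", "start", "end", "major_cn", "minor_cn")])
})
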