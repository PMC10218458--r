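test_that("genome simulation is deterministic with the requested geometry", {
    a <- simGenome(nChrom = 2, chromLength = 1e5, seed = 1)
    b <- simGenome(nChrom = 2, chromLength = 1e5, seed = 1)
    expect_identical(as.character(a$genome), as.character(b$genome))
    expect_equal(unname(Biostrings::width(a$genome)), c(1e5, 1e5))
    expect_equal(length(a$genome), 2L)
    c2 <- simGenome(nChrom = 2, chromLength = 1e5, seed = 2)
    expect_false(identical(as.character(a$genome), as.character(c2$genome)))
    expect_error(simGenome(chromLength = 500), "1 kb")
})

test_that("genome GC content tracks the requested fraction", {
    g <- simGenome(nChrom = 1, chromLength = 4e5, gc = 0.5, seed = 3)$genome
    freq <- Biostrings::alphabetFrequency(g)[1, c("A", "C", "G", "T")]
    gc <- sum(freq[c("C", "G")]) / sum(freq)
    expect_lt(abs(gc - 0.5), 0.02)
})

test_that("mutation simulation is deterministic and truth-consistent", {
    g <- simGenome(nChrom = 2, chromLength = 2e5, seed = 4)
    sbs <- bundledSignatures("SBS96")
    id <- bundledSignatures("ID83")
    w <- c(SBS1 = .2, SBS2 = .2, SBS3 = .2, SBS13 = .2, SBS18 = .2)
    wi <- c(ID1 = .25, ID2 = .25, ID4 = .3, ID6 = .1, ID8 = .1)
    m1 <- simMutations(g$genome, sbs, id, w, wi, nSnv = 60, nIndel = 25,
                       seed = 5)
    m2 <- simMutations(g$genome, sbs, id, w, wi, nSnv = 60, nIndel = 25,
                       seed = 5)
    expect_identical(m1$maf, m2$maf)
    expect_equal(nrow(m1$maf), 85L)
    expect_silent(validateVariants(m1$maf))
    for (i in seq_len(nrow(m1$maf)))
        expect_equal(classifyVariant(m1$maf[i, ], g$genome),
                     m1$truth$channel[i])
    ## empty request -> empty, well-formed table
    m0 <- simMutations(g$genome, sbs, id, w, wi, nSnv = 0, nIndel = 0)
    expect_equal(nrow(m0$maf), 0L)
})

test_that("pipeline closure: pure-signature mutations refit to that signature", {
    g <- simGenome(nChrom = 2, chromLength = 1e6, seed = 6)
    sbs <- bundledSignatures("SBS96")
    w <- c(SBS1 = 1, SBS2 = 0, SBS3 = 0, SBS13 = 0, SBS18 = 0)
    sim <- simMutations(g$genome, sbs, NULL, w, NULL, nSnv = 3000, seed = 7)
    cat0 <- buildCatalog(sim$maf, g$genome, "SBS96")
    fit <- emRefit(cat0, sbs)
    expect_gt(exposures(fit)[["SBS1"]], 0.99)
})

test_that("segment simulation produces valid, deterministic profiles", {
    lay <- testScarLayout(6)
    set.seed(123)
    for (i in 1:20) {
        plant <- c(sample(0:6, 1), sample(0:5, 1), sample(0:5, 1))
        sim <- simSegments(lay, plant[1], plant[2], plant[3],
                           seed = 500 + i)
        s <- sim$segments
        expect_true(all(s$start <= s$end))
        expect_true(all(s$major_cn >= s$minor_cn))
        for (chr in unique(s$chrom)) {
            sc <- s[s$chrom == chr, ]
            sc <- sc[order(sc$start), ]
            expect_equal(sc$start[1], 1)
            expect_equal(sc$end[nrow(sc)],
                         lay@length[match(chr, lay@chrom)])
            if (nrow(sc) > 1)
                expect_true(all(sc$start[-1] == sc$end[-nrow(sc)] + 1))
        }
        expect_equal(unname(sim$truth), plant)
    }
    a <- simSegments(lay, 2, 2, 2, seed = 9)$segments
    b <- simSegments(lay, 2, 2, 2, seed = 9)$segments
    expect_identical(a, b)
    expect_error(simSegments(testScarLayout(1), ntai = 5), "infeasible")
})

test_that("study simulation and full pipeline run end to end", {
    studyDir <- withr::local_tempdir()
    outDir <- withr::local_tempdir()
    simStudy(file.path(studyDir, "study"), nSamples = 3, nSnv = 150,
             nIndel = 30, seed = 11)
    res <- runStudy(file.path(studyDir, "study"), outDir)
    expect_equal(nrow(res$burden), 3L)
    expect_true(all(file.exists(file.path(outDir,
        c("burden.tsv", "catalog_sbs96.tsv", "exposures_sbs96.tsv",
          "scar_scores.tsv", "cohort_summary_categorical.tsv",
          "run_log.json")))))
    ## planted scar truth is recovered by the pipeline
    truth <- read.delim(file.path(studyDir, "study", "truth_scars.tsv"))
    got <- as.data.frame(res$scores)
    m <- merge(truth, got, by = "sample_id")
    expect_equal(m$loh.x, m$loh.y)
    expect_equal(m$lst.x, m$lst.y)
    expect_equal(m$ntai.x, m$ntai.y)
    ## startup validation refuses an incomplete study directory
    expect_error(runStudy(withr::local_tempdir(), outDir), "missing input")
})
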