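test_that("signature files load, reorder and renormalize", {
    sigs <- bundledSignatures("SBS96")
    expect_s4_class(sigs, "SignatureSet")
    expect_equal(unname(rowSums(signatureProbs(sigs))), rep(1, 5),
                 tolerance = 1e-9)
    expect_equal(colnames(signatureProbs(sigs)), sbsChannels())

    ## shuffled rows load to the identical object
    path <- system.file("extdata", "signatures_sbs96_synthetic.tsv",
                        package = "scarsig")
    df <- read.delim(path, check.names = FALSE)
    shuffled <- withr::local_tempfile(fileext = ".tsv")
    set.seed(1)
    write.table(df[sample.int(nrow(df)), ], shuffled, sep = "\t",
                quote = FALSE, row.names = FALSE)
    expect_equal(signatureProbs(readSignatureSet(shuffled, "SBS96")),
                 signatureProbs(sigs))

    ## a missing channel is an error naming it
    broken <- withr::local_tempfile(fileext = ".tsv")
    write.table(df[-1, ], broken, sep = "\t", quote = FALSE,
                row.names = FALSE)
    expect_error(readSignatureSet(broken, "SBS96"), df$Type[1],
                 fixed = TRUE)
})

test_that("EM is exact at vertices and for disjoint-support mixtures", {
    sigs <- disjointSigs()
    S <- signatureProbs(sigs)
    pure <- catalogFromCounts(round(1000 * S["A", ]), "SBS96", "pure")
    f <- emRefit(pure, sigs)
    expect_equal(unname(exposures(f)[["A"]]), 1, tolerance = 1e-6)

    ## 0.7/0.3 mixture with integer channel counts (8000 * 0.7 / 8 = 700)
    mix <- catalogFromCounts(8000 * (0.7 * S["A", ] + 0.3 * S["B", ]),
                             "SBS96", "mix")
    fm <- emRefit(mix, sigs)
    expect_equal(unname(exposures(fm)), c(0.7, 0.3), tolerance = 1e-7)
})

test_that("EM recovers a sampled two-signature mixture within 0.02", {
    sigs <- bundledSignatures("SBS96")
    w <- c(SBS1 = 0.6, SBS3 = 0.4, SBS2 = 0, SBS13 = 0, SBS18 = 0)
    cat0 <- simCatalog(sigs, w, 50000, "s", seed = 99)
    f <- emRefit(cat0, sigs)
    expect_lt(abs(exposures(f)[["SBS1"]] - 0.6), 0.02)
    expect_lt(abs(exposures(f)[["SBS3"]] - 0.4), 0.02)
})

test_that("EM log-likelihood is non-decreasing and matches catalogLoglik", {
    sigs <- bundledSignatures("SBS96")
    for (seed in 1:10) {
        set.seed(seed)
        g <- rgamma(5, 1)
        w <- stats::setNames(g / sum(g), signatureNames(sigs))
        cat0 <- simCatalog(sigs, w, 5000, "s", seed = seed + 100)
        f <- emRefit(cat0, sigs, trace = TRUE)
        tr <- attr(f, "loglikTrace")
        expect_true(all(diff(tr) > -1e-8))
        expect_equal(f@loglik, catalogLoglik(cat0, sigs, exposures(f)))
    }
})

test_that("EM weights are scale-invariant and permutation-equivariant", {
    sigs <- bundledSignatures("SBS96")
    w <- c(SBS1 = .3, SBS2 = .1, SBS3 = .3, SBS13 = .2, SBS18 = .1)
    cat1 <- simCatalog(sigs, w, 3000, "s", seed = 5)
    f1 <- emRefit(cat1, sigs)
    cat10 <- catalogFromCounts(channelCounts(cat1) * 10L, "SBS96", "s")
    f10 <- emRefit(cat10, sigs)
    expect_equal(exposures(f1), exposures(f10), tolerance = 1e-6)

    perm <- c(3, 1, 5, 2, 4)
    sigsP <- signatureSet(signatureProbs(sigs)[perm, ], "SBS96")
    fP <- emRefit(cat1, sigsP)
    expect_equal(exposures(fP), exposures(f1)[signatureNames(sigsP)],
                 tolerance = 1e-9)
})

test_that("unexplainable channels and empty catalogs are errors", {
    sigs <- disjointSigs()
    orphan <- catalogFromCounts(c("A[T>C]A" = 5), "SBS96", "x")
    expect_error(emRefit(orphan, sigs), "A\\[T>C\\]A")
    empty <- catalogFromCounts(integer(0), "SBS96", "x")
    expect_error(emRefit(empty, sigs), "empty")
})

test_that("loglik has the closed forms on degenerate instances", {
    ch <- sbsChannels()
    point <- stats::setNames(rep(0, 96), ch)
    point[1] <- 1
    sigs <- signatureSet(rbind(P = point), "SBS96")
    cat1 <- catalogFromCounts(stats::setNames(50, ch[1]), "SBS96", "x")
    expect_equal(catalogLoglik(cat1, sigs, c(P = 1)), 0)

    unif <- signatureSet(rbind(U = stats::setNames(rep(1 / 96, 96), ch)),
                         "SBS96")
    catN <- catalogFromCounts(stats::setNames(c(10, 20, 3), ch[c(1, 40, 90)]),
                              "SBS96", "x")
    expect_equal(catalogLoglik(catN, unif, c(U = 1)), 33 * log(1 / 96))
})

test_that("exposure recovery holds across Dirichlet-drawn mixtures", {
    sigs <- bundledSignatures("SBS96")
    errs <- vapply(1:20, function(i) {
        set.seed(i)
        gmm <- rgamma(5, 1)
        w <- stats::setNames(gmm / sum(gmm), signatureNames(sigs))
        f <- emRefit(simCatalog(sigs, w, 20000, "s", seed = 1000 + i), sigs)
        mean(abs(exposures(f) - w[names(exposures(f))]))
    }, numeric(1))
    expect_lt(mean(errs), 0.02)
})
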