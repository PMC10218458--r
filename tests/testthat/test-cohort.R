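test_that("aggregated cohort AF follows the zero-alt imputation formula", {
    expect_equal(cohortAggregateAf(c(10, 20), c(40, 60), nCohort = 5), 0.12)
    expect_equal(cohortAggregateAf(15, 30, nCohort = 1), 0.5)
    ## all samples mutated at equal depth: reduces to a/d
    expect_equal(cohortAggregateAf(rep(7, 6), rep(35, 6), nCohort = 6),
                 7 / 35)
    expect_error(cohortAggregateAf(c(5, 5), c(10, 10), nCohort = 1),
                 "smaller")
    expect_error(cohortAggregateAf(12, 10, nCohort = 3), "exceeds")
})

test_that("per-site aggregation groups variants by key", {
    v <- rbind(classTable(rep("Missense_Mutation", 2)),
               classTable("Missense_Mutation"))
    v$Start_Position <- c(100, 100, 200)
    v$t_alt_count <- c(10, 20, 5)
    v$t_depth <- c(40, 60, 50)
    agg <- aggregateCohortAf(v, nCohort = 5)
    expect_equal(nrow(agg), 2L)
    expect_equal(agg$cohort_af[agg$Start_Position == 100], 0.12)
    expect_equal(agg$cohort_af[agg$Start_Position == 200],
                 5 / (50 + 4 * 50))
})

test_that("reference join applies the mean rule and flags absentees", {
    cohort <- data.frame(Chromosome = "chr1", Start_Position = c(1, 2, 3),
                         Reference_Allele = "C", Tumor_Seq_Allele2 = "T",
                         cohort_af = c(.2, .3, .4))
    gnomad <- data.frame(Chromosome = "chr1", Start_Position = c(1, 2),
                         Reference_Allele = "C", Tumor_Seq_Allele2 = "T",
                         af = c(0.10, 0.25))
    kg <- data.frame(Chromosome = "chr1", Start_Position = 1,
                     Reference_Allele = "C", Tumor_Seq_Allele2 = "T",
                     af = 0.20)
    j <- compareToReference(cohort, list(gnomad = gnomad, kg = kg))
    expect_equal(j$ref_af_used, c(0.15, 0.25, NA))
    expect_equal(j$in_reference, c(TRUE, TRUE, FALSE))
    expect_equal(nrow(j), 3L)   # absent variants flagged, never dropped
})

test_that("variant matching counts partition the union of the call sets", {
    mk <- function(pos) {
        v <- classTable(rep("Missense_Mutation", length(pos)))
        v$Start_Position <- pos
        v
    }
    res <- matchVariants(mk(c(1, 2, 3)), mk(c(2, 3, 4)), exonicOnly = FALSE)
    expect_equal(res[c("n_both", "n_wgs_only", "n_panel_only")],
                 list(n_both = 2L, n_wgs_only = 1L, n_panel_only = 1L))
    expect_equal(res$overlap_frac, 2 / 3)
    same <- matchVariants(mk(1:5), mk(1:5), exonicOnly = FALSE)
    expect_equal(same$overlap_frac, 1.0)

    ## intronic WGS calls are excluded before matching, splice kept
    wgs <- classTable(c("Intron", "Splice_Region", "Missense_Mutation"))
    res2 <- matchVariants(wgs, wgs, exonicOnly = TRUE)
    expect_equal(res2$n_both, 2L)
    expect_equal(res2$n_panel_only, 1L)

    ## gene-list prefilter applies to the WGS side
    wgs$Hugo_Symbol <- c("TP53", "TP53", "MUC4")
    res3 <- matchVariants(wgs, wgs, geneList = "TP53", exonicOnly = FALSE)
    expect_equal(res3$n_both + res3$n_wgs_only, 2L)
})

test_that("simulated panel pairs reproduce high germline sharing", {
    wgs <- randomVariantTable(400, seed = 55, samples = "S1")
    panel <- simPanelPair(wgs, sharing = 0.9, fpRate = 0.05, seed = 56)
    res <- matchVariants(wgs, panel, exonicOnly = FALSE)
    expect_gt(res$overlap_frac, 0.84)
})

test_that("HRD-signature correlation handles linear and degenerate input", {
    scores <- hrdClassify(c(5, 10, 20, 30), c(0, 0, 0, 0), c(0, 0, 0, 0),
                          sampleId = paste0("s", 1:4))
    expo <- data.frame(sample_id = paste0("s", 1:4),
                       SBS3 = c(5, 10, 20, 30) / 100,
                       ID6 = c(1, 1, 1, 1),
                       ID8 = c(30, 20, 10, 5) / 100)
    r <- correlateScars(scores, expo)
    expect_equal(r[["SBS3"]], 1.0)
    expect_true(is.na(r[["ID6"]]))      # constant: undefined, not zero
    expect_lt(r[["ID8"]], 0)
    expect_error(correlateScars(scores, expo[1:2, ]), "3 shared")
})

test_that("cohort summary reproduces the printed clinical percentages", {
    meta <- read.delim(system.file("extdata",
                                   "cohort_metadata_synthetic.tsv",
                                   package = "scarsig"))
    s <- summarizeCohort(meta, "cohort",
                         categorical = c("ihc_subtype", "er_status",
                                         "pr_status"),
                         numeric = "age")
    expect_equal(summaryPercent(s, "ihc_subtype", "Luminal A", "adjuvant"),
                 47)
    expect_equal(summaryPercent(s, "ihc_subtype", "Triple negative",
                                "neoadjuvant"), 43)
    expect_equal(summaryPercent(s, "er_status", "positive", "neoadjuvant"),
                 57)
    expect_equal(summaryPercent(s, "pr_status", "positive", "adjuvant"), 73)
    age <- s$numeric[s$numeric$group == "adjuvant", ]
    expect_equal(round(age$mean, 2), 58.93)
    expect_equal(round(age$sd, 2), 13.23)
    expect_equal(c(age$min, age$max), c(32, 80))
    expect_error(summarizeCohort(meta, "nope"), "unknown group")
})

test_that("summary percentages per variable sum to about 100", {
    meta <- read.delim(system.file("extdata",
                                   "cohort_metadata_synthetic.tsv",
                                   package = "scarsig"))
    s <- summarizeCohort(meta, "cohort",
                         categorical = c("ihc_subtype", "pt_stage",
                                         "pn_stage"))
    d <- s$categorical
    for (v in unique(d$variable)) {
        for (g in unique(d$group)) {
            tot <- sum(d$percent[d$variable == v & d$group == g])
            ncat <- sum(d$variable == v & d$group == g)
            expect_lt(abs(tot - 100), 0.5 * ncat + 1e-9)
        }
    }
    ## NA becomes its own category when present
    meta$pt_stage[1] <- NA
    s2 <- summarizeCohort(meta, "cohort", categorical = "pt_stage")
    expect_true("NA" %in% s2$categorical$category)
})
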