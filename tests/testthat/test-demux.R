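# a small fully assembled scheme shared by the demux tests
demuxFixture <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            sets <- fixtureSets()
            g <- buildTagGrid(sets$fw, sets$rv)
            cache <<- selectCombinations(g, sprintf("S%02d", 1:12), seed = 3)
        }
        cache
    }
})

# build a perfect merged read for one sample of the scheme
readFor <- function(sch, sampleIdx, insert) {
    a <- schemeAssignments(sch)
    paste0(fwTags(sch)[a$fw_index[sampleIdx]], sch@fwPrimer, insert,
           revComp(paste0(rvTags(sch)[a$rv_index[sampleIdx]], sch@rvPrimer)))
}

test_that("mergePairs finds the best ungapped overlap", {
    m <- mergePairs("AAAACCCC", revComp("CCCCGGGG"), minOverlap = 4)
    expect_equal(m$sequence, "AAAACCCCGGGG")
    expect_equal(m$overlap, 4L)
    r <- "ACGGATTCAGGATCC"
    m2 <- mergePairs(r, revComp(r), minOverlap = 4)
    expect_equal(m2$sequence, r)
    expect_equal(m2$overlap, nchar(r))
    m3 <- mergePairs("AAAAAAAAAA", revComp("CCCCCCCCCC"), minOverlap = 4)
    expect_true(is.na(m3$sequence))
    # N is uninformative and disagreements become N without qualities
    m4 <- mergePairs("AAAACCNC", revComp("CCCCGGGG"), minOverlap = 4)
    expect_equal(m4$sequence, "AAAACCCCGGGG")
})

test_that("length/overlap filters keep boundaries and remove below", {
    mk <- function(len, ov) S4Vectors::DataFrame(
        id = "x", sequence = strrep("A", len), overlap = ov)
    expect_equal(as.character(filterMerged(mk(299, 150))$bin), "too_short")
    expect_equal(as.character(filterMerged(mk(300, 100))$bin), "kept")
    expect_equal(as.character(filterMerged(mk(350, 99))$bin), "low_overlap")
    expect_equal(as.character(filterMerged(mk(300, 300))$bin), "kept")
})

test_that("matchTags assigns exactly and only on perfect dual tags", {
    sch <- demuxFixture()
    insert <- strrep("ACGGT", 60)
    rd <- readFor(sch, 1, insert)
    hit <- matchTags(rd, sch)
    expect_equal(as.character(hit$bin), "assigned")
    expect_equal(hit$sample_id, schemeAssignments(sch)$sample_id[1])
    expect_equal(hit$insert, insert)
    # reverse-complemented read is recovered by the orientation retry
    hitRc <- matchTags(revComp(rd), sch)
    expect_equal(hitRc$sample_id, hit$sample_id)
    expect_equal(hitRc$insert, insert)
    # any single substitution inside the forward barcode -> unassigned
    for (pos in 1:8) {
        base <- substr(rd, pos, pos)
        mut <- rd
        substr(mut, pos, pos) <- setdiff(BASES, base)[1]
        expect_equal(as.character(matchTags(mut, sch)$bin), "unassigned",
                     info = paste("pos", pos))
    }
    # valid tags forming an unused combination -> mistag bin
    u <- unusedCombinations(sch)[1, ]
    jump <- paste0(fwTags(sch)[u$fw_index], sch@fwPrimer, insert,
                   revComp(paste0(rvTags(sch)[u$rv_index], sch@rvPrimer)))
    expect_equal(as.character(matchTags(jump, sch)$bin), "mistag")
})

test_that("every read lands in exactly one bin", {
    sch <- demuxFixture()
    run <- simulateRun(sch, nReads = 120, rhoMistag = 0.08, shortFrac = 0.05,
                       seed = 19)
    res <- demuxRun(mergePairs(run$r1, run$r2), sch)
    expect_equal(sum(res$binCounts), length(run$r1))
    expect_false(anyNA(res$reads$bin))
    expect_equal(sum(res$sampleCounts), as.integer(res$binCounts[["assigned"]]))
})

test_that("read renaming follows the sample/year/ecosystem convention", {
    expect_equal(renameRead("AEG01", 2011, "G", 7), "AEG01_2011_G_7")
    expect_equal(renameRead("HEF07", 2017, "F", 1), "HEF07_2017_F_1")
    ids <- renameRead("AEG01", 2011, "G", 1:50)
    expect_equal(anyDuplicated(ids), 0)
    expect_error(renameRead("AEG01", 2011, "X", 1), "ecosystem")
})

test_that("low-yield samples are dropped at the strict 10,000-read boundary", {
    counts <- c(A = 9999, B = 10000, C = 50000)
    expect_equal(names(dropLowYield(counts)), c("B", "C"))
    expect_equal(dropLowYield(c(A = 10000, B = 20000)),
                 c(A = 10000, B = 20000))
    # 600 samples with 9 forced below threshold -> 591 retained
    set.seed(23)
    yields <- stats::setNames(round(stats::rnorm(600, 29817, 5000)),
                              sprintf("P%03d", 1:600))
    yields[yields < 10000] <- 12000
    low <- sample(600, 9)
    yields[low] <- sample(1000:9999, 9)
    expect_equal(length(dropLowYield(yields)), 591)
})
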