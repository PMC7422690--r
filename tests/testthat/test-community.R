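traitPath <- function() system.file("extdata", "protist_traits.tsv",
                                    package = "ampliTags")

test_that("rare-OTU filter uses a strict fraction-of-total cutoff", {
    m <- matrix(c(2L, 1L, 19997L), ncol = 1,
                dimnames = list(c("two", "one", "big"), "S1"))
    tab <- OtuTable(m)               # grand total 20,000; 0.01% = 2 reads
    kept <- rownames(rareFilter(tab))
    expect_true("two" %in% kept)     # exactly at threshold: kept
    expect_false("one" %in% kept)    # 0.005%: removed
    expect_equal(rownames(rareFilter(tab, 0)), rownames(tab))
    big <- OtuTable(matrix(100L, 5, 2))
    expect_equal(nrow(rareFilter(big)), 5)
})

test_that("best-hit parsing keeps minimal e-value with identity tie-break", {
    hits <- data.frame(
        qseqid = c("q1", "q1", "q2", "q3", "q3"),
        sseqid = c("s1", "s2", "s3", "s4", "s5"),
        pident = c(90, 99, 95, 97, 99),
        evalue = c(1e-60, 1e-55, 1e-40, 1e-80, 1e-80))
    best <- parseBestHits(hits)
    expect_equal(best$sseqid[best$qseqid == "q1"], "s1")   # min e-value
    expect_false(best$assigned[best$qseqid == "q2"])       # fails 1e-50 gate
    expect_equal(best$sseqid[best$qseqid == "q3"], "s5")   # identity tie-break
    # file input with a malformed row
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c(paste(c("q1", "s1", 98, 300, 2, 0, 1, 300, 1, 300,
                         "1e-120", 500), collapse = "\t"),
                 "broken\trow"), path)
    expect_warning(best2 <- parseBestHits(path), "malformed")
    expect_equal(nrow(best2), 1)
    expect_true(best2$assigned)
})

test_that("non-target OTUs are removed by phylum", {
    tab <- OtuTable(matrix(1:6, 3, 2),
                    taxonomy = data.frame(phylum = c("Cercozoa", "Fungi",
                                                     "Endomyxa")))
    out <- removeNonTarget(tab)
    expect_equal(nrow(out), 2)
    expect_equal(S4Vectors::metadata(out)$retained_frac, 2 / 3)
    mt <- makeOtuTable(nOtus = 100, nontargetFrac = 0.08, seed = 6)
    expect_equal(S4Vectors::metadata(removeNonTarget(mt$table))$retained_frac,
                 0.92)
})

test_that("trait annotation uses the most specific rank with fallback", {
    tab <- OtuTable(matrix(1:3, 3, 1), taxonomy = data.frame(
        species = c("Polymyxa graminis", "Woronina pythii", NA),
        genus = c("Polymyxa", "Woronina", NA),
        order = c("Plasmodiophorida", "Plasmodiophorida", "Glissomonadida")))
    ann <- SummarizedExperiment::rowData(annotateTraits(tab, traitPath()))
    expect_equal(ann$nutrition,
                 c("plant parasite", "hyperparasite of Oomycota",
                   "bacterivore"))
    expect_equal(ann$trait_rank, c("species", "species", "order"))
    # unknown taxa stay unknown; vocabulary violations are input errors
    tab2 <- OtuTable(matrix(1L), taxonomy = data.frame(order = "Novelida"))
    ann2 <- SummarizedExperiment::rowData(annotateTraits(tab2, traitPath()))
    expect_equal(ann2$nutrition, "unknown")
    expect_equal(ann2$trait_rank, "none")
    badTraits <- data.frame(taxon = "X", rank = "order",
                            nutrition = "carnivore",
                            morphology = "naked amoeba",
                            locomotion = "swimming")
    expect_error(annotateTraits(tab2, badTraits), "vocabulary")
})

test_that("guild percentages sum to 100 and reflect the table", {
    m <- matrix(c(10L, 10L), 2, 1, dimnames = list(c("a", "b"), "S1"))
    tab <- OtuTable(m, taxonomy = data.frame(
        nutrition = c("bacterivore", "eukaryvore")))
    g <- guildRelAbund(tab, "nutrition", "reads")
    expect_equal(g$percent[g$category == "bacterivore"], 50)
    expect_equal(g$percent[g$category == "eukaryvore"], 50)
    expect_equal(sum(g$percent), 100)
    mono <- OtuTable(matrix(5L, 3, 2), taxonomy = data.frame(
        nutrition = rep("bacterivore", 3)))
    gm <- guildRelAbund(mono, "nutrition", "reads")
    expect_equal(gm$percent[gm$category == "bacterivore"], 100)
    # permutation of sample order leaves percentages unchanged
    mt <- makeOtuTable(nOtus = 80, nSamples = 8, seed = 10)
    t1 <- mt$table
    perm <- sample(ncol(t1))
    g1 <- guildRelAbund(t1, "nutrition", "reads")
    g2 <- guildRelAbund(t1[, perm], "nutrition", "reads")
    expect_equal(g1, g2)
    expect_true(all(abs(tapply(g1$percent, g1$stratum, sum) - 100) < 1e-9))
})

test_that("sharing statistics count presence across strata", {
    m <- matrix(c(1L, 1L,   # both
                  2L, 0L,   # G only
                  0L, 3L),  # F only
                nrow = 3, byrow = TRUE,
                dimnames = list(paste0("o", 1:3), c("g1", "f1")))
    tab <- OtuTable(m, sampleData = data.frame(ecosystem = c("G", "F")))
    ss <- sharingStats(tab)
    expect_equal(ss$shared, 1)
    expect_equal(ss$unique, c(F = 1L, G = 1L))
    expect_lte(ss$shared + sum(ss$unique), ss$total)
    all2 <- OtuTable(matrix(1L, 4, 4),
                     sampleData = data.frame(ecosystem = rep(c("G", "F"), 2)))
    expect_equal(sharingStats(all2)$shared, 4)
    # planted sharing structure is recovered exactly
    mt <- makeOtuTable(nOtus = 150, nSamples = 10, sharedFrac = 0.8,
                       seed = 12)
    ss2 <- sharingStats(mt$table)
    expect_equal(ss2$shared, sum(mt$truth$category == "shared"))
    expect_equal(unname(ss2$unique[["G"]]),
                 sum(mt$truth$category == "uniqueG"))
    expect_equal(unname(ss2$unique[["F"]]),
                 sum(mt$truth$category == "uniqueF"))
})

test_that("diversity closed forms and ranges", {
    expect_equal(shannonIndex(rep(1, 4)), log(4))
    expect_equal(pielouEvenness(rep(1, 4)), 1)
    expect_equal(shannonIndex(c(0, 7, 0)), 0)
    expect_equal(pielouEvenness(c(0, 7, 0)), 0)   # S = 1: J defined as 0
    expect_equal(brayCurtis(c(2, 2), c(2, 0)), 1 / 3)
    expect_equal(shannonIndex(rep(1, 8), base = 2), 3)
    expect_error(brayCurtis(c(0, 0), c(1, 2)), "all-zero")
    set.seed(17)
    for (i in 1:200) {
        x <- stats::rpois(12, 5); y <- stats::rpois(12, 5)
        if (sum(x) == 0 || sum(y) == 0) next
        bc <- brayCurtis(x, y)
        expect_gte(bc, 0); expect_lte(bc, 1)
        expect_equal(bc, brayCurtis(y, x))
        expect_equal(brayCurtis(x, x), 0)
        expect_equal(bc, sum(abs(x - y)) / sum(x + y))
        S <- sum(x > 0)
        H <- shannonIndex(x)
        expect_gte(H, 0)
        if (S > 0) expect_lte(H, log(S) + 1e-12)
        J <- pielouEvenness(x)
        expect_gte(J, 0); expect_lte(J, 1)
    }
})

test_that("rare and non-target filters commute when both apply", {
    # rare OTUs far below the cutoff in either order, the rest far above:
    # the two removal decisions are then independent and the orders agree
    n <- 55
    counts <- matrix(rep(c(1000L, 1L), c(50, 5)), ncol = 1,
                     dimnames = list(sprintf("o%02d", 1:n), "S1"))
    phyla <- rep(c("Cercozoa", "Fungi", "Cercozoa"), c(40, 10, 5))
    tab <- OtuTable(counts, taxonomy = data.frame(phylum = phyla))
    ab <- removeNonTarget(rareFilter(tab))
    ba <- rareFilter(removeNonTarget(tab))
    expect_setequal(rownames(ab), rownames(ba))
    expect_equal(nrow(ab), 40)
})

test_that("OTU tables round-trip through TSV with sidecars", {
    mt <- makeOtuTable(nOtus = 30, nSamples = 4, seed = 20)
    tab <- mt$table
    d <- withr::local_tempdir()
    writeOtuTable(tab, file.path(d, "counts.tsv"),
                  file.path(d, "tax.tsv"), file.path(d, "samples.tsv"))
    back <- readOtuTable(file.path(d, "counts.tsv"),
                         file.path(d, "tax.tsv"), file.path(d, "samples.tsv"))
    expect_equal(otuCounts(back), otuCounts(tab))
    expect_equal(
        as.character(SummarizedExperiment::rowData(back)$nutrition),
        as.character(SummarizedExperiment::rowData(tab)$nutrition))
    expect_equal(
        as.character(SummarizedExperiment::colData(back)$ecosystem),
        as.character(SummarizedExperiment::colData(tab)$ecosystem))
})
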