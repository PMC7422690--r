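test_that("revComp handles IUPAC codes and is an involution", {
    expect_equal(revComp("GTTAAAAAGCTCGTAGTTG"), "CAACTACGAGCTTTTTAAC")
    expect_equal(revComp("A"), "T")
    expect_equal(revComp("acgtryswkmbdhvn"),
                 revComp(toupper("acgtryswkmbdhvn")))
    set.seed(42)
    for (i in 1:300) {
        x <- randOligo(sample(1:40, 1), names(IUPAC_SETS))
        expect_equal(revComp(revComp(x)), x)
    }
    expect_error(revComp("ACGX"), "non-IUPAC")
})

test_that("iupacCompatible reflects expansion-set intersection", {
    expect_true(iupacCompatible("A", "R"))
    expect_false(iupacCompatible("C", "R"))
    expect_true(all(iupacCompatible("N", names(IUPAC_SETS))))
    # exhaustive against the longhand sets
    for (x in names(IUPAC_SETS)) for (y in names(IUPAC_SETS))
        expect_equal(iupacCompatible(x, y),
                     length(intersect(IUPAC_SETS[[x]], IUPAC_SETS[[y]])) > 0)
})

test_that("iupacDistance counts disjoint-expansion positions", {
    # the two printed forward primers differ only at degenerate positions
    expect_equal(iupacDistance("GTTAAAAAGCTCGTAGTTG",
                               "GTTAAAARGCTCGTAGTYG"), 0)
    expect_equal(iupacDistance("AAAAAAAA", "AAAAAAAT"), 1)
    x <- randOligo(12)
    expect_equal(iupacDistance(x, x), 0)
    expect_error(iupacDistance("AAA", "AAAA"), "equal-length")
})

test_that("iupacDistance is a metric on non-degenerate strings", {
    set.seed(7)
    for (i in 1:200) {
        a <- randOligo(10); b <- randOligo(10); c <- randOligo(10)
        expect_equal(iupacDistance(a, b), iupacDistance(b, a))
        expect_lte(iupacDistance(a, c),
                   iupacDistance(a, b) + iupacDistance(b, c))
    }
})

test_that("maxHomopolymer finds the longest literal run", {
    expect_equal(maxHomopolymer("GTTAAAAAGCTCGTAGTTG"), 5)
    expect_equal(maxHomopolymer("ACGT"), 1)
    expect_equal(maxHomopolymer("AAAA"), 4)
    expect_equal(maxHomopolymer(c("AATT", "A")), c(2L, 1L))
})

test_that("duplexScan worked examples", {
    a <- "ACGTACGT"
    expect_equal(duplexScan(a, revComp(a))$max_run, 8)
    expect_equal(duplexScan("ATATATAT", "ATATATAT")$max_run, 8)
    expect_equal(duplexScan("AAAAAAAA", "CCCCCCCC")$max_run, 0)
})

test_that("duplexScan matches brute-force enumeration and is symmetric", {
    set.seed(11)
    for (i in 1:120) {
        alpha <- if (i %% 4 == 0) names(IUPAC_SETS) else BASES
        a <- randOligo(sample(4:30, 1), alpha)
        b <- randOligo(sample(4:30, 1), alpha)
        got <- duplexScan(a, b)
        want <- oracleDuplex(a, b)
        expect_equal(got$max_run, want$max_run, info = paste(a, b))
        expect_equal(got$three_prime_run, want$three_prime_run,
                     info = paste(a, b))
        expect_equal(duplexScan(b, a)$max_run, got$max_run)
        expect_true(got$three_prime_run <= got$max_run)
        expect_lte(got$max_run, min(nchar(a), nchar(b)))
    }
})

test_that("hairpinScan worked examples and brute-force agreement", {
    expect_true(hairpinScan("GGGCAAAGCCC", stemMin = 4, loopMin = 3))
    expect_false(hairpinScan("GGGCAAAGCCC", stemMin = 5, loopMin = 3))
    expect_false(hairpinScan("AAAAAAAAAAA", stemMin = 2, loopMin = 3))
    set.seed(13)
    for (i in 1:150) {
        s <- randOligo(sample(8:30, 1))
        stem <- sample(2:5, 1); loop <- sample(3:6, 1)
        expect_equal(hairpinScan(s, stem, loop),
                     oracleHairpin(s, stem, loop),
                     info = sprintf("%s stem=%d loop=%d", s, stem, loop))
    }
    expect_error(hairpinScan("ACGT", stemMin = 1), "stemMin")
})

test_that("alignmentConsensus collapses columns per the majority rule", {
    expect_equal(alignmentConsensus(c("ACGT", "ACGT", "ACGA"), 0.5), "ACGT")
    expect_equal(alignmentConsensus(c("ACGT", "ACGT"), 0.9), "ACGT")
    expect_equal(alignmentConsensus(c("AAAA", "GGGG"), 1.0), "RRRR")
    # majority-gap columns are dropped
    expect_equal(alignmentConsensus(c("A-CG", "A-CG", "ATCG"), 0.5), "ACG")
    expect_error(alignmentConsensus("ACGT"), "at least 2")
    expect_error(alignmentConsensus(c("ACGT", "ACG")), "equal length")
    expect_error(alignmentConsensus(c("ACGT", "ACGT"), 0.3), "majorityThreshold")
})

test_that("the printed primer panel is intact", {
    p <- cercozoaPrimers()
    expect_equal(length(p), 5)
    expect_equal(unname(nchar(p[["S615F_Cer"]])), 19)
    # second-round primers sit inside the first-round amplicon orientation
    expect_equal(iupacDistance(p[["S615F_Cerco"]], p[["S615F_Cer"]]), 0)
})
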