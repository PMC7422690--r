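test_that("enumerateCandidates applies composition filters in order", {
    c1 <- designConstraints(barcodeLength = 1, minPairwiseDistance = 1,
                            maxHomopolymerRun = 1, baseCountMin = 0,
                            baseCountMax = 1, gcMin = 0, gcMax = 1)
    expect_equal(enumerateCandidates(c1), c("A", "C", "G", "T"))
    c2 <- designConstraints(barcodeLength = 2, minPairwiseDistance = 1,
                            maxHomopolymerRun = 1, baseCountMin = 0,
                            baseCountMax = 2, gcMin = 0, gcMax = 1)
    cand2 <- enumerateCandidates(c2)
    expect_equal(length(cand2), 12)   # the dinucleotides with unequal letters
    expect_false(any(substr(cand2, 1, 1) == substr(cand2, 2, 2)))
    expect_equal(cand2, sort(cand2))  # lexicographic order
    expect_error(enumerateCandidates(designConstraints(barcodeLength = 13)),
                 "refus")
})

test_that("8-mer candidate count equals a naive independent enumeration", {
    cand <- enumerateCandidates(designConstraints())
    grid <- do.call(expand.grid, c(rep(list(BASES), 8),
                                   stringsAsFactors = FALSE))
    all8 <- do.call(paste0, grid)
    ok <- vapply(strsplit(all8, ""), function(ch) {
        tb <- table(factor(ch, levels = BASES))
        gc <- sum(tb[c("C", "G")]) / 8
        all(tb >= 1 & tb <= 3) && gc >= 0.375 && gc <= 0.625 &&
            max(rle(ch)$lengths) <= 2
    }, logical(1))
    expect_equal(length(cand), sum(ok))
    expect_setequal(cand, all8[ok])
})

test_that("screenAgainstPrimer rejects guaranteed duplexes and passes inert pairs", {
    primer <- cercozoaPrimers()[["S615F_Cer"]]
    bad <- revComp(substr(primer, 1, 8))
    expect_false(screenAgainstPrimer(bad, primer)$pass)
    # A-only barcode cannot pair with an A/T-free complement profile
    expect_true(screenAgainstPrimer("AAAAAAAA", "AAAAAAAAAA")$pass)
    # audit agrees with a direct duplex oracle on the printed primer
    b <- "ACACACAC"
    sc <- screenAgainstPrimer(b, primer)
    want <- oracleDuplex(b, primer)
    expect_equal(sc$primer_duplex_run, want$max_run)
    expect_equal(sc$primer_duplex_3p, want$three_prime_run)
})

test_that("screenAgainstFlank slides the barcode across the window", {
    cons <- designConstraints(flankMatchMax = 7)
    flank <- "ACGTTGCAGGTCAACTGGAT"
    sub <- substr(flank, 5, 12)
    expect_false(screenAgainstFlank(sub, flank, cons))  # 8/8 > 7
    expect_true(screenAgainstFlank("AAAAAAAA", "CCCCCCCCCCCC",
                                   designConstraints(flankMatchMax = 0)))
    set.seed(3)
    for (i in 1:50) {
        b <- randOligo(8); fl <- randOligo(20)
        mx <- designConstraints(flankMatchMax = sample(3:7, 1))
        bm <- strsplit(b, "")[[1]]
        hits <- vapply(1:13, function(off) {
            w <- strsplit(substr(fl, off, off + 7), "")[[1]]
            sum(bm == w)
        }, numeric(1))
        expect_equal(screenAgainstFlank(b, fl, mx),
                     all(hits <= mx@flankMatchMax))
    }
    expect_error(screenAgainstFlank("AAAAAAAA", "ACGT"), "shorter")
})

test_that("selectBarcodes picks the exact maximum on small pools", {
    sel <- selectBarcodes(c("AAAAAAAA", "AAAAAAAT", "CCCCCCCC"),
                          minDistance = 3, targetSize = Inf)
    expect_equal(as.character(sel), c("AAAAAAAA", "CCCCCCCC"))
    pool <- c("AAAA", "AAAT", "CCCC", "GGGG", "TTTT")
    expect_equal(as.character(selectBarcodes(pool, minDistance = 1,
                                             targetSize = Inf)),
                 sort(pool))
    set.seed(21)
    for (i in 1:15) {
        n <- sample(6:15, 1)
        pool <- unique(replicate(n, randOligo(6)))
        d <- sample(2:4, 1)
        got <- selectBarcodes(pool, minDistance = d, targetSize = Inf)
        expect_equal(length(got), oracleMaxSetSize(pool, d),
                     info = paste(d, paste(pool, collapse = ",")))
        dm <- outer(as.character(got), as.character(got), Vectorize(hamming))
        if (length(got) > 1) expect_true(all(dm[upper.tri(dm)] >= d))
    }
})

test_that("greedy selection is reproducible and monotone in distance", {
    cand <- enumerateCandidates(designConstraints())
    s1 <- selectBarcodes(cand, 3, targetSize = 30, seed = 9)
    s2 <- selectBarcodes(cand, 3, targetSize = 30, seed = 9)
    expect_identical(s1, s2)
    big3 <- selectBarcodes(cand, 3, targetSize = Inf, seed = 9)
    big4 <- selectBarcodes(cand, 4, targetSize = Inf, seed = 9)
    expect_lte(length(big4), length(big3))
    expect_warning(selectBarcodes(c("AAAAAAAA", "AAAAAAAT"), 3,
                                  targetSize = 5),
                   "selectable")
})

test_that("designBarcodes output passes independent validation", {
    cons <- designConstraints()
    bs <- designBarcodes(cercozoaPrimers()[["S615F_Cer"]], cons,
                         targetSize = 8, seed = 4)
    expect_s4_class(bs, "BarcodeSet")
    rep <- validateBarcodeSet(bs)
    expect_true(all(rep$pass))
    expect_true(all(nchar(barcodeSeqs(bs)) == 8))
    # audit columns populated for every barcode
    expect_equal(nrow(designAudit(bs)), length(bs))
    expect_true(all(designAudit(bs)$primer_duplex_run < cons@duplexMaxRun))
})

test_that("validateBarcodeSet reports offenders without raising", {
    cons <- designConstraints(minPairwiseDistance = 3)
    s <- BarcodeSet(c("AACCGGTT", "AACCGGTA"), "GTTAAAAAGCTCGTAGTTG",
                    constraints = designConstraints(minPairwiseDistance = 1))
    s@constraints <- cons  # distance 1 < 3: structurally invalid on purpose
    rep <- validateBarcodeSet(s)
    dist <- rep[rep$check == "pairwise_distance", ]
    expect_false(dist$pass)
    expect_match(dist$worst, "AACCGGT")
})

test_that("cross-combination screen flags constructed dimers and passes real sets", {
    sets <- fixtureSets()
    fails <- crossCombinationScreen(sets$fw, sets$rv)
    expect_s3_class(fails, "data.frame")
    # a reverse set built to be complementary to a forward tag must be caught
    fwb <- barcodeSeqs(sets$fw)[1]
    trap <- BarcodeSet(revComp(unname(fwb)),
                       revComp(attachedPrimer(sets$fw)),
                       orientation = "reverse",
                       constraints = designConstraintsOf(sets$fw))
    caught <- crossCombinationScreen(sets$fw, trap)
    expect_true(any(grepl("rv:", caught$oligo_b) | grepl("rv:", caught$oligo_a)))
    expect_true(max(caught$max_run) >= 6)
})
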