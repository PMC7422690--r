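#' Enumerate barcode candidates passing the composition filters
#'
#' Enumerates all `4^L` ACGT k-mers of the constraint length and keeps those
#' with balanced nucleotide content (per-base counts and GC fraction within
#' bounds) and no homopolymer run longer than allowed. Candidates are
#' returned in lexicographic order.
#'
#' @param constraints A [DesignConstraints-class]; `barcodeLength` must be
#'   at most 12 (full enumeration).
#' @return Character vector of candidate barcodes.
#' @examples
#' length(enumerateCandidates(designConstraints()))
#' @export
enumerateCandidates <- function(constraints = designConstraints()) {
    L <- constraints@barcodeLength
    if (L > 12L)
        stop("barcodeLength > 12 would enumerate > 4^12 k-mers; refusing")
    bases <- c("A", "C", "G", "T")
    grid <- do.call(expand.grid,
                    c(rep(list(bases), L), stringsAsFactors = FALSE))
    cand <- sort(do.call(paste0, grid))
    chars <- do.call(rbind, strsplit(cand, "", fixed = TRUE))
    counts <- vapply(bases, function(b) rowSums(chars == b),
                     numeric(length(cand)))
    keep <- rowSums(counts < constraints@baseCountMin |
                    counts > constraints@baseCountMax) == 0L
    gc <- (counts[, "C"] + counts[, "G"]) / L
    keep <- keep & gc >= constraints@gcMin & gc <= constraints@gcMax
    if (constraints@maxHomopolymerRun < L) {
        re <- sprintf("([ACGT])\\1{%d,}", constraints@maxHomopolymerRun)
        keep <- keep & !grepl(re, cand)
    }
    cand[keep]
}

# TRUE when a duplex report is below the rejection thresholds
.duplexOk <- function(rep, constraints) {
    rep$max_run < constraints@duplexMaxRun &&
        rep$three_prime_run < constraints@duplexThreePrimeRun
}

#' Screen one barcode against its primer
#'
#' Applies the secondary-structure screens to a candidate barcode attached
#' 5' of its primer: no hairpin in the tagged oligo (barcode+primer), no
#' heteroduplex between barcode and primer above the duplex thresholds, and
#' no barcode self-dimer above the thresholds.
#'
#' @param barcode ACGT string.
#' @param primer IUPAC primer string.
#' @param constraints A [DesignConstraints-class].
#' @return A list with `pass` (logical) and the individual check results
#'   (`hairpin`, `primer_duplex_run`, `primer_duplex_3p`, `self_dimer_run`,
#'   `self_dimer_3p`).
#' @export
screenAgainstPrimer <- function(barcode, primer,
                                constraints = designConstraints()) {
    barcode <- .checkOligo(barcode, "barcode")
    primer <- .checkOligo(primer, "primer")
    tagged <- paste0(barcode, primer)
    hp <- hairpinScan(tagged, constraints@hairpinStemMin,
                      constraints@hairpinLoopMin)
    het <- duplexScan(barcode, primer)
    self <- duplexScan(barcode, barcode)
    list(pass = !hp && .duplexOk(het, constraints) &&
             .duplexOk(self, constraints),
         hairpin = hp,
         primer_duplex_run = het$max_run,
         primer_duplex_3p = het$three_prime_run,
         self_dimer_run = self$max_run,
         self_dimer_3p = self$three_prime_run)
}

#' Screen one barcode against the template flank consensus
#'
#' A barcode that resembles the template sequence next to the primer
#' annealing site could misprime; candidates are slid along the flanking
#' consensus and rejected when the number of IUPAC-compatible matches at
#' any offset exceeds `flankMatchMax`.
#'
#' @param barcode ACGT string.
#' @param flankConsensus IUPAC consensus of the template region flanking
#'   the primer site (length >= barcode length).
#' @param constraints A [DesignConstraints-class].
#' @return `TRUE` (pass) iff every offset has at most `flankMatchMax`
#'   compatible positions.
#' @export
screenAgainstFlank <- function(barcode, flankConsensus,
                               constraints = designConstraints()) {
    barcode <- .checkOligo(barcode, "barcode")
    flankConsensus <- .checkOligo(flankConsensus, "flank consensus")
    L <- nchar(barcode)
    if (nchar(flankConsensus) < L)
        stop("flank consensus shorter than the barcode")
    bm <- .IUPAC_MASK[.oligoChars(barcode)]
    fm <- .IUPAC_MASK[.oligoChars(flankConsensus)]
    hits <- vapply(seq_len(length(fm) - L + 1L), function(off) {
        sum(bitwAnd(bm, fm[off:(off + L - 1L)]) > 0L)
    }, numeric(1L))
    all(hits <= constraints@flankMatchMax)
}

# exact maximum compatible subset by recursive branch and bound over the
# compatibility graph (edge iff Hamming distance >= minDistance); only used
# for small candidate pools
.maxCompatibleExact <- function(candidates, minDistance) {
    n <- length(candidates)
    if (n <= 1L) return(candidates)
    d <- .hammingMatrix(candidates)
    adj <- d >= minDistance
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    cl <- igraph::largest_cliques(g)
    picks <- lapply(cl, function(v) sort(candidates[as.integer(v)]))
    # deterministic tie-break: lexicographically smallest member list
    keys <- vapply(picks, paste, character(1L), collapse = " ")
    picks[[order(keys)[1L]]]
}

#' Select a mutually distant barcode set from screened candidates
#'
#' Builds the final set under the minimum pairwise Hamming distance
#' constraint. For pools up to `exactMax` candidates the exact maximum
#' compatible subset is found by clique search; larger pools use greedy
#' maximal construction over a seed-keyed shuffle of the candidate order
#' (reproducible, near-maximal in practice). Selection stops at
#' `targetSize`; if fewer barcodes are selectable a warning reports the
#' achieved size.
#'
#' @param candidates Character vector of pre-screened ACGT barcodes.
#' @param minDistance Minimum pairwise Hamming distance (default 3).
#' @param targetSize Stop after this many barcodes (default 18);
#'   `Inf` selects a maximal set.
#' @param seed Integer seed keying the greedy order.
#' @param exactMax Pool size up to which the exact search is used
#'   (default 20).
#' @return Character vector of selected barcodes (lexicographically
#'   sorted), with attribute `achieved` = length.
#' @export
selectBarcodes <- function(candidates, minDistance = 3L, targetSize = 18L,
                           seed = 1L, exactMax = 20L) {
    candidates <- unique(.checkOligo(candidates, "candidates"))
    if (length(unique(nchar(candidates))) > 1L)
        stop("candidates must share one length")
    if (targetSize < 1L) stop("targetSize must be >= 1")
    if (length(candidates) <= exactMax) {
        sel <- .maxCompatibleExact(candidates, minDistance)
        if (length(sel) > targetSize) sel <- sel[seq_len(targetSize)]
    } else {
        ord <- withr::with_seed(seed, sample.int(length(candidates)))
        chars <- do.call(rbind, strsplit(candidates[ord], "", fixed = TRUE))
        selIdx <- integer(0)
        for (i in seq_along(ord)) {
            if (length(selIdx) >= targetSize) break
            if (!length(selIdx)) { selIdx <- i; next }
            dmin <- min(colSums(t(chars[selIdx, , drop = FALSE]) != chars[i, ]))
            if (dmin >= minDistance) selIdx <- c(selIdx, i)
        }
        sel <- sort(candidates[ord][selIdx])
    }
    if (is.finite(targetSize) && length(sel) < targetSize)
        warning(sprintf("only %d of the requested %d barcodes selectable",
                        length(sel), targetSize))
    structure(sel, achieved = length(sel))
}

#' Design a barcode set for one primer
#'
#' Runs the full constraint chain: enumerate composition-balanced,
#' homopolymer-free k-mers; screen each against the primer (hairpin,
#' heteroduplex, self-dimer); screen against the template flank consensus
#' when supplied; then select a mutually distant subset. The returned
#' [BarcodeSet-class] carries a per-barcode audit of every filter.
#'
#' @param primer IUPAC primer string the barcodes are appended to (5').
#' @param constraints A [DesignConstraints-class].
#' @param flankConsensus Optional IUPAC consensus of the template flanking
#'   the primer annealing site; when provided, its `flankWindow` bases
#'   adjacent to the primer are screened against.
#' @param orientation `"forward"` or `"reverse"`.
#' @param targetSize Number of barcodes aimed for (default 18).
#' @param seed Integer seed for the selection order.
#' @return A [BarcodeSet-class].
#' @examples
#' bs <- designBarcodes(cercozoaPrimers()[["S615F_Cer"]], targetSize = 6)
#' barcodeSeqs(bs)
#' @export
designBarcodes <- function(primer, constraints = designConstraints(),
                           flankConsensus = NULL,
                           orientation = c("forward", "reverse"),
                           targetSize = 18L, seed = 1L) {
    orientation <- match.arg(orientation)
    primer <- .checkOligo(primer, "primer")
    cand <- enumerateCandidates(constraints)
    screens <- lapply(cand, screenAgainstPrimer, primer = primer,
                      constraints = constraints)
    passPrimer <- vapply(screens, `[[`, logical(1L), "pass")
    passFlank <- rep(TRUE, length(cand))
    if (!is.null(flankConsensus)) {
        flankConsensus <- .checkOligo(flankConsensus, "flank consensus")
        win <- min(nchar(flankConsensus), constraints@flankWindow)
        window <- substr(flankConsensus,
                         nchar(flankConsensus) - win + 1L,
                         nchar(flankConsensus))
        if (win < constraints@barcodeLength)
            stop("flank window shorter than the barcode length")
        passFlank[passPrimer] <- vapply(
            cand[passPrimer], screenAgainstFlank, logical(1L),
            flankConsensus = window, constraints = constraints)
    }
    pool <- cand[passPrimer & passFlank]
    if (!length(pool))
        stop("no candidate survives the primer/flank screens")
    sel <- selectBarcodes(pool, constraints@minPairwiseDistance,
                          targetSize = targetSize, seed = seed)
    idx <- match(sel, cand)
    audit <- S4Vectors::DataFrame(
        hairpin = vapply(screens[idx], `[[`, logical(1L), "hairpin"),
        primer_duplex_run = vapply(screens[idx], `[[`, integer(1L),
                                   "primer_duplex_run"),
        primer_duplex_3p = vapply(screens[idx], `[[`, integer(1L),
                                  "primer_duplex_3p"),
        self_dimer_run = vapply(screens[idx], `[[`, integer(1L),
                                "self_dimer_run"),
        self_dimer_3p = vapply(screens[idx], `[[`, integer(1L),
                               "self_dimer_3p"),
        flank_pass = passFlank[idx])
    BarcodeSet(as.character(sel), primer, orientation, constraints, audit)
}

#' Cross-dimerization screen over every tagged-primer combination
#'
#' Runs the heteroduplex scan on every pair of tagged oligos
#' (barcode+primer) within and across the forward and reverse sets
#' (fw x fw, rv x rv, fw x rv, including self-pairs) and reports the pairs
#' exceeding the duplex thresholds. An empty result is a pass.
#'
#' @param fwSet,rvSet [BarcodeSet-class] objects (individually validated).
#' @return `data.frame` with columns `oligo_a`, `oligo_b`, `max_run`,
#'   `three_prime_run`; zero rows when no pair cross-dimerizes.
#' @export
crossCombinationScreen <- function(fwSet, rvSet) {
    validObject(fwSet); validObject(rvSet)
    tagged <- c(stats::setNames(taggedOligos(fwSet),
                                paste0("fw:", names(barcodeSeqs(fwSet)))),
                stats::setNames(taggedOligos(rvSet),
                                paste0("rv:", names(barcodeSeqs(rvSet)))))
    cons <- designConstraintsOf(fwSet)
    n <- length(tagged)
    res <- vector("list", n * (n + 1L) / 2L)
    k <- 0L
    for (i in seq_len(n)) for (j in i:n) {
        rep <- duplexScan(tagged[[i]], tagged[[j]])
        if (!.duplexOk(rep, cons)) {
            k <- k + 1L
            res[[k]] <- data.frame(oligo_a = names(tagged)[i],
                                   oligo_b = names(tagged)[j],
                                   max_run = rep$max_run,
                                   three_prime_run = rep$three_prime_run)
        }
    }
    if (k) do.call(rbind, res[seq_len(k)])
    else data.frame(oligo_a = character(), oligo_b = character(),
                    max_run = integer(), three_prime_run = integer())
}

#' Independently re-validate a barcode set
#'
#' Re-checks every set invariant from scratch, independently of how the set
#' was built: distinctness, equal length, alphabet, composition balance,
#' homopolymers, hairpin with the attached primer, heteroduplex with the
#' primer, self-dimers, minimum pairwise distance, and (when a flank
#' consensus is given) the flank screen. Report-only: failures are listed,
#' not raised.
#'
#' @param x A [BarcodeSet-class].
#' @param flankConsensus Optional flank consensus to re-run the flank
#'   screen.
#' @return `data.frame` with columns `check`, `pass`, `worst` (worst
#'   offender or measured extreme).
#' @export
validateBarcodeSet <- function(x, flankConsensus = NULL) {
    b <- barcodeSeqs(x)
    cons <- designConstraintsOf(x)
    chars <- do.call(rbind, strsplit(b, "", fixed = TRUE))
    counts <- vapply(c("A", "C", "G", "T"), function(bb) rowSums(chars == bb),
                     numeric(length(b)))
    gc <- (counts[, "C"] + counts[, "G"]) / nchar(b)
    compOk <- rowSums(counts < cons@baseCountMin |
                      counts > cons@baseCountMax) == 0L &
        gc >= cons@gcMin & gc <= cons@gcMax
    hp <- maxHomopolymer(b)
    primerScreen <- lapply(b, screenAgainstPrimer, primer = attachedPrimer(x),
                           constraints = cons)
    structOk <- vapply(primerScreen, `[[`, logical(1L), "pass")
    rows <- list(
        data.frame(check = "unique", pass = !anyDuplicated(b),
                   worst = if (anyDuplicated(b)) b[duplicated(b)][1L] else ""),
        data.frame(check = "length",
                   pass = all(nchar(b) == cons@barcodeLength),
                   worst = as.character(max(nchar(b)))),
        data.frame(check = "composition", pass = all(compOk),
                   worst = if (all(compOk)) "" else b[!compOk][1L]),
        data.frame(check = "homopolymer",
                   pass = all(hp <= cons@maxHomopolymerRun),
                   worst = b[which.max(hp)]),
        data.frame(check = "primer_structure", pass = all(structOk),
                   worst = if (all(structOk)) "" else b[!structOk][1L]))
    if (length(b) >= 2L) {
        d <- .hammingMatrix(b)
        dmin <- min(d[upper.tri(d)])
        off <- which(d == dmin & upper.tri(d), arr.ind = TRUE)[1L, ]
        rows <- c(rows, list(data.frame(
            check = "pairwise_distance",
            pass = dmin >= cons@minPairwiseDistance,
            worst = sprintf("%s/%s (d=%d)", b[off[1L]], b[off[2L]], dmin))))
    }
    if (!is.null(flankConsensus)) {
        fl <- vapply(b, screenAgainstFlank, logical(1L),
                     flankConsensus = flankConsensus, constraints = cons)
        rows <- c(rows, list(data.frame(
            check = "flank", pass = all(fl),
            worst = if (all(fl)) "" else b[!fl][1L])))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
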