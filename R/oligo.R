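#' @useDynLib ampliTags, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# IUPAC nucleotide codes as 4-bit masks (A=1, C=2, G=4, T=8); two codes are
# compatible iff their expansion sets intersect, i.e. bitwAnd(mask, mask) > 0.
.IUPAC_MASK <- c(
    A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
    R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
    B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

# mask -> smallest covering IUPAC code
.MASK_CODE <- local({
    codes <- setdiff(names(.IUPAC_MASK), "U")
    out <- character(15L)
    out[.IUPAC_MASK[codes]] <- codes
    out
})

.checkOligo <- function(x, what = "oligo") {
    if (!is.character(x) || length(x) == 0L || anyNA(x))
        stop(what, " must be a non-empty character vector without NA")
    x <- toupper(x)
    if (any(nchar(x) == 0L))
        stop(what, " contains an empty sequence")
    bad <- grepl(sprintf("[^%s]", paste(names(.IUPAC_MASK), collapse = "")), x)
    if (any(bad))
        stop("non-IUPAC character in ", what, ": ",
             paste(utils::head(x[bad], 3L), collapse = ", "))
    x
}

.oligoChars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

#' Reverse complement of IUPAC nucleotide strings
#'
#' Reverse-complements one or more nucleotide sequences under full IUPAC
#' rules (R/Y, S/W, K/M, B/V, D/H and N are mapped to their complements).
#' The operation is an involution: `revComp(revComp(x)) == x`.
#'
#' @param x Character vector of IUPAC nucleotide sequences (case-insensitive),
#'   or a [Biostrings::DNAStringSet].
#' @return Character vector of reverse-complemented sequences, uppercase.
#' @examples
#' revComp("GTTAAAAAGCTCGTAGTTG")
#' @export
revComp <- function(x) {
    if (is(x, "XStringSet") || is(x, "XString")) x <- as.character(x)
    x <- .checkOligo(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Compatibility of two IUPAC codes
#'
#' Two IUPAC codes are compatible iff their expansion sets intersect, e.g.
#' `A` is compatible with `R` (= A/G) but not with `Y` (= C/T). Vectorised
#' over pairs of single characters.
#'
#' @param a,b Character vectors of single IUPAC codes (recycled).
#' @return Logical vector.
#' @export
iupacCompatible <- function(a, b) {
    a <- .checkOligo(a); b <- .checkOligo(b)
    if (any(nchar(c(a, b)) != 1L))
        stop("iupacCompatible() expects single characters; see iupacDistance()")
    bitwAnd(.IUPAC_MASK[a], .IUPAC_MASK[b]) > 0L
}

#' Count incompatible positions between two equal-length IUPAC strings
#'
#' The distance counts positions whose IUPAC expansion sets are disjoint, so
#' a degenerate code matches any of its expansions at no cost: the printed
#' Cercozoa-specific primer and its semi-nested counterpart with R/Y wobbles
#' are at distance 0.
#'
#' @param a,b Single IUPAC strings of equal length.
#' @return Integer count of incompatible positions.
#' @export
iupacDistance <- function(a, b) {
    a <- .checkOligo(a); b <- .checkOligo(b)
    if (nchar(a) != nchar(b))
        stop("iupacDistance() requires equal-length sequences (",
             nchar(a), " vs ", nchar(b), ")")
    sum(bitwAnd(.IUPAC_MASK[.oligoChars(a)], .IUPAC_MASK[.oligoChars(b)]) == 0L)
}

# plain Hamming distance on literal characters (barcodes are ACGT-only)
.hamming <- function(a, b) sum(.oligoChars(a) != .oligoChars(b))

# symmetric matrix of pairwise Hamming distances over equal-length strings
.hammingMatrix <- function(x) {
    chars <- do.call(rbind, strsplit(x, "", fixed = TRUE))
    n <- length(x)
    d <- matrix(0L, n, n, dimnames = list(x, x))
    for (i in seq_len(n - 1L)) {
        di <- colSums(t(chars[(i + 1L):n, , drop = FALSE]) != chars[i, ])
        d[i, (i + 1L):n] <- di
        d[(i + 1L):n, i] <- di
    }
    d
}

#' Longest homopolymer run
#'
#' Length of the longest run of one identical literal character, used by the
#' barcode composition screen (balanced content, no homopolymers).
#'
#' @param x Character vector of nucleotide sequences.
#' @return Integer vector of maximal run lengths.
#' @examples
#' maxHomopolymer("GTTAAAAAGCTCGTAGTTG")  # the AAAAA run -> 5
#' @export
maxHomopolymer <- function(x) {
    x <- .checkOligo(x)
    vapply(strsplit(x, "", fixed = TRUE),
           function(ch) max(rle(ch)$lengths), integer(1L))
}

#' Scan two oligos for heteroduplex formation
#'
#' Slides `a` against the reverse complement of `b` over every ungapped
#' offset and reports the longest contiguous complementary run (IUPAC
#' compatibility, so degenerate primer positions pair with any expansion),
#' the longest complementary run anchored at a 3' terminus of either oligo
#' (the primer-extension risk), and the offset of the best run. With
#' `a == b` this is a self-dimer scan. Scoring is match-count based, not
#' thermodynamic.
#'
#' @param a,b Single IUPAC strings.
#' @return A list with elements `max_run`, `three_prime_run` and `offset`
#'   (all integer); `0 <= three_prime_run <= max_run <= min(nchar(a),
#'   nchar(b))`.
#' @examples
#' duplexScan("ACGTACGT", revComp("ACGTACGT"))$max_run  # 8, a perfect duplex
#' @export
duplexScan <- function(a, b) {
    a <- .checkOligo(a); b <- .checkOligo(b)
    .duplex_scan_cpp(a, b)
}

#' Scan an oligo for hairpin potential
#'
#' Tests whether an oligo can fold back on itself: two antiparallel
#' complementary stretches of at least `stemMin` bases enclosing a loop of
#' at least `loopMin` unpaired bases.
#'
#' @param x Single IUPAC string.
#' @param stemMin Minimum stem length in base pairs (>= 2).
#' @param loopMin Minimum loop length in bases (>= 3, the sterical minimum).
#' @return `TRUE` if a hairpin meeting the thresholds exists.
#' @examples
#' hairpinScan("GGGCAAAGCCC", stemMin = 4, loopMin = 3)  # GGGC/GCCC stem
#' @export
hairpinScan <- function(x, stemMin = 4L, loopMin = 3L) {
    x <- .checkOligo(x)
    if (stemMin < 2L) stop("stemMin must be >= 2")
    if (loopMin < 3L) stop("loopMin must be >= 3")
    .hairpin_scan_cpp(x, as.integer(stemMin), as.integer(loopMin))
}

#' IUPAC consensus of an alignment
#'
#' Collapses a gapped alignment into one IUPAC string: per column, every
#' base whose frequency among non-gap characters is at least
#' `1 - majorityThreshold` is retained, and the smallest IUPAC code covering
#' the retained bases is emitted. Columns that are at least 50% gaps are
#' dropped. Degenerate input codes whose frequency passes the bar contribute
#' their full expansion. Used to derive the template consensus flanking the
#' primer annealing site for the barcode flank screen.
#'
#' @param alignment Character vector (>= 2 equal-length gapped IUPAC strings,
#'   gap = `-`) or a [Biostrings::DNAStringSet] / `DNAMultipleAlignment`.
#' @param majorityThreshold Fraction in `[0.5, 1]`; bases with column
#'   frequency `>= 1 - majorityThreshold` are retained (1 keeps every
#'   observed base, 0.5 keeps simple majorities).
#' @return Single IUPAC consensus string.
#' @examples
#' alignmentConsensus(c("ACGT", "ACGT", "ACGA"), majorityThreshold = 0.5)
#' alignmentConsensus(c("AAAA", "GGGG"), majorityThreshold = 1)  # "RRRR"
#' @export
alignmentConsensus <- function(alignment, majorityThreshold = 0.7) {
    if (is(alignment, "DNAMultipleAlignment"))
        alignment <- as.character(Biostrings::DNAStringSet(alignment))
    if (is(alignment, "XStringSet")) alignment <- as.character(alignment)
    if (length(alignment) < 2L)
        stop("alignment must contain at least 2 sequences")
    if (length(unique(nchar(alignment))) != 1L)
        stop("aligned sequences must have equal length")
    if (majorityThreshold < 0.5 || majorityThreshold > 1)
        stop("majorityThreshold must be in [0.5, 1]")
    alignment <- toupper(alignment)
    chars <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
    cutoff <- 1 - majorityThreshold
    cols <- apply(chars, 2L, function(col) {
        nonGap <- col[col != "-"]
        if (length(nonGap) < length(col) / 2) return(NA_character_)
        bad <- setdiff(nonGap, names(.IUPAC_MASK))
        if (length(bad))
            stop("non-IUPAC character in alignment: ", bad[1L])
        freq <- table(nonGap) / length(nonGap)
        keep <- names(freq)[freq >= cutoff]
        if (!length(keep)) keep <- names(freq)[which.max(freq)]
        .MASK_CODE[Reduce(bitwOr, .IUPAC_MASK[keep])]
    })
    paste(cols[!is.na(cols)], collapse = "")
}

#' Printed PCR primers for Cercozoa and Endomyxa metabarcoding
#'
#' The five taxon-specific primers (5'->3') targeting the V4 region of the
#' 18S rRNA gene of Cercozoa and Endomyxa: the first-round primer mix
#' (S615F_Cerco + S615F_Phyt with reverse S963R_Phyt) and the semi-nested
#' second-round pair (S615F_Cer / S947R_Cer) that carries the sample
#' barcodes.
#'
#' @return Named character vector of primer sequences.
#' @examples
#' cercozoaPrimers()[["S615F_Cer"]]
#' @export
cercozoaPrimers <- function() {
    c(S615F_Cerco = "GTTAAAAAGCTCGTAGTTG",
      S615F_Phyt  = "GTTAAAARGCTCGTAGTCG",
      S963R_Phyt  = "CAACTTTCGTTCTTGATYAAA",
      S615F_Cer   = "GTTAAAARGCTCGTAGTYG",
      S947R_Cer   = "AAGARGAYATCCTTGGTG")
}
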