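# Independent brute-force oracles and tiny fixture builders. These stay
# deliberately naive (full enumeration) so they cannot share a bug with the
# package implementations they check.

BASES <- c("A", "C", "G", "T")

randOligo <- function(len, alphabet = BASES) {
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# IUPAC expansion sets written out longhand
IUPAC_SETS <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# can IUPAC codes x and y base-pair? (x pairs with the complement of y's set)
oraclePairs <- function(x, y) {
    compY <- unname(COMPLEMENT[IUPAC_SETS[[y]]])
    length(intersect(IUPAC_SETS[[x]], compY)) > 0
}

# longest complementary run between a and b over all ungapped alignments,
# by full enumeration of (start in a, start in revcomp-frame of b, length)
oracleDuplex <- function(a, b) {
    av <- strsplit(a, "")[[1]]
    bv <- rev(strsplit(b, "")[[1]])  # b read 3'->5', pairs positionally
    n <- length(av); m <- length(bv)
    best <- 0L; best3p <- 0L
    for (ia in seq_len(n)) for (jb in seq_len(m)) {
        k <- 0L
        while (ia + k <= n && jb + k <= m &&
               oraclePairs(av[ia + k], bv[jb + k])) k <- k + 1L
        if (k > best) best <- k
        if (k > 0L) {
            # run touching a's 3' end (position n) or b's 3' end (bv position 1)
            runEnd <- ia + k - 1L
            if (runEnd == n && k > best3p) best3p <- k
            if (jb == 1L && k > best3p) best3p <- k
        }
    }
    list(max_run = best, three_prime_run = best3p)
}

# hairpin by full enumeration of (stem1 start, stem2 start, stem length)
oracleHairpin <- function(s, stemMin, loopMin) {
    v <- strsplit(s, "")[[1]]
    n <- length(v)
    for (k in stemMin:max(stemMin, (n - loopMin) %/% 2)) {
        if (2 * k + loopMin > n) break
        for (i in 1:(n - 2 * k - loopMin + 1)) {
            for (j in (i + k + loopMin):(n - k + 1)) {
                ok <- all(vapply(0:(k - 1), function(t)
                    oraclePairs(v[i + t], v[j + k - 1 - t]), logical(1)))
                if (ok) return(TRUE)
            }
        }
    }
    FALSE
}

hamming <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# maximum mutually-distant subset size by subset enumeration (pools <= 15)
oracleMaxSetSize <- function(pool, minDist) {
    n <- length(pool)
    stopifnot(n <= 15)
    d <- outer(pool, pool, Vectorize(hamming))
    best <- 0L
    for (mask in 0:(2^n - 1)) {
        idx <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
        if (length(idx) <= best) next
        sub <- d[idx, idx, drop = FALSE]
        if (all(sub[upper.tri(sub)] >= minDist)) best <- length(idx)
    }
    best
}

# small ready-made design fixtures shared across tests
fixtureSets <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            p <- cercozoaPrimers()
            fw <- designBarcodes(p[["S615F_Cer"]], targetSize = 18, seed = 1)
            rv <- designBarcodes(p[["S947R_Cer"]], orientation = "reverse",
                                 targetSize = 18, seed = 2)
            cache <<- list(fw = fw, rv = rv)
        }
        cache
    }
})
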