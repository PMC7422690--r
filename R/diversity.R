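#' Alpha diversity: Shannon index and Pielou's evenness
#'
#' `shannonIndex()` computes `H = -sum(p_i * log(p_i))` on relative
#' abundances (zeros contribute nothing); `pielouEvenness()` normalises by
#' the maximum `log(S)` with `S` the number of nonzero taxa, so `J` lies in
#' `[0, 1]` (`J = 0` when `S = 1`, where evenness is undefined and maximal
#' diversity is 0). Both default to natural logarithms (nats), matching the
#' Pielou normalisation; `base = 2` gives bits.
#'
#' @param x Non-negative abundance vector (normalised internally), or a
#'   matrix with samples in rows.
#' @param base Logarithm base (default `exp(1)`).
#' @return Numeric `H` (or vector for a matrix input).
#' @examples
#' shannonIndex(rep(1, 4))          # log(4)
#' pielouEvenness(rep(1, 4))        # 1
#' @export
shannonIndex <- function(x, base = exp(1)) {
    if (is.matrix(x)) return(apply(x, 1L, shannonIndex, base = base))
    if (any(x < 0) || anyNA(x)) stop("abundances must be non-negative")
    unname(vegan::diversity(x, index = "shannon", base = base))
}

#' @rdname shannonIndex
#' @export
pielouEvenness <- function(x, base = exp(1)) {
    if (is.matrix(x)) return(apply(x, 1L, pielouEvenness, base = base))
    S <- sum(x > 0)
    if (S <= 1L) return(0)
    shannonIndex(x, base) / log(S, base = base)
}

#' Bray-Curtis dissimilarity
#'
#' `BC(x, y) = sum(|x_i - y_i|) / sum(x_i + y_i)`, a compositional
#' dissimilarity in `[0, 1]` with `BC(x, x) = 0`.
#'
#' @param x Non-negative abundance vector, or a matrix with samples in
#'   rows (then `y` is ignored and a full `dist` is returned).
#' @param y Second abundance vector, same length as `x`.
#' @return Numeric dissimilarity, or a `dist` object for a matrix input.
#' @examples
#' brayCurtis(c(2, 2), c(2, 0))  # 1/3
#' @export
brayCurtis <- function(x, y = NULL) {
    if (is.matrix(x)) {
        if (any(rowSums(x) == 0)) stop("all-zero sample vector: undefined")
        return(vegan::vegdist(x, method = "bray"))
    }
    if (length(x) != length(y)) stop("x and y must have the same length")
    if (any(c(x, y) < 0)) stop("abundances must be non-negative")
    if (sum(x) == 0 || sum(y) == 0)
        stop("Bray-Curtis is undefined for an all-zero vector")
    as.numeric(vegan::vegdist(rbind(x, y), method = "bray"))
}
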