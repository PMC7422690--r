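#' Build the forward x reverse tag combination grid
#'
#' Every (forward barcode, reverse barcode) pair is one grid cell that can
#' label a sample; 18 + 18 barcodes give 324 combinations.
#'
#' @param fw,rv [BarcodeSet-class] objects (or named character vectors of
#'   tags, in which case the primers are recorded as empty).
#' @return A list of class `TagGrid` with elements `fwTags`, `rvTags`,
#'   `fwPrimer`, `rvPrimer`, `nCells`.
#' @examples
#' g <- buildTagGrid(setNames(c("AACCGGTT", "CCAAGGTT"), c("F1", "F2")),
#'                   setNames(c("TTGGCCAA", "GGTTCCAA"), c("R1", "R2")))
#' g$nCells
#' @export
buildTagGrid <- function(fw, rv) {
    getTags <- function(x, prefix) {
        if (is(x, "BarcodeSet"))
            list(tags = barcodeSeqs(x), primer = attachedPrimer(x))
        else {
            x <- .checkOligo(x, "tags")
            if (is.null(names(x)))
                names(x) <- sprintf("%s%02d", prefix, seq_along(x))
            list(tags = x, primer = "")
        }
    }
    f <- getTags(fw, "F"); r <- getTags(rv, "R")
    if (!length(f$tags) || !length(r$tags))
        stop("both tag sets must be non-empty")
    structure(list(fwTags = f$tags, rvTags = r$tags,
                   fwPrimer = f$primer, rvPrimer = r$primer,
                   nCells = length(f$tags) * length(r$tags)),
              class = "TagGrid")
}

#' Assign samples to grid cells, leaving unused combinations
#'
#' Distributes the samples over the grid so that per-row (forward tag) and
#' per-column (reverse tag) usage counts are balanced to within one of each
#' other, by walking the diagonals of a seed-permuted grid
#' (Latin-square-like). The remaining cells form the deliberately unused
#' set in which tag-jumping products become observable. A warning is issued
#' when more than 75% of the grid is occupied, since little head-room
#' remains for mistag detection.
#'
#' @param grid A `TagGrid` from [buildTagGrid()].
#' @param sampleIds Character vector of unique sample ids; at most one per
#'   grid cell.
#' @param seed Integer seed keying the row/column permutation.
#' @return A [TagScheme-class].
#' @examples
#' g <- buildTagGrid(setNames(c("AACCGGTT", "CCAAGGTT", "ACGTACGT"), NULL),
#'                   setNames(c("TTGGCCAA", "GGTTCCAA", "TGCATGCA"), NULL))
#' selectCombinations(g, paste0("S", 1:6), seed = 1)
#' @export
selectCombinations <- function(grid, sampleIds, seed = 1L) {
    stopifnot(inherits(grid, "TagGrid"))
    n <- length(sampleIds)
    Fn <- length(grid$fwTags); Rn <- length(grid$rvTags)
    if (anyDuplicated(sampleIds)) stop("sample ids must be unique")
    if (n > Fn * Rn) stop("more samples than grid cells")
    if (n > 0.75 * Fn * Rn)
        warning("more than 75% of the grid in use; ",
                "little head-room for mistag detection")
    rowPerm <- withr::with_seed(seed, sample.int(Fn))
    colPerm <- withr::with_seed(seed + 1L, sample.int(Rn))
    k <- seq_len(n) - 1L
    # Round-robin over rows and columns, with the column sequence shifted by
    # one after every lcm(F, R) cells: collision-free up to F*R samples and
    # both margins stay within one of the balanced usage.
    g <- function(a, b) if (b == 0L) a else g(b, a %% b)
    l <- Fn %/% g(Fn, Rn) * Rn
    i <- k %% Fn
    j <- (k + k %/% l) %% Rn
    assignments <- data.frame(sample_id = as.character(sampleIds),
                              fw_index = rowPerm[i + 1L],
                              rv_index = colPerm[j + 1L],
                              stringsAsFactors = FALSE)
    allCells <- expand.grid(fw_index = seq_len(Fn), rv_index = seq_len(Rn))
    usedKey <- paste(assignments$fw_index, assignments$rv_index)
    unused <- allCells[!paste(allCells$fw_index, allCells$rv_index) %in%
                           usedKey, , drop = FALSE]
    rownames(unused) <- NULL
    new("TagScheme", fwTags = grid$fwTags, rvTags = grid$rvTags,
        fwPrimer = grid$fwPrimer, rvPrimer = grid$rvPrimer,
        assignments = assignments, unused = unused)
}

#' Fraction of grid cells where tag jumps are observable
#'
#' A tag-jumping read is only detectable when it lands in an unused cell
#' whose row and column are both in use by real samples (otherwise the
#' chimeric pair contains an unknown tag, or silently collides with a real
#' sample). This returns the fraction of all grid cells that are unused but
#' have both their forward and reverse tag in use.
#'
#' @param x A [TagScheme-class].
#' @return Numeric fraction in `[0, 1]`.
#' @export
mistagExposure <- function(x) {
    a <- x@assignments
    usedF <- unique(a$fw_index); usedR <- unique(a$rv_index)
    u <- x@unused
    exposed <- u$fw_index %in% usedF & u$rv_index %in% usedR
    sum(exposed) / (length(x@fwTags) * length(x@rvTags))
}

#' Read and write tag schemes as TSV
#'
#' The scheme file is a TSV with one row per sample (`sample_id`,
#' `fw_name`, `fw_seq`, `rv_name`, `rv_seq`) preceded by `#tag` header
#' lines declaring the complete forward and reverse tag lists and the
#' primers, so that the unused-combination set round-trips exactly.
#'
#' @param x A [TagScheme-class].
#' @param path File path.
#' @return `writeTagScheme()` returns `path` invisibly; `readTagScheme()`
#'   returns a [TagScheme-class].
#' @export
writeTagScheme <- function(x, path) {
    validObject(x)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
        sprintf("#primer\tfw\t%s", x@fwPrimer),
        sprintf("#primer\trv\t%s", x@rvPrimer),
        sprintf("#tag\tfw\t%s\t%s", names(x@fwTags), x@fwTags),
        sprintf("#tag\trv\t%s\t%s", names(x@rvTags), x@rvTags),
        paste(c("sample_id", "fw_name", "fw_seq", "rv_name", "rv_seq"),
              collapse = "\t")), con)
    a <- x@assignments
    writeLines(paste(a$sample_id,
                     names(x@fwTags)[a$fw_index], x@fwTags[a$fw_index],
                     names(x@rvTags)[a$rv_index], x@rvTags[a$rv_index],
                     sep = "\t"), con)
    invisible(path)
}

#' @rdname writeTagScheme
#' @export
readTagScheme <- function(path) {
    lines <- readLines(path)
    hdr <- lines[startsWith(lines, "#")]
    body <- lines[!startsWith(lines, "#")]
    parts <- strsplit(hdr, "\t", fixed = TRUE)
    prim <- parts[vapply(parts, `[[`, character(1L), 1L) == "#primer"]
    tags <- parts[vapply(parts, `[[`, character(1L), 1L) == "#tag"]
    getPrimer <- function(which) {
        p <- Filter(function(z) z[2L] == which, prim)
        if (length(p) && length(p[[1L]]) >= 3L) p[[1L]][3L] else ""
    }
    getTags <- function(which) {
        t <- Filter(function(z) z[2L] == which, tags)
        stats::setNames(vapply(t, `[[`, character(1L), 4L),
                        vapply(t, `[[`, character(1L), 3L))
    }
    fwT <- getTags("fw"); rvT <- getTags("rv")
    tab <- utils::read.table(text = body, header = TRUE, sep = "\t",
                             colClasses = "character")
    assignments <- data.frame(
        sample_id = tab$sample_id,
        fw_index = match(tab$fw_seq, fwT),
        rv_index = match(tab$rv_seq, rvT),
        stringsAsFactors = FALSE)
    allCells <- expand.grid(fw_index = seq_along(fwT),
                            rv_index = seq_along(rvT))
    unused <- allCells[!paste(allCells$fw_index, allCells$rv_index) %in%
                           paste(assignments$fw_index, assignments$rv_index),
                       , drop = FALSE]
    rownames(unused) <- NULL
    new("TagScheme", fwTags = fwT, rvTags = rvT,
        fwPrimer = getPrimer("fw"), rvPrimer = getPrimer("rv"),
        assignments = assignments, unused = unused)
}
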