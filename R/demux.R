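#' Merge read pairs by their best ungapped overlap
#'
#' Aligns each forward read against the reverse complement of its mate over
#' all ungapped offsets and merges at the longest overlap whose mismatch
#' fraction is at most `maxMismatchFrac`. Disagreements inside the overlap
#' resolve to the higher-quality base when qualities are given, else to
#' `N`; `N` never counts as a mismatch. Pairs with no acceptable overlap
#' are kept with `NA` sequence (a counted failure, not an error).
#'
#' @param r1,r2 Character vectors (or `DNAStringSet`s) of equal length:
#'   forward and reverse reads, both 5'->3' as sequenced.
#' @param minOverlap Minimum acceptable overlap in bases (default 10; the
#'   published read filter of >= 100 bp overlap is applied afterwards by
#'   [filterMerged()]).
#' @param maxMismatchFrac Maximum mismatch fraction inside the overlap
#'   (default 0.1).
#' @param q1,q2 Optional per-base quality strings (same layout as the
#'   reads).
#' @return A [S4Vectors::DataFrame] with columns `id`, `sequence` (`NA` on
#'   failure) and `overlap`.
#' @examples
#' mergePairs("AAAACCCC", revComp("CCCCGGGG"), minOverlap = 4)
#' @export
mergePairs <- function(r1, r2, minOverlap = 10L, maxMismatchFrac = 0.1,
                       q1 = NULL, q2 = NULL) {
    if (is(r1, "XStringSet")) r1 <- as.character(r1)
    if (is(r2, "XStringSet")) r2 <- as.character(r2)
    ids <- names(r1)
    if (is.null(ids)) ids <- sprintf("read%d", seq_along(r1))
    if (length(r1) != length(r2)) stop("r1 and r2 must pair up")
    r1 <- toupper(r1); r2 <- toupper(r2)
    if (any(grepl("[^ACGTN]", c(r1, r2))))
        stop("reads must be over the ACGTN alphabet")
    r2rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(r2)))
    if (!is.null(q1) && !is.null(q2)) {
        q2rc <- vapply(strsplit(q2, "", fixed = TRUE),
                       function(z) paste(rev(z), collapse = ""),
                       character(1L))
    } else {
        q1 <- character(0); q2rc <- character(0)
    }
    res <- .merge_pairs_cpp(r1, r2rc, as.integer(minOverlap),
                            as.numeric(maxMismatchFrac), q1, q2rc)
    S4Vectors::DataFrame(id = ids, sequence = res$sequence,
                         overlap = res$overlap)
}

#' Partition merged reads by the length and overlap filters
#'
#' Applies the assembled-read filters: reads shorter than `minLength` or
#' with an overlap below `minOverlap` are removed (strict less-than, so
#' boundary values are kept: a 300-bp read with a 100-bp overlap passes).
#' Failed merges (`NA` sequence) are binned `merge_failed`.
#'
#' @param merged Output of [mergePairs()], or any data.frame-like with
#'   `sequence` and `overlap` columns.
#' @param minLength Minimum merged length in bp (default 300).
#' @param minOverlap Minimum overlap in bp (default 100).
#' @return The input with an added factor column `bin` in
#'   `{kept, too_short, low_overlap, merge_failed}`; length is tested
#'   before overlap.
#' @export
filterMerged <- function(merged, minLength = 300L, minOverlap = 100L) {
    len <- ifelse(is.na(merged$sequence), NA_integer_, nchar(merged$sequence))
    bin <- rep("kept", nrow(merged))
    bin[!is.na(merged$overlap) & merged$overlap < minOverlap] <- "low_overlap"
    bin[!is.na(len) & len < minLength] <- "too_short"
    bin[is.na(merged$sequence)] <- "merge_failed"
    merged$bin <- factor(bin, levels = c("kept", "too_short", "low_overlap",
                                         "merge_failed"))
    merged
}

# is every read position compatible with the (possibly degenerate) primer?
# reads: character vector of primer-length strings
.primerCompat <- function(reads, primer) {
    pm <- .IUPAC_MASK[.oligoChars(primer)]
    ok <- rep(TRUE, length(reads))
    idx <- which(!is.na(reads) & nchar(reads) == length(pm))
    if (!length(idx)) return(ok & !is.na(reads) & nchar(reads) == length(pm))
    chars <- do.call(rbind, strsplit(reads[idx], "", fixed = TRUE))
    rm <- matrix(.IUPAC_MASK[chars], nrow = length(idx))
    pmMat <- matrix(pm, nrow = length(idx), ncol = length(pm), byrow = TRUE)
    mismatch <- matrix(bitwAnd(rm, pmMat) == 0L, nrow = length(idx))
    comp <- rowSums(mismatch) == 0L
    comp[is.na(comp)] <- FALSE
    out <- rep(FALSE, length(reads))
    out[idx] <- comp
    out
}

# one-orientation exact tag detection; returns fw/rv grid indices (NA when
# a tag or primer is not found) and the trimmed insert
.findTags <- function(seqs, scheme) {
    L <- nchar(scheme@fwTags[1L])
    fwLen <- L + nchar(scheme@fwPrimer)
    rvLen <- L + nchar(scheme@rvPrimer)
    n <- nchar(seqs)
    long <- n >= fwLen + rvLen
    fwBar <- substr(seqs, 1L, L)
    fwIdx <- match(fwBar, scheme@fwTags)
    fwPrimerOk <- if (nchar(scheme@fwPrimer))
        .primerCompat(substr(seqs, L + 1L, fwLen), scheme@fwPrimer)
    else rep(TRUE, length(seqs))
    tail <- substr(seqs, n - rvLen + 1L, n)
    tailRc <- rep(NA_character_, length(seqs))
    ok <- long & !is.na(tail) & nchar(tail) == rvLen
    if (any(ok))
        tailRc[ok] <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(tail[ok])))
    rvBar <- substr(tailRc, 1L, L)
    rvIdx <- match(rvBar, scheme@rvTags)
    rvPrimerOk <- if (nchar(scheme@rvPrimer))
        .primerCompat(substr(tailRc, L + 1L, rvLen), scheme@rvPrimer)
    else rep(TRUE, length(seqs))
    fwIdx[!long | !fwPrimerOk] <- NA_integer_
    rvIdx[!long | !rvPrimerOk] <- NA_integer_
    list(fw = fwIdx, rv = rvIdx,
         insert = substr(seqs, fwLen + 1L, n - rvLen))
}

#' Exact tag detection and sample assignment
#'
#' Classifies merged reads by exact dual-tag matching: the 5' end of a read
#' must equal a forward barcode followed by the forward primer, and its 3'
#' end the reverse complement of a reverse barcode plus primer. Barcode
#' positions are matched literally (no mismatch, no ambiguity); degenerate
#' primer positions match any IUPAC-compatible base. Reads failing in
#' forward orientation are retried reverse-complemented. A read whose two
#' tags form an assigned grid cell goes to that sample with tags and
#' primers trimmed; valid tags forming an unused cell are binned `mistag`
#' (a tag-jumping product); anything else is `unassigned`.
#'
#' @param seqs Character vector (or `DNAStringSet`) of merged reads.
#' @param scheme A [TagScheme-class] carrying tags and primers.
#' @return A [S4Vectors::DataFrame] with columns `sample_id` (`NA` unless
#'   assigned), `bin` (`assigned`/`mistag`/`unassigned`) and `insert` (the
#'   trimmed read, `NA` unless assigned).
#' @export
matchTags <- function(seqs, scheme) {
    validObject(scheme)
    if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
    seqs <- toupper(seqs)
    hit <- .findTags(seqs, scheme)
    retry <- is.na(hit$fw) | is.na(hit$rv)
    if (any(retry)) {
        rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(seqs[retry])))
        hit2 <- .findTags(rc, scheme)
        for (f in c("fw", "rv", "insert"))
            hit[[f]][retry] <- hit2[[f]]
    }
    a <- scheme@assignments
    cellKey <- paste(hit$fw, hit$rv)
    sampleAt <- a$sample_id[match(cellKey, paste(a$fw_index, a$rv_index))]
    bothFound <- !is.na(hit$fw) & !is.na(hit$rv)
    bin <- rep("unassigned", length(seqs))
    bin[bothFound & !is.na(sampleAt)] <- "assigned"
    bin[bothFound & is.na(sampleAt)] <- "mistag"
    S4Vectors::DataFrame(
        sample_id = ifelse(bin == "assigned", sampleAt, NA_character_),
        bin = factor(bin, levels = c("assigned", "mistag", "unassigned")),
        insert = ifelse(bin == "assigned", hit$insert, NA_character_))
}

#' Demultiplex a run of merged reads
#'
#' Full post-merge pipeline: length/overlap filtering ([filterMerged()]),
#' exact tag matching ([matchTags()]), per-sample read binning and a counts
#' table. Every input read lands in exactly one bin
#' (`assigned`, `mistag`, `unassigned`, `too_short`, `low_overlap`,
#' `merge_failed`).
#'
#' @param merged Output of [mergePairs()] (or a DataFrame with `id`,
#'   `sequence`, `overlap`).
#' @param scheme A [TagScheme-class].
#' @param minLength,minOverlap Filter thresholds, see [filterMerged()].
#' @return A list of class `DemuxResult`: `reads` (per-read DataFrame with
#'   `bin`, `sample_id`, `insert`), `sampleCounts` (named integer of
#'   assigned reads per sample, zero-filled), `binCounts` (reads per bin)
#'   and `samples` (list of per-sample insert vectors, named by read id).
#' @export
demuxRun <- function(merged, scheme, minLength = 300L, minOverlap = 100L) {
    flt <- filterMerged(merged, minLength, minOverlap)
    keep <- flt$bin == "kept"
    cls <- S4Vectors::DataFrame(
        sample_id = rep(NA_character_, nrow(flt)),
        bin = factor(rep(NA_character_, nrow(flt)),
                     levels = c("assigned", "mistag", "unassigned",
                                "too_short", "low_overlap", "merge_failed")),
        insert = rep(NA_character_, nrow(flt)))
    cls$bin[!keep] <- as.character(flt$bin[!keep])
    if (any(keep)) {
        m <- matchTags(flt$sequence[keep], scheme)
        cls$sample_id[keep] <- m$sample_id
        cls$bin[keep] <- as.character(m$bin)
        cls$insert[keep] <- m$insert
    }
    cls$id <- flt$id
    sampleIds <- scheme@assignments$sample_id
    sampleCounts <- table(factor(cls$sample_id, levels = sampleIds))
    assigned <- !is.na(cls$sample_id)
    samples <- split(stats::setNames(cls$insert[assigned], cls$id[assigned]),
                     factor(cls$sample_id[assigned], levels = sampleIds))
    structure(list(reads = cls,
                   sampleCounts = stats::setNames(as.integer(sampleCounts),
                                                  names(sampleCounts)),
                   binCounts = table(cls$bin),
                   samples = samples),
              class = "DemuxResult")
}

#' @export
print.DemuxResult <- function(x, ...) {
    cat("DemuxResult:", nrow(x$reads), "reads\n")
    print(x$binCounts)
    invisible(x)
}

#' Canonical read identifier
#'
#' Builds the deterministic identifier `{sample}_{year}_{G|F}_{serial}`
#' used when sorted reads are renamed by sample, sampling year and
#' ecosystem (`G` grassland, `F` forest).
#'
#' @param sampleId Sample code (e.g. `"AEG01"`).
#' @param year Sampling year.
#' @param ecosystem `"G"` or `"F"`.
#' @param serial Integer serial, unique within the sample.
#' @return Character identifier(s).
#' @examples
#' renameRead("AEG01", 2011, "G", 7)
#' @export
renameRead <- function(sampleId, year, ecosystem, serial) {
    if (!all(ecosystem %in% c("G", "F")))
        stop("ecosystem must be 'G' (grassland) or 'F' (forest)")
    sprintf("%s_%d_%s_%d", sampleId, as.integer(year), ecosystem,
            as.integer(serial))
}

#' Drop samples with insufficient sequencing yield
#'
#' Removes samples with fewer than `minReads` assigned reads (strict
#' less-than: a sample at exactly the threshold is kept).
#'
#' @param counts Named numeric/integer vector of reads per sample.
#' @param minReads Yield threshold (default 10000).
#' @return Named vector restricted to the retained samples.
#' @examples
#' dropLowYield(c(A = 9999, B = 10000, C = 50000))
#' @export
dropLowYield <- function(counts, minReads = 10000L) {
    counts[counts >= minReads]
}
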