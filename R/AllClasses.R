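#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment assay assayNames rowData rowData<- colData
NULL

## ---------------------------------------------------------------- constraints

#' DesignConstraints: the barcode constraint chain
#'
#' Holds every threshold of the barcode design filter chain: length,
#' composition balance, homopolymer limit, hairpin/heteroduplex thresholds
#' for the barcode attached 5' of its primer, the template-flank screen, and
#' the minimum pairwise distance between barcodes. Defaults reproduce the
#' published study design (8-nt barcodes, >= 3 base differences); the
#' structure thresholds follow common primer-QC practice and are all
#' adjustable.
#'
#' @slot barcodeLength integer, barcode length in nt (default 8).
#' @slot minPairwiseDistance integer, minimum Hamming distance between any
#'   two barcodes of a set (default 3).
#' @slot maxHomopolymerRun integer, longest allowed single-base run
#'   (default 2, i.e. "no homopolymers").
#' @slot baseCountMin,baseCountMax integer, allowed count of each of
#'   A/C/G/T per barcode (defaults 1 and 3 for an 8-mer: balanced content).
#' @slot gcMin,gcMax numeric, allowed GC fraction (defaults 0.375/0.625).
#' @slot hairpinStemMin,hairpinLoopMin integer, hairpin screen thresholds
#'   applied to barcode+primer (defaults 4 and 3).
#' @slot duplexMaxRun integer, reject when a complementary run of at least
#'   this length exists (default 6).
#' @slot duplexThreePrimeRun integer, reject when a 3'-anchored
#'   complementary run of at least this length exists (default 4).
#' @slot flankMatchMax integer, maximum IUPAC-compatible matches of a
#'   barcode at any offset along the flanking consensus (default 5 of 8).
#' @slot flankWindow integer, bases of template consensus adjacent to the
#'   primer site screened against (default 20).
#' @export
setClass("DesignConstraints", representation(
    barcodeLength = "integer",
    minPairwiseDistance = "integer",
    maxHomopolymerRun = "integer",
    baseCountMin = "integer",
    baseCountMax = "integer",
    gcMin = "numeric",
    gcMax = "numeric",
    hairpinStemMin = "integer",
    hairpinLoopMin = "integer",
    duplexMaxRun = "integer",
    duplexThreePrimeRun = "integer",
    flankMatchMax = "integer",
    flankWindow = "integer"
))

setValidity("DesignConstraints", function(object) {
    msg <- character()
    if (object@minPairwiseDistance < 1L)
        msg <- c(msg, "minPairwiseDistance must be >= 1")
    if (object@barcodeLength < object@minPairwiseDistance)
        msg <- c(msg, "barcodeLength must be >= minPairwiseDistance")
    pos <- c(object@maxHomopolymerRun, object@hairpinStemMin,
             object@hairpinLoopMin, object@duplexMaxRun,
             object@duplexThreePrimeRun, object@flankWindow)
    if (any(pos < 1L))
        msg <- c(msg, "all thresholds must be positive")
    if (object@baseCountMin < 0L || object@baseCountMax < object@baseCountMin)
        msg <- c(msg, "need 0 <= baseCountMin <= baseCountMax")
    if (object@gcMin < 0 || object@gcMax > 1 || object@gcMin > object@gcMax)
        msg <- c(msg, "need 0 <= gcMin <= gcMax <= 1")
    if (object@flankMatchMax < 0L)
        msg <- c(msg, "flankMatchMax must be >= 0")
    if (length(msg)) msg else TRUE
})

#' @describeIn DesignConstraints-class Constructor with study defaults.
#' @param barcodeLength,minPairwiseDistance,maxHomopolymerRun Integers, see
#'   slots.
#' @param baseCountMin,baseCountMax,gcMin,gcMax Composition bounds.
#' @param hairpinStemMin,hairpinLoopMin,duplexMaxRun,duplexThreePrimeRun
#'   Structure-screen thresholds.
#' @param flankMatchMax,flankWindow Flank-screen parameters.
#' @export
designConstraints <- function(barcodeLength = 8L,
                              minPairwiseDistance = 3L,
                              maxHomopolymerRun = 2L,
                              baseCountMin = 1L,
                              baseCountMax = 3L,
                              gcMin = 0.375,
                              gcMax = 0.625,
                              hairpinStemMin = 4L,
                              hairpinLoopMin = 3L,
                              duplexMaxRun = 6L,
                              duplexThreePrimeRun = 4L,
                              flankMatchMax = 5L,
                              flankWindow = 20L) {
    new("DesignConstraints",
        barcodeLength = as.integer(barcodeLength),
        minPairwiseDistance = as.integer(minPairwiseDistance),
        maxHomopolymerRun = as.integer(maxHomopolymerRun),
        baseCountMin = as.integer(baseCountMin),
        baseCountMax = as.integer(baseCountMax),
        gcMin = as.numeric(gcMin),
        gcMax = as.numeric(gcMax),
        hairpinStemMin = as.integer(hairpinStemMin),
        hairpinLoopMin = as.integer(hairpinLoopMin),
        duplexMaxRun = as.integer(duplexMaxRun),
        duplexThreePrimeRun = as.integer(duplexThreePrimeRun),
        flankMatchMax = as.integer(flankMatchMax),
        flankWindow = as.integer(flankWindow))
}

setMethod("show", "DesignConstraints", function(object) {
    cat("DesignConstraints:",
        sprintf("%d-nt barcodes, pairwise Hamming >= %d",
                object@barcodeLength, object@minPairwiseDistance), "\n")
    cat("  composition: each base in [", object@baseCountMin, ",",
        object@baseCountMax, "], GC in [", object@gcMin, ",",
        object@gcMax, "], homopolymer <= ", object@maxHomopolymerRun,
        "\n", sep = "")
    cat("  structure: hairpin stem>=", object@hairpinStemMin, "/loop>=",
        object@hairpinLoopMin, "; duplex reject run>=", object@duplexMaxRun,
        " or 3'-run>=", object@duplexThreePrimeRun, "\n", sep = "")
    cat("  flank: window ", object@flankWindow, " nt, reject > ",
        object@flankMatchMax, " compatible matches\n", sep = "")
})

## ----------------------------------------------------------------- BarcodeSet

#' BarcodeSet: a validated set of sample barcodes for one primer
#'
#' An ordered collection of equal-length ACGT-only barcodes designed for
#' (and screened against) one attached primer, together with the
#' constraints that produced it and a per-barcode audit of every filter
#' outcome. Structural invariants (alphabet, equal length, distinctness,
#' minimum pairwise Hamming distance) are enforced by the class validity;
#' [validateBarcodeSet()] re-checks the full constraint chain
#' independently.
#'
#' @slot barcodes Named character vector of ACGT barcodes.
#' @slot attachedPrimer Character, the primer the barcodes are appended to
#'   (5' of the primer).
#' @slot orientation `"forward"` or `"reverse"`.
#' @slot constraints A [DesignConstraints-class] object.
#' @slot audit A [S4Vectors::DataFrame] with one row per barcode recording
#'   each screen outcome.
#' @export
setClass("BarcodeSet", representation(
    barcodes = "character",
    attachedPrimer = "character",
    orientation = "character",
    constraints = "DesignConstraints",
    audit = "DataFrame"
))

setValidity("BarcodeSet", function(object) {
    b <- object@barcodes
    msg <- character()
    if (!length(b)) msg <- c(msg, "no barcodes")
    if (anyDuplicated(b)) msg <- c(msg, "duplicated barcodes")
    if (length(unique(nchar(b))) > 1L) msg <- c(msg, "unequal barcode lengths")
    if (any(grepl("[^ACGT]", b))) msg <- c(msg, "barcodes must be ACGT-only")
    if (!object@orientation %in% c("forward", "reverse"))
        msg <- c(msg, "orientation must be 'forward' or 'reverse'")
    if (length(b) >= 2L && !length(msg)) {
        d <- .hammingMatrix(b)
        if (min(d[upper.tri(d)]) < object@constraints@minPairwiseDistance)
            msg <- c(msg, sprintf(
                "minimum pairwise distance %d below required %d",
                min(d[upper.tri(d)]), object@constraints@minPairwiseDistance))
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn BarcodeSet-class Constructor.
#' @param barcodes Character vector of ACGT barcodes (names optional;
#'   defaults to `bc01`, `bc02`, ...).
#' @param attachedPrimer IUPAC primer string.
#' @param orientation `"forward"` or `"reverse"`.
#' @param constraints [DesignConstraints-class] used to build the set.
#' @param audit Optional per-barcode audit `DataFrame`.
#' @export
BarcodeSet <- function(barcodes, attachedPrimer,
                       orientation = c("forward", "reverse"),
                       constraints = designConstraints(),
                       audit = NULL) {
    orientation <- match.arg(orientation)
    barcodes <- .checkOligo(barcodes, "barcode")
    if (is.null(names(barcodes)) || anyNA(names(barcodes)))
        names(barcodes) <- sprintf("%s%02d",
                                   if (orientation == "forward") "F" else "R",
                                   seq_along(barcodes))
    if (is.null(audit))
        audit <- S4Vectors::DataFrame(row.names = names(barcodes))
    new("BarcodeSet",
        barcodes = barcodes,
        attachedPrimer = .checkOligo(attachedPrimer, "primer"),
        orientation = orientation,
        constraints = constraints,
        audit = audit)
}

setMethod("show", "BarcodeSet", function(object) {
    cat("BarcodeSet of", length(object@barcodes), object@orientation,
        sprintf("%d-nt barcodes", unique(nchar(object@barcodes))[1L]),
        "for primer", object@attachedPrimer, "\n")
    n <- min(4L, length(object@barcodes))
    cat("  ", paste(sprintf("%s=%s", names(object@barcodes)[seq_len(n)],
                            object@barcodes[seq_len(n)]), collapse = " "),
        if (length(object@barcodes) > n) "..." else "", "\n")
})

#' @describeIn BarcodeSet-class Number of barcodes in the set.
#' @param x A `BarcodeSet`.
#' @export
setMethod("length", "BarcodeSet", function(x) length(x@barcodes))

#' Accessors for BarcodeSet
#'
#' @param x A [BarcodeSet-class].
#' @return `barcodeSeqs()` the named barcode vector; `attachedPrimer()` the
#'   primer string; `tagOrientation()` `"forward"`/`"reverse"`;
#'   `designAudit()` the per-barcode audit table;
#'   `designConstraintsOf()` the [DesignConstraints-class].
#' @name BarcodeSet-accessors
NULL

#' @rdname BarcodeSet-accessors
#' @export
barcodeSeqs <- function(x) x@barcodes

#' @rdname BarcodeSet-accessors
#' @export
attachedPrimer <- function(x) x@attachedPrimer

#' @rdname BarcodeSet-accessors
#' @export
tagOrientation <- function(x) x@orientation

#' @rdname BarcodeSet-accessors
#' @export
designAudit <- function(x) x@audit

#' @rdname BarcodeSet-accessors
#' @export
designConstraintsOf <- function(x) x@constraints

#' Barcode+primer concatenations of a set
#'
#' The tagged oligos actually synthesised: each barcode appended to the 5'
#' end of its primer.
#'
#' @param x A [BarcodeSet-class].
#' @return Named character vector `barcode + primer`.
#' @export
taggedOligos <- function(x) {
    stats::setNames(paste0(x@barcodes, x@attachedPrimer), names(x@barcodes))
}

## ------------------------------------------------------------------ TagScheme

#' TagScheme: sample labeling over the forward x reverse tag grid
#'
#' Maps each sample to one (forward barcode, reverse barcode) cell of the
#' F x R combination grid; the remaining cells are deliberately left unused
#' so that tag-jumping (mistagging) products become observable when they
#' land there.
#'
#' @slot fwTags,rvTags Named character vectors of barcode sequences.
#' @slot fwPrimer,rvPrimer The primers the tags are attached to.
#' @slot assignments `data.frame` with columns `sample_id`, `fw_index`,
#'   `rv_index` (1-based grid indices).
#' @slot unused `data.frame` with columns `fw_index`, `rv_index` listing
#'   unassigned grid cells.
#' @export
setClass("TagScheme", representation(
    fwTags = "character",
    rvTags = "character",
    fwPrimer = "character",
    rvPrimer = "character",
    assignments = "data.frame",
    unused = "data.frame"
))

setValidity("TagScheme", function(object) {
    msg <- character()
    a <- object@assignments
    Fn <- length(object@fwTags); Rn <- length(object@rvTags)
    if (!all(c("sample_id", "fw_index", "rv_index") %in% names(a)))
        return("assignments must have sample_id, fw_index, rv_index")
    if (anyDuplicated(a$sample_id)) msg <- c(msg, "duplicate sample ids")
    key <- paste(a$fw_index, a$rv_index)
    if (anyDuplicated(key)) msg <- c(msg, "two samples share a grid cell")
    if (nrow(a) && (max(a$fw_index) > Fn || max(a$rv_index) > Rn ||
                    min(a$fw_index) < 1L || min(a$rv_index) < 1L))
        msg <- c(msg, "grid indices out of range")
    if (nrow(a) + nrow(object@unused) != Fn * Rn)
        msg <- c(msg, "assigned + unused cells must tile the full grid")
    if (length(intersect(key, paste(object@unused$fw_index,
                                    object@unused$rv_index))))
        msg <- c(msg, "a cell is both assigned and unused")
    if (length(msg)) msg else TRUE
})

setMethod("show", "TagScheme", function(object) {
    cat(sprintf(
        "TagScheme: %d x %d grid (%d cells), %d samples assigned, %d unused\n",
        length(object@fwTags), length(object@rvTags),
        length(object@fwTags) * length(object@rvTags),
        nrow(object@assignments), nrow(object@unused)))
    cat(sprintf("  mistag exposure: %.3f\n", mistagExposure(object)))
})

#' Accessors for TagScheme
#'
#' @param x A [TagScheme-class].
#' @return `fwTags()`/`rvTags()` named tag vectors; `schemeAssignments()`
#'   the sample-to-cell table; `unusedCombinations()` the unused cells.
#' @name TagScheme-accessors
NULL

#' @rdname TagScheme-accessors
#' @export
fwTags <- function(x) x@fwTags

#' @rdname TagScheme-accessors
#' @export
rvTags <- function(x) x@rvTags

#' @rdname TagScheme-accessors
#' @export
schemeAssignments <- function(x) x@assignments

#' @rdname TagScheme-accessors
#' @export
unusedCombinations <- function(x) x@unused

## ------------------------------------------------------------------- OtuTable

#' OtuTable: OTU x sample abundances with taxonomy and traits
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose `counts` assay holds
#' non-negative integer OTU x sample read counts; `rowData` carries the
#' per-OTU taxonomy (best BLAST hit, identity, e-value, rank columns) and,
#' after [annotateTraits()], the functional traits (nutrition, morphology,
#' locomotion); `colData` carries sample metadata (ecosystem `G`/`F`,
#' region, year).
#'
#' @export
setClass("OtuTable", contains = "SummarizedExperiment")

setValidity("OtuTable", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("OtuTable requires a 'counts' assay")
    m <- SummarizedExperiment::assay(object, "counts")
    if (any(m < 0) || anyNA(m)) msg <- c(msg, "counts must be non-negative")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "OTU ids must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be present and unique")
    if (length(msg)) msg else TRUE
})

#' @describeIn OtuTable-class Constructor.
#' @param counts Integer matrix, OTUs in rows, samples in columns.
#' @param taxonomy Optional `DataFrame`/`data.frame` of per-OTU annotation
#'   (row-matched to `counts`).
#' @param sampleData Optional `DataFrame`/`data.frame` of per-sample
#'   metadata.
#' @export
OtuTable <- function(counts, taxonomy = NULL, sampleData = NULL) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        rownames(counts) <- sprintf("OTU%04d", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- sprintf("S%03d", seq_len(ncol(counts)))
    rd <- if (is.null(taxonomy)) S4Vectors::DataFrame(row.names = rownames(counts))
          else S4Vectors::DataFrame(taxonomy, row.names = rownames(counts))
    cd <- if (is.null(sampleData)) S4Vectors::DataFrame(row.names = colnames(counts))
          else S4Vectors::DataFrame(sampleData, row.names = colnames(counts))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), rowData = rd, colData = cd)
    new("OtuTable", se)
}

setMethod("show", "OtuTable", function(object) {
    m <- SummarizedExperiment::assay(object, "counts")
    cat(sprintf("OtuTable: %d OTUs x %d samples, %s reads\n",
                nrow(m), ncol(m), format(sum(m), big.mark = ",")))
    rd <- names(SummarizedExperiment::rowData(object))
    if (length(rd)) cat("  rowData:", paste(rd, collapse = ", "), "\n")
    cd <- names(SummarizedExperiment::colData(object))
    if (length(cd)) cat("  colData:", paste(cd, collapse = ", "), "\n")
})

#' @describeIn OtuTable-class Extract the counts assay.
#' @param x An `OtuTable`.
#' @export
otuCounts <- function(x) SummarizedExperiment::assay(x, "counts")
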