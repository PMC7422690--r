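#' Write a barcode set as FASTA and TSV
#'
#' The FASTA holds the bare barcodes; the TSV adds orientation, the tagged
#' oligo (barcode+primer) and the per-barcode audit columns.
#'
#' @param x A [BarcodeSet-class].
#' @param fastaPath,tsvPath Output paths (either may be `NULL` to skip).
#' @return Invisibly, a list of the written paths.
#' @export
writeBarcodeSet <- function(x, fastaPath = NULL, tsvPath = NULL) {
    validObject(x)
    if (!is.null(fastaPath)) {
        Biostrings::writeXStringSet(
            Biostrings::DNAStringSet(barcodeSeqs(x)), fastaPath)
    }
    if (!is.null(tsvPath)) {
        tab <- data.frame(name = names(barcodeSeqs(x)),
                          sequence = unname(barcodeSeqs(x)),
                          orientation = tagOrientation(x),
                          tagged_oligo = unname(taggedOligos(x)),
                          as.data.frame(designAudit(x)),
                          stringsAsFactors = FALSE)
        utils::write.table(tab, tsvPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(list(fasta = fastaPath, tsv = tsvPath))
}

#' Write a demultiplexing report as JSON
#'
#' Bin counts, per-sample assigned-read counts and the thresholds used,
#' in a machine-readable report.
#'
#' @param res A `DemuxResult` from [demuxRun()].
#' @param path Output JSON path.
#' @param minLength,minOverlap,minYield Thresholds to record.
#' @return `path`, invisibly.
#' @export
writeDemuxReport <- function(res, path, minLength = 300L,
                             minOverlap = 100L, minYield = 10000L) {
    stopifnot(inherits(res, "DemuxResult"))
    report <- list(
        n_reads = nrow(res$reads),
        bins = as.list(stats::setNames(as.integer(res$binCounts),
                                       names(res$binCounts))),
        sample_counts = as.list(res$sampleCounts),
        thresholds = list(min_length = minLength, min_overlap = minOverlap,
                          min_yield = minYield))
    jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE)
    invisible(path)
}

#' Read and write OTU tables as TSV
#'
#' The counts TSV has OTUs in rows and samples in columns; optional
#' sidecar TSVs carry the per-OTU taxonomy/trait annotation (row key
#' `otu_id`) and the per-sample metadata (row key `sample_id`).
#'
#' @param countsPath Counts TSV (first column = OTU id).
#' @param taxonomyPath,samplesPath Optional sidecar TSVs.
#' @return An [OtuTable-class].
#' @export
readOtuTable <- function(countsPath, taxonomyPath = NULL,
                         samplesPath = NULL) {
    counts <- utils::read.delim(countsPath, row.names = 1L,
                                check.names = FALSE)
    taxonomy <- if (!is.null(taxonomyPath)) {
        tax <- utils::read.delim(taxonomyPath, row.names = 1L,
                                 check.names = FALSE)
        tax[rownames(counts), , drop = FALSE]
    }
    samples <- if (!is.null(samplesPath)) {
        sm <- utils::read.delim(samplesPath, row.names = 1L,
                                check.names = FALSE)
        sm[colnames(counts), , drop = FALSE]
    }
    OtuTable(as.matrix(counts), taxonomy = taxonomy, sampleData = samples)
}

#' @rdname readOtuTable
#' @param x An [OtuTable-class].
#' @export
writeOtuTable <- function(x, countsPath, taxonomyPath = NULL,
                          samplesPath = NULL) {
    writeKeyed <- function(df, key, path) {
        out <- data.frame(rownames(df), as.data.frame(df),
                          check.names = FALSE, stringsAsFactors = FALSE)
        names(out)[1L] <- key
        utils::write.table(out, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    writeKeyed(as.data.frame(otuCounts(x)), "otu_id", countsPath)
    if (!is.null(taxonomyPath))
        writeKeyed(as.data.frame(SummarizedExperiment::rowData(x)),
                   "otu_id", taxonomyPath)
    if (!is.null(samplesPath))
        writeKeyed(as.data.frame(SummarizedExperiment::colData(x)),
                   "sample_id", samplesPath)
    invisible(countsPath)
}
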