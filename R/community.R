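#' Remove rare OTUs
#'
#' Drops OTUs whose dataset-wide read sum is below `thresholdFrac` of the
#' grand total (default 0.01%, the rare-cluster noise filter). Strict
#' less-than: an OTU exactly at the threshold is kept.
#'
#' @param x An [OtuTable-class].
#' @param thresholdFrac Fraction of the grand total (default `1e-4`).
#' @return The filtered [OtuTable-class].
#' @export
rareFilter <- function(x, thresholdFrac = 1e-4) {
    m <- otuCounts(x)
    total <- sum(m)
    if (total <= 0) stop("table has no reads")
    keep <- rowSums(m) >= thresholdFrac * total
    x[keep, ]
}

#' Parse tabular alignment results, keeping only the best hit
#'
#' Reads BLAST-style 12-column tabular output (qseqid, sseqid, pident,
#' length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#' bitscore) and keeps, per query, the row with the smallest e-value (ties
#' broken by highest identity, then first occurrence). Queries whose best
#' e-value exceeds `maxEvalue` are reported unassigned. Malformed rows are
#' skipped with a warning.
#'
#' @param hits Path to a tabular hit file, or a `data.frame` with at least
#'   `qseqid`, `sseqid`, `pident`, `evalue` columns.
#' @param maxEvalue E-value gate (default `1e-50`); best hits with
#'   `evalue <= maxEvalue` are assigned.
#' @return `data.frame` with one row per query: `qseqid`, `sseqid`,
#'   `pident`, `evalue`, `assigned` (logical).
#' @export
parseBestHits <- function(hits, maxEvalue = 1e-50) {
    cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore")
    if (is.character(hits) && length(hits) == 1L) {
        lines <- readLines(hits)
        lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
        parts <- strsplit(lines, "\t", fixed = TRUE)
        nf <- lengths(parts)
        bad <- nf < 12L
        if (any(bad)) {
            warning(sum(bad), " malformed row(s) skipped")
            parts <- parts[!bad]
        }
        hits <- as.data.frame(do.call(rbind, parts),
                              stringsAsFactors = FALSE)[, seq_len(12L)]
        names(hits) <- cols
        hits$pident <- suppressWarnings(as.numeric(hits$pident))
        hits$evalue <- suppressWarnings(as.numeric(hits$evalue))
        ok <- !is.na(hits$pident) & !is.na(hits$evalue)
        if (any(!ok)) {
            warning(sum(!ok), " row(s) with non-numeric fields skipped")
            hits <- hits[ok, , drop = FALSE]
        }
    }
    need <- c("qseqid", "sseqid", "pident", "evalue")
    if (!all(need %in% names(hits)))
        stop("hits must contain columns ", paste(need, collapse = ", "))
    ord <- order(hits$qseqid, hits$evalue, -hits$pident)
    hits <- hits[ord, , drop = FALSE]
    best <- hits[!duplicated(hits$qseqid), c("qseqid", "sseqid", "pident",
                                             "evalue"), drop = FALSE]
    best$assigned <- best$evalue <= maxEvalue
    rownames(best) <- NULL
    best
}

#' Remove non-target OTUs
#'
#' Keeps only OTUs whose taxonomy path contains one of the target phyla
#' (default the two targeted protist phyla, Cercozoa and Endomyxa); the
#' retained fraction is attached as attribute `retained_frac`.
#'
#' @param x An [OtuTable-class] whose `rowData` has a `phylum` column or a
#'   `taxonomy` path column.
#' @param targetPhyla Character vector of phyla to keep.
#' @return Filtered [OtuTable-class]; the retained fraction is recorded in
#'   `metadata(x)$retained_frac`.
#' @export
removeNonTarget <- function(x, targetPhyla = c("Cercozoa", "Endomyxa")) {
    rd <- SummarizedExperiment::rowData(x)
    if ("phylum" %in% names(rd)) {
        keep <- rd$phylum %in% targetPhyla
    } else if ("taxonomy" %in% names(rd)) {
        pat <- paste(targetPhyla, collapse = "|")
        keep <- grepl(pat, rd$taxonomy)
    } else {
        stop("rowData needs a 'phylum' or 'taxonomy' column")
    }
    keep[is.na(keep)] <- FALSE
    out <- x[keep, ]
    S4Vectors::metadata(out)$retained_frac <- mean(keep)
    out
}

.TRAIT_FACETS <- c("nutrition", "morphology", "locomotion")

.TRAIT_VOCAB <- list(
    nutrition = c("bacterivore", "eukaryvore", "omnivore", "plant parasite",
                  "hyperparasite of Oomycota", "autotroph", "unknown"),
    morphology = c("naked flagellate", "amoeboflagellate", "naked amoeba",
                   "testate-organic/agglutinated", "testate-siliceous",
                   "unknown"),
    locomotion = c("creeping/gliding", "swimming", "non-motile", "unknown"))

.TRAIT_RANKS <- c("species", "genus", "family", "order", "class")

#' Read and validate a functional-trait lookup table
#'
#' The trait table maps taxa (at any rank from species to class) to closed
#' vocabularies of nutrition (trophic guild), morphology and locomotion. A
#' value outside a vocabulary is an input error. A compact table covering
#' the common Cercozoa/Endomyxa lineages ships with the package under
#' `extdata/protist_traits.tsv`.
#'
#' @param path TSV with columns `taxon`, `rank`, `nutrition`, `morphology`,
#'   `locomotion`; or a `data.frame` with those columns.
#' @return Validated `data.frame`.
#' @examples
#' traits <- readTraitTable(system.file("extdata", "protist_traits.tsv",
#'                                      package = "ampliTags"))
#' head(traits)
#' @export
readTraitTable <- function(path) {
    tab <- if (is.data.frame(path)) path
           else utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("taxon", "rank", .TRAIT_FACETS)
    if (!all(need %in% names(tab)))
        stop("trait table must have columns ", paste(need, collapse = ", "))
    if (anyDuplicated(tab[, c("taxon", "rank")]))
        stop("duplicate (taxon, rank) keys in trait table")
    if (!all(tab$rank %in% .TRAIT_RANKS))
        stop("rank must be one of ", paste(.TRAIT_RANKS, collapse = ", "))
    for (f in .TRAIT_FACETS) {
        bad <- setdiff(unique(tab[[f]]), .TRAIT_VOCAB[[f]])
        if (length(bad))
            stop("value(s) outside the ", f, " vocabulary: ",
                 paste(bad, collapse = ", "))
    }
    tab
}

#' Annotate OTUs with functional traits
#'
#' Looks each OTU up in the trait table at the most specific matching rank
#' (species, then genus, family, order, class); OTUs with no match get
#' `unknown` in all three facets. The rank used is recorded in the
#' `trait_rank` column (`"none"` when unmatched); unknowns are never
#' imputed.
#'
#' @param x An [OtuTable-class] whose `rowData` carries any of the rank
#'   columns `species`, `genus`, `family`, `order`, `class`.
#' @param traits Trait table (path or `data.frame`), see
#'   [readTraitTable()].
#' @return The [OtuTable-class] with `nutrition`, `morphology`,
#'   `locomotion` and `trait_rank` added to `rowData`.
#' @export
annotateTraits <- function(x, traits) {
    traits <- readTraitTable(traits)
    rd <- SummarizedExperiment::rowData(x)
    n <- nrow(x)
    out <- data.frame(nutrition = rep("unknown", n),
                      morphology = rep("unknown", n),
                      locomotion = rep("unknown", n),
                      trait_rank = rep("none", n),
                      stringsAsFactors = FALSE)
    done <- rep(FALSE, n)
    for (rank in .TRAIT_RANKS) {
        if (!rank %in% names(rd)) next
        sub <- traits[traits$rank == rank, , drop = FALSE]
        hit <- match(as.character(rd[[rank]]), sub$taxon)
        take <- !done & !is.na(hit)
        if (!any(take)) next
        for (f in .TRAIT_FACETS) out[[f]][take] <- sub[[f]][hit[take]]
        out$trait_rank[take] <- rank
        done <- done | take
    }
    for (f in c(.TRAIT_FACETS, "trait_rank"))
        SummarizedExperiment::rowData(x)[[f]] <- out[[f]]
    x
}

#' Relative abundance of functional categories
#'
#' Summarises one trait facet as per-category percentages, overall and per
#' ecosystem stratum, under either weighting mode: `reads` weights each
#' OTU by its read counts, `otus` counts each OTU once (presence in the
#' stratum). Both modes are reported because published community summaries
#' use either convention; the mode is labeled in the output.
#'
#' @param x A trait-annotated [OtuTable-class] (see [annotateTraits()]).
#' @param facet `"nutrition"`, `"morphology"` or `"locomotion"`.
#' @param weight `"reads"` or `"otus"`.
#' @return `data.frame` with columns `stratum` (`all` plus each ecosystem
#'   value present), `category`, `percent`, `weight`; percentages sum to
#'   100 within each stratum.
#' @export
guildRelAbund <- function(x, facet = c("nutrition", "morphology",
                                       "locomotion"),
                          weight = c("reads", "otus")) {
    facet <- match.arg(facet)
    weight <- match.arg(weight)
    rd <- SummarizedExperiment::rowData(x)
    if (!facet %in% names(rd))
        stop("run annotateTraits() first: no '", facet, "' annotation")
    cats <- factor(rd[[facet]], levels = .TRAIT_VOCAB[[facet]])
    m <- otuCounts(x)
    cd <- SummarizedExperiment::colData(x)
    strata <- list(all = seq_len(ncol(m)))
    if ("ecosystem" %in% names(cd))
        for (e in sort(unique(as.character(cd$ecosystem))))
            strata[[e]] <- which(cd$ecosystem == e)
    res <- lapply(names(strata), function(s) {
        cols <- strata[[s]]
        w <- if (weight == "reads") rowSums(m[, cols, drop = FALSE])
             else as.numeric(rowSums(m[, cols, drop = FALSE]) > 0)
        tot <- sum(w)
        if (tot == 0) return(NULL)
        pct <- 100 * tapply(w, cats, sum, default = 0) / tot
        data.frame(stratum = s, category = names(pct),
                   percent = as.numeric(pct), weight = weight,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' Shared and unique OTUs across strata
#'
#' For a sample metadata field (e.g. ecosystem), counts OTUs present
#' (nonzero total) in every stratum value (`shared`) and OTUs present in
#' exactly one (`unique` per stratum).
#'
#' @param x An [OtuTable-class].
#' @param stratum Name of a `colData` column with at least 2 values.
#' @return A list: `shared` (integer), `unique` (named integer per
#'   stratum), `presentPerStratum` (OTUs present per stratum), `total`
#'   (OTUs in the table).
#' @export
sharingStats <- function(x, stratum = "ecosystem") {
    cd <- SummarizedExperiment::colData(x)
    if (!stratum %in% names(cd)) stop("no colData column '", stratum, "'")
    g <- as.character(cd[[stratum]])
    vals <- sort(unique(g))
    if (length(vals) < 2L) stop("stratum needs at least 2 values")
    m <- otuCounts(x)
    pres <- vapply(vals, function(v)
        rowSums(m[, g == v, drop = FALSE]) > 0, logical(nrow(m)))
    nPres <- rowSums(pres)
    uniq <- vapply(seq_along(vals), function(i)
        sum(pres[, i] & nPres == 1L), integer(1L))
    list(shared = sum(nPres == length(vals)),
         unique = stats::setNames(uniq, vals),
         presentPerStratum = stats::setNames(colSums(pres), vals),
         total = nrow(m))
}
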