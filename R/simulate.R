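#' @importFrom withr with_seed
NULL

# deterministic concretization of a degenerate primer: position p of copy s
# cycles through the expansion set, so every expansion base appears at a
# near-equal frequency across copies
.concretize <- function(primer, index) {
    ch <- .oligoChars(primer)
    vapply(seq_along(ch), function(p) {
        exp <- c("A", "C", "G", "T")[bitwAnd(.IUPAC_MASK[ch[p]],
                                             c(1L, 2L, 4L, 8L)) > 0L]
        exp[(index - 1L) %% length(exp) + 1L]
    }, character(1L))
}

#' Simulate a reference alignment with planted primer sites
#'
#' Generates an ungapped-by-default alignment whose consensus contains the
#' given primer at a given position: at the primer site each sequence
#' carries a concretization of the (possibly degenerate) primer that cycles
#' through the expansion sets, so the IUPAC consensus of the site
#' reproduces the primer exactly. Flanking columns copy a random backbone
#' base with probability `flankConservation` and mutate uniformly
#' otherwise.
#'
#' @param nSeqs Number of sequences (default 30).
#' @param length Alignment length in columns (default 120).
#' @param primer IUPAC primer string to plant.
#' @param primerStart 1-based column of the primer site.
#' @param flankConservation Probability that a flank column base matches
#'   the backbone (1 = perfectly conserved flanks; default 0.9).
#' @param seed Integer seed; same seed, identical output.
#' @return A list: `alignment` (named character vector), `primerStart`,
#'   `primerEnd`, `backbone` (the ungapped flank template).
#' @export
makeReferenceAlignment <- function(nSeqs = 30L, length = 120L, primer,
                                   primerStart = 51L,
                                   flankConservation = 0.9, seed = 1L) {
    primer <- .checkOligo(primer, "primer")
    pl <- nchar(primer)
    if (primerStart < 1L || primerStart + pl - 1L > length)
        stop("primer site outside the alignment")
    withr::with_seed(seed, {
        backbone <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
        seqs <- vapply(seq_len(nSeqs), function(s) {
            ch <- backbone
            mut <- stats::runif(length) > flankConservation
            ch[mut] <- sample(c("A", "C", "G", "T"), sum(mut),
                              replace = TRUE)
            ch[primerStart:(primerStart + pl - 1L)] <- .concretize(primer, s)
            paste(ch, collapse = "")
        }, character(1L))
    })
    names(seqs) <- sprintf("ref%03d", seq_len(nSeqs))
    list(alignment = seqs, primerStart = as.integer(primerStart),
         primerEnd = as.integer(primerStart + pl - 1L),
         backbone = paste(backbone, collapse = ""))
}

#' Simulate a dual-tagged amplicon run with ground truth
#'
#' Emulates the study's library layout: each read is a full amplicon
#' `fwTag + fwPrimer + insert + revcomp(rvTag + rvPrimer)` drawn from its
#' sample's OTU composition, split into a forward/reverse read pair of
#' `readLen` bases. A fraction `rhoMistag` of reads has one tag (forward
#' or reverse, equiprobably) swapped to another used tag of the same side
#' — the tag-jumping model — and a fraction `shortFrac` has its insert
#' truncated so the merged read falls below 300 bp. The manifest records
#' the per-read truth, so demultiplexing accuracy is exactly measurable.
#'
#' @param scheme A [TagScheme-class] with non-empty primers.
#' @param nReads Reads per sample: scalar or vector named by sample id.
#' @param nOtus Number of template OTU sequences (default 20).
#' @param composition Optional `nOtus x nSamples` matrix of per-sample OTU
#'   proportions (columns named by sample); default log-normal.
#' @param rhoMistag,shortFrac Noise rates in `[0, 1]` (defaults 0).
#' @param readLen Read length in bp (default 300, MiSeq v3).
#' @param insertRange Insert length range, bp (default `c(330, 370)`).
#' @param lognormalSigma Sigma of the default log-normal abundance model.
#' @param seed Integer seed; regeneration is deterministic.
#' @return A list of class `SimulatedRun`: `r1`, `r2` (named character
#'   read vectors), `manifest` (per-read `data.frame`: `id`, `sample`,
#'   `otu`, `mistag`, `mistag_observable`, `short`), `otuSeqs`,
#'   `params`.
#' @export
simulateRun <- function(scheme, nReads = 500L, nOtus = 20L,
                        composition = NULL, rhoMistag = 0, shortFrac = 0,
                        readLen = 300L, insertRange = c(330L, 370L),
                        lognormalSigma = 1, seed = 1L) {
    validObject(scheme)
    if (rhoMistag < 0 || rhoMistag > 1 || shortFrac < 0 || shortFrac > 1)
        stop("rates must be in [0, 1]")
    if (!nchar(scheme@fwPrimer) || !nchar(scheme@rvPrimer))
        stop("scheme must carry primers to build full amplicons")
    a <- scheme@assignments
    samples <- a$sample_id
    if (length(nReads) == 1L)
        nReads <- stats::setNames(rep(as.integer(nReads), length(samples)),
                                  samples)
    nReads <- nReads[samples]
    usedF <- unique(a$fw_index); usedR <- unique(a$rv_index)
    unusedKey <- paste(scheme@unused$fw_index, scheme@unused$rv_index)
    withr::with_seed(seed, {
        lens <- sample(insertRange[1L]:insertRange[2L], nOtus,
                       replace = TRUE)
        otuSeqs <- stats::setNames(
            vapply(lens, function(l)
                paste(sample(c("A", "C", "G", "T"), l, replace = TRUE),
                      collapse = ""), character(1L)),
            sprintf("OTU%03d", seq_len(nOtus)))
        if (is.null(composition)) {
            composition <- vapply(samples, function(s) {
                w <- stats::rlnorm(nOtus, 0, lognormalSigma)
                w / sum(w)
            }, numeric(nOtus))
            rownames(composition) <- names(otuSeqs)
        }
        rows <- lapply(seq_along(samples), function(si) {
            n <- nReads[si]
            if (n == 0L) return(NULL)
            data.frame(sample = samples[si],
                       fw = a$fw_index[si], rv = a$rv_index[si],
                       otu = sample(names(otuSeqs), n, replace = TRUE,
                                    prob = composition[, si]),
                       stringsAsFactors = FALSE)
        })
        man <- do.call(rbind, rows)
        nTot <- nrow(man)
        man$id <- sprintf("r%06d", seq_len(nTot))
        man$mistag <- stats::runif(nTot) < rhoMistag
        man$short <- stats::runif(nTot) < shortFrac
        # tag-jump: swap one tag to another *used* tag of the same side
        for (i in which(man$mistag)) {
            if (stats::runif(1) < 0.5 && length(usedF) > 1L) {
                man$fw[i] <- sample(setdiff(usedF, man$fw[i]), 1L)
            } else if (length(usedR) > 1L) {
                man$rv[i] <- sample(setdiff(usedR, man$rv[i]), 1L)
            }
        }
        man$mistag_observable <-
            paste(man$fw, man$rv) %in% unusedKey
        fwPrim <- vapply(seq_len(nTot), function(i)
            paste(.concretize(scheme@fwPrimer, i), collapse = ""),
            character(1L))
        rvPrim <- vapply(seq_len(nTot), function(i)
            paste(.concretize(scheme@rvPrimer, i), collapse = ""),
            character(1L))
        insert <- unname(otuSeqs[man$otu])
        if (any(man$short))
            insert[man$short] <- substr(insert[man$short], 1L, 150L)
        amplicon <- paste0(scheme@fwTags[man$fw], fwPrim, insert,
                           revComp(paste0(scheme@rvTags[man$rv], rvPrim)))
        alen <- nchar(amplicon)
        r1 <- substr(amplicon, 1L, pmin(readLen, alen))
        r2 <- revComp(substr(amplicon, pmax(1L, alen - readLen + 1L), alen))
    })
    names(r1) <- names(r2) <- man$id
    structure(list(r1 = r1, r2 = r2,
                   manifest = man[, c("id", "sample", "otu", "fw", "rv",
                                      "mistag", "mistag_observable",
                                      "short")],
                   otuSeqs = otuSeqs, composition = composition,
                   params = list(rhoMistag = rhoMistag,
                                 shortFrac = shortFrac, readLen = readLen,
                                 seed = seed)),
              class = "SimulatedRun")
}

#' @export
print.SimulatedRun <- function(x, ...) {
    cat("SimulatedRun:", length(x$r1), "read pairs,",
        length(x$otuSeqs), "OTUs,",
        sum(x$manifest$mistag), "mistagged,",
        sum(x$manifest$short), "shortened\n")
    invisible(x)
}

# largest-remainder allocation of n items to the given fractions
.allocate <- function(n, frac) {
    frac <- frac / sum(frac)
    raw <- n * frac
    base <- floor(raw)
    left <- n - sum(base)
    if (left > 0) {
        extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
        base[extra] <- base[extra] + 1L
    }
    as.integer(base)
}

# taxon pool used to annotate synthetic OTUs; lineages and guild structure
# reflect the targeted protist phyla
.SYNTH_TAXA <- data.frame(
    phylum = c("Cercozoa", "Cercozoa", "Cercozoa", "Cercozoa",
               "Cercozoa", "Endomyxa", "Endomyxa", "Endomyxa",
               "Endomyxa", "Endomyxa"),
    class = c("Sarcomonadea", "Sarcomonadea", "Imbricatea", "Thecofilosea",
              "Sarcomonadea", "Phytomyxea", "Phytomyxea", "Phytomyxea",
              "Proteomyxidea", "Proteomyxidea"),
    order = c("Glissomonadida", "Cercomonadida", "Euglyphida",
              "Cryomonadida", "Glissomonadida", "Plasmodiophorida",
              "Plasmodiophorida", "Plasmodiophorida", "Vampyrellida",
              "Vampyrellida"),
    genus = c("Sandona", "Cercomonas", "Euglypha", "Rhogostoma",
              "Neoheteromita", "Polymyxa", "Spongospora", "Woronina",
              "Vampyrella", "Leptophrys"),
    species = c(NA, NA, NA, NA, NA, "Polymyxa graminis",
                "Spongospora nasturtii", "Woronina pythii", NA, NA),
    stringsAsFactors = FALSE)

#' Simulate an OTU table with planted structure
#'
#' Builds an [OtuTable-class] with known ground truth: a `sharedFrac`
#' fraction of OTUs present in both ecosystems, the rest split 75/25
#' between grassland-only and forest-only; trophic guilds allocated to
#' OTUs by largest remainder from `guildMixture`; per-sample abundances
#' from a log-normal/multinomial model; optionally a `nontargetFrac`
#' fraction of OTUs annotated to non-target phyla. Presence structure is
#' enforced exactly (every OTU is seeded into each ecosystem it belongs
#' to), so sharing counts are recovered exactly by [sharingStats()].
#'
#' @param nOtus,nSamples Table dimensions (desk-scale default 200 x 12;
#'   the study scale is 2101 x 600).
#' @param sharedFrac Fraction of OTUs present in both ecosystems.
#' @param guildMixture Named fractions over the nutrition vocabulary
#'   (default approximates a soil protist community dominated by
#'   bacterivores).
#' @param nontargetFrac Fraction of OTUs annotated to non-target phyla
#'   (default 0).
#' @param meanReads Mean reads per sample (default 30000).
#' @param lognormalSigma Abundance heterogeneity (default 1.5).
#' @param seed Integer seed.
#' @return A list: `table` (the [OtuTable-class]) and `truth` (planted
#'   categories, guild labels and mixture, per-sample composition).
#' @export
makeOtuTable <- function(nOtus = 200L, nSamples = 12L, sharedFrac = 0.8,
                         guildMixture = c(bacterivore = 0.50,
                                          omnivore = 0.23,
                                          eukaryvore = 0.10,
                                          `plant parasite` = 0.05,
                                          `hyperparasite of Oomycota` = 0.008,
                                          unknown = 0.112),
                         nontargetFrac = 0, meanReads = 30000L,
                         lognormalSigma = 1.5, seed = 1L) {
    stopifnot(sharedFrac >= 0, sharedFrac <= 1,
              nontargetFrac >= 0, nontargetFrac < 1)
    if (is.null(names(guildMixture)) ||
        !all(names(guildMixture) %in% .TRAIT_VOCAB$nutrition))
        stop("guildMixture must be named by the nutrition vocabulary")
    withr::with_seed(seed, {
        half <- nSamples %/% 2L
        eco <- rep(c("G", "F"), c(nSamples - half, half))
        region <- rep_len(c("A", "H", "S"), nSamples)
        sampleData <- data.frame(
            ecosystem = eco, region = c(A = "Alb", H = "Hainich",
                                        S = "Schorfheide")[region],
            year = rep_len(c(2011L, 2017L), nSamples),
            row.names = sprintf("%sE%s%02d", region, eco,
                                seq_len(nSamples)),
            stringsAsFactors = FALSE)
        nShared <- round(sharedFrac * nOtus)
        rest <- nOtus - nShared
        nUniqG <- round(0.75 * rest)
        category <- sample(rep(c("shared", "uniqueG", "uniqueF"),
                               c(nShared, nUniqG, rest - nUniqG)))
        nNon <- round(nontargetFrac * nOtus)
        nontarget <- seq_len(nOtus) %in% sample.int(nOtus, nNon)
        # guilds for target OTUs by largest-remainder allocation
        guild <- rep("unknown", nOtus)
        tgt <- which(!nontarget)
        alloc <- .allocate(length(tgt), guildMixture)
        guild[sample(tgt)] <- rep(names(guildMixture), alloc)
        guild[nontarget] <- "unknown"
        # taxonomy names come from the protist pool; the planted guild is
        # stored directly as the table's functional annotation, mirroring a
        # pre-annotated published abundance table
        taxIdx <- sample.int(nrow(.SYNTH_TAXA), nOtus, replace = TRUE)
        taxonomy <- .SYNTH_TAXA[taxIdx, ]
        taxonomy$phylum[nontarget] <- rep_len(c("Fungi", "Ciliophora"),
                                              nNon)
        taxonomy$class[nontarget] <- NA
        taxonomy$order[nontarget] <- NA
        taxonomy$genus[nontarget] <- NA
        taxonomy$species[nontarget] <- NA
        rownames(taxonomy) <- NULL
        taxonomy$nutrition <- guild
        baseline <- stats::rlnorm(nOtus, 0, lognormalSigma)
        counts <- matrix(0L, nOtus, nSamples,
                         dimnames = list(sprintf("OTU%04d", seq_len(nOtus)),
                                         rownames(sampleData)))
        for (j in seq_len(nSamples)) {
            inEco <- category == "shared" |
                (category == "uniqueG" & eco[j] == "G") |
                (category == "uniqueF" & eco[j] == "F") | nontarget
            w <- baseline * inEco
            counts[, j] <- stats::rmultinom(1L, meanReads, w / sum(w))[, 1L]
        }
        # enforce the planted presence structure exactly
        for (e in c("G", "F")) {
            cols <- which(eco == e)
            should <- category == "shared" | nontarget |
                (category == "uniqueG" & e == "G") |
                (category == "uniqueF" & e == "F")
            absent <- which(should &
                            rowSums(counts[, cols, drop = FALSE]) == 0L)
            if (length(absent))
                counts[cbind(absent,
                             sample(cols, length(absent), replace = TRUE))] <- 1L
        }
    })
    tab <- OtuTable(counts, taxonomy = taxonomy, sampleData = sampleData)
    list(table = tab,
         truth = list(category = stats::setNames(category, rownames(counts)),
                      guild = stats::setNames(guild, rownames(counts)),
                      guildMixture = guildMixture / sum(guildMixture),
                      nontarget = stats::setNames(nontarget,
                                                  rownames(counts)),
                      sharedFrac = nShared / nOtus,
                      seed = seed))
}
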