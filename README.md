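# ampliTags

Design dual 8-nt sample barcodes for taxon-specific PCR primers, lay them
out on a forward × reverse tagging grid that exposes tag jumping, demultiplex
merged amplicon reads by exact tag matching, and post-process OTU tables
with functional-trait (trophic guild) annotation and diversity summaries.

The package targets metabarcoding studies that label each sample with a
*pair* of barcodes appended to the 5' ends of both PCR primers (dual
indexing). It was built around a soil-protist use case — taxon-specific 18S
V4 primers for the protistan phyla Cercozoa and Endomyxa, 18 + 18 barcodes,
150 of 324 grid combinations used — but every step is parameterised and
works for any primer pair.

## What it computes

**Barcode design.** All 4^L barcode candidates are filtered through a
constraint chain:

1. balanced nucleotide content — each base count within bounds and GC
   fraction in `[0.375, 0.625]` — and no homopolymer runs (> 2);
2. no hairpin in the tagged oligo (barcode + primer): no two antiparallel
   complementary stretches of ≥ `stemMin` = 4 bases around a loop of ≥
   `loopMin` = 3;
3. no heteroduplex with the attached primer and no self-dimer: reject when
   the longest contiguous IUPAC-compatible complementary run is ≥ 6, or a
   3'-anchored run is ≥ 4 (match-count scoring, not thermodynamic);
4. no resemblance to the template consensus flanking the primer annealing
   site (≤ 5 of 8 compatible positions at every offset of a 20-nt window);
5. minimum pairwise Hamming distance ≥ 3 within the final set (exact
   maximum-subset search on small pools, seeded greedy on large ones), plus
   a cross-dimerization screen over every barcode+primer combination of the
   forward and reverse sets.

**Tagging scheme.** Samples are spread over the F × R grid with per-row and
per-column usage balanced to within one, leaving the remaining combinations
deliberately unused; `mistagExposure()` reports the fraction of grid cells
in which a tag-jumping chimera becomes observable.

**Demultiplexing.** Read pairs are merged at their best ungapped overlap,
filtered (merged length < 300 bp or overlap < 100 bp removed), and matched
*exactly*: barcodes literally, degenerate primer positions by IUPAC
compatibility. Reads whose valid tag pair is an unused grid cell are binned
as mistags; samples under 10,000 reads can be dropped (`dropLowYield()`).

**Community summaries.** OTU tables (a `SummarizedExperiment` subclass)
support the rare-cluster filter (< 0.01 % of all reads), BLAST-style
best-hit parsing (minimal e-value, gate at 1e-50), non-target removal,
trait annotation at the most specific matching rank, guild relative
abundances (read- or OTU-weighted), OTU sharing across strata, and
Shannon `H = −Σ pᵢ ln pᵢ`, Pielou `J = H / ln S`, Bray–Curtis
`BC = Σ|xᵢ−yᵢ| / Σ(xᵢ+yᵢ)`.

**Synthetic data.** `makeReferenceAlignment()`, `simulateRun()` and
`makeOtuTable()` generate every input with full ground truth (per-read
sample of origin, mistag flags, planted guild mixtures and sharing
fractions), so the whole pipeline is testable end to end without any
sequencing data.

## Worked example

```r
library(ampliTags)

p  <- cercozoaPrimers()                       # the five printed primers
fw <- designBarcodes(p[["S615F_Cer"]], targetSize = 18, seed = 1)
rv <- designBarcodes(p[["S947R_Cer"]], orientation = "reverse",
                     targetSize = 18, seed = 2)
fw
#> BarcodeSet of 18 forward 8-nt barcodes for primer GTTAAAARGCTCGTAGTYG
#>    F01=ACGGCTGA F02=ACTGAACG F03=AGCGCATC F04=CATAGGTA ...

sch <- selectCombinations(buildTagGrid(fw, rv), sprintf("S%02d", 1:12),
                          seed = 3)
run <- simulateRun(sch, nReads = 850, rhoMistag = 0.02, seed = 11)
res <- demuxRun(mergePairs(run$r1, run$r2), sch)
res$binCounts
#>     assigned       mistag   unassigned    too_short  low_overlap merge_failed
#>         9997          203            0            0            0            0
```

Every assigned read went to its true sample (the 203 tag-jumped reads landed
in the mistag bin — with 12 samples on an 18 × 18 grid every single-tag jump
is observable). On the community side:

```r
mt <- makeOtuTable(nOtus = 200, nSamples = 12, sharedFrac = 0.8, seed = 5)
sharingStats(mt$table)[c("shared", "unique")]
#> $shared [1] 160        $unique  F 10  G 30

head(guildRelAbund(mt$table, "nutrition", "reads"), 4)
#>  stratum       category  percent weight
#>      all    bacterivore 59.06     reads
#>      all     eukaryvore 10.82     reads
#>      all       omnivore 16.28     reads
#>      all plant parasite  1.72     reads

shannonIndex(otuCounts(mt$table)[, 1])   # 4.196 nats
pielouEvenness(otuCounts(mt$table)[, 1]) # 0.80
```

The planted sharing structure (160 shared, 30 grassland-only, 10
forest-only of 200 OTUs) is recovered exactly; guild percentages differ
from the planted OTU-level mixture because they are read-weighted over a
log-normal abundance model.

A thin CLI over the same functions lives in
`inst/scripts/amplitags-cli.R` (`design`, `scheme`, `demux`, `simulate`
subcommands).

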