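---
title: "Dual-index barcode design, mistag-aware demultiplexing and trait-annotated OTU summaries"
author: "ampliTags"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-index barcode design and mistag-aware demultiplexing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliTags)
```

# The problem

Multiplexed amplicon sequencing labels each sample with short barcodes
appended to the PCR primers. Tagging only one primer is unsafe: chimeric
library molecules and index hopping ("tag jumping", mistagging) move reads
between samples undetectably. Dual indexing — a barcode on *both* the
forward and the reverse primer — turns each sample into a cell of an
F × R grid, and deliberately leaving part of that grid unused makes
tag-jumping products visible: a read whose two tags form an unused
combination cannot come from any real sample.

`ampliTags` implements this design end to end for taxon-specific primers:
barcode generation under a combinatorial constraint chain, grid layout,
exact-match demultiplexing, and downstream OTU-table summaries with
functional (trophic guild) annotation. The driving use case is 18S V4
metabarcoding of the soil protist phyla Cercozoa and Endomyxa with the
semi-nested primer pair carried by `cercozoaPrimers()`, 8-nt barcodes,
18 + 18 tags, and 150 of the 324 combinations used for samples.

# Barcode design model

Candidates are all `4^L` ACGT words of length `L` (default 8; enumeration
is refused above `L = 12`). The constraint chain, held in a
`DesignConstraints` object, is:

* **Composition balance.** Each base count in `[1, 3]` for an 8-mer, GC
  fraction in `[0.375, 0.625]`, homopolymer runs ≤ 2. The source
  procedure asked for "balanced content, no homopolymers" without
  quantifying either; these bounds are this package's concrete reading and
  are all adjustable.
* **Secondary structure.** The barcode is prepended to the 5' end of its
  primer (as synthesised) and the tagged oligo is scanned for hairpins:
  two antiparallel complementary stretches of ≥ `stemMin = 4` bases
  enclosing a loop of ≥ `loopMin = 3` (3 is the sterical minimum loop).
  The barcode is also scanned against the primer (heteroduplex) and
  against itself (self-dimer) over every ungapped offset; a candidate is
  rejected when the longest contiguous complementary run reaches
  `duplexMaxRun = 6`, or a run anchored at a 3' terminus reaches
  `duplexThreePrimeRun = 4` (3'-anchored duplexes are the
  primer-extension risk). Degenerate primer positions (R, Y, ...) pair
  with any base their expansion can pair with. Scoring is match-count
  based, not thermodynamic: the design procedure this implements is
  combinatorial, and nearest-neighbour ΔG models would import large
  parameter tables without changing which gross failure modes are caught.
  These run-length thresholds follow common primer-QC practice; the
  original tool's internal thresholds are not published, so ours are
  declared stand-ins and are configuration-exposed.
* **Template flank.** A barcode that resembles the template immediately
  5' of the primer annealing site could misprime. The IUPAC consensus of
  the reference alignment over the `flankWindow = 20` adjacent columns is
  computed (`alignmentConsensus()`: per column, every base at frequency ≥
  `1 − majorityThreshold` among non-gap characters is retained and covered
  by the smallest IUPAC code; columns ≥ 50 % gaps are dropped), and a
  candidate fails when any offset along that window has more than
  `flankMatchMax = 5` of 8 IUPAC-compatible positions.
* **Pairwise distance.** The final set must have minimum pairwise Hamming
  distance ≥ 3. Hamming (not edit) distance is the right metric here
  because the barcodes are fixed-length and matched literally. On
  candidate pools of ≤ 20 the exact maximum mutually-compatible subset is
  found by clique search over the distance graph (ties broken toward the
  lexicographically smallest set); the design-scale pools (thousands of
  8-mers) use greedy maximal construction over a seed-keyed shuffle, which
  is reproducible and near-maximal, and whose loss the exact small-pool
  route bounds in the test suite. Selection stops at `targetSize`
  (default 18); falling short is a warning with the achieved size, not an
  error.
* **Cross-dimerization.** `crossCombinationScreen()` re-scans every pair
  of tagged oligos across the forward and reverse sets (including
  self-pairs, ≤ (n(n+1))/2 comparisons) and reports offending pairs.

`validateBarcodeSet()` re-checks every constraint independently of how a
set was built and names the worst offender per check.

# Tagging scheme

`selectCombinations()` walks the grid row-round-robin with the column
sequence shifted by one after every `lcm(F, R)` cells. This is
collision-free up to `F·R` samples and keeps per-row and per-column usage
within one of balanced — a Latin-square-like layout. The motivation is
mistag detectability: `mistagExposure()` is the fraction of grid cells
that are unused while both their row and column are in use (the cells
where a single-tag jump between real samples becomes observable), and a
balanced layout keeps it near-maximal for a given sample count. The
sample order defines the assignment order; the row/column permutations are
keyed by the seed. The published layout the defaults reproduce — 150
samples on 18 × 18 — leaves 174 unused cells. How the original study chose
its 150 cells is not recorded; any balanced scheme satisfies the stated
goal.

# Demultiplexing

Read pairs are merged at the longest ungapped overlap whose mismatch
fraction is ≤ `maxMismatchFrac = 0.1` (N is uninformative; disagreements
resolve to the higher-quality base, or N without qualities). Assembled
reads shorter than 300 bp or with overlap below 100 bp are removed —
all removal thresholds in the pipeline are strict less-than, so boundary
values (300 bp, 100 bp, a 10,000-read sample, an OTU at exactly 0.01 %)
are kept.

Tag detection is exact: the read's 5' end must equal a forward barcode
literally, followed by the forward primer with IUPAC compatibility at its
degenerate positions; the 3' end must equal the reverse complement of a
reverse barcode + primer. Reads failing in forward orientation are retried
reverse-complemented (the merged-read orientation is arbitrary). A valid
tag pair that maps to an assigned cell yields the sample (tags and primers
trimmed); a valid pair in an unused cell is a mistag; anything else —
including any single-base barcode error, since the sets are distance-3 —
is unassigned. Every read lands in exactly one of
`assigned | mistag | unassigned | too_short | low_overlap | merge_failed`.

Fuzzy barcode matching with error correction is deliberately out of scope:
the workflow this supports matches tags with no differences allowed.

# OTU-table summaries

`OtuTable` extends `SummarizedExperiment`: a `counts` assay, per-OTU
taxonomy/traits in `rowData`, per-sample metadata in `colData`. The
post-clustering steps are:

* `rareFilter()` — OTUs below 0.01 % of all reads removed (equality kept);
* `parseBestHits()` — per query the minimal-e-value row (ties: higher
  identity, then first occurrence), gated at e ≤ 1e-50; malformed rows are
  skipped with a warning;
* `removeNonTarget()` — taxonomy must contain a target phylum (default
  Cercozoa or Endomyxa);
* `annotateTraits()` — nutrition/morphology/locomotion looked up at the
  most specific matching rank (species → genus → family → order → class),
  provenance recorded, unknowns never imputed, vocabularies closed
  (violations are input errors). A compact trait table for the common
  cercozoan/endomyxan lineages ships in `extdata/protist_traits.tsv`.
* `guildRelAbund()` — per-category percentages, overall and per ecosystem.
  Published community summaries are ambiguous about whether such
  percentages weight by reads or by OTU counts, so both modes are
  implemented and the mode is labelled in the output; they answer
  different questions (read-weighted percentages track community biomass
  proxies, OTU-weighted ones track richness composition).
* `sharingStats()` — OTUs present in every stratum (shared) or exactly one
  (unique).
* `shannonIndex()` / `pielouEvenness()` / `brayCurtis()` — computed in
  natural logarithms by default (matching the Pielou normalisation
  `J = H / ln S`; `J` is defined 0 when `S = 1`), with a `base` argument
  for bits; vegan provides the numerics behind the module surface, and the
  closed forms are asserted in the tests.

# The synthetic-data generator

The generator produces every input the toolkit consumes, with ground
truth, and its defaults are the study conditions, not tuning knobs:

* `makeReferenceAlignment()` plants a primer into an alignment by cycling
  each degenerate position through its expansion set (so the consensus
  recovers the primer exactly) and conserves flanks with probability
  `flankConservation` (default 0.9, a moderately conserved rRNA flank).
* `simulateRun()` builds full amplicons `fwTag + fwPrimer + insert +
  revcomp(rvTag + rvPrimer)` with inserts of 330–370 bp (amplicons ≈
  383–423 bp, so 2 × 300 bp reads overlap by ≥ 100 bp, matching the MiSeq
  v3 layout), splits them into read pairs, and injects noise: a fraction
  `rhoMistag` of reads has one tag swapped to another *used* tag of the
  same side — the simplest model consistent with tag jumping — and a
  fraction `shortFrac` has its insert truncated so the merged read fails
  the 300-bp filter. Per-sample compositions default to a log-normal
  abundance model (the standard skewed-community stand-in; no abundance
  model is prescribed by the source procedure).
* `makeOtuTable()` plants ecosystem-sharing structure (a `sharedFrac`
  fraction present in both grassland and forest, the rest split 75/25
  grassland-/forest-only, mirroring the asymmetry of unique OTUs in the
  motivating study), trophic-guild labels allocated by largest remainder
  from a `guildMixture` (default dominated by bacterivores, as in soil
  protist communities), optional non-target OTUs, and
  log-normal/multinomial abundances; presence structure is enforced
  exactly, so sharing counts are recovered exactly by `sharingStats()`.
  Desk scale is 200 OTUs × 12 samples; the study scale (2,101 × 600) is a
  parameter choice away and is exercised once in the acceptance tests.

What the generator does **not** emulate: sequencing errors (substitutions,
indels, quality decay), chimeras, PCR bias, or real taxonomic sequence
structure (inserts are i.i.d. random). Passing tests therefore demonstrate
the correctness of the combinatorics, matching and bookkeeping — not
robustness to read errors, which an exact-match demultiplexer by
construction does not attempt; error-containing reads fall into the
unassigned bin in real data after the upstream quality trimming this
package leaves to dedicated tools.

# Numerical and degenerate-input choices

* All seeds flow through explicit `seed` arguments (`withr::with_seed`),
  so generation is byte-deterministic and never disturbs the caller's RNG
  state.
* Degenerate IUPAC codes compare by expansion-set intersection everywhere;
  barcodes themselves are restricted to ACGT.
* `iupacDistance()` requires equal lengths; `brayCurtis()` on an all-zero
  vector is an error (undefined); an empty or non-IUPAC oligo is an input
  error; merge failures and sub-target barcode yields are *outcomes*
  (counted / warned), not exceptions.
* Best-hit ties break deterministically (e-value, then identity, then file
  order); clique-search ties break toward the lexicographically smallest
  barcode set; percentages sum to 100 within 1e-9 per stratum.

# Problem sizes in the test suite

The suite runs the full 8-mer enumeration (65,536 candidates) and complete
18 + 18 designs for both printed primers; demultiplexing checks use 12
samples × 850 read pairs (10,200 reads) per run; brute-force oracles cover
oligos ≤ 30 nt and selection pools ≤ 15 (subset enumeration); the
study-scale synthetic table is 2,101 OTUs × 600 samples. These sizes keep
every oracle exhaustive where it is meant to be exhaustive while the whole
suite stays fast.

# Known limitations

* Structure screens are run-length heuristics; melting temperature and
  thermodynamic folding are out of scope (primers are inputs here, not
  designed).
* The merger is a simple best-ungapped-overlap assembler intended for
  simulated and well-behaved data; production runs typically use a
  dedicated assembler upstream and feed merged reads in.
* OTU clustering, chimera detection, BLAST execution, ordination and
  model-based statistics are intentionally outside the package boundary.
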