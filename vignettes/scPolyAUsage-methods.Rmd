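---
title: "Poly(A) site usage from 3' scRNA-seq: models and methods"
author: "scPolyAUsage package authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Poly(A) site usage from 3' scRNA-seq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Oligo-dT-primed 3' single-cell RNA-seq reads terminate at the mRNA
cleavage/polyadenylation site, so the alignments implicitly encode which
poly(A) site each transcript used. Two obstacles stand between the raw
alignments and a usable per-cell site-usage table. First, oligo-dT also
primes at genomic adenosine stretches inside transcripts (internal
priming), producing reads that end at places that are not poly(A) sites.
Second, there is no a-priori catalogue of the sites actually used in a
given dataset; annotated transcript ends are incomplete and cell-type
specific sites are common. scPolyAUsage therefore (i) builds a
dataset-specific poly(A) site reference from the alignments themselves,
(ii) counts read 3' ends per site and cell into a sparse matrix, and
(iii) tests alternative polyadenylation (APA) between two cell groups
with a pseudo-replicate negative-binomial model.

# Junction evidence

A read that runs through the cleavage site into the poly(A) tail aligns
up to the cleavage base and carries the tail as a soft-clipped suffix of
(mostly) `A` (`+` strand) or a soft-clipped `T`-rich prefix (`-` strand,
in SAM forward orientation). `detectJunctionReads()` calls a read a
poly(A) junction read when the clip is at least `min_clip = 6` nt long
with A (or T) fraction at least `min_a_frac = 0.8`. Each junction read
yields a cleavage event at the last aligned base (`+`) or the base
immediately preceding the alignment start (`-`); this coordinate
convention is used consistently by the simulator, the event BED export
and the peak-support counter. Both thresholds are exposed because they
trade sensitivity against misclassifying templated A runs; the defaults
follow common practice for tail-detection heuristics.

# Read filtering

`deduplicateReads()` keeps one read per (cell barcode, UMI, 3'-end
coordinate, strand) key - the 3' end rather than the leftmost position,
because a 3'-tagged assay accumulates duplicates at the cleavage site;
the highest-MAPQ member wins, ties by first occurrence. No UMI-graph
collapsing is attempted: with a position in the key, sequencing-error
UMI networks mostly collapse the same way, and the simple rule is exact
and order-insensitive. `filterAmbiguous()` keeps `MAPQ >= 255`, the
unique-alignment convention of the common upstream aligner; both
thresholds are configurable.

Internal-priming removal (`filterGenomicA()`) asks whether the
`a_window = 10` template bases immediately downstream of the read's 3'
end could have primed the read: A fraction `>= 0.7` or a run of `>= 6`
consecutive A disqualifies the read. The test runs in two rounds. Reads
whose 3' end lies in an annotated exon are evaluated on the *spliced*
transcript sequence (round 1): an intronic A stretch that is spliced out
of the mature mRNA cannot have primed a cDNA, so judging those reads on
genomic sequence would remove them wrongly. All remaining reads are
evaluated on genomic sequence (round 2). When fewer than `a_window`
spliced bases remain before the transcript end the window is completed
with genomic flank. If the 3' end is exonic in several transcripts, the
read is removed when *any* containing transcript's window qualifies
(conservative). Reads whose soft clip qualifies as a junction tail are
exempt: a non-templated tail is direct evidence of genuine cleavage, and
without the exemption the filter would delete true sites that happen to
sit near genomic A. The numeric defaults (10 nt / 0.7 / 6) mirror widely
used internal-priming heuristics; they are deliberately config-exposed
since protocols differ in their priming stringency.

# Peak calling: two prongs, splitting, retention

The caller is a deterministic coverage threshold-and-merge over aligned
blocks (spliced `N` gaps contribute no coverage): maximal intervals with
per-base coverage `>= min_cov`, merging neighbours separated by fewer
than `max_gap = 25` zero-coverage bases; the summit is the leftmost
coverage maximum. Determinism matters here: every result is exactly
reproducible and testable against a brute-force per-base oracle, and the
discriminating steps of the method are the retention and splitting rules
rather than a peak caller's statistics.

Peaks are called in two prongs: all filtered reads (`min_cov = 5`) and
junction reads only (`min_cov = 2`). The junction prong exists to rescue
genuine low-coverage sites - a site seen by only three tail-bearing
reads is real but invisible to the all-reads coverage floor.
`splitMultimodal()` partitions any peak at internal zero-coverage runs
of `gap_len = 10` bases or more, recomputing summit and counts per
fragment. Finally `retainJunctionSupported()` keeps only peaks
containing at least `min_support = 3` cleavage events - the default
requirement of three supporting junction reads; datasets with shallow
depth may justify lowering it to 2 or 1. Support is counted across the
whole peak interval (the summit-window alternative is not specified
anywhere authoritative; whole-peak containment is the simpler and more
sensitive choice and is what the tests pin down).

# Transcription units and the final reference

`buildTuReference()` merges each gene's same-strand transcripts into one
transcription unit (TU), extends it 5,000 bases 3' (sites downstream of
annotated ends are common), and collects annotated transcript end sites,
exon/intron partitions, 3' UTR features and a TSS-proximal window of 300
bases (a width chosen here; annotations do not define "TSS-proximal").
Peaks overlapping exactly one TU-or-flank are assigned
(`assignPeaksToTu()`); peaks touching zero or two TUs are dropped as
unassignable. `applyPeakFilters()` then applies, in order: the
processing-region length cap (1,000 bp), the per-gene minimum usage
share (10%, computed once against the totals entering the usage rule -
the filter is single-pass, not iterated, so removing a peak does not
re-inflate its siblings' shares within the same run), and optionally the
PAS rule: keep a peak only if a canonical hexamer (AATAAA/ATTAAA plus
ten single-base variants) occurs within 50 nt upstream of the summit in
transcription sense, or the peak lies within 50 nt of an annotated
transcript end site. `mergeProngs()` unions the two prongs with
all-reads precedence on overlap (that prong carries full coverage
statistics). TU 3' ends are then truncated to the most downstream
assigned peak, peaks are classified by genomic context in priority order
3'UTR > TSS-proximal > Exonic > Intronic > Flank, peaks fragmented by
spliced alignments are flagged (advisory only), and names are assigned
as `[TU]:[gene]:[P#]` - `P0` for single-peak genes, else `P1..Pn` from
the most upstream to the most downstream site in transcription
direction.

# Counting and pseudo-replicate testing

`buildPeakCellMatrix()` increments (peak, cell) when a read's 3'-end
coordinate falls inside the peak on the matching strand; the 3' end is
the cleavage-proximal, informative coordinate (an `any_overlap` mode
exists for sensitivity studies). The matrix is a
`SingleCellExperiment`-backed sparse container; merging across samples
rewrites barcode suffixes to the sample index so colliding barcodes stay
distinguishable, and conserves the grand total.

APA testing follows a pseudo-replicate design: for each group, three
draws of `floor(0.7 * n_cells)` distinct cells (without replacement
within a draw; draws may share cells - the replicate draws are
independent subsamples of the same population) are summed into
pseudo-bulk columns. Testable peaks come from multi-peak genes (P0
excluded - usage is undefined with one site) and must be expressed in at
least 10% of the cells of one group.

For each testable peak the two-bin response (this peak vs the rest of
its gene) over the six pseudo-bulk columns is fit with a log-linear
negative-binomial model containing replicate, bin and group-by-bin
interaction terms, by iteratively reweighted least squares with a fixed
per-peak dispersion. The dispersion is a method-of-moments estimate
across pseudo-replicates: within each (group, bin) cell,
`var - mean` is computed across the replicate draws, clipped below at
zero (overdispersion cannot be negative), pooled over cells against the
squared means, and floored at `1e-4`. The interaction is tested with a
1-df likelihood-ratio statistic. Because the dispersion is estimated
from very few replicates, the chi-square reference for that statistic is
anti-conservative at this sample size; the statistic is therefore
referred to an F(1, d) distribution with d equal to the
dispersion-estimation degrees of freedom (number of (group, bin) cells
times replicates-minus-one; 8 at the defaults) - the standard
quasi-likelihood remedy for a likelihood-ratio statistic computed with
a dispersion estimated from few replicates. The calibration this buys
is checked directly by the test suite and the acceptance script on a
500-gene null simulation. The usage log2 fold change is computed from
replicate-summed counts as
`log2(((c1+0.5)/(o1+0.5)) / ((c2+0.5)/(o2+0.5)))`, with 0.5
pseudocounts to avoid division by zero. P-values are BH-adjusted across
all tested peaks (the adjustment procedure is configurable; BH is the
conventional choice). A peak is called significant (`int_sig`) iff
`padj < 0.01`, `|log2FC| > 1.5` and `|Δ fractional usage| > 0.1`, where
fractional usage divides a peak's full-group pseudo-bulk count (all
cells, not pseudo-replicates) by the gene's group total.

Pseudo-bulk DEG testing reuses the machinery at the gene level: NB fit
of per-TU totals against group vs intercept with log library-size
offsets, the same F-referenced 1-df LRT, BH adjustment, and a
significant-genes table at `padj < 0.05` (a package choice; the DEG
threshold is not part of the APA rule set).

# The synthetic-data generator

`simulateReference()`/`simulateReads()` build a miniature genome whose
truth is known exactly, exercising every artifact class the pipeline
must handle. Default study conditions: 2 chromosomes of 100 kb, 20
two-exon genes (alternating strand), 2-3 cleavage sites per gene 300 bp
apart in the terminal exon, two groups of 40 cells, 50 reads per cell,
20% internal-priming rate, 10% PCR-duplicate rate, 5% ambiguous reads,
12-nt A tails, 60-nt aligned reads, cleavage jitter uniform on +-5 nt
(hence the +-10 nt recovery tolerance used downstream).

Design choices a reader should know:

* **One transcript isoform per cleavage site.** Multi-site genes in
  curated annotations typically carry isoforms ending at the distinct
  poly(A) sites, so every planted site is an annotated TES. This is also
  load-bearing for the default PAS filter: with fixed-length reads, the
  coverage summit sits roughly one read length upstream of the cleavage
  site, so the summit-anchored 50-nt hexamer window cannot see a PAS
  planted at the biological ~21 nt upstream of cleavage; such sites pass
  the rule through TES proximity instead. Consequently the default
  simulation does not exercise discovery of PAS-orphan novel sites -
  that behavior is covered by constructed fixtures and by runs with
  `PAS_filtering` off.
* **Usage fractions bounded away from the filter.** Per-gene fractions
  are drawn as `(1 + U(0,1)) / sum`, keeping every site's expected share
  at or above 20% so that multinomial sampling noise cannot push a
  genuinely used site under the 10% usage filter.
* **Controlled cleavage-adjacent sequence.** The 16 transcript-sense
  bases after each site are C/G so a genuine read's downstream window
  can never look like internal priming even before the junction-tail
  exemption; each gene carries one planted 15-nt A stretch (transcript
  sense) as its mispriming locus, and misprimed reads end exactly at it
  with no soft clip.
* **Barcodes** are 16-nt deterministic sequences suffixed `-1`,
  matching the common convention; UMIs are unique per cell by
  construction, so duplicate keys arise only from planted duplicates.
* **Reads are emitted pre-aligned (SAM).** The pipeline consumes
  alignments; no aligner (or error model, or FASTQ) is in the loop.

What the generator does *not* emulate: sequencing errors, soft-clip
impurity, variable read lengths, ambient RNA, isoform-level expression
differences, or spliced junction reads near peaks (fragmentation
flagging is exercised with constructed spliced fixtures instead). A
green test suite on this generator therefore demonstrates correctness of
the implemented rules under clean conditions, not robustness to every
artifact of real libraries.

# Problem sizes and numerics

The validation dataset is 4,000 reads across 20 genes; the end-to-end
pipeline on it, the 500-gene null calibration and the 100-gene swap
power simulation are the sizes used throughout the tests and the
acceptance script - small enough to re-run interactively, large enough
for the Monte-Carlo bounds used in the checks. IRLS iterates at most 100
times to a relative log-likelihood tolerance of `1e-8` with the linear
predictor clamped to [-30, 30]; non-convergence is recorded (p = 1,
flagged) rather than silently accepted. Degenerate inputs - empty read
sets, genes with zero group totals, windows truncated at chromosome
ends - produce empty-but-well-formed outputs, `NA` fractions, or
truncated windows respectively, and the pipeline's stage runner turns
any stage failure into an error naming the stage and its log.

# Known limitations

The dispersion model is a crude per-peak moment estimate with no
information sharing across peaks, which costs power at very low counts
relative to shrinkage-based exon-usage testers; the peak caller is not a
statistical model and will merge distinct sites closer than the gap
parameters; barcode harmonization against external single-cell objects
and binary browser formats (bigWig/bigBed) are out of scope - bedGraph
and BED text tracks are emitted and can be converted with the standard
UCSC utilities.
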