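#' @import methods
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- DataFrame Rle runValue runLength
#' @importFrom GenomicRanges GRanges seqnames start end width strand strand<-
#'   findOverlaps countOverlaps reduce sort.GenomicRanges
#' @importFrom IRanges IRanges ranges overlapsAny subsetByOverlaps
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement readDNAStringSet
#'   writeXStringSet letterFrequency vcountPattern subseq
#' @importFrom GenomicAlignments GAlignments cigar njunc grglist
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @importClassesFrom GenomicAlignments GAlignments
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqinfo
#' @importFrom stats rbinom runif setNames p.adjust pchisq dnbinom rnbinom
#'   rmultinom var ks.test ppoints
#' @importFrom utils read.delim write.table head tail
NULL

#' Synthetic 3' scRNA-seq dataset with ground truth
#'
#' Container for one simulated dataset: a miniature genome, a GTF-style gene
#' annotation, tagged read alignments, the table of true cleavage sites with
#' per-group usage fractions, and the planted internal-priming (genomic
#' A-stretch) loci. Produced by [simulateReference()] + [simulateReads()].
#'
#' @slot genome [Biostrings::DNAStringSet] of chromosome sequences.
#' @slot annotation `GRanges` with GTF-style columns (`type`, `gene_id`,
#'   `gene_name`, `transcript_id`).
#' @slot truth `data.frame` with one row per true cleavage site: `gene`,
#'   `chrom`, `strand`, `site`, `pos` (1-based cleavage coordinate, junction
#'   convention) and one `frac_<group>` column per cell group.
#' @slot misprimeLoci `GRanges` of planted A-stretch loci; metadata column
#'   `end3` holds the 3' end coordinate at which misprimed reads terminate.
#' @slot reads [GenomicAlignments::GAlignments] with tag metadata columns
#'   (`CB`, `UB`, `mapq`, `clip5`, `clip3`) plus truth labels (`origin`,
#'   `gene`, `site_pos`, `is_dup`).
#' @slot config the [simConfig()] list used to generate the object.
#' @exportClass PolyASimulation
setClass("PolyASimulation",
    slots = c(genome = "DNAStringSet", annotation = "GRanges",
              truth = "data.frame", misprimeLoci = "GRanges",
              reads = "GAlignments", config = "list"))

setValidity("PolyASimulation", function(object) {
    tr <- object@truth
    need <- c("gene", "chrom", "strand", "site", "pos")
    if (!all(need %in% names(tr)))
        return(paste("truth lacks columns:",
                     paste(setdiff(need, names(tr)), collapse = ", ")))
    fcols <- grep("^frac_", names(tr), value = TRUE)
    if (length(fcols) == 0L) return("truth has no frac_<group> columns")
    for (fc in fcols) {
        s <- tapply(tr[[fc]], tr$gene, sum)
        if (any(abs(s - 1) > 1e-9))
            return(sprintf("per-gene fractions in %s do not sum to 1", fc))
    }
    if (!all(tr$chrom %in% names(object@genome)))
        return("truth chromosomes missing from genome")
    TRUE
})

setMethod("show", "PolyASimulation", function(object) {
    cat("PolyASimulation:", length(object@genome), "chromosome(s),",
        length(unique(object@truth$gene)), "genes,",
        nrow(object@truth), "cleavage sites,",
        length(object@reads), "reads\n")
    cat("  groups:", paste(sub("^frac_", "",
        grep("^frac_", names(object@truth), value = TRUE)), collapse = ", "),
        "| planted mispriming loci:", length(object@misprimeLoci), "\n")
})

#' @describeIn PolyASimulation-accessors genome sequences
#' @export
simGenome <- function(x) x@genome
#' @describeIn PolyASimulation-accessors GTF-style annotation
#' @export
simAnnotation <- function(x) x@annotation
#' @describeIn PolyASimulation-accessors truth table of cleavage sites
#' @export
simTruth <- function(x) x@truth
#' @describeIn PolyASimulation-accessors simulated tagged alignments
#' @export
simReads <- function(x) x@reads
#' Accessors for PolyASimulation
#'
#' @param x a `PolyASimulation`
#' @name PolyASimulation-accessors
#' @describeIn PolyASimulation-accessors planted mispriming loci
#' @export
misprimeLoci <- function(x) x@misprimeLoci

#' Transcription-unit reference derived from a gene annotation
#'
#' One transcription unit (TU) per gene (and strand): the union span of the
#' gene's transcripts, extended 3' by a flank. Carries the interval sets used
#' for genomic-context classification (3' UTR, TSS-proximal, exon, intron)
#' and the annotated transcript end sites.
#'
#' @slot tus `GRanges`, one per TU, metadata `tu_id`, `gene`, `flank_end`.
#' @slot flank `GRanges` of the 3' flank region per TU.
#' @slot exons,utr3,tss,introns `GRanges` interval sets with `gene` column.
#' @slot tes `GRanges` width-1 annotated transcript end sites with `gene`.
#' @slot flankWidth integer, the flank length in bases (default 5000).
#' @exportClass TuReference
setClass("TuReference",
    slots = c(tus = "GRanges", flank = "GRanges", exons = "GRanges",
              utr3 = "GRanges", tss = "GRanges", introns = "GRanges",
              tes = "GRanges", flankWidth = "integer"))

setValidity("TuReference", function(object) {
    m <- mcols(object@tus)
    if (!all(c("tu_id", "gene", "flank_end") %in% names(m)))
        return("tus must carry tu_id, gene and flank_end")
    if (anyDuplicated(m$tu_id)) return("tu_id not unique")
    if (length(object@flank) != length(object@tus))
        return("flank must parallel tus")
    TRUE
})

setMethod("show", "TuReference", function(object) {
    cat("TuReference:", length(object@tus), "TUs,",
        length(object@tes), "annotated TES,",
        object@flankWidth, "bp 3' flank\n")
})

#' @describeIn TuReference-accessors TU ranges
#' @export
tuRanges <- function(x) x@tus
#' Accessors for TuReference
#' @param x a `TuReference`
#' @name TuReference-accessors
#' @describeIn TuReference-accessors annotated transcript end sites
#' @export
tuTes <- function(x) x@tes

#' Sparse peak-by-cell count matrix
#'
#' A thin wrapper around [SingleCellExperiment::SingleCellExperiment] holding
#' non-negative integer counts of read 3' ends per poly(A) site peak (rows)
#' and cell barcode (columns). `rowRanges` hold the annotated peaks;
#' `colData` records barcode and sample of origin; `metadata(x)$unassigned`
#' counts reads whose 3' end hit no peak.
#'
#' @exportClass PeakCellMatrix
setClass("PeakCellMatrix", contains = "SingleCellExperiment")

setValidity("PeakCellMatrix", function(object) {
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' required")
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(cts@x < 0)) return("counts must be non-negative")
    if (!all(c("barcode", "sample") %in%
             names(SummarizedExperiment::colData(object))))
        return("colData must carry barcode and sample")
    if (anyDuplicated(colnames(object))) return("barcodes must be unique")
    TRUE
})

setMethod("show", "PeakCellMatrix", function(object) {
    cts <- SummarizedExperiment::assay(object, "counts")
    cat("PeakCellMatrix:", nrow(object), "peaks x", ncol(object), "cells |",
        "assigned reads:", sum(cts), "| unassigned:",
        if (is.null(metadata(object)$unassigned)) 0L
        else metadata(object)$unassigned, "\n")
})

#' @describeIn PeakCellMatrix-accessors the sparse count matrix
#' @export
peakCounts <- function(x) SummarizedExperiment::assay(x, "counts")
#' Accessors for PeakCellMatrix
#' @param x a `PeakCellMatrix`
#' @name PeakCellMatrix-accessors
#' @describeIn PeakCellMatrix-accessors reads not assigned to any peak
#' @export
unassignedCount <- function(x) {
    u <- metadata(x)$unassigned
    if (is.null(u)) 0L else u
}
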