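# Text-format I/O: SAM round trips via Rsamtools, interval tracks via
# rtracklayer, tables as TSV. All coordinates in tables are 1-based
# inclusive (GTF convention); BED/bedGraph exports are 0-based half-open
# as produced by rtracklayer.

#' Write tagged alignments as SAM
#'
#' Reconstructs each record's SEQ from the genome (aligned blocks) plus the
#' stored soft-clip sequences, so records satisfy the SAM length contract.
#' Only S/M/N CIGAR operations are supported.
#'
#' @param reads `GAlignments` with metadata columns `CB`, `UB`, `mapq`,
#'   `clip5`, `clip3`.
#' @param file output path.
#' @param genome `DNAStringSet` covering all read chromosomes.
#' @return `file`, invisibly.
#' @export
writeTaggedSam <- function(reads, file, genome) {
    m <- mcols(reads)
    if (length(reads) &&
        any(grepl("[IDHP=X]", GenomicAlignments::cigar(reads))))
        stop("writeTaggedSam supports only S/M/N CIGAR operations")
    hdr <- c("@HD\tVN:1.6\tSO:unsorted",
             paste0("@SQ\tSN:", names(genome), "\tLN:",
                    Biostrings::width(genome)))
    if (length(reads) == 0L) {
        writeLines(hdr, file)
        return(invisible(file))
    }
    blocks <- GenomicAlignments::grglist(reads)
    flat <- unlist(blocks, use.names = FALSE)
    GenomicRanges::strand(flat) <- "*"   # SEQ is stored forward-strand
    grpIdx <- rep(seq_along(reads), S4Vectors::elementNROWS(blocks))
    o <- order(grpIdx, GenomicRanges::start(flat))  # ascending within read
    flat <- flat[o]; grpIdx <- grpIdx[o]
    flatSeq <- as.character(.getSeqGR(genome, flat))
    bseq <- vapply(split(flatSeq, factor(grpIdx, seq_along(reads))),
                   paste, character(1), collapse = "")
    c5 <- ifelse(is.na(m$clip5), "", m$clip5)
    c3 <- ifelse(is.na(m$clip3), "", m$clip3)
    seqs <- paste0(c5, bseq, c3)
    flag <- ifelse(as.character(GenomicAlignments::strand(reads)) == "-",
                   16L, 0L)
    qn <- names(reads)
    if (is.null(qn)) qn <- sprintf("r%06d", seq_along(reads))
    lines <- paste(qn, flag,
                   as.character(GenomicAlignments::seqnames(reads)),
                   GenomicAlignments::start(reads), m$mapq,
                   GenomicAlignments::cigar(reads), "*", 0L, 0L, seqs, "*",
                   paste0("CB:Z:", m$CB), paste0("UB:Z:", m$UB),
                   sep = "\t")
    writeLines(c(hdr, lines), file)
    invisible(file)
}

#' Read tagged alignments from SAM or BAM
#'
#' SAM input is converted to BAM via [Rsamtools::asBam] first. Soft-clip
#' prefix/suffix sequences are extracted from SEQ using the CIGAR. MAPQ 255
#' ("unavailable" in the SAM spec, but the unique-alignment convention of
#' common scRNA-seq aligners) is preserved as 255.
#'
#' @param file path to a `.sam` or `.bam` file.
#' @return `GAlignments` with metadata columns `CB`, `UB`, `mapq`, `clip5`,
#'   `clip3`.
#' @export
readTaggedReads <- function(file) {
    if (grepl("\\.sam$", file, ignore.case = TRUE)) {
        dest <- tempfile(fileext = "")
        bam <- Rsamtools::asBam(file, destination = dest, overwrite = TRUE,
                                indexDestination = FALSE)
    } else bam <- file
    param <- Rsamtools::ScanBamParam(what = c("mapq", "seq", "qname"),
                                     tag = c("CB", "UB"))
    ga <- GenomicAlignments::readGAlignments(bam, param = param)
    cig <- GenomicAlignments::cigar(ga)
    sq <- as.character(mcols(ga)$seq)
    cl5 <- cl3 <- character(length(ga))
    lead <- regmatches(cig, regexpr("^[0-9]+S", cig))
    trail <- regmatches(cig, regexpr("[0-9]+S$", cig))
    hasLead <- grepl("^[0-9]+S", cig)
    hasTrail <- grepl("[0-9]+S$", cig)
    n5 <- integer(length(ga)); n3 <- integer(length(ga))
    n5[hasLead] <- as.integer(sub("S$", "", lead))
    n3[hasTrail] <- as.integer(sub("S$", "", trail))
    cl5 <- substr(sq, 1L, n5)
    cl3 <- substr(sq, nchar(sq) - n3 + 1L, nchar(sq))
    cl3[n3 == 0L] <- ""
    mq <- mcols(ga)$mapq
    mq[is.na(mq)] <- 255L   # htslib may surface MAPQ 255 as NA
    out <- ga
    nm <- mcols(ga)$qname
    mcols(out) <- S4Vectors::DataFrame(CB = mcols(ga)$CB, UB = mcols(ga)$UB,
                                       mapq = mq, clip5 = cl5, clip3 = cl3)
    names(out) <- nm
    out
}

#' Read a one-barcode-per-line subset file
#'
#' @param file path to a headerless TSV, one cell barcode per row
#'   (`[sample]_subset_barcodes.tsv` convention).
#' @return character vector of barcodes.
#' @export
readBarcodeList <- function(file) {
    bc <- readLines(file)
    bc <- trimws(bc)
    bc[nzchar(bc)]
}

#' Keep only reads from a set of cell barcodes
#'
#' @param reads tagged `GAlignments`.
#' @param barcodes character vector of barcodes to keep.
#' @return the subset, with a message reporting how many reads were dropped.
#' @export
subsetByBarcodes <- function(reads, barcodes) {
    keep <- !is.na(mcols(reads)$CB) & mcols(reads)$CB %in% barcodes
    .msg("barcode subset: kept ", sum(keep), "/", length(reads), " reads")
    reads[keep]
}

#' Read cell-group metadata
#'
#' The first column must contain the cell barcodes; `column` names the
#' column holding the testing-group labels.
#'
#' @param file CSV path.
#' @param column name of the group-label column.
#' @return named character vector: barcode -> group label.
#' @export
readCellMetadata <- function(file, column) {
    df <- utils::read.csv(file, stringsAsFactors = FALSE)
    if (!column %in% names(df))
        stop("metadata lacks column '", column, "'")
    stats::setNames(as.character(df[[column]]), as.character(df[[1]]))
}

# ---- peak tables ----------------------------------------------------------

#' Write a peak table as TSV (1-based inclusive coordinates)
#'
#' @param peaks `GRanges` with peak metadata columns.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writePeaksTsv <- function(peaks, file) {
    df <- as.data.frame(peaks)
    names(df)[names(df) == "seqnames"] <- "chrom"
    df$width <- NULL
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' Read a peak table written by [writePeaksTsv()]
#'
#' @param file TSV path.
#' @return `GRanges` with the stored metadata columns.
#' @export
readPeaksTsv <- function(file) {
    df <- utils::read.delim(file, stringsAsFactors = FALSE)
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start, df$end),
                                 strand = df$strand)
    extra <- setdiff(names(df), c("chrom", "start", "end", "strand"))
    mcols(gr) <- S4Vectors::DataFrame(df[extra])
    gr
}

#' Write the final annotated peak reference table
#'
#' Produces the `[file_prefix]_final_peak_universe_updated.txt` layout:
#' peak name, 1-based inclusive coordinates, strand, genomic-context class,
#' fragmentation flag, junction support and read count, plus the gene/TU
#' bookkeeping columns.
#'
#' @param peaks named, classified `GRanges` (see [namePeaks()]).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writePeakReference <- function(peaks, file) {
    m <- mcols(peaks)
    df <- data.frame(
        name = m$peak_name,
        chrom = as.character(GenomicRanges::seqnames(peaks)),
        start = GenomicRanges::start(peaks),
        end = GenomicRanges::end(peaks),
        strand = as.character(GenomicRanges::strand(peaks)),
        class = m$class,
        fragmented_flag = m$fragmented_flag,
        junction_support = m$junction_support,
        read_count = m$read_count,
        gene = m$gene, tu_id = m$tu_id, peak_number = m$peak_number,
        prong = m$prong, summit = m$summit, gene_usage = m$gene_usage)
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' Read a final peak reference table
#'
#' @param file path written by [writePeakReference()].
#' @return `GRanges` with the reference metadata columns (`peak_name`,
#'   `class`, `fragmented_flag`, `junction_support`, `read_count`, `gene`,
#'   `tu_id`, `peak_number`, `prong`, `summit`, `gene_usage`).
#' @export
readPeakReference <- function(file) {
    df <- utils::read.delim(file, stringsAsFactors = FALSE)
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start, df$end),
                                 strand = df$strand)
    mcols(gr) <- S4Vectors::DataFrame(
        peak_name = df$name, class = df$class,
        fragmented_flag = df$fragmented_flag,
        junction_support = df$junction_support, read_count = df$read_count,
        gene = df$gene, tu_id = df$tu_id, peak_number = df$peak_number,
        prong = df$prong, summit = df$summit, gene_usage = df$gene_usage)
    gr
}

#' Write cleavage events as 6-column BED
#'
#' Name is `cb:ub`, score 0; the cleavage coordinate convention (last
#' aligned base on +, base before the alignment start on -) is stated in a
#' track header comment.
#'
#' @param events cleavage-event `GRanges` from [detectJunctionReads()].
#' @param file BED output path.
#' @return `file`, invisibly.
#' @export
writeCleavageBed <- function(events, file) {
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(events)),
        start = GenomicRanges::start(events) - 1L,
        end = GenomicRanges::end(events),
        name = if (length(events)) paste0(mcols(events)$cb, ":",
                                          mcols(events)$ub)
               else character(0),
        score = rep(0L, length(events)),
        strand = as.character(GenomicRanges::strand(events)))
    con <- file(file, "w")
    writeLines(paste0("# cleavage coordinate: last aligned base (+ strand),",
                      " base preceding alignment start (- strand);",
                      " intervals 0-based half-open"), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    close(con)
    invisible(file)
}

#' Read cleavage events from a BED file written by [writeCleavageBed()]
#'
#' @param file BED path.
#' @return cleavage-event `GRanges` with `cb` and `ub` columns.
#' @export
readCleavageBed <- function(file) {
    df <- utils::read.delim(file, header = FALSE, comment.char = "#",
                            stringsAsFactors = FALSE)
    nm <- strsplit(df$V4, ":", fixed = TRUE)
    GenomicRanges::GRanges(df$V1, IRanges::IRanges(df$V2 + 1L, df$V3),
                           strand = df$V6,
                           cb = vapply(nm, `[`, character(1), 1L),
                           ub = vapply(nm, `[`, character(1), 2L))
}
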