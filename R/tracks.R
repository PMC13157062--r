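#' Write stranded per-base coverage as bedGraph
#'
#' One file per strand (`<prefix>_plus.bedGraph`, `<prefix>_minus.bedGraph`),
#' 0-based half-open intervals with adjacent equal-value runs merged;
#' zero-coverage runs are omitted. bedGraph is the text form of the usual
#' bigWig QC tracks (convert with `bedGraphToBigWig` if a browser-ready
#' binary is wanted).
#'
#' @param reads tagged `GAlignments`.
#' @param prefix file-name prefix (may include a directory).
#' @return character vector of the two paths, invisibly.
#' @export
writeStrandedCoverage <- function(reads, prefix) {
    out <- c(plus = paste0(prefix, "_plus.bedGraph"),
             minus = paste0(prefix, "_minus.bedGraph"))
    for (st in c("+", "-")) {
        sub <- reads[as.character(GenomicAlignments::strand(reads)) == st]
        f <- if (st == "+") out["plus"] else out["minus"]
        if (length(sub) == 0L) { file.create(f); next }
        gr <- methods::as(.blockCoverage(sub), "GRanges")
        gr <- gr[mcols(gr)$score > 0]
        GenomicRanges::strand(gr) <- "*"
        rtracklayer::export(gr, f, format = "bedGraph")
    }
    invisible(out)
}

#' Write per-group fractional-usage tracks
#'
#' Each tested peak emits one interval carrying its group's fractional
#' usage; P0 peaks (single-site genes) are not part of fractional usage
#' and are absent by construction. Files follow the
#' `[group_1]_v_[group_2]-[group]_<strand>.bedGraph` pattern.
#'
#' @param res APA results data.frame from [runApaTest()].
#' @param reference final peak reference `GRanges` with `peak_name`.
#' @param dir output directory.
#' @param group_one,group_two the tested group labels.
#' @return character vector of written paths, invisibly.
#' @export
writeFractionalTracks <- function(res, reference, dir, group_one,
                                  group_two) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    written <- character(0)
    if (nrow(res) == 0L) return(invisible(written))
    ix <- match(res$peak, mcols(reference)$peak_name)
    for (g in c(group_one, group_two)) {
        fr <- res[[paste0("frac_", g)]]
        for (st in c("+", "-")) {
            sel <- !is.na(fr) & !is.na(ix) &
                as.character(GenomicRanges::strand(reference))[ix] == st
            f <- file.path(dir, paste0(group_one, "_v_", group_two, "-",
                                       g, "_",
                                       if (st == "+") "plus" else "minus",
                                       ".bedGraph"))
            if (!any(sel)) { file.create(f); written <- c(written, f); next }
            gr <- reference[ix[sel]]
            df <- data.frame(
                chrom = as.character(GenomicRanges::seqnames(gr)),
                start = GenomicRanges::start(gr) - 1L,
                end = GenomicRanges::end(gr),
                score = fr[sel])
            df <- df[order(df$chrom, df$start), ]
            utils::write.table(df, f, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = FALSE)
            written <- c(written, f)
        }
    }
    invisible(written)
}

#' Start an empty filtering-statistics ledger
#'
#' @return zero-row data.frame with the stage-tally columns.
#' @export
newRefStats <- function() {
    data.frame(stage = character(0), reads_in = integer(0),
               reads_out = integer(0), peaks_in = integer(0),
               peaks_out = integer(0))
}

#' Append one stage's tallies to a statistics ledger
#'
#' @param stats ledger from [newRefStats()].
#' @param stage stage label.
#' @param reads_in,reads_out,peaks_in,peaks_out tallies (NA when a stage
#'   does not touch that quantity).
#' @return the extended ledger.
#' @export
addRefStat <- function(stats, stage, reads_in = NA, reads_out = NA,
                       peaks_in = NA, peaks_out = NA) {
    rbind(stats, data.frame(stage = stage,
                            reads_in = as.integer(reads_in),
                            reads_out = as.integer(reads_out),
                            peaks_in = as.integer(peaks_in),
                            peaks_out = as.integer(peaks_out)))
}

#' Write the `[file_prefix]_PA_ref_stats.txt` report
#'
#' One row per pipeline stage with read and peak counts in and out,
#' summarizing how each filtering step refined the data.
#'
#' @param stats ledger from [addRefStat()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeRefStats <- function(stats, file) {
    utils::write.table(stats, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' Read a statistics report written by [writeRefStats()]
#'
#' @param file path.
#' @return data.frame ledger.
#' @export
readRefStats <- function(file) {
    utils::read.delim(file, stringsAsFactors = FALSE)
}
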