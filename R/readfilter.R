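#' Read-filtering configuration
#'
#' Thresholds for deduplication-adjacent filtering and the two-round
#' genomic-A (internal priming) filter. The A-content defaults mirror
#' common internal-priming heuristics for oligo-dT protocols: a read is an
#' artifact candidate when the 10 template bases downstream of its 3' end
#' are >= 70% adenosine or contain a run of >= 6 consecutive A.
#'
#' @param min_mapq minimum MAPQ retained (255 = unique-alignment convention
#'   of common scRNA-seq aligners).
#' @param a_window downstream window length in bases.
#' @param a_frac_threshold adenosine fraction at or above which the window
#'   qualifies as internal priming.
#' @param a_run_threshold length of a consecutive-A run that qualifies.
#' @param min_clip,min_a_frac junction-tail parameters used for the
#'   exemption of poly(A) junction reads (see [detectJunctionReads()]).
#' @return a list of class `filterConfig`.
#' @export
filterConfig <- function(min_mapq = 255L, a_window = 10L,
                         a_frac_threshold = 0.7, a_run_threshold = 6L,
                         min_clip = 6L, min_a_frac = 0.8) {
    stopifnot(a_window >= 1L, a_frac_threshold >= 0, a_frac_threshold <= 1,
              a_run_threshold >= 1L)
    structure(list(min_mapq = as.integer(min_mapq),
                   a_window = as.integer(a_window),
                   a_frac_threshold = a_frac_threshold,
                   a_run_threshold = as.integer(a_run_threshold),
                   min_clip = as.integer(min_clip),
                   min_a_frac = min_a_frac),
              class = c("filterConfig", "list"))
}

#' Remove PCR duplicates
#'
#' Reads sharing (cell barcode, UMI, 3'-end coordinate, strand) are PCR
#' duplicates of one molecule; exactly one is retained per key - the
#' highest-MAPQ member, ties broken by first occurrence. The 3'-end
#' coordinate (not the leftmost position) is the key component because
#' 3'-tagged reads pile up at the cleavage site. Reads lacking a CB or UB
#' tag are dropped (count reported).
#'
#' @param reads tagged `GAlignments`.
#' @return deduplicated `GAlignments`, input order preserved.
#' @export
deduplicateReads <- function(reads) {
    m <- mcols(reads)
    tagged <- !is.na(m$CB) & !is.na(m$UB) & nzchar(m$CB) & nzchar(m$UB)
    if (any(!tagged))
        .msg("dedup: dropped ", sum(!tagged), " reads lacking CB/UB tags")
    reads <- reads[tagged]
    if (length(reads) == 0L) return(reads)
    m <- mcols(reads)
    key <- paste(m$CB, m$UB, .threePrimeEnd(reads),
                 as.character(GenomicAlignments::strand(reads)), sep = "\r")
    o <- order(key, -m$mapq, seq_along(reads), method = "radix")
    keep <- o[!duplicated(key[o])]
    reads[sort(keep)]
}

#' Remove ambiguously mapped reads
#'
#' @param reads tagged `GAlignments`.
#' @param min_mapq minimum MAPQ retained.
#' @return reads with `mapq >= min_mapq`.
#' @export
filterAmbiguous <- function(reads, min_mapq = 255L) {
    reads[mcols(reads)$mapq >= min_mapq]
}

# does the downstream window qualify as internal priming?
.windowIsPrimed <- function(win, cfg) {
    .letterFrac(win, "A") >= cfg$a_frac_threshold |
        .maxRun(win, "A") >= cfg$a_run_threshold
}

# spliced transcript models from a GTF-style GRanges: per transcript a list
# with strand-ordered exons and cumulative widths, plus the spliced sequence.
.transcriptModels <- function(annotation, genome) {
    ex <- annotation[mcols(annotation)$type == "exon"]
    if (length(ex) == 0L) return(list())
    keys <- unique(mcols(ex)$transcript_id)
    out <- lapply(keys, function(tx) {
        e <- ex[mcols(ex)$transcript_id == tx]
        neg <- as.character(GenomicRanges::strand(e)[1]) == "-"
        e <- e[order(GenomicRanges::start(e), decreasing = neg)]
        seqs <- .getSeqGR(genome, e)   # transcript sense per exon
        list(exons = e, strand = if (neg) "-" else "+",
             cumw = cumsum(GenomicRanges::width(e)),
             seq = paste(as.character(seqs), collapse = ""))
    })
    names(out) <- keys
    out
}

# transcript-sense coordinate of genomic position p within model tm, or NA
.txCoord <- function(tm, p) {
    e <- tm$exons
    w <- GenomicRanges::width(e)
    off <- c(0L, tm$cumw[-length(w)])
    for (i in seq_along(e)) {
        s <- GenomicRanges::start(e)[i]; en <- GenomicRanges::end(e)[i]
        if (p >= s && p <= en) {
            return(off[i] + if (tm$strand == "+") p - s + 1L else en - p + 1L)
        }
    }
    NA_integer_
}

#' Two-round genomic-A (internal priming) filter
#'
#' A read is removed when the `a_window` template bases immediately
#' downstream of its 3' end - genomic sense for + reads, reverse-complement
#' of the upstream genomic window for - reads - are A-rich (fraction >=
#' `a_frac_threshold`) or contain a run of >= `a_run_threshold` consecutive
#' A. Round 1 evaluates reads whose 3' end falls in an annotated exon on the
#' spliced transcript sequence (so intronic A stretches spliced out of the
#' mature transcript cannot cause false removals); when fewer than
#' `a_window` spliced bases remain the window is completed with genomic
#' sequence past the transcript end. Round 2 evaluates all remaining reads
#' on the genomic sequence. Reads whose soft-clip tail qualifies as a
#' poly(A) junction tail are exempt: their non-templated tail is direct
#' evidence of genuine cleavage.
#'
#' @param reads tagged `GAlignments`.
#' @param genome `DNAStringSet`.
#' @param annotation GTF-style `GRanges` (used for round 1; may be `NULL`
#'   to apply the genomic round to every read).
#' @param cfg a [filterConfig()].
#' @return `list(kept=, removed=)`, a partition of `reads`.
#' @export
filterGenomicA <- function(reads, genome, annotation = NULL,
                           cfg = filterConfig()) {
    if (length(reads) == 0L)
        return(list(kept = reads, removed = reads))
    exempt <- isJunctionRead(reads, min_clip = cfg$min_clip,
                             min_a_frac = cfg$min_a_frac)
    st <- as.character(GenomicAlignments::strand(reads))
    p3 <- .threePrimeEnd(reads)
    chr <- as.character(GenomicAlignments::seqnames(reads))
    w <- cfg$a_window
    primed <- logical(length(reads))

    genomicWindow <- function(i) {
        if (st[i] == "+")
            as.character(.getSeqGR(genome, GenomicRanges::GRanges(chr[i],
                IRanges::IRanges(p3[i] + 1L, p3[i] + w), strand = "+")))
        else
            as.character(.getSeqGR(genome, GenomicRanges::GRanges(chr[i],
                IRanges::IRanges(p3[i] - w, p3[i] - 1L), strand = "-")))
    }

    exonic <- logical(length(reads))
    tms <- list()
    if (!is.null(annotation)) {
        ex <- annotation[mcols(annotation)$type == "exon"]
        if (length(ex)) {
            endGr <- GenomicRanges::GRanges(chr, IRanges::IRanges(p3, p3),
                                            strand = st)
            exonic <- IRanges::overlapsAny(endGr, ex, ignore.strand = FALSE)
            tms <- .transcriptModels(annotation, genome)
        }
    }
    for (i in seq_len(length(reads))) {
        if (exempt[i]) next
        win <- NULL
        if (exonic[i]) {
            # round 1: spliced-transcript window(s); removed if any
            # containing transcript's window qualifies
            for (tm in tms) {
                if (tm$strand != st[i]) next
                tp <- .txCoord(tm, p3[i])
                if (is.na(tp)) next
                avail <- substr(tm$seq, tp + 1L,
                                min(nchar(tm$seq), tp + w))
                if (nchar(avail) < w) {
                    # complete with genomic flank past the transcript end
                    need <- w - nchar(avail)
                    lastE <- tm$exons[length(tm$exons)]
                    if (tm$strand == "+") {
                        gpad <- GenomicRanges::GRanges(chr[i],
                            IRanges::IRanges(GenomicRanges::end(lastE) + 1L,
                                GenomicRanges::end(lastE) + need),
                            strand = "+")
                    } else {
                        gpad <- GenomicRanges::GRanges(chr[i],
                            IRanges::IRanges(
                                GenomicRanges::start(lastE) - need,
                                GenomicRanges::start(lastE) - 1L),
                            strand = "-")
                    }
                    avail <- paste0(avail,
                                    as.character(.getSeqGR(genome, gpad)))
                }
                if (.windowIsPrimed(avail, cfg)) { primed[i] <- TRUE; break }
            }
        } else {
            # round 2: genomic window
            primed[i] <- .windowIsPrimed(genomicWindow(i), cfg)
        }
    }
    .msg("genomic-A filter: removed ", sum(primed), "/", length(reads),
         " reads (", sum(exempt), " junction-tail exempt)")
    list(kept = reads[!primed], removed = reads[primed])
}
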