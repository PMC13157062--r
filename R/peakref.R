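#' Peak-calling configuration
#'
#' The caller is a deterministic coverage threshold-and-merge: maximal
#' intervals of per-base coverage >= `min_cov`, merging intervals separated
#' by fewer than `max_gap` zero-coverage bases. Coverage is computed over
#' aligned blocks only (spliced N gaps contribute nothing). The junction
#' prong uses a lower coverage floor to rescue low-coverage sites.
#'
#' @param min_cov_all coverage floor for the all-reads prong.
#' @param min_cov_junction coverage floor for the junction-reads prong.
#' @param max_gap zero-coverage gap below which adjacent intervals merge.
#' @param gap_len internal zero-coverage run length at which a multimodal
#'   peak is split.
#' @param min_support minimum distinct junction-read support for a peak to
#'   be retained (default 3).
#' @return a list of class `peakCallConfig`.
#' @export
peakCallConfig <- function(min_cov_all = 5L, min_cov_junction = 2L,
                           max_gap = 25L, gap_len = 10L, min_support = 3L) {
    structure(list(min_cov_all = as.integer(min_cov_all),
                   min_cov_junction = as.integer(min_cov_junction),
                   max_gap = as.integer(max_gap),
                   gap_len = as.integer(gap_len),
                   min_support = as.integer(min_support)),
              class = c("peakCallConfig", "list"))
}

# summit (leftmost coverage maximum) and 3'-end read count for intervals
# [s, e] on one chromosome
.peakStats <- function(cov, s, e, ends3) {
    summit <- integer(length(s)); rc <- integer(length(s))
    for (i in seq_along(s)) {
        v <- as.integer(S4Vectors::window(cov, s[i], e[i]))
        summit[i] <- s[i] + which.max(v) - 1L
        rc[i] <- sum(ends3 >= s[i] & ends3 <= e[i])
    }
    list(summit = summit, read_count = rc)
}

#' Call candidate poly(A) site peaks from stranded coverage
#'
#' Maximal intervals with per-base aligned-block coverage >= `min_cov`;
#' adjacent intervals separated by fewer than `max_gap` zero-coverage bases
#' are merged. The summit is the leftmost coverage maximum; `read_count`
#' counts reads whose 3' end lies inside the peak.
#'
#' @param reads single-strand `GAlignments` subset.
#' @param min_cov coverage floor.
#' @param max_gap merge gap in zero-coverage bases.
#' @return coordinate-sorted `GRanges` with `summit` and `read_count`.
#' @export
callCandidatePeaks <- function(reads, min_cov = 5L, max_gap = 25L) {
    if (length(reads) == 0L)
        return(GenomicRanges::GRanges(summit = integer(0),
                                      read_count = integer(0)))
    st <- .checkSingleStrand(reads)
    covl <- .blockCoverage(reads)
    p3 <- .threePrimeEnd(reads)
    chr <- as.character(GenomicAlignments::seqnames(reads))
    out <- list()
    for (ch in names(covl)) {
        cov <- covl[[ch]]
        sl <- IRanges::slice(cov, lower = min_cov, rangesOnly = TRUE)
        if (length(sl) == 0L) next
        s <- IRanges::start(sl); e <- IRanges::end(sl)
        # merge when < max_gap zero-coverage bases separate two islands
        grp <- integer(length(s)); grp[1] <- 1L
        if (length(s) > 1L) for (i in 2:length(s)) {
            gapZeros <- if (s[i] - e[i - 1L] <= 1L) 0L else
                sum(as.integer(S4Vectors::window(cov, e[i - 1L] + 1L,
                                                 s[i] - 1L)) == 0L)
            grp[i] <- if (gapZeros < max_gap) grp[i - 1L] else
                grp[i - 1L] + 1L
        }
        f <- factor(grp, levels = unique(grp))
        ms <- tapply(s, f, min); me <- tapply(e, f, max)
        stats <- .peakStats(cov, as.integer(ms), as.integer(me),
                            p3[chr == ch])
        out[[ch]] <- GenomicRanges::GRanges(
            factor(rep(ch, length(ms)), levels = names(covl)),
            IRanges::IRanges(as.integer(ms), as.integer(me)), strand = st,
            summit = stats$summit, read_count = stats$read_count)
    }
    if (length(out) == 0L)
        return(GenomicRanges::GRanges(summit = integer(0),
                                      read_count = integer(0)))
    GenomicRanges::sort(do.call(c, unname(out)))
}

# boundaries of non-gap segments after removing zero runs >= gap_len from a
# coverage vector (1-based offsets within the vector)
.zeroRunSplit <- function(v, gap_len) {
    r <- rle(v == 0L)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    isGap <- r$values & r$lengths >= gap_len
    keep <- !isGap
    if (!any(keep)) return(data.frame(start = integer(0), end = integer(0)))
    # merge consecutive kept runs
    grp <- cumsum(c(TRUE, diff(which(keep)) > 1L))
    f <- factor(grp, levels = unique(grp))
    data.frame(start = as.integer(tapply(starts[keep], f, min)),
               end = as.integer(tapply(ends[keep], f, max)))
}

#' Split multimodal peaks at internal coverage gaps
#'
#' Each peak is partitioned at every internal run of at least `gap_len`
#' zero-coverage bases; fragments recompute summit, read count and (when
#' `events` is supplied) junction support, and are returned in coordinate
#' order.
#'
#' @param peaks `GRanges` from [callCandidatePeaks()].
#' @param reads the same single-strand reads the peaks were called from.
#' @param gap_len zero-run length that triggers a split.
#' @param events optional cleavage events for junction-support recount.
#' @return `GRanges` of fragments.
#' @export
splitMultimodal <- function(peaks, reads, gap_len = 10L, events = NULL) {
    if (length(peaks) == 0L) return(peaks)
    covl <- .blockCoverage(reads)
    p3 <- .threePrimeEnd(reads)
    chr <- as.character(GenomicAlignments::seqnames(reads))
    frags <- list()
    for (i in seq_along(peaks)) {
        ch <- as.character(GenomicRanges::seqnames(peaks)[i])
        s <- GenomicRanges::start(peaks)[i]
        e <- GenomicRanges::end(peaks)[i]
        v <- as.integer(S4Vectors::window(covl[[ch]], s, e))
        seg <- .zeroRunSplit(v, gap_len)
        stats <- .peakStats(covl[[ch]], s + seg$start - 1L,
                            s + seg$end - 1L, p3[chr == ch])
        frags[[i]] <- GenomicRanges::GRanges(
            factor(rep(ch, nrow(seg)), levels = names(covl)),
            IRanges::IRanges(s + seg$start - 1L, s + seg$end - 1L),
            strand = GenomicRanges::strand(peaks)[i],
            summit = stats$summit, read_count = stats$read_count)
    }
    out <- GenomicRanges::sort(do.call(c, unname(frags)))
    if (!is.null(events))
        mcols(out)$junction_support <- GenomicRanges::countOverlaps(
            out, events, ignore.strand = FALSE)
    out
}

#' Retain junction-supported peaks
#'
#' Junction support is the number of cleavage events whose coordinate lies
#' inside the peak; peaks below `min_support` (default 3 supporting
#' junction reads) are discarded as unsupported artifacts.
#'
#' @param peaks `GRanges`.
#' @param events cleavage-event `GRanges`, same strand convention.
#' @param min_support minimum support.
#' @return surviving peaks with a `junction_support` column.
#' @export
retainJunctionSupported <- function(peaks, events, min_support = 3L) {
    mcols(peaks)$junction_support <- GenomicRanges::countOverlaps(
        peaks, events, ignore.strand = FALSE)
    peaks[mcols(peaks)$junction_support >= min_support]
}

#' Build one peak-calling prong
#'
#' The `all_reads` prong calls peaks on every filtered read; the
#' `junction_reads` prong calls on the junction-read subset only, with a
#' lower coverage floor, to recover genuine low-coverage sites. Both prongs
#' are then split at coverage gaps and retained by junction support.
#'
#' @param reads filtered tagged `GAlignments` (both strands allowed).
#' @param events cleavage events from [detectJunctionReads()].
#' @param prong `"all_reads"` or `"junction_reads"`.
#' @param cfg a [peakCallConfig()].
#' @return retained peaks with `summit`, `read_count`, `junction_support`
#'   and `prong` columns.
#' @export
buildProng <- function(reads, events, prong = c("all_reads",
                                                "junction_reads"),
                       cfg = peakCallConfig()) {
    prong <- match.arg(prong)
    if (prong == "junction_reads") {
        reads <- reads[isJunctionRead(reads)]
        min_cov <- cfg$min_cov_junction
    } else min_cov <- cfg$min_cov_all
    out <- list()
    for (st in c("+", "-")) {
        sub <- reads[as.character(GenomicAlignments::strand(reads)) == st]
        if (length(sub) == 0L) next
        ev <- events[as.character(GenomicRanges::strand(events)) == st]
        pk <- callCandidatePeaks(sub, min_cov = min_cov,
                                 max_gap = cfg$max_gap)
        pk <- splitMultimodal(pk, sub, gap_len = cfg$gap_len)
        pk <- retainJunctionSupported(pk, ev, min_support = cfg$min_support)
        if (length(pk)) out[[st]] <- pk
    }
    if (length(out) == 0L)
        return(GenomicRanges::GRanges(summit = integer(0),
                                      read_count = integer(0),
                                      junction_support = integer(0),
                                      prong = character(0)))
    pk <- GenomicRanges::sort(do.call(c, unname(out)), ignore.strand = TRUE)
    mcols(pk)$prong <- prong
    pk
}
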