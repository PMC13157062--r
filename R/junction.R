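#' Identify poly(A) junction reads
#'
#' A + read is a junction read when its 3' soft-clip (`clip3`) is at least
#' `min_clip` long with adenosine fraction >= `min_a_frac`; a - read when
#' its 5' soft-clip (`clip5`, stored in genomic forward orientation) is
#' T-rich by the same rule. The non-templated tail marks the transition
#' from template to poly(A) and thus the cleavage site.
#'
#' @param reads tagged `GAlignments` with `clip5`/`clip3` columns.
#' @param min_clip minimum soft-clip length.
#' @param min_a_frac minimum A (or T) fraction of the clip.
#' @return logical vector along `reads`.
#' @export
isJunctionRead <- function(reads, min_clip = 6L, min_a_frac = 0.8) {
    if (length(reads) == 0L) return(logical(0))
    m <- mcols(reads)
    neg <- as.character(GenomicAlignments::strand(reads)) == "-"
    clip <- ifelse(neg, m$clip5, m$clip3)
    clip[is.na(clip)] <- ""
    frac <- ifelse(neg, .letterFrac(clip, "T"), .letterFrac(clip, "A"))
    nchar(clip) >= min_clip & frac >= min_a_frac
}

#' Derive cleavage events from poly(A) junction reads
#'
#' Each qualifying read yields one event at its cleavage coordinate: the
#' last aligned base for + reads, the base immediately preceding the
#' alignment start for - reads (the first non-templated base, read in
#' genomic order).
#'
#' @inheritParams isJunctionRead
#' @return width-1 `GRanges` with metadata columns `cb` and `ub`.
#' @export
detectJunctionReads <- function(reads, min_clip = 6L, min_a_frac = 0.8) {
    hit <- isJunctionRead(reads, min_clip, min_a_frac)
    r <- reads[hit]
    pos <- .cleavagePos(r)
    ok <- pos >= 1L
    r <- r[ok]; pos <- pos[ok]
    GenomicRanges::GRanges(
        as.character(GenomicAlignments::seqnames(r)),
        IRanges::IRanges(pos, pos),
        strand = as.character(GenomicAlignments::strand(r)),
        cb = mcols(r)$CB, ub = mcols(r)$UB,
        seqlengths = GenomeInfoDb::seqlengths(r))
}
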