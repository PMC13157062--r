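# Internal helpers shared across modules.

# 3'-end coordinate of each alignment (1-based): last aligned base for +,
# first aligned base for -. This is the informative coordinate of a 3'-tagged
# read and the deduplication key component.
.threePrimeEnd <- function(reads) {
    ifelse(as.character(GenomicAlignments::strand(reads)) == "-",
           GenomicAlignments::start(reads), GenomicAlignments::end(reads))
}

# Cleavage coordinate under the junction convention: for + the last aligned
# base; for - the base immediately before the alignment start (the first
# non-templated base read in genomic order).
.cleavagePos <- function(reads) {
    ifelse(as.character(GenomicAlignments::strand(reads)) == "-",
           GenomicAlignments::start(reads) - 1L,
           GenomicAlignments::end(reads))
}

# Fraction of `letter` in each string of a character vector; 0-length -> 0.
.letterFrac <- function(x, letter) {
    x[is.na(x)] <- ""
    n <- nchar(x)
    cnt <- vapply(strsplit(x, ""), function(ch) sum(ch == letter), 0L)
    ifelse(n == 0L, 0, cnt / n)
}

# Length of the longest run of `letter` in each string.
.maxRun <- function(x, letter) {
    x[is.na(x)] <- ""
    vapply(x, function(s) {
        if (!nzchar(s)) return(0L)
        r <- rle(strsplit(s, "")[[1]] == letter)
        m <- r$lengths[r$values]
        if (length(m)) max(m) else 0L
    }, 0L, USE.NAMES = FALSE)
}

# Extract sequences for a GRanges from an in-memory DNAStringSet genome,
# reverse-complementing minus-strand ranges. Coordinates are clipped to the
# chromosome; callers relying on clipping get the available bases only.
.getSeqGR <- function(genome, gr) {
    if (length(gr) == 0L) return(Biostrings::DNAStringSet())
    chr <- as.character(GenomicRanges::seqnames(gr))
    if (!all(chr %in% names(genome)))
        stop("genome lacks chromosome(s): ",
             paste(unique(setdiff(chr, names(genome))), collapse = ", "))
    len <- Biostrings::width(genome)[match(chr, names(genome))]
    s <- pmax(GenomicRanges::start(gr), 1L)
    e <- pmin(GenomicRanges::end(gr), len)
    out <- Biostrings::DNAStringSet(vapply(seq_along(gr), function(i) {
        if (s[i] > e[i]) return("")
        as.character(Biostrings::subseq(genome[[chr[i]]], s[i], e[i]))
    }, character(1)))
    neg <- as.character(GenomicRanges::strand(gr)) == "-"
    if (any(neg)) out[neg] <- Biostrings::reverseComplement(out[neg])
    out
}

# Run code under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, code) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

# Sorted stranded coverage (RleList) over aligned blocks; N gaps and soft
# clips contribute nothing.
.blockCoverage <- function(reads) {
    GenomicAlignments::coverage(reads)
}

.checkSingleStrand <- function(reads) {
    st <- unique(as.character(GenomicAlignments::strand(reads)))
    if (length(st) > 1L)
        stop("reads must be a single-strand subset; got strands: ",
             paste(st, collapse = ", "))
    invisible(st)
}

.msg <- function(...) message("[scPolyAUsage] ", ...)
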