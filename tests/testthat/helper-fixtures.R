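# Shared fixtures (built once per run) and independent brute-force oracles.

.fixtures <- new.env(parent = emptyenv())

# the standard validation dataset, plus its filtered reads/events/reference
sharedSim <- function() {
    if (is.null(.fixtures$sim))
        .fixtures$sim <- simulatePolyADataset(simConfig())
    .fixtures$sim
}

sharedFiltered <- function() {
    if (is.null(.fixtures$filtered)) {
        sim <- sharedSim()
        dd <- deduplicateReads(simReads(sim))
        amb <- filterAmbiguous(dd)
        fa <- suppressMessages(filterGenomicA(amb, simGenome(sim),
                                              simAnnotation(sim)))
        .fixtures$filtered <- list(dedup = dd, ambig = amb, kept = fa$kept,
                                   removed = fa$removed)
    }
    .fixtures$filtered
}

sharedReference <- function() {
    if (is.null(.fixtures$reference)) {
        sim <- sharedSim()
        reads <- sharedFiltered()$kept
        ev <- detectJunctionReads(reads)
        turef <- buildTuReference(simAnnotation(sim))
        fa <- suppressMessages({
            a <- assignPeaksToTu(buildProng(reads, ev, "all_reads"), turef)
            applyPeakFilters(a, peakFilterConfig(), simGenome(sim), turef)
        })
        fj <- suppressMessages({
            a <- assignPeaksToTu(buildProng(reads, ev, "junction_reads"),
                                 turef)
            applyPeakFilters(a, peakFilterConfig(), simGenome(sim), turef)
        })
        merged <- mergeProngs(fa, fj)
        turef2 <- updateTuEnds(turef, merged)
        merged <- namePeaks(flagFragmented(classifyPeaks(merged, turef2),
                                           reads))
        .fixtures$reference <- list(events = ev, turef = turef2,
                                    peaks = merged)
    }
    .fixtures$reference
}

sharedMatrix <- function() {
    if (is.null(.fixtures$matrix))
        .fixtures$matrix <- suppressMessages(buildPeakCellMatrix(
            sharedFiltered()$kept, sharedReference()$peaks))
    .fixtures$matrix
}

sharedGroups <- function() {
    md <- simCellMetadata(sharedSim())
    stats::setNames(md$test_ident, md$barcode)
}

# construct a GAlignments fixture from a compact spec
makeReads <- function(chrom, start, cigar, strand, cb = "CB1", ub = NULL,
                      mapq = 255L, clip5 = "", clip3 = "",
                      seqlengths = c(chr1 = 100000L, chr2 = 100000L)) {
    n <- max(length(chrom), length(start), length(cigar), length(strand))
    if (is.null(ub)) ub <- paste0("U", seq_len(n))
    ga <- GenomicAlignments::GAlignments(
        seqnames = S4Vectors::Rle(factor(rep_len(chrom, n),
                                         levels = names(seqlengths))),
        pos = as.integer(rep_len(start, n)),
        cigar = rep_len(cigar, n),
        strand = S4Vectors::Rle(GenomicRanges::strand(rep_len(strand, n))),
        seqlengths = seqlengths)
    S4Vectors::mcols(ga) <- S4Vectors::DataFrame(
        CB = rep_len(cb, n), UB = rep_len(ub, n),
        mapq = as.integer(rep_len(mapq, n)),
        clip5 = rep_len(clip5, n), clip3 = rep_len(clip3, n))
    names(ga) <- paste0("r", seq_len(n))
    ga
}

# ---- brute-force oracles (kept independent of package internals) ---------

# per-base threshold-and-merge peak caller over explicit block intervals
oracleCallPeaks <- function(blocks, ends3, chromLen, min_cov, max_gap) {
    cov <- integer(chromLen)
    for (b in blocks) cov[b[1]:b[2]] <- cov[b[1]:b[2]] + 1L
    above <- which(cov >= min_cov)
    if (length(above) == 0L)
        return(data.frame(start = integer(0), end = integer(0),
                          summit = integer(0), read_count = integer(0)))
    brk <- c(0L, which(diff(above) > 1L), length(above))
    isl <- data.frame(start = above[brk[-length(brk)] + 1L],
                      end = above[brk[-1]])
    # merge islands separated by < max_gap zero-coverage bases
    out <- isl[1, , drop = FALSE]
    if (nrow(isl) > 1L) for (i in 2:nrow(isl)) {
        gap <- (out$end[nrow(out)] + 1L):(isl$start[i] - 1L)
        if (sum(cov[gap] == 0L) < max_gap)
            out$end[nrow(out)] <- isl$end[i]
        else out <- rbind(out, isl[i, ])
    }
    out$summit <- vapply(seq_len(nrow(out)), function(i) {
        v <- cov[out$start[i]:out$end[i]]
        out$start[i] + which.max(v) - 1L
    }, 0L)
    out$read_count <- vapply(seq_len(nrow(out)), function(i)
        sum(ends3 >= out$start[i] & ends3 <= out$end[i]), 0L)
    out
}

# zero-run splitter over an explicit coverage vector
oracleZeroSplit <- function(v, gap_len) {
    inGap <- v == 0L
    segs <- data.frame(start = integer(0), end = integer(0))
    i <- 1L
    while (i <= length(v)) {
        if (!inGap[i]) {
            j <- i
            while (j < length(v) && !inGap[j + 1L]) j <- j + 1L
            segs <- rbind(segs, data.frame(start = i, end = j))
            i <- j + 1L
        } else i <- i + 1L
    }
    # re-merge segments separated by short zero runs
    if (nrow(segs) > 1L) {
        keep <- segs[1, , drop = FALSE]
        for (k in 2:nrow(segs)) {
            if (segs$start[k] - keep$end[nrow(keep)] - 1L < gap_len)
                keep$end[nrow(keep)] <- segs$end[k]
            else keep <- rbind(keep, segs[k, ])
        }
        segs <- keep
    }
    segs
}

# sorted step-up BH
oracleBH <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    adj <- pmin(adj, 1)
    out <- numeric(n)
    out[o] <- adj
    out
}

# priority classification over explicit interval sets
oracleClassify <- function(pkStart, pkEnd, pkStrand, sets) {
    hits <- function(set) {
        if (nrow(set) == 0L) return(FALSE)
        any(set$strand == pkStrand & set$start <= pkEnd &
                set$end >= pkStart)
    }
    if (hits(sets$utr3)) return("3'UTR")
    if (hits(sets$tss)) return("TSS-proximal")
    if (hits(sets$exon)) return("Exonic")
    if (hits(sets$intron)) return("Intronic")
    "Flank"
}

# per-read 3'-end containment counter
oracleCount <- function(end3, strand, cb, peaks) {
    tallies <- list()
    unassigned <- 0L
    for (i in seq_along(end3)) {
        hit <- which(peaks$strand == strand[i] & peaks$start <= end3[i] &
                         peaks$end >= end3[i])
        if (length(hit) == 0L) { unassigned <- unassigned + 1L; next }
        key <- paste(peaks$name[hit[1]], cb[i])
        tallies[[key]] <- (tallies[[key]] %||% 0L) + 1L
    }
    list(tallies = tallies, unassigned = unassigned)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# End-to-end runs on written files; built once and reused across blocks.
pipelineRun <- local({
    cache <- NULL
    function() {
        if (!is.null(cache)) return(cache)
        d <- file.path(tempdir(), "pipe-e2e")
        writeSimulation(sharedSim(), d)
        cfg <- pipelineConfig(
            fasta = file.path(d, "genome.fa"),
            gtf = file.path(d, "annotation.gtf"),
            alignments = c(sim = file.path(d, "reads.sam")),
            output_dir = file.path(d, "outputs"), compartment = "sim",
            group_one = "group1", group_two = "group2",
            metadata_file = file.path(d, "metadata.csv"))
        out <- suppressWarnings(runPipeline(cfg))
        cache <<- list(dir = d, cfg = cfg, out = out)
        cache
    }
})

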