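#' Peak-filtering configuration
#'
#' Defaults follow the printed rules: processing regions longer than
#' 1,000 bp and peaks below 10% of their gene's read total are removed;
#' optional poly(A)-signal (PAS) filtering retains a peak only if a
#' canonical hexamer occurs within `pas_window` bases upstream of its
#' summit (transcription sense) or the peak lies within `max_tes_dist` of
#' an annotated transcript end site. The hexamer set is the canonical
#' AATAAA/ATTAAA plus ten common single-base variants.
#'
#' @param max_region_len maximum processing-region length in bases.
#' @param min_gene_usage minimum per-gene read share.
#' @param pas_filtering logical; apply the PAS/TES retention rule.
#' @param pas_hexamers character vector of PAS motifs.
#' @param pas_window bases upstream of the summit searched for a motif.
#' @param max_tes_dist maximum distance to an annotated TES.
#' @param flank 3' flank length in bases used for TU extension.
#' @param tss_width width of the TSS-proximal interval.
#' @return a list of class `peakFilterConfig`.
#' @export
peakFilterConfig <- function(max_region_len = 1000L, min_gene_usage = 0.10,
                             pas_filtering = TRUE,
                             pas_hexamers = c("AATAAA", "ATTAAA", "AGTAAA",
                                              "TATAAA", "CATAAA", "GATAAA",
                                              "AATATA", "AATACA", "AATAGA",
                                              "AATGAA", "ACTAAA", "AAGAAA"),
                             pas_window = 50L, max_tes_dist = 50L,
                             flank = 5000L, tss_width = 300L) {
    structure(list(max_region_len = as.integer(max_region_len),
                   min_gene_usage = min_gene_usage,
                   pas_filtering = isTRUE(pas_filtering),
                   pas_hexamers = toupper(pas_hexamers),
                   pas_window = as.integer(pas_window),
                   max_tes_dist = as.integer(max_tes_dist),
                   flank = as.integer(flank),
                   tss_width = as.integer(tss_width)),
              class = c("peakFilterConfig", "list"))
}

#' Build a transcription-unit reference from a gene annotation
#'
#' Same-strand transcripts of a gene are merged into one transcription unit
#' (TU) spanning their union; each TU is extended by `flank` bases in the
#' 3' direction (to capture unannotated distal sites) and TU ids are
#' assigned in coordinate order starting at 1. Genes with transcripts on
#' both strands yield one TU per strand (with a warning). Annotated
#' transcript end sites, exon/intron partitions, 3' UTR features (when the
#' GTF provides them) and TSS-proximal windows are collected for later
#' classification.
#'
#' @param annotation GTF-style `GRanges` with `type`, `gene_name` (or
#'   `gene_id`) and `transcript_id` columns.
#' @param flank 3' extension in bases (default 5,000).
#' @param tss_width TSS-proximal window width (default 300).
#' @return a [TuReference].
#' @export
buildTuReference <- function(annotation, flank = 5000L, tss_width = 300L) {
    m <- mcols(annotation)
    gname <- if ("gene_name" %in% names(m) && !all(is.na(m$gene_name)))
        m$gene_name else m$gene_id
    tx <- annotation[m$type == "transcript"]
    txg <- gname[m$type == "transcript"]
    if (length(tx) == 0L) {  # derive transcript spans from exons
        ex0 <- annotation[m$type == "exon"]
        sp <- split(ex0, mcols(ex0)$transcript_id)
        tx <- unlist(GenomicRanges::reduce(sp, min.gapwidth = 1e9),
                     use.names = FALSE)
        txg <- gname[m$type == "exon"][!duplicated(
            mcols(ex0)$transcript_id)]
    }
    key <- paste(txg, as.character(GenomicRanges::strand(tx)), sep = "\r")
    both <- tapply(as.character(GenomicRanges::strand(tx)), txg,
                   function(s) length(unique(s)) > 1L)
    if (any(both))
        warning("gene(s) with transcripts on both strands, one TU per ",
                "strand: ", paste(names(both)[both], collapse = ", "))
    sp <- split(seq_along(tx), key)
    tus <- do.call(c, unname(lapply(sp, function(ix) {
        r <- range(tx[ix])
        mcols(r)$gene <- txg[ix[1]]
        r
    })))
    o <- order(as.character(GenomicRanges::seqnames(tus)),
               GenomicRanges::start(tus))
    tus <- tus[o]
    mcols(tus)$tu_id <- seq_along(tus)
    neg <- as.character(GenomicRanges::strand(tus)) == "-"
    mcols(tus)$flank_end <- ifelse(neg,
        pmax(GenomicRanges::start(tus) - flank, 1L),
        GenomicRanges::end(tus) + flank)
    flankGr <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(tus),
        IRanges::IRanges(
            ifelse(neg, mcols(tus)$flank_end,
                   GenomicRanges::end(tus) + 1L),
            ifelse(neg, GenomicRanges::start(tus) - 1L,
                   mcols(tus)$flank_end)),
        strand = GenomicRanges::strand(tus),
        tu_id = mcols(tus)$tu_id, gene = mcols(tus)$gene)

    ex <- annotation[m$type == "exon"]
    exg <- gname[m$type == "exon"]
    exons <- do.call(c, unname(lapply(split(seq_along(ex), exg),
        function(ix) {
            r <- GenomicRanges::reduce(ex[ix])
            mcols(r)$gene <- exg[ix[1]]
            r
        })))
    introns <- do.call(c, unname(lapply(seq_along(tus), function(i) {
        g <- mcols(tus)$gene[i]
        gex <- exons[mcols(exons)$gene == g &
                     as.character(GenomicRanges::strand(exons)) ==
                         as.character(GenomicRanges::strand(tus)[i])]
        r <- GenomicRanges::setdiff(tus[i], gex, ignore.strand = FALSE)
        mcols(r) <- S4Vectors::DataFrame(gene = rep(g, length(r)))
        r
    })))
    u3 <- annotation[m$type %in% c("three_prime_utr", "3UTR", "UTR3")]
    if (length(u3)) mcols(u3) <- S4Vectors::DataFrame(
        gene = gname[m$type %in% c("three_prime_utr", "3UTR", "UTR3")])
    else u3 <- GenomicRanges::GRanges(gene = character(0))

    txneg <- as.character(GenomicRanges::strand(tx)) == "-"
    tssPos <- ifelse(txneg, GenomicRanges::end(tx),
                     GenomicRanges::start(tx))
    tss <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(tx),
        IRanges::IRanges(ifelse(txneg, tssPos - tss_width + 1L, tssPos),
                         ifelse(txneg, tssPos,
                                tssPos + tss_width - 1L)),
        strand = GenomicRanges::strand(tx), gene = txg)
    tesPos <- ifelse(txneg, GenomicRanges::start(tx),
                     GenomicRanges::end(tx))
    tes <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(tx), IRanges::IRanges(tesPos, tesPos),
        strand = GenomicRanges::strand(tx), gene = txg)

    methods::new("TuReference", tus = tus, flank = flankGr, exons = exons,
                 utr3 = u3, tss = tss, introns = introns, tes = tes,
                 flankWidth = as.integer(flank))
}

#' Assign peaks to a single transcription unit
#'
#' A peak is kept only when it overlaps (strand-matched) exactly one TU or
#' that TU's 3' flank; peaks overlapping zero or multiple TUs are dropped
#' and the counts reported.
#'
#' @param peaks `GRanges`.
#' @param turef a [TuReference].
#' @return assigned peaks with `tu_id` and `gene` columns.
#' @export
assignPeaksToTu <- function(peaks, turef) {
    tus <- turef@tus
    region <- GenomicRanges::punion(tus, turef@flank, fill.gap = TRUE)
    mcols(region) <- mcols(tus)[c("tu_id", "gene")]
    hits <- GenomicRanges::findOverlaps(peaks, region,
                                        ignore.strand = FALSE)
    nhit <- GenomicRanges::countOverlaps(peaks, region,
                                         ignore.strand = FALSE)
    .msg("TU assignment: ", sum(nhit == 0L), " peaks hit no TU, ",
         sum(nhit > 1L), " hit multiple TUs; kept ", sum(nhit == 1L))
    keep <- which(nhit == 1L)
    sel <- hits[S4Vectors::queryHits(hits) %in% keep]
    out <- peaks[S4Vectors::queryHits(sel)]
    mcols(out)$tu_id <- mcols(region)$tu_id[S4Vectors::subjectHits(sel)]
    mcols(out)$gene <- mcols(region)$gene[S4Vectors::subjectHits(sel)]
    out
}

#' Does a peak carry a poly(A) signal near its summit?
#'
#' TRUE when any configured hexamer occurs on the peak strand within
#' `pas_window` bases upstream of the summit (transcription direction),
#' summit included; the window is clipped at chromosome bounds.
#'
#' @param peaks `GRanges` with a `summit` column.
#' @param genome `DNAStringSet`.
#' @param cfg a [peakFilterConfig()].
#' @return logical vector along `peaks`.
#' @export
pasMatch <- function(peaks, genome, cfg = peakFilterConfig()) {
    if (length(peaks) == 0L) return(logical(0))
    s <- mcols(peaks)$summit
    neg <- as.character(GenomicRanges::strand(peaks)) == "-"
    win <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(peaks),
        IRanges::IRanges(ifelse(neg, s, pmax(1L, s - cfg$pas_window)),
                         ifelse(neg, s + cfg$pas_window, s)),
        strand = GenomicRanges::strand(peaks))
    seqs <- .getSeqGR(genome, win)   # transcription sense
    hit <- rep(FALSE, length(peaks))
    for (hx in cfg$pas_hexamers)
        hit <- hit | Biostrings::vcountPattern(hx, seqs) > 0L
    hit
}

#' Apply processing-region filters to assigned peaks
#'
#' In order: (1) drop peaks whose region exceeds `max_region_len`;
#' (2) per gene, drop peaks whose read share of the gene total (computed
#' once, before any usage-based removal) is below `min_gene_usage`;
#' (3) when `pas_filtering` is on, retain only peaks with a PAS motif near
#' the summit or lying within `max_tes_dist` of an annotated transcript end
#' site. The computed share is stored as `gene_usage`.
#'
#' @param peaks assigned peaks (with `tu_id`, `gene`, `read_count`).
#' @param cfg a [peakFilterConfig()].
#' @param genome `DNAStringSet` (needed when `pas_filtering`).
#' @param turef [TuReference] (needed when `pas_filtering`).
#' @param counts optional per-peak read counts overriding `read_count`.
#' @return surviving peaks with a `gene_usage` column.
#' @export
applyPeakFilters <- function(peaks, cfg = peakFilterConfig(),
                             genome = NULL, turef = NULL, counts = NULL) {
    if (length(peaks) == 0L) return(peaks)
    if (is.null(counts)) counts <- mcols(peaks)$read_count
    keepLen <- GenomicRanges::width(peaks) <= cfg$max_region_len
    peaks <- peaks[keepLen]; counts <- counts[keepLen]
    if (length(peaks) == 0L) return(peaks)
    tot <- tapply(counts, mcols(peaks)$gene, sum)
    share <- counts / as.numeric(tot[mcols(peaks)$gene])
    share[!is.finite(share)] <- 0
    mcols(peaks)$gene_usage <- share
    keepUse <- share >= cfg$min_gene_usage
    peaks <- peaks[keepUse]
    if (cfg$pas_filtering && length(peaks)) {
        if (is.null(genome) || is.null(turef))
            stop("pas_filtering requires genome and turef")
        pas <- pasMatch(peaks, genome, cfg)
        d <- GenomicRanges::distanceToNearest(peaks, turef@tes,
                                              ignore.strand = FALSE)
        nearTes <- rep(FALSE, length(peaks))
        nearTes[S4Vectors::queryHits(d)] <-
            mcols(d)$distance <= cfg$max_tes_dist
        peaks <- peaks[pas | nearTes]
    }
    peaks
}

#' Merge the two peak-calling prongs
#'
#' Union of both filtered prongs; where a junction-prong peak overlaps an
#' all-reads-prong peak on the same strand the all-reads peak wins (it
#' carries full coverage statistics) and the junction peak is discarded.
#'
#' @param prong_all filtered all-reads-prong peaks.
#' @param prong_junction filtered junction-prong peaks.
#' @return coordinate-sorted merged peaks, non-overlapping per strand.
#' @export
mergeProngs <- function(prong_all, prong_junction) {
    drop <- IRanges::overlapsAny(prong_junction, prong_all,
                                 ignore.strand = FALSE)
    cols <- intersect(names(mcols(prong_all)),
                      names(mcols(prong_junction)))
    out <- c(prong_all[, cols], prong_junction[!drop][, cols])
    GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Update TU 3' ends to the most downstream assigned peak
#'
#' Each TU's effective 3' end becomes the downstream-most boundary of its
#' assigned peaks (strand-aware), capped at the flank end; TUs without
#' peaks are unchanged.
#'
#' @param turef a [TuReference].
#' @param peaks assigned peaks carrying `tu_id`.
#' @return the updated [TuReference].
#' @export
updateTuEnds <- function(turef, peaks) {
    tus <- turef@tus
    for (i in seq_along(tus)) {
        pk <- peaks[mcols(peaks)$tu_id == mcols(tus)$tu_id[i]]
        if (length(pk) == 0L) next
        if (as.character(GenomicRanges::strand(tus)[i]) == "+") {
            newEnd <- min(max(GenomicRanges::end(pk)),
                          mcols(tus)$flank_end[i])
            GenomicRanges::end(tus)[i] <- max(newEnd,
                GenomicRanges::start(tus)[i])
        } else {
            newStart <- max(min(GenomicRanges::start(pk)),
                            mcols(tus)$flank_end[i])
            GenomicRanges::start(tus)[i] <- min(newStart,
                GenomicRanges::end(tus)[i])
        }
    }
    methods::initialize(turef, tus = tus)
}

#' Classify peaks by genomic context
#'
#' First matching label in priority order 3'UTR, TSS-proximal, Exonic,
#' Intronic, Flank; overlap means at least one shared base with the
#' strand-matched interval set, and Flank is assigned when only the 3'
#' extension is touched.
#'
#' @param peaks assigned peaks.
#' @param turef a [TuReference].
#' @return peaks with a `class` column.
#' @export
classifyPeaks <- function(peaks, turef) {
    cls <- rep("Flank", length(peaks))
    ov <- function(set) if (length(set) == 0L) rep(FALSE, length(peaks))
        else IRanges::overlapsAny(peaks, set, ignore.strand = FALSE)
    inIntron <- ov(turef@introns); cls[inIntron] <- "Intronic"
    inExon <- ov(turef@exons); cls[inExon] <- "Exonic"
    inTss <- ov(turef@tss); cls[inTss] <- "TSS-proximal"
    inU3 <- ov(turef@utr3); cls[inU3] <- "3'UTR"
    mcols(peaks)$class <- cls
    peaks
}

#' Flag peaks likely fragmented by spliced alignments
#'
#' Two adjacent peaks of the same TU are both flagged when at least one
#' spliced read has aligned blocks overlapping both peaks while its N gap
#' spans the whole inter-peak interval - evidence that one processing
#' region was split by a spliced alignment. The flag is advisory; no peak
#' is removed.
#'
#' @param peaks assigned peaks carrying `tu_id`.
#' @param reads `GAlignments` including spliced (N-gap) alignments.
#' @return peaks with a logical `fragmented_flag` column.
#' @export
flagFragmented <- function(peaks, reads) {
    flag <- rep(FALSE, length(peaks))
    spliced <- reads[GenomicAlignments::njunc(reads) > 0L]
    if (length(spliced) && length(peaks) > 1L) {
        blocks <- GenomicAlignments::grglist(spliced)
        gaps <- GenomicAlignments::junctions(spliced)
        for (tu in unique(mcols(peaks)$tu_id)) {
            ix <- which(mcols(peaks)$tu_id == tu)
            if (length(ix) < 2L) next
            ix <- ix[order(GenomicRanges::start(peaks)[ix])]
            for (k in seq_len(length(ix) - 1L)) {
                a <- ix[k]; b <- ix[k + 1L]
                gapS <- GenomicRanges::end(peaks)[a] + 1L
                gapE <- GenomicRanges::start(peaks)[b] - 1L
                if (gapE < gapS) next
                inter <- GenomicRanges::GRanges(
                    GenomicRanges::seqnames(peaks)[a],
                    IRanges::IRanges(gapS, gapE),
                    strand = GenomicRanges::strand(peaks)[a])
                ovA <- IRanges::overlapsAny(blocks, peaks[a],
                                            ignore.strand = FALSE)
                ovB <- IRanges::overlapsAny(blocks, peaks[b],
                                            ignore.strand = FALSE)
                spans <- vapply(seq_along(gaps), function(k)
                    any(IRanges::overlapsAny(inter, gaps[[k]],
                                             type = "within",
                                             ignore.strand = TRUE)),
                    logical(1))
                if (any(ovA & ovB & spans)) flag[c(a, b)] <- TRUE
            }
        }
    }
    mcols(peaks)$fragmented_flag <- flag
    peaks
}

#' Name peaks within their transcription unit
#'
#' Name format `[TU number]:[Gene name]:[Peak number]`: P0 for a gene's
#' single peak, else P1..Pn ordered from the most upstream to the most
#' downstream site in the transcription direction (on the minus strand the
#' most upstream peak has the highest coordinate).
#'
#' @param peaks assigned (and typically classified) peaks.
#' @return peaks with `peak_number` and `peak_name` columns; re-running on
#'   its own output is the identity.
#' @export
namePeaks <- function(peaks) {
    pn <- character(length(peaks))
    for (tu in unique(mcols(peaks)$tu_id)) {
        ix <- which(mcols(peaks)$tu_id == tu)
        if (length(ix) == 1L) { pn[ix] <- "P0"; next }
        neg <- as.character(GenomicRanges::strand(peaks)[ix[1]]) == "-"
        o <- order(GenomicRanges::start(peaks)[ix], decreasing = neg)
        pn[ix[o]] <- paste0("P", seq_along(ix))
    }
    mcols(peaks)$peak_number <- pn
    mcols(peaks)$peak_name <- paste(mcols(peaks)$tu_id,
                                    mcols(peaks)$gene, pn, sep = ":")
    peaks
}
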