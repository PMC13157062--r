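# compact GTF-style annotation builder for constructed gene layouts
makeAnnotation <- function(genes) {
    rows <- list()
    for (g in names(genes)) {
        spec <- genes[[g]]
        for (t in names(spec$tx)) {
            ex <- spec$tx[[t]]   # matrix of exon start/end
            tspan <- c(min(ex[, 1]), max(ex[, 2]))
            rows[[length(rows) + 1L]] <- data.frame(
                start = c(tspan[1], ex[, 1]), end = c(tspan[2], ex[, 2]),
                type = c("transcript", rep("exon", nrow(ex))),
                strand = spec$strand, gene_id = g, gene_name = g,
                transcript_id = t)
        }
        if (!is.null(spec$utr3))
            rows[[length(rows) + 1L]] <- data.frame(
                start = spec$utr3[1], end = spec$utr3[2],
                type = "three_prime_utr", strand = spec$strand,
                gene_id = g, gene_name = g, transcript_id = NA)
    }
    df <- do.call(rbind, rows)
    GenomicRanges::GRanges("chr1", IRanges::IRanges(df$start, df$end),
                           strand = df$strand, type = df$type,
                           gene_id = df$gene_id, gene_name = df$gene_name,
                           transcript_id = df$transcript_id)
}

peaksAt <- function(start, end, strand = "+", tu_id = NA_integer_,
                    gene = NA_character_, read_count = 10L,
                    summit = NULL) {
    n <- length(start)
    GenomicRanges::GRanges("chr1", IRanges::IRanges(start, end),
        strand = rep_len(strand, n),
        summit = if (is.null(summit)) as.integer((start + end) / 2)
                 else summit,
        read_count = rep_len(as.integer(read_count), n),
        junction_support = 5L, prong = "all_reads",
        tu_id = rep_len(tu_id, n), gene = rep_len(gene, n))
}

test_that("TU span merges transcripts and extends 5 kb downstream", {
    ann <- makeAnnotation(list(G1 = list(strand = "+", tx = list(
        t1 = rbind(c(100, 500), c(700, 1000)),
        t2 = rbind(c(150, 500), c(700, 1200))))))
    turef <- buildTuReference(ann)
    tu <- tuRanges(turef)
    expect_length(tu, 1L)
    expect_equal(GenomicRanges::start(tu), 100L)
    expect_equal(GenomicRanges::end(tu), 1200L)
    expect_equal(S4Vectors::mcols(tu)$flank_end, 6200L)
    # minus-strand flank extends to lower coordinates
    annM <- makeAnnotation(list(G2 = list(strand = "-", tx = list(
        t1 = rbind(c(6000, 7000))))))
    tuM <- tuRanges(buildTuReference(annM))
    expect_equal(S4Vectors::mcols(tuM)$flank_end, 1000L)
    # random multi-transcript genes: span equals brute-force min/max
    set.seed(4)
    for (rep in 1:15) {
        k <- sample(2:4, 1)
        st <- sample(1000:5000, k)
        en <- st + sample(500:2000, k, replace = TRUE)
        ann2 <- makeAnnotation(list(GX = list(strand = "+",
            tx = stats::setNames(lapply(seq_len(k), function(i)
                rbind(c(st[i], en[i]))), paste0("t", seq_len(k))))))
        tu2 <- tuRanges(buildTuReference(ann2))
        expect_equal(GenomicRanges::start(tu2), min(st))
        expect_equal(GenomicRanges::end(tu2), max(en))
    }
})

test_that("peaks map to exactly one TU or are dropped", {
    ann <- makeAnnotation(list(
        G1 = list(strand = "+", tx = list(t1 = rbind(c(1000, 3000)))),
        G2 = list(strand = "+", tx = list(t2 = rbind(c(20000, 22000))))))
    turef <- buildTuReference(ann)
    pk <- peaksAt(c(1500, 2900, 30000), c(1600, 21000, 30100))
    out <- suppressMessages(assignPeaksToTu(pk, turef))
    # peak 1 inside G1; peak 2 spans both TUs (dropped); peak 3 hits none
    expect_length(out, 1L)
    expect_equal(S4Vectors::mcols(out)$gene, "G1")
    # strand mismatch drops too
    pkM <- peaksAt(1500, 1600, strand = "-")
    expect_length(suppressMessages(assignPeaksToTu(pkM, turef)), 0L)
    # all-pairs overlap oracle on a random layout
    set.seed(9)
    for (rep in 1:15) {
        gs <- sort(sample(seq(1000, 80000, by = 4000), 4))
        annR <- makeAnnotation(stats::setNames(lapply(gs, function(s)
            list(strand = "+", tx = list(t = rbind(c(s, s + 2500))))),
            paste0("G", seq_along(gs))))
        turefR <- buildTuReference(annR, flank = 1000L)
        ps <- sample.int(90000L, 30L)
        pkR <- peaksAt(ps, ps + sample(50:500, 30, replace = TRUE))
        outR <- suppressMessages(assignPeaksToTu(pkR, turefR))
        nOv <- vapply(seq_along(pkR), function(i) sum(
            GenomicRanges::start(pkR)[i] <= gs + 2500 + 1000 &
            GenomicRanges::end(pkR)[i] >= gs), 0L)
        expect_equal(length(outR), sum(nOv == 1L))
    }
})

test_that("length and usage filters apply the printed thresholds", {
    # 1,500 bp region is dropped, 1,000 bp kept
    pk <- peaksAt(c(100, 3000), c(1599, 3999), tu_id = 1L, gene = "G1")
    out <- applyPeakFilters(pk, peakFilterConfig(pas_filtering = FALSE))
    expect_equal(GenomicRanges::width(out), 1000L)
    # usage shares {0.95, 0.05}: the 5% peak is dropped
    pk2 <- peaksAt(c(100, 300), c(150, 350), tu_id = 1L, gene = "G1",
                   read_count = c(95L, 5L))
    out2 <- applyPeakFilters(pk2, peakFilterConfig(pas_filtering = FALSE))
    expect_equal(S4Vectors::mcols(out2)$read_count, 95L)
    expect_equal(S4Vectors::mcols(out2)$gene_usage, 0.95)
    # a share exactly at 10% is retained (minimum usage, not exclusive)
    pk3 <- peaksAt(c(100, 300), c(150, 350), tu_id = 1L, gene = "G1",
                   read_count = c(90L, 10L))
    expect_length(applyPeakFilters(pk3,
        peakFilterConfig(pas_filtering = FALSE)), 2L)
})

test_that("survivors equal a rule-by-rule oracle in the stated order", {
    set.seed(21)
    for (rep in 1:20) {
        n <- 12L
        st <- sort(sample.int(50000L, n)) + c(0L, cumsum(rep(600L, n - 1L)))
        wid <- sample(c(50L, 200L, 1200L), n, replace = TRUE,
                      prob = c(0.5, 0.4, 0.1))
        gene <- sample(paste0("G", 1:3), n, replace = TRUE)
        cnt <- sample(1:100, n, replace = TRUE)
        pk <- peaksAt(st, st + wid - 1L, gene = gene, read_count = cnt,
                      tu_id = match(gene, paste0("G", 1:3)))
        out <- applyPeakFilters(pk, peakFilterConfig(pas_filtering = FALSE))
        # oracle: length rule, then one-pass usage rule on survivors
        keep <- wid <= 1000L
        tot <- tapply(cnt[keep], gene[keep], sum)
        share <- cnt / as.numeric(tot[gene])
        keep2 <- keep & share >= 0.10
        expect_equal(GenomicRanges::start(out), st[keep2])
    }
})

test_that("PAS motifs are found upstream of the summit, strand-aware", {
    genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
        strrep("C", 500), "AATAAA", strrep("C", 494))))
    # + peak with summit 20 nt downstream of the motif
    pk <- peaksAt(480, 560, summit = 526L)
    expect_true(pasMatch(pk, genome, peakFilterConfig()))
    # motif outside the 50-nt window
    pkFar <- peaksAt(480, 700, summit = 650L)
    expect_false(pasMatch(pkFar, genome, peakFilterConfig()))
    # minus-strand: revcomp TTTATT upstream in transcription direction
    genomeM <- Biostrings::DNAStringSet(c(chr1 = paste0(
        strrep("C", 500), "TTTATT", strrep("C", 494))))
    pkM <- peaksAt(450, 530, strand = "-", summit = 480L)
    expect_true(pasMatch(pkM, genomeM, peakFilterConfig()))
    # brute-force substring oracle over random windows
    set.seed(33)
    cfg <- peakFilterConfig()
    for (rep in 1:30) {
        sq <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE),
                    collapse = "")
        gen <- Biostrings::DNAStringSet(c(chr1 = sq))
        smt <- sample(200:1800, 1)
        pkR <- peaksAt(smt - 30, smt + 30, summit = smt)
        win <- substr(sq, smt - cfg$pas_window, smt)
        orc <- any(vapply(cfg$pas_hexamers, grepl, logical(1), x = win,
                          fixed = TRUE))
        expect_equal(pasMatch(pkR, gen, cfg), orc)
    }
})

test_that("prong merge keeps the all-reads peak on overlap", {
    a <- peaksAt(100, 200, tu_id = 1L, gene = "G1")
    j <- peaksAt(c(150, 5000), c(250, 5100), tu_id = 1L, gene = "G1")
    S4Vectors::mcols(j)$prong <- "junction_reads"
    out <- mergeProngs(a, j)
    expect_length(out, 2L)
    expect_setequal(S4Vectors::mcols(out)$prong,
                    c("all_reads", "junction_reads"))
    # identical peak in both prongs: one survivor, all_reads
    out2 <- mergeProngs(a, {
        b <- a; S4Vectors::mcols(b)$prong <- "junction_reads"; b
    })
    expect_length(out2, 1L)
    expect_equal(S4Vectors::mcols(out2)$prong, "all_reads")
    # precedence oracle on random overlapping sets
    set.seed(41)
    for (rep in 1:20) {
        sa <- sort(sample.int(5000L, 6L)) * 3L
        sj <- sort(sample.int(5000L, 6L)) * 3L
        pa <- peaksAt(sa, sa + 100L, tu_id = 1L, gene = "G")
        pj <- peaksAt(sj, sj + 100L, tu_id = 1L, gene = "G")
        S4Vectors::mcols(pj)$prong <- "junction_reads"
        got <- mergeProngs(pa, pj)
        keepJ <- vapply(seq_along(pj), function(i)
            !any(sj[i] <= sa + 100L & sj[i] + 100L >= sa), logical(1))
        expect_equal(length(got), length(pa) + sum(keepJ))
    }
})

test_that("TU ends move to the most downstream assigned peak", {
    ann <- makeAnnotation(list(
        G1 = list(strand = "+", tx = list(t1 = rbind(c(1000, 3000)))),
        G2 = list(strand = "-", tx = list(t2 = rbind(c(40000, 42000))))))
    turef <- buildTuReference(ann)
    pk <- c(peaksAt(5900, 6000, tu_id = 1L, gene = "G1"),
            peaksAt(38000, 38100, strand = "-", tu_id = 2L, gene = "G2"))
    up <- updateTuEnds(turef, pk)
    tu <- tuRanges(up)
    expect_equal(GenomicRanges::end(tu)[1], 6000L)    # peak in + flank
    expect_equal(GenomicRanges::start(tu)[2], 38000L) # peak in - flank
    # TU without peaks unchanged
    up2 <- updateTuEnds(turef, pk[0])
    expect_equal(GenomicRanges::end(tuRanges(up2)),
                 GenomicRanges::end(tuRanges(turef)))
    # extremum oracle with random placements
    set.seed(51)
    for (rep in 1:15) {
        ps <- sample(1500:7500, 5L)
        pkR <- peaksAt(ps, ps + 50L, tu_id = 1L, gene = "G1")
        upR <- updateTuEnds(turef, pkR)
        expect_equal(GenomicRanges::end(tuRanges(upR))[1],
                     min(max(ps + 50L), 8000L))
    }
})

test_that("classification follows the printed priority order", {
    # gene with 3' UTR overlapping an intron of another isoform
    ann <- makeAnnotation(list(G1 = list(strand = "+",
        tx = list(t1 = rbind(c(1000, 2000), c(3000, 4000)),
                  t2 = rbind(c(1000, 2000), c(3500, 4000))),
        utr3 = c(3800, 4000))))
    turef <- buildTuReference(ann)
    classes <- function(pk) S4Vectors::mcols(
        classifyPeaks(pk, turef))$class
    expect_equal(classes(peaksAt(3850, 3900, tu_id = 1L)), "3'UTR")
    expect_equal(classes(peaksAt(1100, 1150, tu_id = 1L)),
                 "TSS-proximal")
    expect_equal(classes(peaksAt(1500, 1550, tu_id = 1L)), "Exonic")
    expect_equal(classes(peaksAt(2400, 2450, tu_id = 1L)), "Intronic")
    expect_equal(classes(peaksAt(5000, 5050, tu_id = 1L)), "Flank")
    # a peak overlapping both UTR and intron gets the UTR label
    expect_equal(classes(peaksAt(2900, 3850, tu_id = 1L)), "3'UTR")
})

test_that("classification equals brute-force priority evaluation", {
    ann <- makeAnnotation(list(G1 = list(strand = "+",
        tx = list(t1 = rbind(c(1000, 2000), c(3000, 4000))),
        utr3 = c(3800, 4000))))
    turef <- buildTuReference(ann)
    sets <- list(
        utr3 = data.frame(start = 3800, end = 4000, strand = "+"),
        tss = data.frame(start = 1000, end = 1299, strand = "+"),
        exon = data.frame(start = c(1000, 3000), end = c(2000, 4000),
                          strand = "+"),
        intron = data.frame(start = 2001, end = 2999, strand = "+"))
    set.seed(61)
    for (rep in 1:50) {
        s <- sample(900:9000, 1)
        pk <- peaksAt(s, s + sample(20:400, 1), tu_id = 1L, gene = "G1")
        got <- S4Vectors::mcols(classifyPeaks(pk, turef))$class
        expect_equal(got, oracleClassify(GenomicRanges::start(pk),
                                         GenomicRanges::end(pk), "+",
                                         sets))
    }
})

test_that("spliced reads bridging two peaks flag both as fragmented", {
    pk <- peaksAt(c(1000, 2000), c(1100, 2100), tu_id = 1L, gene = "G1")
    # spliced read: 50M900N50M covering 1050..1999+gap..2049
    spliced <- makeReads("chr1", 1051L, "50M900N50M", "+")
    out <- flagFragmented(pk, spliced)
    expect_equal(S4Vectors::mcols(out)$fragmented_flag, c(TRUE, TRUE))
    # no spliced reads: no flags
    plain <- makeReads("chr1", 1051L, "100M", "+")
    expect_equal(S4Vectors::mcols(flagFragmented(pk, plain))$
                     fragmented_flag, c(FALSE, FALSE))
    # spliced read touching only one peak: no flag
    oneSide <- makeReads("chr1", 1051L, "50M200N50M", "+")
    expect_equal(S4Vectors::mcols(flagFragmented(pk, oneSide))$
                     fragmented_flag, c(FALSE, FALSE))
    # different TU: no flag
    pk2 <- pk
    S4Vectors::mcols(pk2)$tu_id <- c(1L, 2L)
    expect_equal(S4Vectors::mcols(flagFragmented(pk2, spliced))$
                     fragmented_flag, c(FALSE, FALSE))
})

test_that("peak naming is ordered in the transcription direction", {
    pk <- peaksAt(c(100, 500), c(150, 550), tu_id = 7L, gene = "GENEA")
    nm <- namePeaks(pk)
    expect_equal(S4Vectors::mcols(nm)$peak_name,
                 c("7:GENEA:P1", "7:GENEA:P2"))
    # single peak gets P0
    one <- namePeaks(peaksAt(100, 150, tu_id = 3L, gene = "GENEB"))
    expect_equal(S4Vectors::mcols(one)$peak_name, "3:GENEB:P0")
    # minus strand: most upstream = highest coordinate
    pkM <- peaksAt(c(100, 500), c(150, 550), strand = "-", tu_id = 9L,
                   gene = "GENEC")
    nmM <- namePeaks(pkM)
    expect_equal(S4Vectors::mcols(nmM)$peak_number, c("P2", "P1"))
    # renaming is stable
    again <- namePeaks(nm)
    expect_equal(S4Vectors::mcols(again)$peak_name,
                 S4Vectors::mcols(nm)$peak_name)
})

test_that("the final reference is consistent and round-trips as TSV", {
    ref <- sharedReference()$peaks
    # non-overlapping per strand, each peak has one TU and one class
    for (st in c("+", "-")) {
        sub <- ref[as.character(GenomicRanges::strand(ref)) == st]
        expect_equal(sum(GenomicRanges::countOverlaps(sub, sub) > 1L), 0L)
    }
    expect_false(any(is.na(S4Vectors::mcols(ref)$tu_id)))
    expect_true(all(S4Vectors::mcols(ref)$class %in%
        c("3'UTR", "TSS-proximal", "Exonic", "Intronic", "Flank")))
    f <- withr::local_tempfile(fileext = ".txt")
    writePeakReference(ref, f)
    back <- readPeakReference(f)
    expect_equal(GenomicRanges::start(back), GenomicRanges::start(ref))
    expect_equal(S4Vectors::mcols(back)$peak_name,
                 S4Vectors::mcols(ref)$peak_name)
    expect_equal(S4Vectors::mcols(back)$junction_support,
                 S4Vectors::mcols(ref)$junction_support)
})
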