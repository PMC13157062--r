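#' Pipeline configuration
#'
#' Assembles the module configurations and the run-level settings
#' (compartment prefix, chromosome subset, samples, barcode subsetting,
#' PAS filtering, testing groups) into one object. Keys mirror the
#' conventional `config.yaml` vocabulary (`compartment`, `chrs`,
#' `samples`, `subset`, `PAS_filtering`, `group_one`, `group_two`,
#' `meta_testing_column`, paths).
#'
#' @param fasta genome FASTA path.
#' @param gtf annotation GTF path.
#' @param alignments named character vector, sample name -> SAM/BAM path.
#' @param output_dir output tree root (an `outputs/` and `logs/` tree is
#'   created under it).
#' @param compartment file-name prefix for outputs.
#' @param chrs optional chromosome subset (character vector or
#'   comma-separated string).
#' @param subset logical; subset each sample to the barcodes listed in
#'   `[barcodepath]/[sample]_subset_barcodes.tsv`.
#' @param barcodepath directory of per-sample barcode lists.
#' @param PAS_filtering logical; apply the poly(A)-signal retention rule.
#' @param group_one,group_two testing group labels.
#' @param meta_testing_column metadata column with the group labels.
#' @param metadata_file cell-metadata CSV (first column = barcode).
#' @param filter a [filterConfig()].
#' @param peaks a [peakCallConfig()].
#' @param peak_filters a [peakFilterConfig()].
#' @param test a [testConfig()].
#' @return a list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(fasta, gtf, alignments, output_dir = "outputs",
                           compartment = "sample", chrs = NULL,
                           subset = FALSE, barcodepath = NULL,
                           PAS_filtering = TRUE, group_one = NULL,
                           group_two = NULL,
                           meta_testing_column = "test_ident",
                           metadata_file = NULL,
                           filter = filterConfig(),
                           peaks = peakCallConfig(),
                           peak_filters = peakFilterConfig(),
                           test = testConfig()) {
    if (is.null(names(alignments)))
        names(alignments) <- paste0("sample", seq_along(alignments))
    if (is.character(chrs) && length(chrs) == 1L && grepl(",", chrs))
        chrs <- trimws(strsplit(chrs, ",")[[1]])
    peak_filters$pas_filtering <- isTRUE(PAS_filtering)
    structure(list(fasta = fasta, gtf = gtf, alignments = alignments,
                   output_dir = output_dir, compartment = compartment,
                   chrs = chrs, subset = isTRUE(subset),
                   barcodepath = barcodepath,
                   PAS_filtering = isTRUE(PAS_filtering),
                   group_one = group_one, group_two = group_two,
                   meta_testing_column = meta_testing_column,
                   metadata_file = metadata_file, filter = filter,
                   peaks = peaks, peak_filters = peak_filters,
                   test = test),
              class = c("pipelineConfig", "list"))
}

#' Read a pipeline configuration file
#'
#' YAML (or key: value text) configuration whose keys mirror
#' [pipelineConfig()] plus the flat per-module numeric keys (e.g.
#' `min_mapq`, `a_window`, `min_cov_all`, `max_region_len`,
#' `min_gene_usage`, `n_pseudoreps`, ...). Unknown keys warn but do not
#' fail; `"true"`/`"false"` strings become logicals.
#'
#' @param path config file path.
#' @return a `pipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    tolog <- function(v) if (is.character(v))
        tolower(v) %in% "true" else isTRUE(v)
    topKeys <- c("fasta", "gtf", "alignments", "samples", "output_dir",
                 "compartment", "chrs", "subset", "barcodepath",
                 "PAS_filtering", "group_one", "group_two",
                 "meta_testing_column", "metadata_file", "seed")
    fcKeys <- c("min_mapq", "a_window", "a_frac_threshold",
                "a_run_threshold", "min_clip", "min_a_frac")
    pcKeys <- c("min_cov_all", "min_cov_junction", "max_gap", "gap_len",
                "min_support")
    pfKeys <- c("max_region_len", "min_gene_usage", "pas_window",
                "max_tes_dist", "flank", "tss_width")
    tcKeys <- c("n_pseudoreps", "sample_frac", "alpha", "lfc_thresh",
                "dfrac_thresh", "min_cell_expr_pct", "deg_alpha")
    unknown <- setdiff(names(y), c(topKeys, fcKeys, pcKeys, pfKeys, tcKeys))
    if (length(unknown))
        warning("ignoring unknown config keys: ",
                paste(unknown, collapse = ", "))
    fc <- do.call(filterConfig, y[intersect(names(y), fcKeys)])
    pc <- do.call(peakCallConfig, y[intersect(names(y), pcKeys)])
    pf <- do.call(peakFilterConfig, y[intersect(names(y), pfKeys)])
    tcArgs <- y[intersect(names(y), tcKeys)]
    if (!is.null(y$seed)) tcArgs$seed <- y$seed
    tc <- do.call(testConfig, tcArgs)
    aln <- unlist(y$alignments)
    if (!is.null(y$samples) && is.null(names(aln)))
        names(aln) <- unlist(y$samples)
    pipelineConfig(fasta = y$fasta, gtf = y$gtf, alignments = aln,
                   output_dir = if (is.null(y$output_dir)) "outputs"
                                else y$output_dir,
                   compartment = if (is.null(y$compartment)) "sample"
                                 else y$compartment,
                   chrs = y$chrs, subset = tolog(y$subset),
                   barcodepath = y$barcodepath,
                   PAS_filtering = if (is.null(y$PAS_filtering)) TRUE
                                   else tolog(y$PAS_filtering),
                   group_one = y$group_one, group_two = y$group_two,
                   meta_testing_column =
                       if (is.null(y$meta_testing_column)) "test_ident"
                       else y$meta_testing_column,
                   metadata_file = y$metadata_file, filter = fc,
                   peaks = pc, peak_filters = pf, test = tc)
}

.outDir <- function(cfg, ...) {
    d <- file.path(cfg$output_dir, ...)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    d
}

# run a stage with per-stage log capture; failures abort with the stage
# name and log path
.stageLog <- function(cfg, stage, expr) {
    ld <- file.path(cfg$output_dir, "logs")
    dir.create(ld, recursive = TRUE, showWarnings = FALSE)
    lf <- file.path(ld, paste0(stage, ".log"))
    con <- file(lf, "w")
    on.exit(close(con))
    tryCatch(
        withCallingHandlers(expr,
            message = function(m) {
                writeLines(trimws(conditionMessage(m)), con)
                invokeRestart("muffleMessage")
            },
            warning = function(w) {
                writeLines(paste("WARNING:", conditionMessage(w)), con)
            }),
        error = function(e) stop("stage '", stage, "' failed (log: ", lf,
                                 "): ", conditionMessage(e), call. = FALSE))
}

.appendStats <- function(cfg, ...) {
    f <- file.path(.outDir(cfg, "stats"),
                   paste0(cfg$compartment, "_PA_ref_stats.txt"))
    stats <- if (file.exists(f)) readRefStats(f) else newRefStats()
    writeRefStats(addRefStat(stats, ...), f)
}

.filteredSam <- function(cfg, sample, which = c("after", "before")) {
    which <- match.arg(which)
    file.path(.outDir(cfg, "1d_merged_bams"),
              paste0(sample, "_", which, "_genomicAfiltering.sam"))
}

.loadFiltered <- function(cfg, which = "after") {
    rs <- lapply(names(cfg$alignments), function(s)
        readTaggedReads(.filteredSam(cfg, s, which)))
    do.call(c, rs)
}

#' Preprocessing stage: dedup, MAPQ filter, genomic-A filter
#'
#' Reads each sample's alignments, removes PCR duplicates and ambiguously
#' mapped reads, optionally subsets to listed barcodes, writes the
#' before-filter reads and QC coverage tracks, applies the two-round
#' genomic-A filter and writes the after-filter reads and tracks.
#'
#' @param cfg a [pipelineConfig()].
#' @return invisibly, per-sample counts.
#' @export
stagePreprocess <- function(cfg) .stageLog(cfg, "preprocess", {
    genome <- Biostrings::readDNAStringSet(cfg$fasta)
    names(genome) <- sub("\\s.*", "", names(genome))
    annotation <- rtracklayer::import(cfg$gtf, format = "gtf")
    stats <- list()
    allBefore <- list()
    for (s in names(cfg$alignments)) {
        reads <- readTaggedReads(cfg$alignments[[s]])
        n0 <- length(reads)
        if (!is.null(cfg$chrs))
            reads <- reads[as.character(
                GenomicAlignments::seqnames(reads)) %in% cfg$chrs]
        reads <- deduplicateReads(reads)
        nd <- length(reads)
        reads <- filterAmbiguous(reads, cfg$filter$min_mapq)
        na <- length(reads)
        if (cfg$subset) {
            bcf <- file.path(cfg$barcodepath,
                             paste0(s, "_subset_barcodes.tsv"))
            reads <- subsetByBarcodes(reads, readBarcodeList(bcf))
        }
        writeTaggedSam(reads, .filteredSam(cfg, s, "before"), genome)
        fa <- filterGenomicA(reads, genome, annotation, cfg$filter)
        writeTaggedSam(fa$kept, .filteredSam(cfg, s, "after"), genome)
        .appendStats(cfg, paste0(s, ":dedup"), n0, nd)
        .appendStats(cfg, paste0(s, ":mapq_filter"), nd, na)
        .appendStats(cfg, paste0(s, ":genomicA_filter"), length(reads),
                     length(fa$kept))
        allBefore[[s]] <- reads
        stats[[s]] <- c(input = n0, dedup = nd, mapq = na,
                        after = length(fa$kept))
    }
    td <- .outDir(cfg, "qc_ucsc_tracks")
    before <- do.call(c, unname(allBefore))
    writeStrandedCoverage(before,
        file.path(td, "before_genomicAfiltering_merged"))
    writeStrandedCoverage(.loadFiltered(cfg, "after"),
        file.path(td, "after_genomicAfiltering_merged"))
    invisible(stats)
})

#' Peak-calling stage: junction detection and the two prongs
#'
#' @param cfg a [pipelineConfig()].
#' @return invisibly, the two prong peak sets.
#' @export
stagePeaks <- function(cfg) .stageLog(cfg, "peaks", {
    reads <- .loadFiltered(cfg, "after")
    events <- detectJunctionReads(reads, cfg$filter$min_clip,
                                  cfg$filter$min_a_frac)
    writeCleavageBed(events, file.path(.outDir(cfg, "2b_polyA_junctions"),
        paste0(cfg$compartment, "_cleavage_events.bed")))
    pAll <- buildProng(reads, events, "all_reads", cfg$peaks)
    pJun <- buildProng(reads, events, "junction_reads", cfg$peaks)
    d <- .outDir(cfg, "2d_peak_refs")
    writePeaksTsv(pAll, file.path(d, paste0(cfg$compartment,
                                            "_all_reads_peaks.txt")))
    writePeaksTsv(pJun, file.path(d, paste0(cfg$compartment,
                                            "_polyA_reads_peaks.txt")))
    .appendStats(cfg, "prong_all_reads", reads_in = length(reads),
                 reads_out = length(reads), peaks_out = length(pAll))
    .appendStats(cfg, "prong_junction_reads", reads_in = length(reads),
                 reads_out = length(reads), peaks_out = length(pJun))
    invisible(list(all_reads = pAll, junction_reads = pJun))
})

#' Annotation stage: TU reference, filtering, merging, classification
#'
#' @param cfg a [pipelineConfig()].
#' @return invisibly, the final annotated peak reference `GRanges`.
#' @export
stageAnnotate <- function(cfg) .stageLog(cfg, "annotate", {
    genome <- Biostrings::readDNAStringSet(cfg$fasta)
    names(genome) <- sub("\\s.*", "", names(genome))
    annotation <- rtracklayer::import(cfg$gtf, format = "gtf")
    turef <- buildTuReference(annotation, cfg$peak_filters$flank,
                              cfg$peak_filters$tss_width)
    d2 <- file.path(cfg$output_dir, "2d_peak_refs")
    pAll <- readPeaksTsv(file.path(d2, paste0(cfg$compartment,
                                              "_all_reads_peaks.txt")))
    pJun <- readPeaksTsv(file.path(d2, paste0(cfg$compartment,
                                              "_polyA_reads_peaks.txt")))
    doProng <- function(pk) {
        n0 <- length(pk)
        pk <- assignPeaksToTu(pk, turef)
        pk <- applyPeakFilters(pk, cfg$peak_filters, genome, turef)
        .msg("prong filtering: ", n0, " -> ", length(pk), " peaks")
        pk
    }
    fAll <- doProng(pAll); fJun <- doProng(pJun)
    .appendStats(cfg, "assign_and_filter_all_reads",
                 peaks_in = length(pAll), peaks_out = length(fAll))
    .appendStats(cfg, "assign_and_filter_junction_reads",
                 peaks_in = length(pJun), peaks_out = length(fJun))
    merged <- mergeProngs(fAll, fJun)
    .appendStats(cfg, "merge_two_prongs",
                 peaks_in = length(fAll) + length(fJun),
                 peaks_out = length(merged))
    turef <- updateTuEnds(turef, merged)
    merged <- classifyPeaks(merged, turef)
    reads <- .loadFiltered(cfg, "after")
    merged <- flagFragmented(merged, reads)
    merged <- namePeaks(merged)
    d3 <- .outDir(cfg, "3e_fragmented_peaks_to_merge")
    writePeakReference(merged, file.path(d3,
        paste0(cfg$compartment, "_final_peak_universe_updated.txt")))
    # browser annotation track + fully filtered read coverage
    ta <- .outDir(cfg, "track_annotations")
    bed <- merged
    names(bed) <- NULL
    mcols(bed) <- S4Vectors::DataFrame(name = mcols(merged)$peak_name,
                                       score = rep(0L, length(merged)))
    rtracklayer::export(bed, file.path(ta,
        paste0(cfg$compartment, "_peak_annotations.bed")), format = "bed")
    keep <- IRanges::overlapsAny(GenomicRanges::GRanges(
        GenomicAlignments::seqnames(reads),
        IRanges::IRanges(.threePrimeEnd(reads), .threePrimeEnd(reads)),
        strand = GenomicAlignments::strand(reads)), merged,
        ignore.strand = FALSE)
    writeStrandedCoverage(reads[keep],
        file.path(.outDir(cfg, "filtered_tracks"),
                  paste0(cfg$compartment, "_peak_filtered")))
    .appendStats(cfg, "peak_filtered_reads", reads_in = length(reads),
                 reads_out = sum(keep))
    invisible(merged)
})

#' Counting stage: per-sample peak-by-cell matrices and the merged matrix
#'
#' @param cfg a [pipelineConfig()].
#' @return invisibly, the merged [PeakCellMatrix].
#' @export
stageCount <- function(cfg) .stageLog(cfg, "count", {
    reference <- readPeakReference(file.path(cfg$output_dir,
        "3e_fragmented_peaks_to_merge",
        paste0(cfg$compartment, "_final_peak_universe_updated.txt")))
    mats <- lapply(names(cfg$alignments), function(s) {
        reads <- readTaggedReads(.filteredSam(cfg, s, "after"))
        m <- buildPeakCellMatrix(reads, reference, sample = s)
        writeMatrixDir(m, file.path(.outDir(cfg, "4b_peakcount"), s))
        m
    })
    merged <- mergeMatrices(mats)
    writeMatrixDir(merged,
                   .outDir(cfg, "5a_merged_cellranger_peakcount"))
    gm <- geneCellMatrix(merged)
    gd <- .outDir(cfg, "5a_merged_cellranger_genecount")
    Matrix::writeMM(gm, file.path(gd, "matrix.mtx"))
    utils::write.table(data.frame(rownames(gm), rownames(gm),
                                  rep("Gene", nrow(gm))),
                       file.path(gd, "features.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    writeLines(as.character(colnames(gm)), file.path(gd, "barcodes.tsv"))
    .appendStats(cfg, "peak_matrix",
                 reads_in = sum(Matrix::colSums(peakCounts(merged))) +
                     unassignedCount(merged),
                 reads_out = sum(Matrix::colSums(peakCounts(merged))),
                 peaks_in = nrow(merged), peaks_out = nrow(merged))
    invisible(merged)
})

#' APA-testing stage
#'
#' @param cfg a [pipelineConfig()].
#' @return invisibly, the APA results data.frame.
#' @export
stageApa <- function(cfg) .stageLog(cfg, "apa", {
    x <- readMatrixDir(file.path(cfg$output_dir,
                                 "5a_merged_cellranger_peakcount"))
    rd <- SummarizedExperiment::rowData(x)
    rd$peak_number <- sub(".*:", "", rownames(x))
    SummarizedExperiment::rowData(x) <- rd
    groups <- readCellMetadata(cfg$metadata_file, cfg$meta_testing_column)
    d <- .outDir(cfg, "5b_APA_testing")
    f <- file.path(d, paste0(cfg$group_one, "_v_", cfg$group_two,
                             "_res.txt"))
    if (nrow(x) == 0L || ncol(x) == 0L) {
        warning("empty matrix; writing empty APA results")
        utils::write.table(data.frame(), f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        return(invisible(data.frame()))
    }
    res <- runApaTest(x, groups, cfg$test, cfg$group_one, cfg$group_two)
    utils::write.table(res, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    reference <- readPeakReference(file.path(cfg$output_dir,
        "3e_fragmented_peaks_to_merge",
        paste0(cfg$compartment, "_final_peak_universe_updated.txt")))
    writeFractionalTracks(res, reference,
                          file.path(cfg$output_dir,
                                    "fractional_usage_tracks"),
                          cfg$group_one, cfg$group_two)
    invisible(res)
})

#' Pseudo-bulk DEG-testing stage
#'
#' @param cfg a [pipelineConfig()].
#' @return invisibly, the DEG result list.
#' @export
stageDeg <- function(cfg) .stageLog(cfg, "deg", {
    x <- readMatrixDir(file.path(cfg$output_dir,
                                 "5a_merged_cellranger_peakcount"))
    groups <- readCellMetadata(cfg$metadata_file, cfg$meta_testing_column)
    d <- .outDir(cfg, "5b_DEG_testing")
    fa <- file.path(d, paste0(cfg$group_one, "_v_", cfg$group_two,
                              "_LRT_all_genes.txt"))
    fs <- file.path(d, paste0(cfg$group_one, "_v_", cfg$group_two,
                              "_LRT_sig_genes.txt"))
    if (nrow(x) == 0L || ncol(x) == 0L) {
        warning("empty matrix; writing empty DEG results")
        utils::write.table(data.frame(), fa, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        utils::write.table(data.frame(), fs, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        return(invisible(list(all = data.frame(), sig = data.frame())))
    }
    deg <- degTest(x, groups, cfg$test, cfg$group_one, cfg$group_two)
    utils::write.table(deg$all, fa, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(deg$sig, fs, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(deg)
})

#' Tracks stage: regenerate QC coverage tracks from the stage outputs
#'
#' Rewrites the before/after genomic-A-filtering stranded coverage tracks
#' from the stage SAMs; useful after manual edits or partial runs.
#'
#' @param cfg a [pipelineConfig()].
#' @return invisibly, the track directory.
#' @export
stageTracks <- function(cfg) .stageLog(cfg, "tracks", {
    td <- .outDir(cfg, "qc_ucsc_tracks")
    writeStrandedCoverage(.loadFiltered(cfg, "before"),
        file.path(td, "before_genomicAfiltering_merged"))
    writeStrandedCoverage(.loadFiltered(cfg, "after"),
        file.path(td, "after_genomicAfiltering_merged"))
    invisible(td)
})

#' Run the full pipeline end to end
#'
#' Executes preprocessing, junction/peak calling, TU annotation and
#' filtering, counting, APA testing and DEG testing in order, writing all
#' artifacts under `cfg$output_dir` with per-stage logs.
#'
#' @param cfg a [pipelineConfig()].
#' @return invisibly, a list with the final reference, merged matrix, APA
#'   and DEG results.
#' @export
runPipeline <- function(cfg) {
    statsFile <- file.path(cfg$output_dir, "stats",
                           paste0(cfg$compartment, "_PA_ref_stats.txt"))
    if (file.exists(statsFile)) unlink(statsFile)
    stagePreprocess(cfg)
    stagePeaks(cfg)
    reference <- stageAnnotate(cfg)
    matrix <- stageCount(cfg)
    apa <- if (!is.null(cfg$group_one) && !is.null(cfg$metadata_file))
        stageApa(cfg) else NULL
    deg <- if (!is.null(cfg$group_one) && !is.null(cfg$metadata_file))
        stageDeg(cfg) else NULL
    invisible(list(reference = reference, matrix = matrix, apa = apa,
                   deg = deg))
}
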