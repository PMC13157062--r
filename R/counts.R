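#' Count read 3' ends per peak and cell
#'
#' A read increments cell (peak, barcode) when its 3'-end coordinate lies
#' inside the peak on the matching strand - the cleavage-proximal end is
#' the informative coordinate of a 3'-tagged read. `mode = "any_overlap"`
#' instead assigns any read whose alignment overlaps the peak (for
#' sensitivity studies). Reads hitting no peak are tallied in
#' `metadata()$unassigned`.
#'
#' @param reads filtered, deduplicated tagged `GAlignments`.
#' @param reference annotated peak `GRanges`, non-overlapping per strand,
#'   with `peak_name` (and ideally `gene`) columns.
#' @param mode assignment rule.
#' @param sample sample label stored in `colData`.
#' @return a [PeakCellMatrix].
#' @export
buildPeakCellMatrix <- function(reads, reference,
                                mode = c("three_prime", "any_overlap"),
                                sample = "sample1") {
    mode <- match.arg(mode)
    rn <- mcols(reference)$peak_name
    if (is.null(rn)) rn <- paste0("peak", seq_along(reference))
    barcodes <- sort(unique(mcols(reads)$CB))
    if (mode == "three_prime") {
        p3 <- .threePrimeEnd(reads)
        q <- GenomicRanges::GRanges(
            as.character(GenomicAlignments::seqnames(reads)),
            IRanges::IRanges(p3, p3),
            strand = GenomicAlignments::strand(reads))
    } else {
        q <- GenomicRanges::granges(methods::as(reads, "GRanges"))
    }
    hits <- GenomicRanges::findOverlaps(q, reference,
                                        ignore.strand = FALSE)
    # the reference is non-overlapping per strand, so at most one hit;
    # guard anyway by keeping the first
    hits <- hits[!duplicated(S4Vectors::queryHits(hits))]
    i <- S4Vectors::subjectHits(hits)
    j <- match(mcols(reads)$CB[S4Vectors::queryHits(hits)], barcodes)
    mat <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                                dims = c(length(reference),
                                         length(barcodes)),
                                dimnames = list(rn, barcodes))
    unassigned <- length(reads) - length(hits)
    .msg("matrix: assigned ", length(hits), " reads, unassigned ",
         unassigned)
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = methods::as(mat, "CsparseMatrix")),
        rowRanges = reference,
        colData = S4Vectors::DataFrame(barcode = barcodes,
                                       sample = rep(sample,
                                                    length(barcodes)),
                                       row.names = barcodes))
    out <- methods::new("PeakCellMatrix", sce)
    metadata(out)$unassigned <- unassigned
    out
}

#' Merge peak-by-cell matrices across samples
#'
#' Columns are concatenated over an identical peak universe. With
#' `suffix_mode = "index"` each barcode's trailing `-<n>` suffix is
#' rewritten to the sample index (`-1` in sample 2 becomes `-2`), so the
#' same physical barcode sequenced in two samples stays distinguishable.
#'
#' @param matrices list of [PeakCellMatrix] objects sharing row names.
#' @param suffix_mode `"index"` (rewrite suffixes) or `"none"`.
#' @return the merged [PeakCellMatrix].
#' @export
mergeMatrices <- function(matrices, suffix_mode = c("index", "none")) {
    suffix_mode <- match.arg(suffix_mode)
    stopifnot(length(matrices) >= 1L)
    rn <- rownames(matrices[[1]])
    for (k in seq_along(matrices)) {
        miss <- setdiff(rn, rownames(matrices[[k]]))
        extra <- setdiff(rownames(matrices[[k]]), rn)
        if (length(miss) || length(extra))
            stop("matrix ", k, " row universe mismatch; missing: ",
                 paste(utils::head(miss, 5), collapse = ","), " extra: ",
                 paste(utils::head(extra, 5), collapse = ","))
    }
    parts <- lapply(seq_along(matrices), function(k) {
        x <- matrices[[k]]
        cts <- peakCounts(x)
        if (length(rn)) cts <- cts[rn, , drop = FALSE]
        bc <- colnames(cts)
        if (suffix_mode == "index")
            bc <- sub("-[0-9]+$", paste0("-", k), bc)
        colnames(cts) <- bc
        cd <- SummarizedExperiment::colData(x)
        cd$barcode <- bc
        rownames(cd) <- bc
        list(cts = cts, cd = cd)
    })
    cts <- do.call(cbind, lapply(parts, `[[`, "cts"))
    cd <- do.call(rbind, lapply(parts, `[[`, "cd"))
    if (anyDuplicated(colnames(cts)))
        stop("barcode collision after suffixing")
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = cts),
        rowRanges = SummarizedExperiment::rowRanges(matrices[[1]]),
        colData = cd)
    out <- methods::new("PeakCellMatrix", sce)
    metadata(out)$unassigned <- sum(vapply(matrices, unassignedCount, 0L))
    out
}

#' Collapse a peak matrix to a gene-by-cell matrix
#'
#' Per-TU column sums of the peak matrix (no second counting pass).
#'
#' @param x a [PeakCellMatrix] whose rowRanges carry `gene`.
#' @return sparse `dgCMatrix`, genes x cells.
#' @export
geneCellMatrix <- function(x) {
    gene <- mcols(SummarizedExperiment::rowRanges(x))$gene
    if (is.null(gene)) stop("rowRanges lack a gene column")
    cts <- peakCounts(x)
    if (nrow(cts) == 0L)
        return(methods::as(cts, "CsparseMatrix"))
    agg <- Matrix::sparse.model.matrix(~ 0 + g,
                                       data.frame(g = factor(gene)))
    out <- Matrix::t(agg) %*% cts
    rownames(out) <- levels(factor(gene))
    methods::as(out, "CsparseMatrix")
}

#' Write a matrix as a MatrixMarket triplet directory
#'
#' Emits `matrix.mtx`, `features.tsv` (peak name, gene, type) and
#' `barcodes.tsv` in the conventional 10x triplet layout (uncompressed).
#'
#' @param x a [PeakCellMatrix].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeMatrixDir <- function(x, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    cts <- peakCounts(x)
    Matrix::writeMM(cts, file.path(dir, "matrix.mtx"))
    gene <- mcols(SummarizedExperiment::rowRanges(x))$gene
    if (is.null(gene)) gene <- rownames(x)
    utils::write.table(
        data.frame(rownames(x), gene, rep("Peak", nrow(x))),
        file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    writeLines(as.character(colnames(x)), file.path(dir, "barcodes.tsv"))
    invisible(dir)
}

#' Read a MatrixMarket triplet directory written by [writeMatrixDir()]
#'
#' @param dir directory with `matrix.mtx`, `features.tsv`, `barcodes.tsv`.
#' @param sample sample label for `colData`.
#' @return a [PeakCellMatrix] (rowRanges absent; row names = peak names,
#'   with gene stored in `rowData`).
#' @export
readMatrixDir <- function(dir, sample = "sample1") {
    cts <- Matrix::readMM(file.path(dir, "matrix.mtx"))
    cts <- methods::as(methods::as(methods::as(cts, "dMatrix"),
                                   "generalMatrix"), "CsparseMatrix")
    featFile <- file.path(dir, "features.tsv")
    feat <- if (file.size(featFile) > 0)
        utils::read.delim(featFile, header = FALSE,
                          stringsAsFactors = FALSE)
    else data.frame(V1 = character(0), V2 = character(0))
    bc <- readLines(file.path(dir, "barcodes.tsv"))
    dimnames(cts) <- list(feat$V1, bc)
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = cts),
        rowData = S4Vectors::DataFrame(gene = feat$V2,
                                       row.names = feat$V1),
        colData = S4Vectors::DataFrame(barcode = bc,
                                       sample = rep(sample, length(bc)),
                                       row.names = bc))
    methods::new("PeakCellMatrix", sce)
}
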