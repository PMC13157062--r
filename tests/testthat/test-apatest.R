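toyMatrix <- function(counts, genes, peakNumbers, barcodes = NULL) {
    if (is.null(barcodes)) barcodes <- paste0("c", seq_len(ncol(counts)))
    dimnames(counts) <- list(paste0(seq_along(genes), ":", genes, ":",
                                    peakNumbers), barcodes)
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = methods::as(Matrix::Matrix(counts,
            sparse = TRUE), "CsparseMatrix")),
        rowData = S4Vectors::DataFrame(gene = genes,
                                       peak_number = peakNumbers,
                                       row.names = rownames(counts)),
        colData = S4Vectors::DataFrame(barcode = barcodes,
                                       sample = "s1",
                                       row.names = barcodes))
    methods::new("PeakCellMatrix", sce)
}

test_that("pseudo-replicates draw floor(0.7 n) distinct cells", {
    set.seed(1)
    cts <- Matrix::Matrix(matrix(rpois(40, 5), 4, 10), sparse = TRUE)
    dimnames(cts) <- list(paste0("p", 1:4), paste0("c", 1:10))
    groups <- stats::setNames(rep("A", 10), colnames(cts))
    pr <- makePseudoreplicates(cts, groups, testConfig(seed = 2))
    expect_equal(ncol(pr$counts), 3L)
    for (cells in pr$cells) {
        expect_length(cells, 7L)              # floor(0.7 * 10)
        expect_equal(anyDuplicated(cells), 0L)
        expect_equal(unname(pr$counts[, 1]),
                     unname(Matrix::rowSums(cts[, pr$cells[[1]]])))
    }
    # sample_frac = 1 makes every replicate the full group sum
    prFull <- makePseudoreplicates(cts, groups,
                                   testConfig(sample_frac = 1))
    for (k in 1:3)
        expect_equal(unname(prFull$counts[, k]),
                     unname(Matrix::rowSums(cts)))
    # fixed seed reproduces bit-identical tables
    pr2 <- makePseudoreplicates(cts, groups, testConfig(seed = 2))
    expect_identical(pr$counts, pr2$counts)
    expect_identical(pr$cells, pr2$cells)
    # a group below 2 cells is a hard error
    expect_error(makePseudoreplicates(cts[, 1, drop = FALSE],
        groups[1], testConfig()), "fewer than 2")
})

test_that("testable peaks exclude P0 and low-expression peaks", {
    # gene G1 has two peaks; G2 is single-peak (P0); p2 is expressed in
    # only 1/20 cells per group (5% < 10%)
    n <- 40L
    cts <- matrix(0, 3, n)
    cts[1, ] <- rpois(n, 5) + 1
    cts[2, c(1, 21)] <- 3
    cts[3, ] <- rpois(n, 5) + 1
    m <- toyMatrix(cts, c("G1", "G1", "G2"), c("P1", "P2", "P0"))
    groups <- stats::setNames(rep(c("A", "B"), each = 20), colnames(m))
    testable <- filterTestable(m, groups, testConfig())
    expect_setequal(testable, "1:G1:P1")
    # column-scan oracle on a random matrix
    set.seed(14)
    rc <- matrix(rbinom(20 * n, 1, 0.2) * rpois(20 * n, 3), 20, n)
    genes <- rep(paste0("g", 1:10), each = 2)
    pn <- rep(c("P1", "P2"), 10)
    mR <- toyMatrix(rc, genes, pn)
    got <- filterTestable(mR, groups, testConfig())
    orc <- rownames(mR)[vapply(seq_len(20), function(i) {
        a <- mean(rc[i, 1:20] > 0) * 100
        b <- mean(rc[i, 21:40] > 0) * 100
        max(a, b) >= 10
    }, logical(1))]
    expect_setequal(got, orc)
})

test_that("identical group counts give log2FC 0 and a null p-value", {
    tab <- rbind(p1 = rep(c(30, 31, 29), 2), p2 = rep(c(70, 69, 71), 2))
    grp <- factor(rep(c("A", "B"), each = 3))
    r <- testPeakUsage(tab, grp)
    expect_equal(r$log2FC, c(0, 0))
    expect_true(all(r$pvalue > 0.9))
    # swapping group labels flips the log2FC sign, p unchanged
    tab2 <- rbind(p1 = c(80, 82, 78, 20, 22, 18),
                  p2 = c(20, 18, 22, 80, 78, 82))
    rAB <- testPeakUsage(tab2, grp)
    rBA <- testPeakUsage(tab2, factor(rep(c("B", "A"), each = 3)))
    expect_equal(rAB$log2FC, -rBA$log2FC, tolerance = 1e-9)
    expect_equal(rAB$pvalue, rBA$pvalue, tolerance = 1e-9)
})

test_that("the IRLS NB fit matches glm with a fixed-theta NB family", {
    skip_if_not_installed("MASS")
    set.seed(31)
    for (rep in 1:20) {
        n <- 12L
        X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
        y <- rnbinom(n, mu = exp(1.5 + 0.4 * X[, 2]), size = 10)
        alpha <- 0.1
        ours <- scPolyAUsage:::.nbFit(y, X, alpha = alpha)
        ref <- suppressWarnings(stats::glm(y ~ X[, 2] + X[, 3],
            family = MASS::negative.binomial(theta = 1 / alpha)))
        expect_equal(unname(ours$beta), unname(stats::coef(ref)),
                     tolerance = 1e-4)
    }
})

test_that("null pseudo-bulk tables give roughly uniform p-values", {
    set.seed(8)
    ps <- numeric(0)
    for (g in 1:150) {
        mu <- runif(2, 40, 120)
        tab <- rbind(p1 = rnbinom(6, mu = mu[1], size = 1 / 0.05),
                     p2 = rnbinom(6, mu = mu[2], size = 1 / 0.05))
        grp <- factor(rep(c("A", "B"), each = 3))
        ps <- c(ps, testPeakUsage(tab, grp)$pvalue)
    }
    expect_lt(mean(ps < 0.05), 0.09)
    expect_gt(mean(ps < 0.5), 0.35)
})

test_that("a strong usage swap is detected with high power", {
    set.seed(9)
    hits <- 0L
    for (g in 1:50) {
        tab <- rbind(p1 = c(rnbinom(3, mu = 160, size = 20),
                            rnbinom(3, mu = 40, size = 20)),
                     p2 = c(rnbinom(3, mu = 40, size = 20),
                            rnbinom(3, mu = 160, size = 20)))
        grp <- factor(rep(c("A", "B"), each = 3))
        r <- testPeakUsage(tab, grp)
        hits <- hits + (r$pvalue[1] < 0.01 & abs(r$log2FC[1]) > 1.5)
    }
    expect_gte(hits / 50, 0.9)
})

test_that("BH adjustment equals hand-computed and brute-force values", {
    expect_equal(adjustBH(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(adjustBH(0.2), 0.2)
    set.seed(17)
    for (rep in 1:50) {
        p <- runif(sample(1:40, 1))
        expect_equal(adjustBH(p), oracleBH(p))
    }
})

test_that("fractional usage divides by the gene's group total", {
    cts <- matrix(0, 3, 4)
    cts[1, ] <- c(3, 0, 5, 2)    # G1 P1
    cts[2, ] <- c(7, 0, 5, 8)    # G1 P2
    cts[3, ] <- c(1, 1, 0, 0)    # G2 P0
    m <- toyMatrix(cts, c("G1", "G1", "G2"), c("P1", "P2", "P0"))
    groups <- stats::setNames(c("A", "A", "B", "B"), colnames(m))
    fr <- fractionalUsage(m, groups)
    expect_equal(unname(fr[1:2, "A"]), c(0.3, 0.7))
    expect_equal(unname(fr[1:2, "B"]), c(0.35, 0.65))
    # zero group total yields NA
    expect_true(is.na(fr[3, "B"]))
    expect_equal(unname(fr[3, "A"]), 1)
    # per-gene per-group fractions sum to 1 on the simulated matrix
    frS <- fractionalUsage(sharedMatrix(), sharedGroups())
    gene <- S4Vectors::mcols(SummarizedExperiment::rowRanges(
        sharedMatrix()))$gene
    for (g in colnames(frS)) {
        sums <- tapply(frS[, g], gene, sum)
        expect_equal(as.vector(sums[!is.na(sums)]),
                     rep(1, sum(!is.na(sums))), tolerance = 1e-12)
    }
})

test_that("significance needs all three thresholds", {
    base <- data.frame(padj = 0.005, log2FC = 2, dfrac = 0.2)
    cfg <- testConfig()
    expect_true(callSignificant(base, cfg)$int_sig)
    expect_false(callSignificant(transform(base, dfrac = 0.05),
                                 cfg)$int_sig)
    expect_false(callSignificant(transform(base, log2FC = 1.2),
                                 cfg)$int_sig)
    expect_false(callSignificant(transform(base, padj = 0.02),
                                 cfg)$int_sig)
    # boundary values are not significant (strict inequalities)
    expect_false(callSignificant(data.frame(padj = 0.01, log2FC = 2,
                                            dfrac = 0.2), cfg)$int_sig)
    expect_false(callSignificant(data.frame(padj = 0.005, log2FC = 1.5,
                                            dfrac = 0.2), cfg)$int_sig)
    expect_false(callSignificant(data.frame(padj = 0.005, log2FC = 2,
                                            dfrac = 0.1), cfg)$int_sig)
    # predicate oracle on random rows
    set.seed(23)
    df <- data.frame(padj = runif(200), log2FC = rnorm(200, 0, 2),
                     dfrac = runif(200, -0.5, 0.5))
    got <- callSignificant(df, cfg)$int_sig
    orc <- df$padj < 0.01 & abs(df$log2FC) > 1.5 & abs(df$dfrac) > 0.1
    expect_equal(got, orc)
})

test_that("DEG testing recovers a planted fold change", {
    set.seed(27)
    n <- 40L
    # 30 null genes and one 4-fold up gene, modest per-cell counts
    cts <- matrix(rpois(31 * n, 4), 31, n)
    cts[31, 1:20] <- rpois(20, 16)
    m <- toyMatrix(cts, paste0("g", 1:31), rep("P0", 31))
    groups <- stats::setNames(rep(c("A", "B"), each = 20), colnames(m))
    deg <- suppressMessages(degTest(m, groups, testConfig(seed = 3)))
    expect_equal(nrow(deg$all), 31L)
    g31 <- deg$all[deg$all$gene == "g31", ]
    expect_lt(g31$padj, 0.05)
    expect_gt(g31$log2FC, 1)         # group A over group B
    # null genes: roughly uniform p-values
    nullP <- deg$all$pvalue[deg$all$gene != "g31"]
    expect_lt(mean(nullP < 0.05), 0.25)
})

test_that("runApaTest produces a coherent results table", {
    m <- sharedMatrix()
    groups <- sharedGroups()
    res <- suppressMessages(runApaTest(m, groups, testConfig()))
    expect_true(all(c("peak", "gene", "log2FC", "pvalue", "padj",
                      "frac_group1", "frac_group2", "dfrac",
                      "int_sig") %in% names(res)))
    # only multi-peak genes, no P0
    expect_false(any(grepl(":P0$", res$peak)))
    # fractions in [0, 1]
    expect_true(all(res$frac_group1 >= 0 & res$frac_group1 <= 1,
                    na.rm = TRUE))
    # int_sig is exactly the triple-threshold predicate
    expect_equal(res$int_sig,
                 res$padj < 0.01 & abs(res$log2FC) > 1.5 &
                     abs(res$dfrac) > 0.1)
    # label swap flips signs
    res2 <- suppressMessages(runApaTest(m, groups, testConfig(),
        group_one = "group2", group_two = "group1"))
    ix <- match(res$peak, res2$peak)
    expect_equal(res$log2FC, -res2$log2FC[ix], tolerance = 1e-9)
    expect_equal(res$pvalue, res2$pvalue[ix], tolerance = 1e-9)
})
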