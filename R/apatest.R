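#' APA testing configuration
#'
#' Defaults follow the printed testing rules: three pseudo-replicates each
#' drawn as 70% of a group's cells without replacement; significance
#' requires adjusted p < 0.01, |log2 fold change| > 1.5 and |fractional
#' usage difference| > 0.1; peaks expressed in fewer than 10% of cells in
#' both groups are not testable.
#'
#' @param n_pseudoreps pseudo-replicates per group.
#' @param sample_frac fraction of cells drawn per pseudo-replicate.
#' @param alpha adjusted-p threshold.
#' @param lfc_thresh |log2FC| threshold.
#' @param dfrac_thresh |delta fractional usage| threshold.
#' @param min_cell_expr_pct minimum percent of cells (in at least one
#'   group) with nonzero counts for a peak to be testable.
#' @param deg_alpha adjusted-p threshold for the DEG significant-genes
#'   table.
#' @param seed RNG seed for pseudo-replicate draws.
#' @return a list of class `testConfig`.
#' @export
testConfig <- function(n_pseudoreps = 3L, sample_frac = 0.70, alpha = 0.01,
                       lfc_thresh = 1.5, dfrac_thresh = 0.1,
                       min_cell_expr_pct = 10, deg_alpha = 0.05,
                       seed = 1L) {
    stopifnot(sample_frac > 0, sample_frac <= 1, n_pseudoreps >= 1L)
    structure(list(n_pseudoreps = as.integer(n_pseudoreps),
                   sample_frac = sample_frac, alpha = alpha,
                   lfc_thresh = lfc_thresh, dfrac_thresh = dfrac_thresh,
                   min_cell_expr_pct = min_cell_expr_pct,
                   deg_alpha = deg_alpha, seed = as.integer(seed)),
              class = c("testConfig", "list"))
}

# resolve a counts matrix plus row annotation from a PeakCellMatrix or a
# plain (sparse) matrix
.resolveCounts <- function(x) {
    if (methods::is(x, "PeakCellMatrix")) {
        rr <- SummarizedExperiment::rowRanges(x)
        ann <- if (methods::is(rr, "GRanges") && length(rr))
            as.data.frame(mcols(rr)) else
            as.data.frame(SummarizedExperiment::rowData(x))
        list(counts = peakCounts(x), ann = ann)
    } else list(counts = x, ann = data.frame(row.names = rownames(x)))
}

#' Build pseudo-replicate pseudo-bulk tables
#'
#' For each group, draws `n_pseudoreps` independent subsets of
#' `floor(sample_frac * n_cells)` distinct cells (without replacement
#' within a draw; draws may share cells) and sums counts over the drawn
#' cells. Seeded and bit-reproducible.
#'
#' @param x a [PeakCellMatrix] or sparse counts matrix.
#' @param groups named character vector mapping barcode to group label;
#'   barcodes without a label are ignored (count reported).
#' @param cfg a [testConfig()].
#' @return list with `counts` (features x (groups*reps) matrix), `group`
#'   (factor over columns), `rep` (integer over columns) and `cells` (the
#'   drawn barcodes per column).
#' @export
makePseudoreplicates <- function(x, groups, cfg = testConfig()) {
    rc <- .resolveCounts(x)
    cts <- rc$counts
    lab <- groups[colnames(cts)]
    unlabeled <- sum(is.na(lab))
    if (unlabeled)
        .msg("pseudo-replicates: ignoring ", unlabeled,
             " unlabeled barcodes")
    lv <- sort(unique(lab[!is.na(lab)]))
    .withSeed(cfg$seed, {
        cols <- list(); grp <- character(0); rp <- integer(0)
        cells <- list()
        for (g in lv) {
            bc <- colnames(cts)[!is.na(lab) & lab == g]
            if (length(bc) < 2L)
                stop("group '", g, "' has fewer than 2 cells")
            nd <- floor(cfg$sample_frac * length(bc))
            for (r in seq_len(cfg$n_pseudoreps)) {
                drawn <- sample(bc, nd, replace = FALSE)
                cols[[paste0(g, "_rep", r)]] <-
                    Matrix::rowSums(cts[, drawn, drop = FALSE])
                cells[[paste0(g, "_rep", r)]] <- drawn
                grp <- c(grp, g); rp <- c(rp, r)
            }
        }
        list(counts = do.call(cbind, cols), group = factor(grp, levels = lv),
             rep = rp, cells = cells)
    })
}

#' Testable peaks for APA analysis
#'
#' Differential usage needs at least two sites per gene, so P0 peaks
#' (single-peak genes) are excluded; a peak must additionally show nonzero
#' counts in at least `min_cell_expr_pct` percent of the cells of one
#' group.
#'
#' @param x a [PeakCellMatrix] whose row annotation carries `peak_number`.
#' @param groups named barcode-to-label map.
#' @param cfg a [testConfig()].
#' @return character vector of testable peak names.
#' @export
filterTestable <- function(x, groups, cfg = testConfig()) {
    rc <- .resolveCounts(x)
    cts <- rc$counts
    pe <- rc$ann$peak_number
    if (is.null(pe)) stop("row annotation lacks peak_number")
    lab <- groups[colnames(cts)]
    lv <- sort(unique(lab[!is.na(lab)]))
    exprOk <- rep(FALSE, nrow(cts))
    for (g in lv) {
        sel <- !is.na(lab) & lab == g
        if (!any(sel)) next
        pct <- 100 * Matrix::rowSums(cts[, sel, drop = FALSE] > 0) /
            sum(sel)
        exprOk <- exprOk | pct >= cfg$min_cell_expr_pct
    }
    rownames(cts)[pe != "P0" & exprOk]
}

# ---- negative-binomial IRLS machinery ------------------------------------

# Log-linear NB fit with fixed dispersion alpha (var = mu + alpha*mu^2) by
# iteratively reweighted least squares; returns the NB log-likelihood.
.nbFit <- function(y, X, offset = rep(0, length(y)), alpha, maxit = 100L,
                   tol = 1e-8) {
    eta <- log(pmax(y, 0.5)) # includes offset implicitly at start
    llOld <- -Inf
    converged <- FALSE
    for (it in seq_len(maxit)) {
        eta <- pmin(pmax(eta, -30), 30)
        mu <- exp(eta)
        w <- mu / (1 + alpha * mu)
        z <- (eta - offset) + (y - mu) / mu
        fit <- stats::lm.wfit(X, z, w)
        beta <- fit$coefficients
        beta[is.na(beta)] <- 0
        eta <- drop(X %*% beta) + offset
        ll <- sum(stats::dnbinom(y, mu = exp(pmin(pmax(eta, -30), 30)),
                                 size = 1 / alpha, log = TRUE))
        if (is.finite(ll) && abs(ll - llOld) < tol * (abs(ll) + 1)) {
            converged <- TRUE
            break
        }
        llOld <- ll
    }
    list(beta = beta, mu = exp(pmin(pmax(eta, -30), 30)), ll = ll,
         converged = converged, iter = it)
}

# Method-of-moments dispersion pooled over replicate cells (each cell =
# one (group, bin) combination observed across pseudo-replicates).
# Per-cell moment contributions (var - mean) are clipped at zero before
# pooling - overdispersion cannot be negative - and the pooled estimate is
# floored. Returns the estimate and its degrees of freedom (sum of
# per-cell replicate df), which calibrate the test's F reference.
.dispersionMoM <- function(y, cell, floor = 1e-4) {
    num <- 0; den <- 0; df <- 0L
    for (cl in unique(cell)) {
        v <- y[cell == cl]
        if (length(v) < 2L) next
        m <- mean(v)
        num <- num + max(stats::var(v) - m, 0)
        den <- den + m^2
        df <- df + length(v) - 1L
    }
    if (den <= 0) return(list(alpha = floor, df = df))
    list(alpha = max(floor, num / den), df = df)
}

#' Differential usage test for the peaks of one gene
#'
#' For each tested peak the per-pseudo-replicate counts are folded into a
#' two-bin response (this peak vs the rest of the gene) and a
#' negative-binomial log-linear model with replicate, bin and group-by-bin
#' interaction terms is fit by IRLS, with a per-peak method-of-moments
#' dispersion (floored at 1e-4) estimated across pseudo-replicates. The
#' p-value is a 1-df likelihood-ratio test of the interaction, referred to
#' an F(1, d) distribution where d is the dispersion-estimation df (with
#' few pseudo-replicates the moment dispersion estimate is noisy, and a
#' plain chi-square reference is anti-conservative at this sample size);
#' the usage log2 fold change compares (peak + 0.5)/(others + 0.5) ratios
#' between groups on replicate-summed counts. Non-convergence after 100
#' IRLS iterations yields p = 1 and a flag.
#'
#' @param geneCounts matrix (peaks x pseudo-replicate columns) for one
#'   gene, all peaks included (they define the gene total).
#' @param group factor over columns (two levels).
#' @param test rownames to test (default all).
#' @return data.frame with `peak`, `pvalue`, `log2FC`, `converged`.
#' @export
testPeakUsage <- function(geneCounts, group, test = rownames(geneCounts)) {
    stopifnot(nrow(geneCounts) >= 2L, nlevels(factor(group)) == 2L)
    group <- factor(group)
    tot <- colSums(geneCounts)
    ncol6 <- ncol(geneCounts)
    repf <- factor(seq_len(ncol6))
    g2 <- levels(group)[2]
    out <- lapply(test, function(pk) {
        yThis <- geneCounts[pk, ]
        yOther <- tot - yThis
        y <- c(yThis, yOther)
        bin <- factor(rep(c("this", "others"), each = ncol6),
                      levels = c("others", "this"))
        cell <- paste(rep(as.character(group), 2L), bin)
        disp <- .dispersionMoM(y, cell)
        alpha <- disp$alpha
        Xr <- stats::model.matrix(~ repf2 + bin2,
            data.frame(repf2 = rep(repf, 2L), bin2 = bin))
        int <- as.numeric(bin == "this" & rep(group, 2L) == g2)
        Xf <- cbind(Xr, interaction = int)
        fr <- .nbFit(y, Xr, alpha = alpha)
        ff <- .nbFit(y, Xf, alpha = alpha)
        conv <- fr$converged && ff$converged
        stat <- max(0, 2 * (ff$ll - fr$ll))
        p <- if (conv && disp$df > 0)
            stats::pf(stat, 1, disp$df, lower.tail = FALSE) else 1
        c1 <- sum(yThis[group == levels(group)[1]])
        o1 <- sum(yOther[group == levels(group)[1]])
        c2 <- sum(yThis[group == g2])
        o2 <- sum(yOther[group == g2])
        lfc <- log2(((c1 + 0.5) / (o1 + 0.5)) / ((c2 + 0.5) / (o2 + 0.5)))
        data.frame(peak = pk, pvalue = p, log2FC = lfc, converged = conv)
    })
    do.call(rbind, out)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement
#' (the standard BH procedure).
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values.
#' @export
adjustBH <- function(p) stats::p.adjust(p, method = "BH")

#' Per-group fractional usage of each peak within its gene
#'
#' Divides each peak's group pseudo-bulk count (all cells of the group) by
#' the group total across the gene's peaks. Genes with a zero group total
#' yield `NA`.
#'
#' @param x a [PeakCellMatrix] with `gene` row annotation.
#' @param groups named barcode-to-label map.
#' @return matrix, peaks x groups, of fractions in `[0, 1]`.
#' @export
fractionalUsage <- function(x, groups) {
    rc <- .resolveCounts(x)
    cts <- rc$counts
    gene <- rc$ann$gene
    if (is.null(gene)) stop("row annotation lacks gene")
    lab <- groups[colnames(cts)]
    lv <- sort(unique(lab[!is.na(lab)]))
    out <- matrix(NA_real_, nrow(cts), length(lv),
                  dimnames = list(rownames(cts), lv))
    for (g in lv) {
        sel <- !is.na(lab) & lab == g
        bulk <- Matrix::rowSums(cts[, sel, drop = FALSE])
        tot <- tapply(bulk, gene, sum)[gene]
        out[, g] <- ifelse(tot > 0, bulk / tot, NA_real_)
    }
    out
}

#' Apply the significance thresholds
#'
#' `int_sig` is TRUE iff adjusted p < `alpha` AND |log2FC| > `lfc_thresh`
#' AND |delta fractional usage| > `dfrac_thresh`.
#'
#' @param res APA results data.frame with `padj`, `log2FC`, `dfrac`.
#' @param cfg a [testConfig()].
#' @return `res` with an `int_sig` logical column.
#' @export
callSignificant <- function(res, cfg = testConfig()) {
    res$int_sig <- res$padj < cfg$alpha &
        abs(res$log2FC) > cfg$lfc_thresh &
        abs(res$dfrac) > cfg$dfrac_thresh
    res$int_sig[is.na(res$int_sig)] <- FALSE
    res
}

#' Run the full APA differential-usage analysis
#'
#' Builds pseudo-replicates, selects testable peaks (multi-peak genes,
#' expression filter), runs the per-gene NB interaction LRT, adjusts
#' p-values (BH), computes full-group fractional usage and calls
#' significance.
#'
#' @param x a [PeakCellMatrix] with `gene` and `peak_number` row
#'   annotation.
#' @param groups named barcode-to-label map (exactly two labels among the
#'   matrix's cells, or use `group_one`/`group_two` to pick two).
#' @param cfg a [testConfig()].
#' @param group_one,group_two optional explicit group labels; group order
#'   defines the sign of `log2FC` and `dfrac`.
#' @return data.frame, one row per tested peak, including pseudo-bulk
#'   counts per replicate, `log2FC`, `pvalue`, `padj`, per-group
#'   fractions, `dfrac` and `int_sig`.
#' @export
runApaTest <- function(x, groups, cfg = testConfig(), group_one = NULL,
                       group_two = NULL) {
    if (!is.null(group_one))
        groups <- groups[groups %in% c(group_one, group_two)]
    lv <- sort(unique(stats::na.omit(
        groups[colnames(.resolveCounts(x)$counts)])))
    if (length(lv) != 2L)
        stop("APA testing needs exactly two groups; got: ",
             paste(lv, collapse = ", "))
    if (is.null(group_one)) { group_one <- lv[1]; group_two <- lv[2] }
    rc <- .resolveCounts(x)
    gene <- rc$ann$gene
    names(gene) <- rownames(rc$counts)
    pr <- makePseudoreplicates(x, groups, cfg)
    testable <- filterTestable(x, groups, cfg)
    frac <- fractionalUsage(x, groups)

    res <- list()
    for (g in unique(gene[testable])) {
        pk <- names(gene)[gene == g]
        tp <- intersect(testable, pk)
        if (length(tp) < 1L || length(pk) < 2L) next
        tab <- pr$counts[pk, , drop = FALSE]
        # sign convention: group_one over group_two
        grp <- factor(pr$group, levels = c(group_one, group_two))
        r <- testPeakUsage(tab, grp, test = tp)
        r$gene <- g
        res[[g]] <- r
    }
    if (length(res) == 0L) {
        .msg("APA: no testable genes")
        return(data.frame())
    }
    res <- do.call(rbind, res)
    rownames(res) <- NULL
    # testPeakUsage log2FC sign convention: group_one over group_two
    res$padj <- adjustBH(res$pvalue)
    f1 <- frac[res$peak, group_one]
    f2 <- frac[res$peak, group_two]
    cts <- pr$counts[res$peak, , drop = FALSE]
    res <- cbind(res[c("peak", "gene")], as.data.frame(cts),
                 res[c("log2FC", "pvalue", "padj")],
                 stats::setNames(data.frame(f1, f2),
                                 paste0("frac_", c(group_one, group_two))),
                 dfrac = f1 - f2, converged = res$converged)
    res <- callSignificant(res, cfg)
    res
}

#' Pseudo-bulk differential gene expression LRT
#'
#' Per-gene negative-binomial fit of pseudo-replicate totals against group
#' versus intercept-only, with log library-size offsets and a 1-df
#' likelihood-ratio test (F reference, as in [testPeakUsage()]); BH
#' adjustment. All-zero genes are skipped.
#'
#' @param x a [PeakCellMatrix] (collapsed to genes internally) or a
#'   gene-by-cell sparse matrix.
#' @param groups named barcode-to-label map.
#' @param cfg a [testConfig()].
#' @param group_one,group_two optional explicit group labels.
#' @return list with `all` (every tested gene) and `sig`
#'   (padj < `deg_alpha`) data.frames of `gene`, `log2FC`, `pvalue`,
#'   `padj`.
#' @export
degTest <- function(x, groups, cfg = testConfig(), group_one = NULL,
                    group_two = NULL) {
    gm <- if (methods::is(x, "PeakCellMatrix")) geneCellMatrix(x) else x
    if (!is.null(group_one))
        groups <- groups[groups %in% c(group_one, group_two)]
    pr <- makePseudoreplicates(gm, groups, cfg)
    lv <- levels(pr$group)
    if (length(lv) != 2L)
        stop("DEG testing needs exactly two groups")
    if (is.null(group_one)) { group_one <- lv[1]; group_two <- lv[2] }
    grp <- factor(as.character(pr$group), levels = c(group_one, group_two))
    off <- log(pmax(colSums(pr$counts), 1))
    X1 <- stats::model.matrix(~ grp)
    X0 <- X1[, 1, drop = FALSE]
    skipped <- 0L
    rows <- list()
    for (g in rownames(pr$counts)) {
        y <- pr$counts[g, ]
        if (all(y == 0)) { skipped <- skipped + 1L; next }
        disp <- .dispersionMoM(y, as.character(grp))
        f1 <- .nbFit(y, X1, offset = off, alpha = disp$alpha)
        f0 <- .nbFit(y, X0, offset = off, alpha = disp$alpha)
        stat <- max(0, 2 * (f1$ll - f0$ll))
        p <- if (disp$df > 0)
            stats::pf(stat, 1, disp$df, lower.tail = FALSE) else 1
        # model coefficient is log(group_two/group_one); report
        # group_one over group_two to match the APA sign convention
        lfc <- -f1$beta[2] / log(2)
        rows[[g]] <- data.frame(gene = g, log2FC = lfc, pvalue = p)
    }
    if (skipped) .msg("DEG: skipped ", skipped, " all-zero genes")
    all <- do.call(rbind, rows)
    rownames(all) <- NULL
    all$padj <- adjustBH(all$pvalue)
    list(all = all, sig = all[all$padj < cfg$deg_alpha, , drop = FALSE])
}
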