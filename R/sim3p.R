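#' Simulation configuration for synthetic 3' scRNA-seq data
#'
#' Parameters of the synthetic-data generator. Defaults describe the standard
#' validation dataset used throughout the package: a 2-chromosome, 20-gene
#' miniature genome with 2-3 poly(A) sites per gene, two cell groups of 40
#' cells, 50 reads per cell, a 20% internal-priming (genomic-A) rate, 10%
#' PCR-duplicate rate and 5% ambiguously mapped reads.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_len chromosome length in bases.
#' @param n_genes number of genes.
#' @param peaks_per_gene integer range `c(min, max)` of cleavage sites per gene.
#' @param groups character vector of cell-group labels.
#' @param cells_per_group cells per group.
#' @param reads_per_cell reads per cell.
#' @param duplicate_rate probability that a read is a PCR duplicate of an
#'   earlier read from the same cell (shares CB, UMI, position, strand).
#' @param mispriming_rate probability that a read arises from internal
#'   priming at a planted genomic A stretch (no soft-clip tail).
#' @param ambiguous_rate probability that a read is flagged multi-mapped
#'   (low MAPQ).
#' @param tail_len length of the non-templated poly(A) soft-clip tail.
#' @param read_len aligned read length in bases.
#' @param jitter cleavage-position jitter, uniform on `[-jitter, jitter]`.
#' @param swap_frac fraction of genes whose site-usage fractions are reversed
#'   in all groups after the first (an induced APA shift); 0 = global null.
#' @param site_fracs optional fixed usage fractions applied to genes whose
#'   site count matches `length(site_fracs)`.
#' @param seed RNG seed; a fixed seed yields byte-identical outputs.
#' @return a validated list of class `simConfig`.
#' @export
simConfig <- function(n_chroms = 2L, chrom_len = 100000L, n_genes = 20L,
                      peaks_per_gene = c(2L, 3L),
                      groups = c("group1", "group2"),
                      cells_per_group = 40L, reads_per_cell = 50L,
                      duplicate_rate = 0.1, mispriming_rate = 0.2,
                      ambiguous_rate = 0.05, tail_len = 12L, read_len = 60L,
                      jitter = 5L, swap_frac = 0, site_fracs = NULL,
                      seed = 1L) {
    cfg <- list(n_chroms = as.integer(n_chroms),
                chrom_len = as.integer(chrom_len),
                n_genes = as.integer(n_genes),
                peaks_per_gene = as.integer(range(peaks_per_gene)),
                groups = as.character(groups),
                cells_per_group = as.integer(cells_per_group),
                reads_per_cell = as.integer(reads_per_cell),
                duplicate_rate = duplicate_rate,
                mispriming_rate = mispriming_rate,
                ambiguous_rate = ambiguous_rate,
                tail_len = as.integer(tail_len),
                read_len = as.integer(read_len),
                jitter = as.integer(jitter),
                swap_frac = swap_frac, site_fracs = site_fracs,
                seed = as.integer(seed))
    probs <- c(cfg$duplicate_rate, cfg$mispriming_rate, cfg$ambiguous_rate,
               cfg$swap_frac)
    if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
    cnts <- c(cfg$n_chroms, cfg$chrom_len, cfg$n_genes, cfg$peaks_per_gene,
              cfg$cells_per_group, cfg$reads_per_cell, cfg$tail_len,
              cfg$read_len)
    if (any(cnts < 1L)) stop("counts must be >= 1")
    class(cfg) <- c("simConfig", "list")
    cfg
}

# Gene architecture in transcript-local coordinates (0-based):
#   exon1 [0,199] -- intron [200,499] -- exon2 [500, span-1]
# cleavage site k sits at local 900 + (k-1)*300; span ends at the last site.
# The 3' UTR is local [800, span-1]; a canonical AATAAA is planted 20-25 nt
# upstream of every site; the 16 transcript-sense bases after each site are
# C/G only so that cleavage-adjacent windows are never mistaken for internal
# priming; a 15-nt A stretch (transcript sense) at local [560,574] is the
# planted mispriming locus.
.SIM <- list(exon1 = c(0L, 199L), intron = c(200L, 499L), exon2_start = 500L,
             utr3_start = 800L, first_site = 900L, site_gap = 300L,
             mp_local = c(560L, 574L), mp_len = 15L, pas_off = c(25L, 20L),
             margin = 6000L)

# local (0-based, transcript sense) -> genomic (1-based) for a gene placed at
# g0 with span `span` on `strand`.
.loc2gen <- function(local, g0, span, strand) {
    if (strand == "+") g0 + local else g0 + span - 1L - local
}

# map a local interval to a genomic (start, end) pair
.locInt <- function(a, b, g0, span, strand) {
    x <- .loc2gen(c(a, b), g0, span, strand)
    c(min(x), max(x))
}

#' Simulate a miniature genome, annotation and cleavage-site truth
#'
#' Builds `cfg$n_chroms` random chromosomes, places `cfg$n_genes` two-exon
#' genes (alternating strand) with 2-3 cleavage sites each, plants a
#' canonical poly(A) signal upstream of every site and one >=10-nt genomic
#' A stretch (transcript sense) inside each gene as an internal-priming
#' locus, and draws per-group site-usage fractions.
#'
#' @param cfg a [simConfig()].
#' @return a [PolyASimulation] with empty `reads`.
#' @export
simulateReference <- function(cfg = simConfig()) {
    stopifnot(inherits(cfg, "simConfig"))
    .withSeed(cfg$seed, {
        S <- .SIM
        per_chrom <- ceiling(cfg$n_genes / cfg$n_chroms)
        spacing <- (cfg$chrom_len - 2L * S$margin) %/% per_chrom
        max_span <- S$first_site + (cfg$peaks_per_gene[2] - 1L) * S$site_gap + 1L
        if (spacing < max_span + 5500L)
            stop("gene placement impossible within chrom_len: need spacing >= ",
                 max_span + 5500L, ", have ", spacing)
        chroms <- paste0("chr", seq_len(cfg$n_chroms))
        genome <- Biostrings::DNAStringSet(vapply(chroms, function(ch)
            paste(sample(c("A", "C", "G", "T"), cfg$chrom_len,
                         replace = TRUE), collapse = ""), character(1)))
        names(genome) <- chroms

        edit <- function(ch, gstart, gend, txSeq, strand) {
            s <- if (strand == "+") txSeq else
                as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(txSeq)))
            Biostrings::subseq(genome[[ch]], gstart, gend) <<-
                Biostrings::DNAString(s)
        }

        ann <- list(); truth <- list(); mp <- list()
        for (i in seq_len(cfg$n_genes)) {
            ch <- chroms[((i - 1L) %% cfg$n_chroms) + 1L]
            slot <- ((i - 1L) %/% cfg$n_chroms)
            g0 <- S$margin + slot * spacing + 1L
            strand <- if (i %% 2L == 1L) "+" else "-"
            nsite <- sample(seq(cfg$peaks_per_gene[1], cfg$peaks_per_gene[2]),
                            1L)
            site_loc <- S$first_site + (seq_len(nsite) - 1L) * S$site_gap
            span <- site_loc[nsite] + 1L
            gene <- sprintf("GENE%02d", i)

            # sequence edits (transcript-sense strings)
            mpi <- .locInt(S$mp_local[1], S$mp_local[2], g0, span, strand)
            edit(ch, mpi[1], mpi[2], strrep("A", S$mp_len), strand)
            for (sl in site_loc) {
                pas <- .locInt(sl - S$pas_off[1], sl - S$pas_off[2],
                               g0, span, strand)
                edit(ch, pas[1], pas[2], "AATAAA", strand)
                dw <- .locInt(sl + 1L, sl + 16L, g0, span, strand)
                edit(ch, dw[1], dw[2],
                     paste(sample(c("C", "G"), 16L, replace = TRUE),
                           collapse = ""), strand)
            }

            # annotation features: one isoform per cleavage site (multi-site
            # genes in curated annotations typically have isoforms ending at
            # the distinct poly(A) sites), all sharing the TSS and intron
            gspan <- .locInt(0L, span - 1L, g0, span, strand)
            u3 <- .locInt(S$utr3_start, span - 1L, g0, span, strand)
            feat <- data.frame(
                chrom = ch, start = c(gspan[1], u3[1]),
                end = c(gspan[2], u3[2]),
                type = c("gene", "three_prime_utr"), strand = strand,
                gene_id = paste0("g", i), gene_name = gene,
                transcript_id = c(NA, paste0("t", i, ".", nsite)))
            for (k in seq_len(nsite)) {
                tsp <- .locInt(0L, site_loc[k], g0, span, strand)
                e1 <- .locInt(S$exon1[1], S$exon1[2], g0, span, strand)
                e2 <- .locInt(S$exon2_start, site_loc[k], g0, span, strand)
                feat <- rbind(feat, data.frame(
                    chrom = ch, start = c(tsp[1], e1[1], e2[1]),
                    end = c(tsp[2], e1[2], e2[2]),
                    type = c("transcript", "exon", "exon"), strand = strand,
                    gene_id = paste0("g", i), gene_name = gene,
                    transcript_id = paste0("t", i, ".", k)))
            }
            ann[[i]] <- feat

            # usage fractions: group 1 baseline, optionally reversed in the
            # other groups for swap genes; fixed site_fracs override when the
            # site count matches.
            if (!is.null(cfg$site_fracs) &&
                length(cfg$site_fracs) == nsite) {
                f1 <- cfg$site_fracs / sum(cfg$site_fracs)
            } else {
                # every planted site is genuinely used: fractions bounded
                # away from the 10% per-gene usage floor even after
                # multinomial sampling noise
                f1 <- 1 + stats::runif(nsite)
                f1 <- f1 / sum(f1)
            }
            swapped <- stats::runif(1) < cfg$swap_frac
            fr <- lapply(seq_along(cfg$groups), function(k)
                if (k > 1L && swapped) rev(f1) else f1)
            names(fr) <- paste0("frac_", cfg$groups)

            m <- as.integer(vapply(site_loc, .loc2gen, numeric(1), g0 = g0,
                                   span = span, strand = strand))
            pos <- if (strand == "+") m else m - 1L
            truth[[i]] <- data.frame(gene = gene, chrom = ch, strand = strand,
                                     site = seq_len(nsite), pos = pos,
                                     swapped = swapped, as.data.frame(fr))
            end3 <- .loc2gen(S$mp_local[1] - 1L, g0, span, strand)
            mp[[i]] <- data.frame(gene = gene, chrom = ch, strand = strand,
                                  start = mpi[1], end = mpi[2], end3 = end3)
        }

        anndf <- do.call(rbind, ann)
        annotation <- GenomicRanges::GRanges(
            anndf$chrom, IRanges::IRanges(anndf$start, anndf$end),
            strand = anndf$strand, type = anndf$type, gene_id = anndf$gene_id,
            gene_name = anndf$gene_name, transcript_id = anndf$transcript_id,
            seqlengths = stats::setNames(Biostrings::width(genome),
                                         names(genome)))
        mpdf <- do.call(rbind, mp)
        mploci <- GenomicRanges::GRanges(
            mpdf$chrom, IRanges::IRanges(mpdf$start, mpdf$end),
            strand = mpdf$strand, gene = mpdf$gene, end3 = mpdf$end3,
            seqlengths = stats::setNames(Biostrings::width(genome),
                                         names(genome)))
        methods::new("PolyASimulation", genome = genome,
                     annotation = annotation,
                     truth = do.call(rbind, truth), misprimeLoci = mploci,
                     reads = GenomicAlignments::GAlignments(),
                     config = unclass(cfg))
    })
}

# deterministic DNA encoding of an integer as a fixed-length barcode/UMI
.intToSeq <- function(i, len) {
    alpha <- c("A", "C", "G", "T")
    out <- character(len)
    for (k in seq_len(len)) {
        out[k] <- alpha[(i %% 4L) + 1L]
        i <- i %/% 4L
    }
    paste(rev(out), collapse = "")
}

#' Simulate tagged 3' read alignments from a reference with truth
#'
#' Every genuine read ends at one of its gene's true cleavage sites (drawn
#' per the cell group's usage fractions, jittered by up to `cfg$jitter` nt)
#' and carries a non-templated A-tail soft clip (`clip3` of A on +,
#' `clip5` of T on -). Misprimed reads terminate at the planted A stretch
#' with no soft clip; duplicates copy (CB, UMI, position, strand) from an
#' earlier read of the same cell; ambiguous reads get MAPQ 3, all others
#' MAPQ 255.
#'
#' @param sim a [PolyASimulation] from [simulateReference()].
#' @param cfg simulation config; defaults to the one stored in `sim`.
#' @return [GenomicAlignments::GAlignments] with metadata columns `CB`,
#'   `UB`, `mapq`, `clip5`, `clip3` and truth labels `origin`
#'   (`genuine`/`misprimed`), `gene`, `site`, `cleave_pos` (the realized
#'   cleavage coordinate, junction convention) and `is_dup`.
#' @export
simulateReads <- function(sim, cfg = NULL) {
    stopifnot(methods::is(sim, "PolyASimulation"))
    if (is.null(cfg)) cfg <- do.call(simConfig, sim@config)
    truth <- sim@truth
    mp <- as.data.frame(sim@misprimeLoci)
    mp$chrom <- as.character(mp$seqnames)
    mp$strand <- as.character(mp$strand)
    genes <- unique(truth$gene)
    bySite <- split(truth, truth$gene)

    .withSeed(cfg$seed + 1L, {
        n_cells <- cfg$cells_per_group * length(cfg$groups)
        cell_group <- rep(cfg$groups, each = cfg$cells_per_group)
        barcodes <- paste0(vapply(seq_len(n_cells), .intToSeq, character(1),
                                  len = 16L), "-1")
        rl <- cfg$read_len; tl <- cfg$tail_len
        recs <- vector("list", n_cells * cfg$reads_per_cell)
        idx <- 0L
        for (ci in seq_len(n_cells)) {
            grp <- cell_group[ci]
            fcol <- paste0("frac_", grp)
            cellStart <- idx + 1L
            for (j in seq_len(cfg$reads_per_cell)) {
                idx <- idx + 1L
                if (j > 1L && stats::runif(1) < cfg$duplicate_rate) {
                    src <- recs[[sample(seq(cellStart, idx - 1L), 1L)]]
                    src$is_dup <- TRUE
                    recs[[idx]] <- src
                    next
                }
                umi <- .intToSeq((ci - 1L) * cfg$reads_per_cell + j, 10L)
                mapq <- if (stats::runif(1) < cfg$ambiguous_rate) 3L else 255L
                gi <- sample(length(genes), 1L)
                g <- genes[gi]
                if (stats::runif(1) < cfg$mispriming_rate) {
                    m <- mp[mp$gene == g, ]
                    if (m$strand == "+") {
                        st <- m$end3 - rl + 1L; cg <- paste0(rl, "M")
                        c5 <- ""; c3 <- ""
                    } else {
                        st <- m$end3; cg <- paste0(rl, "M")
                        c5 <- ""; c3 <- ""
                    }
                    recs[[idx]] <- list(chrom = m$chrom, start = st,
                        cigar = cg, strand = m$strand, mapq = mapq,
                        CB = barcodes[ci], UB = umi, clip5 = c5, clip3 = c3,
                        origin = "misprimed", gene = g, site = NA_integer_,
                        cleave_pos = NA_integer_, is_dup = FALSE)
                    next
                }
                ts <- bySite[[g]]
                k <- sample(nrow(ts), 1L, prob = ts[[fcol]])
                jit <- sample(seq(-cfg$jitter, cfg$jitter), 1L)
                if (ts$strand[1] == "+") {
                    endp <- ts$pos[k] + jit
                    st <- endp - rl + 1L
                    cg <- paste0(rl, "M", tl, "S")
                    c5 <- ""; c3 <- strrep("A", tl)
                    cpos <- endp
                } else {
                    st <- ts$pos[k] + 1L + jit
                    cg <- paste0(tl, "S", rl, "M")
                    c5 <- strrep("T", tl); c3 <- ""
                    cpos <- st - 1L
                }
                recs[[idx]] <- list(chrom = ts$chrom[1], start = st,
                    cigar = cg, strand = ts$strand[1], mapq = mapq,
                    CB = barcodes[ci], UB = umi, clip5 = c5, clip3 = c3,
                    origin = "genuine", gene = g, site = ts$site[k],
                    cleave_pos = cpos, is_dup = FALSE)
            }
        }
        df <- data.frame(
            chrom = vapply(recs, function(r) r$chrom, character(1)),
            start = vapply(recs, function(r) as.numeric(r$start),
                           numeric(1)),
            cigar = vapply(recs, function(r) r$cigar, character(1)),
            strand = vapply(recs, function(r) r$strand, character(1)),
            mapq = vapply(recs, function(r) as.integer(r$mapq),
                          integer(1)),
            CB = vapply(recs, function(r) r$CB, character(1)),
            UB = vapply(recs, function(r) r$UB, character(1)),
            clip5 = vapply(recs, function(r) r$clip5, character(1)),
            clip3 = vapply(recs, function(r) r$clip3, character(1)),
            origin = vapply(recs, function(r) r$origin, character(1)),
            gene = vapply(recs, function(r) r$gene, character(1)),
            site = vapply(recs, function(r) as.integer(r$site),
                          integer(1)),
            cleave_pos = vapply(recs, function(r)
                as.integer(r$cleave_pos), integer(1)),
            is_dup = vapply(recs, function(r) r$is_dup, logical(1)),
            stringsAsFactors = FALSE)
        ga <- GenomicAlignments::GAlignments(
            seqnames = S4Vectors::Rle(factor(df$chrom,
                                             levels = names(sim@genome))),
            pos = as.integer(df$start), cigar = df$cigar,
            strand = S4Vectors::Rle(GenomicRanges::strand(df$strand)),
            seqlengths = stats::setNames(Biostrings::width(sim@genome),
                                         names(sim@genome)))
        names(ga) <- sprintf("r%06d", seq_along(ga))
        mcols(ga) <- S4Vectors::DataFrame(
            CB = df$CB, UB = df$UB, mapq = df$mapq, clip5 = df$clip5,
            clip3 = df$clip3, origin = df$origin, gene = df$gene,
            site = df$site, cleave_pos = df$cleave_pos, is_dup = df$is_dup)
        ga
    })
}

#' Simulate a complete dataset (reference + reads)
#'
#' @param cfg a [simConfig()].
#' @return a [PolyASimulation] with the `reads` slot populated.
#' @export
simulatePolyADataset <- function(cfg = simConfig()) {
    sim <- simulateReference(cfg)
    sim@reads <- simulateReads(sim, cfg)
    methods::validObject(sim)
    sim
}

#' Cell metadata for a simulated dataset
#'
#' @param sim a [PolyASimulation] (with reads) or a [simConfig()].
#' @return `data.frame` with columns `barcode`, `test_ident`, `sample`;
#'   first column is the cell barcode.
#' @export
simCellMetadata <- function(sim) {
    cfg <- if (inherits(sim, "simConfig")) sim else
        do.call(simConfig, sim@config)
    n_cells <- cfg$cells_per_group * length(cfg$groups)
    data.frame(
        barcode = paste0(vapply(seq_len(n_cells), .intToSeq, character(1),
                                len = 16L), "-1"),
        test_ident = rep(cfg$groups, each = cfg$cells_per_group),
        sample = "sim")
}

#' Write a simulated dataset to disk as plain-text standard formats
#'
#' Emits `genome.fa`, `annotation.gtf`, `reads.sam` (with `CB:Z`/`UB:Z`
#' tags), `truth.tsv`, `misprime_loci.tsv` and `metadata.csv` under `dir`.
#'
#' @param sim a [PolyASimulation] with reads.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    Biostrings::writeXStringSet(sim@genome, file.path(dir, "genome.fa"))
    rtracklayer::export(sim@annotation, file.path(dir, "annotation.gtf"),
                        format = "gtf")
    writeTaggedSam(sim@reads, file.path(dir, "reads.sam"), sim@genome)
    utils::write.table(sim@truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(sim@misprimeLoci),
                       file.path(dir, "misprime_loci.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.csv(simCellMetadata(sim), file.path(dir, "metadata.csv"),
                     row.names = FALSE, quote = FALSE)
    invisible(dir)
}
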