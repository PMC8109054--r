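#' Simulate an in vivo pooled CRISPR screen
#'
#' Generative model of a transplantation screen, stochastic at every
#' sampling stage and deterministic in between:
#' \enumerate{
#'   \item plasmid pool skew: per-guide abundances ~ lognormal(0,
#'     \code{plasmidLogSd}), normalized to proportions;
#'   \item transduction: T0 cell counts ~ multinomial
#'     (\code{cellsTransduced}, plasmid proportions);
#'   \item engraftment bottleneck: per mouse, engrafted cells ~ multinomial
#'     (\code{engraftingCellsPerMouse}, T0 proportions) — the dominant
#'     noise source of in vivo screens;
#'   \item selection: each guide's cells split into an edited fraction
#'     (\code{editingEfficiency}) growing by \code{2^guide_effect} over the
#'     assay and an unedited fraction with effect 0; expected T12 abundance
#'     = engrafted * baseline growth * (eff * 2^effect + (1 - eff)), where
#'     baseline growth \code{2^(days / doublingTimeDays)} is common to all
#'     guides;
#'   \item sequencing: per-sample counts ~ Dirichlet-multinomial
#'     (\code{readDepth}; per-guide concentration proportional to
#'     \code{seqDispersion}), T0 included.
#' }
#' Fitness effects are specified per gene as log2 growth multipliers over
#' the whole assay (negative = dropout); each targeting guide draws its own
#' effect = gene effect + N(0, \code{guideEffectSd}), modeling variable
#' guide efficacy. The NTC always has effect 0.
#'
#' Defaults mirror the screen this package was designed around: 1e6 cells
#' transduced, 5 recipient mice, a 12-day assay, bottleneck of 2e5
#' engrafting cells (about 410 cells per guide for a 486-guide library),
#' 90% functional editing, and one shared T0 pool sequenced once.
#'
#' @param library an \code{\link{SgRNALibrary}}.
#' @param geneEffects named numeric vector of per-gene log2 fitness effects
#'   over the assay (names must be library genes); unnamed genes have
#'   effect 0.
#' @param guideEffectSd sd of the guide-level normal deviation around the
#'   gene effect (default 0.3), applied to every targeting and
#'   positive-control guide.
#' @param plasmidLogSd lognormal sd of plasmid pool skew (default 0.5).
#' @param cellsTransduced total cells at T0 (default 1e6).
#' @param engraftingCellsPerMouse bottleneck size per mouse (default 2e5).
#' @param nMice number of replicate recipients (default 5).
#' @param days assay duration in days (default 12).
#' @param doublingTimeDays baseline doubling time (default 1); with
#'   \code{days} it sets only the common expansion factor.
#' @param readDepth sequencing reads per sample (default 5e6).
#' @param seqDispersion Dirichlet-multinomial concentration: per-guide
#'   concentration is \code{proportion * n_guides * seqDispersion}
#'   (default 1000); \code{Inf} gives plain multinomial sequencing.
#' @param editingEfficiency fraction of transduced cells functionally
#'   knocked out per guide, in [0, 1] (default 0.9).
#' @param seed integer seed; identical configuration and seed give
#'   byte-identical output.
#' @return a \code{\link{SimulatedScreen}}.
#' @export
#' @examples
#' lib <- buildLibrary(sprintf("Gene%d", 1:6), guidesPerGene = 2,
#'                     nPositiveControl = 2, nNontargeting = 1, seed = 1)
#' sim <- simulateScreen(lib, geneEffects = c(Gene1 = -3), nMice = 3,
#'                       cellsTransduced = 1e4,
#'                       engraftingCellsPerMouse = 5e3,
#'                       readDepth = 1e5, seed = 7)
#' screenCounts(sim)
simulateScreen <- function(library,
                           geneEffects = numeric(0),
                           guideEffectSd = 0.3,
                           plasmidLogSd = 0.5,
                           cellsTransduced = 1e6,
                           engraftingCellsPerMouse = 2e5,
                           nMice = 5,
                           days = 12,
                           doublingTimeDays = 1,
                           readDepth = 5e6,
                           seqDispersion = 1000,
                           editingEfficiency = 0.9,
                           seed = 1) {
    stopifnot(is(library, "SgRNALibrary"),
              .is_count1(cellsTransduced, min = 1),
              .is_count1(engraftingCellsPerMouse, min = 1),
              .is_count1(nMice, min = 1),
              .is_count1(readDepth, min = 1),
              days > 0, doublingTimeDays > 0, seqDispersion > 0,
              editingEfficiency >= 0, editingEfficiency <= 1,
              guideEffectSd >= 0, plasmidLogSd >= 0)
    if (engraftingCellsPerMouse > cellsTransduced)
        stop("infeasible configuration: bottleneck exceeds transduced cells")
    gd <- as.data.frame(guideData(library))
    G <- nrow(gd)
    if (length(geneEffects)) {
        if (is.null(names(geneEffects)))
            stop("'geneEffects' must be a named vector")
        unknown <- setdiff(names(geneEffects), gd$gene)
        if (length(unknown))
            stop("geneEffects for genes absent from library: ",
                 paste(unknown, collapse = ", "))
    }
    set.seed(seed)

    gene_eff <- setNames(rep(0, G), gd$guide_id)
    hit <- gd$gene %in% names(geneEffects)
    gene_eff[hit] <- geneEffects[gd$gene[hit]]
    guide_eff <- gene_eff +
        ifelse(gd$role == "nontargeting", 0, rnorm(G, 0, guideEffectSd))
    guide_eff[gd$role == "nontargeting"] <- 0

    ## (1) plasmid skew, (2) transduction
    plasmid <- rlnorm(G, 0, plasmidLogSd)
    p0 <- plasmid / sum(plasmid)
    t0_cells <- as.integer(rmultinom(1L, cellsTransduced, p0))
    p_t0 <- t0_cells / sum(t0_cells)

    ## (4) guide-wise expected growth over the assay
    baseline <- 2^(days / doublingTimeDays)
    mult <- editingEfficiency * 2^guide_eff + (1 - editingEfficiency)

    engrafted <- matrix(0L, nrow = G, ncol = nMice)
    t12_expected <- matrix(0, nrow = G, ncol = nMice)
    counts <- matrix(0L, nrow = G, ncol = nMice + 1L)
    ## shared T0 sequenced once
    counts[, 1L] <- .rdirmnom(readDepth, p_t0, seqDispersion)
    for (m in seq_len(nMice)) {
        ## (3) engraftment bottleneck
        eng <- as.integer(rmultinom(1L, engraftingCellsPerMouse, p_t0))
        engrafted[, m] <- eng
        exp12 <- eng * baseline * mult
        t12_expected[, m] <- exp12
        p12 <- if (sum(exp12) > 0) exp12 / sum(exp12) else p_t0
        ## (5) overdispersed sequencing
        counts[, m + 1L] <- .rdirmnom(readDepth, p12, seqDispersion)
    }
    dimnames(counts) <- list(gd$guide_id,
                             c("T0", paste0("T12_m", seq_len(nMice))))
    colnames(engrafted) <- colnames(t12_expected) <-
        paste0("m", seq_len(nMice))

    sample_info <- data.frame(
        sample_id = colnames(counts),
        timepoint = c("T0", rep("T12", nMice)),
        replicate = c(NA_character_, paste0("m", seq_len(nMice))),
        stringsAsFactors = FALSE)
    sc <- ScreenCounts(counts, sampleInfo = sample_info, library = library,
                       totalReads = rep(readDepth, nMice + 1L))
    truth <- S4Vectors::DataFrame(
        guide_id = gd$guide_id, gene = gd$gene, role = gd$role,
        gene_effect = unname(gene_eff), guide_effect = unname(guide_eff),
        plasmid_prop = p0, t0_cells = t0_cells,
        engrafted = I(engrafted), t12_expected = I(t12_expected),
        row.names = gd$guide_id)
    cfg <- list(geneEffects = geneEffects, guideEffectSd = guideEffectSd,
                plasmidLogSd = plasmidLogSd,
                cellsTransduced = cellsTransduced,
                engraftingCellsPerMouse = engraftingCellsPerMouse,
                nMice = nMice, days = days,
                doublingTimeDays = doublingTimeDays,
                readDepth = readDepth, seqDispersion = seqDispersion,
                editingEfficiency = editingEfficiency, seed = seed,
                library = libraryName(library))
    new("SimulatedScreen", counts = sc, truth = truth, config = cfg)
}

#' @rdname SimulatedScreen-class
#' @export
setMethod("screenCounts", "SimulatedScreen", function(x) x@counts)

#' @rdname SimulatedScreen-class
#' @export
setMethod("simTruth", "SimulatedScreen", function(x) x@truth)

#' @rdname SimulatedScreen-class
#' @export
setMethod("simConfig", "SimulatedScreen", function(x) x@config)

#' @rdname SimulatedScreen-class
#' @export
setMethod("show", "SimulatedScreen", function(object) {
    cfg <- object@config
    nz <- sum(object@truth$gene_effect != 0 &
              !duplicated(object@truth$gene))
    cat(sprintf(
        "SimulatedScreen: %d guides, %d mice, depth %g reads/sample\n",
        nrow(object@truth), cfg$nMice, cfg$readDepth))
    cat(sprintf("  genes with nonzero fitness effect: %d (seed %d)\n",
                nz, cfg$seed))
})

#' Emit FASTQ reads for a simulated screen
#'
#' Writes one FASTQ file per sample of a \code{\link{SimulatedScreen}},
#' each read carrying the sample's guide spacer behind the vector anchor
#' (count-faithful: guide g appears exactly count[g, s] times), plus a
#' sample sheet TSV, so the simulated screen can be pushed through
#' \code{\link{countReads}} end to end.
#'
#' @param screen a \code{\link{SimulatedScreen}}.
#' @param dir output directory (created if needed).
#' @param anchor vector constant region placed 5' of the spacer.
#' @param prefix bases placed 5' of the anchor.
#' @param suffix bases placed 3' of the spacer (scaffold start).
#' @param gzip write gzipped FASTQ (default \code{FALSE}).
#' @return the sample sheet as a data.frame (columns \code{sample_id},
#'   \code{timepoint}, \code{replicate}, \code{fastq_path}), invisibly
#'   also written to \code{file.path(dir, "samples.tsv")}.
#' @export
writeScreenFastq <- function(screen, dir, anchor = "GAAACACCG",
                             prefix = "TTGTGGAAAGGACGAAACACCG",
                             suffix = "GTTTTAGAGCTAGAAATAGCAAG",
                             gzip = FALSE) {
    stopifnot(is(screen, "SimulatedScreen"))
    ## prefix already ends in the anchor in the default vector context;
    ## ensure the anchor is present exactly where extraction expects it
    if (!endsWith(prefix, anchor)) prefix <- paste0(prefix, anchor)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    sc <- screenCounts(screen)
    m <- SummarizedExperiment::assay(sc, "counts")
    sp <- SummarizedExperiment::rowData(sc)$spacer
    cd <- SummarizedExperiment::colData(sc)
    ext <- if (gzip) ".fastq.gz" else ".fastq"
    paths <- character(ncol(m))
    for (j in seq_len(ncol(m))) {
        cnt <- m[, j]
        seqs <- rep(paste0(prefix, sp, suffix), times = cnt)
        ids <- paste0(colnames(m)[j], "_read", seq_along(seqs))
        paths[j] <- file.path(dir, paste0(colnames(m)[j], ext))
        writeFastq(data.frame(id = ids, seq = seqs,
                              stringsAsFactors = FALSE), paths[j])
    }
    sheet <- data.frame(sample_id = colnames(m),
                        timepoint = cd$timepoint,
                        replicate = cd$replicate,
                        fastq_path = paths, stringsAsFactors = FALSE)
    .write_tsv(sheet, file.path(dir, "samples.tsv"))
    sheet
}

#' Simulate amplicon sequencing reads around a cut site
#'
#' Test-bed generator for \code{\link{quantifyEditing}}: a fixed share of
#' reads (\code{round(nReads * editingFraction)}) carries exactly one indel
#' whose reference span intersects the predicted cut site (size uniform in
#' \code{indelSizeRange}, deletion/insertion coin-flip; deletions are
#' placed to cover the cut coordinate, insertions at the cut), and every
#' read receives independent per-base substitution noise. Truth labels are
#' returned alongside the reads.
#'
#' @param amplicon an \code{\link{Amplicon}}.
#' @param editingFraction fraction of reads carrying an indel, in [0, 1].
#' @param nReads number of reads.
#' @param indelSizeRange integer interval of indel sizes (default 1..10).
#' @param substitutionErrorRate per-base substitution probability (default
#'   0.01).
#' @param seed integer seed.
#' @return a list with \code{reads} (data.frame \code{id}, \code{seq},
#'   \code{qual}, FASTQ-ready) and \code{truth} (data.frame \code{id},
#'   \code{edited}, \code{indel_type}, \code{indel_pos},
#'   \code{indel_len}).
#' @export
simulateAmpliconReads <- function(amplicon, editingFraction, nReads,
                                  indelSizeRange = c(1L, 10L),
                                  substitutionErrorRate = 0.01,
                                  seed = 1) {
    stopifnot(is(amplicon, "Amplicon"),
              editingFraction >= 0, editingFraction <= 1,
              .is_count1(nReads, min = 1),
              length(indelSizeRange) == 2,
              indelSizeRange[1] >= 1,
              indelSizeRange[2] >= indelSizeRange[1],
              substitutionErrorRate >= 0, substitutionErrorRate < 1)
    set.seed(seed)
    ref <- amplicon@sequence
    L <- nchar(ref)
    cut0 <- predictCutSite(amplicon)  # 0-based
    n_edit <- round(nReads * editingFraction)
    edited <- c(rep(TRUE, n_edit), rep(FALSE, nReads - n_edit))

    seqs <- character(nReads)
    itype <- rep(NA_character_, nReads)
    ipos <- rep(NA_integer_, nReads)
    ilen <- rep(NA_integer_, nReads)
    for (i in seq_len(nReads)) {
        s <- ref
        if (edited[i]) {
            len <- sample(indelSizeRange[1]:indelSizeRange[2], 1L)
            if (runif(1) < 0.5) {             # deletion covering the cut
                start0 <- cut0 - sample(0:(len - 1L), 1L)
                start0 <- max(0L, min(start0, L - len))
                s <- paste0(substr(s, 1L, start0),
                            substr(s, start0 + len + 1L, L))
                itype[i] <- "deletion"; ipos[i] <- start0; ilen[i] <- len
            } else {                          # insertion at the cut
                ins <- paste(sample(DNA_BASES, len, replace = TRUE),
                             collapse = "")
                s <- paste0(substr(s, 1L, cut0 + 1L), ins,
                            substr(s, cut0 + 2L, L))
                itype[i] <- "insertion"; ipos[i] <- cut0 + 1L
                ilen[i] <- len
            }
        }
        if (substitutionErrorRate > 0) {
            ch <- strsplit(s, "")[[1]]
            err <- which(runif(length(ch)) < substitutionErrorRate)
            if (length(err))
                ch[err] <- vapply(ch[err], function(b)
                    sample(setdiff(DNA_BASES, b), 1L), character(1))
            s <- paste(ch, collapse = "")
        }
        seqs[i] <- s
    }
    ids <- sprintf("%s_read%06d", amplicon@name, seq_len(nReads))
    list(reads = data.frame(id = ids, seq = seqs,
                            qual = strrep("I", nchar(seqs)),
                            stringsAsFactors = FALSE),
         truth = data.frame(id = ids, edited = edited, indel_type = itype,
                            indel_pos = ipos, indel_len = ilen,
                            stringsAsFactors = FALSE))
}

#' Recovery of planted effects by the scoring pipeline
#'
#' Compares gene scores computed from a simulated screen against the
#' simulator's ground truth: genes with a nonzero planted effect are
#' positives (negative effect should be called positive_regulator,
#' positive effect negative_regulator), genes with effect 0 are negatives
#' and should be classified \code{"none"}.
#'
#' @param screen a \code{\link{SimulatedScreen}}.
#' @param scores result of \code{\link{scoreGenes}} on the screen's
#'   counts.
#' @return a list: \code{hits} (data.frame per true-effect gene:
#'   \code{gene}, \code{effect}, \code{expected_class}, \code{called},
#'   \code{rank} in the matching direction list), \code{sensitivity}
#'   (NA when there are no positives), \code{specificity}, and
#'   \code{n_positive}/\code{n_negative}.
#' @export
truthRecoveryReport <- function(screen, scores) {
    stopifnot(is(screen, "SimulatedScreen"))
    truth <- as.data.frame(simTruth(screen))
    gs <- scores$geneScores
    gene_eff <- truth[!duplicated(truth$gene) &
                      truth$role != "nontargeting",
                      c("gene", "gene_effect")]
    if (!setequal(gene_eff$gene, gs$gene))
        stop("gene sets of truth and scores do not match")
    pos <- gene_eff[gene_eff$gene_effect != 0, , drop = FALSE]
    neg <- gene_eff[gene_eff$gene_effect == 0, , drop = FALSE]
    hits <- NULL
    if (nrow(pos)) {
        hits <- do.call(rbind, lapply(seq_len(nrow(pos)), function(i) {
            g <- pos$gene[i]; e <- pos$gene_effect[i]
            expect <- if (e < 0) "positive_regulator" else
                "negative_regulator"
            row <- gs[gs$gene == g, , drop = FALSE]
            data.frame(gene = g, effect = e, expected_class = expect,
                       called = row$classification == expect,
                       rank = if (e < 0) row$rank_depletion else
                           row$rank_enrichment,
                       stringsAsFactors = FALSE)
        }))
    }
    sens <- if (nrow(pos)) mean(hits$called) else NA_real_
    spec <- if (nrow(neg))
        mean(gs$classification[match(neg$gene, gs$gene)] == "none")
        else NA_real_
    list(hits = hits, sensitivity = sens, specificity = spec,
         n_positive = nrow(pos), n_negative = nrow(neg))
}
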