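#' Normalize raw guide counts to reads per million
#'
#' The representation of guide g in sample s is
#' \deqn{rep_{gs} = 10^6 (c_{gs} + k) / \sum_g (c_{gs} + k)}
#' with pseudocount k (default 1). The pseudocount keeps strongly depleted
#' guides (zero T12 counts) at a finite, strictly positive representation so
#' that fold changes are defined; screens with >30-fold depletions need it.
#' With pseudocount 0, the representation is scale invariant: multiplying a
#' sample's raw counts by a constant leaves it unchanged.
#'
#' @param x a \code{\link{ScreenCounts}} or a nonnegative count matrix
#'   (guides x samples).
#' @param pseudocount nonnegative real added to every count before scaling
#'   (default 1).
#' @return a numeric matrix of reads-per-million representations with the
#'   dimnames of the input counts.
#' @export
normalizeCounts <- function(x, pseudocount = 1) {
    stopifnot(is.numeric(pseudocount), length(pseudocount) == 1,
              pseudocount >= 0)
    m <- if (is(x, "ScreenCounts"))
        SummarizedExperiment::assay(x, "counts") else as.matrix(x)
    if (any(m < 0)) stop("counts must be nonnegative")
    adj <- m + pseudocount
    tot <- colSums(adj)
    zero <- which(tot == 0)
    if (length(zero))
        stop("sample(s) with zero total count and zero pseudocount: ",
             paste(colnames(m)[zero] %||% zero, collapse = ", "))
    sweep(adj, 2, tot, "/") * 1e6
}

#' Per-replicate T12/T0 fold changes
#'
#' For each replicate r, \code{fc[g, r] = rep[g, T12_r] / rep[g, T0_r]}.
#' The screen design this models sequences one shared T0 pool (the
#' transduced cells before transplant) against one T12 sample per recipient
#' mouse; a single T0 sample therefore pairs with every replicate.
#' Per-replicate T0 samples are also supported, either through matching
#' \code{replicate} labels in \code{sampleInfo} or an explicit
#' \code{pairing}.
#'
#' @param rep representation matrix from \code{\link{normalizeCounts}}
#'   (strictly positive).
#' @param sampleInfo \code{data.frame}/\code{DataFrame} with
#'   \code{sample_id}, \code{timepoint}, \code{replicate} for the columns
#'   of \code{rep}; taken from \code{colData} when a
#'   \code{\link{ScreenCounts}} was normalized and passed here as
#'   \code{counts}.
#' @param pairing optional \code{data.frame} with columns \code{replicate},
#'   \code{t12}, \code{t0} (sample ids) overriding the automatic pairing.
#' @return numeric matrix of fold changes, guides x replicates, with
#'   replicate labels as column names.
#' @export
foldChange <- function(rep, sampleInfo, pairing = NULL) {
    sampleInfo <- as.data.frame(sampleInfo)
    if (is.null(pairing)) {
        t12 <- sampleInfo[sampleInfo$timepoint == "T12", , drop = FALSE]
        t0 <- sampleInfo[sampleInfo$timepoint == "T0", , drop = FALSE]
        if (nrow(t12) == 0) stop("no T12 samples to pair")
        if (nrow(t0) == 0) stop("no T0 sample to pair against")
        t0_for <- function(repl) {
            hit <- t0$sample_id[!is.na(t0$replicate) &
                                t0$replicate == repl]
            if (length(hit) == 1) return(hit)
            if (nrow(t0) == 1) return(t0$sample_id)  # shared T0 pool
            stop("ambiguous T0 pairing for replicate ", repl)
        }
        pairing <- data.frame(
            replicate = t12$replicate, t12 = t12$sample_id,
            t0 = vapply(t12$replicate, t0_for, character(1)),
            stringsAsFactors = FALSE)
    }
    missing <- setdiff(c(pairing$t12, pairing$t0), colnames(rep))
    if (length(missing))
        stop("sample(s) in pairing absent from representation table: ",
             paste(missing, collapse = ", "))
    if (any(rep[, unique(c(pairing$t12, pairing$t0))] <= 0))
        stop("representations must be strictly positive (use a pseudocount)")
    fc <- rep[, pairing$t12, drop = FALSE] /
        rep[, pairing$t0, drop = FALSE]
    colnames(fc) <- pairing$replicate
    fc
}

#' Median fold change across replicates
#'
#' The screen's ranking statistic: per guide, the sample median of the
#' per-replicate fold changes (for an even number of replicates, the
#' midpoint of the central pair), with log2 applied after taking the
#' median.
#'
#' @param fc fold-change matrix from \code{\link{foldChange}} (guides x
#'   replicates).
#' @return a \code{data.frame} with one row per guide: \code{guide_id}, one
#'   \code{fc_<replicate>} column per replicate, \code{median_fc}, and
#'   \code{log2_median_fc} (exactly \code{log2(median_fc)}).
#' @export
medianFoldChange <- function(fc) {
    fc <- as.matrix(fc)
    if (ncol(fc) < 1) stop("at least one replicate is required")
    med <- apply(fc, 1, stats::median)
    out <- data.frame(guide_id = rownames(fc), fc,
                      stringsAsFactors = FALSE, check.names = FALSE)
    colnames(out)[-1] <- paste0("fc_", colnames(fc))
    out$median_fc <- med
    out$log2_median_fc <- log2(med)
    rownames(out) <- NULL
    out
}

#' Convenience wrapper: counts to guide-level median fold changes
#'
#' Runs \code{\link{normalizeCounts}}, \code{\link{foldChange}} and
#' \code{\link{medianFoldChange}} on a \code{\link{ScreenCounts}} and
#' annotates the result with gene and role from its rowData.
#'
#' @param counts a \code{\link{ScreenCounts}} with guide rowData.
#' @param pseudocount see \code{\link{normalizeCounts}}.
#' @param pairing see \code{\link{foldChange}}.
#' @return the \code{\link{medianFoldChange}} data.frame with \code{gene}
#'   and \code{role} columns prepended after \code{guide_id}.
#' @export
screenFoldChanges <- function(counts, pseudocount = 1, pairing = NULL) {
    stopifnot(is(counts, "ScreenCounts"))
    rep <- normalizeCounts(counts, pseudocount = pseudocount)
    fc <- foldChange(rep, SummarizedExperiment::colData(counts),
                     pairing = pairing)
    med <- medianFoldChange(fc)
    rd <- SummarizedExperiment::rowData(counts)
    ann <- data.frame(gene = rd$gene, role = rd$role,
                      stringsAsFactors = FALSE)[
        match(med$guide_id, rownames(rd)), , drop = FALSE]
    cbind(med[, "guide_id", drop = FALSE], ann,
          med[, -1, drop = FALSE], row.names = NULL)
}

#' Rank genes by the number of guides past the fold-change threshold
#'
#' For each gene, counts guides with median fold change at or beyond the
#' threshold in each direction (\code{median_fc <= 1/fcThreshold} depleted,
#' \code{>= fcThreshold} enriched; the default threshold 2 corresponds to
#' |log2 median FC| >= 1). A gene is called a \emph{positive regulator}
#' (its loss depletes the cells) when at least \code{minGuides} guides are
#' depleted and depleted guides outnumber enriched ones; \emph{negative
#' regulator} symmetrically. Genes are ranked separately for each
#' direction: primarily by the direction's guide count (descending), ties
#' broken by |median of the gene's guide log2 median FCs| (descending),
#' then gene name. Nontargeting guides are excluded from gene scoring and
#' reported separately.
#'
#' @param medians guide-level data.frame from
#'   \code{\link{screenFoldChanges}} (or \code{\link{medianFoldChange}}
#'   plus a \code{library}).
#' @param library optional \code{\link{SgRNALibrary}} supplying
#'   gene/role annotation when \code{medians} lacks those columns.
#' @param fcThreshold fold-change threshold > 1 (default 2).
#' @param minGuides minimum guides past threshold for a hit (default 2).
#' @return a list with components
#'   \describe{
#'     \item{geneScores}{data.frame, one row per gene: \code{gene},
#'       \code{n_guides}, \code{n_depleted}, \code{n_enriched},
#'       \code{summary_log2fc}, \code{classification},
#'       \code{rank_depletion}, \code{rank_enrichment}; sorted by depletion
#'       rank.}
#'     \item{depletion, enrichment}{the same table sorted by the
#'       respective ranking.}
#'     \item{ntc}{guide-level rows for nontargeting guides.}
#'   }
#' @export
scoreGenes <- function(medians, library = NULL, fcThreshold = 2,
                       minGuides = 2) {
    stopifnot(is.numeric(fcThreshold), fcThreshold > 1,
              .is_count1(minGuides, min = 1))
    if (!all(c("gene", "role") %in% colnames(medians))) {
        if (is.null(library))
            stop("'medians' lacks gene/role columns; supply 'library'")
        gd <- guideData(library)
        hit <- match(medians$guide_id, gd$guide_id)
        if (anyNA(hit))
            stop("guide(s) absent from library: ",
                 paste(medians$guide_id[is.na(hit)], collapse = ", "))
        medians$gene <- gd$gene[hit]
        medians$role <- gd$role[hit]
    }
    ntc <- medians[medians$role == "nontargeting", , drop = FALSE]
    targ <- medians[medians$role != "nontargeting", , drop = FALSE]
    genes <- unique(targ$gene)
    scores <- do.call(rbind, lapply(genes, function(g) {
        gi <- targ[targ$gene == g, , drop = FALSE]
        data.frame(
            gene = g,
            n_guides = nrow(gi),
            n_depleted = sum(gi$median_fc <= 1 / fcThreshold),
            n_enriched = sum(gi$median_fc >= fcThreshold),
            summary_log2fc = stats::median(gi$log2_median_fc),
            stringsAsFactors = FALSE)
    }))
    scores$classification <- with(scores, ifelse(
        n_depleted >= minGuides & n_depleted > n_enriched,
        "positive_regulator",
        ifelse(n_enriched >= minGuides & n_enriched > n_depleted,
               "negative_regulator", "none")))
    rank_by <- function(count) {
        ord <- order(-count, -abs(scores$summary_log2fc), scores$gene)
        rk <- integer(nrow(scores)); rk[ord] <- seq_len(nrow(scores)); rk
    }
    scores$rank_depletion <- rank_by(scores$n_depleted)
    scores$rank_enrichment <- rank_by(scores$n_enriched)
    scores <- scores[order(scores$rank_depletion), , drop = FALSE]
    rownames(scores) <- NULL
    list(geneScores = scores,
         depletion = scores[order(scores$rank_depletion), , drop = FALSE],
         enrichment = scores[order(scores$rank_enrichment), , drop = FALSE],
         ntc = ntc)
}

#' Guide-level waterfall table
#'
#' Guides sorted by log2 median fold change, descending (ties keep stable
#' input order) — the tabular form of the classic screen waterfall plot,
#' with the enrichment/depletion thresholds at log2 = +1/-1 (fold change
#' 2.0) annotated per guide.
#'
#' @param medians guide-level data.frame from
#'   \code{\link{screenFoldChanges}}.
#' @param log2Threshold absolute log2 threshold to annotate (default 1).
#' @return a data.frame with \code{rank}, \code{guide_id}, \code{gene},
#'   \code{role} (when present), \code{median_fc}, \code{log2_median_fc},
#'   \code{status} (\code{enriched}/\code{depleted}/\code{within}); the
#'   threshold is attached as attribute \code{"log2_threshold"}.
#' @export
waterfallTable <- function(medians, log2Threshold = 1) {
    ord <- order(-medians$log2_median_fc)  # stable in R
    keep <- intersect(c("guide_id", "gene", "role", "median_fc",
                        "log2_median_fc"), colnames(medians))
    out <- medians[ord, keep, drop = FALSE]
    out$status <- ifelse(out$log2_median_fc >= log2Threshold, "enriched",
                         ifelse(out$log2_median_fc <= -log2Threshold,
                                "depleted", "within"))
    out <- cbind(rank = seq_len(nrow(out)), out)
    rownames(out) <- NULL
    attr(out, "log2_threshold") <- log2Threshold
    out
}

#' Plot a guide-level waterfall
#'
#' Base-graphics rendering of \code{\link{waterfallTable}}: ranked log2
#' median fold changes with dotted threshold lines at +/- the annotated
#' log2 threshold.
#'
#' @param wf a waterfall table from \code{\link{waterfallTable}}.
#' @param ... passed to \code{plot}.
#' @return invisibly, \code{wf}.
#' @importFrom graphics abline points
#' @export
plotWaterfall <- function(wf, ...) {
    thr <- attr(wf, "log2_threshold") %||% 1
    plot(wf$rank, wf$log2_median_fc, type = "h", col = "grey60",
         xlab = "sgRNA rank", ylab = "log2 median fold change (T12/T0)",
         ...)
    abline(h = c(-thr, thr), lty = 3, col = c("blue", "red"))
    ntc <- wf$role == "nontargeting"
    if (any(ntc, na.rm = TRUE))
        points(wf$rank[ntc], wf$log2_median_fc[ntc], col = "red", pch = 17)
    invisible(wf)
}

#' Normalize an output percentage to its input percentage
#'
#' Competition and homing assays report the percentage of marked
#' (sgRNA-expressing, GFP+) cells in a tissue normalized to the marked
#' percentage of the input cells, to compensate for differences in
#' transduction efficiency: ratio = percentOut / percentIn.
#'
#' @param percentOut output percentage, in (0, 100].
#' @param percentIn input percentage, in (0, 100]; must be > 0.
#' @return the ratio; 1 means no change relative to input.
#' @export
#' @examples
#' normalizeToInput(30, 60)  # 0.5
normalizeToInput <- function(percentOut, percentIn) {
    if (any(percentIn <= 0)) stop("'percentIn' must be > 0")
    stopifnot(all(percentOut >= 0), all(percentOut <= 100),
              all(percentIn <= 100))
    percentOut / percentIn
}
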