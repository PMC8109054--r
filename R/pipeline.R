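#' Run the screen analysis pipeline end to end
#'
#' Orchestrates simulate (optional) -> count -> normalize -> fold change ->
#' median -> gene ranking -> waterfall, writing all artifacts plus a run
#' manifest and a log to an output directory. Every stage calls the same
#' exported functions a user would call interactively, so end-to-end output
#' equals stage-wise composition on identical inputs, and all randomness
#' flows from \code{config$seed}.
#'
#' The \code{config} list understands:
#' \describe{
#'   \item{outDir}{output directory (required).}
#'   \item{library}{an \code{\link{SgRNALibrary}}, or \code{libraryTsv}, a
#'     path to a library table.}
#'   \item{simulate}{list of \code{\link{simulateScreen}} arguments (minus
#'     library/seed) to run a synthetic screen; when
#'     \code{simulate$emitFastq} is \code{TRUE} the simulated counts are
#'     round-tripped through FASTQ emission and \code{\link{countReads}}.}
#'   \item{sampleSheet}{path to a sample sheet TSV (\code{sample_id},
#'     \code{timepoint}, \code{replicate}, \code{fastq_path}) for a real
#'     run; or \code{countsTsv} + \code{sampleInfo} for precomputed
#'     counts.}
#'   \item{counting}{list: \code{anchor}, \code{maxMismatches},
#'     \code{searchWindow}, \code{bothStrands}.}
#'   \item{scoring}{list: \code{pseudocount} (default 1),
#'     \code{fcThreshold} (default 2), \code{minGuides} (default 2).}
#'   \item{seed}{integer seed for synthetic runs (default 1).}
#' }
#'
#' @param config a configuration list as above.
#' @return invisibly, a list with the artifact paths (\code{counts_tsv},
#'   \code{guide_tsv}, \code{gene_tsv}, \code{waterfall_tsv},
#'   \code{summary_json}, \code{manifest_json}, \code{log}) and the
#'   in-memory objects (\code{counts}, \code{medians}, \code{scores},
#'   \code{waterfall}, and \code{screen} for synthetic runs).
#' @export
runScreenPipeline <- function(config) {
    if (is.null(config$outDir))
        .stop_stage("config", "'outDir' is required")
    for (p in c("libraryTsv", "sampleSheet", "countsTsv")) {
        if (!is.null(config[[p]]) && !file.exists(config[[p]]))
            .stop_stage("config", sprintf("%s file not found: '%s'",
                                          p, config[[p]]))
    }
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    log_path <- file.path(config$outDir, "run.log")
    log_con <- file(log_path, open = "wt")
    on.exit(close(log_con))
    say <- function(fmt, ...) {
        msg <- sprintf(paste0("[%s] ", fmt),
                       format(Sys.time(), "%H:%M:%S"), ...)
        writeLines(msg, log_con)
        message(msg)
    }
    seed <- config$seed %||% 1L
    scoring <- config$scoring %||% list()
    pseudocount <- scoring$pseudocount %||% 1
    fcThreshold <- scoring$fcThreshold %||% 2
    minGuides <- scoring$minGuides %||% 2
    cnt_cfg <- config$counting %||% list()

    inputs <- character(0)

    ## ---- library ----
    library <- config$library
    if (is.null(library)) {
        if (is.null(config$libraryTsv))
            .stop_stage("library", "no 'library' or 'libraryTsv' supplied")
        library <- readLibraryTsv(config$libraryTsv)
        inputs <- c(inputs, config$libraryTsv)
    }
    say("library: %d guides", length(library))

    ## ---- counts ----
    screen <- NULL
    if (!is.null(config$simulate)) {
        sim_args <- config$simulate
        emitFastq <- isTRUE(sim_args$emitFastq)
        sim_args$emitFastq <- NULL
        screen <- do.call(simulateScreen,
                          c(list(library = library, seed = seed), sim_args))
        say("simulated screen: %d mice, depth %g",
            simConfig(screen)$nMice, simConfig(screen)$readDepth)
        if (emitFastq) {
            fq_dir <- file.path(config$outDir, "fastq")
            sheet <- writeScreenFastq(screen, fq_dir,
                anchor = cnt_cfg$anchor %||% "GAAACACCG")
            counts <- do.call(countReads, c(list(reads = sheet,
                                                 library = library),
                                            cnt_cfg))
            say("counted emitted FASTQ: %d samples", ncol(counts))
        } else {
            counts <- screenCounts(screen)
        }
    } else if (!is.null(config$sampleSheet)) {
        sheet <- .read_tsv(config$sampleSheet)
        inputs <- c(inputs, config$sampleSheet, sheet$fastq_path)
        counts <- do.call(countReads, c(list(reads = sheet,
                                             library = library), cnt_cfg))
        say("counted %d samples from FASTQ", ncol(counts))
    } else if (!is.null(config$countsTsv)) {
        si <- config$sampleInfo
        if (is.character(si)) { inputs <- c(inputs, si); si <- .read_tsv(si) }
        counts <- readCountsTsv(config$countsTsv, sampleInfo = si,
                                library = library)
        inputs <- c(inputs, config$countsTsv)
        say("loaded counts TSV: %d samples", ncol(counts))
    } else {
        .stop_stage("counts",
                    "supply 'simulate', 'sampleSheet' or 'countsTsv'")
    }

    ## ---- scoring ----
    medians <- screenFoldChanges(counts, pseudocount = pseudocount)
    scores <- scoreGenes(medians, fcThreshold = fcThreshold,
                         minGuides = minGuides)
    wf <- waterfallTable(medians, log2Threshold = log2(fcThreshold))
    say("scored %d genes; top depletion: %s; top enrichment: %s",
        nrow(scores$geneScores), scores$depletion$gene[1],
        scores$enrichment$gene[1])

    ## ---- artifacts ----
    paths <- list(
        counts_tsv = file.path(config$outDir, "counts.tsv"),
        guide_tsv = file.path(config$outDir, "guide_scores.tsv"),
        gene_tsv = file.path(config$outDir, "gene_scores.tsv"),
        waterfall_tsv = file.path(config$outDir, "waterfall.tsv"),
        summary_json = file.path(config$outDir, "summary.json"),
        manifest_json = file.path(config$outDir, "manifest.json"),
        log = log_path)
    writeCountsTsv(counts, paths$counts_tsv)
    .write_tsv(medians, paths$guide_tsv)
    .write_tsv(scores$geneScores, paths$gene_tsv)
    .write_tsv(wf, paths$waterfall_tsv)

    cd <- SummarizedExperiment::colData(counts)
    hits_dep <- scores$geneScores$gene[
        scores$geneScores$classification == "positive_regulator"]
    hits_enr <- scores$geneScores$gene[
        scores$geneScores$classification == "negative_regulator"]
    summary <- list(
        n_guides = nrow(counts),
        n_samples = ncol(counts),
        total_reads = as.list(setNames(cd$total_reads, colnames(counts))),
        unassigned_fraction = as.list(setNames(
            ifelse(cd$total_reads > 0, cd$unassigned / cd$total_reads, 0),
            colnames(counts))),
        ambiguous_reads = as.list(setNames(cd$ambiguous,
                                           colnames(counts))),
        fc_threshold = fcThreshold,
        log2_threshold = log2(fcThreshold),
        min_guides_for_hit = minGuides,
        positive_regulators = as.list(hits_dep),
        negative_regulators = as.list(hits_enr),
        top_depleted_genes = as.list(utils::head(scores$depletion$gene, 10)),
        top_enriched_genes = as.list(utils::head(scores$enrichment$gene, 10)))
    jsonlite::write_json(summary, paths$summary_json, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)

    manifest <- list(
        config = .manifest_config(config),
        seed = seed,
        input_md5 = as.list(tools::md5sum(unique(inputs))),
        package_version = as.character(utils::packageVersion("vivoscreen")))
    jsonlite::write_json(manifest, paths$manifest_json, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    say("artifacts written to %s", config$outDir)

    invisible(c(paths, list(counts = counts, medians = medians,
                            scores = scores, waterfall = wf,
                            screen = screen)))
}

## config echo with non-serializable members replaced by descriptions
.manifest_config <- function(config) {
    cfg <- config
    if (is(cfg$library, "SgRNALibrary"))
        cfg$library <- sprintf("<SgRNALibrary '%s', %d guides>",
                               libraryName(cfg$library),
                               length(cfg$library))
    cfg
}

#' Summarize pipeline artifacts
#'
#' Reads the artifact files of a \code{\link{runScreenPipeline}} output
#' directory and produces a short human-readable report plus a stable JSON
#' structure (counts QC, the log2 fold-change threshold lines, hit lists in
#' both directions).
#'
#' @param dir a pipeline output directory.
#' @return a list with \code{text} (character vector of report lines) and
#'   \code{json} (the summary structure); the text is also printed.
#' @export
reportSummary <- function(dir) {
    sj <- file.path(dir, "summary.json")
    if (!file.exists(sj)) stop("no summary.json in '", dir, "'")
    s <- jsonlite::read_json(sj, simplifyVector = TRUE)
    gene_tsv <- file.path(dir, "gene_scores.tsv")
    genes <- if (file.exists(gene_tsv)) .read_tsv(gene_tsv) else NULL
    txt <- c(
        sprintf("Screen summary: %d guides x %d samples", s$n_guides,
                s$n_samples),
        sprintf("Unassigned read fraction: %s",
                paste(sprintf("%s=%.3f", names(s$unassigned_fraction),
                              unlist(s$unassigned_fraction)),
                      collapse = ", ")),
        sprintf("Thresholds: fold change %.2f (log2 +/- %.2f), >= %d guides per hit",
                s$fc_threshold, s$log2_threshold, s$min_guides_for_hit),
        sprintf("Positive regulators (loss depletes): %s",
                if (length(s$positive_regulators))
                    paste(unlist(s$positive_regulators), collapse = ", ")
                else "none"),
        sprintf("Negative regulators (loss enriches): %s",
                if (length(s$negative_regulators))
                    paste(unlist(s$negative_regulators), collapse = ", ")
                else "none"))
    if (!is.null(genes) && nrow(genes))
        txt <- c(txt, sprintf("Top of depletion ranking: %s",
                              paste(utils::head(genes$gene, 5),
                                    collapse = ", ")))
    writeLines(txt)
    invisible(list(text = txt, json = s))
}
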