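#' Extract the candidate spacer from a sequencing read
#'
#' Screen reads carry the 20-nt spacer immediately 3' of a constant vector
#' region; the default anchor \code{"GAAACACCG"} is the 3' end of the hU6
#' constant region of pLKO5-style sgRNA vectors. The spacer is the
#' \code{spacerLength}-mer immediately following the first anchor occurrence
#' whose start lies within \code{searchWindow}. All coordinates are 0-based,
#' half-open.
#'
#' @param reads character vector of read sequences (ACGTN alphabet).
#' @param anchor constant sequence expected immediately 5' of the spacer.
#' @param spacerLength spacer length (default 20).
#' @param searchWindow integer vector \code{c(start, end)}: 0-based
#'   half-open range of allowed anchor start positions, or \code{NULL}
#'   (default) for anywhere in the read.
#' @return character vector of extracted spacers, \code{NA} where no anchor
#'   was found in the window or too few bases follow it.
#' @export
#' @examples
#' extractSpacer(paste0("TTGAAACACCG", strrep("A", 20), "GTTT"))
extractSpacer <- function(reads, anchor = "GAAACACCG", spacerLength = 20L,
                          searchWindow = NULL) {
    stopifnot(.is_string(anchor), nchar(anchor) >= 1,
              .is_count1(spacerLength, min = 1))
    if (!is.null(searchWindow))
        stopifnot(length(searchWindow) == 2, searchWindow[1] >= 0,
                  searchWindow[2] >= searchWindow[1])
    vapply(reads, function(rd) {
        if (is.na(rd)) return(NA_character_)
        hits <- gregexpr(anchor, rd, fixed = TRUE)[[1]]
        if (hits[1] == -1L) return(NA_character_)
        starts0 <- hits - 1L  # 0-based anchor starts
        if (!is.null(searchWindow))
            starts0 <- starts0[starts0 >= searchWindow[1] &
                               starts0 < searchWindow[2]]
        # first anchor occurrence with a full spacer after it
        for (s0 in starts0) {
            from <- s0 + nchar(anchor) + 1L  # 1-based spacer start
            if (from + spacerLength - 1L <= nchar(rd))
                return(substr(rd, from, from + spacerLength - 1L))
        }
        NA_character_
    }, character(1), USE.NAMES = FALSE)
}

## assign candidate spacers to library guides; returns per-read guide index
## (NA = unassigned), with attribute "ambiguous" = logical per read
.assign_spacers <- function(cand, lib_spacers, maxMismatches = 0L) {
    idx <- match(cand, lib_spacers)
    ambiguous <- rep(FALSE, length(cand))
    if (maxMismatches >= 1L) {
        todo <- which(is.na(idx) & !is.na(cand) &
                      nchar(cand) == nchar(lib_spacers[1]))
        if (length(todo)) {
            libmat <- do.call(rbind, strsplit(lib_spacers, ""))
            uniq <- unique(cand[todo])
            umap <- lapply(uniq, function(sp) {
                chars <- strsplit(sp, "")[[1]]
                # N never matches: count it as a mismatch at every guide
                d <- rowSums(libmat != matrix(chars, nrow = nrow(libmat),
                                              ncol = ncol(libmat),
                                              byrow = TRUE))
                hit <- which(d <= 1L)
                if (length(hit) == 1L) hit else if (length(hit) > 1L) -1L
                else NA_integer_
            })
            names(umap) <- uniq
            res <- unlist(umap[cand[todo]], use.names = FALSE)
            amb <- !is.na(res) & res == -1L
            res[amb] <- NA_integer_
            idx[todo] <- res
            ambiguous[todo] <- amb
        }
    }
    attr(idx, "ambiguous") <- ambiguous
    idx
}

#' Count sgRNA reads into a guide-by-sample table
#'
#' Each read increments exactly one guide (exact spacer match after anchored
#' extraction; with \code{maxMismatches = 1}, a read whose spacer has no
#' exact match is assigned to a unique library guide at Hamming distance 1)
#' or the sample's unassigned tally. Reads whose spacer matches two or more
#' guides at distance 1 are counted as unassigned and tallied separately as
#' ambiguous. Per sample, assigned + unassigned = reads processed.
#'
#' @param reads per-sample read sources: either a named list of character
#'   vectors of read sequences (one element per sample), or a sample sheet
#'   \code{data.frame} with columns \code{sample_id}, \code{timepoint},
#'   \code{replicate}, \code{fastq_path}.
#' @param library an \code{\link{SgRNALibrary}}.
#' @param sampleInfo when \code{reads} is a list: a \code{data.frame} with
#'   columns \code{sample_id}, \code{timepoint} (\code{"T0"}/\code{"T12"})
#'   and \code{replicate}, one row per sample in order. Ignored when
#'   \code{reads} is a sample sheet.
#' @param anchor,spacerLength,searchWindow see \code{\link{extractSpacer}}.
#' @param maxMismatches 0 (exact only, default) or 1.
#' @param bothStrands also search the reverse complement of reads that have
#'   no anchor on the forward strand (default \code{FALSE}; amplicon
#'   primers fix read orientation in the assay this models).
#' @return a \code{\link{ScreenCounts}}.
#' @export
countReads <- function(reads, library, sampleInfo = NULL,
                       anchor = "GAAACACCG", spacerLength = 20L,
                       searchWindow = NULL, maxMismatches = 0L,
                       bothStrands = FALSE) {
    stopifnot(is(library, "SgRNALibrary"), maxMismatches %in% c(0L, 1L))
    if (is.data.frame(reads)) {
        sheet <- reads
        req <- c("sample_id", "timepoint", "replicate", "fastq_path")
        if (!all(req %in% colnames(sheet)))
            stop("sample sheet must have columns: ",
                 paste(req, collapse = ", "))
        missing <- sheet$fastq_path[!file.exists(sheet$fastq_path)]
        if (length(missing))
            stop("FASTQ file not found: ", paste(missing, collapse = ", "))
        reads <- lapply(sheet$fastq_path, function(p) readFastq(p)$seq)
        names(reads) <- sheet$sample_id
        sampleInfo <- sheet[, c("sample_id", "timepoint", "replicate")]
    }
    if (is.null(sampleInfo))
        stop("'sampleInfo' is required when 'reads' is a list")
    if (anyDuplicated(sampleInfo$sample_id))
        stop("sample labels must be unique")
    stopifnot(length(reads) == nrow(sampleInfo))

    lib_sp <- guideData(library)$spacer
    G <- length(library)
    counts <- matrix(0L, nrow = G, ncol = length(reads),
                     dimnames = list(guideIds(library),
                                     sampleInfo$sample_id))
    unassigned <- integer(length(reads))
    ambiguous <- integer(length(reads))
    totals <- integer(length(reads))
    for (j in seq_along(reads)) {
        rds <- reads[[j]]
        totals[j] <- length(rds)
        if (!length(rds)) next
        cand <- extractSpacer(rds, anchor = anchor,
                              spacerLength = spacerLength,
                              searchWindow = searchWindow)
        if (bothStrands) {
            miss <- is.na(cand)
            if (any(miss))
                cand[miss] <- extractSpacer(.revcomp(rds[miss]),
                                            anchor = anchor,
                                            spacerLength = spacerLength,
                                            searchWindow = searchWindow)
        }
        idx <- .assign_spacers(cand, lib_sp, maxMismatches)
        tab <- tabulate(idx, nbins = G)
        counts[, j] <- as.integer(tab)
        unassigned[j] <- sum(is.na(idx))
        ambiguous[j] <- sum(attr(idx, "ambiguous"))
    }
    ScreenCounts(counts, sampleInfo = sampleInfo, library = library,
                 totalReads = totals, unassigned = unassigned,
                 ambiguous = ambiguous)
}

#' Construct a ScreenCounts object
#'
#' @param counts integer matrix, guides x samples; rownames are guide ids.
#' @param sampleInfo \code{data.frame} with columns \code{sample_id},
#'   \code{timepoint}, \code{replicate}, one row per column of
#'   \code{counts}.
#' @param library optional \code{\link{SgRNALibrary}} supplying rowData
#'   (gene, role, spacer); row order must match.
#' @param totalReads,unassigned,ambiguous optional per-sample integer
#'   vectors; \code{totalReads} defaults to \code{colSums(counts) +
#'   unassigned}.
#' @return a \code{\link{ScreenCounts}}.
#' @rdname ScreenCounts-class
#' @export
ScreenCounts <- function(counts, sampleInfo, library = NULL,
                         totalReads = NULL, unassigned = NULL,
                         ambiguous = NULL) {
    counts <- as.matrix(counts)
    mode(counts) <- "integer"
    if (is.null(unassigned)) unassigned <- integer(ncol(counts))
    if (is.null(ambiguous)) ambiguous <- integer(ncol(counts))
    if (is.null(totalReads)) totalReads <- colSums(counts) + unassigned
    cd <- S4Vectors::DataFrame(
        sample_id = sampleInfo$sample_id,
        timepoint = sampleInfo$timepoint,
        replicate = as.character(sampleInfo$replicate),
        total_reads = as.integer(totalReads),
        unassigned = as.integer(unassigned),
        ambiguous = as.integer(ambiguous),
        row.names = sampleInfo$sample_id)
    rd <- NULL
    if (!is.null(library)) {
        if (!identical(rownames(counts), guideIds(library)))
            stop("count matrix rows must match the library's guide ids")
        rd <- guideData(library)[, c("gene", "role", "spacer")]
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd,
        rowData = rd)
    new("ScreenCounts", se)
}

#' @rdname ScreenCounts-class
#' @param x a \code{ScreenCounts}.
#' @export
unassignedReads <- function(x) {
    stopifnot(is(x, "ScreenCounts"))
    setNames(SummarizedExperiment::colData(x)$unassigned, colnames(x))
}

#' @rdname ScreenCounts-class
#' @export
ambiguousReads <- function(x) {
    stopifnot(is(x, "ScreenCounts"))
    setNames(SummarizedExperiment::colData(x)$ambiguous, colnames(x))
}

#' Write / read a count matrix as TSV
#'
#' Rows are guide ids, columns sample ids, with an \code{unassigned} footer
#' row holding each sample's unassigned read tally. \code{readCountsTsv}
#' reconstructs a \code{\link{ScreenCounts}} given the accompanying sample
#' sheet (or sample info) used to produce it.
#'
#' @param x a \code{\link{ScreenCounts}}.
#' @param file TSV path.
#' @return \code{writeCountsTsv}: the path, invisibly;
#'   \code{readCountsTsv}: a \code{\link{ScreenCounts}}.
#' @export
writeCountsTsv <- function(x, file) {
    stopifnot(is(x, "ScreenCounts"))
    m <- SummarizedExperiment::assay(x, "counts")
    df <- data.frame(guide_id = c(rownames(m), "unassigned"),
                     rbind(m, unassignedReads(x)),
                     check.names = FALSE, stringsAsFactors = FALSE)
    .write_tsv(df, file)
    invisible(file)
}

#' @rdname writeCountsTsv
#' @param sampleInfo \code{data.frame} with \code{sample_id},
#'   \code{timepoint}, \code{replicate} for the samples in the file.
#' @param library optional \code{\link{SgRNALibrary}} for rowData.
#' @export
readCountsTsv <- function(file, sampleInfo, library = NULL) {
    df <- .read_tsv(file)
    stopifnot(colnames(df)[1] == "guide_id")
    foot <- df$guide_id == "unassigned"
    m <- as.matrix(df[!foot, -1, drop = FALSE])
    rownames(m) <- df$guide_id[!foot]
    unass <- if (any(foot))
        as.integer(df[foot, -1, drop = FALSE][1, ]) else NULL
    sampleInfo <- sampleInfo[match(colnames(m), sampleInfo$sample_id), ,
                             drop = FALSE]
    ScreenCounts(m, sampleInfo = sampleInfo, library = library,
                 unassigned = unass)
}

#' @rdname ScreenCounts-class
#' @param object a \code{ScreenCounts}.
#' @export
setMethod("show", "ScreenCounts", function(object) {
    cd <- SummarizedExperiment::colData(object)
    cat(sprintf("ScreenCounts: %d guides x %d samples (%d T0, %d T12)\n",
                nrow(object), ncol(object), sum(cd$timepoint == "T0"),
                sum(cd$timepoint == "T12")))
    frac <- ifelse(cd$total_reads > 0,
                   1 - cd$unassigned / cd$total_reads, NA_real_)
    cat(sprintf("  assigned read fraction: %s\n",
                paste(sprintf("%s=%.3f", colnames(object), frac),
                      collapse = ", ")))
})
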