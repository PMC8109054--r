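#' SgRNALibrary: the guide pool of a pooled CRISPR screen
#'
#' An ordered collection of sgRNAs, each with a unique identifier, a target
#' gene symbol, a role (\code{"targeting"}, \code{"positive_control"} or
#' \code{"nontargeting"}) and a unique 20-nt spacer over the ACGT alphabet.
#' Nontargeting guides carry the gene label \code{"NTC"}. The library is the
#' reference universe for read counting and gene scoring.
#'
#' @slot name single character, name of the library.
#' @slot guides a \code{\link[S4Vectors]{DataFrame}} with columns
#'   \code{guide_id}, \code{gene}, \code{role}, \code{spacer}.
#'
#' @seealso \code{\link{buildLibrary}}, \code{\link{validateLibrary}},
#'   \code{\link{writeReferenceFasta}}
#' @export
setClass("SgRNALibrary",
    slots = c(name = "character", guides = "DataFrame"))

setValidity("SgRNALibrary", function(object) {
    rep <- validateLibrary(as.data.frame(object@guides))
    if (rep$valid) TRUE else paste(unlist(rep[c("duplicate_ids",
        "duplicate_spacers", "malformed")]), collapse = "; ")
})

#' ScreenCounts: guide-by-sample read counts of a pooled screen
#'
#' A \code{\link[SummarizedExperiment]{SummarizedExperiment}} holding the
#' nonnegative integer \code{counts} assay (guides x samples), guide
#' annotation (\code{gene}, \code{role}, \code{spacer}) in \code{rowData},
#' and sample annotation in \code{colData}: \code{timepoint} (\code{"T0"} or
#' \code{"T12"}), \code{replicate}, and per-sample read-accounting columns
#' \code{total_reads}, \code{unassigned} (reads not attributable to any
#' guide) and \code{ambiguous} (reads matching two or more guides within the
#' mismatch budget; a subset of \code{unassigned}). Per sample,
#' \code{sum(counts) + unassigned == total_reads}.
#'
#' @seealso \code{\link{countReads}}, \code{\link{normalizeCounts}}
#' @export
setClass("ScreenCounts", contains = "SummarizedExperiment")

setValidity("ScreenCounts", function(object) {
    msg <- character(0)
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        m <- SummarizedExperiment::assay(object, "counts")
        if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
            msg <- c(msg, "counts must be nonnegative integers")
    }
    cd <- SummarizedExperiment::colData(object)
    for (col in c("timepoint", "replicate"))
        if (!col %in% colnames(cd))
            msg <- c(msg, sprintf("colData column '%s' is required", col))
    if ("timepoint" %in% colnames(cd) &&
        !all(cd$timepoint %in% c("T0", "T12")))
        msg <- c(msg, "timepoint must be 'T0' or 'T12'")
    if (all(c("total_reads", "unassigned") %in% colnames(cd)) &&
        "counts" %in% SummarizedExperiment::assayNames(object)) {
        tot <- colSums(SummarizedExperiment::assay(object, "counts")) +
            cd$unassigned
        if (any(tot != cd$total_reads))
            msg <- c(msg, "sum(counts) + unassigned must equal total_reads")
    }
    if (length(msg)) msg else TRUE
})

#' Amplicon: a PCR amplicon around a CRISPR target site
#'
#' Holds the amplicon sequence, the 20-nt protospacer expected within it and
#' the strand on which the protospacer matches. The protospacer (or its
#' reverse complement) must occur exactly once in the amplicon, and the
#' amplicon must extend at least 10 bases beyond the spacer length, so that
#' a cut site strictly inside the amplicon can be predicted.
#'
#' @slot name single character.
#' @slot sequence single character, the amplicon sequence (ACGT).
#' @slot spacer single character, the 20-nt protospacer (as in the guide).
#' @slot strand \code{"+"} if the spacer matches the amplicon forward
#'   strand, \code{"-"} if only its reverse complement does.
#'
#' @seealso \code{\link{Amplicon}}, \code{\link{predictCutSite}},
#'   \code{\link{quantifyEditing}}
#' @export
setClass("Amplicon",
    slots = c(name = "character", sequence = "character",
              spacer = "character", strand = "character"))

setValidity("Amplicon", function(object) {
    msg <- character(0)
    if (!.valid_spacer(object@sequence, nchar(object@sequence)) ||
        nchar(object@sequence) < 1)
        msg <- c(msg, "sequence must be a nonempty ACGT string")
    if (!.valid_spacer(object@spacer, 20L))
        msg <- c(msg, "spacer must be a 20-nt ACGT string")
    if (nchar(object@sequence) < nchar(object@spacer) + 10L)
        msg <- c(msg, "amplicon must be at least spacer length + 10 long")
    if (!object@strand %in% c("+", "-"))
        msg <- c(msg, "strand must be '+' or '-'")
    nf <- .count_occurrences(object@sequence, object@spacer) +
        .count_occurrences(object@sequence, .revcomp(object@spacer))
    if (nf != 1L)
        msg <- c(msg, sprintf(
            "spacer (or its reverse complement) must occur exactly once in the amplicon (found %d)", nf))
    if (length(msg)) msg else TRUE
})

## fixed-string occurrence count (overlapping)
.count_occurrences <- function(seq, pat) {
    length(Biostrings::matchPattern(pat, Biostrings::DNAString(seq)))
}

#' SimulatedScreen: a synthetic pooled screen with ground truth
#'
#' Couples a \code{\link{ScreenCounts}} count table (one shared T0 sample
#' plus one T12 sample per simulated recipient mouse) with the per-guide
#' ground truth that generated it and an echo of the simulation
#' configuration.
#'
#' The truth \code{DataFrame} has one row per guide with columns
#' \code{guide_id}, \code{gene}, \code{role}, \code{gene_effect},
#' \code{guide_effect} (log2 growth multipliers over the assay applied to
#' knocked-out cells; 0 for the NTC), \code{plasmid_prop}, \code{t0_cells},
#' and matrix columns \code{engrafted} and \code{t12_expected} (one column
#' per mouse).
#'
#' @slot counts a \code{\link{ScreenCounts}}.
#' @slot truth a \code{\link[S4Vectors]{DataFrame}} as described above.
#' @slot config list echoing the \code{\link{simulateScreen}} arguments.
#'
#' @seealso \code{\link{simulateScreen}}, \code{\link{truthRecoveryReport}}
#' @export
setClass("SimulatedScreen",
    slots = c(counts = "ScreenCounts", truth = "DataFrame", config = "list"))

setValidity("SimulatedScreen", function(object) {
    msg <- character(0)
    if (nrow(object@truth) != nrow(object@counts))
        msg <- c(msg, "truth and counts must have one row per guide")
    if ("role" %in% colnames(object@truth) &&
        "guide_effect" %in% colnames(object@truth)) {
        ntc <- object@truth$role == "nontargeting"
        if (any(object@truth$guide_effect[ntc] != 0))
            msg <- c(msg, "nontargeting guides must have effect 0")
    }
    if (length(msg)) msg else TRUE
})
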