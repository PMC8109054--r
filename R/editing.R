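#' Construct an Amplicon
#'
#' @param name amplicon name.
#' @param sequence the amplicon sequence (ACGT), e.g. the PCR product
#'   around the target site.
#' @param spacer the 20-nt protospacer expected within the amplicon, given
#'   in guide orientation; the constructor locates it on either strand.
#' @return an \code{\link{Amplicon}}; the match strand is determined
#'   automatically (error if the spacer is absent or occurs more than
#'   once).
#' @rdname Amplicon-class
#' @export
Amplicon <- function(name, sequence, spacer) {
    stopifnot(.is_string(name), .is_string(sequence), .is_string(spacer))
    sequence <- toupper(sequence); spacer <- toupper(spacer)
    n_fwd <- .count_occurrences(sequence, spacer)
    n_rev <- .count_occurrences(sequence, .revcomp(spacer))
    if (n_fwd + n_rev == 0)
        stop(sprintf("spacer not found in amplicon '%s'", name))
    if (n_fwd + n_rev > 1)
        stop(sprintf("spacer occurs %d times in amplicon '%s'",
                     n_fwd + n_rev, name))
    new("Amplicon", name = name, sequence = sequence, spacer = spacer,
        strand = if (n_fwd == 1) "+" else "-")
}

#' @rdname Amplicon-class
#' @export
setMethod("show", "Amplicon", function(object) {
    cat(sprintf("Amplicon '%s': %d bp, protospacer on '%s' strand, cut site %d\n",
                object@name, nchar(object@sequence), object@strand,
                predictCutSite(object)))
})

#' Predict the Cas9 cut site of an amplicon
#'
#' SpCas9 makes a blunt cut 3 bp 5' of the PAM, i.e. between protospacer
#' positions 17 and 18. For a protospacer starting at 0-based amplicon
#' position s, the returned cut coordinate is \code{s + 17} on the forward
#' strand and \code{s + 3} when the protospacer matches the reverse strand
#' (the mirror-image position in forward coordinates). The coordinate is
#' 0-based and strictly inside the amplicon.
#'
#' @param x an \code{\link{Amplicon}}.
#' @return integer 0-based cut coordinate.
#' @rdname Amplicon-class
#' @export
setMethod("predictCutSite", "Amplicon", function(x) {
    pat <- if (x@strand == "+") x@spacer else .revcomp(x@spacer)
    hit <- Biostrings::matchPattern(pat, Biostrings::DNAString(x@sequence))
    s <- BiocGenerics::start(hit)[1] - 1L  # 0-based spacer start
    if (x@strand == "+") s + 17L else s + 3L
})

#' Globally align a read against an amplicon
#'
#' Needleman-Wunsch alignment under unit costs (match 0, mismatch 1, gap
#' 1), with deterministic tie-breaking (mismatch preferred over a gap,
#' deletion over insertion) and indels canonicalized to their leftmost
#' equivalent placement, so a deletion inside a homopolymer is always
#' reported at the run's left edge. Indel positions are 0-based amplicon
#' coordinates; a deletion of length L at position p removes reference
#' bases [p, p+L), an insertion at position p adds read bases immediately
#' before reference base p.
#'
#' @param read a read sequence (nonempty character).
#' @param amplicon an \code{\link{Amplicon}}.
#' @return a list: \code{edit_distance}, \code{indels} (data.frame
#'   \code{pos}, \code{length}, \code{type} in
#'   \code{c("insertion","deletion")}), \code{aligned_read},
#'   \code{aligned_ref}.
#' @export
alignRead <- function(read, amplicon) {
    stopifnot(is(amplicon, "Amplicon"), .is_string(read), nchar(read) > 0)
    res <- .nw_align_cpp(toupper(read), amplicon@sequence)
    indels <- data.frame(
        pos = as.integer(res$indel_pos),
        length = as.integer(res$indel_len),
        type = c("insertion", "deletion")[as.integer(res$indel_type)],
        stringsAsFactors = FALSE)
    list(edit_distance = res$edit_distance, indels = indels,
         aligned_read = res$aligned_read, aligned_ref = res$aligned_ref)
}

## does an indel's reference span intersect [cut - w, cut + w]?
## deletions span [pos, pos + length); an insertion is a zero-length event
## between bases pos-1 and pos and counts if it falls within or immediately
## after the window (an insertion exactly at the blunt cut has pos = cut+1)
.indel_in_window <- function(indels, cut, w) {
    if (!nrow(indels)) return(FALSE)
    del <- indels$type == "deletion"
    hit_del <- del & indels$pos <= cut + w &
        (indels$pos + indels$length - 1L) >= cut - w
    hit_ins <- !del & indels$pos >= cut - w & indels$pos <= cut + w + 1L
    any(hit_del | hit_ins)
}

#' Quantify CRISPR editing efficiency from amplicon reads
#'
#' Each read is globally aligned against the amplicon
#' (\code{\link{alignRead}}); reads whose edit distance exceeds
#' \code{maxEditDistanceFraction} of their length are discarded as
#' unalignable (chimeras/garbage). An aligned read is called \emph{edited}
#' iff it contains at least one indel whose reference span intersects the
#' window of \code{cutWindow} bases around the predicted cut site
#' (\code{\link{predictCutSite}}). The editing fraction is the read-level
#' statistic n_edited / n_aligned; substitution-only errors never produce
#' edited calls, and multiple indels in one read count the read once.
#'
#' @param reads character vector of read sequences, a data.frame from
#'   \code{\link{readFastq}}, or a path to a FASTQ(.gz) file.
#' @param amplicon an \code{\link{Amplicon}}.
#' @param cutWindow half-width in bases of the editing window around the
#'   cut site (default 3).
#' @param maxEditDistanceFraction discard reads with edit distance above
#'   this fraction of read length (default 0.3).
#' @return an object of class \code{"EditingResult"}: a list with
#'   \code{n_reads_total}, \code{n_reads_aligned}, \code{n_edited},
#'   \code{editing_fraction}, \code{indel_size_histogram} (data.frame
#'   \code{type}, \code{length}, \code{count} over cut-window indels of
#'   edited reads), and \code{per_read} (data.frame \code{aligned},
#'   \code{edited}, \code{edit_distance}).
#' @export
quantifyEditing <- function(reads, amplicon, cutWindow = 3L,
                            maxEditDistanceFraction = 0.3) {
    stopifnot(is(amplicon, "Amplicon"), .is_count1(cutWindow, min = 0),
              maxEditDistanceFraction >= 0)
    if (is.character(reads) && length(reads) == 1 && file.exists(reads))
        reads <- readFastq(reads)
    if (is.data.frame(reads)) reads <- reads$seq
    cut <- predictCutSite(amplicon)
    n_total <- length(reads)
    aligned <- logical(n_total); edited <- logical(n_total)
    dist <- integer(n_total)
    sizes <- list()
    for (i in seq_along(reads)) {
        al <- alignRead(reads[i], amplicon)
        dist[i] <- al$edit_distance
        if (al$edit_distance > maxEditDistanceFraction * nchar(reads[i]))
            next
        aligned[i] <- TRUE
        hit <- .indel_in_window(al$indels, cut, cutWindow)
        edited[i] <- hit
        if (hit) {
            keep <- vapply(seq_len(nrow(al$indels)), function(k)
                .indel_in_window(al$indels[k, , drop = FALSE], cut,
                                 cutWindow), logical(1))
            sizes[[length(sizes) + 1L]] <- al$indels[keep, c("type",
                                                             "length")]
        }
    }
    n_aligned <- sum(aligned)
    if (n_aligned == 0)
        stop("no reads aligned to the amplicon; editing fraction undefined")
    hist <- if (length(sizes)) {
        agg <- stats::aggregate(
            count ~ type + length,
            data = cbind(do.call(rbind, sizes), count = 1L), FUN = sum)
        agg[order(agg$type, agg$length), , drop = FALSE]
    } else data.frame(type = character(0), length = integer(0),
                      count = integer(0))
    rownames(hist) <- NULL
    structure(list(
        n_reads_total = n_total,
        n_reads_aligned = n_aligned,
        n_edited = sum(edited),
        editing_fraction = sum(edited) / n_aligned,
        indel_size_histogram = hist,
        per_read = data.frame(aligned = aligned, edited = edited,
                              edit_distance = dist)),
        class = "EditingResult")
}

#' @export
print.EditingResult <- function(x, ...) {
    cat(sprintf(
        "EditingResult: %d reads, %d aligned, %d edited (%.1f%% editing)\n",
        x$n_reads_total, x$n_reads_aligned, x$n_edited,
        100 * x$editing_fraction))
    invisible(x)
}
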