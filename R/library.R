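#' Construct an SgRNALibrary from a guide table
#'
#' Low-level constructor; most users will call \code{\link{buildLibrary}} or
#' \code{\link{readLibraryTsv}}. The table is validated against the library
#' invariants (unique guide ids, unique spacers, 20-nt ACGT spacers, NTC
#' gene label on nontargeting guides) and construction fails if any is
#' violated.
#'
#' @param guides a \code{data.frame} or \code{DataFrame} with columns
#'   \code{guide_id}, \code{gene}, \code{role}, \code{spacer}.
#' @param name single character, library name.
#' @return an \code{\link{SgRNALibrary}}.
#' @export
#' @examples
#' SgRNALibrary(data.frame(
#'     guide_id = "Gene1_sg1", gene = "Gene1", role = "targeting",
#'     spacer = "ACGTACGTACGTACGTACGT"))
SgRNALibrary <- function(guides, name = "sgRNA_library") {
    stopifnot(.is_string(name))
    guides <- as.data.frame(guides, stringsAsFactors = FALSE)
    req <- c("guide_id", "gene", "role", "spacer")
    if (!all(req %in% colnames(guides)))
        stop("guide table must have columns: ", paste(req, collapse = ", "))
    rep <- validateLibrary(guides)
    if (!rep$valid)
        stop("invalid sgRNA library: ",
             paste(unlist(rep[c("duplicate_ids", "duplicate_spacers",
                                "malformed")]), collapse = "; "))
    gd <- S4Vectors::DataFrame(guides[, req, drop = FALSE])
    rownames(gd) <- gd$guide_id
    new("SgRNALibrary", name = name, guides = gd)
}

#' Build an sgRNA library from a gene list
#'
#' Models the composition of a pooled screen library: \code{guidesPerGene}
#' guides per target gene (in input gene order), then guides for a
#' positive-control essential gene, then nontargeting control (NTC) guides.
#' The screen this package was designed around used 96 cell-surface genes
#' with 5 guides each, 5 guides against the essential gene \emph{Hoxa9} and
#' one NTC, i.e. 486 unique guides.
#'
#' Guide sequence design is out of scope here (screens use external design
#' tools); when \code{spacers} are not supplied, unique random 20-mers are
#' generated deterministically from \code{seed} as placeholders, so the
#' whole pipeline can run on synthetic data.
#'
#' @param genes character vector of unique gene symbols.
#' @param guidesPerGene number of guides per gene (default 5).
#' @param positiveControlGene symbol of the positive-control gene, or
#'   \code{NULL} for none (default \code{"Hoxa9"}).
#' @param nPositiveControl number of positive-control guides (default 5).
#' @param nNontargeting number of nontargeting guides (default 1); these get
#'   gene label \code{"NTC"}.
#' @param spacers optional explicit character vector of unique 20-nt spacers,
#'   one per guide, in library order.
#' @param seed integer seed for placeholder spacer generation.
#' @param name library name.
#' @return an \code{\link{SgRNALibrary}} of
#'   \code{length(genes) * guidesPerGene + nPositiveControl + nNontargeting}
#'   guides, in deterministic order: genes in input order, then
#'   positive-control guides, then NTC guides.
#' @export
#' @examples
#' lib <- buildLibrary(sprintf("Gene%02d", 1:10), guidesPerGene = 5,
#'                     nPositiveControl = 5, nNontargeting = 1, seed = 1)
#' length(lib)  # 56
buildLibrary <- function(genes, guidesPerGene = 5,
                         positiveControlGene = "Hoxa9",
                         nPositiveControl = 5, nNontargeting = 1,
                         spacers = NULL, seed = 1,
                         name = "sgRNA_library") {
    if (length(genes) < 1 || anyNA(genes))
        stop("'genes' must be a non-empty character vector")
    if (anyDuplicated(genes))
        stop("duplicate gene names: ",
             paste(unique(genes[duplicated(genes)]), collapse = ", "))
    stopifnot(.is_count1(guidesPerGene, min = 0),
              .is_count1(nPositiveControl, min = 0),
              .is_count1(nNontargeting, min = 0))
    if (is.null(positiveControlGene)) nPositiveControl <- 0

    gene_col <- rep(genes, each = guidesPerGene)
    role_col <- rep("targeting", length(gene_col))
    id_col <- if (length(gene_col))
        paste0(gene_col, "_sg",
               rep(seq_len(guidesPerGene), times = length(genes)))
    else character(0)
    if (nPositiveControl > 0) {
        gene_col <- c(gene_col, rep(positiveControlGene, nPositiveControl))
        role_col <- c(role_col, rep("positive_control", nPositiveControl))
        id_col <- c(id_col, paste0(positiveControlGene, "_pc",
                                   seq_len(nPositiveControl)))
    }
    if (nNontargeting > 0) {
        gene_col <- c(gene_col, rep("NTC", nNontargeting))
        role_col <- c(role_col, rep("nontargeting", nNontargeting))
        id_col <- c(id_col, paste0("NTC_sg", seq_len(nNontargeting)))
    }
    n <- length(id_col)
    if (is.null(spacers)) {
        spacers <- local({
            old <- if (exists(".Random.seed", globalenv()))
                get(".Random.seed", globalenv()) else NULL
            on.exit(if (!is.null(old))
                assign(".Random.seed", old, globalenv()))
            set.seed(seed)
            .random_spacers(n)
        })
    } else {
        if (length(spacers) != n)
            stop(sprintf("%d spacers supplied for %d guides",
                         length(spacers), n))
        if (anyDuplicated(spacers)) stop("supplied spacers are not unique")
        if (!all(.valid_spacer(spacers)))
            stop("supplied spacers must be 20-nt ACGT strings")
    }
    SgRNALibrary(data.frame(guide_id = id_col, gene = gene_col,
                            role = role_col, spacer = spacers,
                            stringsAsFactors = FALSE), name = name)
}

#' Validate a guide table against the library invariants
#'
#' Reports, never raises: returns lists of duplicate spacers, duplicate
#' guide ids and malformed entries (bad spacer length/alphabet, illegal
#' role, nontargeting guides not labeled NTC). The report is empty (and
#' \code{valid} is \code{TRUE}) iff the table satisfies all invariants.
#' Optionally flags spacer pairs within Hamming distance 1 of each other
#' (\code{crossMatch}) — near-identical spacers can cause multi-locus
#' cutting and ambiguous read assignment; off by default.
#'
#' @param x an \code{\link{SgRNALibrary}} or a guide \code{data.frame} with
#'   columns \code{guide_id}, \code{gene}, \code{role}, \code{spacer}.
#' @param crossMatch logical; also report spacer pairs at Hamming
#'   distance <= 1 (default \code{FALSE}).
#' @return a list with character vectors \code{duplicate_ids},
#'   \code{duplicate_spacers}, \code{malformed}, \code{cross_matches}, and
#'   a logical \code{valid}.
#' @export
validateLibrary <- function(x, crossMatch = FALSE) {
    df <- if (is(x, "SgRNALibrary")) as.data.frame(x@guides) else
        as.data.frame(x, stringsAsFactors = FALSE)
    dup_ids <- character(0); dup_sp <- character(0); mal <- character(0)
    if (anyDuplicated(df$guide_id)) {
        bad <- unique(df$guide_id[duplicated(df$guide_id)])
        dup_ids <- sprintf("duplicate guide_id '%s'", bad)
    }
    if (anyDuplicated(df$spacer)) {
        for (sp in unique(df$spacer[duplicated(df$spacer)]))
            dup_sp <- c(dup_sp, sprintf(
                "spacer '%s' shared by guides: %s", sp,
                paste(df$guide_id[df$spacer == sp], collapse = ", ")))
    }
    ok_sp <- .valid_spacer(df$spacer)
    if (any(!ok_sp))
        mal <- c(mal, sprintf("guide '%s': spacer is not a 20-nt ACGT string",
                              df$guide_id[!ok_sp]))
    ok_role <- df$role %in% c("targeting", "positive_control", "nontargeting")
    if (any(!ok_role))
        mal <- c(mal, sprintf("guide '%s': unknown role '%s'",
                              df$guide_id[!ok_role], df$role[!ok_role]))
    ntc_bad <- df$role == "nontargeting" & df$gene != "NTC"
    if (any(ntc_bad, na.rm = TRUE))
        mal <- c(mal, sprintf(
            "guide '%s': nontargeting guides must have gene label 'NTC'",
            df$guide_id[ntc_bad]))
    cross <- character(0)
    if (crossMatch && nrow(df) > 1 && all(ok_sp)) {
        mat <- do.call(rbind, strsplit(df$spacer, ""))
        for (i in seq_len(nrow(df) - 1)) {
            d <- rowSums(mat[-seq_len(i), , drop = FALSE] !=
                         matrix(mat[i, ], nrow = nrow(df) - i,
                                ncol = ncol(mat), byrow = TRUE))
            hit <- which(d <= 1)
            if (length(hit))
                cross <- c(cross, sprintf(
                    "guides '%s' and '%s' within Hamming distance 1",
                    df$guide_id[i], df$guide_id[i + hit]))
        }
    }
    list(duplicate_ids = dup_ids, duplicate_spacers = dup_sp,
         malformed = mal, cross_matches = cross,
         valid = !length(dup_ids) && !length(dup_sp) && !length(mal))
}

#' Write the library reference as multi-FASTA
#'
#' One record per guide, header = guide id, sequence = spacer. Reading the
#' file back (\code{readDNAStringSet}) reconstructs the library's id-to-
#' spacer map exactly. An empty library yields an empty FASTA.
#'
#' @param library an \code{\link{SgRNALibrary}}.
#' @param file destination path.
#' @return the path, invisibly.
#' @export
writeReferenceFasta <- function(library, file) {
    stopifnot(is(library, "SgRNALibrary"))
    Biostrings::writeXStringSet(spacers(library), filepath = file)
    invisible(file)
}

#' Read / write a library table as TSV
#'
#' Tab-delimited with header \code{guide_id}, \code{gene}, \code{role},
#' \code{spacer}.
#'
#' @param file path to a TSV file.
#' @param name library name for the object read.
#' @return \code{readLibraryTsv}: an \code{\link{SgRNALibrary}}.
#' @export
readLibraryTsv <- function(file, name = basename(file)) {
    SgRNALibrary(.read_tsv(file), name = name)
}

#' @rdname readLibraryTsv
#' @param library an \code{\link{SgRNALibrary}}.
#' @export
writeLibraryTsv <- function(library, file) {
    stopifnot(is(library, "SgRNALibrary"))
    .write_tsv(as.data.frame(library@guides), file)
    invisible(file)
}

## ---- accessors ----

#' @rdname SgRNALibrary-class
#' @export
setMethod("guideIds", "SgRNALibrary", function(x) x@guides$guide_id)

#' @rdname SgRNALibrary-class
#' @export
setMethod("spacers", "SgRNALibrary", function(x) {
    Biostrings::DNAStringSet(setNames(x@guides$spacer, x@guides$guide_id))
})

#' @rdname SgRNALibrary-class
#' @export
setMethod("guideData", "SgRNALibrary", function(x) x@guides)

#' @rdname SgRNALibrary-class
#' @export
setMethod("libraryName", "SgRNALibrary", function(x) x@name)

#' @rdname SgRNALibrary-class
#' @export
setMethod("length", "SgRNALibrary", function(x) nrow(x@guides))

#' @rdname SgRNALibrary-class
#' @export
setMethod("show", "SgRNALibrary", function(object) {
    tab <- table(object@guides$role)
    cat(sprintf("SgRNALibrary '%s': %d guides (%d genes)\n",
                object@name, nrow(object@guides),
                length(unique(object@guides$gene[
                    object@guides$role != "nontargeting"]))))
    cat("  roles:", paste(sprintf("%s=%d", names(tab), tab),
                          collapse = ", "), "\n")
})

#' @rdname SgRNALibrary-class
#' @param row.names,optional,... passed on to the data.frame method.
#' @export
as.data.frame.SgRNALibrary <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
    as.data.frame(x@guides, row.names = row.names, optional = optional, ...)
}
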