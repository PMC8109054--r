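#' Read a FASTQ file (plain or gzipped)
#'
#' Streams 4-line FASTQ records into a data.frame of id, sequence and
#' quality strings, in file order. Truncated or malformed records raise an
#' error naming the offending record and line.
#'
#' @param file path to a \code{.fastq} or \code{.fastq.gz} file.
#' @return a data.frame with columns \code{id}, \code{seq}, \code{qual};
#'   one row per read.
#' @export
readFastq <- function(file) {
    if (!file.exists(file)) stop("FASTQ file not found: ", file)
    con <- gzfile(file, open = "rt")
    on.exit(close(con))
    lines <- readLines(con, warn = FALSE)
    n <- length(lines)
    if (n %% 4L != 0L)
        stop(sprintf(
            "truncated FASTQ record %d in '%s' (file has %d lines, not a multiple of 4)",
            n %/% 4L + 1L, file, n))
    if (n == 0L)
        return(data.frame(id = character(0), seq = character(0),
                          qual = character(0), stringsAsFactors = FALSE))
    hdr <- lines[seq(1L, n, by = 4L)]
    sq <- lines[seq(2L, n, by = 4L)]
    plus <- lines[seq(3L, n, by = 4L)]
    ql <- lines[seq(4L, n, by = 4L)]
    bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
    if (length(bad))
        stop(sprintf("malformed FASTQ record %d in '%s' (line %d)",
                     bad[1], file, (bad[1] - 1L) * 4L + 1L))
    bad <- which(nchar(sq) != nchar(ql))
    if (length(bad))
        stop(sprintf(
            "FASTQ record %d in '%s': sequence and quality lengths differ",
            bad[1], file))
    data.frame(id = sub("^@", "", hdr), seq = sq, qual = ql,
               stringsAsFactors = FALSE)
}

#' Write reads as FASTQ
#'
#' @param reads a data.frame with columns \code{id}, \code{seq} and
#'   optionally \code{qual} (a constant Phred-40 'I' string is used when
#'   absent), or a named character vector of sequences.
#' @param file destination path; a \code{.gz} suffix triggers gzip
#'   compression.
#' @return the path, invisibly.
#' @export
writeFastq <- function(reads, file) {
    if (is.character(reads))
        reads <- data.frame(id = names(reads) %||%
                                paste0("read", seq_along(reads)),
                            seq = unname(reads), stringsAsFactors = FALSE)
    if (is.null(reads$qual))
        reads$qual <- strrep("I", nchar(reads$seq))
    con <- if (grepl("\\.gz$", file)) gzfile(file, "wt") else
        file(file, "wt")
    on.exit(close(con))
    if (nrow(reads))
        writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n",
                          reads$qual), con)
    invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
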