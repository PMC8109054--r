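## internal helpers shared across modules

DNA_BASES <- c("A", "C", "G", "T")

.is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

.is_count1 <- function(x, min = 0) {
    is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min &&
        x == as.integer(round(x))
}

.revcomp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## spacer / sequence sanity: ACGT only, fixed length
.valid_spacer <- function(x, len = 20L) {
    !is.na(x) & nchar(x) == len & grepl("^[ACGT]+$", x)
}

.read_tsv <- function(path) {
    utils::read.delim(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE)
}

.write_tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
}

## Dirichlet-multinomial draw: n trials over proportions p with per-category
## concentration alpha_i = p_i * length(p) * dispersion. dispersion = Inf
## degenerates to a plain multinomial.
.rdirmnom <- function(n, p, dispersion) {
    stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-8)
    if (is.infinite(dispersion)) {
        return(as.integer(stats::rmultinom(1L, n, p)))
    }
    alpha <- p * length(p) * dispersion
    g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
    g[alpha == 0] <- 0
    if (sum(g) == 0) g <- p  # pathological all-zero gamma draw
    as.integer(stats::rmultinom(1L, n, g / sum(g)))
}

## deterministic random spacers: unique 20-mers, collisions redrawn
.random_spacers <- function(n, len = 20L) {
    out <- character(0)
    while (length(out) < n) {
        need <- n - length(out)
        draw <- vapply(seq_len(need), function(i) {
            paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
        }, character(1))
        out <- unique(c(out, draw))
    }
    out[seq_len(n)]
}

.stop_stage <- function(stage, msg) {
    stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
}
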