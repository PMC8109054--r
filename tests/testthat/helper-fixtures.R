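## shared fixtures, built in code at test time

random_dna <- function(n, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## the screen-scale library: 96 genes x 5 + 5 positive-control + 1 NTC
screen_library <- function(seed = 42) {
    buildLibrary(sprintf("Gene%02d", 1:96), guidesPerGene = 5,
                 positiveControlGene = "Hoxa9", nPositiveControl = 5,
                 nNontargeting = 1, seed = seed)
}

tiny_library <- function(nGenes = 3, guidesPerGene = 2, seed = 1) {
    buildLibrary(paste0("G", seq_len(nGenes)),
                 guidesPerGene = guidesPerGene,
                 positiveControlGene = NULL, nPositiveControl = 0,
                 nNontargeting = 1, seed = seed)
}

## a 200-bp amplicon with the protospacer starting at 0-based position 90
test_amplicon <- function(seed = 5, strand = "+") {
    set.seed(seed)
    spacer <- random_dna(20)
    left <- random_dna(90)
    right <- random_dna(90)
    embedded <- if (strand == "+") spacer else
        as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(spacer)))
    Amplicon("test_amp", paste0(left, embedded, right), spacer)
}

## reads carrying a spacer behind the default vector anchor
anchored_read <- function(spacer, prefix = "TT", anchor = "GAAACACCG",
                          suffix = "GTTTTAG") {
    paste0(prefix, anchor, spacer, suffix)
}

## independent brute-force counter: exact substring scan, no shared code
## with countReads beyond the library table
oracle_count <- function(reads, lib_df, anchor = "GAAACACCG") {
    counts <- setNames(integer(nrow(lib_df)), lib_df$guide_id)
    unassigned <- 0L
    for (rd in reads) {
        hit <- NA_character_
        pos <- regexpr(anchor, rd, fixed = TRUE)
        if (pos > 0) {
            sp <- substr(rd, pos + nchar(anchor), pos + nchar(anchor) + 19L)
            if (nchar(sp) == 20L) {
                k <- which(lib_df$spacer == sp)
                if (length(k) == 1) hit <- lib_df$guide_id[k]
            }
        }
        if (is.na(hit)) unassigned <- unassigned + 1L
        else counts[hit] <- counts[hit] + 1L
    }
    list(counts = counts, unassigned = unassigned)
}

## independent gene scorer: literal threshold counting per gene
oracle_score <- function(medians, fcThreshold = 2, minGuides = 2) {
    targ <- medians[medians$role != "nontargeting", ]
    out <- lapply(split(targ, targ$gene), function(gi) {
        nd <- sum(gi$median_fc <= 1 / fcThreshold)
        ne <- sum(gi$median_fc >= fcThreshold)
        cls <- "none"
        if (nd >= minGuides && nd > ne) cls <- "positive_regulator"
        if (ne >= minGuides && ne > nd) cls <- "negative_regulator"
        data.frame(gene = gi$gene[1], n_depleted = nd, n_enriched = ne,
                   classification = cls, stringsAsFactors = FALSE)
    })
    do.call(rbind, unname(out))
}
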