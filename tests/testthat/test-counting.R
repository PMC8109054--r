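test_that("readFastq parses records in order, plain and gzipped", {
    fq <- tempfile(fileext = ".fastq")
    writeLines(c("@r1", "ACGT", "+", "IIII",
                 "@r2", "TTTT", "+", "JJJJ"), fq)
    out <- readFastq(fq)
    expect_identical(out$id, c("r1", "r2"))
    expect_identical(out$seq, c("ACGT", "TTTT"))
    expect_identical(out$qual, c("IIII", "JJJJ"))

    fqgz <- tempfile(fileext = ".fastq.gz")
    con <- gzfile(fqgz, "wt")
    writeLines(readLines(fq), con); close(con)
    expect_identical(readFastq(fqgz), out)
})

test_that("truncated FASTQ raises an error naming the record", {
    fq <- tempfile(fileext = ".fastq")
    writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "TTTT", "+"), fq)
    expect_error(readFastq(fq), "record 2")
})

test_that("writeFastq / readFastq round trip", {
    df <- data.frame(id = c("a", "b"), seq = c("ACGTA", "GG"),
                     qual = c("IIIII", "II"), stringsAsFactors = FALSE)
    fq <- tempfile(fileext = ".fastq.gz")
    writeFastq(df, fq)
    expect_identical(readFastq(fq), df)
})

test_that("extractSpacer returns the 20-mer after the first in-window anchor", {
    sp <- strrep("ACGT", 5)
    expect_identical(extractSpacer(anchored_read(sp)), sp)
    ## read lacking the anchor
    expect_identical(extractSpacer("ACGTACGTACGTACGT"), NA_character_)
    ## anchor found but too few bases after it
    expect_identical(extractSpacer(paste0("GAAACACCG", strrep("A", 10))),
                     NA_character_)
    ## anchor at window edge with exactly spacerLength bases remaining:
    ## read = 2 pad + 9 anchor + 20 spacer; anchor start (0-based) is 2,
    ## allowed by the half-open window [0, 3)
    rd <- paste0("TT", "GAAACACCG", sp)
    expect_identical(extractSpacer(rd, searchWindow = c(0, 3)), sp)
    ## ... and excluded by [0, 2)
    expect_identical(extractSpacer(rd, searchWindow = c(0, 2)),
                     NA_character_)
})

test_that("extractSpacer agrees with a brute-force substring scan", {
    set.seed(31)
    anchor <- "GAAACACCG"
    oracle <- function(rd, win) {
        for (s0 in 0:(nchar(rd) - 1)) {
            if (!is.null(win) && (s0 < win[1] || s0 >= win[2])) next
            if (substr(rd, s0 + 1, s0 + nchar(anchor)) == anchor &&
                s0 + nchar(anchor) + 20 <= nchar(rd))
                return(substr(rd, s0 + nchar(anchor) + 1,
                              s0 + nchar(anchor) + 20))
        }
        NA_character_
    }
    for (i in 1:40) {
        rd <- random_dna(sample(20:60, 1))
        if (runif(1) < 0.5)  # plant an anchor at a random position
            rd <- paste0(substr(rd, 1, sample(0:10, 1)), anchor, rd)
        win <- if (runif(1) < 0.5) NULL else c(0, sample(1:20, 1))
        expect_identical(
            extractSpacer(rd, searchWindow = win),
            oracle(rd, win))
    }
})

test_that("countReads assigns constructed reads and conserves totals", {
    lib <- tiny_library(nGenes = 2, guidesPerGene = 1)  # 2 guides + NTC
    spA <- guideData(lib)$spacer[1]
    reads <- list(s1 = c(anchored_read(spA), anchored_read(spA),
                         "GGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGG"))
    si <- data.frame(sample_id = "s1", timepoint = "T0",
                     replicate = NA_character_)
    sc <- countReads(reads, lib, sampleInfo = si)
    m <- SummarizedExperiment::assay(sc, "counts")
    expect_identical(m[guideIds(lib)[1], "s1"], 2L)
    expect_identical(sum(m), 2L)
    expect_identical(unname(unassignedReads(sc)), 1L)
    ## conservation: assigned + unassigned = reads processed
    cd <- SummarizedExperiment::colData(sc)
    expect_identical(unname(colSums(m) + cd$unassigned),
                     unname(as.double(cd$total_reads)))
})

test_that("empty read stream yields an all-zero column", {
    lib <- tiny_library()
    sc <- countReads(list(empty = character(0)), lib,
                     sampleInfo = data.frame(sample_id = "empty",
                                             timepoint = "T0",
                                             replicate = NA))
    expect_true(all(SummarizedExperiment::assay(sc, "counts") == 0))
    expect_identical(unname(unassignedReads(sc)), 0L)
})

test_that("Hamming-1 matching assigns unique neighbors, drops ambiguous", {
    spacers <- c(strrep("A", 20), strrep("C", 20),
                 paste0(strrep("G", 10), strrep("T", 10)))
    lib <- buildLibrary(c("X", "Y", "Z"), guidesPerGene = 1,
                        positiveControlGene = NULL, nNontargeting = 0,
                        spacers = spacers)
    one_off <- paste0("C", strrep("A", 19))  # distance 1 from X only
    si <- data.frame(sample_id = "s", timepoint = "T0", replicate = NA)

    sc0 <- countReads(list(s = anchored_read(one_off)), lib,
                      sampleInfo = si, maxMismatches = 0)
    expect_identical(unname(unassignedReads(sc0)), 1L)

    sc1 <- countReads(list(s = anchored_read(one_off)), lib,
                      sampleInfo = si, maxMismatches = 1)
    m <- SummarizedExperiment::assay(sc1, "counts")
    expect_identical(m["X_sg1", "s"], 1L)
    expect_identical(unname(ambiguousReads(sc1)), 0L)

    ## a library with two guides at distance 2; a read between them is
    ## at distance 1 from both -> ambiguous, counted unassigned
    sp_amb <- c(strrep("A", 20), paste0("CC", strrep("A", 18)))
    lib2 <- buildLibrary(c("P", "Q"), guidesPerGene = 1,
                         positiveControlGene = NULL, nNontargeting = 0,
                         spacers = sp_amb)
    between <- paste0("C", strrep("A", 19))
    sc2 <- countReads(list(s = anchored_read(between)), lib2,
                      sampleInfo = si, maxMismatches = 1)
    expect_true(all(SummarizedExperiment::assay(sc2, "counts") == 0))
    expect_identical(unname(unassignedReads(sc2)), 1L)
    expect_identical(unname(ambiguousReads(sc2)), 1L)
})

test_that("counting is order-independent and matches the brute-force oracle", {
    set.seed(17)
    lib <- tiny_library(nGenes = 5, guidesPerGene = 2)  # 11 guides
    gd <- as.data.frame(guideData(lib))
    for (rep_i in 1:5) {
        reads <- c(
            vapply(sample(gd$spacer, 30, replace = TRUE), anchored_read,
                   character(1), USE.NAMES = FALSE),
            replicate(10, random_dna(40)))
        si <- data.frame(sample_id = "s", timepoint = "T0",
                         replicate = NA)
        sc <- countReads(list(s = reads), lib, sampleInfo = si)
        orc <- oracle_count(reads, gd)
        m <- SummarizedExperiment::assay(sc, "counts")[, 1]
        expect_identical(m, orc$counts)
        expect_identical(unname(unassignedReads(sc)), orc$unassigned)

        ## permuting reads leaves the table unchanged
        sc_perm <- countReads(list(s = sample(reads)), lib,
                              sampleInfo = si)
        expect_identical(SummarizedExperiment::assay(sc_perm, "counts"),
                         SummarizedExperiment::assay(sc, "counts"))
    }
})

test_that("reverse-complement reads count only with bothStrands", {
    lib <- tiny_library(nGenes = 2, guidesPerGene = 1)
    sp <- guideData(lib)$spacer[1]
    rc_read <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(anchored_read(sp))))
    si <- data.frame(sample_id = "s", timepoint = "T0", replicate = NA)
    sc_fwd <- countReads(list(s = rc_read), lib, sampleInfo = si)
    expect_identical(unname(unassignedReads(sc_fwd)), 1L)
    sc_both <- countReads(list(s = rc_read), lib, sampleInfo = si,
                          bothStrands = TRUE)
    expect_identical(
        SummarizedExperiment::assay(sc_both, "counts")[1, 1], 1L)
})

test_that("counts TSV round trip with unassigned footer", {
    lib <- tiny_library()
    si <- data.frame(sample_id = c("a", "b"), timepoint = c("T0", "T12"),
                     replicate = c(NA, "m1"))
    m <- matrix(c(5L, 0L, 2L, 1L, 3L, 4L, 9L, 2L, 0L, 1L, 1L, 0L, 7L, 2L),
                nrow = 7)[seq_len(length(lib)), , drop = FALSE]
    dimnames(m) <- list(guideIds(lib), si$sample_id)
    sc <- ScreenCounts(m, sampleInfo = si, library = lib,
                       unassigned = c(3L, 1L))
    tsv <- tempfile(fileext = ".tsv")
    writeCountsTsv(sc, tsv)
    back <- readCountsTsv(tsv, sampleInfo = si, library = lib)
    expect_identical(SummarizedExperiment::assay(back, "counts"),
                     SummarizedExperiment::assay(sc, "counts"))
    expect_identical(unassignedReads(back), unassignedReads(sc))
})
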