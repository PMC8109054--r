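test_that("normalizeCounts scales to reads per million", {
    m <- matrix(c(1, 1, 3, 1), nrow = 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
    rep0 <- normalizeCounts(m, pseudocount = 0)
    expect_equal(rep0[, "s1"], c(g1 = 5e5, g2 = 5e5))
    expect_equal(rep0[, "s2"], c(g1 = 7.5e5, g2 = 2.5e5))
    expect_equal(unname(colSums(rep0)), c(1e6, 1e6))

    ## pseudocount keeps zero counts strictly positive
    m2 <- matrix(c(0, 10), nrow = 2)
    expect_true(all(normalizeCounts(m2, pseudocount = 1) > 0))

    ## all-zero sample with pseudocount 0 errors, naming the sample
    m3 <- matrix(c(1, 2, 0, 0), nrow = 2,
                 dimnames = list(NULL, c("ok", "empty")))
    expect_error(normalizeCounts(m3, pseudocount = 0), "empty")
})

test_that("representation is scale invariant at pseudocount 0", {
    set.seed(4)
    m <- matrix(rpois(20, 50) + 1, nrow = 5,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
    r1 <- normalizeCounts(m, pseudocount = 0)
    m_scaled <- m
    m_scaled[, 2] <- m[, 2] * 17
    r2 <- normalizeCounts(m_scaled, pseudocount = 0)
    expect_equal(r1, r2)
})

test_that("foldChange divides T12 by T0 with a shared T0 pool", {
    rep <- matrix(c(100, 100, 50, 300, 100, 100), nrow = 2,
                  dimnames = list(c("g1", "g2"),
                                  c("T0", "T12_m1", "T12_m2")))
    si <- data.frame(sample_id = colnames(rep),
                     timepoint = c("T0", "T12", "T12"),
                     replicate = c(NA, "m1", "m2"))
    fc <- foldChange(rep, si)
    expect_equal(fc["g1", "m1"], 0.5)
    expect_equal(fc["g2", "m1"], 3.0)
    expect_equal(unname(fc[, "m2"]), c(1.0, 1.0))

    ## identical T12 and T0 columns give fc = 1 everywhere
    rep_id <- cbind(rep[, 1, drop = FALSE], T12_m1 = rep[, 1])
    si_id <- data.frame(sample_id = colnames(rep_id),
                        timepoint = c("T0", "T12"), replicate = c(NA, "m1"))
    expect_true(all(foldChange(rep_id, si_id) == 1))

    ## missing sample in an explicit pairing errors
    expect_error(
        foldChange(rep, si, pairing = data.frame(
            replicate = "m1", t12 = "T12_m1", t0 = "T0_missing")),
        "T0_missing")
})

test_that("per-replicate T0 samples pair by replicate label", {
    rep <- matrix(c(100, 200, 50, 100), nrow = 1,
                  dimnames = list("g", c("T0_m1", "T0_m2", "T12_m1",
                                         "T12_m2")))
    si <- data.frame(sample_id = colnames(rep),
                     timepoint = c("T0", "T0", "T12", "T12"),
                     replicate = c("m1", "m2", "m1", "m2"))
    fc <- foldChange(rep, si)
    expect_equal(unname(fc["g", ]), c(0.5, 0.5))
})

test_that("medianFoldChange takes the classical sample median, log2 after", {
    fc <- matrix(c(0.25, 0.5, 1.0), nrow = 1,
                 dimnames = list("g", c("m1", "m2", "m3")))
    out <- medianFoldChange(fc)
    expect_equal(out$median_fc, 0.5)
    expect_equal(out$log2_median_fc, -1)

    ## single replicate: the median is the value itself
    out1 <- medianFoldChange(fc[, 1, drop = FALSE])
    expect_equal(out1$median_fc, 0.25)

    ## even replicate count: midpoint of the central pair
    out2 <- medianFoldChange(matrix(c(0.5, 2.0), nrow = 1,
                                    dimnames = list("g", c("m1", "m2"))))
    expect_equal(out2$median_fc, 1.25)

    ## log2 column is exactly log2 of the median column
    set.seed(8)
    fc_r <- matrix(exp(rnorm(50)), nrow = 10,
                   dimnames = list(paste0("g", 1:10), paste0("m", 1:5)))
    out_r <- medianFoldChange(fc_r)
    expect_identical(out_r$log2_median_fc, log2(out_r$median_fc))
})

test_that("scoreGenes counts guides past threshold and classifies hits", {
    mk <- function(gene, med) data.frame(
        guide_id = paste0(gene, "_", seq_along(med)), gene = gene,
        role = "targeting", median_fc = med, log2_median_fc = log2(med),
        stringsAsFactors = FALSE)
    ## all five guides depleted at least 2-fold -> 5/5, positive regulator
    ## (the essential-control behavior)
    med <- rbind(mk("Ess", c(0.5, 0.4, 0.3, 0.2, 0.1)),
                 mk("Null", rep(1.0, 5)))
    sc <- scoreGenes(med)
    ess <- sc$geneScores[sc$geneScores$gene == "Ess", ]
    expect_identical(ess$n_depleted, 5L)
    expect_identical(ess$classification, "positive_regulator")
    nul <- sc$geneScores[sc$geneScores$gene == "Null", ]
    expect_identical(nul$n_depleted + nul$n_enriched, 0L)
    expect_identical(nul$classification, "none")

    ## guide log2 medians {-2.1, -0.5, -0.2, +0.1, -3.0}: exactly the two
    ## guides beyond |log2| >= 1 count as depleted
    med2 <- mk("Two", 2^c(-2.1, -0.5, -0.2, 0.1, -3.0))
    sc2 <- scoreGenes(med2)
    expect_identical(sc2$geneScores$n_depleted, 2L)
    expect_identical(sc2$geneScores$classification, "positive_regulator")
})

test_that("scoreGenes matches a brute-force threshold-count oracle", {
    set.seed(23)
    for (i in 1:10) {
        ngene <- sample(3:8, 1)
        med <- do.call(rbind, lapply(seq_len(ngene), function(g) {
            n <- sample(2:6, 1)
            fc <- 2^rnorm(n, 0, 1.2)
            data.frame(guide_id = sprintf("G%d_sg%d", g, seq_len(n)),
                       gene = paste0("G", g), role = "targeting",
                       median_fc = fc, log2_median_fc = log2(fc),
                       stringsAsFactors = FALSE)
        }))
        sc <- scoreGenes(med)
        orc <- oracle_score(med)
        got <- sc$geneScores[match(orc$gene, sc$geneScores$gene), ]
        expect_identical(got$n_depleted, orc$n_depleted)
        expect_identical(got$n_enriched, orc$n_enriched)
        expect_identical(got$classification, orc$classification)
    }
})

test_that("gene ranking is a deterministic total order", {
    mk <- function(gene, med, role = "targeting") data.frame(
        guide_id = paste0(gene, "_", seq_along(med)), gene = gene,
        role = role, median_fc = med, log2_median_fc = log2(med),
        stringsAsFactors = FALSE)
    ## same depleted count: tie broken by |summary log2fc|, then name
    med <- rbind(mk("B", c(0.4, 0.4, 1)), mk("A", c(0.4, 0.4, 1)),
                 mk("C", c(0.2, 0.2, 1)))
    sc <- scoreGenes(med)
    expect_identical(sc$depletion$gene, c("C", "A", "B"))

    ## NTC guides are excluded from gene scoring, reported separately
    med_ntc <- rbind(med, mk("NTC", 1.0, role = "nontargeting"))
    sc2 <- scoreGenes(med_ntc)
    expect_false("NTC" %in% sc2$geneScores$gene)
    expect_identical(sc2$ntc$gene, "NTC")
})

test_that("waterfallTable sorts log2 descending with stable ties", {
    med <- data.frame(guide_id = c("a", "b", "c"), gene = "G",
                      role = "targeting", median_fc = 2^c(-2, 0, 1),
                      log2_median_fc = c(-2, 0, 1),
                      stringsAsFactors = FALSE)
    wf <- waterfallTable(med)
    expect_equal(wf$log2_median_fc, c(1, 0, -2))
    expect_identical(wf$status, c("enriched", "within", "depleted"))
    expect_identical(nrow(wf), nrow(med))
    ## ties keep input order
    med_t <- med; med_t$log2_median_fc <- c(0, 0, 0)
    expect_identical(waterfallTable(med_t)$guide_id, c("a", "b", "c"))
    ## monotone non-increasing
    set.seed(2)
    med_r <- med[sample(1:3, 30, replace = TRUE), ]
    med_r$log2_median_fc <- rnorm(30)
    wf_r <- waterfallTable(med_r)
    expect_true(all(diff(wf_r$log2_median_fc) <= 0))
})

test_that("normalizeToInput is the output/input percentage ratio", {
    expect_equal(normalizeToInput(30, 60), 0.5)
    expect_equal(normalizeToInput(90, 45), 2.0)
    for (x in c(0.1, 5, 50, 100)) expect_equal(normalizeToInput(x, x), 1)
    expect_error(normalizeToInput(10, 0), "percentIn")
})
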