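test_that("site weight table: uniform within kind class, TS enrichment, e = 0", {
    ref <- syntheticReference(1000, topology = "linear", seed = 5)
    gene <- geneAnnotation(ref, 201, 800, "bla", "+")

    cfg1 <- simulationConfig("prokaryote", nMolecules = 100, seed = 1)
    swt <- siteWeightTable(ref, gene, cfg1)   # e = 1 everywhere
    expect_equal(length(unique(swt$weight)), 1L)
    expect_equal(sum(swt$weight), 1.0)

    cfg6 <- simulationConfig("prokaryote", nMolecules = 100, seed = 1,
                             tcrEnrichment = c(bla = 6))
    swt6 <- siteWeightTable(ref, gene, cfg6)
    inGene <- swt6$pos5 >= 201 & swt6$pos5 <= 800
    ts <- swt6$strand == tsStrand(gene)
    wTS <- sum(swt6$weight[inGene & ts])
    wNTS <- sum(swt6$weight[inGene & !ts])
    nTS <- sum(inGene & ts); nNTS <- sum(inGene & !ts)
    ## closed form: expected TS:NTS sampling ratio per site class is e
    expect_equal((wTS / nTS) / (wNTS / nNTS), 6.0)

    cfg0 <- simulationConfig("prokaryote", nMolecules = 2000, seed = 2,
                             tcrEnrichment = c(bla = 0))
    sim0 <- simulateExcisionProducts(ref, gene, cfg0)
    inG <- sim0$truth$damage_pos >= 201 & sim0$truth$damage_pos <= 800
    expect_equal(sum(inG & sim0$truth$strand == tsStrand(gene)), 0L)
})

test_that("excision products: empty case, length mix, damage at the configured offset", {
    ref <- syntheticReference(3000, seed = 8)
    cfg <- simulationConfig("prokaryote", nMolecules = 0, seed = 3)
    empty <- simulateExcisionProducts(ref, GRanges(), cfg)
    expect_length(empty$inserts, 0)
    expect_equal(nrow(empty$truth), 0)

    cfg <- simulationConfig("prokaryote", nMolecules = 10000, seed = 3)
    sim <- simulateExcisionProducts(ref, GRanges(), cfg)
    full <- !sim$truth$degraded
    f13 <- mean(sim$truth$length[full] == 13)
    expect_lt(abs(f13 - 0.85), 0.02)

    ## every non-degraded read carries a sampled-kind dipyrimidine (TT under
    ## the prokaryote default) at the offset configured for its length
    off <- c("12" = 8, "13" = 8, "14" = 9)
    d <- off[as.character(sim$truth$length[full])]
    expect_true(all(substr(sim$inserts[full], d, d + 1) == "TT"))

    ## degraded products are 5'-truncations of length 4-11
    expect_true(all(sim$truth$length[sim$truth$degraded] %in% 4:11))
})

test_that("UMI/adapter attachment: identity case, lengths, seeded distinct UMIs", {
    ref <- syntheticReference(500, seed = 2)
    cfg0 <- simulationConfig("prokaryote", nMolecules = 5, seed = 4,
                             umiLength = 0, adapter3 = "")
    ins <- c("ACGTACGTACGTA", "TTTTAAAACCCCG")
    lig0 <- attachAdaptersAndUmi(ins, cfg0)
    expect_identical(lig0$reads, ins)

    cfg8 <- simulationConfig("prokaryote", nMolecules = 5, seed = 4)
    set.seed(99)
    lig8 <- attachAdaptersAndUmi(ins, cfg8)
    expect_equal(nchar(lig8$reads),
                 nchar(ins) + 8 + nchar(cfg8@adapter3))
    expect_equal(nchar(lig8$umi), c(8L, 8L))
    ## same insert twice: UMIs distinct in this seeded fixture
    set.seed(100)
    two <- attachAdaptersAndUmi(rep("ACGTACGTACGTA", 2), cfg8)
    expect_false(two$umi[1] == two$umi[2])
})

test_that("PCR duplication: identity at mean 0, Poisson mean, byte-identical copies", {
    ref <- syntheticReference(2000, seed = 6)
    cfg <- simulationConfig("prokaryote", nMolecules = 10000, seed = 5,
                            degradationFraction = 0)
    sim <- simulateExcisionProducts(ref, GRanges(), cfg)
    lig <- attachAdaptersAndUmi(sim$inserts, cfg)

    cfg0 <- cfg; cfg0@pcrDupMean <- 0
    out0 <- applyPcrDuplication(lig$reads, sim$truth, cfg0)
    expect_identical(out0$reads, lig$reads)
    expect_identical(out0$truth, sim$truth)

    set.seed(77)
    out1 <- applyPcrDuplication(lig$reads, sim$truth, cfg)  # mean 1
    ratio <- length(out1$reads) / length(lig$reads)
    expect_lt(abs(ratio - 2.0), 0.05)
    dup <- out1$truth$is_pcr_duplicate
    m <- match(out1$truth$parent_id[dup], sim$truth$read_id)
    expect_identical(out1$reads[dup], lig$reads[m])
})

test_that("emitted length histogram is consistent with the configured weights", {
    ref <- syntheticReference(3000, seed = 9)
    cfg <- simulationConfig("prokaryote", nMolecules = 10000, seed = 21,
                            degradationFraction = 0)
    sim <- simulateExcisionProducts(ref, GRanges(), cfg)
    obs <- table(factor(sim$truth$length, levels = 12:14))
    gof <- chisq.test(obs, p = c(0.05, 0.85, 0.10))
    expect_gt(gof$p.value, 0.01)
})

test_that("expected TS/NTS count ratio under e = 1 equals the TT strand ratio", {
    ref <- syntheticReference(4000, seed = 10)
    gene <- geneAnnotation(ref, 1001, 3000, "bla", "+")
    cfg <- simulationConfig("prokaryote", nMolecules = 100000, seed = 31)
    sim <- simulateExcisionProducts(ref, gene, cfg)
    inG <- sim$truth$damage_pos >= 1001 & sim$truth$damage_pos <= 3000
    ts <- sum(inG & sim$truth$strand == tsStrand(gene))
    nts <- sum(inG & sim$truth$strand != tsStrand(gene))
    ratio <- ts / nts
    expected <- ttStrandRatio(ref, gene)
    se <- ratio * sqrt(1 / ts + 1 / nts)   # delta method on the count ratio
    expect_lt(abs(ratio - expected), 3 * se)
})

test_that("identical seeds give byte-identical FASTQ pairs; read ids leak no truth", {
    ref <- syntheticReference(2000, seed = 12)
    gene <- geneAnnotation(ref, 501, 1500, "bla", "+")
    cfg <- simulationConfig("prokaryote", nMolecules = 2000, seed = 55)
    d1 <- tempfile(); d2 <- tempfile()
    p1 <- simulateExperimentPair(ref, gene, cfg, c(bla = 2), c(bla = 1), d1)
    p2 <- simulateExperimentPair(ref, gene, cfg, c(bla = 2), c(bla = 1), d2)
    expect_identical(readLines(p1$fastq_plus), readLines(p2$fastq_plus))
    expect_identical(readLines(p1$fastq_minus), readLines(p2$fastq_minus))
    ## the two libraries differ (distinct derived seeds)
    expect_false(identical(readLines(p1$fastq_plus),
                           readLines(p1$fastq_minus)))
    ids <- sub("^@", "", grep("^@", readLines(p1$fastq_plus), value = TRUE))
    expect_true(all(grepl("^mol[0-9]+(\\.d[0-9]+)?$", ids)))
    ## FASTQ round-trips through a standard parser
    back <- Biostrings::readDNAStringSet(p1$fastq_plus, format = "fastq")
    expect_equal(length(back), length(ids))
})
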