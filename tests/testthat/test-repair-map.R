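test_that("damage filter keeps exactly the reads with the dipyrimidine in place", {
    spec <- damageFilterSpec(13, c(8, 9), "TT")
    gr <- mkAlignments(
        start = c(10, 30, 50, 70),
        strand = c("+", "+", "-", "+"),
        insert = c("AAAAAAATTAAAA",   # TT at 8-9 -> kept
                   "AAAAAATTAAAAA",   # TT at 7-8 only -> removed
                   "AAAAAAATTAAAA",   # kept (minus strand, read-level check)
                   "AAAAAAATTAAA"),   # 12-mer -> removed (length)
        refLength = 200)
    df <- damageFilter(gr, spec)
    expect_equal(df$stats$kept, 2L)
    expect_equal(df$stats$removed_length, 1L)
    expect_equal(df$stats$removed_no_dipy, 1L)
    expect_equal(df$stats$input,
                 df$stats$kept + df$stats$removed_length +
                 df$stats$removed_no_dipy)
    expect_true(all(substr(mcols(df$alignments)$insert, 8, 9) == "TT"))

    ## all-kind filter admits TC at the damage positions
    grTC <- mkAlignments(20, "+", "AAAAAAATCAAAA", refLength = 200)
    expect_equal(damageFilter(grTC, damageFilterSpec(13, c(8, 9)))$stats$kept,
                 1L)
    expect_equal(damageFilter(grTC, spec)$stats$kept, 0L)
})

test_that("subsampling is uniform, seeded, and a no-op at full size", {
    gr <- mkAlignments(start = 1:100, strand = rep(c("+", "-"), 50),
                       insert = rep(strrep("ACGTT", 3), 100),
                       refLength = 500)
    expect_length(subsampleAlignments(gr, 0, seed = 1), 0)
    expect_warning(full <- subsampleAlignments(gr, 200, seed = 1),
                   "returning all")
    expect_identical(full, gr)
    s1 <- subsampleAlignments(gr, 40, seed = 9)
    s2 <- subsampleAlignments(gr, 40, seed = 9)
    expect_identical(start(s1), start(s2))
    expect_length(s1, 40)
})

test_that("length distribution fractions sum to one and find the modal product", {
    gr <- mkAlignments(start = c(1, 5, 9),
                       strand = "+",
                       insert = c(strrep("A", 13), strrep("C", 13),
                                  strrep("G", 14)),
                       refLength = 100)
    ld <- lengthDistribution(gr)
    expect_equal(ld$fraction[ld$length == 13], 2 / 3)
    expect_equal(ld$fraction[ld$length == 14], 1 / 3)
    expect_equal(sum(ld$fraction), 1)
    expect_equal(nrow(lengthDistribution(gr[0])), 0)

    ref <- syntheticReference(3000, seed = 23)
    cfg <- simulationConfig("prokaryote", nMolecules = 10000, seed = 71)
    aln <- alignReads(buildIndex(ref),
        preprocessReads(simulateLibrary(ref, GRanges(), cfg)$reads,
                        layoutFromConfig(cfg))$kept)$alignments
    ld2 <- lengthDistribution(aln)
    expect_equal(ld2$length[which.max(ld2$count)], 13L)
})

test_that("nucleotide profile rows sum to one; filtered positions are pure T", {
    gr1 <- mkAlignments(1, "+", "TT", refLength = 10)
    np <- nucleotideProfile(gr1, 2)
    expect_equal(unname(np[1, ]), c(0, 0, 0, 1))
    expect_equal(unname(np[2, ]), c(0, 0, 0, 1))

    ref <- syntheticReference(3000, seed = 24)
    cfg <- simulationConfig("prokaryote", nMolecules = 5000, seed = 72)
    spec <- damageFilterSpec(13, c(8, 9), "TT")
    kept <- processInMemory(ref, GRanges(), cfg, spec)
    np13 <- nucleotideProfile(kept, 13)
    expect_equal(rowSums(np13), rep(1, 13), ignore_attr = TRUE)
    expect_equal(unname(np13[8, "T"]), 1)
    expect_equal(unname(np13[9, "T"]), 1)
})

test_that("5'-flank frequency matches the sequence background under uniform sampling", {
    ref <- syntheticReference(4000, topology = "circular", seed = 25)
    cfg <- simulationConfig("prokaryote", nMolecules = 20000, seed = 73,
                            degradationFraction = 0)
    spec <- damageFilterSpec(13, c(8, 9), "TT")
    kept <- processInMemory(ref, GRanges(), cfg, spec,
                            multimapper = "random_one")
    f <- flankBaseFrequency(kept, spec)
    expect_equal(sum(f), 1)
    bg <- flankBackground(ref, "TT", "A")
    se <- sqrt(bg * (1 - bg) / length(kept))
    expect_lt(abs(f[["A"]] - bg), 3 * se)

    expect_error(flankBaseFrequency(kept[0], spec), "no reads")
    allA <- mkAlignments(1, "+", "AAAAAAATTAAAA", refLength = 100)
    expect_equal(flankBaseFrequency(allA, spec)[["A"]], 1.0)
})

test_that("damage-site coordinates follow the strand-mirror arithmetic", {
    spec <- damageFilterSpec(13, c(8, 9), "TT")
    ## plus read starting at 1-based 101: damage 5' base at 101 + 8 - 1 = 108
    grP <- mkAlignments(101, "+", "AAAAAAATTAAAA", refLength = 500)
    expect_equal(damageSitePositions(grP, spec), 108L)
    ## minus read at the same start: mirrored, 101 + 13 - 8 = 106
    grM <- mkAlignments(101, "-", "AAAAAAATTAAAA", refLength = 500)
    expect_equal(damageSitePositions(grM, spec), 106L)

    map <- coverageTracks(c(grP, grM), spec, mode = "damage_site")
    expect_equal(which(repairVector(map, "+") > 0), 108L)
    expect_equal(which(repairVector(map, "-") > 0), 106L)
    expect_equal(sum(repairVector(map, "+")), 1)
    expect_equal(sum(repairVector(map, "-")), 1)
})

test_that("footprint totals conserve read bases; damage totals conserve reads", {
    ref <- syntheticReference(2000, topology = "circular", seed = 26)
    cfg <- simulationConfig("prokaryote", nMolecules = 3000, seed = 74)
    spec <- damageFilterSpec(13, c(8, 9), "TT")
    kept <- processInMemory(ref, GRanges(), cfg, spec)
    st <- as.character(strand(kept))

    dmap <- coverageTracks(kept, spec, mode = "damage_site", ref = ref)
    expect_equal(sum(repairVector(dmap, "+")), sum(st == "+"))
    expect_equal(sum(repairVector(dmap, "-")), sum(st == "-"))

    fmap <- coverageTracks(kept, spec, mode = "footprint", ref = ref)
    expect_equal(sum(repairVector(fmap, "+")) + sum(repairVector(fmap, "-")),
                 sum(width(kept)))
})

test_that("bedGraph output merges equal runs and round-trips", {
    v <- c(0, 0, 3, 3, 3, 1, 0, 2, 2, 0)
    map <- new("RepairMap", refName = "p", plus = v, minus = numeric(10),
               mode = "damage_site")
    path <- tempfile(fileext = ".bedgraph")
    writeBedGraph(map, path, "+")
    lines <- readLines(path)
    expect_equal(length(lines), 3)        # three non-zero runs, merged
    expect_equal(readBedGraph(path, 10), v)

    empty <- new("RepairMap", refName = "p", plus = numeric(10),
                 minus = numeric(10), mode = "damage_site")
    pathE <- tempfile(fileext = ".bedgraph")
    writeBedGraph(empty, pathE, "+")
    expect_equal(readBedGraph(pathE, 10), numeric(10))
})
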