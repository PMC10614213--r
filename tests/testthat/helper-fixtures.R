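suppressPackageStartupMessages({
    library(GenomicRanges)
    library(S4Vectors)
})

## independent reverse complement (no Biostrings, no package internals)
rcNaive <- function(x) {
    vapply(x, function(s) {
        paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
              collapse = "")
    }, character(1), USE.NAMES = FALSE)
}

## independent full-scan exact-match oracle: slide a window over every
## start position on the (virtually extended, if circular) reference and
## compare strings directly
naiveScanOracle <- function(refSeq, topology, query) {
    n <- nchar(refSeq)
    k <- nchar(query)
    ext <- if (topology == "circular")
        paste0(refSeq, substr(refSeq, 1L, k - 1L)) else refSeq
    nStart <- if (topology == "circular") n else n - k + 1L
    if (nStart < 1L)
        return(data.frame(start = integer(0), strand = character(0)))
    starts <- seq_len(nStart)
    win <- substring(ext, starts, starts + k - 1L)
    rcq <- rcNaive(query)
    out <- rbind(
        data.frame(start = starts[win == query],
                   strand = rep("+", sum(win == query))),
        data.frame(start = starts[win == rcq],
                   strand = rep("-", sum(win == rcq))))
    out[order(out$start, out$strand), , drop = FALSE]
}

randomSeq <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## construct an alignment GRanges by hand, mirroring alignReads() output
mkAlignments <- function(start, strand, insert, refLength = NULL,
                         topology = "linear", umi = NULL,
                         refname = "ref") {
    gr <- GRanges(rep(refname, length(insert)),
                  IRanges::IRanges(start = start, width = nchar(insert)),
                  strand = strand)
    mcols(gr)$read_id <- sprintf("r%04d", seq_along(gr))
    mcols(gr)$umi <- if (is.null(umi)) rep("", length(gr)) else umi
    mcols(gr)$insert <- insert
    metadata(gr)$refLength <- refLength
    metadata(gr)$topology <- topology
    gr
}

writeTempFasta <- function(records) {
    path <- tempfile(fileext = ".fa")
    writeLines(unlist(lapply(names(records), function(nm)
        c(paste0(">", nm), records[[nm]]))), path)
    path
}

writeTempBed <- function(lines) {
    path <- tempfile(fileext = ".bed")
    writeLines(lines, path)
    path
}

## run one simulated library through preprocess -> align -> damage filter,
## in memory; returns damage-filtered alignments. Composition nulls (flank
## frequencies) use multimapper = "random_one": discarding ambiguous
## placements censors reads whose k-mer repeats on a small reference and
## deterministically distorts base composition.
processInMemory <- function(ref, genes, cfg, spec,
                            multimapper = "discard") {
    lib <- simulateLibrary(ref, genes, cfg)
    pp <- preprocessReads(lib$reads, layoutFromConfig(cfg))
    al <- alignReads(buildIndex(ref), pp$kept, multimapper = multimapper,
                     seed = cfg@seed)
    damageFilter(al$alignments, spec)$alignments
}
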