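#' Exact-match index over a small reference
#'
#' Supports lookup of all exact occurrences of a query on either strand of a
#' plasmid-scale reference, including occurrences spanning the junction of a
#' circular reference (reported modulo reference length). Built lazily: a
#' hash table of all reference substrings is materialised per query length
#' on first use. Substrings containing N are never indexed, so N bases abort
#' exact matches.
#'
#' @slot ref the indexed [XRReference-class].
#' @slot tables environment caching one lookup table per substring length.
#' @export
setClass("ExcisionIndex",
    slots = c(ref = "XRReference", tables = "environment"))

setMethod("show", "ExcisionIndex", function(object) {
    cat(sprintf("ExcisionIndex over '%s' (%d nt, %s); %d length table(s) built\n",
        refName(object@ref), refLength(object@ref),
        refTopology(object@ref), length(ls(object@tables))))
})

#' Build an exact-match index
#'
#' @param ref an [XRReference-class].
#' @return an [ExcisionIndex-class].
#' @export
buildIndex <- function(ref) {
    new("ExcisionIndex", ref = ref, tables = new.env(parent = emptyenv()))
}

## data.table of all length-L reference substrings on both strands, keyed by
## sequence. start = leftmost plus-strand coordinate (1-based, modulo length
## for circular junction-spanning windows).
.lengthTable <- function(index, L) {
    key <- as.character(L)
    tab <- index@tables[[key]]
    if (!is.null(tab)) return(tab)
    ref <- index@ref
    n <- refLength(ref)
    circ <- refTopology(ref) == "circular"
    nStart <- if (circ) n else n - L + 1L
    if (nStart < 1L) {
        tab <- data.table::data.table(seq = character(0), start = integer(0),
                                      strand = character(0), key = "seq")
        index@tables[[key]] <- tab
        return(tab)
    }
    s <- .refCharExtended(ref, L - 1L)
    starts <- seq_len(nStart)
    plus <- substring(s, starts, starts + L - 1L)
    minus <- .revcompChar(plus)
    tab <- data.table::data.table(
        seq = c(plus, minus), start = rep(starts, 2L),
        strand = rep(c("+", "-"), each = nStart))
    tab <- tab[!grepl("N", tab$seq, fixed = TRUE)]
    data.table::setkey(tab, seq)
    index@tables[[key]] <- tab
    tab
}

#' Find all exact occurrences of one query
#'
#' @param index an [ExcisionIndex-class].
#' @param query nucleotide string (length >= 4).
#' @return data.frame with \code{start} (leftmost plus-strand coordinate,
#'   1-based) and \code{strand}, one row per hit (0 rows if none).
#' @export
lookupQuery <- function(index, query) {
    stopifnot(nchar(query) >= 4L)
    tab <- .lengthTable(index, nchar(query))
    hits <- tab[list(query), nomatch = NULL]
    data.frame(start = hits$start, strand = hits$strand,
               stringsAsFactors = FALSE)
}

#' Align processed inserts by exact full-length matching
#'
#' Every insert is matched exactly (no mismatches or gaps are ever produced)
#' against both strands of the reference. Inserts with no exact occurrence
#' are counted unaligned; inserts with more than one occurrence are handled
#' per the multimapper policy (default: discarded, counted). \code{start} is
#' always the leftmost plus-strand coordinate regardless of strand (BED
#' convention).
#'
#' @param index an [ExcisionIndex-class].
#' @param processed data.frame with \code{read_id}, \code{umi},
#'   \code{insert} (as from [preprocessReads()]).
#' @param multimapper \code{"discard"} (default) or \code{"random_one"}.
#' @param minLen inserts shorter than this are counted unaligned (index
#'   minimum query length).
#' @param seed optional seed for \code{"random_one"}.
#' @return list with \code{alignments} (a [GenomicRanges::GRanges] with
#'   mcols \code{read_id}, \code{umi}, \code{insert}; reference length and
#'   topology in \code{metadata()}) and \code{stats}
#'   (input/aligned/unaligned/multimapped counts).
#' @export
alignReads <- function(index, processed, multimapper = c("discard", "random_one"),
                       minLen = 4L, seed = NULL) {
    multimapper <- match.arg(multimapper)
    if (!is.null(seed)) set.seed(seed)
    ref <- index@ref
    nIn <- nrow(processed)
    q <- data.table::data.table(read_id = processed$read_id,
                                umi = processed$umi,
                                insert = processed$insert,
                                L = nchar(processed$insert))
    tooShort <- q$L < minLen
    res <- list()
    nUnaligned <- sum(tooShort)
    nMulti <- 0L
    for (len in sort(unique(q$L[!tooShort]))) {
        tab <- .lengthTable(index, len)
        qs <- q[list(len), on = "L"]
        hits <- tab[qs, on = c(seq = "insert"), allow.cartesian = TRUE]
        nh <- hits[, list(n = sum(!is.na(start))), by = "read_id"]
        uniqIds <- nh$read_id[nh$n == 1L]
        nUnaligned <- nUnaligned + sum(nh$n == 0L)
        multiIds <- nh$read_id[nh$n > 1L]
        keep <- hits[!is.na(hits$start) & hits$read_id %in% uniqIds]
        if (multimapper == "random_one" && length(multiIds)) {
            mm <- hits[!is.na(hits$start) & hits$read_id %in% multiIds]
            pick <- mm[, .SD[sample.int(.N, 1L)], by = "read_id"]
            keep <- rbind(keep, pick, use.names = TRUE)
        } else {
            nMulti <- nMulti + length(multiIds)
        }
        if (nrow(keep))
            res[[as.character(len)]] <- data.frame(
                read_id = keep$read_id, umi = keep$umi, insert = keep$seq,
                start = keep$start, strand = keep$strand, L = len,
                stringsAsFactors = FALSE)
    }
    df <- if (length(res)) do.call(rbind, res) else
        data.frame(read_id = character(0), umi = character(0),
                   insert = character(0), start = integer(0),
                   strand = character(0), L = integer(0))
    gr <- GenomicRanges::GRanges(
        seqnames = rep(refName(ref), nrow(df)),
        ranges = IRanges::IRanges(start = df$start, width = df$L),
        strand = df$strand)
    mcols(gr)$read_id <- df$read_id
    mcols(gr)$umi <- df$umi
    mcols(gr)$insert <- df$insert
    metadata(gr)$refLength <- refLength(ref)
    metadata(gr)$topology <- refTopology(ref)
    stats <- list(input = nIn, aligned = length(gr),
                  unaligned = nUnaligned, multimapped = nMulti)
    stopifnot(stats$input == stats$aligned + stats$unaligned +
              stats$multimapped)
    list(alignments = gr, stats = stats)
}

#' Re-extract the reference substring under an alignment
#'
#' Round-trip check helper: for every alignment, extracting \code{width}
#' bases at \code{start} on the aligned strand (5'->3' on that strand, with
#' circular wrap) must reproduce the insert exactly.
#'
#' @param ref an [XRReference-class].
#' @param alignments alignment GRanges (see [alignReads()]).
#' @return character vector of extracted sequences.
#' @export
extractAligned <- function(ref, alignments) {
    if (length(alignments) == 0L) return(character(0))
    L <- GenomicRanges::width(alignments)
    s <- .refCharExtended(ref, max(L) - 1L)
    st <- GenomicRanges::start(alignments)
    out <- substring(s, st, st + L - 1L)
    isM <- as.character(GenomicRanges::strand(alignments)) == "-"
    out[isM] <- .revcompChar(out[isM])
    out
}

#' Write alignments as BED6
#'
#' BED columns: chrom, start, end (0-based half-open, converted by
#' rtracklayer), \code{read_id:umi}, score 0, strand.
#'
#' @param alignments alignment GRanges (see [alignReads()]).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeAlignmentsBed <- function(alignments, path) {
    gr <- GenomicRanges::granges(alignments)
    gr$name <- paste(mcols(alignments)$read_id, mcols(alignments)$umi,
                     sep = ":")
    gr$score <- rep(0L, length(gr))
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}

#' UMI-aware deduplication of aligned reads
#'
#' Collapses alignment records sharing (start, strand, length, UMI) — the
#' signature of a PCR copy — to one record. Records at the same position
#' with different UMIs are genuine repeated repair events at one site and
#' are kept. This is the post-alignment alternative to raw-read
#' deduplication.
#'
#' @param alignments alignment GRanges (see [alignReads()]).
#' @return list with \code{alignments} (collapsed) and \code{removed}
#'   (count).
#' @export
dedupAlignedUmi <- function(alignments) {
    if (length(alignments) == 0L)
        return(list(alignments = alignments, removed = 0L))
    key <- paste(GenomicRanges::start(alignments),
                 as.character(GenomicRanges::strand(alignments)),
                 GenomicRanges::width(alignments),
                 mcols(alignments)$umi, sep = "\r")
    dup <- duplicated(key)
    list(alignments = alignments[!dup], removed = sum(dup))
}
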