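#' Library trim layout
#'
#' The read layout shared between the simulator and the trimmer: a UMI
#' prefix of fixed length, the insert, and a 3' adapter suffix.
#'
#' @param umiLength UMI prefix length (0 for libraries without a UMI).
#' @param adapter3 3' adapter sequence ("" disables adapter search).
#' @param minOverlap minimum adapter prefix length that counts as an
#'   adapter hit when the adapter runs off the 3' end of the read.
#' @param maxMismatch mismatches tolerated in the adapter match (default 0,
#'   exact).
#' @param minLen,maxLen inserts shorter than \code{minLen} are discarded as
#'   \code{too_short}; inserts longer than \code{maxLen} as
#'   \code{too_long}, and adapter-less reads longer than \code{maxLen} as
#'   \code{no_adapter}.
#' @return a list of class \code{"xrLayout"}.
#' @export
trimLayout <- function(umiLength = 8, adapter3 = DEFAULT_ADAPTER3,
        minOverlap = 5, maxMismatch = 0, minLen = 4, maxLen = 40) {
    stopifnot(umiLength >= 0, minOverlap >= 1, maxMismatch >= 0,
              minLen >= 1, maxLen >= minLen)
    structure(list(umiLength = as.integer(umiLength), adapter3 = adapter3,
                   minOverlap = as.integer(minOverlap),
                   maxMismatch = as.integer(maxMismatch),
                   minLen = as.integer(minLen), maxLen = as.integer(maxLen)),
              class = "xrLayout")
}

#' Layout implied by a simulation configuration
#'
#' @param config a [SimulationConfig-class].
#' @param ... further arguments to [trimLayout()].
#' @export
layoutFromConfig <- function(config, ...) {
    trimLayout(umiLength = config@umiLength, adapter3 = config@adapter3, ...)
}

#' Remove duplicate raw reads
#'
#' Collapses byte-identical full raw sequences to their first occurrence.
#' Because the UMI is part of the raw sequence, identical inserts from
#' distinct molecules (distinct UMIs) survive: only PCR copies (and, without
#' a UMI, coincidental exact repeats) are removed.
#'
#' @param reads character vector of raw read sequences (optionally named by
#'   read id).
#' @return list with \code{reads} (unique, first occurrences) and
#'   \code{removed} (count).
#' @export
dedupRaw <- function(reads) {
    dup <- duplicated(unname(reads))
    list(reads = reads[!dup], removed = sum(dup))
}

## leftmost adapter occurrence allowing <= maxMismatch mismatches, in one
## string; returns start position within `rest` or -1. Slow path, used only
## when maxMismatch > 0.
.fuzzyAdapterPos <- function(rest, adapter, minOverlap, maxMismatch) {
    n <- nchar(rest); m <- nchar(adapter)
    rs <- strsplit(rest, "")[[1]]
    as <- strsplit(adapter, "")[[1]]
    lastStart <- n - minOverlap + 1L
    for (p in seq_len(max(lastStart, 0L))) {
        k <- min(m, n - p + 1L)
        if (sum(rs[p:(p + k - 1L)] != as[seq_len(k)]) <= maxMismatch)
            return(p)
    }
    -1L
}

#' Trim UMI and 3' adapter from raw reads
#'
#' The first \code{umiLength} bases become the UMI; the 3' adapter is
#' located as the leftmost occurrence (after the UMI) of the adapter, or of
#' an adapter prefix of length >= \code{minOverlap} ending flush with the
#' read's 3' end (adapter running off the read). The insert is everything
#' between. Reads are flagged rather than dropped, so counts are conserved.
#'
#' @param reads character vector of raw reads (names = read ids).
#' @param layout a [trimLayout()] list.
#' @return data.frame with \code{read_id}, \code{umi}, \code{insert} and
#'   \code{reason} (\code{NA} if kept, else \code{"no_adapter"},
#'   \code{"too_short"} or \code{"too_long"}).
#' @export
trimReads <- function(reads, layout = trimLayout()) {
    n <- length(reads)
    ids <- if (is.null(names(reads))) sprintf("read%07d", seq_len(n))
           else names(reads)
    seqs <- unname(reads)
    reason <- rep(NA_character_, n)
    umiL <- layout$umiLength
    shortRaw <- nchar(seqs) < umiL
    reason[shortRaw] <- "too_short"
    umi <- ifelse(shortRaw, "", substr(seqs, 1L, umiL))
    rest <- ifelse(shortRaw, "", substr(seqs, umiL + 1L, nchar(seqs)))

    ad <- layout$adapter3
    pos <- rep(-1L, n)
    if (nzchar(ad)) {
        if (layout$maxMismatch == 0L) {
            pos <- as.integer(regexpr(ad, rest, fixed = TRUE))
            ## adapter running off the 3' end: longest adapter prefix that is
            ## a suffix of the remaining read (longest = leftmost start)
            todo <- pos < 0L & !shortRaw
            ks <- if (nchar(ad) - 1L >= layout$minOverlap)
                      seq(nchar(ad) - 1L, layout$minOverlap) else integer(0)
            for (k in ks) {
                if (!any(todo)) break
                hit <- todo & nchar(rest) >= k &
                       endsWith(rest, substr(ad, 1L, k))
                pos[hit] <- nchar(rest[hit]) - k + 1L
                todo <- todo & !hit
            }
        } else {
            pos <- vapply(rest, .fuzzyAdapterPos, integer(1), adapter = ad,
                          minOverlap = layout$minOverlap,
                          maxMismatch = layout$maxMismatch,
                          USE.NAMES = FALSE)
            pos[shortRaw] <- -1L
        }
    }
    insert <- ifelse(pos > 0L, substr(rest, 1L, pos - 1L), rest)
    noAd <- !shortRaw & pos < 0L & nzchar(ad) & nchar(rest) > layout$maxLen
    reason[noAd] <- "no_adapter"
    ok <- is.na(reason)
    reason[ok & nchar(insert) < layout$minLen] <- "too_short"
    ok <- is.na(reason)
    reason[ok & nchar(insert) > layout$maxLen] <- "too_long"
    data.frame(read_id = ids, umi = umi, insert = insert, reason = reason,
               stringsAsFactors = FALSE)
}

#' Preprocess a raw library: dedup, trim, extract inserts
#'
#' Runs [dedupRaw()] (default on, the order used for UMI-bearing libraries:
#' duplicates are removed while the UMI is still part of the raw sequence)
#' followed by [trimReads()]. Counts are conserved exactly:
#' input = duplicate + kept + no_adapter + too_short + too_long.
#'
#' @param input path to a FASTQ file, or a named character vector of raw
#'   read sequences.
#' @param layout a [trimLayout()] list.
#' @param dedup remove byte-identical raw reads first (default TRUE).
#' @param tsvOut optional path; kept reads written as TSV
#'   (read_id, umi, insert).
#' @return list with \code{kept} (data.frame read_id/umi/insert) and
#'   \code{stats} (named list of counts).
#' @export
preprocessReads <- function(input, layout = trimLayout(), dedup = TRUE,
                            tsvOut = NULL) {
    reads <- if (is.character(input) && length(input) == 1L &&
                 file.exists(input)) .readFastqSeqs(input) else input
    nIn <- length(reads)
    nDup <- 0L
    if (dedup) {
        dd <- dedupRaw(reads)
        reads <- dd$reads
        nDup <- dd$removed
    }
    tr <- trimReads(reads, layout)
    kept <- tr[is.na(tr$reason), c("read_id", "umi", "insert")]
    rownames(kept) <- NULL
    stats <- list(input = nIn, duplicate = nDup, kept = nrow(kept),
                  no_adapter = sum(tr$reason == "no_adapter", na.rm = TRUE),
                  too_short = sum(tr$reason == "too_short", na.rm = TRUE),
                  too_long = sum(tr$reason == "too_long", na.rm = TRUE))
    stopifnot(stats$input == stats$duplicate + stats$kept +
              stats$no_adapter + stats$too_short + stats$too_long)
    if (!is.null(tsvOut))
        utils::write.table(kept, tsvOut, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    list(kept = kept, stats = stats)
}
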