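#' Damage-position read filter specification
#'
#' The read selection used before plotting and strand counting: keep only
#' reads of exactly one length carrying a dipyrimidine at a fixed pair of
#' consecutive 1-based read positions (read 5'->3' on the read's own
#' strand). The canonical prokaryotic setting is 13-nt reads with the
#' dipyrimidine at positions 8-9; the eukaryotic setting is 26-nt reads
#' with the dipyrimidine at positions 19-20.
#'
#' @slot readLength required read length.
#' @slot dipyPositions integer pair of consecutive 1-based read positions.
#' @slot kinds dipyrimidine kinds accepted (default all four; set
#'   \code{"TT"} for a CPD/TT-only filter).
#' @export
setClass("DamageFilterSpec",
    slots = c(readLength = "integer", dipyPositions = "integer",
              kinds = "character"))

setValidity("DamageFilterSpec", function(object) {
    msg <- character(0)
    p <- object@dipyPositions
    if (length(p) != 2L || p[2] != p[1] + 1L)
        msg <- c(msg, "dipyPositions must be two consecutive positions")
    if (p[1] < 1L || p[2] > object@readLength)
        msg <- c(msg, "dipyPositions must lie within the read")
    if (!all(object@kinds %in% DIPY_KINDS) || !length(object@kinds))
        msg <- c(msg, "kinds must be a non-empty subset of TT/TC/CT/CC")
    if (length(msg)) msg else TRUE
})

setMethod("show", "DamageFilterSpec", function(object) {
    cat(sprintf("DamageFilterSpec: %d-nt reads, dipyrimidine (%s) at %d-%d\n",
        object@readLength, paste(object@kinds, collapse = "/"),
        object@dipyPositions[1], object@dipyPositions[2]))
})

#' @rdname DamageFilterSpec-class
#' @param readLength,dipyPositions,kinds see slots above.
#' @export
damageFilterSpec <- function(readLength = 13L, dipyPositions = c(8L, 9L),
                             kinds = DIPY_KINDS) {
    new("DamageFilterSpec", readLength = as.integer(readLength),
        dipyPositions = as.integer(dipyPositions), kinds = kinds)
}

#' @rdname DamageFilterSpec-class
#' @export
prokaryoteFilter <- function(kinds = DIPY_KINDS)
    damageFilterSpec(13L, c(8L, 9L), kinds)

#' @rdname DamageFilterSpec-class
#' @export
eukaryoteFilter <- function(kinds = DIPY_KINDS)
    damageFilterSpec(26L, c(19L, 20L), kinds)

#' Apply the damage-position read filter
#'
#' Keeps alignments whose insert has exactly the specified length and whose
#' bases at the specified positions form a dinucleotide of an accepted kind.
#' The check is made on the read's own sequence (identical to the reference
#' under exact alignment, and usable pre-alignment).
#'
#' @param alignments alignment GRanges (see [alignReads()]).
#' @param spec a [DamageFilterSpec-class].
#' @return list with \code{alignments} (kept) and \code{stats}
#'   (input / kept / removed_length / removed_no_dipy).
#' @export
damageFilter <- function(alignments, spec) {
    ins <- mcols(alignments)$insert
    okLen <- nchar(ins) == spec@readLength
    d <- spec@dipyPositions[1]
    dinuc <- substr(ins, d, d + 1L)
    okDipy <- okLen & dinuc %in% spec@kinds
    stats <- list(input = length(alignments), kept = sum(okDipy),
                  removed_length = sum(!okLen),
                  removed_no_dipy = sum(okLen & !okDipy))
    stopifnot(stats$input == stats$kept + stats$removed_length +
              stats$removed_no_dipy)
    list(alignments = alignments[okDipy], stats = stats)
}

#' Subsample alignments uniformly without replacement
#'
#' @param alignments alignment GRanges.
#' @param n target size (the customary depth-matching size is 200,000).
#' @param seed integer seed.
#' @return subsampled GRanges; if \code{n} >= input size the input is
#'   returned unchanged with a warning.
#' @export
subsampleAlignments <- function(alignments, n = 200000L, seed = 1L) {
    stopifnot(n >= 0)
    if (n >= length(alignments)) {
        if (n > length(alignments))
            warning("requested subsample of ", n, " from ",
                    length(alignments), " alignments; returning all")
        return(alignments)
    }
    set.seed(seed)
    alignments[sort(sample.int(length(alignments), n))]
}

#' Read length distribution
#'
#' @param alignments alignment GRanges.
#' @return data.frame with \code{length}, \code{count}, \code{fraction}
#'   (fractions sum to 1; zero rows for empty input).
#' @export
lengthDistribution <- function(alignments) {
    if (length(alignments) == 0L)
        return(data.frame(length = integer(0), count = integer(0),
                          fraction = numeric(0)))
    tab <- table(GenomicRanges::width(alignments))
    data.frame(length = as.integer(names(tab)),
               count = as.integer(tab),
               fraction = as.numeric(tab) / length(alignments))
}

#' Positional nucleotide profile
#'
#' Base frequencies at each 1-based read position (the 5' end of the
#' excision product is position 1), over reads of a single length.
#'
#' @param alignments alignment GRanges.
#' @param L read length; only reads of this length contribute.
#' @return L x 4 matrix of frequencies with columns A, C, G, T; each row
#'   sums to 1 given at least one read.
#' @export
nucleotideProfile <- function(alignments, L) {
    ins <- mcols(alignments)$insert
    ins <- ins[nchar(ins) == L]
    mat <- matrix(0, nrow = L, ncol = 4,
                  dimnames = list(seq_len(L), c("A", "C", "G", "T")))
    if (length(ins) == 0L) return(mat)
    for (j in seq_len(L)) {
        b <- factor(substr(ins, j, j), levels = c("A", "C", "G", "T"))
        mat[j, ] <- as.integer(table(b)) / length(ins)
    }
    mat
}

#' Base frequencies immediately 5' of the damage dinucleotide
#'
#' The fraction of reads whose base at (first dipyrimidine position - 1)
#' equals each of A, C, G, T — the within-read analogue of
#' [flankBackground()], quantifying the 5'-flank preference of the excision
#' nuclease relative to the sequence-composition null.
#'
#' @param alignments damage-filtered alignment GRanges.
#' @param spec the [DamageFilterSpec-class] used for filtering (first
#'   dipyrimidine position must be >= 2).
#' @return named numeric of length 4 (A, C, G, T), summing to 1.
#' @export
flankBaseFrequency <- function(alignments, spec) {
    stopifnot(spec@dipyPositions[1] >= 2L)
    ins <- mcols(alignments)$insert
    ins <- ins[nchar(ins) == spec@readLength]
    if (length(ins) == 0L) stop("no reads")
    b <- factor(substr(ins, spec@dipyPositions[1] - 1L,
                       spec@dipyPositions[1] - 1L),
                levels = c("A", "C", "G", "T"))
    f <- as.numeric(table(b)) / length(ins)
    names(f) <- c("A", "C", "G", "T")
    f
}

#' Strand-resolved repair map
#'
#' Per-position, per-strand counts over the reference: either one count per
#' read at its damage-site coordinate, or counts at every covered position
#' (read footprints).
#'
#' @slot refName reference name.
#' @slot plus,minus numeric count vectors, one entry per reference position.
#' @slot mode \code{"damage_site"} or \code{"footprint"}.
#' @export
setClass("RepairMap",
    slots = c(refName = "character", plus = "numeric", minus = "numeric",
              mode = "character"))

setValidity("RepairMap", function(object) {
    msg <- character(0)
    if (length(object@plus) != length(object@minus))
        msg <- c(msg, "plus and minus vectors must have equal length")
    if (any(object@plus < 0) || any(object@minus < 0))
        msg <- c(msg, "counts must be non-negative")
    if (!object@mode %in% c("damage_site", "footprint"))
        msg <- c(msg, "mode must be 'damage_site' or 'footprint'")
    if (length(msg)) msg else TRUE
})

setMethod("show", "RepairMap", function(object) {
    cat(sprintf("RepairMap '%s' (%s): %d positions, totals +%g / -%g\n",
        object@refName, object@mode, length(object@plus),
        sum(object@plus), sum(object@minus)))
})

#' @rdname RepairMap-class
#' @param map a \code{RepairMap}.
#' @param strand \code{"+"} or \code{"-"}.
#' @export
repairVector <- function(map, strand = c("+", "-")) {
    strand <- match.arg(strand)
    if (strand == "+") map@plus else map@minus
}

#' Damage-site coordinates of aligned reads
#'
#' The plus-strand 1-based coordinate of the damage dinucleotide's 5' base:
#' \code{start + d - 1} for plus-strand reads and (mirrored)
#' \code{start + length - d} for minus-strand reads, where \code{d} is the
#' first dipyrimidine read position. Wraps modulo reference length for
#' circular references.
#'
#' @param alignments alignment GRanges (see [alignReads()]).
#' @param spec a [DamageFilterSpec-class].
#' @return integer vector of coordinates, one per alignment.
#' @export
damageSitePositions <- function(alignments, spec) {
    d <- spec@dipyPositions[1]
    s <- GenomicRanges::start(alignments)
    L <- GenomicRanges::width(alignments)
    isP <- as.character(GenomicRanges::strand(alignments)) == "+"
    pos <- ifelse(isP, s + d - 1L, s + L - d)
    n <- metadata(alignments)$refLength
    if (!is.null(n) && identical(metadata(alignments)$topology, "circular"))
        pos <- ((pos - 1L) %% n) + 1L
    as.integer(pos)
}

#' Build strand-resolved coverage tracks
#'
#' @param alignments alignment GRanges (typically damage-filtered).
#' @param spec a [DamageFilterSpec-class] (used for the damage-site
#'   coordinate in \code{"damage_site"} mode).
#' @param mode \code{"damage_site"}: one count per read at its damage-site
#'   coordinate; \code{"footprint"}: one count at every read-covered
#'   position.
#' @param ref the [XRReference-class] (for length and topology; defaults to
#'   the metadata recorded on the alignments).
#' @return a [RepairMap-class].
#' @export
coverageTracks <- function(alignments, spec,
                           mode = c("damage_site", "footprint"), ref = NULL) {
    mode <- match.arg(mode)
    n <- if (!is.null(ref)) refLength(ref) else metadata(alignments)$refLength
    circ <- if (!is.null(ref)) refTopology(ref) == "circular"
            else identical(metadata(alignments)$topology, "circular")
    if (is.null(n)) stop("reference length unknown; supply 'ref'")
    refNm <- if (!is.null(ref)) refName(ref)
             else as.character(GenomicRanges::seqnames(alignments)[1])
    if (length(alignments) == 0L) refNm <- if (!is.null(ref)) refName(ref) else "ref"
    st <- as.character(GenomicRanges::strand(alignments))
    vec <- function(sel) {
        if (mode == "damage_site") {
            pos <- damageSitePositions(alignments[sel], spec)
            tabulate(pos, nbins = n)
        } else {
            ir <- IRanges::IRanges(
                start = GenomicRanges::start(alignments[sel]),
                width = GenomicRanges::width(alignments[sel]))
            if (circ) {
                over <- IRanges::end(ir) > n
                main <- IRanges::restrict(ir, start = 1L, end = n)
                wrap <- IRanges::IRanges(
                    start = 1L, width = IRanges::end(ir)[over] - n)
                cov <- IRanges::coverage(c(main, wrap), width = n)
            } else {
                cov <- IRanges::coverage(ir, width = n)
            }
            as.numeric(cov)
        }
    }
    new("RepairMap", refName = refNm, plus = as.numeric(vec(st == "+")),
        minus = as.numeric(vec(st == "-")), mode = mode)
}

#' Write one strand of a repair map as bedGraph
#'
#' Runs of equal non-zero value are merged into single intervals;
#' coordinates are the bedGraph native 0-based half-open convention.
#'
#' @param map a [RepairMap-class].
#' @param path output path.
#' @param strand \code{"+"} or \code{"-"}.
#' @return the path, invisibly.
#' @export
writeBedGraph <- function(map, path, strand = c("+", "-")) {
    strand <- match.arg(strand)
    v <- repairVector(map, strand)
    r <- S4Vectors::Rle(v)
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- ends - S4Vectors::runLength(r) + 1L
    keep <- S4Vectors::runValue(r) != 0
    gr <- GenomicRanges::GRanges(rep(map@refName, sum(keep)),
        IRanges::IRanges(start = starts[keep], end = ends[keep]),
        score = S4Vectors::runValue(r)[keep])
    rtracklayer::export(gr, path, format = "bedGraph")
    invisible(path)
}

#' Read a bedGraph file back into a per-position vector
#'
#' @param path bedGraph path.
#' @param n reference length.
#' @return numeric vector of length \code{n} (zero where no interval).
#' @export
readBedGraph <- function(path, n) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    v <- numeric(n)
    for (i in seq_along(gr)) {
        v[GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]] <-
            gr$score[i]
    }
    v
}
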