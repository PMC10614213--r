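#' @import methods
#' @importFrom S4Vectors mcols mcols<- metadata metadata<-
NULL

DIPY_KINDS <- c("TT", "TC", "CT", "CC")

#' Reference sequence with topology
#'
#' An \code{XRReference} holds a single named nucleotide sequence (the plasmid
#' or genome segment that is the coordinate frame for all downstream repair
#' statistics) together with its topology. Plasmids are typically circular;
#' circular topology makes the junction between the last and first base a
#' legitimate dinucleotide and alignment position.
#'
#' All coordinates exposed by this package are 1-based closed (the
#' GRanges/Bioconductor convention); BED and bedGraph files read or written by
#' the package use their native 0-based half-open convention.
#'
#' @slot name single non-empty character, the sequence name.
#' @slot sequence a [Biostrings::DNAString] over the alphabet A, C, G, T, N.
#' @slot topology either \code{"linear"} or \code{"circular"}.
#' @export
setClass("XRReference",
    slots = c(name = "character", sequence = "DNAString",
              topology = "character"))

setValidity("XRReference", function(object) {
    msg <- character(0)
    if (length(object@name) != 1L || !nzchar(object@name))
        msg <- c(msg, "'name' must be a single non-empty string")
    if (length(object@sequence) < 1L)
        msg <- c(msg, "sequence must have length >= 1")
    if (!(length(object@topology) == 1L &&
          object@topology %in% c("linear", "circular")))
        msg <- c(msg, "'topology' must be 'linear' or 'circular'")
    freq <- Biostrings::alphabetFrequency(object@sequence)
    bad <- sum(freq) - sum(freq[c("A", "C", "G", "T", "N")])
    if (bad > 0L)
        msg <- c(msg, sprintf(
            "sequence of '%s' contains %d characters outside {A,C,G,T,N}",
            object@name, bad))
    if (length(msg)) msg else TRUE
})

#' Construct a reference
#'
#' @param name sequence name (single non-empty string).
#' @param sequence character string or [Biostrings::DNAString]; lowercase
#'   (soft-masked) bases are uppercased.
#' @param topology \code{"linear"} (default) or \code{"circular"}.
#' @return an [XRReference-class] object.
#' @examples
#' ref <- XRReference("p", "ACGTACGT", topology = "circular")
#' refLength(ref)
#' @export
XRReference <- function(name, sequence, topology = c("linear", "circular")) {
    topology <- match.arg(topology)
    if (is.character(sequence))
        sequence <- Biostrings::DNAString(toupper(sequence))
    new("XRReference", name = as.character(name), sequence = sequence,
        topology = topology)
}

#' @rdname XRReference
#' @param object,ref an \code{XRReference}.
#' @export
setGeneric("refName", function(object) standardGeneric("refName"))
#' @rdname XRReference
#' @export
setMethod("refName", "XRReference", function(object) object@name)

#' @rdname XRReference
#' @export
setGeneric("refTopology", function(object) standardGeneric("refTopology"))
#' @rdname XRReference
#' @export
setMethod("refTopology", "XRReference", function(object) object@topology)

#' @rdname XRReference
#' @export
setGeneric("refSequence", function(object) standardGeneric("refSequence"))
#' @rdname XRReference
#' @export
setMethod("refSequence", "XRReference", function(object) object@sequence)

#' @rdname XRReference
#' @export
refLength <- function(ref) length(ref@sequence)

setMethod("show", "XRReference", function(object) {
    cat(sprintf("XRReference '%s': %d nt, %s\n", object@name,
                length(object@sequence), object@topology))
})

.refChar <- function(ref) as.character(ref@sequence)

## reference string virtually extended past the end by `extra` bases for
## circular topology, so substring() never runs off the junction
.refCharExtended <- function(ref, extra) {
    s <- .refChar(ref)
    if (ref@topology == "circular" && extra > 0L)
        s <- paste0(s, substr(s, 1L, extra))
    s
}

#' Read references from a FASTA file
#'
#' One [XRReference-class] per FASTA record, in file order. Sequences are
#' uppercased; any character outside A/C/G/T/N is a hard error naming the
#' offending record.
#'
#' @param path path to a FASTA file.
#' @param topology topology for the records, recycled across records.
#' @return a named list of [XRReference-class] objects.
#' @export
readReferenceFasta <- function(path, topology = "linear") {
    if (!file.exists(path)) stop("FASTA file not found: ", path)
    ## read without alphabet coercion: Biostrings' DNA reader silently drops
    ## invalid letters, but they must be a hard error naming the record
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) stop("FASTA file contains no records: ", path)
    nms <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
    topology <- rep_len(topology, length(set))
    refs <- lapply(seq_along(set), function(i) {
        s <- toupper(as.character(set[[i]]))
        bad <- gsub("[ACGTN]", "", s)
        if (nzchar(bad))
            stop(sprintf("record '%s' contains non-nucleotide characters: %s",
                 nms[i], paste(unique(strsplit(bad, "")[[1]]),
                               collapse = ", ")))
        XRReference(nms[i], s, topology = topology[i])
    })
    names(refs) <- nms
    refs
}

.tsStrandChar <- function(sense) ifelse(sense == "+", "-", "+")

#' Transcribed strand of genes
#'
#' The transcribed (template) strand is the strand opposite the sense
#' (coding) strand recorded in the annotation.
#'
#' @param genes a [GenomicRanges::GRanges] of gene annotations whose strand
#'   is the sense strand.
#' @return character vector of \code{"+"}/\code{"-"}, one per gene.
#' @export
tsStrand <- function(genes) {
    .tsStrandChar(as.character(GenomicRanges::strand(genes)))
}

#' Construct a gene annotation
#'
#' @param ref an [XRReference-class].
#' @param start,end 1-based closed interval on the reference.
#' @param gene gene name.
#' @param sense sense (coding) strand, \code{"+"} or \code{"-"}.
#' @param label optional free-text label (e.g. promoter class).
#' @return a [GenomicRanges::GRanges] with the sense strand in
#'   \code{strand()} and the gene name in \code{names()} and \code{$name}.
#' @export
geneAnnotation <- function(ref, start, end, gene, sense, label = NA_character_) {
    gr <- GenomicRanges::GRanges(refName(ref),
        IRanges::IRanges(start = start, end = end), strand = sense,
        name = gene, label = label)
    names(gr) <- gene
    .validateGenes(gr, ref)
    gr
}

.validateGenes <- function(gr, ref) {
    st <- as.character(GenomicRanges::strand(gr))
    for (i in seq_along(gr)) {
        if (as.character(GenomicRanges::seqnames(gr))[i] != refName(ref))
            stop(sprintf("gene record %d ('%s'): chrom '%s' does not match reference '%s'",
                 i, gr$name[i], as.character(GenomicRanges::seqnames(gr))[i],
                 refName(ref)))
        if (!st[i] %in% c("+", "-"))
            stop(sprintf("gene record %d ('%s'): strand must be '+' or '-'",
                         i, gr$name[i]))
        if (GenomicRanges::end(gr)[i] > refLength(ref))
            stop(sprintf("gene record %d ('%s'): end %d exceeds reference length %d",
                 i, gr$name[i], GenomicRanges::end(gr)[i], refLength(ref)))
        if (GenomicRanges::width(gr)[i] < 1L)
            stop(sprintf("gene record %d ('%s'): empty interval", i, gr$name[i]))
    }
    invisible(gr)
}

#' Read gene annotations from a BED6 file
#'
#' Intervals are validated against the reference; the BED strand column is the
#' sense strand of the gene (the transcribed strand is its opposite, see
#' [tsStrand()]). Errors name the offending record number.
#'
#' @param path path to a BED6 file (chrom, start, end, name, score, strand).
#' @param ref the [XRReference-class] the intervals live on.
#' @return a [GenomicRanges::GRanges], one range per gene, names set to the
#'   BED name column.
#' @export
readGeneBed <- function(path, ref) {
    if (!file.exists(path)) stop("gene BED file not found: ", path)
    gr <- rtracklayer::import(path, format = "BED")
    if (length(gr) == 0L) stop("gene BED file contains no records: ", path)
    if (is.null(gr$name)) gr$name <- paste0("gene", seq_along(gr))
    names(gr) <- gr$name
    .validateGenes(gr, ref)
    gr
}

#' Enumerate dipyrimidine sites on both strands
#'
#' UV photoproducts (chiefly cyclobutane pyrimidine dimers, CPDs) form at
#' adjacent pyrimidines. This enumerates every dinucleotide of the requested
#' kinds on both strands. A minus-strand site is a dinucleotide that reads as
#' the requested kind 5'->3' on the minus strand, i.e. its plus-strand bases
#' are the reverse complement (TT sites on the minus strand are AA on the
#' plus strand). For a circular reference the junction dinucleotide (last
#' base + first base) is included. N bases never form sites.
#'
#' @param ref an [XRReference-class].
#' @param kinds subset of \code{c("TT","TC","CT","CC")}.
#' @return data.frame with columns \code{pos5} (1-based plus-strand
#'   coordinate of the dinucleotide's 5' base *as read on its own strand*:
#'   the leftmost base for plus sites, the rightmost for minus sites),
#'   \code{strand}, and \code{kind}; sorted by (pos5, strand).
#' @export
enumerateDipyrimidines <- function(ref, kinds = DIPY_KINDS) {
    stopifnot(all(kinds %in% DIPY_KINDS), length(kinds) >= 1L)
    n <- refLength(ref)
    s <- .refCharExtended(ref, 1L)
    nPairs <- if (ref@topology == "circular") n else n - 1L
    if (nPairs < 1L)
        return(data.frame(pos5 = integer(0), strand = character(0),
                          kind = character(0)))
    left <- seq_len(nPairs)
    dinuc <- substring(s, left, left + 1L)
    ## plus-strand: dinucleotide read as-is; pos5 = left base
    plusHit <- dinuc %in% kinds
    ## minus-strand: kind is revcomp of the plus-strand dinucleotide;
    ## its 5' base sits at the right (larger plus coordinate) base
    rcKind <- c(AA = "TT", GA = "TC", AG = "CT", GG = "CC")[dinuc]
    minusHit <- !is.na(rcKind) & rcKind %in% kinds
    res <- rbind(
        data.frame(pos5 = left[plusHit], strand = rep("+", sum(plusHit)),
                   kind = dinuc[plusHit]),
        data.frame(pos5 = ((left[minusHit]) %% n) + 1L,
                   strand = rep("-", sum(minusHit)),
                   kind = unname(rcKind[minusHit])))
    res <- res[order(res$pos5, res$strand), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' TT strand ratio of a gene (TS/NTS)
#'
#' Ratio of the number of TT dinucleotides on the transcribed strand to the
#' number on the nontranscribed strand within the gene interval: the
#' sequence-composition baseline against which strand-resolved repair counts
#' can be interpreted. A site is counted when the plus-strand coordinate of
#' its 5' base (see [enumerateDipyrimidines()]) lies inside the interval.
#'
#' @param ref an [XRReference-class].
#' @param gene a single-range [GenomicRanges::GRanges] (sense strand in
#'   \code{strand()}).
#' @return the TS/NTS TT-count ratio (numeric scalar).
#' @export
ttStrandRatio <- function(ref, gene) {
    stopifnot(length(gene) == 1L)
    .validateGenes(gene, ref)
    sites <- enumerateDipyrimidines(ref, "TT")
    inside <- sites$pos5 >= GenomicRanges::start(gene) &
              sites$pos5 <= GenomicRanges::end(gene)
    ts <- tsStrand(gene)
    nTS <- sum(inside & sites$strand == ts)
    nNTS <- sum(inside & sites$strand != ts)
    if (nNTS == 0L)
        stop("undefined ratio: no TT sites on the nontranscribed strand")
    nTS / nNTS
}

#' Background base composition 5' of dipyrimidine sites
#'
#' Over all sites of one dipyrimidine kind on both strands, the fraction
#' whose immediately 5' neighbour (on the site's own strand) equals `base`.
#' This is the sequence-composition null for the 5'-flank preference observed
#' in excision products. Sites whose 5' neighbour falls off a linear
#' reference are excluded from the denominator.
#'
#' @param ref an [XRReference-class] of length >= 3.
#' @param kind one of \code{"TT","TC","CT","CC"}.
#' @param base the flanking base to count (\code{"A"}, \code{"C"},
#'   \code{"G"} or \code{"T"}).
#' @return fraction in \[0, 1\].
#' @export
flankBackground <- function(ref, kind, base) {
    stopifnot(refLength(ref) >= 3L, kind %in% DIPY_KINDS,
              base %in% c("A", "C", "G", "T"))
    n <- refLength(ref)
    sites <- enumerateDipyrimidines(ref, kind)
    if (nrow(sites) == 0L) stop("no ", kind, " sites on reference")
    s <- .refChar(ref)
    circ <- ref@topology == "circular"
    flank <- rep(NA_character_, nrow(sites))
    isP <- sites$strand == "+"
    ## plus-strand site at pos5 p: 5' neighbour is plus base p-1
    pPos <- sites$pos5[isP] - 1L
    if (circ) pPos <- ((pPos - 1L) %% n) + 1L
    ok <- pPos >= 1L
    flank[which(isP)[ok]] <- substring(s, pPos[ok], pPos[ok])
    ## minus-strand site at pos5 p: 5' neighbour on the minus strand is the
    ## complement of the plus base at p+1
    mPos <- sites$pos5[!isP] + 1L
    if (circ) mPos <- ((mPos - 1L) %% n) + 1L
    ok <- mPos <= n
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    flank[which(!isP)[ok]] <- comp[substring(s, mPos[ok], mPos[ok])]
    denom <- sum(!is.na(flank))
    if (denom == 0L) stop("no ", kind, " sites with a defined 5' neighbour")
    sum(flank == base, na.rm = TRUE) / denom
}
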