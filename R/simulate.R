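#' Simulation configuration for synthetic excision-product libraries
#'
#' Holds the generative model for one library: the excised-oligomer length
#' distribution, where within a read the damage dinucleotide sits, which
#' dipyrimidine kinds are damaged, per-gene transcription-coupled repair
#' (TCR) enrichment of the transcribed strand, 5'-degradation of a fraction
#' of products, PCR duplication, and the library layout (UMI length and 3'
#' adapter) shared with the trimmer.
#'
#' @slot mode \code{"prokaryote"} or \code{"eukaryote"}.
#' @slot nMolecules number of (pre-PCR) molecules to draw.
#' @slot lengthWeights named numeric, probability of each product length;
#'   must sum to 1.
#' @slot damageOffset named numeric, for each length the 1-based read
#'   position of the damage dinucleotide's 5' base.
#' @slot kindWeights named numeric over dipyrimidine kinds; must sum to 1.
#' @slot tcrEnrichment named numeric, per-gene multiplier (>= 0) applied to
#'   damage-site weights on the gene's transcribed strand.
#' @slot degradationFraction probability a product is emitted as a
#'   5'-truncated degradation fragment of length 4-11.
#' @slot pcrDupMean Poisson mean number of extra PCR copies per molecule.
#' @slot umiLength length of the random unique molecular identifier prefix.
#' @slot adapter3 3' adapter sequence appended to each insert.
#' @slot seed integer seed making the library deterministic.
#' @export
setClass("SimulationConfig",
    slots = c(mode = "character", nMolecules = "numeric",
              lengthWeights = "numeric", damageOffset = "numeric",
              kindWeights = "numeric", tcrEnrichment = "numeric",
              degradationFraction = "numeric", pcrDupMean = "numeric",
              umiLength = "numeric", adapter3 = "character",
              seed = "numeric"))

setValidity("SimulationConfig", function(object) {
    msg <- character(0)
    if (!object@mode %in% c("prokaryote", "eukaryote"))
        msg <- c(msg, "mode must be 'prokaryote' or 'eukaryote'")
    if (object@nMolecules < 0) msg <- c(msg, "nMolecules must be >= 0")
    if (abs(sum(object@lengthWeights) - 1) > 1e-9)
        msg <- c(msg, "lengthWeights must sum to 1")
    if (!all(names(object@lengthWeights) %in% names(object@damageOffset)))
        msg <- c(msg, "every length in lengthWeights needs a damageOffset")
    if (abs(sum(object@kindWeights) - 1) > 1e-9)
        msg <- c(msg, "kindWeights must sum to 1")
    if (!all(names(object@kindWeights) %in% DIPY_KINDS))
        msg <- c(msg, "kindWeights names must be dipyrimidine kinds")
    if (any(object@tcrEnrichment < 0))
        msg <- c(msg, "tcrEnrichment multipliers must be >= 0")
    if (object@degradationFraction < 0 || object@degradationFraction > 1)
        msg <- c(msg, "degradationFraction must be in [0, 1]")
    if (object@pcrDupMean < 0) msg <- c(msg, "pcrDupMean must be >= 0")
    if (object@umiLength < 0) msg <- c(msg, "umiLength must be >= 0")
    L <- as.integer(names(object@lengthWeights))
    d <- object@damageOffset[names(object@lengthWeights)]
    if (any(d < 1 | d >= L))
        msg <- c(msg, "damageOffset must satisfy 1 <= offset < length")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf("SimulationConfig (%s): %d molecules, lengths %s, UMI %d nt\n",
        object@mode, as.integer(object@nMolecules),
        paste(names(object@lengthWeights), collapse = "/"),
        as.integer(object@umiLength)))
})

## Illumina small-RNA style 3' adapter; stands in for the (configurable)
## library layout.
DEFAULT_ADAPTER3 <- "TGGAATTCTCGGGTGCCAAGG"

#' Build a simulation configuration
#'
#' Mode presets follow the biology of nucleotide excision repair: prokaryotic
#' (UvrABC) excision products are dominated by 13-mers with the damage at
#' read positions 8-9 (~85% 13-mers, ~10% 14-mers with the dimer at 9-10,
#' ~5% 12-mers), with an 8-nt UMI in the adapter; eukaryotic products are
#' 24-30 nt peaking at 26-27 with the dimer ~7 nt from the 3' end (a 26-mer
#' carries it at positions 19-20), without a UMI.
#'
#' @param mode \code{"prokaryote"} (default) or \code{"eukaryote"}.
#' @param nMolecules number of molecules before PCR duplication.
#' @param tcrEnrichment named numeric, per-gene transcribed-strand weight
#'   multiplier (name = gene name); genes not listed get 1.
#' @param lengthWeights,damageOffset,kindWeights,degradationFraction,pcrDupMean,umiLength,adapter3
#'   override the mode preset (see [SimulationConfig-class]).
#' @param seed integer seed.
#' @return a validated [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig("prokaryote", nMolecules = 1000, seed = 7)
#' @export
simulationConfig <- function(mode = c("prokaryote", "eukaryote"),
        nMolecules = 10000, tcrEnrichment = numeric(0),
        lengthWeights = NULL, damageOffset = NULL, kindWeights = NULL,
        degradationFraction = 0.05, pcrDupMean = 1,
        umiLength = NULL, adapter3 = DEFAULT_ADAPTER3, seed = 1) {
    mode <- match.arg(mode)
    if (mode == "prokaryote") {
        if (is.null(lengthWeights))
            lengthWeights <- c("12" = 0.05, "13" = 0.85, "14" = 0.10)
        if (is.null(damageOffset))
            damageOffset <- c("12" = 8, "13" = 8, "14" = 9)
        if (is.null(kindWeights)) kindWeights <- c(TT = 1)
        if (is.null(umiLength)) umiLength <- 8
    } else {
        if (is.null(lengthWeights))
            lengthWeights <- c("24" = 0.04, "25" = 0.13, "26" = 0.30,
                               "27" = 0.27, "28" = 0.13, "29" = 0.08,
                               "30" = 0.05)
        if (is.null(damageOffset)) {
            L <- as.integer(names(lengthWeights))
            damageOffset <- stats::setNames(L - 7, names(lengthWeights))
        }
        if (is.null(kindWeights)) kindWeights <- c(TT = 1)
        if (is.null(umiLength)) umiLength <- 0
    }
    new("SimulationConfig", mode = mode, nMolecules = nMolecules,
        lengthWeights = lengthWeights, damageOffset = damageOffset,
        kindWeights = kindWeights, tcrEnrichment = tcrEnrichment,
        degradationFraction = degradationFraction, pcrDupMean = pcrDupMean,
        umiLength = umiLength, adapter3 = adapter3, seed = seed)
}

#' Damage-site sampling weights
#'
#' Enumerates the eligible dipyrimidine sites of the configured kinds and
#' assigns each a sampling weight: the kind's weight, multiplied by the
#' gene's TCR enrichment factor when the site lies on that gene's
#' transcribed strand inside the gene interval. Weights are normalised to
#' sum to 1. This is where strand-asymmetric (transcription-coupled) repair
#' enters the generative model.
#'
#' @param ref an [XRReference-class].
#' @param genes gene [GenomicRanges::GRanges] (may be empty).
#' @param config a [SimulationConfig-class].
#' @return data.frame with the [enumerateDipyrimidines()] columns plus
#'   \code{weight}.
#' @export
siteWeightTable <- function(ref, genes, config) {
    kinds <- names(config@kindWeights)
    sites <- enumerateDipyrimidines(ref, kinds)
    if (nrow(sites) == 0L)
        stop("no eligible dipyrimidine sites on reference '", refName(ref), "'")
    w <- unname(config@kindWeights[sites$kind])
    if (length(genes)) .validateGenes(genes, ref)
    for (i in seq_along(genes)) {
        g <- genes[i]
        e <- config@tcrEnrichment[g$name]
        if (is.na(e) || e == 1) next
        hit <- sites$strand == tsStrand(g) &
               sites$pos5 >= GenomicRanges::start(g) &
               sites$pos5 <= GenomicRanges::end(g)
        w[hit] <- w[hit] * e
    }
    tot <- sum(w)
    if (tot <= 0) stop("all site weights are zero")
    sites$weight <- w / tot
    sites
}

.randomBases <- function(n, len) {
    if (n == 0L || len == 0L) return(rep("", n))
    m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
                nrow = n)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Simulate excision products with ground truth
#'
#' Draws \code{nMolecules} damage sites from [siteWeightTable()], a product
#' length for each, places the product so the damage dinucleotide's 5' base
#' sits at the configured offset (1-based within the read, 5'->3' on the
#' damaged strand), and extracts the insert sequence. A configured fraction
#' of products is emitted as 5'-truncated nucleolytic degradation fragments
#' (uniform length 4-11, keeping the 3' end). Placements that would run off
#' a linear reference are resampled (counted in
#' \code{attr(, "resampled")}); circular references wrap. Deterministic
#' under \code{config@seed}.
#'
#' @inheritParams siteWeightTable
#' @return list with \code{inserts} (character vector) and \code{truth}
#'   (data.frame: read_id, start, strand, length, gene, damage_pos,
#'   degraded, is_pcr_duplicate, parent_id; coordinates 1-based).
#' @export
simulateExcisionProducts <- function(ref, genes, config) {
    set.seed(config@seed)
    .simulateProductsNoSeed(ref, genes, config)
}

.simulateProductsNoSeed <- function(ref, genes, config) {
    n <- as.integer(config@nMolecules)
    if (n == 0L)
        return(list(inserts = character(0), truth = .emptyTruth()))
    swt <- siteWeightTable(ref, genes, config)
    refLen <- refLength(ref)
    circ <- refTopology(ref) == "circular"
    maxL <- max(as.integer(names(config@lengthWeights)))
    sExt <- .refCharExtended(ref, maxL)

    idx <- sample.int(nrow(swt), n, replace = TRUE, prob = swt$weight)
    L <- as.integer(sample(names(config@lengthWeights), n, replace = TRUE,
                           prob = config@lengthWeights))
    resampled <- 0L
    repeat {
        d <- as.integer(config@damageOffset[as.character(L)])
        pos5 <- swt$pos5[idx]
        strand <- swt$strand[idx]
        ## damage 5' base at read position d:
        ##   plus  strand: start = pos5 - d + 1
        ##   minus strand: pos5 = start + L - d  =>  start = pos5 - L + d
        start <- ifelse(strand == "+", pos5 - d + 1L, pos5 - L + d)
        if (circ) {
            start <- ((start - 1L) %% refLen) + 1L
            bad <- rep(FALSE, n)
        } else {
            bad <- start < 1L | start + L - 1L > refLen
        }
        if (!any(bad)) break
        resampled <- resampled + sum(bad)
        idx[bad] <- sample.int(nrow(swt), sum(bad), replace = TRUE,
                               prob = swt$weight)
        L[bad] <- as.integer(sample(names(config@lengthWeights), sum(bad),
                             replace = TRUE, prob = config@lengthWeights))
    }
    inserts <- substring(sExt, start, start + L - 1L)
    isM <- strand == "-"
    if (any(isM)) inserts[isM] <- .revcompChar(inserts[isM])

    ## 5'-truncated degradation fragments: keep the 3' end
    degraded <- stats::runif(n) < config@degradationFraction
    tlen <- L
    if (any(degraded)) {
        t <- sample(4:11, sum(degraded), replace = TRUE)
        t <- pmin(t, L[degraded] - 1L)
        inserts[degraded] <- substring(inserts[degraded],
                                       L[degraded] - t + 1L)
        tlen[degraded] <- t
        ## insert start on the plus strand moves only for + reads
        shift <- L[degraded] - t
        isP <- strand[degraded] == "+"
        startDeg <- start[degraded]
        startDeg[isP] <- startDeg[isP] + shift[isP]
        if (circ) startDeg <- ((startDeg - 1L) %% refLen) + 1L
        start[degraded] <- startDeg
    }

    gene <- rep(NA_character_, n)
    for (i in seq_along(genes)) {
        g <- genes[i]
        hit <- swt$pos5[idx] >= GenomicRanges::start(g) &
               swt$pos5[idx] <= GenomicRanges::end(g)
        gene[hit] <- g$name
    }
    truth <- data.frame(
        read_id = sprintf("mol%07d", seq_len(n)),
        start = start, strand = strand, length = tlen, gene = gene,
        damage_pos = swt$pos5[idx], degraded = degraded,
        is_pcr_duplicate = FALSE, parent_id = NA_character_,
        stringsAsFactors = FALSE)
    attr(truth, "resampled") <- resampled
    list(inserts = inserts, truth = truth)
}

.emptyTruth <- function() {
    data.frame(read_id = character(0), start = integer(0),
               strand = character(0), length = integer(0),
               gene = character(0), damage_pos = integer(0),
               degraded = logical(0), is_pcr_duplicate = logical(0),
               parent_id = character(0), stringsAsFactors = FALSE)
}

#' Ligate UMI and 3' adapter onto inserts
#'
#' Raw read = random UMI prefix (\code{umiLength} bases, independent per
#' molecule) + insert + 3' adapter. Uses the current RNG stream (seed once
#' per library, e.g. via [simulateLibrary()]).
#'
#' @param inserts character vector of insert sequences.
#' @param config a [SimulationConfig-class].
#' @return list with \code{reads} and \code{umi} character vectors.
#' @export
attachAdaptersAndUmi <- function(inserts, config) {
    umi <- .randomBases(length(inserts), as.integer(config@umiLength))
    list(reads = paste0(umi, inserts, config@adapter3), umi = umi)
}

#' Apply PCR duplication
#'
#' Each molecule gains k extra byte-identical copies, k ~
#' Poisson(\code{pcrDupMean}). Duplicates are flagged in the truth table with
#' their parent read id. Uses the current RNG stream.
#'
#' @param reads character vector of raw reads.
#' @param truth truth data.frame as from [simulateExcisionProducts()].
#' @param config a [SimulationConfig-class].
#' @return list with expanded \code{reads} and \code{truth}.
#' @export
applyPcrDuplication <- function(reads, truth, config) {
    if (config@pcrDupMean == 0 || length(reads) == 0L)
        return(list(reads = reads, truth = truth))
    k <- stats::rpois(length(reads), config@pcrDupMean)
    idx <- rep(seq_along(reads), k + 1L)
    within <- sequence(k + 1L)
    truth2 <- truth[idx, , drop = FALSE]
    truth2$is_pcr_duplicate <- within > 1L
    truth2$parent_id <- ifelse(within > 1L, truth$read_id[idx],
                               NA_character_)
    truth2$read_id <- ifelse(within > 1L,
        paste0(truth$read_id[idx], ".d", within - 1L), truth$read_id[idx])
    rownames(truth2) <- NULL
    list(reads = reads[idx], truth = truth2)
}

#' Simulate a full library (products + UMI/adapters + PCR)
#'
#' Seeds the RNG once from \code{config@seed}, then runs
#' [simulateExcisionProducts()], [attachAdaptersAndUmi()] and
#' [applyPcrDuplication()], so the whole library is reproducible.
#'
#' @inheritParams siteWeightTable
#' @return list with \code{reads} (named character vector of raw reads,
#'   names = read ids) and \code{truth} (data.frame including \code{umi}).
#' @export
simulateLibrary <- function(ref, genes, config) {
    set.seed(config@seed)
    prod <- .simulateProductsNoSeed(ref, genes, config)
    lig <- attachAdaptersAndUmi(prod$inserts, config)
    prod$truth$umi <- lig$umi
    prod$truth$insert <- prod$inserts
    dup <- applyPcrDuplication(lig$reads, prod$truth, config)
    reads <- dup$reads
    names(reads) <- dup$truth$read_id
    list(reads = reads, truth = dup$truth)
}

.writeFastq <- function(reads, path, qualChar = "I") {
    x <- Biostrings::DNAStringSet(unname(reads))
    names(x) <- names(reads)
    q <- Biostrings::BStringSet(strrep(qualChar, nchar(reads)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
    invisible(path)
}

#' Simulate an mfd+/mfd- library pair
#'
#' Generates two libraries differing only in their per-gene
#' transcribed-strand enrichment maps — emulating a transcription-repair
#' coupling factor proficient (mfd+) versus deficient (mfd-) experiment —
#' and writes each as FASTQ (constant Q40 qualities) plus a ground-truth
#' TSV. The two libraries use distinct seeds derived from
#' \code{config@seed}; read ids carry no truth information.
#'
#' @inheritParams siteWeightTable
#' @param ePlus,eMinus named numeric TCR enrichment maps for the two
#'   libraries (default: all genes at 1).
#' @param outDir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return list with paths \code{fastq_plus}, \code{fastq_minus},
#'   \code{truth_plus}, \code{truth_minus} and the two truth data.frames.
#' @export
simulateExperimentPair <- function(ref, genes, config,
        ePlus = numeric(0), eMinus = numeric(0),
        outDir = tempdir(), prefix = "lib") {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    cfgP <- config; cfgP@tcrEnrichment <- ePlus
    cfgP@seed <- (config@seed * 2 + 1) %% 2147483647
    cfgM <- config; cfgM@tcrEnrichment <- eMinus
    cfgM@seed <- (config@seed * 2 + 2) %% 2147483647
    libP <- simulateLibrary(ref, genes, cfgP)
    libM <- simulateLibrary(ref, genes, cfgM)
    paths <- list(
        fastq_plus = file.path(outDir, paste0(prefix, "_mfdplus.fastq")),
        fastq_minus = file.path(outDir, paste0(prefix, "_mfdminus.fastq")),
        truth_plus = file.path(outDir, paste0(prefix, "_mfdplus.truth.tsv")),
        truth_minus = file.path(outDir, paste0(prefix, "_mfdminus.truth.tsv")))
    .writeFastq(libP$reads, paths$fastq_plus)
    .writeFastq(libM$reads, paths$fastq_minus)
    utils::write.table(libP$truth, paths$truth_plus, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(libM$truth, paths$truth_minus, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    c(paths, list(truthPlus = libP$truth, truthMinus = libM$truth))
}

#' Synthetic plasmid reference
#'
#' A seeded random-composition reference standing in for a plasmid substrate
#' in simulations; synthetic — it has no biological sequence content.
#'
#' @param length reference length in nt.
#' @param name reference name.
#' @param topology \code{"circular"} (default, as for a plasmid) or
#'   \code{"linear"}.
#' @param seed integer seed.
#' @param gc GC content of the random sequence.
#' @return an [XRReference-class].
#' @export
syntheticReference <- function(length = 7000, name = "plasmid",
        topology = "circular", seed = 1, gc = 0.5) {
    set.seed(seed)
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    XRReference(name,
        paste(sample(names(p), length, replace = TRUE, prob = p),
              collapse = ""),
        topology = topology)
}
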