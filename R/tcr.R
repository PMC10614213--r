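#' Count damage reads per gene and strand
#'
#' A read is assigned to a gene when its damage-site coordinate (see
#' [damageSitePositions()]) lies inside the gene interval. Reads on the
#' gene's transcribed strand (the strand opposite the annotated sense
#' strand) increment \code{ts_count}, all others \code{nts_count}. A read
#' may count toward several overlapping genes.
#'
#' @param alignments damage-filtered alignment GRanges.
#' @param spec the [DamageFilterSpec-class] (for the damage-site
#'   coordinate).
#' @param genes gene [GenomicRanges::GRanges].
#' @return data.frame with \code{gene}, \code{ts_count}, \code{nts_count},
#'   one row per gene in input order.
#' @export
countByGene <- function(alignments, spec, genes) {
    pos <- damageSitePositions(alignments, spec)
    st <- as.character(GenomicRanges::strand(alignments))
    ts <- tsStrand(genes)
    out <- data.frame(gene = genes$name,
                      ts_count = integer(length(genes)),
                      nts_count = integer(length(genes)),
                      stringsAsFactors = FALSE)
    for (i in seq_along(genes)) {
        inside <- pos >= GenomicRanges::start(genes)[i] &
                  pos <= GenomicRanges::end(genes)[i]
        out$ts_count[i] <- sum(inside & st == ts[i])
        out$nts_count[i] <- sum(inside & st != ts[i])
    }
    out
}

#' TS/NTS repair ratio
#'
#' @param counts data.frame with \code{ts_count} and \code{nts_count}
#'   (as from [countByGene()]).
#' @return numeric vector of ts/nts ratios; \code{NA} (with a warning)
#'   where the NTS count is zero, since the ratio is then undefined.
#' @export
tsNtsRatio <- function(counts) {
    r <- ifelse(counts$nts_count > 0,
                counts$ts_count / counts$nts_count, NA_real_)
    if (anyNA(r))
        warning("undefined ratio: zero NTS count; reported as NA")
    r
}

#' Transcription-coupled repair (TCR) ratio of ratios
#'
#' TCR is defined as the TS/NTS repair ratio in the coupling-factor
#' proficient (mfd+) library divided by the TS/NTS ratio in the deficient
#' (mfd-) library; TCR > 1 indicates Mfd-dependent transcription-coupled
#' repair.
#'
#' @param ratioPlus,ratioMinus TS/NTS ratios of the two libraries
#'   (vectorised).
#' @return numeric vector; \code{NA} (with a warning) where
#'   \code{ratioMinus} is non-positive or missing. Full precision is
#'   retained; round only for display.
#' @examples
#' tcrRatio(1.63, 0.66)   # ~2.47
#' @export
tcrRatio <- function(ratioPlus, ratioMinus) {
    bad <- !is.finite(ratioMinus) | ratioMinus <= 0
    r <- ifelse(bad, NA_real_, ratioPlus / ratioMinus)
    if (any(bad))
        warning("undefined TCR: mfd- ratio non-positive or NA")
    r
}

#' TCR from strand counts of both libraries
#'
#' Equals \code{tcrRatio(tsNtsRatio(plus), tsNtsRatio(minus))};
#' algebraically the cross-ratio
#' (ts+ x nts-) / (nts+ x ts-). Zero denominators give NA fields.
#'
#' @param countsPlus,countsMinus data.frames from [countByGene()] for the
#'   mfd+ and mfd- libraries (matched by \code{gene}).
#' @return data.frame with \code{gene}, \code{ratio_plus},
#'   \code{ratio_minus}, \code{tcr}.
#' @export
tcrFromCounts <- function(countsPlus, countsMinus) {
    m <- match(countsPlus$gene, countsMinus$gene)
    if (anyNA(m)) stop("gene sets of the two libraries differ")
    cm <- countsMinus[m, , drop = FALSE]
    rp <- suppressWarnings(tsNtsRatio(countsPlus))
    rm <- suppressWarnings(tsNtsRatio(cm))
    data.frame(gene = countsPlus$gene, ratio_plus = rp, ratio_minus = rm,
               tcr = suppressWarnings(tcrRatio(rp, rm)),
               stringsAsFactors = FALSE)
}

#' Optional TT-frequency normalization
#'
#' Divides each library's TS/NTS repair ratio by the gene's TT strand ratio
#' (see [ttStrandRatio()]), expressing repair per potential CPD site. The
#' TCR ratio-of-ratios is unchanged: the normalization cancels exactly.
#' Off by default in reports.
#'
#' @param result data.frame from [tcrFromCounts()].
#' @param ref an [XRReference-class].
#' @param genes gene GRanges covering the genes in \code{result}.
#' @return \code{result} with added \code{tt_ratio},
#'   \code{ratio_plus_ttnorm}, \code{ratio_minus_ttnorm} columns.
#' @export
normalizeByTt <- function(result, ref, genes) {
    idx <- match(result$gene, genes$name)
    if (anyNA(idx)) stop("gene(s) missing from annotation: ",
                         paste(result$gene[is.na(idx)], collapse = ", "))
    ttr <- vapply(idx, function(i) ttStrandRatio(ref, genes[i]), numeric(1))
    result$tt_ratio <- ttr
    result$ratio_plus_ttnorm <- result$ratio_plus / ttr
    result$ratio_minus_ttnorm <- result$ratio_minus / ttr
    result
}

#' Format and write the per-gene TCR report table
#'
#' Columns: gene, TS/NTS in mfd+, TS/NTS in mfd-, TCR; values rounded to
#' two decimals for display (full precision stays in the input), \code{NA}
#' where undefined, rows in input order.
#'
#' @param results data.frame from [tcrFromCounts()].
#' @param path optional TSV output path.
#' @return the formatted data.frame (invisibly if \code{path} is given).
#' @export
reportTable <- function(results, path = NULL) {
    fmt <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.2f", x))
    out <- data.frame(gene = results$gene,
                      ts_nts_mfd_plus = fmt(results$ratio_plus),
                      ts_nts_mfd_minus = fmt(results$ratio_minus),
                      tcr = fmt(results$tcr), stringsAsFactors = FALSE)
    if (!is.null(path)) {
        utils::write.table(out, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        return(invisible(out))
    }
    out
}

#' Seeded bootstrap confidence interval for a gene's TCR
#'
#' Resamples reads (with replacement) within each library and recomputes
#' the TCR ratio-of-ratios, giving a percentile interval.
#'
#' @param alignmentsPlus,alignmentsMinus damage-filtered alignment GRanges
#'   of the two libraries.
#' @param spec the [DamageFilterSpec-class].
#' @param gene a single-range gene GRanges.
#' @param B number of bootstrap replicates.
#' @param level confidence level.
#' @param seed integer seed.
#' @return named numeric: \code{tcr}, \code{lower}, \code{upper}.
#' @export
tcrBootstrap <- function(alignmentsPlus, alignmentsMinus, spec, gene,
                         B = 200L, level = 0.95, seed = 1L) {
    set.seed(seed)
    point <- tcrFromCounts(countByGene(alignmentsPlus, spec, gene),
                           countByGene(alignmentsMinus, spec, gene))$tcr
    reps <- vapply(seq_len(B), function(b) {
        ap <- alignmentsPlus[sample.int(length(alignmentsPlus),
                                        replace = TRUE)]
        am <- alignmentsMinus[sample.int(length(alignmentsMinus),
                                         replace = TRUE)]
        suppressWarnings(tcrFromCounts(countByGene(ap, spec, gene),
                                       countByGene(am, spec, gene))$tcr)
    }, numeric(1))
    qs <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                          na.rm = TRUE)
    c(tcr = point, lower = unname(qs[1]), upper = unname(qs[2]))
}
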