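#' Benchmark a call set against a truth set
#'
#' Genotype-aware comparison over the analysis region (the supplied regions
#' intersected with the truth set's confident regions). Calls and truth are
#' both atomically decomposed, so an MNV and its component SNVs count
#' identically on either side. Under the default strict mode a call matching
#' a truth allele but with the wrong zygosity counts as a false positive
#' (and the truth entry as a false negative); \code{gtMode = "allele"}
#' matches on the allele alone. True negatives are the analysis-region bases
#' not occupied by any TP/FP/FN position, computed over all strata and
#' repeated per stratum row.
#'
#' @param x Calls: a \linkS4class{CallSet}, \linkS4class{CombinedCallSet}, or
#'   GRanges with \code{ref}/\code{alt}/\code{zygosity} columns.
#' @param truth A \linkS4class{TruthSet}.
#' @param regions Optional GRanges further restricting the analysis.
#' @param gtMode "strict" (allele + zygosity) or "allele".
#' @return A \code{data.frame} with rows SNV/INDEL/ALL and columns
#'   \code{tp}, \code{fp}, \code{fn}, \code{tn}; the analysis-region size is
#'   attached as \code{attr(, "regionBases")}.
#' @export
compareToTruth <- function(x, truth, regions = NULL,
        gtMode = c("strict", "allele")) {
    gtMode <- match.arg(gtMode)
    analysis <- if (is.null(regions)) confidentRegions(truth) else
        intersectRegions(regions, confidentRegions(truth))
    bases <- totalBases(analysis)
    if (bases == 0)
        stop("empty analysis region (regions do not intersect the confident regions)")
    ct <- if (methods::is(x, "CombinedCallSet")) {
        gr <- calls(x); mc <- S4Vectors::mcols(gr)
        data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
            pos = GenomicRanges::start(gr), ref = mc$ref, alt = mc$alt,
            zygosity = ifelse(is.na(mc$zygosityA), mc$zygosityB, mc$zygosityA),
            stringsAsFactors = FALSE)
    } else callTable(x)
    tt <- callTable(calls(truth))
    ct <- restrictTable(decomposeMnv(ct), analysis)
    tt <- restrictTable(decomposeMnv(tt), analysis)
    keyFun <- if (gtMode == "strict") {
        function(d) genotypeKey(d$chrom, d$pos, d$ref, d$alt, d$zygosity)
    } else {
        function(d) variantKey(d$chrom, d$pos, d$ref, d$alt)
    }
    ct <- ct[!duplicated(keyFun(ct)), , drop = FALSE]
    tt <- tt[!duplicated(keyFun(tt)), , drop = FALSE]
    kc <- keyFun(ct)
    kt <- keyFun(tt)
    isTp <- kc %in% kt
    isFn <- !(kt %in% kc)
    strat <- function(cls) {
        ci <- ct$vclass %in% cls
        ti <- tt$vclass %in% cls
        c(tp = sum(isTp & ci), fp = sum(!isTp & ci), fn = sum(isFn & ti))
    }
    res <- rbind(SNV = strat("SNV"), INDEL = strat("INDEL"),
        ALL = strat(c("SNV", "INDEL", "MNV")))
    usedPos <- unique(c(paste(ct$chrom, ct$pos), paste(tt$chrom[isFn], tt$pos[isFn])))
    tn <- bases - length(usedPos)
    out <- data.frame(stratum = rownames(res), tp = res[, "tp"],
        fp = res[, "fp"], fn = res[, "fn"], tn = tn, row.names = NULL,
        stringsAsFactors = FALSE)
    attr(out, "regionBases") <- bases
    out
}

#' Derive sensitivity, FP/Mb and PPV from confusion counts
#'
#' Sensitivity = 100 * TP/(TP+FN); false positives per megabase =
#' FP / (region bases / 1e6); PPV = 100 * TP/(TP+FP). Undefined ratios (0/0)
#' are NA, never 0 or 100.
#'
#' @param counts Output of \code{\link{compareToTruth}}, or any data.frame
#'   with \code{tp}, \code{fp}, \code{fn} columns.
#' @param regionBases Analysis-region size in bases; defaults to the
#'   attribute \code{compareToTruth} attaches.
#' @return \code{counts} with \code{sensitivity_pct}, \code{fp_per_mb} and
#'   \code{ppv_pct} columns added.
#' @export
computeMetrics <- function(counts, regionBases = attr(counts, "regionBases")) {
    if (is.null(regionBases) || is.na(regionBases) || regionBases <= 0)
        stop("regionBases must be a positive number")
    counts$sensitivity_pct <- ifelse(counts$tp + counts$fn > 0,
        100 * counts$tp / (counts$tp + counts$fn), NA_real_)
    counts$fp_per_mb <- counts$fp / (regionBases / 1e6)
    counts$ppv_pct <- ifelse(counts$tp + counts$fp > 0,
        100 * counts$tp / (counts$tp + counts$fp), NA_real_)
    counts
}

#' Share-of-total and PPV per confidence category
#'
#' The computation behind the per-category report: each category's share of
#' all emitted calls and its positive predictive value from its FP/TP
#' counts.
#'
#' @param counts A \code{data.frame} with columns \code{category}, \code{fp},
#'   \code{tp}.
#' @return The input with \code{n}, \code{share_pct}, \code{ppv_pct} and
#'   formatted \code{share_fmt}/\code{ppv_fmt} columns (shares to one
#'   decimal; PPVs per \code{\link{formatPct}}).
#' @export
categoryTable <- function(counts) {
    counts$n <- counts$fp + counts$tp
    total <- sum(counts$n)
    counts$share_pct <- if (total > 0) 100 * counts$n / total else NA_real_
    counts$ppv_pct <- ifelse(counts$n > 0, 100 * counts$tp / counts$n, NA_real_)
    counts$share_fmt <- sprintf("%.1f", roundHalfUp(counts$share_pct, 1L))
    counts$ppv_fmt <- formatPct(counts$ppv_pct)
    counts
}

#' Per-category PPV of a combined call set against a truth set
#'
#' Classified calls are restricted to the analysis region (regions
#' intersected with the truth confident regions); within it, every call
#' matching a truth entry (allele and zygosity under strict mode) is a TP,
#' anything else an FP, giving one PPV per confidence category plus its
#' share of the total.
#'
#' @param ccs A \linkS4class{CombinedCallSet}.
#' @param truth A \linkS4class{TruthSet}.
#' @param regions Optional GRanges.
#' @param gtMode "strict" or "allele".
#' @return A \code{data.frame} with one row per category (see
#'   \code{\link{categoryTable}}).
#' @export
ppvByCategory <- function(ccs, truth, regions = NULL,
        gtMode = c("strict", "allele")) {
    gtMode <- match.arg(gtMode)
    analysis <- if (is.null(regions)) confidentRegions(truth) else
        intersectRegions(regions, confidentRegions(truth))
    gr <- calls(ccs)
    mc <- S4Vectors::mcols(gr)
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
        pos = GenomicRanges::start(gr), ref = mc$ref, alt = mc$alt,
        zygosity = ifelse(is.na(mc$zygosityA), mc$zygosityB, mc$zygosityA),
        category = mc$category, stringsAsFactors = FALSE)
    df <- restrictTable(df, analysis)
    tt <- decomposeMnv(callTable(calls(truth)))
    tkey <- if (gtMode == "strict")
        genotypeKey(tt$chrom, tt$pos, tt$ref, tt$alt, tt$zygosity) else
        variantKey(tt$chrom, tt$pos, tt$ref, tt$alt)
    ckey <- if (gtMode == "strict")
        genotypeKey(df$chrom, df$pos, df$ref, df$alt, df$zygosity) else
        variantKey(df$chrom, df$pos, df$ref, df$alt)
    isTp <- ckey %in% tkey
    counts <- data.frame(category = CATEGORY_LEVELS,
        fp = vapply(CATEGORY_LEVELS, function(k)
            sum(df$category == k & !isTp), integer(1L)),
        tp = vapply(CATEGORY_LEVELS, function(k)
            sum(df$category == k & isTp), integer(1L)),
        row.names = NULL, stringsAsFactors = FALSE)
    categoryTable(counts)
}

#' Restrict a truth set to a subset of variants
#'
#' Used for restricted-sensitivity analyses (e.g. rare variants only): the
#' truth calls are intersected with the subset while the confident regions
#' are left unchanged.
#'
#' @param truth A \linkS4class{TruthSet}.
#' @param subset Canonical variants: a GRanges or data.frame with
#'   \code{chrom}/\code{pos}/\code{ref}/\code{alt}, or a character vector of
#'   \code{chrom:pos:ref:alt} keys.
#' @return A \linkS4class{TruthSet}.
#' @export
restrictTruth <- function(truth, subset) {
    keys <- if (is.character(subset)) subset
    else if (is.data.frame(subset))
        variantKey(subset$chrom, subset$pos, subset$ref, subset$alt)
    else {
        mc <- S4Vectors::mcols(subset)
        variantKey(as.character(GenomicRanges::seqnames(subset)),
            GenomicRanges::start(subset), mc$ref, mc$alt)
    }
    gr <- calls(truth)
    mc <- S4Vectors::mcols(gr)
    own <- variantKey(as.character(GenomicRanges::seqnames(gr)),
        GenomicRanges::start(gr), mc$ref, mc$alt)
    new("TruthSet", calls = gr[own %in% keys],
        confidentRegions = confidentRegions(truth),
        versionLabel = paste0(truth@versionLabel, " (subset)"))
}
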