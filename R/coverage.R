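#' GC fraction of intervals
#'
#' (G+C)/(A+C+G+T) over each interval; ambiguous bases (N etc.) are excluded
#' from the denominator, and an interval with no unambiguous base is NA.
#'
#' @param intervals GRanges (1-based closed).
#' @param reference Named DNAStringSet of contig sequences.
#' @return Numeric vector in [0, 1] (or NA), one value per interval.
#' @export
computeGc <- function(intervals, reference) {
    if (!methods::is(reference, "DNAStringSet"))
        reference <- Biostrings::DNAStringSet(reference)
    ctg <- as.character(GenomicRanges::seqnames(intervals))
    if (!all(ctg %in% names(reference)))
        stop("interval contigs absent from the reference")
    seqs <- Biostrings::DNAStringSet(lapply(seq_along(intervals), function(i)
        Biostrings::subseq(reference[[ctg[i]]],
            GenomicRanges::start(intervals)[i], GenomicRanges::end(intervals)[i])))
    freq <- Biostrings::letterFrequency(seqs, c("A", "C", "G", "T"))
    denom <- rowSums(freq)
    gc <- (freq[, "G"] + freq[, "C"]) / denom
    gc[denom == 0] <- NA_real_
    gc
}

#' Pad exon intervals by a flank
#'
#' Analytic exome regions commonly include a few bases of flank on each side
#' of every coding exon so that splice-site variants are captured; this
#' helper widens a BED-derived GRanges accordingly (it is not applied
#' implicitly anywhere).
#'
#' @param exons GRanges.
#' @param flank Bases added on both sides (default 10).
#' @return The widened GRanges (start floored at 1).
#' @export
padExons <- function(exons, flank = 10L) {
    GenomicRanges::start(exons) <- pmax(1L, GenomicRanges::start(exons) - as.integer(flank))
    GenomicRanges::end(exons) <- GenomicRanges::end(exons) + as.integer(flank)
    exons
}

#' Per-exon raw and normalized mean depth for one platform
#'
#' The exome-wide mean is the exon-base-weighted average depth over all exon
#' bases; each exon's mean depth is then scaled by
#' \code{targetMean / exome-wide mean} (one global scalar per platform, not
#' per chromosome), so the base-weighted mean of the normalized depths equals
#' \code{targetMean}. Zero stays zero here; mapping zeros to 1 for log
#' plotting is a separate export-side step.
#'
#' @param exonsGr GRanges of exons.
#' @param track A \linkS4class{CoverageTrack}.
#' @param targetMean Normalization target (default 100).
#' @return A \code{data.frame} with \code{raw} and \code{norm} per-exon mean
#'   depths; the scale factor is attached as \code{attr(, "scale")}.
#' @export
normalizeDepths <- function(exonsGr, track, targetMean = 100) {
    raw <- meanDepth(track, exonsGr)
    w <- GenomicRanges::width(exonsGr)
    exomeMean <- sum(raw * w) / sum(w)
    if (!is.finite(exomeMean) || exomeMean <= 0)
        stop("exome-wide mean depth is zero; cannot normalize")
    sc <- targetMean / exomeMean
    out <- data.frame(raw = raw, norm = raw * sc)
    attr(out, "scale") <- sc
    out
}

#' Per-exon coverage comparison between two platforms
#'
#' Computes per-exon mean depth for both platforms, normalizes each platform
#' to a common exome-wide mean, adds a log-plot depth column with zeros
#' mapped to 1 (plot/export only; thresholds always use the true normalized
#' depth), and optionally the per-exon GC fraction.
#'
#' @param exonsGr GRanges of exons (include flanks beforehand if desired,
#'   see \code{\link{padExons}}).
#' @param trackA,trackB \linkS4class{CoverageTrack}s.
#' @param reference Optional named DNAStringSet; when supplied a \code{gc}
#'   column is computed.
#' @param targetMean Normalization target (default 100).
#' @return The exon GRanges with metadata columns \code{exon_id}, \code{gc}
#'   (if available), \code{raw_A}, \code{raw_B}, \code{norm_A},
#'   \code{norm_B}, \code{plot_A}, \code{plot_B}.
#' @export
exonCoverage <- function(exonsGr, trackA, trackB, reference = NULL,
        targetMean = 100) {
    dA <- normalizeDepths(exonsGr, trackA, targetMean)
    dB <- normalizeDepths(exonsGr, trackB, targetMean)
    mc <- S4Vectors::DataFrame(
        exon_id = if (!is.null(names(exonsGr)) && all(nzchar(names(exonsGr))))
            names(exonsGr) else sprintf("exon_%06d", seq_along(exonsGr)),
        gc = if (is.null(reference)) NA_real_ else computeGc(exonsGr, reference),
        raw_A = dA$raw, raw_B = dB$raw,
        norm_A = dA$norm, norm_B = dB$norm,
        plot_A = pmax(dA$norm, 1), plot_B = pmax(dB$norm, 1))
    out <- GenomicRanges::granges(exonsGr)
    S4Vectors::mcols(out) <- mc
    out
}

#' Quadrant counts of exons by per-platform coverage
#'
#' Classifies every exon by whether each platform's normalized mean depth
#' reaches the threshold, yielding the four quadrants of the cross-platform
#' coverage scatter: both platforms at or above threshold, A only, B only,
#' neither.
#'
#' @param ec Output of \code{\link{exonCoverage}}.
#' @param threshold Depth threshold (default 20).
#' @return A \code{data.frame} with rows \code{both_ge}, \code{a_only},
#'   \code{b_only}, \code{neither}: counts, percentages of total, and
#'   one-decimal formatted percentages.
#' @export
quadrantCounts <- function(ec, threshold = 20) {
    mc <- S4Vectors::mcols(ec)
    a <- mc$norm_A >= threshold
    b <- mc$norm_B >= threshold
    n <- c(both_ge = sum(a & b), a_only = sum(a & !b),
        b_only = sum(!a & b), neither = sum(!a & !b))
    total <- length(ec)
    data.frame(quadrant = names(n), count = as.integer(n),
        pct = if (total) 100 * as.integer(n) / total else NA_real_,
        pct_fmt = sprintf("%.1f", roundHalfUp(100 * as.integer(n) / max(total, 1L), 1L)),
        row.names = NULL, stringsAsFactors = FALSE)
}

#' Low-coverage exon counts per GC bin per platform
#'
#' Histograms the exons whose normalized depth is below the threshold, per
#' platform, over GC-content bins covering [0, 1] (right-open except the
#' last bin, so GC = 1 lands in the final bin).
#'
#' @param ec Output of \code{\link{exonCoverage}} with a \code{gc} column.
#' @param threshold Depth threshold (default 20).
#' @param binWidth GC bin width (default 0.05).
#' @return A \code{data.frame} with \code{gc_low}, \code{gc_high},
#'   \code{low_A}, \code{low_B} per bin.
#' @export
gcBinLowCoverage <- function(ec, threshold = 20, binWidth = 0.05) {
    mc <- S4Vectors::mcols(ec)
    gc <- mc$gc
    if (all(is.na(gc))) stop("no GC fractions present; supply a reference to exonCoverage")
    if (any(gc < 0 | gc > 1, na.rm = TRUE)) stop("GC fraction outside [0, 1]")
    breaks <- seq(0, 1, by = binWidth)
    if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
    bin <- findInterval(gc, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    nb <- length(breaks) - 1L
    lowA <- mc$norm_A < threshold
    lowB <- mc$norm_B < threshold
    data.frame(gc_low = breaks[-length(breaks)], gc_high = breaks[-1L],
        low_A = vapply(seq_len(nb), function(i)
            sum(lowA & bin == i, na.rm = TRUE), integer(1L)),
        low_B = vapply(seq_len(nb), function(i)
            sum(lowB & bin == i, na.rm = TRUE), integer(1L)))
}
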