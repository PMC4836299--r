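#' Variant normalization and multi-nucleotide decomposition
#'
#' Different variant callers can emit the same underlying change under
#' different names: padded alleles, right-shifted indels in repeat runs, or a
#' multi-nucleotide variant (MNV) versus its component SNVs. Cross-platform
#' comparison requires one canonical name per variant: alleles are trimmed of
#' shared leading/trailing bases (keeping the single anchor base VCF requires
#' for indels) and indels are shifted to the leftmost position compatible with
#' the reference sequence.
#'
#' @name variant-normalization
NULL

# Normalize one variant. refseq is a single DNAString/character for the
# contig, or NULL for trim-only mode. Returns list(pos, ref, alt, trimOnly).
.normalizeOne <- function(pos, ref, alt, refseq = NULL, window = 200L) {
    if (!nzchar(ref) || !nzchar(alt))
        stop("empty allele at position ", pos)
    if (ref == alt)
        stop("not a variant at position ", pos, ": ref == alt ('", ref, "')")
    if (!is.null(refseq)) {
        seen <- as.character(Biostrings::subseq(refseq, pos, pos + nchar(ref) - 1L))
        if (!identical(seen, ref))
            stop("reference mismatch at position ", pos, ": allele '", ref,
                "' but reference has '", seen, "'")
    }
    minPos <- pos - as.integer(window)
    repeat {
        nr <- nchar(ref); na <- nchar(alt)
        if (substr(ref, nr, nr) == substr(alt, na, na)) {
            # shared rightmost base: truncate; left-extend if an allele empties
            ref <- substr(ref, 1L, nr - 1L)
            alt <- substr(alt, 1L, na - 1L)
            if (!nzchar(ref) || !nzchar(alt)) {
                if (is.null(refseq))
                    stop("left-alignment needs reference context at position ",
                        pos, " (trim-only mode cannot extend)")
                if (pos - 1L < 1L)
                    stop("left-alignment ran off the start of the contig at position ", pos)
                if (pos - 1L < minPos)
                    stop("left-alignment exceeded the ", window,
                        " bp context window at position ", pos)
                b <- as.character(Biostrings::subseq(refseq, pos - 1L, pos - 1L))
                ref <- paste0(b, ref)
                alt <- paste0(b, alt)
                pos <- pos - 1L
            }
        } else if (nr >= 2L && na >= 2L && substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
            ref <- substring(ref, 2L)
            alt <- substring(alt, 2L)
            pos <- pos + 1L
        } else break
        if (ref == alt)
            stop("not a variant at position ", pos, ": alleles identical after trimming")
    }
    if (ref == alt)
        stop("not a variant at position ", pos, ": alleles identical after trimming")
    list(pos = pos, ref = ref, alt = alt, trimOnly = is.null(refseq))
}

#' Normalize small variants to their canonical representation
#'
#' Trims shared bases and left-aligns indels so that equivalent
#' representations become identical. With a reference the result is the unique
#' leftmost representation; without one only trimming is performed and the
#' result is flagged \code{trim_only}.
#'
#' @param chrom Character vector of contig names.
#' @param pos Integer vector, 1-based leftmost reference positions.
#' @param ref,alt Character vectors of alleles over A/C/G/T.
#' @param reference Optional named \link[Biostrings]{DNAStringSet} (or named
#'   character vector) of contig sequences providing left-alignment context.
#' @param window Maximum left shift in bp before an error is raised (default
#'   200); shifting beyond the supplied context is an error, never a silent
#'   stop.
#' @return A \code{data.frame} with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{vclass} (SNV/MNV/INDEL) and
#'   \code{trim_only}.
#' @examples
#' normalizeVariant("chr1", 100L, "AT", "AC")  # -> chr1:101 T>C
#' @export
normalizeVariant <- function(chrom, pos, ref, alt, reference = NULL, window = 200L) {
    n <- length(pos)
    stopifnot(length(chrom) == n, length(ref) == n, length(alt) == n)
    ref <- toupper(as.character(ref))
    alt <- toupper(as.character(alt))
    bad <- grepl("[^ACGT]", ref) | grepl("[^ACGT]", alt)
    if (any(bad))
        stop("alleles must be non-empty strings over A/C/G/T (offending index ",
            which(bad)[1L], ")")
    if (!is.null(reference) && !methods::is(reference, "DNAStringSet"))
        reference <- Biostrings::DNAStringSet(reference)
    out <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
        ref = ref, alt = alt, vclass = NA_character_,
        trim_only = is.null(reference), stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
        rs <- NULL
        if (!is.null(reference)) {
            if (!out$chrom[i] %in% names(reference))
                stop("contig '", out$chrom[i], "' absent from the reference")
            rs <- reference[[out$chrom[i]]]
        }
        v <- .normalizeOne(out$pos[i], out$ref[i], out$alt[i], rs, window)
        out$pos[i] <- v$pos
        out$ref[i] <- v$ref
        out$alt[i] <- v$alt
    }
    out$vclass <- variantClass(out$ref, out$alt)
    out
}

#' Decompose multi-nucleotide variants into component SNVs
#'
#' MNVs are split into one SNV per position at which ref and alt differ; SNVs
#' and indels pass through unchanged. Applying all component SNVs to the
#' reference reconstructs the haplotype the MNV describes, so atomic
#' comparison across platforms is lossless for substitutions.
#'
#' @param variants A \code{data.frame} with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt} (canonical), plus any per-call columns, which are
#'   copied onto every component row.
#' @return A \code{data.frame} of the same shape; MNV rows are replaced by
#'   their component SNV rows and \code{vclass} is recomputed.
#' @export
decomposeMnv <- function(variants) {
    vclass <- variantClass(variants$ref, variants$alt)
    isMnv <- vclass == "MNV"
    if (!any(isMnv)) {
        variants$vclass <- vclass
        return(variants)
    }
    keep <- variants[!isMnv, , drop = FALSE]
    pieces <- lapply(which(isMnv), function(i) {
        r <- strsplit(variants$ref[i], "")[[1L]]
        a <- strsplit(variants$alt[i], "")[[1L]]
        d <- which(r != a)
        out <- variants[rep(i, length(d)), , drop = FALSE]
        out$pos <- variants$pos[i] + d - 1L
        out$ref <- r[d]
        out$alt <- a[d]
        out
    })
    out <- rbind(keep, do.call(rbind, pieces))
    out <- out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
    rownames(out) <- NULL
    out$vclass <- variantClass(out$ref, out$alt)
    out
}

#' Do two platform calls describe the same variant?
#'
#' TRUE iff the normalized variants are identical and the zygosities agree.
#' Under the default atomic mode both sides are decomposed first, so an MNV on
#' one platform matches its component SNVs on the other only when every
#' component (with equal zygosity) is present; \code{callsMatch} compares one
#' call against one call, set-level pairing lives in
#' \code{\link{matchCallsets}}.
#'
#' @param a,b Single-row \code{data.frame}s (or lists) with \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}, \code{zygosity}; alleles must already
#'   be canonical.
#' @param mnvMode \code{"atomic"} (decompose before comparing) or
#'   \code{"whole"}.
#' @return Logical scalar; symmetric in its arguments.
#' @export
callsMatch <- function(a, b, mnvMode = c("atomic", "whole")) {
    mnvMode <- match.arg(mnvMode)
    atoms <- function(x) {
        df <- data.frame(chrom = x$chrom, pos = as.integer(x$pos),
            ref = x$ref, alt = x$alt, stringsAsFactors = FALSE)
        if (mnvMode == "atomic") df <- decomposeMnv(df)
        sort(genotypeKey(df$chrom, df$pos, df$ref, df$alt, x$zygosity))
    }
    identical(atoms(a), atoms(b))
}
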