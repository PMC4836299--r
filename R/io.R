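#' Construct a CallSet from a normalized call table
#'
#' @param df \code{data.frame} with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{zygosity} and optionally \code{dp},
#'   \code{gq}, \code{upstreamFilter}, \code{passStatus}.
#' @param platformId "A" or "B".
#' @param trimOnly Whether normalization lacked reference context.
#' @return A \linkS4class{CallSet}.
#' @export
callSet <- function(df, platformId, trimOnly = FALSE) {
    n <- nrow(df)
    gr <- GenomicRanges::GRanges(df$chrom,
        IRanges::IRanges(df$pos, width = nchar(df$ref)))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        ref = as.character(df$ref),
        alt = as.character(df$alt),
        vclass = variantClass(df$ref, df$alt),
        zygosity = as.character(df$zygosity),
        dp = if ("dp" %in% names(df)) as.integer(df$dp) else rep(NA_integer_, n),
        gq = if ("gq" %in% names(df)) as.integer(df$gq) else rep(NA_integer_, n),
        upstreamFilter = if ("upstreamFilter" %in% names(df))
            as.character(df$upstreamFilter) else rep("PASS", n),
        passStatus = if ("passStatus" %in% names(df))
            as.character(df$passStatus) else rep("PASS", n))
    gr <- GenomicRanges::sort(gr)
    new("CallSet", calls = gr, platformId = platformId, trimOnly = trimOnly)
}

# Internal: turn a CallSet (or truth GRanges) into the plain call table the
# matching/benchmark code works on.
callTable <- function(x) {
    gr <- if (methods::is(x, "CallSet") || methods::is(x, "TruthSet")) calls(x) else x
    mc <- S4Vectors::mcols(gr)
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
        pos = GenomicRanges::start(gr),
        ref = mc$ref, alt = mc$alt,
        vclass = variantClass(mc$ref, mc$alt),
        zygosity = mc$zygosity, stringsAsFactors = FALSE)
    for (col in c("dp", "gq", "upstreamFilter", "passStatus"))
        if (col %in% colnames(mc)) df[[col]] <- mc[[col]]
    df
}

#' Read a single-sample VCF into a CallSet
#'
#' Each record is split into one call per alternate allele, alleles are
#' normalized (left-aligned when a reference is supplied, trimmed otherwise),
#' and genotypes are mapped to zygosity: a genotype homozygous for the allele
#' is HOM_ALT, any other genotype carrying it is HET. Hom-ref and missing
#' genotypes are skipped and counted in a message, as are symbolic or
#' non-ACGT alleles. Records whose FILTER is neither PASS nor missing get
#' \code{passStatus = "CALLER_FILTERED"}.
#'
#' @param path Path to a VCF 4.x file (plain or bgzipped).
#' @param platformId "A" or "B".
#' @param reference Optional named DNAStringSet for left-alignment.
#' @param aliases Optional named character vector mapping the file's contig
#'   names onto the analysis names (e.g. \code{c(`1` = "chr1")}).
#' @param window Left-alignment window in bp (default 200).
#' @return A \linkS4class{CallSet}.
#' @export
readCallset <- function(path, platformId, reference = NULL, aliases = NULL,
        window = 200L) {
    if (!file.exists(path)) stop("no such file: ", path)
    vcf <- VariantAnnotation::readVcf(path)
    if (ncol(vcf) > 1L)
        stop("multi-sample VCF '", path,
            "': subset to one sample first (e.g. bcftools view -s SAMPLE)")
    if (ncol(vcf) < 1L || !"GT" %in% names(VariantAnnotation::geno(vcf)))
        stop("VCF '", path, "' lacks a per-sample GT field")
    rr <- SummarizedExperiment::rowRanges(vcf)
    chrom <- applyContigAliases(as.character(GenomicRanges::seqnames(rr)), aliases)
    pos <- GenomicRanges::start(rr)
    ref <- as.character(VariantAnnotation::ref(vcf))
    altL <- VariantAnnotation::alt(vcf)
    altL <- lapply(seq_along(altL), function(i) as.character(altL[[i]]))
    gt <- as.character(VariantAnnotation::geno(vcf)$GT[, 1L])
    gmat <- VariantAnnotation::geno(vcf)
    dp <- if ("DP" %in% names(gmat)) suppressWarnings(as.integer(gmat$DP[, 1L]))
        else rep(NA_integer_, length(gt))
    gq <- if ("GQ" %in% names(gmat)) suppressWarnings(as.integer(gmat$GQ[, 1L]))
        else rep(NA_integer_, length(gt))
    filt <- as.character(rr$FILTER)

    skippedGeno <- 0L
    skippedAllele <- 0L
    rows <- vector("list", length(gt))
    for (i in seq_along(gt)) {
        al <- strsplit(gt[i], "[/|]")[[1L]]
        if (!length(al) || any(al == ".")) { skippedGeno <- skippedGeno + 1L; next }
        ai <- suppressWarnings(as.integer(al))
        if (anyNA(ai) || all(ai == 0L)) { skippedGeno <- skippedGeno + 1L; next }
        recRows <- list()
        for (j in sort(unique(ai[ai > 0L]))) {
            a <- altL[[i]][j]
            if (is.na(a) || grepl("[^ACGT]", a) || !nzchar(a)) {
                skippedAllele <- skippedAllele + 1L
                next
            }
            zyg <- if (all(ai == j)) "HOM_ALT" else "HET"
            recRows[[length(recRows) + 1L]] <- data.frame(chrom = chrom[i],
                pos = pos[i], ref = ref[i], alt = a, zygosity = zyg,
                dp = dp[i], gq = gq[i], upstreamFilter = filt[i],
                stringsAsFactors = FALSE)
        }
        if (length(recRows)) rows[[i]] <- do.call(rbind, recRows)
    }
    df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
    if (skippedGeno + skippedAllele > 0L)
        message(sprintf("readCallset('%s'): skipped %d hom-ref/missing genotype(s), %d symbolic/non-ACGT allele(s)",
            basename(path), skippedGeno, skippedAllele))
    if (is.null(df))
        df <- data.frame(chrom = character(), pos = integer(), ref = character(),
            alt = character(), zygosity = character(), dp = integer(),
            gq = integer(), upstreamFilter = character(), stringsAsFactors = FALSE)
    if (nrow(df)) {
        if (!is.null(reference))
            checkContigOverlap(df$chrom, names(reference), c("call set", "reference"))
        nv <- normalizeVariant(df$chrom, df$pos, df$ref, df$alt, reference, window)
        df$pos <- nv$pos; df$ref <- nv$ref; df$alt <- nv$alt
    }
    df$passStatus <- ifelse(isCallerFiltered(df$upstreamFilter),
        "CALLER_FILTERED", "PASS")
    callSet(df, platformId, trimOnly = is.null(reference))
}

# Internal: write a call table as a single-sample VCF via VariantAnnotation.
# df needs chrom/pos/ref/alt/zygosity and optionally dp/gq/upstreamFilter plus
# any info columns given in infoCols (a named list of vectors + header types).
writeVcfRecords <- function(df, path, sample = "SAMPLE", infoCols = NULL,
        infoHeader = NULL, metaLines = NULL) {
    ord <- order(df$chrom, df$pos, df$ref, df$alt)
    df <- df[ord, , drop = FALSE]
    n <- nrow(df)
    hdr <- VariantAnnotation::VCFHeader(samples = sample)
    meta <- list(fileformat = S4Vectors::DataFrame(Value = "VCFv4.2",
        row.names = "fileformat"))
    if (!is.null(metaLines))
        meta$orthocombine <- S4Vectors::DataFrame(Value = unname(metaLines),
            row.names = names(metaLines))
    VariantAnnotation::meta(hdr) <- IRanges::DataFrameList(meta)
    VariantAnnotation::geno(hdr) <- S4Vectors::DataFrame(
        Number = c("1", "1", "1"), Type = c("String", "Integer", "Integer"),
        Description = c("Genotype", "Read depth", "Genotype quality"),
        row.names = c("GT", "DP", "GQ"))
    if (!is.null(infoHeader))
        VariantAnnotation::info(hdr) <- infoHeader
    rr <- GenomicRanges::GRanges(df$chrom,
        IRanges::IRanges(df$pos, width = nchar(df$ref)))
    gt <- ifelse(df$zygosity == "HOM_ALT", "1/1", "0/1")
    dp <- if ("dp" %in% names(df)) as.integer(df$dp) else rep(NA_integer_, n)
    gq <- if ("gq" %in% names(df)) as.integer(df$gq) else rep(NA_integer_, n)
    filt <- if ("upstreamFilter" %in% names(df)) {
        f <- as.character(df$upstreamFilter)
        ifelse(is.na(f) | f == "", ".", f)
    } else rep("PASS", n)
    fx <- S4Vectors::DataFrame(
        REF = Biostrings::DNAStringSet(if (n) df$ref else character()),
        ALT = IRanges::CharacterList(as.list(if (n) df$alt else character())),
        QUAL = rep(NA_real_, n), FILTER = filt)
    geno <- S4Vectors::SimpleList(
        GT = matrix(gt, ncol = 1L, dimnames = list(NULL, sample)),
        DP = matrix(dp, ncol = 1L, dimnames = list(NULL, sample)),
        GQ = matrix(gq, ncol = 1L, dimnames = list(NULL, sample)))
    args <- list(rowRanges = rr, fixed = fx, geno = geno,
        colData = S4Vectors::DataFrame(Samples = 1L, row.names = sample))
    if (!is.null(infoCols))
        args$info <- S4Vectors::DataFrame(lapply(infoCols, function(x) x[ord]))
    v <- do.call(VariantAnnotation::VCF, args)
    S4Vectors::metadata(v)$header <- hdr
    VariantAnnotation::writeVcf(v, path)
    invisible(path)
}

#' Write a CallSet as a single-sample VCF
#'
#' Reading the file back with \code{\link{readCallset}} recovers the same
#' canonical call table (domain-level round trip).
#'
#' @param cs A \linkS4class{CallSet}.
#' @param path Output path.
#' @param sample Sample name for the VCF column.
#' @return The path, invisibly.
#' @export
writeCallsetVcf <- function(cs, path, sample = "SAMPLE") {
    writeVcfRecords(callTable(cs), path, sample = sample)
}

#' Read a BED file of intervals
#'
#' BED coordinates are 0-based half-open on disk; the returned GRanges is
#' 1-based closed, the convention used throughout the package.
#'
#' @param path BED3/BED4 file.
#' @param aliases Optional contig alias map (named character vector).
#' @return A GRanges (unmerged, in file order after sorting).
#' @export
readBed <- function(path, aliases = NULL) {
    if (!file.exists(path)) stop("no such file: ", path)
    gr <- rtracklayer::import(path, format = "BED")
    if (!is.null(aliases)) {
        new <- applyContigAliases(GenomeInfoDb::seqlevels(gr), aliases)
        gr <- GenomeInfoDb::renameSeqlevels(gr, setNames(new, GenomeInfoDb::seqlevels(gr)))
    }
    GenomicRanges::sort(gr)
}

#' Write intervals as BED
#'
#' @param gr GRanges (1-based closed internally; written 0-based half-open).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeBed <- function(gr, path) {
    df <- data.frame(as.character(GenomicRanges::seqnames(gr)),
        GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
    nm <- names(gr)
    if (!is.null(nm)) df[[4L]] <- nm
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
        col.names = FALSE)
    invisible(path)
}

#' Intersect interval sets
#'
#' Returns the bases present in every input set; commutative and associative,
#' and the result never exceeds the smallest input.
#'
#' @param ... GRanges, or a single list of GRanges.
#' @return A reduced GRanges of the common bases.
#' @export
intersectRegions <- function(...) {
    sets <- list(...)
    if (length(sets) == 1L && is.list(sets[[1L]]) && !methods::is(sets[[1L]], "GRanges"))
        sets <- sets[[1L]]
    if (!length(sets)) stop("need at least one interval set")
    out <- GenomicRanges::reduce(sets[[1L]], ignore.strand = TRUE)
    for (s in sets[-1L])
        out <- GenomicRanges::intersect(out, GenomicRanges::reduce(s, ignore.strand = TRUE),
            ignore.strand = TRUE)
    GenomicRanges::sort(out)
}

#' Total bases covered by an interval set
#'
#' Overlaps are merged first, so the count is invariant to interval order and
#' pre-merging.
#'
#' @param gr A GRanges.
#' @return Integer number of distinct bases.
#' @export
totalBases <- function(gr) {
    sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(gr, ignore.strand = TRUE))))
}

#' Construct a CoverageTrack from depth runs
#'
#' @param runs GRanges (1-based closed) with a numeric \code{depth} metadata
#'   column. Runs may not overlap with conflicting depths.
#' @param platformId "A" or "B".
#' @return A \linkS4class{CoverageTrack}; positions outside all runs have
#'   depth 0.
#' @export
coverageTrack <- function(runs, platformId) {
    if (!"depth" %in% colnames(S4Vectors::mcols(runs)))
        stop("runs need a 'depth' metadata column")
    d <- S4Vectors::mcols(runs)$depth
    if (any(is.na(d)) || any(d < 0)) stop("depths must be non-negative")
    hits <- GenomicRanges::findOverlaps(runs, drop.self = TRUE, drop.redundant = TRUE)
    if (length(hits)) {
        q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
        if (any(d[q] != d[s]))
            stop("overlapping depth runs with conflicting depths")
        # equal-depth overlaps: merge per depth value
        parts <- split(runs, d)
        runs <- unlist(GenomicRanges::GRangesList(lapply(names(parts), function(k) {
            g <- GenomicRanges::reduce(parts[[k]], ignore.strand = TRUE)
            S4Vectors::mcols(g)$depth <- as.numeric(k)
            g
        })), use.names = FALSE)
        d <- S4Vectors::mcols(runs)$depth
    }
    rle <- GenomicRanges::coverage(runs, weight = as.numeric(d))
    new("CoverageTrack", depth = rle, platformId = platformId)
}

#' Read a depth-of-coverage track
#'
#' Accepts 4-column run form (contig, start, end, depth; BED-style 0-based
#' half-open, as bedtools genomecov -bga or bedGraph writes) or 3-column
#' per-base form (contig, 1-based position, depth; as samtools depth writes).
#'
#' @param path Tab- or space-separated text file.
#' @param platformId "A" or "B".
#' @param aliases Optional contig alias map.
#' @return A \linkS4class{CoverageTrack}.
#' @export
readCoverage <- function(path, platformId, aliases = NULL) {
    if (!file.exists(path)) stop("no such file: ", path)
    tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
        comment.char = "#")
    if (ncol(tab) == 4L) {
        runs <- GenomicRanges::GRanges(applyContigAliases(tab[[1L]], aliases),
            IRanges::IRanges(tab[[2L]] + 1L, tab[[3L]]))
        S4Vectors::mcols(runs)$depth <- tab[[4L]]
    } else if (ncol(tab) == 3L) {
        runs <- GenomicRanges::GRanges(applyContigAliases(tab[[1L]], aliases),
            IRanges::IRanges(tab[[2L]], width = 1L))
        S4Vectors::mcols(runs)$depth <- tab[[3L]]
    } else {
        stop("coverage file '", path,
            "' must have 4 columns (contig,start,end,depth) or 3 (contig,pos,depth)")
    }
    if (any(S4Vectors::mcols(runs)$depth < 0)) stop("negative depth in ", path)
    coverageTrack(runs, platformId)
}

#' Write a CoverageTrack as a 4-column run file
#'
#' @param track A \linkS4class{CoverageTrack}.
#' @param path Output path (contig, start, end, depth; 0-based half-open).
#' @param keepZero Whether to write zero-depth runs (default FALSE; absent
#'   means depth 0 on reading).
#' @return The path, invisibly.
#' @export
writeCoverage <- function(track, path, keepZero = FALSE) {
    rows <- list()
    for (ctg in names(track@depth)) {
        r <- track@depth[[ctg]]
        ends <- cumsum(S4Vectors::runLength(r))
        starts <- c(1L, utils::head(ends, -1L) + 1L)
        val <- S4Vectors::runValue(r)
        keep <- if (keepZero) rep(TRUE, length(val)) else val != 0
        if (any(keep))
            rows[[ctg]] <- data.frame(ctg, starts[keep] - 1L, ends[keep],
                val[keep])
    }
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(character(), integer(), integer(), numeric())
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
        col.names = FALSE)
    invisible(path)
}

#' Depth at genomic positions
#'
#' @param track A \linkS4class{CoverageTrack}.
#' @param chrom,pos Parallel vectors of contig names and 1-based positions.
#' @return Numeric vector of depths; positions outside the track are 0.
#' @export
depthAt <- function(track, chrom, pos) {
    chrom <- as.character(chrom)
    out <- numeric(length(pos))
    for (ctg in unique(chrom)) {
        idx <- which(chrom == ctg)
        if (!ctg %in% names(track@depth)) next
        r <- track@depth[[ctg]]
        p <- pos[idx]
        ok <- p >= 1L & p <= length(r)
        if (any(ok)) out[idx[ok]] <- as.numeric(r[p[ok]])
    }
    out
}

# Internal: the depth Rle for a contig, zero-padded to at least minLen.
contigRle <- function(track, ctg, minLen) {
    r <- if (ctg %in% names(track@depth)) track@depth[[ctg]] else S4Vectors::Rle(numeric(0))
    if (length(r) < minLen) r <- c(r, S4Vectors::Rle(0, minLen - length(r)))
    r
}

#' Per-interval mean depth
#'
#' @param track A \linkS4class{CoverageTrack}.
#' @param regions GRanges of intervals.
#' @return Numeric vector of per-base mean depths, one per interval.
#' @export
meanDepth <- function(track, regions) {
    out <- numeric(length(regions))
    ctgs <- as.character(GenomicRanges::seqnames(regions))
    for (ctg in unique(ctgs)) {
        idx <- which(ctgs == ctg)
        r <- contigRle(track, ctg, max(GenomicRanges::end(regions)[idx]))
        v <- IRanges::Views(r, GenomicRanges::start(regions)[idx],
            GenomicRanges::end(regions)[idx])
        out[idx] <- IRanges::viewMeans(v)
    }
    out
}

#' Construct a TruthSet
#'
#' @param calls GRanges with \code{ref}, \code{alt}, \code{zygosity} metadata
#'   columns (canonical alleles).
#' @param regions GRanges of confident regions.
#' @param versionLabel Free-text label.
#' @param dropOutside Drop truth calls outside the confident regions with a
#'   message (default TRUE); with FALSE such calls are a validity error.
#' @return A \linkS4class{TruthSet}.
#' @export
truthSet <- function(calls, regions, versionLabel = "synthetic",
        dropOutside = TRUE) {
    regions <- GenomicRanges::reduce(GenomicRanges::sort(regions),
        ignore.strand = TRUE)
    if (!"vclass" %in% colnames(S4Vectors::mcols(calls)))
        S4Vectors::mcols(calls)$vclass <- variantClass(
            S4Vectors::mcols(calls)$ref, S4Vectors::mcols(calls)$alt)
    if (length(calls) && dropOutside) {
        inside <- IRanges::overlapsAny(calls, regions, type = "within")
        if (!all(inside)) {
            message(sprintf("truthSet: dropping %d call(s) outside confident regions",
                sum(!inside)))
            calls <- calls[inside]
        }
    }
    new("TruthSet", calls = GenomicRanges::sort(calls),
        confidentRegions = regions, versionLabel = versionLabel)
}

#' Read a truth set from a VCF and confident-region BED
#'
#' Uses the same reading and normalization path as platform call sets, so
#' both sides of a benchmark are normalized identically.
#'
#' @param vcfPath Truth VCF.
#' @param bedPath Confident-region BED.
#' @param reference Optional named DNAStringSet for left-alignment.
#' @param versionLabel Label stored on the object (default the VCF filename).
#' @param aliases Optional contig alias map.
#' @return A \linkS4class{TruthSet}.
#' @export
readTruthSet <- function(vcfPath, bedPath, reference = NULL,
        versionLabel = basename(vcfPath), aliases = NULL) {
    cs <- readCallset(vcfPath, "A", reference = reference, aliases = aliases)
    regions <- readBed(bedPath, aliases = aliases)
    gr <- calls(cs)
    S4Vectors::mcols(gr) <- S4Vectors::mcols(gr)[c("ref", "alt", "vclass", "zygosity")]
    truthSet(gr, regions, versionLabel)
}
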