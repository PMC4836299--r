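#' Pass-filter thresholds
#'
#' Calls from platform A must exceed minimum depth and genotype quality to
#' count as Pass: DP strictly greater than \code{minDp} and GQ strictly
#' greater than \code{minGq} (defaults 8 and 20, chosen to lose as few true
#' variants as possible while removing most false positives). Calls failing
#' either bound are retained as NoPass rather than discarded; a missing GQ is
#' NoPass. Calls already removed by the upstream caller's FILTER column stay
#' \code{CALLER_FILTERED} and are never upgraded.
#'
#' @param minDp,minGq Strict lower bounds (a call with DP exactly
#'   \code{minDp} fails).
#' @return A named list used by \code{\link{applyPassFilter}} and
#'   \code{\link{combineCallsets}}.
#' @export
passThresholds <- function(minDp = 8L, minGq = 20L) {
    stopifnot(minDp >= 0, minGq >= 0)
    list(minDp = as.integer(minDp), minGq = as.integer(minGq))
}

# Internal: pass status for a call table (platform A semantics).
passStatusFor <- function(df, thresholds = passThresholds()) {
    status <- ifelse(isCallerFiltered(df$upstreamFilter), "CALLER_FILTERED",
        ifelse(!is.na(df$dp) & df$dp > thresholds$minDp &
               !is.na(df$gq) & df$gq > thresholds$minGq, "PASS", "NOPASS"))
    status
}

#' Apply the DP/GQ pass filter to a platform-A CallSet
#'
#' @param cs A \linkS4class{CallSet} with platform role "A".
#' @param thresholds A \code{\link{passThresholds}} list.
#' @return The CallSet with \code{passStatus} set to PASS/NOPASS (existing
#'   CALLER_FILTERED statuses are preserved).
#' @export
applyPassFilter <- function(cs, thresholds = passThresholds()) {
    if (platformId(cs) != "A")
        stop("the DP/GQ pass filter applies to platform A calls only")
    gr <- calls(cs)
    df <- callTable(cs)
    newStatus <- passStatusFor(df, thresholds)
    nMissingGq <- sum(newStatus == "NOPASS" & is.na(df$gq))
    if (nMissingGq)
        message(sprintf("applyPassFilter: %d call(s) NoPass for missing GQ", nMissingGq))
    S4Vectors::mcols(gr)$passStatus <- newStatus
    methods::initialize(cs, calls = gr)
}

# Internal: deduplicate identical calls (same variant + zygosity) in one
# platform's table, warning with the count.
dedupCalls <- function(df, label) {
    key <- genotypeKey(df$chrom, df$pos, df$ref, df$alt, df$zygosity)
    dup <- duplicated(key)
    if (any(dup)) {
        warning(sprintf("platform %s: %d duplicate identical call(s) removed",
            label, sum(dup)), call. = FALSE)
        df <- df[!dup, , drop = FALSE]
    }
    df
}

# Internal: pair two decomposed canonical call tables. Returns one row per
# matched site: the variant key columns, per-platform evidence (NA where the
# platform made no call), provenance and a conflict flag (the other platform
# called something different at the same locus).
matchTables <- function(tA, tB) {
    tA <- dedupCalls(tA, "A")
    tB <- dedupCalls(tB, "B")
    kA <- genotypeKey(tA$chrom, tA$pos, tA$ref, tA$alt, tA$zygosity)
    kB <- genotypeKey(tB$chrom, tB$pos, tB$ref, tB$alt, tB$zygosity)
    hitB <- match(kA, kB)
    matchedB <- !is.na(hitB)
    soloB <- setdiff(seq_len(nrow(tB)), hitB[matchedB])
    locusA <- paste(tA$chrom, tA$pos, sep = ":")
    locusB <- paste(tB$chrom, tB$pos, sep = ":")
    n <- nrow(tA) + length(soloB)
    out <- data.frame(
        chrom = c(tA$chrom, tB$chrom[soloB]),
        pos = c(tA$pos, tB$pos[soloB]),
        ref = c(tA$ref, tB$ref[soloB]),
        alt = c(tA$alt, tB$alt[soloB]),
        zygosityA = c(tA$zygosity, rep(NA_character_, length(soloB))),
        zygosityB = c(ifelse(matchedB, tB$zygosity[hitB], NA_character_),
            tB$zygosity[soloB]),
        dpA = c(tA$dp, rep(NA_integer_, length(soloB))),
        gqA = c(tA$gq, rep(NA_integer_, length(soloB))),
        passA = c(tA$passStatus, rep(NA_character_, length(soloB))),
        dpB = c(ifelse(matchedB, tB$dp[hitB], NA_integer_), tB$dp[soloB]),
        provenance = c(ifelse(matchedB, "BOTH", "A_ONLY"),
            rep("B_ONLY", length(soloB))),
        stringsAsFactors = FALSE)
    out$vclass <- variantClass(out$ref, out$alt)
    # conflict: the opposite platform has some call at this locus that did
    # not pair with this one (different allele or zygosity)
    conflict <- logical(n)
    iA <- seq_len(nrow(tA))
    conflict[iA][!matchedB] <- locusA[!matchedB] %in% locusB
    if (length(soloB)) {
        idxB <- nrow(tA) + seq_along(soloB)
        conflict[idxB] <- locusB[soloB] %in% locusA
    }
    out$conflict <- conflict
    rownames(out) <- NULL
    out[order(out$chrom, out$pos, out$ref, out$alt, out$provenance), , drop = FALSE]
}

#' Match two platforms' call sets
#'
#' Every input call appears in exactly one matched site; calls pair iff the
#' canonical variant and zygosity agree (after atomic MNV decomposition under
#' the default mode). Unpaired calls at a locus where the other platform
#' called a different allele or zygosity are flagged \code{conflict}.
#'
#' @param csA,csB \linkS4class{CallSet}s for platforms A and B.
#' @param mnvMode "atomic" (decompose MNVs before matching; the robust
#'   default, since whole-MNV naming differs between callers) or "whole".
#' @return A \code{data.frame} of matched sites with per-platform evidence
#'   columns, \code{provenance} (BOTH/A_ONLY/B_ONLY) and \code{conflict}.
#' @export
matchCallsets <- function(csA, csB, mnvMode = c("atomic", "whole")) {
    mnvMode <- match.arg(mnvMode)
    tA <- callTable(csA)
    tB <- callTable(csB)
    if (mnvMode == "atomic") {
        tA <- decomposeMnv(tA)
        tB <- decomposeMnv(tB)
    }
    matchTables(tA, tB)
}

# Internal: the decision table mapping matched-site evidence to a category.
#   (1) A Pass call matching a B call            -> ORTHOGONALLY_CONFIRMED
#   (2) A NoPass/filtered call matching a B call -> RELIABLE
#   (3) singleton A Pass call                    -> LIKELY_TP
#   (4) singleton B call, A not covered          -> LIKELY_TP
#   (5) singleton A NoPass/filtered call         -> LIKELY_FP
#   (6) singleton B call, A covered (by depth,
#       or A called something else here)         -> LIKELY_FP
classifyRow <- function(provenance, passA, coveredAEff) {
    if (provenance == "BOTH") {
        if (passA == "PASS") "ORTHOGONALLY_CONFIRMED" else "RELIABLE"
    } else if (provenance == "A_ONLY") {
        if (passA == "PASS") "LIKELY_TP" else "LIKELY_FP"
    } else if (provenance == "B_ONLY") {
        if (coveredAEff) "LIKELY_FP" else "LIKELY_TP"
    } else {
        stop("cannot classify a site with neither platform's call")
    }
}

#' Classify matched sites into confidence categories
#'
#' Applies the category decision table: concordant calls are Orthogonally
#' Confirmed when the platform-A call passes DP/GQ (Reliable otherwise);
#' singleton A calls are Likely TP when Pass, Likely FP when NoPass;
#' singleton B calls are Likely TP only when platform A had no usable
#' coverage at the site (otherwise Likely FP). A site counts as covered on a
#' platform when its track depth is at least \code{coveredDepth}; for rule
#' purposes a conflicting A call at the locus also counts as A coverage.
#'
#' @param matched Output of \code{\link{matchCallsets}}.
#' @param covA,covB \linkS4class{CoverageTrack}s (NULL = no coverage
#'   anywhere).
#' @param coveredDepth Minimum depth for "covered" (default 8, mirroring the
#'   DP > 8 callability bound).
#' @return \code{matched} with \code{coveredA}, \code{coveredB} and
#'   \code{category} columns added.
#' @export
classifySites <- function(matched, covA = NULL, covB = NULL, coveredDepth = 8L) {
    n <- nrow(matched)
    dA <- if (is.null(covA)) numeric(n) else depthAt(covA, matched$chrom, matched$pos)
    dB <- if (is.null(covB)) numeric(n) else depthAt(covB, matched$chrom, matched$pos)
    matched$coveredA <- dA >= coveredDepth
    matched$coveredB <- dB >= coveredDepth
    coveredAEff <- matched$coveredA | matched$conflict
    matched$category <- vapply(seq_len(n), function(i) {
        classifyRow(matched$provenance[i], matched$passA[i], coveredAEff[i])
    }, character(1L))
    matched
}

# Internal: restrict a call table to calls whose 1-based position lies inside
# a region interval.
restrictTable <- function(df, regions) {
    if (is.null(regions) || !nrow(df)) return(df)
    gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$pos, width = 1L))
    df[IRanges::overlapsAny(gr, regions), , drop = FALSE]
}

#' Combine two platforms' calls into a classified call set
#'
#' The end-to-end driver: platform-B calls removed by their caller's FILTER
#' are dropped (they were filtered upstream), MNVs are decomposed under the
#' default atomic mode, the DP/GQ pass filter is applied to platform A, calls
#' are restricted to \code{regions} (a call counts iff its position lies in a
#' region interval), matched across platforms and classified. Deterministic
#' for fixed inputs.
#'
#' @param csA,csB \linkS4class{CallSet}s (roles A and B).
#' @param covA,covB \linkS4class{CoverageTrack}s, or NULL.
#' @param regions Optional GRanges restricting the analysis.
#' @param thresholds \code{\link{passThresholds}} for platform A.
#' @param coveredDepth Depth bound for the covered predicate (default 8).
#' @param mnvMode "atomic" or "whole".
#' @return A \linkS4class{CombinedCallSet}.
#' @export
combineCallsets <- function(csA, csB, covA = NULL, covB = NULL, regions = NULL,
        thresholds = passThresholds(), coveredDepth = 8L,
        mnvMode = c("atomic", "whole")) {
    mnvMode <- match.arg(mnvMode)
    if (platformId(csA) != "A" || platformId(csB) != "B")
        stop("combineCallsets expects platform roles A and B in that order")
    tA <- callTable(csA)
    tB <- callTable(csB)
    nFiltB <- sum(tB$passStatus == "CALLER_FILTERED")
    if (nFiltB) {
        message(sprintf("combineCallsets: dropping %d caller-filtered platform-B call(s)", nFiltB))
        tB <- tB[tB$passStatus != "CALLER_FILTERED", , drop = FALSE]
    }
    if (mnvMode == "atomic") {
        tA <- decomposeMnv(tA)
        tB <- decomposeMnv(tB)
    }
    tA$passStatus <- passStatusFor(tA, thresholds)
    if (!is.null(regions)) {
        if (nrow(tA)) checkContigOverlap(tA$chrom,
            as.character(GenomicRanges::seqnames(regions)), c("call set A", "regions"))
        tA <- restrictTable(tA, regions)
        tB <- restrictTable(tB, regions)
        if (!nrow(tA) && !nrow(tB))
            warning("no calls fall inside the analysis regions", call. = FALSE)
    }
    matched <- matchTables(tA, tB)
    matched <- classifySites(matched, covA, covB, coveredDepth)
    gr <- GenomicRanges::GRanges(matched$chrom,
        IRanges::IRanges(matched$pos, width = nchar(matched$ref)))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        ref = matched$ref, alt = matched$alt, vclass = matched$vclass,
        zygosityA = matched$zygosityA, zygosityB = matched$zygosityB,
        dpA = matched$dpA, dpB = matched$dpB, gqA = matched$gqA,
        passA = matched$passA, coveredA = matched$coveredA,
        coveredB = matched$coveredB, conflict = matched$conflict,
        provenance = matched$provenance, category = matched$category)
    cfg <- list(minDp = thresholds$minDp, minGq = thresholds$minGq,
        coveredDepth = as.integer(coveredDepth), mnvMode = mnvMode,
        regionBases = if (is.null(regions)) NA_real_ else totalBases(regions))
    new("CombinedCallSet", calls = GenomicRanges::sort(gr), config = cfg)
}

#' Write a CombinedCallSet as an annotated VCF
#'
#' One record per classified call, with INFO keys CATEGORY, PLATFORMS (the
#' provenance), DP_A, DP_B and GQ_A. The genotype column carries the
#' platform-A zygosity when present, otherwise platform B's.
#'
#' @param ccs A \linkS4class{CombinedCallSet}.
#' @param path Output path.
#' @param sample Sample name.
#' @return The path, invisibly.
#' @export
writeCombinedVcf <- function(ccs, path, sample = "SAMPLE") {
    gr <- calls(ccs)
    mc <- S4Vectors::mcols(gr)
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
        pos = GenomicRanges::start(gr), ref = mc$ref, alt = mc$alt,
        zygosity = ifelse(is.na(mc$zygosityA), mc$zygosityB, mc$zygosityA),
        dp = ifelse(is.na(mc$dpA), mc$dpB, mc$dpA), gq = mc$gqA,
        upstreamFilter = "PASS", stringsAsFactors = FALSE)
    infoHeader <- S4Vectors::DataFrame(
        Number = rep("1", 5L),
        Type = c("String", "String", "Integer", "Integer", "Integer"),
        Description = c("Confidence category", "Calling platforms",
            "Platform A depth", "Platform B depth", "Platform A genotype quality"),
        row.names = c("CATEGORY", "PLATFORMS", "DP_A", "DP_B", "GQ_A"))
    cfg <- runConfig(ccs)
    metaLines <- c(orthocombineVersion = as.character(packageVersion("orthocombine")),
        orthocombineConfig = paste(names(cfg), unlist(lapply(cfg, as.character)),
            sep = "=", collapse = ";"))
    writeVcfRecords(df, path, sample = sample,
        infoCols = list(CATEGORY = mc$category, PLATFORMS = mc$provenance,
            DP_A = mc$dpA, DP_B = mc$dpB, GQ_A = mc$gqA),
        infoHeader = infoHeader, metaLines = metaLines)
}

#' Read back a combined VCF written by \code{\link{writeCombinedVcf}}
#'
#' Recovers the per-call categories (used by replicate cross-tabulation when
#' runs are exchanged as files).
#'
#' @param path VCF written by \code{\link{writeCombinedVcf}}.
#' @param aliases Optional contig alias map.
#' @return A \linkS4class{CombinedCallSet} (evidence columns that the VCF
#'   does not carry are NA).
#' @export
readCombinedVcf <- function(path, aliases = NULL) {
    vcf <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    info <- VariantAnnotation::info(vcf)
    chrom <- applyContigAliases(as.character(GenomicRanges::seqnames(rr)), aliases)
    ref <- as.character(VariantAnnotation::ref(vcf))
    alt <- vapply(VariantAnnotation::alt(vcf), function(x) as.character(x)[1L], character(1L))
    gt <- as.character(VariantAnnotation::geno(vcf)$GT[, 1L])
    gr <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(GenomicRanges::start(rr), width = nchar(ref)))
    prov <- as.character(info$PLATFORMS)
    zyg <- ifelse(gt == "1/1", "HOM_ALT", "HET")
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        ref = ref, alt = alt, vclass = variantClass(ref, alt),
        zygosityA = ifelse(prov == "B_ONLY", NA_character_, zyg),
        zygosityB = ifelse(prov == "A_ONLY", NA_character_, zyg),
        dpA = suppressWarnings(as.integer(info$DP_A)),
        dpB = suppressWarnings(as.integer(info$DP_B)),
        gqA = suppressWarnings(as.integer(info$GQ_A)),
        passA = NA_character_, coveredA = NA, coveredB = NA, conflict = NA,
        provenance = prov, category = as.character(info$CATEGORY))
    new("CombinedCallSet", calls = GenomicRanges::sort(gr), config = list())
}
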