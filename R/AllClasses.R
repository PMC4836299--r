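#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom IRanges RleList
NULL

REQUIRED_CALL_MCOLS <- c("ref", "alt", "vclass", "zygosity", "dp", "gq",
    "upstreamFilter", "passStatus")

#' CallSet: one platform's variant calls
#'
#' A thin S4 container around a \link[GenomicRanges]{GRanges} whose metadata
#' columns carry, per call: \code{ref}, \code{alt}, \code{vclass}
#' (SNV/MNV/INDEL), \code{zygosity} (HET/HOM_ALT), \code{dp}, \code{gq}
#' (phred-scaled, NA when absent), \code{upstreamFilter} (the caller's FILTER
#' string) and \code{passStatus} (PASS/NOPASS/CALLER_FILTERED). Hom-ref
#' genotypes are never stored. \code{platformId} is role-based: "A" is the
#' hybrid-capture/reversible-terminator platform whose calls are subject to
#' the DP/GQ pass filter, "B" the amplicon/semiconductor platform whose calls
#' arrive pre-filtered by its own caller.
#'
#' @slot calls GRanges of width \code{nchar(ref)} at the variant position.
#' @slot platformId "A" or "B".
#' @slot trimOnly TRUE when calls were normalized without reference context
#'   (trimming only, no left-alignment).
#' @exportClass CallSet
setClass("CallSet", representation(
    calls = "GRanges",
    platformId = "character",
    trimOnly = "logical"
))

setValidity("CallSet", function(object) {
    msg <- character()
    mc <- S4Vectors::mcols(object@calls)
    missing <- setdiff(REQUIRED_CALL_MCOLS, colnames(mc))
    if (length(missing))
        msg <- c(msg, paste("missing call columns:", paste(missing, collapse = ", ")))
    if (!(length(object@platformId) == 1L && object@platformId %in% c("A", "B")))
        msg <- c(msg, "platformId must be \"A\" or \"B\"")
    if (length(object@trimOnly) != 1L)
        msg <- c(msg, "trimOnly must be a single logical")
    if (!length(missing) && length(object@calls)) {
        if (!all(mc$zygosity %in% ZYGOSITY_LEVELS))
            msg <- c(msg, "zygosity must be HET or HOM_ALT")
        if (any(!is.na(mc$dp) & mc$dp < 0))
            msg <- c(msg, "dp must be >= 0")
        if (!all(mc$passStatus %in% c("PASS", "NOPASS", "CALLER_FILTERED")))
            msg <- c(msg, "passStatus must be PASS, NOPASS or CALLER_FILTERED")
        if (any(mc$ref == mc$alt))
            msg <- c(msg, "ref must differ from alt")
    }
    if (length(msg)) msg else TRUE
})

#' TruthSet: high-confidence calls plus their confident regions
#'
#' @slot calls GRanges with \code{ref}, \code{alt}, \code{vclass},
#'   \code{zygosity} metadata columns; every call lies inside
#'   \code{confidentRegions}.
#' @slot confidentRegions Reduced GRanges of confident bases.
#' @slot versionLabel Free-text label of the truth-set release.
#' @exportClass TruthSet
setClass("TruthSet", representation(
    calls = "GRanges",
    confidentRegions = "GRanges",
    versionLabel = "character"
))

setValidity("TruthSet", function(object) {
    msg <- character()
    mc <- S4Vectors::mcols(object@calls)
    need <- c("ref", "alt", "vclass", "zygosity")
    if (!all(need %in% colnames(mc)))
        msg <- c(msg, paste("truth calls need columns:", paste(need, collapse = ", ")))
    if (length(object@calls)) {
        inside <- IRanges::overlapsAny(object@calls, object@confidentRegions,
            type = "within")
        if (!all(inside))
            msg <- c(msg, sprintf("%d truth call(s) outside confident regions",
                sum(!inside)))
    }
    if (length(msg)) msg else TRUE
})

#' CoverageTrack: per-base read depth for one platform
#'
#' Depth is stored as a run-length list per contig
#' (\link[IRanges]{RleList}); positions absent from the track have depth 0.
#'
#' @slot depth Integer RleList keyed by contig.
#' @slot platformId "A" or "B".
#' @exportClass CoverageTrack
setClass("CoverageTrack", representation(
    depth = "RleList",
    platformId = "character"
))

setValidity("CoverageTrack", function(object) {
    msg <- character()
    if (!(length(object@platformId) == 1L && object@platformId %in% c("A", "B")))
        msg <- c(msg, "platformId must be \"A\" or \"B\"")
    if (length(object@depth) && any(vapply(object@depth, function(r) {
            v <- S4Vectors::runValue(r); length(v) && min(v) < 0
        }, logical(1L))))
        msg <- c(msg, "depths must be >= 0")
    if (length(msg)) msg else TRUE
})

#' CombinedCallSet: classified union of two platform call sets
#'
#' The output of \code{\link{combineCallsets}}: one row per emitted call with
#' both platforms' evidence (\code{zygosityA/B}, \code{dpA/B}, \code{gqA},
#' \code{passA}), coverage on each platform at the site, the provenance
#' (\code{A_ONLY}, \code{B_ONLY}, \code{BOTH}) and the assigned confidence
#' category.
#'
#' @slot calls GRanges, one range per classified call.
#' @slot config Named list of the effective thresholds and modes.
#' @exportClass CombinedCallSet
setClass("CombinedCallSet", representation(
    calls = "GRanges",
    config = "list"
))

setValidity("CombinedCallSet", function(object) {
    msg <- character()
    mc <- S4Vectors::mcols(object@calls)
    need <- c("ref", "alt", "vclass", "category", "provenance",
        "zygosityA", "zygosityB", "dpA", "dpB", "gqA", "passA",
        "coveredA", "coveredB")
    if (!all(need %in% colnames(mc)))
        msg <- c(msg, paste("missing columns:",
            paste(setdiff(need, colnames(mc)), collapse = ", ")))
    else if (length(object@calls)) {
        if (!all(mc$category %in% CATEGORY_LEVELS))
            msg <- c(msg, "unknown category value")
        if (any(mc$provenance == "NONE"))
            msg <- c(msg, "call with neither platform present")
    }
    if (length(msg)) msg else TRUE
})

#' PlatformProfile: error structure of a simulated platform
#'
#' Parameterizes the synthetic-fixture generator: per-class sensitivity,
#' false-positive density, zygosity-error rate, a dispersed depth model and a
#' GC-dropout term. \code{nopassRate} applies to platform A only (the platform
#' whose calls face the DP/GQ pass filter).
#'
#' @slot snvSensitivity,indelSensitivity Probability a truth variant of the
#'   class is called.
#' @slot fpPerMb Expected false positives per megabase of exon.
#' @slot zygosityErrorRate Probability a called variant's zygosity is flipped.
#' @slot meanDepth Mean exon depth before GC dropout.
#' @slot depthDispersion Negative-binomial size parameter (larger = tighter).
#' @slot gcDropoutDirection "AT" (depth lost in AT-rich exons) or "GC".
#' @slot gcDropoutStrength Fraction of depth lost at the GC extreme, in [0,1].
#' @slot nopassRate Probability a platform-A call is emitted with
#'   sub-threshold DP or GQ.
#' @exportClass PlatformProfile
setClass("PlatformProfile", representation(
    snvSensitivity = "numeric",
    indelSensitivity = "numeric",
    fpPerMb = "numeric",
    zygosityErrorRate = "numeric",
    meanDepth = "numeric",
    depthDispersion = "numeric",
    gcDropoutDirection = "character",
    gcDropoutStrength = "numeric",
    nopassRate = "numeric"
))

setValidity("PlatformProfile", function(object) {
    msg <- character()
    inUnit <- function(x) length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
    if (!inUnit(object@snvSensitivity)) msg <- c(msg, "snvSensitivity must be in [0,1]")
    if (!inUnit(object@indelSensitivity)) msg <- c(msg, "indelSensitivity must be in [0,1]")
    if (!(object@fpPerMb >= 0)) msg <- c(msg, "fpPerMb must be >= 0")
    if (!inUnit(object@zygosityErrorRate)) msg <- c(msg, "zygosityErrorRate must be in [0,1]")
    if (!(object@meanDepth > 0)) msg <- c(msg, "meanDepth must be > 0")
    if (!(object@depthDispersion > 0)) msg <- c(msg, "depthDispersion must be > 0")
    if (!object@gcDropoutDirection %in% c("AT", "GC"))
        msg <- c(msg, "gcDropoutDirection must be \"AT\" or \"GC\"")
    if (!inUnit(object@gcDropoutStrength)) msg <- c(msg, "gcDropoutStrength must be in [0,1]")
    if (!inUnit(object@nopassRate)) msg <- c(msg, "nopassRate must be in [0,1]")
    if (length(msg)) msg else TRUE
})

#' ToyGenome: generated contigs with exon annotation
#'
#' @slot sequences Named DNAStringSet of contig sequences.
#' @slot exons GRanges of exons with a \code{gc} metadata column holding the
#'   GC fraction each exon was generated with.
#' @exportClass ToyGenome
setClass("ToyGenome", representation(
    sequences = "DNAStringSet",
    exons = "GRanges"
))

setValidity("ToyGenome", function(object) {
    msg <- character()
    if (is.null(names(object@sequences)))
        msg <- c(msg, "contig sequences must be named")
    if (length(object@exons)) {
        ctg <- as.character(GenomicRanges::seqnames(object@exons))
        if (!all(ctg %in% names(object@sequences)))
            msg <- c(msg, "exon contigs absent from sequences")
        else {
            len <- Biostrings::width(object@sequences)[match(ctg, names(object@sequences))]
            if (any(GenomicRanges::end(object@exons) > len) ||
                any(GenomicRanges::start(object@exons) < 1L))
                msg <- c(msg, "exons extend beyond their contig")
        }
        if (!"gc" %in% colnames(S4Vectors::mcols(object@exons)))
            msg <- c(msg, "exons need a gc metadata column")
    }
    if (length(msg)) msg else TRUE
})
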