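#' Accessors for orthocombine containers
#'
#' \code{calls()} returns the underlying GRanges of a CallSet, TruthSet or
#' CombinedCallSet; \code{platformId()} the platform role ("A"/"B");
#' \code{confidentRegions()} a TruthSet's confident-region GRanges;
#' \code{categoryCounts()} the per-category tally of a CombinedCallSet;
#' \code{runConfig()} the effective configuration a CombinedCallSet was
#' produced with; \code{exons()} and \code{sequences()} the annotation and
#' contigs of a ToyGenome.
#'
#' @param x An orthocombine object.
#' @return See details per generic.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' @rdname accessors
#' @export
setGeneric("platformId", function(x) standardGeneric("platformId"))

#' @rdname accessors
#' @export
setGeneric("confidentRegions", function(x) standardGeneric("confidentRegions"))

#' @rdname accessors
#' @export
setGeneric("categoryCounts", function(x) standardGeneric("categoryCounts"))

#' @rdname accessors
#' @export
setGeneric("runConfig", function(x) standardGeneric("runConfig"))

#' @rdname accessors
#' @export
setGeneric("exons", function(x) standardGeneric("exons"))

#' @rdname accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname accessors
#' @export
setMethod("calls", "CallSet", function(x) x@calls)

#' @rdname accessors
#' @export
setMethod("calls", "TruthSet", function(x) x@calls)

#' @rdname accessors
#' @export
setMethod("calls", "CombinedCallSet", function(x) x@calls)

#' @rdname accessors
#' @export
setMethod("platformId", "CallSet", function(x) x@platformId)

#' @rdname accessors
#' @export
setMethod("platformId", "CoverageTrack", function(x) x@platformId)

#' @rdname accessors
#' @export
setMethod("confidentRegions", "TruthSet", function(x) x@confidentRegions)

#' @rdname accessors
#' @export
setMethod("categoryCounts", "CombinedCallSet", function(x) {
    cat <- S4Vectors::mcols(x@calls)$category
    out <- table(factor(cat, levels = CATEGORY_LEVELS))
    setNames(as.integer(out), CATEGORY_LEVELS)
})

#' @rdname accessors
#' @export
setMethod("runConfig", "CombinedCallSet", function(x) x@config)

#' @rdname accessors
#' @export
setMethod("exons", "ToyGenome", function(x) x@exons)

#' @rdname accessors
#' @export
setMethod("sequences", "ToyGenome", function(x) x@sequences)

setMethod("show", "CallSet", function(object) {
    cat(sprintf("CallSet (platform %s): %d call(s)%s\n", object@platformId,
        length(object@calls),
        if (object@trimOnly) " [trim-only normalization]" else ""))
    if (length(object@calls)) {
        tab <- table(S4Vectors::mcols(object@calls)$vclass)
        cat("  classes:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
        tab <- table(S4Vectors::mcols(object@calls)$passStatus)
        cat("  pass:   ", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
    }
})

setMethod("show", "TruthSet", function(object) {
    cat(sprintf("TruthSet '%s': %d call(s) over %d confident interval(s) (%s bases)\n",
        object@versionLabel, length(object@calls),
        length(object@confidentRegions),
        format(totalBases(object@confidentRegions), big.mark = ",")))
})

setMethod("show", "CoverageTrack", function(object) {
    cat(sprintf("CoverageTrack (platform %s): %d contig(s)\n",
        object@platformId, length(object@depth)))
})

setMethod("show", "CombinedCallSet", function(object) {
    cat(sprintf("CombinedCallSet: %d classified call(s)\n", length(object@calls)))
    cc <- categoryCounts(object)
    for (k in names(cc)) cat(sprintf("  %-22s %d\n", k, cc[[k]]))
})

setMethod("show", "PlatformProfile", function(object) {
    cat(sprintf(paste0("PlatformProfile: sens SNV=%.3f indel=%.3f, FP/Mb=%.2f, ",
        "zygosity err=%.4f,\n  depth mean=%.0f size=%.1f, GC dropout %s/%.2f, ",
        "NoPass rate=%.3f\n"),
        object@snvSensitivity, object@indelSensitivity, object@fpPerMb,
        object@zygosityErrorRate, object@meanDepth, object@depthDispersion,
        object@gcDropoutDirection, object@gcDropoutStrength, object@nopassRate))
})

setMethod("show", "ToyGenome", function(object) {
    cat(sprintf("ToyGenome: %d contig(s) (%s bases), %d exon(s) (%s bases)\n",
        length(object@sequences),
        format(sum(Biostrings::width(object@sequences)), big.mark = ","),
        length(object@exons),
        format(sum(GenomicRanges::width(object@exons)), big.mark = ",")))
})
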