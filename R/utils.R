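#' @importFrom methods new validObject is setValidity show slot
#' @importFrom stats rbeta rbinom rnbinom rpois runif setNames
#' @importFrom utils read.table write.table packageVersion
NULL

CATEGORY_LEVELS <- c("ORTHOGONALLY_CONFIRMED", "RELIABLE", "LIKELY_TP", "LIKELY_FP")
CROSSTAB_LEVELS <- c(CATEGORY_LEVELS, "NOT_CALLED")
ZYGOSITY_LEVELS <- c("HET", "HOM_ALT")

#' Variant class of a ref/alt allele pair
#'
#' SNV for a single-base substitution, MNV for an equal-length multi-base
#' substitution, INDEL otherwise.
#'
#' @param ref,alt Character vectors of reference and alternate alleles.
#' @return Character vector over \code{c("SNV", "MNV", "INDEL")}.
#' @export
variantClass <- function(ref, alt) {
    nr <- nchar(ref)
    na <- nchar(alt)
    ifelse(nr != na, "INDEL", ifelse(nr == 1L, "SNV", "MNV"))
}

# Canonical site key: chrom:pos:ref:alt (zygosity-insensitive identity).
variantKey <- function(chrom, pos, ref, alt) {
    paste(chrom, pos, ref, alt, sep = ":")
}

# Key including zygosity, used for cross-platform genotype-aware matching.
genotypeKey <- function(chrom, pos, ref, alt, zygosity) {
    paste(chrom, pos, ref, alt, zygosity, sep = ":")
}

# round() away from the banker's edge: percentages printed the way report
# tables print them (half-up at the last digit).
roundHalfUp <- function(x, digits = 0L) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a percentage the way the category report prints it
#'
#' Two decimals, except values of at least 99.99 which carry three so that
#' near-perfect predictive values (e.g. one error in ~50,000 calls) remain
#' distinguishable from 100.
#'
#' @param x Numeric percentage (0-100 scale), possibly NA.
#' @return Character vector.
#' @export
formatPct <- function(x) {
    out <- ifelse(is.na(x), NA_character_,
        ifelse(!is.na(x) & x >= 99.99 & x < 100,
            sprintf("%.3f", roundHalfUp(x, 3L)),
            sprintf("%.2f", roundHalfUp(x, 2L))))
    out
}

# Internal: TRUE where the FILTER string counts as caller-filtered
# (anything other than PASS or missing).
isCallerFiltered <- function(filter) {
    !(is.na(filter) | filter == "PASS" | filter == "." | filter == "")
}

# Harmonize contig names via an explicit alias map (named character vector:
# names are source contigs, values the canonical names). A non-empty overlap
# is required; disjoint contig universes without a map are an error rather
# than a silent zero-overlap analysis.
applyContigAliases <- function(contigs, aliases = NULL) {
    contigs <- as.character(contigs)
    if (!is.null(aliases)) {
        hit <- contigs %in% names(aliases)
        contigs[hit] <- unname(aliases[contigs[hit]])
    }
    contigs
}

checkContigOverlap <- function(a, b, what = c("call set", "regions")) {
    if (length(a) && length(b) && !length(intersect(unique(a), unique(b)))) {
        stop("contig names of ", what[1L], " (", paste(utils::head(unique(a), 3), collapse = ","),
            ") share nothing with ", what[2L], " (",
            paste(utils::head(unique(b), 3), collapse = ","),
            "); supply a contig alias map (e.g. c(`1` = \"chr1\"))")
    }
    invisible(TRUE)
}
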