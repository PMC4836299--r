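#' Cross-tabulate confidence categories between replicate runs
#'
#' Variants are matched across the two runs by canonical identity
#' (chrom:pos:ref:alt, ignoring zygosity: a zygosity flip between runs shows
#' up as a category change, not as a new variant). A variant absent from one
#' run maps to NOT_CALLED on that side; a variant absent from both is not
#' observable, so the NOT_CALLED/NOT_CALLED cell is structurally zero.
#'
#' @param run1,run2 \linkS4class{CombinedCallSet}s from the same individual.
#' @param regions GRanges restricting both runs to a shared analysis region
#'   (required: category mixtures are only comparable over the same bases).
#' @return A 5x5 integer matrix, rows = run 1 categories, columns = run 2.
#' @export
crosstabCategories <- function(run1, run2, regions) {
    if (missing(regions) || is.null(regions))
        stop("a shared analysis region is required")
    grab <- function(ccs) {
        gr <- calls(ccs)
        mc <- S4Vectors::mcols(gr)
        df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
            pos = GenomicRanges::start(gr), ref = mc$ref, alt = mc$alt,
            category = mc$category, stringsAsFactors = FALSE)
        df <- restrictTable(df, regions)
        key <- variantKey(df$chrom, df$pos, df$ref, df$alt)
        df <- df[!duplicated(key), , drop = FALSE]
        setNames(df$category, variantKey(df$chrom, df$pos, df$ref, df$alt))
    }
    c1 <- grab(run1)
    c2 <- grab(run2)
    keys <- union(names(c1), names(c2))
    cat1 <- ifelse(keys %in% names(c1), c1[keys], "NOT_CALLED")
    cat2 <- ifelse(keys %in% names(c2), c2[keys], "NOT_CALLED")
    table(factor(cat1, levels = CROSSTAB_LEVELS),
        factor(cat2, levels = CROSSTAB_LEVELS))
}

#' Per-category repeat rate from a category cross-tabulation
#'
#' The fraction of run-1 variants of a category assigned the same category
#' in run 2: diagonal cell over row sum. NA for an empty row.
#'
#' @param tab Matrix from \code{\link{crosstabCategories}}, or any square
#'   matrix with category dimnames.
#' @param category Row/column name; default all categories.
#' @return Named numeric vector of repeat rates.
#' @export
repeatRate <- function(tab, category = rownames(tab)) {
    vapply(category, function(k) {
        rs <- sum(tab[k, ])
        if (rs > 0) tab[k, k] / rs else NA_real_
    }, numeric(1L))
}
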