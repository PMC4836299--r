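test_that("GC fraction excludes ambiguous bases", {
    ref <- Biostrings::DNAStringSet(c(c1 = "ATATGCGCACGTN"))
    iv <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(1L, 5L, 9L), c(4L, 8L, 13L)))
    expect_equal(computeGc(iv, ref), c(0, 1, 0.5))
    allN <- Biostrings::DNAStringSet(c(c1 = "NNNN"))
    expect_true(is.na(computeGc(GenomicRanges::GRanges("c1",
        IRanges::IRanges(1L, 4L)), allN)))
})

test_that("depth normalization scales to the target exome-wide mean", {
    exonsGr <- GenomicRanges::GRanges("c1",
        IRanges::IRanges(c(1L, 101L), width = 100L))
    runs <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(1L, 101L), width = 100L))
    S4Vectors::mcols(runs)$depth <- c(100, 100)
    nd <- normalizeDepths(exonsGr, coverageTrack(runs, "A"))
    expect_equal(nd$norm, nd$raw)  # mean already 100

    S4Vectors::mcols(runs)$depth <- c(90, 10)  # exome mean 50
    nd <- normalizeDepths(exonsGr, coverageTrack(runs, "A"))
    expect_equal(nd$norm, c(180, 20))

    zero <- GenomicRanges::GRanges("c1", IRanges::IRanges(1L, 10L))
    S4Vectors::mcols(zero)$depth <- 0
    expect_error(normalizeDepths(exonsGr, coverageTrack(zero, "A")), "zero")
})

test_that("per-exon means match a per-base brute-force average", {
    set.seed(17)
    nExon <- 60L
    exonsGr <- GenomicRanges::GRanges("c1",
        IRanges::IRanges(seq(1L, by = 150L, length.out = nExon),
            width = sample(40:120, nExon, replace = TRUE)))
    runs <- GenomicRanges::GRanges("c1",
        IRanges::IRanges(seq(1L, by = 37L, length.out = 260L), width = 37L))
    S4Vectors::mcols(runs)$depth <- sample(0:80, 260L, replace = TRUE)
    tr <- coverageTrack(runs, "A")
    got <- meanDepth(tr, exonsGr)
    want <- vapply(seq_len(nExon), function(i) {
        p <- GenomicRanges::start(exonsGr)[i]:GenomicRanges::end(exonsGr)[i]
        mean(depthAt(tr, rep("c1", length(p)), p))
    }, numeric(1L))
    expect_equal(got, want)

    nd <- normalizeDepths(exonsGr, tr, targetMean = 100)
    w <- GenomicRanges::width(exonsGr)
    expect_lt(abs(sum(nd$norm * w) / sum(w) / 100 - 1), 1e-9)
})

test_that("quadrants classify every exon and survive joint rescaling", {
    exonsGr <- GenomicRanges::GRanges("c1",
        IRanges::IRanges(c(1L, 101L, 201L, 301L), width = 100L))
    mkTrack <- function(depths, id) {
        runs <- GenomicRanges::GRanges("c1",
            IRanges::IRanges(c(1L, 101L, 201L, 301L), width = 100L))
        S4Vectors::mcols(runs)$depth <- depths
        coverageTrack(runs, id)
    }
    # engineered so each exon lands in a different quadrant after
    # normalization to mean 100 (mean of each track is 100 already)
    trA <- mkTrack(c(190, 180, 15, 15), "A")
    trB <- mkTrack(c(190, 15, 180, 15), "B")
    ec <- exonCoverage(exonsGr, trA, trB)
    q <- quadrantCounts(ec)
    expect_equal(setNames(q$count, q$quadrant),
        c(both_ge = 1L, a_only = 1L, b_only = 1L, neither = 1L))
    expect_equal(sum(q$count), length(exonsGr))

    # multiplying both raw tracks by a constant changes nothing
    trA5 <- mkTrack(5 * c(190, 180, 15, 15), "A")
    trB5 <- mkTrack(5 * c(190, 15, 180, 15), "B")
    q5 <- quadrantCounts(exonCoverage(exonsGr, trA5, trB5))
    expect_equal(q5$count, q$count)
})

test_that("the quadrant percentage is reported to one decimal", {
    q <- data.frame(count = c(183148L, 0L, 0L, 4327L))
    expect_equal(sprintf("%.1f", orthocombine:::roundHalfUp(
        100 * 4327 / 187475, 1L)), "2.3")
})

test_that("zero-depth exons floor at 1 only in the plot columns", {
    exonsGr <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(1L, 101L), width = 100L))
    runs <- GenomicRanges::GRanges("c1", IRanges::IRanges(1L, 100L))
    S4Vectors::mcols(runs)$depth <- 40
    ec <- exonCoverage(exonsGr, coverageTrack(runs, "A"), coverageTrack(runs, "B"))
    mc <- S4Vectors::mcols(ec)
    expect_equal(mc$norm_A[2], 0)
    expect_equal(mc$plot_A[2], 1)
    q <- quadrantCounts(ec, threshold = 0.5)  # thresholds see the true zero
    expect_equal(q$count[q$quadrant == "neither"], 1L)
})

test_that("GC binning puts gc = 1 in the last bin and catches bad input", {
    exonsGr <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(1L, 101L), width = 100L))
    runs <- GenomicRanges::GRanges("c1", IRanges::IRanges(1L, 200L))
    S4Vectors::mcols(runs)$depth <- 100
    ec <- exonCoverage(exonsGr, coverageTrack(runs, "A"), coverageTrack(runs, "B"))
    S4Vectors::mcols(ec)$gc <- c(0.5, 1.0)
    bins <- gcBinLowCoverage(ec, threshold = 20)
    expect_equal(sum(bins$low_A), 0L)  # everything covered
    S4Vectors::mcols(ec)$norm_A <- c(50, 5)
    bins <- gcBinLowCoverage(ec, threshold = 20)
    expect_equal(bins$low_A[nrow(bins)], 1L)
    S4Vectors::mcols(ec)$gc <- c(0.5, 1.2)
    expect_error(gcBinLowCoverage(ec), "\\[0, 1\\]")
})

test_that("platform-specific GC dropout lands in opposite GC tails", {
    # a broad GC spread so both tails are populated
    genome <- toyGenome(nContigs = 1L, exonsPerContig = 600L, exonWidth = 150L,
        gap = 50L, gcAlpha = 1.2, gcBeta = 1.2, seed = 23L)
    truth <- generateTruth(genome, nSnv = 10L, nIndel = 0L, seed = 24L)
    pA <- platformProfile(meanDepth = 100, depthDispersion = 5,
        gcDropoutDirection = "AT", gcDropoutStrength = 1)
    pB <- platformProfile(meanDepth = 100, depthDispersion = 5,
        gcDropoutDirection = "GC", gcDropoutStrength = 1)
    simA <- simulatePlatformCalls(truth, pA, genome, "A", seed = 25L)
    simB <- simulatePlatformCalls(truth, pB, genome, "B", seed = 26L)
    ec <- exonCoverage(exons(genome), simA$coverage, simB$coverage,
        reference = sequences(genome))
    q <- quadrantCounts(ec)
    expect_gt(q$count[q$quadrant == "a_only"], 0L)
    expect_gt(q$count[q$quadrant == "b_only"], 0L)
    bins <- gcBinLowCoverage(ec)
    lowGc <- bins$gc_high <= 0.3
    highGc <- bins$gc_low >= 0.7
    # A's low-coverage mass concentrates at low GC, B's at high GC
    expect_gt(sum(bins$low_A[lowGc]), sum(bins$low_A[highGc]))
    expect_gt(sum(bins$low_B[highGc]), sum(bins$low_B[lowGc]))
})

test_that("exon padding widens intervals without going below base 1", {
    g <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(5L, 100L), c(20L, 150L)))
    p <- padExons(g, 10L)
    expect_equal(GenomicRanges::start(p), c(1L, 90L))
    expect_equal(GenomicRanges::end(p), c(30L, 160L))
})
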