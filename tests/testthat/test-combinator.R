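mkCs <- function(pos, ref, alt, zygosity = "HET", dp = 30L, gq = 60L,
        filter = "PASS", platform = "A", chrom = "c1") {
    n <- length(pos)
    callSet(data.frame(chrom = rep(chrom, length.out = n), pos = pos, ref = ref, alt = alt,
        zygosity = rep(zygosity, length.out = n), dp = rep(dp, length.out = n),
        gq = rep(gq, length.out = n),
        upstreamFilter = rep(filter, length.out = n),
        stringsAsFactors = FALSE), platform)
}

constTrack <- function(depth, platform, to = 100000L) {
    runs <- GenomicRanges::GRanges("c1", IRanges::IRanges(1L, to))
    S4Vectors::mcols(runs)$depth <- depth
    coverageTrack(runs, platform)
}

test_that("the DP/GQ pass filter uses strict bounds and never upgrades", {
    cs <- mkCs(pos = c(10L, 20L, 30L, 40L, 50L),
        ref = "A", alt = "T",
        dp = c(9L, 8L, 100L, 50L, NA),
        gq = c(21L, 99L, 20L, NA, 60L),
        filter = c("PASS", "PASS", "PASS", "PASS", "lowqual"))
    expect_message(f <- applyPassFilter(cs), "missing GQ")
    st <- callTable(calls(f))$passStatus
    expect_equal(st, c("PASS",     # dp=9  > 8, gq=21 > 20
                       "NOPASS",   # dp=8 fails the strict bound
                       "NOPASS",   # gq=20 fails the strict bound
                       "NOPASS",   # missing GQ
                       "CALLER_FILTERED"))
    expect_error(applyPassFilter(mkCs(1L, "A", "T", platform = "B")), "platform A")
})

test_that("matched sites partition the input calls", {
    a <- mkCs(pos = c(10L, 20L, 30L, 40L, 50L), ref = "A", alt = "T")
    b <- mkCs(pos = c(10L, 20L, 30L, 40L, 50L), ref = "A", alt = "T", platform = "B")
    m <- matchCallsets(a, b)
    expect_equal(nrow(m), 5L)
    expect_equal(unique(m$provenance), "BOTH")

    b2 <- mkCs(pos = c(60L, 70L), ref = "A", alt = "T", platform = "B")
    a2 <- mkCs(pos = c(10L, 20L, 30L), ref = "A", alt = "T")
    m2 <- matchCallsets(a2, b2)
    expect_equal(nrow(m2), 5L)
    expect_equal(sum(m2$provenance == "A_ONLY"), 3L)
    expect_equal(sum(m2$provenance == "B_ONLY"), 2L)
    expect_false(any(m2$conflict))

    dup <- mkCs(pos = c(10L, 10L), ref = "A", alt = "T")
    expect_warning(matchCallsets(dup, b2), "duplicate")
})

test_that("discordant calls at one locus become conflicting singletons", {
    a <- mkCs(10L, "A", "T", zygosity = "HET")
    b <- mkCs(10L, "A", "T", zygosity = "HOM_ALT", platform = "B")
    m <- matchCallsets(a, b)
    expect_equal(nrow(m), 2L)
    expect_setequal(m$provenance, c("A_ONLY", "B_ONLY"))
    expect_true(all(m$conflict))
})

test_that("classification follows the category decision table", {
    zero <- constTrack(0, "A")
    deep <- constTrack(50, "A")
    mk <- function(prov, passA, conflict = FALSE) data.frame(chrom = "c1",
        pos = 10L, ref = "A", alt = "T",
        zygosityA = if (prov == "B_ONLY") NA_character_ else "HET",
        zygosityB = if (prov == "A_ONLY") NA_character_ else "HET",
        dpA = 30L, gqA = 60L, passA = passA, dpB = 25L,
        provenance = prov, vclass = "SNV", conflict = conflict,
        stringsAsFactors = FALSE)
    cls <- function(df, covA) classifySites(df, covA, constTrack(25, "B"))$category
    expect_equal(cls(mk("BOTH", "PASS"), deep), "ORTHOGONALLY_CONFIRMED")
    expect_equal(cls(mk("BOTH", "NOPASS"), deep), "RELIABLE")
    expect_equal(cls(mk("BOTH", "CALLER_FILTERED"), deep), "RELIABLE")
    expect_equal(cls(mk("A_ONLY", "PASS"), deep), "LIKELY_TP")
    expect_equal(cls(mk("A_ONLY", "NOPASS"), deep), "LIKELY_FP")
    expect_equal(cls(mk("B_ONLY", NA_character_), zero), "LIKELY_TP")
    expect_equal(cls(mk("B_ONLY", NA_character_), deep), "LIKELY_FP")
    # a conflicting A call counts as platform-A coverage for rule purposes
    expect_equal(cls(mk("B_ONLY", NA_character_, conflict = TRUE), zero),
        "LIKELY_FP")
})

test_that("combining empty inputs yields an empty classified set", {
    e <- mkCs(integer(0), character(0), character(0))
    eb <- mkCs(integer(0), character(0), character(0), platform = "B")
    ccs <- combineCallsets(e, eb)
    expect_equal(sum(categoryCounts(ccs)), 0L)
    expect_equal(length(calls(ccs)), 0L)
})

test_that("categories partition all emitted calls and platform order only relabels", {
    set.seed(21)
    inst <- randomInstance(101L)
    csA <- makeCallSet(inst$dfA, "A")
    csB <- makeCallSet(inst$dfB, "B")
    covA <- blockTrack(inst$blocksA, "A")
    covB <- blockTrack(inst$blocksB, "B")
    ccs <- suppressWarnings(combineCallsets(csA, csB, covA, covB))
    cc <- categoryCounts(ccs)
    expect_equal(sum(cc), length(calls(ccs)))
    # pairing structure is symmetric: swapping inputs only relabels platforms
    m1 <- suppressWarnings(matchCallsets(csA, csB))
    m2 <- suppressWarnings(matchCallsets(makeCallSet(inst$dfB, "A"),
        makeCallSet(inst$dfA, "B")))
    t1 <- table(factor(m1$provenance, c("BOTH", "A_ONLY", "B_ONLY")))
    t2 <- table(factor(m2$provenance, c("BOTH", "A_ONLY", "B_ONLY")))
    expect_equal(as.integer(t1["BOTH"]), as.integer(t2["BOTH"]))
    expect_equal(as.integer(t1["A_ONLY"]), as.integer(t2["B_ONLY"]))
    expect_equal(as.integer(t1["B_ONLY"]), as.integer(t2["A_ONLY"]))
})

test_that("raising the depth threshold only demotes, never promotes", {
    fx <- tinyFixture()
    base <- combineCallsets(fx$csA, fx$csB, fx$covA, fx$covB, fx$regions)
    strict <- combineCallsets(fx$csA, fx$csB, fx$covA, fx$covB, fx$regions,
        thresholds = passThresholds(minDp = 40L))
    key <- function(ccs) {
        gr <- calls(ccs)
        setNames(S4Vectors::mcols(gr)$category,
            paste(GenomicRanges::seqnames(gr), GenomicRanges::start(gr),
                S4Vectors::mcols(gr)$ref, S4Vectors::mcols(gr)$alt))
    }
    k1 <- key(base); k2 <- key(strict)
    expect_setequal(names(k1), names(k2))
    allowed <- list(
        ORTHOGONALLY_CONFIRMED = c("ORTHOGONALLY_CONFIRMED", "RELIABLE"),
        RELIABLE = "RELIABLE",
        LIKELY_TP = c("LIKELY_TP", "LIKELY_FP"),
        LIKELY_FP = "LIKELY_FP")
    for (k in names(k1))
        expect_true(k2[[k]] %in% allowed[[k1[[k]]]],
            info = paste(k, k1[[k]], "->", k2[[k]]))
    expect_true(any(k2 == "RELIABLE" & k1 == "ORTHOGONALLY_CONFIRMED"))
})

test_that("classification agrees with the brute-force oracle on random instances", {
    for (seed in 300:314) {
        inst <- randomInstance(seed, maxCalls = 60L)
        ccs <- suppressWarnings(combineCallsets(
            makeCallSet(inst$dfA, "A"), makeCallSet(inst$dfB, "B"),
            blockTrack(inst$blocksA, "A"), blockTrack(inst$blocksB, "B")))
        got <- calls(ccs)
        gotKeys <- sort(paste(GenomicRanges::seqnames(got), GenomicRanges::start(got),
            S4Vectors::mcols(got)$ref, S4Vectors::mcols(got)$alt,
            S4Vectors::mcols(got)$category))
        want <- oracleCombine(inst$dfA, inst$dfB, inst$depthA, inst$depthB)
        wantKeys <- sort(paste(want$chrom, want$pos, want$ref, want$alt,
            want$category))
        expect_equal(gotKeys, wantKeys, info = paste("seed", seed))
    }
})

test_that("the combined VCF round-trips categories", {
    fx <- tinyFixture()
    ccs <- combineCallsets(fx$csA, fx$csB, fx$covA, fx$covB, fx$regions)
    path <- withr::local_tempfile(fileext = ".vcf")
    writeCombinedVcf(ccs, path)
    lines <- readLines(path)
    expect_true(any(grepl("CATEGORY=ORTHOGONALLY_CONFIRMED", lines)))
    back <- readCombinedVcf(path)
    expect_equal(categoryCounts(back), categoryCounts(ccs))
})
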