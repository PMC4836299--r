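# Internal helpers reused across test files.
callTable <- function(x) orthocombine:::callTable(x)

# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: normalization is checked against a whole-string diff of
# the mutated haplotype, matching against an all-pairs scan, and
# classification against a freshly written if-chain over the decision table.

# Apply a variant to a contig string and return the mutated haplotype.
applyVariantToSeq <- function(seq, pos, ref, alt) {
    stopifnot(substr(seq, pos, pos + nchar(ref) - 1L) == ref)
    paste0(substr(seq, 1L, pos - 1L), alt,
        substr(seq, pos + nchar(ref), nchar(seq)))
}

# Leftmost minimal representation by diffing the full reference string
# against the full mutated haplotype: trim the maximal common suffix, then
# the maximal common prefix that still leaves one base in each allele.
oracleNormalize <- function(seq, pos, ref, alt) {
    altSeq <- applyVariantToSeq(seq, pos, ref, alt)
    r <- strsplit(seq, "")[[1L]]
    a <- strsplit(altSeq, "")[[1L]]
    nr <- length(r); na <- length(a)
    j <- 0L
    while (j < min(nr, na) && r[nr - j] == a[na - j]) j <- j + 1L
    j <- min(j, min(nr, na) - 1L)  # keep >= 1 char in the shorter allele
    maxI <- min(nr, na) - j - 1L
    i <- 0L
    while (i < maxI && r[i + 1L] == a[i + 1L]) i <- i + 1L
    refAll <- paste(r[(i + 1L):(nr - j)], collapse = "")
    altAll <- paste(a[(i + 1L):(na - j)], collapse = "")
    # substitutions: also trim any remaining shared suffix/prefix pairs
    while (nchar(refAll) > 1L && nchar(altAll) > 1L &&
           substr(refAll, nchar(refAll), nchar(refAll)) ==
           substr(altAll, nchar(altAll), nchar(altAll))) {
        refAll <- substr(refAll, 1L, nchar(refAll) - 1L)
        altAll <- substr(altAll, 1L, nchar(altAll) - 1L)
    }
    while (nchar(refAll) > 1L && nchar(altAll) > 1L &&
           substr(refAll, 1L, 1L) == substr(altAll, 1L, 1L)) {
        refAll <- substring(refAll, 2L)
        altAll <- substring(altAll, 2L)
        i <- i + 1L
    }
    list(pos = i + 1L, ref = refAll, alt = altAll)
}

# Per-base split of an MNV, written independently of decomposeMnv().
oracleAtoms <- function(df) {
    rows <- list()
    for (k in seq_len(nrow(df))) {
        ref <- df$ref[k]; alt <- df$alt[k]
        if (nchar(ref) == nchar(alt) && nchar(ref) > 1L) {
            for (o in seq_len(nchar(ref))) {
                rb <- substr(ref, o, o); ab <- substr(alt, o, o)
                if (rb != ab)
                    rows[[length(rows) + 1L]] <- data.frame(chrom = df$chrom[k],
                        pos = df$pos[k] + o - 1L, ref = rb, alt = ab,
                        zygosity = df$zygosity[k], dp = df$dp[k], gq = df$gq[k],
                        upstreamFilter = df$upstreamFilter[k],
                        stringsAsFactors = FALSE)
            }
        } else {
            rows[[length(rows) + 1L]] <- df[k, c("chrom", "pos", "ref", "alt",
                "zygosity", "dp", "gq", "upstreamFilter")]
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

# Quadratic all-pairs matcher + decision-table classifier. depthA/depthB are
# functions(chrom, pos) -> depth. Returns a data.frame with one row per
# emitted call and its category. For every A call the full B table is
# scanned field by field (no key join).
oracleCombine <- function(dfA, dfB, depthA, depthB, minDp = 8L, minGq = 20L,
        coveredDepth = 8L) {
    dfA <- oracleAtoms(dfA)
    dfB <- oracleAtoms(dfB)
    dfA <- dfA[!duplicated(paste(dfA$chrom, dfA$pos, dfA$ref, dfA$alt, dfA$zygosity)), ]
    dfB <- dfB[!duplicated(paste(dfB$chrom, dfB$pos, dfB$ref, dfB$alt, dfB$zygosity)), ]
    passA <- character(nrow(dfA))
    for (i in seq_len(nrow(dfA))) {
        f <- dfA$upstreamFilter[i]
        if (!is.na(f) && !f %in% c("PASS", ".", "")) passA[i] <- "CALLER_FILTERED"
        else if (!is.na(dfA$dp[i]) && dfA$dp[i] > minDp &&
                 !is.na(dfA$gq[i]) && dfA$gq[i] > minGq) passA[i] <- "PASS"
        else passA[i] <- "NOPASS"
    }
    usedB <- rep(FALSE, nrow(dfB))
    catA <- character(nrow(dfA))
    for (i in seq_len(nrow(dfA))) {
        js <- which(!usedB & dfB$chrom == dfA$chrom[i] & dfB$pos == dfA$pos[i] &
            dfB$ref == dfA$ref[i] & dfB$alt == dfA$alt[i] &
            dfB$zygosity == dfA$zygosity[i])
        if (length(js)) {
            usedB[js[1L]] <- TRUE
            catA[i] <- if (passA[i] == "PASS") "ORTHOGONALLY_CONFIRMED" else "RELIABLE"
        } else {
            catA[i] <- if (passA[i] == "PASS") "LIKELY_TP" else "LIKELY_FP"
        }
    }
    solo <- which(!usedB)
    catB <- vapply(solo, function(j) {
        aAtLocus <- any(dfA$chrom == dfB$chrom[j] & dfA$pos == dfB$pos[j])
        covered <- depthA(dfB$chrom[j], dfB$pos[j]) >= coveredDepth || aAtLocus
        if (covered) "LIKELY_FP" else "LIKELY_TP"
    }, character(1L))
    out <- rbind(
        data.frame(chrom = dfA$chrom, pos = dfA$pos, ref = dfA$ref,
            alt = dfA$alt, zygosity = dfA$zygosity, category = catA,
            stringsAsFactors = FALSE),
        data.frame(chrom = dfB$chrom[solo], pos = dfB$pos[solo],
            ref = dfB$ref[solo], alt = dfB$alt[solo],
            zygosity = dfB$zygosity[solo],
            category = as.character(catB), stringsAsFactors = FALSE))
    rownames(out) <- NULL
    out
}

# Random canonical instance for the matching/classification oracle: SNVs and
# occasional MNVs at distinct loci, shared between platforms at a given rate,
# with random sub-threshold DP/GQ and random coverage.
randomInstance <- function(seed, maxCalls = 200L) {
    set.seed(seed)
    nA <- sample.int(maxCalls, 1L)
    nB <- sample.int(maxCalls, 1L)
    nShared <- sample.int(min(nA, nB), 1L)
    loci <- sample(seq(10L, 99990L, by = 10L), nA + nB - nShared)
    mkVars <- function(pos) {
        n <- length(pos)
        isMnv <- runif(n) < 0.1
        w <- ifelse(isMnv, sample(2:3, n, replace = TRUE), 1L)
        ref <- vapply(seq_len(n), function(i) paste(sample(
            if (isMnv[i]) c("A", "C") else c("A", "C", "G", "T"),
            w[i], replace = TRUE), collapse = ""), character(1L))
        alt <- vapply(seq_len(n), function(i) if (isMnv[i])
            paste(sample(c("G", "T"), w[i], replace = TRUE), collapse = "")
            else sample(setdiff(c("A", "C", "G", "T"), ref[i]), 1L), character(1L))
        data.frame(chrom = "c1", pos = pos, ref = ref, alt = alt,
            zygosity = sample(c("HET", "HOM_ALT"), n, replace = TRUE),
            dp = sample(c(0:12, 30L, 50L), n, replace = TRUE),
            gq = sample(c(0:25, 60L, 99L), n, replace = TRUE),
            upstreamFilter = sample(c("PASS", "PASS", "PASS", "lowqual"), n,
                replace = TRUE),
            stringsAsFactors = FALSE)
    }
    shared <- mkVars(loci[seq_len(nShared)])
    onlyA <- if (nA > nShared) mkVars(loci[nShared + seq_len(nA - nShared)]) else NULL
    onlyB <- if (nB > nShared) mkVars(loci[nA + seq_len(nB - nShared)]) else NULL
    sharedB <- shared
    sharedB$dp <- sample(c(0:12, 30L, 50L), nrow(sharedB), replace = TRUE)
    # a fraction of "shared" loci get discordant zygosity -> conflicting sites
    flip <- runif(nrow(sharedB)) < 0.15
    sharedB$zygosity[flip] <- ifelse(sharedB$zygosity[flip] == "HET", "HOM_ALT", "HET")
    dfA <- rbind(shared, onlyA)
    dfB <- rbind(sharedB, onlyB)
    dfB$upstreamFilter <- "PASS"
    # random coverage: depth 0/5/30 in 10 kb blocks
    blocksA <- sample(c(0, 5, 30), 10L, replace = TRUE)
    blocksB <- sample(c(0, 5, 30), 10L, replace = TRUE)
    list(dfA = dfA, dfB = dfB,
        depthA = function(chrom, pos) blocksA[pmin(10L, (pos - 1L) %/% 10000L + 1L)],
        depthB = function(chrom, pos) blocksB[pmin(10L, (pos - 1L) %/% 10000L + 1L)],
        blocksA = blocksA, blocksB = blocksB)
}

# CoverageTrack matching the block depth functions above.
blockTrack <- function(blocks, platformId) {
    runs <- GenomicRanges::GRanges("c1",
        IRanges::IRanges(seq(1L, by = 10000L, length.out = 10L), width = 10000L))
    S4Vectors::mcols(runs)$depth <- blocks
    coverageTrack(runs, platformId)
}

makeCallSet <- function(df, platformId) {
    df$passStatus <- ifelse(!is.na(df$upstreamFilter) &
        !df$upstreamFilter %in% c("PASS", ".", ""), "CALLER_FILTERED", "PASS")
    callSet(df, platformId)
}

# Random DNA string.
randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
    collapse = "")

# Shared exome-like fixture, generated once per test session.
.fixtureCache <- new.env(parent = emptyenv())
exomeFixture <- function(seed = 42L) {
    key <- paste0("ex", seed)
    if (is.null(.fixtureCache[[key]])) {
        dir <- file.path(tempdir(), paste0("exome_fixture_", seed))
        paths <- generateFixtureBundle(exomeLikeConfig(), dir, seed = seed)
        ref <- Biostrings::readDNAStringSet(paths$reference)
        names(ref) <- sub("\\s.*$", "", names(ref))
        .fixtureCache[[key]] <- list(
            paths = paths, ref = ref,
            csA = readCallset(paths$calls_a, "A", reference = ref),
            csB = readCallset(paths$calls_b, "B", reference = ref),
            covA = readCoverage(paths$coverage_a, "A"),
            covB = readCoverage(paths$coverage_b, "B"),
            regions = readBed(paths$exons),
            truth = readTruthSet(paths$truth_vcf, paths$truth_bed, reference = ref))
    }
    .fixtureCache[[key]]
}

tinyFixture <- function() {
    if (is.null(.fixtureCache$tiny)) {
        dir <- file.path(tempdir(), "tiny_fixture")
        paths <- tinyBundle(dir)
        ref <- Biostrings::readDNAStringSet(paths$reference)
        names(ref) <- sub("\\s.*$", "", names(ref))
        .fixtureCache$tiny <- list(
            paths = paths, ref = ref,
            csA = readCallset(paths$calls_a, "A", reference = ref),
            csB = readCallset(paths$calls_b, "B", reference = ref),
            covA = readCoverage(paths$coverage_a, "A"),
            covB = readCoverage(paths$coverage_b, "B"),
            regions = readBed(paths$exons),
            truth = readTruthSet(paths$truth_vcf, paths$truth_bed, reference = ref))
    }
    .fixtureCache$tiny
}
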