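#' Construct a PlatformProfile
#'
#' @param snvSensitivity,indelSensitivity Per-class call probability.
#' @param fpPerMb Expected false positives per megabase of exon.
#' @param zygosityErrorRate Probability a called variant's zygosity flips.
#' @param meanDepth Mean exon depth before GC dropout.
#' @param depthDispersion Negative-binomial size (larger = tighter depths).
#' @param gcDropoutDirection "AT" or "GC": the GC extreme where depth is
#'   lost.
#' @param gcDropoutStrength Fraction of depth lost at that extreme, in
#'   [0, 1].
#' @param nopassRate Probability a platform-A call carries sub-threshold DP
#'   or GQ.
#' @return A \linkS4class{PlatformProfile}.
#' @export
platformProfile <- function(snvSensitivity = 0.99, indelSensitivity = 0.9,
        fpPerMb = 2, zygosityErrorRate = 0.002, meanDepth = 100,
        depthDispersion = 5, gcDropoutDirection = c("AT", "GC"),
        gcDropoutStrength = 0, nopassRate = 0) {
    gcDropoutDirection <- match.arg(gcDropoutDirection)
    new("PlatformProfile", snvSensitivity = snvSensitivity,
        indelSensitivity = indelSensitivity, fpPerMb = fpPerMb,
        zygosityErrorRate = zygosityErrorRate, meanDepth = meanDepth,
        depthDispersion = depthDispersion,
        gcDropoutDirection = gcDropoutDirection,
        gcDropoutStrength = gcDropoutStrength, nopassRate = nopassRate)
}

#' @rdname platformProfile
#' @param x A PlatformProfile (for \code{profileToList}) or a named list as
#'   produced by it (for \code{profileFromList}); the list form is what the
#'   YAML config and manifests carry.
#' @export
profileToList <- function(x) {
    nm <- methods::slotNames("PlatformProfile")
    setNames(lapply(nm, function(s) methods::slot(x, s)), nm)
}

#' @rdname platformProfile
#' @export
profileFromList <- function(x) {
    do.call(platformProfile, x[names(x) %in% methods::slotNames("PlatformProfile")])
}

# Run expr with a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
        if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
        else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion",
        sample.kind = "Rejection")
    expr
}

BASES <- c("A", "C", "G", "T")

#' Generate a toy genome with GC-controlled exons
#'
#' Contigs are random sequence with exons at regular spacing; each exon's
#' sequence is generated to match a GC fraction drawn from a beta
#' distribution (realized GC is exact to the rounding of \code{gc * width},
#' well within 0.02). Deterministic for a fixed seed.
#'
#' @param nContigs Number of contigs.
#' @param exonsPerContig Exons per contig.
#' @param exonWidth Exon width in bp.
#' @param gap Intergenic gap between exons in bp.
#' @param gcAlpha,gcBeta Beta-distribution parameters for per-exon GC
#'   (defaults give a broad distribution centered near 0.48, emulating the
#'   GC spread of capture exomes).
#' @param seed Integer seed.
#' @return A \linkS4class{ToyGenome}.
#' @export
toyGenome <- function(nContigs = 1L, exonsPerContig = 100L, exonWidth = 200L,
        gap = 100L, gcAlpha = 5, gcBeta = 5.5, seed = 1L) {
    withSeed(seed, {
        seqs <- character(nContigs)
        exonList <- vector("list", nContigs)
        for (ci in seq_len(nContigs)) {
            ctg <- sprintf("ctg%02d", ci)
            len <- gap + exonsPerContig * (exonWidth + gap)
            chars <- sample(BASES, len, replace = TRUE)
            starts <- gap + 1L + (seq_len(exonsPerContig) - 1L) * (exonWidth + gap)
            gc <- rbeta(exonsPerContig, gcAlpha, gcBeta)
            for (ei in seq_len(exonsPerContig)) {
                nGc <- round(gc[ei] * exonWidth)
                isGc <- rep(FALSE, exonWidth)
                if (nGc > 0) isGc[sample.int(exonWidth, nGc)] <- TRUE
                ex <- ifelse(isGc, sample(c("G", "C"), exonWidth, replace = TRUE),
                    sample(c("A", "T"), exonWidth, replace = TRUE))
                chars[starts[ei]:(starts[ei] + exonWidth - 1L)] <- ex
            }
            seqs[ci] <- paste(chars, collapse = "")
            gr <- GenomicRanges::GRanges(ctg,
                IRanges::IRanges(starts, width = exonWidth))
            S4Vectors::mcols(gr)$gc <- gc
            exonList[[ci]] <- gr
        }
        names(seqs) <- sprintf("ctg%02d", seq_len(nContigs))
        ex <- unlist(GenomicRanges::GRangesList(exonList), use.names = FALSE)
        names(ex) <- sprintf("exon_%06d", seq_along(ex))
        new("ToyGenome", sequences = Biostrings::DNAStringSet(seqs), exons = ex)
    })
}

# Positions inside exons, at least `margin` bases from either exon edge.
exonInteriorPositions <- function(genome, margin = 10L) {
    ex <- exons(genome)
    keep <- GenomicRanges::width(ex) > 2L * margin
    ex <- ex[keep]
    pos <- unlist(lapply(seq_along(ex), function(i)
        (GenomicRanges::start(ex)[i] + margin):(GenomicRanges::end(ex)[i] - margin)))
    ctg <- rep(as.character(GenomicRanges::seqnames(ex)), GenomicRanges::width(ex) - 2L * margin)
    data.frame(chrom = ctg, pos = pos, stringsAsFactors = FALSE)
}

# Draw n distinct sites with >= spacing bp between sites on a contig.
drawSpacedSites <- function(cand, n, spacing = 10L) {
    if (n == 0L) return(cand[0L, , drop = FALSE])
    if (n > nrow(cand) / 10L)
        stop("infeasible variant density: ", n, " sites over ", nrow(cand), " bases")
    take <- min(nrow(cand), ceiling(n * 1.5) + 20L)
    for (round in 1:10) {
        idx <- sort(sample.int(nrow(cand), take))
        sel <- cand[idx, , drop = FALSE]
        ord <- order(sel$chrom, sel$pos)
        sel <- sel[ord, , drop = FALSE]
        ok <- c(TRUE, diff(sel$pos) >= spacing | sel$chrom[-1L] != sel$chrom[-nrow(sel)])
        sel <- sel[ok, , drop = FALSE]
        if (nrow(sel) >= n) return(sel[sample.int(nrow(sel), n), , drop = FALSE])
        take <- min(nrow(cand), take * 2L)
    }
    stop("could not place ", n, " variants with ", spacing, " bp spacing")
}

#' Generate a synthetic truth set over a toy genome
#'
#' Variants are canonical, non-overlapping (at least 10 bp apart), lie inside
#' exons, and are deterministic for a fixed seed. SNVs substitute one of the
#' three non-reference bases; indels are 1-3 bp insertions or deletions,
#' left-aligned against the genome. The exons serve as the confident
#' regions.
#'
#' @param genome A \linkS4class{ToyGenome}.
#' @param nSnv,nIndel Variant counts.
#' @param hetFraction Probability a variant is heterozygous.
#' @param seed Integer seed.
#' @return A \linkS4class{TruthSet}.
#' @export
generateTruth <- function(genome, nSnv, nIndel, hetFraction = 0.67, seed = 1L) {
    withSeed(seed, {
        ref <- sequences(genome)
        if (nSnv + nIndel == 0L) {
            gr <- GenomicRanges::GRanges()
            S4Vectors::mcols(gr) <- S4Vectors::DataFrame(ref = character(),
                alt = character(), vclass = character(), zygosity = character())
            return(truthSet(gr, exons(genome), "synthetic-truth"))
        }
        cand <- exonInteriorPositions(genome)
        sites <- drawSpacedSites(cand, nSnv + nIndel, spacing = 10L)
        sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
        isSnv <- rep(FALSE, nrow(sites))
        if (nSnv > 0) isSnv[sample.int(nrow(sites), nSnv)] <- TRUE
        refAll <- character(nrow(sites))
        altAll <- character(nrow(sites))
        for (i in seq_len(nrow(sites))) {
            rs <- ref[[sites$chrom[i]]]
            b <- as.character(Biostrings::subseq(rs, sites$pos[i], sites$pos[i]))
            if (isSnv[i]) {
                refAll[i] <- b
                altAll[i] <- sample(setdiff(BASES, b), 1L)
            } else {
                len <- sample(1:3, 1L)
                if (runif(1) < 0.5) {  # insertion
                    refAll[i] <- b
                    altAll[i] <- paste0(b, paste(sample(BASES, len, replace = TRUE),
                        collapse = ""))
                } else {               # deletion
                    refAll[i] <- as.character(Biostrings::subseq(rs, sites$pos[i],
                        sites$pos[i] + len))
                    altAll[i] <- b
                }
            }
        }
        nv <- normalizeVariant(sites$chrom, sites$pos, refAll, altAll, ref)
        nv$zygosity <- ifelse(runif(nrow(nv)) < hetFraction, "HET", "HOM_ALT")
        # left-alignment can shift a variant; drop any that now collide
        key <- variantKey(nv$chrom, nv$pos, nv$ref, nv$alt)
        nv <- nv[!duplicated(key), , drop = FALSE]
        gr <- GenomicRanges::GRanges(nv$chrom,
            IRanges::IRanges(nv$pos, width = nchar(nv$ref)))
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(ref = nv$ref, alt = nv$alt,
            vclass = nv$vclass, zygosity = nv$zygosity)
        truthSet(gr, exons(genome), "synthetic-truth")
    })
}

# Multiplicative depth factor for an exon's GC under a dropout profile:
# linear in |gc - 0.5| on the dropout side, 1 - strength at the extreme.
gcDepthFactor <- function(gc, direction, strength) {
    d <- if (direction == "AT") pmax(0, 0.5 - gc) else pmax(0, gc - 0.5)
    1 - strength * 2 * d
}

#' Simulate one platform's call set and coverage track
#'
#' Each truth variant is emitted with its class sensitivity, with zygosity
#' flipped at the profile's error rate; false positives are placed uniformly
#' over exon bases at the profile's per-Mb rate (SNVs with a uniform
#' non-reference allele, plus 1-bp indels); exon depth is drawn from a
#' negative binomial around the profile mean scaled by the GC-dropout
#' factor, and the DP field of each call is its exon's depth. For platform A
#' a \code{nopassRate} fraction of calls is emitted with sub-threshold DP or
#' GQ. Deterministic for a fixed seed.
#'
#' @param truth A \linkS4class{TruthSet}.
#' @param profile A \linkS4class{PlatformProfile}.
#' @param genome The \linkS4class{ToyGenome} the truth was generated on.
#' @param platformId "A" or "B".
#' @param seed Integer seed.
#' @return \code{list(calls = CallSet, coverage = CoverageTrack)}.
#' @export
simulatePlatformCalls <- function(truth, profile, genome, platformId = "A",
        seed = 1L) {
    withSeed(seed, {
        ex <- exons(genome)
        gc <- S4Vectors::mcols(ex)$gc
        mu <- profile@meanDepth *
            gcDepthFactor(gc, profile@gcDropoutDirection, profile@gcDropoutStrength)
        depth <- rnbinom(length(ex), size = profile@depthDispersion, mu = pmax(mu, 1e-9))
        runs <- GenomicRanges::granges(ex)
        S4Vectors::mcols(runs)$depth <- depth
        track <- coverageTrack(runs, platformId)

        tt <- callTable(calls(truth))
        sens <- ifelse(tt$vclass == "SNV", profile@snvSensitivity,
            profile@indelSensitivity)
        called <- runif(nrow(tt)) < sens
        emitted <- tt[called, , drop = FALSE]
        flip <- runif(nrow(emitted)) < profile@zygosityErrorRate
        emitted$zygosity <- ifelse(flip,
            ifelse(emitted$zygosity == "HET", "HOM_ALT", "HET"), emitted$zygosity)

        exonMb <- sum(as.numeric(GenomicRanges::width(ex))) / 1e6
        nFp <- rpois(1L, profile@fpPerMb * exonMb)
        fp <- NULL
        if (nFp > 0) {
            cand <- exonInteriorPositions(genome)
            cand <- cand[!(paste(cand$chrom, cand$pos) %in%
                c(paste(tt$chrom, tt$pos), paste(tt$chrom, tt$pos + 1L),
                  paste(tt$chrom, tt$pos - 1L))), , drop = FALSE]
            sites <- drawSpacedSites(cand, nFp, spacing = 10L)
            ref <- sequences(genome)
            refAll <- character(nFp); altAll <- character(nFp)
            isSnv <- runif(nFp) < 0.9
            for (i in seq_len(nFp)) {
                b <- as.character(Biostrings::subseq(ref[[sites$chrom[i]]],
                    sites$pos[i], sites$pos[i]))
                if (isSnv[i]) {
                    refAll[i] <- b
                    altAll[i] <- sample(setdiff(BASES, b), 1L)
                } else if (runif(1) < 0.5) {
                    refAll[i] <- b
                    altAll[i] <- paste0(b, sample(BASES, 1L))
                } else {
                    refAll[i] <- as.character(Biostrings::subseq(ref[[sites$chrom[i]]],
                        sites$pos[i], sites$pos[i] + 1L))
                    altAll[i] <- b
                }
            }
            fp <- normalizeVariant(sites$chrom, sites$pos, refAll, altAll, ref)
            fp$zygosity <- "HET"
        }
        df <- rbind(emitted[c("chrom", "pos", "ref", "alt", "zygosity")],
            if (is.null(fp)) NULL else fp[c("chrom", "pos", "ref", "alt", "zygosity")])
        df <- df[!duplicated(variantKey(df$chrom, df$pos, df$ref, df$alt)), ,
            drop = FALSE]
        n <- nrow(df)
        hit <- GenomicRanges::findOverlaps(
            GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$pos, width = 1L)),
            ex, select = "first")
        df$dp <- as.integer(depth[hit])
        df$dp[is.na(df$dp)] <- 0L
        df$gq <- sample(40:99, n, replace = TRUE)
        if (platformId == "A" && profile@nopassRate > 0 && n > 0) {
            nopass <- runif(n) < profile@nopassRate
            viaDp <- nopass & runif(n) < 0.5
            df$dp[viaDp] <- sample(0:8, sum(viaDp), replace = TRUE)
            df$gq[nopass & !viaDp] <- sample(0:20, sum(nopass & !viaDp), replace = TRUE)
        }
        df$upstreamFilter <- "PASS"
        list(calls = callSet(df, platformId), coverage = track)
    })
}

# Internal: write a TruthSet's calls + regions.
writeTruthFiles <- function(truth, vcfPath, bedPath) {
    tt <- callTable(calls(truth))
    writeVcfRecords(tt, vcfPath, sample = "TRUTH")
    writeBed(confidentRegions(truth), bedPath)
    invisible(NULL)
}

#' Default configuration of the exome-like fixture bundle
#'
#' A scaled-down exome: 3 Mb of 200 bp exons over two contigs, ~1,700 truth
#' variants (SNV:indel about 33:1, heterozygous fraction 0.67), and two
#' platform profiles with the error structure of a hybrid-capture
#' reversible-terminator platform (role A: SNV sensitivity 0.996, indel
#' 0.95, 1.85 FP/Mb, AT-side GC dropout, NoPass rate 0.003) and an
#' amplicon semiconductor platform (role B: SNV 0.969, indel 0.51, 2.66
#' FP/Mb, GC-side dropout).
#'
#' @return A nested list consumable by \code{\link{generateFixtureBundle}}.
#' @export
exomeLikeConfig <- function() {
    list(
        genome = list(nContigs = 2L, exonsPerContig = 7500L, exonWidth = 200L,
            gap = 100L),
        truth = list(nSnv = 1650L, nIndel = 50L, hetFraction = 0.67),
        profileA = profileToList(platformProfile(snvSensitivity = 0.996,
            indelSensitivity = 0.95, fpPerMb = 1.85, zygosityErrorRate = 0.002,
            meanDepth = 125, depthDispersion = 5, gcDropoutDirection = "AT",
            gcDropoutStrength = 0.7, nopassRate = 0.003)),
        profileB = profileToList(platformProfile(snvSensitivity = 0.969,
            indelSensitivity = 0.51, fpPerMb = 2.66, zygosityErrorRate = 0.002,
            meanDepth = 133, depthDispersion = 5, gcDropoutDirection = "GC",
            gcDropoutStrength = 0.7, nopassRate = 0)))
}

#' Generate a fixture bundle on disk
#'
#' Writes a reference FASTA, exon BED, truth VCF + confident-region BED, two
#' platform VCFs, two coverage run files, and a YAML manifest recording the
#' configuration and seeds. Deterministic for a fixed config + seed.
#'
#' @param config Nested list as from \code{\link{exomeLikeConfig}} (elements
#'   \code{genome}, \code{truth}, \code{profileA}, \code{profileB}).
#' @param outDir Output directory (created if needed).
#' @param seed Master seed; sub-seeds for genome, truth and the two
#'   platforms are derived from it.
#' @return Named list of the file paths written, invisibly.
#' @export
generateFixtureBundle <- function(config, outDir, seed = 1L) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    seed <- as.integer(seed)
    genome <- do.call(toyGenome, c(config$genome, list(seed = seed)))
    truth <- do.call(generateTruth, c(list(genome = genome), config$truth,
        list(seed = seed + 1L)))
    simA <- simulatePlatformCalls(truth, profileFromList(config$profileA),
        genome, platformId = "A", seed = seed + 2L)
    simB <- simulatePlatformCalls(truth, profileFromList(config$profileB),
        genome, platformId = "B", seed = seed + 3L)
    paths <- list(
        reference = file.path(outDir, "reference.fa"),
        exons = file.path(outDir, "exons.bed"),
        truth_vcf = file.path(outDir, "truth.vcf"),
        truth_bed = file.path(outDir, "truth_regions.bed"),
        calls_a = file.path(outDir, "calls_A.vcf"),
        calls_b = file.path(outDir, "calls_B.vcf"),
        coverage_a = file.path(outDir, "coverage_A.bed"),
        coverage_b = file.path(outDir, "coverage_B.bed"),
        manifest = file.path(outDir, "manifest.yaml"))
    Biostrings::writeXStringSet(sequences(genome), paths$reference)
    writeBed(exons(genome), paths$exons)
    writeTruthFiles(truth, paths$truth_vcf, paths$truth_bed)
    writeCallsetVcf(simA$calls, paths$calls_a, sample = "PLATFORM_A")
    writeCallsetVcf(simB$calls, paths$calls_b, sample = "PLATFORM_B")
    writeCoverage(simA$coverage, paths$coverage_a)
    writeCoverage(simB$coverage, paths$coverage_b)
    manifest <- list(tool = "orthocombine",
        version = as.character(packageVersion("orthocombine")),
        seed = seed,
        subSeeds = list(genome = seed, truth = seed + 1L,
            platformA = seed + 2L, platformB = seed + 3L),
        config = config,
        files = lapply(paths, basename))
    yaml::write_yaml(manifest, paths$manifest)
    invisible(paths)
}

#' The "tiny" hand-checkable fixture bundle
#'
#' Twelve variants on one 1,200 bp contig with three exons, constructed so
#' that every confidence category occurs with known counts when the two
#' platform call sets are combined: five Orthogonally Confirmed (one
#' expressed with padded alleles on platform A, one indel right-shifted on
#' platform A inside a planted homopolymer), two Reliable (one NoPass by DP,
#' one by GQ), three Likely TP (two Pass singletons on A, one platform-B
#' singleton with no platform-A coverage), and two Likely FP (one NoPass A
#' singleton, one B singleton with deep A coverage). Fully deterministic.
#'
#' @param outDir Output directory.
#' @return Named list of file paths (as \code{\link{generateFixtureBundle}}),
#'   invisibly.
#' @export
tinyBundle <- function(outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    chars <- rep(BASES, length.out = 1200L)
    chars[154:161] <- c("C", "T", "A", "A", "A", "A", "A", "G")
    ref <- Biostrings::DNAStringSet(setNames(paste(chars, collapse = ""), "chr1"))
    exonsGr <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(101L, 501L, 901L), c(300L, 700L, 1100L)))
    names(exonsGr) <- c("exon_1", "exon_2", "exon_3")
    S4Vectors::mcols(exonsGr)$gc <- computeGc(exonsGr, ref)

    # canonical truth for the 12 sites (s3 is the homopolymer deletion)
    truthDf <- data.frame(
        chrom = "chr1",
        pos = c(121L, 140L, 155L, 181L, 201L, 222L, 241L, 521L, 542L, 561L,
            582L, 921L),
        ref = c("A", "T", "TA", "A", "A", "C", "A", "A", "C", "A", "C", "A"),
        alt = c("G", "G", "T", "C", "T", "T", "G", "T", "A", "G", "G", "C"),
        zygosity = c("HET", "HOM_ALT", "HET", "HET", "HOM_ALT", "HET", "HET",
            "HET", "HOM_ALT", "HET", "HET", "HET"),
        stringsAsFactors = FALSE)
    truthGr <- GenomicRanges::GRanges(truthDf$chrom,
        IRanges::IRanges(truthDf$pos, width = nchar(truthDf$ref)))
    S4Vectors::mcols(truthGr) <- S4Vectors::DataFrame(ref = truthDf$ref,
        alt = truthDf$alt, vclass = variantClass(truthDf$ref, truthDf$alt),
        zygosity = truthDf$zygosity)
    truth <- truthSet(truthGr, exonsGr, "tiny-truth")

    # platform A: sites 1-9 and 11, with s2 padded and s3 right-shifted
    dfA <- data.frame(
        chrom = "chr1",
        pos = c(121L, 139L, 159L, 181L, 201L, 222L, 241L, 521L, 542L, 561L),
        ref = c("A", "GT", "AA", "A", "A", "C", "A", "A", "C", "A"),
        alt = c("G", "GG", "A", "C", "T", "T", "G", "T", "A", "G"),
        zygosity = truthDf$zygosity[c(1:9, 10L)],
        dp = c(30L, 30L, 30L, 30L, 30L, 5L, 30L, 50L, 45L, 4L),
        gq = c(60L, 60L, 60L, 60L, 60L, 60L, 10L, 80L, 77L, 70L),
        upstreamFilter = "PASS", stringsAsFactors = FALSE)
    # platform B: sites 1-7 (canonical forms), 10 and 12
    dfB <- data.frame(
        chrom = "chr1",
        pos = c(121L, 140L, 155L, 181L, 201L, 222L, 241L, 921L, 582L),
        ref = c("A", "T", "TA", "A", "A", "C", "A", "A", "C"),
        alt = c("G", "G", "T", "C", "T", "T", "G", "C", "G"),
        zygosity = truthDf$zygosity[c(1:7, 12L, 11L)],
        dp = 25L, gq = 50L, upstreamFilter = "PASS", stringsAsFactors = FALSE)
    covA <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(101L, 501L), c(300L, 700L)))
    S4Vectors::mcols(covA)$depth <- c(30, 50)
    covB <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(101L, 501L, 901L), c(300L, 700L, 1100L)))
    S4Vectors::mcols(covB)$depth <- 25

    paths <- list(
        reference = file.path(outDir, "reference.fa"),
        exons = file.path(outDir, "exons.bed"),
        truth_vcf = file.path(outDir, "truth.vcf"),
        truth_bed = file.path(outDir, "truth_regions.bed"),
        calls_a = file.path(outDir, "calls_A.vcf"),
        calls_b = file.path(outDir, "calls_B.vcf"),
        coverage_a = file.path(outDir, "coverage_A.bed"),
        coverage_b = file.path(outDir, "coverage_B.bed"),
        manifest = file.path(outDir, "manifest.yaml"))
    Biostrings::writeXStringSet(ref, paths$reference)
    writeBed(exonsGr, paths$exons)
    writeTruthFiles(truth, paths$truth_vcf, paths$truth_bed)
    writeVcfRecords(dfA, paths$calls_a, sample = "PLATFORM_A")
    writeVcfRecords(dfB, paths$calls_b, sample = "PLATFORM_B")
    writeCoverage(coverageTrack(covA, "A"), paths$coverage_a)
    writeCoverage(coverageTrack(covB, "B"), paths$coverage_b)
    yaml::write_yaml(list(tool = "orthocombine",
        version = as.character(packageVersion("orthocombine")),
        bundle = "tiny", files = lapply(paths, basename)), paths$manifest)
    invisible(paths)
}
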