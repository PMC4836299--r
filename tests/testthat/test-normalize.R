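test_that("shared-base trimming produces the canonical representation", {
    v <- normalizeVariant("chr1", 100L, "AT", "AC")
    expect_equal(v$pos, 101L)
    expect_equal(v$ref, "T")
    expect_equal(v$alt, "C")
    expect_equal(v$vclass, "SNV")
    expect_true(v$trim_only)

    v <- normalizeVariant("chr2", 500L, "G", "T")
    expect_equal(unlist(v[c("pos", "ref", "alt")], use.names = FALSE),
        c("500", "G", "T"))
})

test_that("indels are left-aligned to the leftmost placement in a repeat run", {
    ref <- Biostrings::DNAStringSet(c(c1 = "TAAAG"))
    v <- normalizeVariant("c1", 3L, "AA", "A", reference = ref)
    expect_equal(v$pos, 1L)
    expect_equal(v$ref, "TA")
    expect_equal(v$alt, "T")
    expect_equal(v$vclass, "INDEL")
    expect_false(v$trim_only)
    # the whole-haplotype diff oracle agrees
    o <- oracleNormalize("TAAAG", 3L, "AA", "A")
    expect_equal(list(v$pos, v$ref, v$alt), list(o$pos, o$ref, o$alt))
})

test_that("normalization agrees with the haplotype-diff oracle on random indels", {
    set.seed(7)
    for (k in 1:60) {
        # sequences with deliberate repeat structure to force shifting
        seq <- paste0(randomSeq(30),
            paste(rep(sample(c("A", "T", "AT", "CAG"), 1L), 8L), collapse = ""),
            randomSeq(30))
        n <- nchar(seq)
        pos <- sample(20:(n - 20L), 1L)
        if (runif(1) < 0.5) {
            len <- sample(1:4, 1L)
            ref <- substr(seq, pos, pos + len)
            alt <- substr(seq, pos, pos)
        } else {
            ref <- substr(seq, pos, pos)
            alt <- paste0(ref, randomSeq(sample(1:4, 1L)))
        }
        v <- normalizeVariant("c1", pos, ref, alt,
            reference = Biostrings::DNAStringSet(c(c1 = seq)))
        o <- oracleNormalize(seq, pos, ref, alt)
        expect_equal(list(v$pos, v$ref, v$alt), list(o$pos, o$ref, o$alt),
            info = sprintf("seed case %d: %d %s>%s over %s", k, pos, ref, alt, seq))
    }
})

test_that("normalization is idempotent and invariant to allele padding", {
    set.seed(11)
    seq <- randomSeq(4000)
    ref <- Biostrings::DNAStringSet(c(c1 = seq))
    for (k in 1:40) {
        pos <- sample(300:3500, 1L)
        kind <- sample(c("snv", "ins", "del"), 1L)
        b <- substr(seq, pos, pos)
        if (kind == "snv") { r <- b; a <- sample(setdiff(c("A","C","G","T"), b), 1L) }
        else if (kind == "ins") { r <- b; a <- paste0(b, randomSeq(sample(1:3, 1L))) }
        else { r <- substr(seq, pos, pos + sample(1:3, 1L)); a <- b }
        v1 <- normalizeVariant("c1", pos, r, a, ref)
        v2 <- normalizeVariant("c1", v1$pos, v1$ref, v1$alt, ref)
        expect_equal(v1[c("pos", "ref", "alt")], v2[c("pos", "ref", "alt")])
        # re-express with up to 5 padding bases on both sides and renormalize
        pad <- sample(1:5, 1L)
        left <- substr(seq, v1$pos - pad, v1$pos - 1L)
        right <- substr(seq, v1$pos + nchar(v1$ref), v1$pos + nchar(v1$ref) + pad - 1L)
        v3 <- normalizeVariant("c1", v1$pos - pad, paste0(left, v1$ref, right),
            paste0(left, v1$alt, right), ref)
        expect_equal(v1[c("pos", "ref", "alt")], v3[c("pos", "ref", "alt")])
    }
})

test_that("normalization rejects malformed input", {
    ref <- Biostrings::DNAStringSet(c(c1 = "ACGTACGTAC"))
    expect_error(normalizeVariant("c1", 3L, "T", "C", reference = ref),
        "reference mismatch")
    expect_error(normalizeVariant("c1", 3L, "G", "G"), "not a variant")
    expect_error(normalizeVariant("c1", 2L, "CGT", "CAT", reference = ref,
        window = 200L), NA)
    # a deletion pinned in a repeat that would shift past the window errors
    longRep <- Biostrings::DNAStringSet(c(c1 = paste0("T", strrep("A", 50), "G")))
    expect_error(normalizeVariant("c1", 40L, "AA", "A", reference = longRep,
        window = 5L), "window")
    expect_error(normalizeVariant("c1", 5L, "N", "A"), "A/C/G/T")
})

test_that("MNVs decompose to component SNVs and nothing else", {
    d <- decomposeMnv(data.frame(chrom = "chr1", pos = 100L, ref = "AG",
        alt = "TC", stringsAsFactors = FALSE))
    expect_equal(d$pos, c(100L, 101L))
    expect_equal(d$ref, c("A", "G"))
    expect_equal(d$alt, c("T", "C"))

    d <- decomposeMnv(data.frame(chrom = "chr1", pos = 100L, ref = "AGG",
        alt = "TGC", stringsAsFactors = FALSE))
    expect_equal(d$pos, c(100L, 102L))  # unchanged middle base emits nothing
    expect_equal(d$alt, c("T", "C"))

    d <- decomposeMnv(data.frame(chrom = "chr1", pos = 100L, ref = "A",
        alt = "AT", stringsAsFactors = FALSE))
    expect_equal(nrow(d), 1L)
    expect_equal(d$vclass, "INDEL")
})

test_that("applying an MNV's atoms reconstructs the same haplotype as the MNV", {
    set.seed(3)
    for (k in 1:25) {
        seq <- randomSeq(60)
        w <- sample(2:5, 1L)
        pos <- sample(10:40, 1L)
        ref <- substr(seq, pos, pos + w - 1L)
        alt <- randomSeq(w)
        if (alt == ref) next
        v <- normalizeVariant("c1", pos, ref, alt,
            Biostrings::DNAStringSet(c(c1 = seq)))
        atoms <- decomposeMnv(v)
        hapMnv <- applyVariantToSeq(seq, v$pos, v$ref, v$alt)
        hapAtoms <- seq
        for (i in rev(seq_len(nrow(atoms))))  # right to left, positions stay valid
            hapAtoms <- applyVariantToSeq(hapAtoms, atoms$pos[i], atoms$ref[i],
                atoms$alt[i])
        expect_equal(hapAtoms, hapMnv)
    }
})

test_that("call matching requires identical variant and zygosity", {
    a <- list(chrom = "chr1", pos = 100L, ref = "A", alt = "T", zygosity = "HET")
    b <- a
    expect_true(callsMatch(a, b))
    b$zygosity <- "HOM_ALT"
    expect_false(callsMatch(a, b))
    # an MNV matches its component SNVs under atomic mode only
    mnv <- list(chrom = "chr1", pos = 100L, ref = c("AG"), alt = c("TC"),
        zygosity = "HET")
    snvs <- list(chrom = c("chr1", "chr1"), pos = c(100L, 101L),
        ref = c("A", "G"), alt = c("T", "C"), zygosity = "HET")
    expect_true(callsMatch(mnv, snvs))
    expect_true(callsMatch(snvs, mnv))  # symmetric
    expect_false(callsMatch(mnv, snvs, mnvMode = "whole"))
})
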