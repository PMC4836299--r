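---
title: "Orthogonal dual-platform confirmation of exome variants: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orthogonal dual-platform confirmation of exome variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

High-throughput sequencing platforms have raw error rates that are too high
for unreviewed clinical reporting, so variant calls are traditionally
confirmed one at a time by Sanger sequencing. `orthocombine` implements the
alternative: sequence the same sample with two *orthogonal* chemistries —
independent both in how targets are selected (bait hybridization vs
multiplex PCR) and in how bases are read (reversible terminators vs
semiconductor pH sensing) — and treat cross-platform agreement as
confirmation. The two platforms play fixed roles: **A** is the
hybrid-capture/reversible-terminator platform, whose calls carry the
depth/quality pass filter; **B** is the amplicon/semiconductor platform,
whose calls arrive pre-filtered by its own caller and are consumed as-is
(any non-PASS `FILTER` string removes a B call upstream of classification).

The unit of analysis is the *emitted call*: every call made by either
platform, after harmonization, is assigned exactly one of four confidence
categories by a decision table over three attributes — does the other
platform make the identical call (allele **and** zygosity), does the
platform-A call pass its DP/GQ filter, and is the site covered on the
platform that did not call it:

1. A Pass call matching a B call → **Orthogonally Confirmed** (OC);
2. A NoPass or caller-filtered call matching a B call → **Reliable**;
3. a singleton A Pass call → **Likely True Positive**;
4. a singleton B call with no usable A coverage → **Likely True Positive**
   (platform A could not have seen it);
5. a singleton A NoPass call → **Likely False Positive**;
6. a singleton B call where A *was* covered (or called a different allele
   or zygosity there) → **Likely False Positive**.

The assumptions are: errors on the two platforms are (approximately)
independent, so coincident identical errors are rare; and zygosity is
diploid HET/HOM-ALT (hom-ref genotypes are never represented as calls).

# Harmonization: one name per variant

Callers express the same change in different ways. Before any comparison,
every call is reduced to canonical form:

* **Trimming** removes shared leading/trailing bases (keeping the single
  anchor base VCF requires for indels).
* **Left alignment** shifts indels to the leftmost position compatible with
  the reference; the unique canonical name. Without a reference only
  trimming is possible and results are flagged `trim_only`.
* **Multi-allelic records** are split into one call per alternate allele; a
  genotype homozygous for the allele is HOM_ALT, any other genotype carrying
  it is HET.
* **MNV decomposition** (default mode `atomic`): equal-length multi-base
  substitutions are split into their component SNVs before matching, because
  caller-dependent MNV naming is a documented source of spurious
  discordance. Decomposition is lossless for substitutions — applying the
  components reproduces the haplotype the MNV describes — and a `whole`
  mode preserves MNVs intact for users who want name-level matching.
  Whether the original integration algorithm matched MNVs whole or
  atomically is not documented; atomic is the robust default and both are
  provided.
* Indels are never decomposed; structural variants, breakends, symbolic
  alleles and spanning deletions are out of scope and skipped on reading.

# Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `minDp` | 8 | reads | Pass requires `DP > 8`; strict bound, chosen to lose as few true variants as possible while removing most false positives |
| `minGq` | 20 | phred | Pass requires `GQ > 20`, strict bound; missing GQ is NoPass |
| `coveredDepth` | 8 | reads | a site is "covered" on a platform at depth ≥ 8, mirroring the DP callability bound; no published numeric definition exists, so it is configurable |
| `mnvMode` | `atomic` | — | see above |
| `gtMode` | `strict` | — | benchmark counts an allele-right/zygosity-wrong call as FP + FN (the strictest reading); `allele` relaxes to allele-only |
| `targetMean` | 100 | × | depth normalization target for cross-platform exon comparison |
| quadrant `threshold` | 20 | × | the coverage level considered sufficient for calling in the quadrant analysis |
| `window` | 200 | bp | maximum left shift during normalization; exceeding the supplied context is an error, never a silent stop |

Thresholds are *strict* lower bounds: `DP = 8` or `GQ = 20` fails. Raising
`minDp`/`minGq` can only demote calls (OC → Reliable, Likely TP → Likely
FP), never promote them — a monotonicity the tests verify.

# Benchmarking conventions

The analysis region is the user's region set intersected with the truth
set's confident regions; calls count when their 1-based position lies inside
it. Both call set and truth pass through the same reading and normalization
path, so representation differences cannot masquerade as FPs. True
negatives are reported as analysis-region bases minus the distinct positions
occupied by TP/FP/FN calls, computed once over all strata (per-stratum TN
is not a meaningful quantity at base resolution). FP/Mb uses the
analysis-region size in megabases as its denominator; published tables of
this quantity are reproducible only to about ±0.02 because their exact
denominator is not stated — the package reports the formulaic value.
Published indel sensitivities are similarly not exactly reproducible from
their own printed TP/FN counts; the package always reports
`100·TP/(TP+FN)` and leaves the discrepancy documented rather than
replicating unknown accounting. Ratios with zero denominators (0/0) are
reported as absent (`NA`), never as 0% or 100%.

Report formatting: percentages carry two decimals, except per-category PPV
at ≥ 99.99%, which carries three — one error among ~50,000 confirmed calls
is a PPV of 99.998%, which two decimals would round indistinguishably from
perfection. Rounding is half-up, matching how report tables are printed.

# Coverage analysis

Per-exon mean depth is the per-base average over the exon interval; if an
analytic design includes splice-site flanks the BED should already carry
them (`padExons()` widens by a configurable flank, default 10 bp, but
nothing pads implicitly). Normalization is one global scalar per platform —
`targetMean` divided by the exon-base-weighted exome mean — not
per-chromosome; afterwards the base-weighted mean of normalized depths
equals the target to within 1e-9 relative error. The log-plot convention of
flooring zero-depth exons at 1× applies only to the `plot_*` export columns;
threshold tests always see the true normalized depth. The quadrant test uses
normalized depth (consistent with normalized axes); GC bins cover [0,1]
right-open except the last bin, so GC = 1 lands in the final bin, and GC
fractions exclude ambiguous bases from the denominator.

# The synthetic-fixture generator

The generator exists so that every module is testable without external
data. It emulates, at the call/coverage level the tool consumes (never
reads):

* **Truth sets**: canonical, non-overlapping (≥ 10 bp spacing) variants
  inside exons; HET with probability `hetFraction`; indels 1–3 bp,
  left-aligned.
* **Platform error structure**: each truth variant is called with its
  class sensitivity; called variants flip zygosity at `zygosityErrorRate`;
  false positives arrive at `fpPerMb` uniformly over exon bases (SNV alleles
  uniform over the three non-reference bases, indel FPs 1 bp); platform A
  emits a `nopassRate` fraction of calls with sub-threshold DP or GQ.
* **Depth**: per-exon negative-binomial counts (`size = depthDispersion`)
  around `meanDepth`, multiplied by a GC-dropout factor linear in
  |GC − 0.5| on one side (direction `AT` or `GC`, losing `strength` of the
  depth at the extreme) — the minimal model that reproduces "both platforms
  do best at mid-GC, each fails at an opposite extreme". No published depth
  distribution exists; the negative-binomial family with configurable
  dispersion is the standard choice for over-dispersed coverage.

The default `exomeLikeConfig()` is a deliberate scale-down: 3 Mb of 200 bp
exons on two contigs and ~1,700 truth variants (SNV:indel 33:1,
`hetFraction` 0.67, matching exome-scale proportions), with profile values
taken from the measured platform behaviors: role A SNV/indel sensitivity
0.996/0.95, 1.85 FP/Mb, AT-side dropout, NoPass rate 0.003 (the observed
Reliable-to-OC proportion); role B 0.969/0.51, 2.66 FP/Mb, GC-side dropout.
The zygosity-error rate (0.002) and dispersion (`size` 5) are not published
quantities; they were fixed once at values typical for germline exome data.
These problem sizes keep a full generate–classify–benchmark cycle around a
minute while leaving binomial standard errors small enough for 3-sd
parameter-recovery checks.

What the generator does **not** emulate — and therefore what passing tests
cannot certify about real data: alignment- and context-dependent error
modes (homopolymer indel error clustering, strand bias, mappability),
correlated errors between platforms (shared amplification artifacts violate
the independence assumption), within-exon depth structure, contamination,
and low-VAF somatic signal. The "tiny" bundle is the complementary
fixture: twelve hand-placed variants (including a padded-allele SNV and a
right-shifted homopolymer deletion) whose classification is derived by hand
from the decision table, with every category represented.

# Numerical and design choices

* **Coordinates**: BED input/output is 0-based half-open; everything
  internal is 1-based closed; conversions happen only at I/O boundaries.
* **Contig naming**: "chr1" vs "1" mismatches are bridged only by an
  explicit alias map; disjoint contig universes raise an error, never a
  silent zero-overlap analysis.
* **Conflicting calls** (the two platforms call different alleles, or the
  same allele with different zygosity, at one locus) are *not* concordant:
  each side is classified under its singleton rule, with the conflicting A
  call counting as platform-A coverage for rule 6 — so a B singleton
  opposite a different A call is Likely FP even where the depth track is
  thin. This tie-break emits two classified calls per conflicting locus.
* **Duplicates**: identical calls within one platform are deduplicated with
  a warning.
* **Degenerate inputs**: empty call sets classify to an empty, valid result;
  an empty analysis region is an error; `ref == alt` after trimming is a
  not-a-variant error; reference/allele mismatch is an error naming the
  position; overlapping coverage runs with conflicting depths are an error.
* **Replicate cross-tabulation** matches variants across runs by canonical
  identity *ignoring zygosity*: a zygosity flip between runs is a category
  change of one variant, not a disappearance plus a new variant. The
  Not-Called/Not-Called cell is structurally zero (a variant absent from
  both runs is unobservable). The shared analysis region is a required
  argument because category mixtures are only comparable over the same
  bases.
* **Roles, not vendors**: categories are defined over roles A/B so any two
  orthogonal platforms can be substituted.
* **Determinism**: all generators take explicit seeds, use R's
  Mersenne-Twister with fixed normal/sample kinds, and restore the caller's
  RNG state; the same config + seed reproduces byte-identical fixture
  bodies.

# Known limitations

* Matching is representation-based after normalization; it does not perform
  haplotype-replay comparison, so complex nearby-variant equivalences that
  only align at the haplotype level (the vcfeval class of matches) can
  still count as discordant.
* Coverage is consumed pre-computed (BED-style runs or per-base text); the
  package never re-derives depth from alignments.
* Two platforms only; three-way integration, somatic/low-VAF calling and
  phasing are out of scope.
* The B platform's upstream artifact filters are consumed only through its
  VCF `FILTER` column; all non-PASS values are treated alike because no
  finer mapping is published.
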