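---
title: "Methods: quantification, classification, clustering and cross-platform comparison of a four-stage berry transcriptome"
author: "BerrySeq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: berry development transcriptome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BerrySeq)
```

BerrySeq implements the analysis chain for a bulk RNA-Seq time course over
four developmental stages of the grape berry — young berry (E-L 31), early
veraison (E-L 35), late veraison (E-L 36) and harvest-ripe fruit (E-L 38)
on the modified Eichhorn–Lorenz scale. The design has one pooled library
per stage and no biological replicates, which shapes every method choice
below: expression differences are described by fold-change classification
and clustering rather than by replicate-based statistical tests.

# Quantification

## Read and alignment acceptance

Reads shorter than 60 nt after trimming or carrying more than two
ambiguous bases are excluded (`filterReads()`). Alignment candidates are
accepted only when *strictly* more than 98% of aligned bases are identical
and *strictly* more than 50% of the read aligned contiguously
(`filterAlignments()`); the strictness follows the wording of the
acceptance rule, and the generous aligned-fraction threshold tolerates
reads overhanging transcript ends (UTR not present in the reference).

## Proportional allocation of multi-mapped reads

Transcript families (stilbene synthases, terpene synthases) share enough
sequence that a read can align acceptably to several transcripts. The
allocator (`allocateReads()`) is a deliberate two-pass procedure:

1. reads with exactly one accepted candidate are counted as **unique
   reads** of that transcript;
2. each multi-candidate read is split across its candidates with weights
   proportional to the unique-read counts frozen in pass 1.

Allocation is single-pass by design — unique anchors are *not* updated as
multi-mapped mass accumulates, i.e. this is not an EM estimator. When all
candidates of a read have zero unique reads the proportional rule is
undefined (0/0); the read is split equally, which preserves the
conservation property: total allocated mass equals the number of reads
with at least one accepted candidate (asserted to 1e-6 relative tolerance
in the tests). Fractional counts are carried unrounded into RPKM.

## RPKM, detection, binning

`rpkm = allocated / ((length/1000) × (totalMapped/1e6))`. The denominator
uses the per-stage total of *allocated* (fractional) reads by default;
`quantifyStages(integerTotals = TRUE)` switches to rounded totals — the
distinction is immaterial at realistic depths but is exposed because the
convention is genuinely ambiguous. An RPKM of 0.5 at 40 million mapped
100 nt reads corresponds to a mean per-base coverage of 2
(`expectedCoverage()`), which motivates the detection rule: a transcript
is detected at RPKM ≥ 0.5, or rescued below that floor by ≥ 5 uniquely
matched reads. Abundance bins use boundaries `>200` (strict),
`[10, 200]`, `[0.5, 10)`, and "below 0.5 with ≥ 5 unique reads"; the
boundary conventions are documented in `abundanceBins()` and chosen so the
bins partition the detected set exactly.

# Stage-specific up-regulation

Fold changes between stages are computed after clamping **both** numerator
and denominator to a floor of 0.1 RPKM (`flooredFoldChange()`): the pair
(0.02, 1.00) is a 10-fold increase, not 50-fold. The floor applies to
both sides because only that reading makes the clamped ratio consistent
in the worked example above and keeps the reciprocity property
`fold(a,b) · fold(b,a) = 1` above the floor.

A transcript is *specifically up-regulated* at one stage when its floored
fold versus **each** of the other three stages is at least 3
(`stageSpecificCalls()`). At most one stage can win (if stage s beats
stage o 3-fold, o cannot beat s 3-fold), so calls are mutually exclusive
by construction. The binned magnitude ([3,10), [10,50), [50,∞)) is the
*minimum* fold versus the other stages — the conservative choice; which
pairwise fold defines the bin does not affect class membership, only the
bin label. Joint veraison calls (`veraisonCalls()`) require all four
folds of E-L 35 and E-L 36 against E-L 31 and E-L 38 to reach the
threshold, with the bin again set by the minimum. Thresholds are
inclusive (≥ 3, ≥ 10, ≥ 50).

# Profile normalization and clustering

`normalizeProfiles()` follows a fixed order of operations: discard rows
with all four RPKM below 0.5; multiply each remaining row by a scale
factor making its sum of squares exactly 1; centre to zero mean; discard
rows whose normalized range (max − min) is below 0.5. Centring breaks the
unit sum of squares, so that invariant is asserted on the pre-centring
values (the `scaled` slot). Whether the range filter acts before or after
normalization is genuinely ambiguous in this kind of protocol; we follow
the order above and expose `rangeOn = "raw"` as the alternative. A row of
exact zeros cannot reach the scaling step (0 < 0.5 fails the first
filter); the code still raises a defensive error if one does.

`kmeansStable()` runs Lloyd's algorithm (Euclidean metric) from `nRuns`
independent uniform random draws of k distinct profiles, reporting the
best within-cluster sum of squares and **how many runs reached it**
(objective equality at 1e-8 relative tolerance) — the "result found N
times" stability record. Falling short of `requiredRepeats` (default 3)
warns rather than fails: stability is a diagnostic, not a validity
condition. Implementation details that matter: an empty cluster is
re-seeded with the point currently farthest from its centroid;
assignment ties break to the lowest cluster index; the per-iteration
objective is non-increasing (property-tested). Defaults are k = 20 and
1000 restarts; the recovery tests in this package use 10 planted shapes
with k = 10 and 200–500 restarts, enough for the restart mechanism to
reach the global optimum on separated data — with too few restarts the
reported solution is demonstrably a merged-cluster local optimum.

`labelArchetypes()` names each centroid by the best-correlating template
(Pearson, after applying the same scale-and-centre transform to the
templates) when that correlation is ≥ 0.8, else "unlabeled"; exact ties
break alphabetically. The 0.8 threshold and the tie rule are artifact
choices — template naming is presentation, not inference.

# GO enrichment and group scores

`enrichCluster()` tests each term present in a cluster with the one-sided
hypergeometric upper tail (at least `k_in` annotated among `n_cluster`
draws from `N_bg` with `K_bg` annotated), then controls the FDR across
the cluster's tested terms with Benjamini–Hochberg. The FDR wording in
array-era tooling is loose; BH on hypergeometric p-values is the
defensible reading and is what we implement. Only terms at FDR ≤ 0.05
enter the summary. Term-to-process grouping is supplied as an explicit
two-column map (the synthetic generator builds one); semantic-similarity
grouping of GO terms is deliberately out of scope. The group score is
`Σ 100 × (−log10 FDR)` over member terms: one term at FDR 0.01 scores
200, at 1e-10 scores 1000, and any included term contributes at least
100 × (−log10 0.05) ≈ 130.1. FDR values underflowing to zero are clamped
to 1e-300 before the logarithm.

# Cross-platform comparison

`buildMatchedPairs()` pairs transcripts with microarray probesets after
removing cross-hybridizing probesets (suffixes `_s`, `_x`, `_a`) and
probesets whose EST match e-value exceeds zero. When several probesets
match one transcript, the one whose 4-stage pattern correlates best
(Spearman) with the transcript's log2(RPKM+1) pattern is kept. What
"most closely correlating" is measured against is not standardized; we
correlate against the RNA-Seq pattern and note the circularity risk this
introduces into per-transcript pattern statistics (the retained probeset
is selected for agreement).

`applyExpressionFloors()` recomputes the intensity floor as the 25th
percentile of per-pair mean log2 intensity from the data at hand (any
printed absolute value is array-specific and never hard-coded) and flags
RNA-Seq expression at mean RPKM ≥ 0.5; both floors are inclusive and
computed from per-transcript means across stages (per-stage filtering is
the switchable alternative). `globalStageCorrelation()` reports per-stage
Spearman ρ (average ranks on ties) and the four-stage mean;
`patternCorrelationHistogram()` reports per-transcript 4-point
correlations binned at 0.9, 0.6, 0.3, 0, −0.3, −0.6, −0.9. On four
points, Spearman without ties takes only the eleven values
−1, −0.8, …, 0.8, 1 (enumerable over the 24 rank permutations); a
pattern constant on either platform has no defined rank correlation and
is counted in a reserved "undefined" bin rather than silently dropped.

# The synthetic-data generator

Because no raw data accompanies the study design this package targets,
every input is generated with known ground truth (`generateCatalog()`,
`generateAlignments()`, `generateProbesets()`), and the generator is
first-class, tested code.

* **Catalog.** Ten archetype shapes (`berryArchetypes()`) — stage-specific
  peaks, monotone ramps, joint veraison-up, the veraison dip — each
  occupy 5% of the catalog by default, the remainder flat. The templates'
  amplitudes are free parameters; the shipped set was fixed once, at
  design time, with a minimum pairwise normalized distance of 0.23 and
  all normalized ranges above the 0.5 range filter. True RPKM is
  `amplitude × template × exp(noise)` with log-normal amplitudes
  (meanlog log 20, sdlog 1) and per-stage log-normal noise of sd 0.05 by
  default. Flat profiles stay within a 3-fold max/min ratio.
* **Reads.** Per-stage depth defaults to 50,000 reads; expected counts
  are proportional to `true_rpkm × length` (multinomial at fixed depth).
  15% of reads receive 2–4 candidates within randomly partnered homology
  groups, mirroring the ~85% single-location mapping rate of deep berry
  data; the 2–4 multiplicity is a default, not a claim about real family
  structure. 8% of reads violate read QC (matching the ~8% loss between
  generated and counted reads in comparable datasets) and 2% carry
  candidates failing the alignment thresholds, so every filter is
  exercised.
* **GO annotation.** One term per archetype is planted into 50% of the
  archetype's members (at least 5) and ~5% of the background; every
  transcript additionally draws Poisson(2) background terms.
* **Probesets.** With an explicit `noiseSd`, intensities are an affine
  function of log2(RPKM+1) plus Gaussian noise. With `noiseSd = NULL`,
  intensities are built on per-stage normal scores through a Gaussian
  copula with latent correlation `r = 2 sin(π ρ / 6)`, so the expected
  Spearman correlation equals the planted `platform_rho` (default 0.7)
  exactly — an affine-plus-noise model cannot target a rank correlation
  independently of the RPKM marginal. The planted correlation refers to
  the full matched population; applying expression floors truncates both
  margins and attenuates the observed ρ, so recovery is measured on all
  validly matched pairs.

What the generator does **not** emulate: base-level sequencing error and
quality strings, positional coverage bias, transcript-family sequence
structure (homology groups are random partners), RMA preprocessing
artefacts, and biological replicate variation. Tests passing on this
generator therefore validate the *algorithms* — filters, allocator,
normalization, clustering, enrichment arithmetic, correlation machinery —
not the end-to-end behaviour on real libraries.

# Problem sizes and numerical choices

The shipped tests run at desk scale, chosen so the full suite completes
in well under a minute: catalogs of 100–800 transcripts (3000 for the
correlation recovery, giving ~2000 matched pairs), 2,000–50,000 reads
per stage, 15–500 clustering restarts. The noiseless read-based recovery
test uses 250 transcripts at 50,000 reads per stage (≈ 200 reads per
transcript — still several-fold shallower than a production berry
library). Numerical tolerances: unit sum of squares and zero mean at
1e-9; allocation conservation at 1e-6 relative; k-means objective
identity at 1e-8 relative; oracle equivalences at 1e-12.

# Known limitations

* No replicate-based inference anywhere; fold-change classification is
  descriptive.
* The allocator's proportional rule inherits the biases of its unique
  anchors; for recently duplicated isogenes above the identity threshold
  the split is essentially arbitrary, and expression of such pairs should
  not be over-read.
* Best-probeset selection against the RNA-Seq pattern inflates
  per-transcript cross-platform agreement for multi-probeset transcripts.
* k-means with random restarts can report a stable-looking local optimum
  if `nRuns` is small relative to k; the `timesFound` record is the
  intended diagnostic.
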