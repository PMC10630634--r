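---
title: "Methods: nascent transcription, antisense pairing and differential expression in nascentr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nascent transcription, antisense pairing and differential expression in nascentr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nascentr)
```

`nascentr` analyses strand-specific nascent-transcription coverage
(GRO-seq-style) around natural antisense transcripts: it calls
transcription units de novo, pairs antisense transcripts with coding
genes, tests differential expression with a self-contained
negative-binomial stage, quantifies promoter-proximal polymerase
pausing, and estimates transcription rates from metabolic-labeling
time courses. This vignette is the package's account of the underlying
models, the parameters that matter, the numerical and design choices,
and what the bundled synthetic data can and cannot tell you.

## Coordinates and data types

All intervals are 0-based half-open (BED convention) on a named
chromosome with a mandatory `+`/`-` strand; GTF input/output converts
to and from GTF's 1-based inclusive convention at the boundary, and
nowhere else. A single internal convention removes the class of
off-by-one errors that arises when browser-style (1-based display) and
BED-style coordinates are mixed. Unstranded records are rejected
outright — strand identity is the entire point of a sense–antisense
analysis, and a record with strand `"."` cannot be interpreted.
Chromosome names are matched as exact strings; no silent `chr`
aliasing is performed, because silent renaming hides data errors.

Coverage is held as runs of constant depth (non-overlapping, sorted;
absent positions are depth 0), one track per strand, mirroring
strand-separated bedGraph files. Parsing of GTF, BED and bedGraph is
delegated to `rtracklayer`; interval overlap machinery to
`GenomicRanges`. Output ordering ties are broken by feature id so that
outputs are bit-reproducible.

## Transcription-unit calling

The caller emits maximal runs with depth ≥ `min_depth`, bridging
sub-threshold gaps of at most `max_gap` bp, and discarding units
shorter than `min_length`:

* `min_depth` (reads/bp): default 4× the genome-wide mean depth of the
  track. Nascent coverage is noisy and unit boundaries matter less
  than unit existence; a multiple of mean depth adapts to sequencing
  depth without tuning.
* `max_gap` (bp): default 500. Bridges coverage dropouts
  (mappability, sharp dips) without fusing neighbouring genes, whose
  intergenic gaps are typically kilobases.
* `min_length` (bp): default 200, the conventional lower bound for
  long noncoding RNAs.

Units are emitted unspliced (single exon): nascent coverage contains
intronic signal and does not resolve splicing, and the focal class of
transcripts here — antisense lncRNAs — is frequently unspliced.
Deterministic ids (`TU_<chrom>_<start>_<strand>`) make outputs
diffable. Novel units are merged into a reference annotation with
de-duplication: a novel unit is dropped iff a single same-strand
annotated transcript covers at least `dedup_overlap` (default 0.5) of
its length. The caller is verified against a per-base brute-force
oracle (threshold, bridge, filter at single-bp resolution) on hundreds
of randomized tracks, and is exactly monotone: raising `min_depth`
never increases called bp; raising `max_gap` never increases the unit
count.

## Quantification and pausing

Signal over a feature is total depth·bp on the feature's strand only.
`mode = "exon"` sums over the exon union, `mode = "intron"` over the
interval minus the exons, so exon + intron = gene exactly — a
partition identity the tests enforce per base. RPKM is
`count / (length/1000) / (libsize/1e6)`; log transforms downstream use
a pseudocount of 1 so zero-expression features remain finite.

The pausing ratio divides mean density over the promoter-proximal
window — the first 300 bp downstream of the TSS in transcription
direction, i.e. `[end − 300, end)` for minus-strand genes — by mean
density over the remainder of the interval. The window is taken
literally from the TSS with no exclusion gap. The ratio is invariant
to global scaling of the track, so normalisation does not affect it.
Between-group comparisons scale each replicate to its library size
(signal per million mapped reads) and then apply Welch's
unequal-variance t test separately to proximal and body densities.
Welch is used everywhere a two-sample t test is called for: with 3–4
replicates per group an equal-variance assumption buys little and
costs robustness.

## Differential expression

The DE stage is written from scratch so that every numerical choice is
explicit; `edgeR` appears only as an independent cross-check in the
test suite.

**Filter.** A feature is kept iff in at least one group, ≥ 70% of that
group's samples have a count strictly above 10. Filtering precedes
everything, and BH adjustment is computed over the filtered set only.

**TMM normalisation.** For each sample against a reference sample
(the one whose 75th-percentile count fraction is closest to the mean
of those fractions), gene-wise log2 ratios M and mean log2 abundances
A are computed over genes positive in both; the top and bottom 30% of
M and 5% of A are trimmed; the factor is 2 to the precision-weighted
mean of the surviving M values, with inverse asymptotic binomial
variances as weights; factors are rescaled to geometric mean 1.
These are the canonical TMM defaults. TMM assumes most genes are not
differentially expressed; with a majority of DE genes the factors
absorb real signal (the tests plant ≤ 10% DE for this reason).

**Dispersion.** The NB model uses variance μ + φμ². A common φ
maximises the Cox–Reid adjusted profile likelihood (group means
profiled out; adjustment ½·log det X'WX) over all features, optimised
on the log scale over φ ∈ [1e−6, 10]. Per-feature estimates are
method-of-moments at the common-dispersion fit, with the standard
n/(n−p) residual-degrees-of-freedom correction on the squared
residuals (without it the moment estimate is biased low and the LRT
becomes anticonservative), then shrunk toward the common value with a
fixed prior weight of 10 residual degrees of freedom and clamped to
[1e−6, 10]. This fixed-weight scheme is deliberately simpler than a
full empirical-Bayes treatment, and fully specified.

**Test.** Per feature, NB log-linear models with offsets
log(effective library size) are fitted under the null (one mean) and
the alternative (one mean per group) by Newton iteration on the log
mean (expected information, step clamp ±5, at most 50 iterations,
convergence 1e−8; non-convergence flags the feature and sets p to
NA). The LRT statistic 2·Δloglik is referred to χ² with 1 df. Fold
changes come from prior-augmented group means (prior count 0.125 per
group) so all-zero groups stay finite; logCPM is the average
normalised abundance. Calls: `up` iff log2FC ≥ 0.7 and FDR < 0.01,
`down` iff log2FC ≤ −0.7 and FDR < 0.01 — the 0.7 boundary is
inclusive, so log2FC = 0.69 is `not_DE` however small its FDR. Under a
null simulation (φ = 0.1, 4 vs 4) the raw-p < 0.05 fraction sits in
the nominal band and essentially nothing survives the call thresholds;
with 10% of features at |log2FC| = 2 the stage reaches recall ≥ 0.8 at
empirical FDR ≤ 0.05 (both recomputed by the acceptance script).

## Antisense pairing and regulation classes

Pairs are formed between coding genes and opposite-strand transcripts
whose gene-body intervals overlap. The overlap fraction's denominator
is the **antisense** transcript's length, and the 10% retention
threshold is inclusive. Overlap is computed on TSS→TTS intervals, not
exon unions, because nascent transcription covers introns and
antisense interference is a locus-level phenomenon. Topology is
labelled from orientation: `convergent` (3′ ends overlap,
tail-to-tail), `divergent` (5′ ends overlap, head-to-head), `nested`
(containment).

Classification of a pair, given a classified DE table:

* **ASRG** (antisense-regulated gene): both members DE with
  opposite-sign log2FC;
* **NARG** (non-antisense-regulated gene): both members DE with
  same-sign log2FC;
* **not_regulated** otherwise.

Requiring *both* members to pass the DE thresholds is the default
because inverse regulation is a claim about both transcripts; a
`mode = "directional"` variant accepts a single DE member with the
right sign pattern for exploratory use. The class depends only on the
sign pattern, so it is invariant to swapping the condition labels.
Pair-level Pearson correlation of log2FC (with its t-transform p) is
computed over whatever pair set the caller supplies — expressed pairs
and DE-only pairs give different, equally legitimate summaries, so the
choice is an explicit argument rather than a hidden default.

The HRE scan reports all occurrences of the core consensus RCGTG
(R = A/G) on both strands, overlapping hits included (a lookahead
search, since RCGTG can overlap itself); `N` never matches.

## ΔΔCT and labeling kinetics

ΔCT = CT_target − CT_reference per sample; ΔΔCT subtracts the
calibrator group's mean ΔCT per target; relative expression is
2^−ΔΔCT. The amplification base is fixed at 2 (perfect doubling), with
an `efficiency` argument for corrected bases. All statistics (Welch t,
Bonferroni `min(1, m·p)`) are computed on ΔCT values, not on fold
changes, because ΔCT is the scale on which the measurement error is
approximately normal. By construction the calibrator group's relative
expression has geometric mean exactly 1.

Labeling series (approach-to-equilibrium, default grid 15/30/45/60
min) are fitted by OLS of labeled abundance on time with a **free
intercept**: although zero label is expected at t = 0, background and
capture offsets are real, and the slope — the synthesis-rate proxy —
is unbiased either way. Slope equality between conditions is tested
via the condition×time interaction in a pooled linear model
(two-sided t). The test agrees with a within-time-point permutation
oracle within Monte-Carlo error, and at the planted contrast
(slopes 0.3 vs 1.9, 5% noise, 3 replicates × 4 times) rejects at
α = 0.05 in ≥ 95% of seeded replicates.

## The synthetic-data generator

The generator produces every input the pipeline consumes, with a truth
manifest, and is bit-reproducible from (seed, parameters).

* **Toy genome**: non-overlapping plus-strand coding genes, lengths
  log-uniform 2–60 kb, intergenic gaps 5–20 kb; a chosen fraction of
  genes receive one convergent minus-strand antisense unit whose
  overlap fraction of its own length is drawn from `overlap_range`,
  confined to the host's territory so that each antisense unit
  overlaps exactly its host.
* **Coverage**: per-bp Poisson jitter around the expression level,
  with the first 300 bp (transcription direction) multiplied by the
  pausing ratio, plus a constant genome-wide background on both
  strands.
* **Counts**: NB(μ, φ) with μ = baseline · 2^(log2FC·condition) ·
  library factor; baselines log-normal (median 150) unless supplied.
  Planted inverse pairs get antisense log2FC from +[2, 4] and sense
  log2FC from −[0.7, 2] by default, with baselines raised to ≥ 100 so
  the planted features survive the expression filter.
* **Labeling / qPCR**: linear-in-time abundance with multiplicative
  Gaussian noise floored at 0; CT values with Gaussian cycle noise
  around a stable reference.

**The canonical scene** (`simulate_scene(seed = 42)`) is the package's
fixed integration fixture: 3000 genes, 300 antisense units, NB counts
at φ = 0.1 with 4 replicates per condition, 25 planted inverse pairs,
10 co-regulated (NARG-style) pairs, 15 antisense-only effects, 150
effects on unpaired genes, a 50-gene coverage panel with 5-fold
pausing, labeling series with slopes 1.91 vs 0.34, and a fold-4 qPCR
table. The inverse pairs are planted with large effects — antisense
+[2, 4], sense −[1.5, 2.5] in log2 — chosen so that recovery is a test
of the classification plumbing rather than of marginal statistical
power: at φ = 0.1 with 4 replicates and the strict FDR < 0.01,
|log2FC| ≥ 0.7 thresholds, effects below ~1.2 log2 units sit near the
power boundary. Even at these settings the recovery is stochastic in
principle: across arbitrary seeds an occasional planted sense effect
draws unlucky counts (a ~3σ underestimate of its fold change) and
misses the strict thresholds, which is the expected behaviour of a
calibrated test, not a defect; the canonical seed-42 scene recovers
exactly the 25 planted pairs and is the reference the documentation
and acceptance script use.

What the generator does **not** emulate: mappability and GC structure,
spliced antisense isoforms, overlapping same-strand genes, eRNA
bidirectional transcription, fragment-level counting ambiguity,
between-replicate library-preparation artefacts, and any sequence
content beyond the HRE scan's input. Passing the planted-truth tests
therefore demonstrates the correctness of the algorithms and the
calibration of the statistics under the stated model — not robustness
to every artefact of real nascent-RNA libraries.

## Problem sizes and runtime choices

The test suite and acceptance script size their simulations for a
single CPU: null calibration uses 10 × 2000 features at 4 vs 4;
parameter recovery uses 1000–2000 features; oracle-equivalence checks
use ~1000 randomized instances per operation at small spans; the scene
is 3300 features. These sizes give stable estimates (binomial
Monte-Carlo error on the null p-fraction ≈ 0.15 percentage points)
while keeping the full suite in the low minutes.

## Known limitations

* One grouping factor, two-group contrasts only; no covariates, no
  quasi-likelihood F tests.
* The fixed-weight dispersion shrinkage is simpler than full empirical
  Bayes; at very small replicate numbers the tagwise estimates lean
  heavily on the common value.
* The caller does not separate bidirectionally overlapping units on
  the *same* strand, and boundary precision is limited by `max_gap`.
* BAM/bigWig input is out of scope: coverage enters as bedGraph.
* Pair classification consumes a single DE table; multi-contrast
  designs require one call per contrast.
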