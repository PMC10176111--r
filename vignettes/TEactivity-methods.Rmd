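---
title: "TEactivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TEactivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical models, the defaults, and the design
choices behind TEactivity: a pipeline for transposable-element (TE) and
piRNA-cluster transcription analysis in replicated mutant panels, such as
histone H3K36-methylation mutants in *Drosophila*.

## Data model and containers

All annotations live in `FeatureSet`, a `GRanges` subclass with a `kind`
(repeat, gene, precursor, region) and a unique `feature_id` per record.
Internally everything is on the GRanges convention (1-based, closed);
conversions happen only at file boundaries — BED (0-based half-open) and
RepeatMasker `.out`/GTF (1-based inclusive) load to identical ranges, and a
BED written by `writeFeatureBed()` re-loads to identical intervals and
identifiers. Repeat classes are parsed from the `order/family` string: the
text before `/` is the order, after it the family; without a `/` the family
equals the order (so `Simple_repeat` is both). Orders outside the closed
vocabulary (LTR, LINE, DNA, Simple_repeat, Satellite, RC) fall in an
`Other` bucket so that composition tables always sum to one.

Counts live in `TECountSet`, a `RangedSummarizedExperiment` with a single
integer `counts` assay and the sample sheet (`sample_id`, `condition`,
`batch`, `replicate`, `library_size`) in `colData`.

## Counting

`countFeatures()` retains primary alignments with mapping quality at least
`minMapq` (default 1, i.e. the mapQ > 0 uniqueness criterion), collapses
mates sharing a read id into one fragment, and increments features by
overlap. The default `every_overlap` mode lets a fragment count once toward
every feature it touches — the behaviour of probe-based quantitation tools
over overlapping repeat annotations — while `largest_overlap` gives
disjoint counting, with ties broken deterministically toward the
lexicographically smallest `feature_id`. Reference spans come from the
CIGAR (M/D/N/=/X consume reference), so spliced reads span their introns.
Fragments on chromosomes absent from the annotation are skipped, tallied
and reported rather than being a hard error, because repeat annotations
frequently omit scaffolds present in the aligner index. Counting is
unstranded by default; most bulk RNA-seq protocols feeding this kind of
analysis are unstranded, and a `stranded` flag is available.

## Differential transcription

Counts are modelled as negative binomial with variance $\mu + \alpha\mu^2$.

* **Normalization.** `sizeFactorsMedianOfRatios()` implements
  median-of-ratios factors over the features with all-positive counts,
  rescaled to geometric mean 1, with a total-count fallback (and warning)
  when no reference feature exists. Note a structural caveat: factors
  estimated on a matrix in which *most features are truly perturbed*
  absorb the signal. This matters for piRNA precursors, where nearly every
  feature sits inside a responding cluster; `runPipeline()` therefore
  normalizes precursor counts with factors estimated from the gene count
  matrix, whose perturbed fraction is small.
* **Dispersion.** `estimateDispersionMM()` is a per-feature
  method-of-moments estimate: the within-group (group-mean-centred) pooled
  variance $s^2$ and grand mean $\bar\mu$ of normalized counts give
  $\hat\alpha = (s^2 - \bar\mu)/\bar\mu^2$, clipped to
  $[10^{-8}, 10]$. It is deterministic and directly checkable against
  simulation, at the cost of no information sharing across features.
* **Wald test.** For a two-group contrast, group means are estimated on
  normalized counts and stabilized with a pseudocount of 0.5;
  $\log_2\mathrm{FC} = \log_2((\hat\mu_t + 0.5)/(\hat\mu_c + 0.5))$ with
  delta-method standard error
  $se^2 = (1/\ln 2)^2\,[(1/n_t)(1/\hat\mu_t+\alpha) +
  (1/n_c)(1/\hat\mu_c+\alpha)]$.
  The reference distribution is the package's one deliberate departure
  from the plain Wald recipe: with $\hat\alpha$ plugged in at five
  replicates per group, a standard-normal reference is anticonservative
  (measured empirical type-I error 0.082 at nominal 0.05 on null NB
  simulations at $n = 5+5$, $\mu = 50$, $\alpha = 0.1$), because the
  normal ignores the estimation noise of $\hat\alpha$. Referring the
  statistic to a Student $t$ with $n_t + n_c - 2$ degrees of freedom — the
  same small-sample device used by moderated-statistic frameworks —
  restores calibration (measured 0.048). When the user supplies a known
  dispersion the normal reference is used, as the plug-in noise is absent.
* **Selection.** `selectUp()` applies the strict thresholds
  $\log_2\mathrm{FC} > 2$ and (BH-adjusted by default) $p < 0.05$.
  Adjusted p is the default reading of "*P* < 0.05" because that is the
  convention of NB differential-expression software; `useAdjusted = FALSE`
  preserves the raw-p reading.
* Features with zero counts in both groups are reported `untested`
  (log2FC 0, p 1) and excluded from the BH multiplicity count.

## Double-control consistency filter

`controlConsistencyFilter()` removes from a contrast every feature
significantly changed (adjusted p < 0.05 by default, optionally with an
absolute log2FC floor) in *either* of two control comparisons: wild-type
batch 1 vs batch 2, and control genotype vs wild type. The union rule is
deliberately aggressive — a feature that misbehaves between any pair of
controls cannot support a mutant-effect claim. The criterion (alpha,
adjusted vs raw, fold floor) is configurable because "significantly
changed" admits several readings; the default is significance alone.

## Composition, partition, context, density

* `compositionChiSquare()` is a textbook goodness-of-fit test of the
  up-set's class composition against genome abundance
  ($\chi^2 = \sum_k (O_k - n e_k)^2 / (n e_k)$, df = K−1, via
  `chisq.test`), with a two-sample contingency mode for comparing two
  observed compositions. Genome abundance defaults to element counts
  (annotation records); base-pair weighting is a flag, since either is a
  defensible notion of "expected ratio".
* `partitionByMutants()` assigns every base-set feature its exact
  membership signature over the mutant up-sets — all $2^m$ classes,
  including `none` and the full intersection, are reported explicitly so
  the counts always cover the base set.
* `classifyGenomicContext()` uses ≥ 1 bp overlap with gene spans and the
  priority expressed gene > unexpressed gene > intergenic on ambiguity
  (a deterministic, order-independent rule); "expressed in wild type"
  means mean normalized WT count ≥ 10 by default. Elements in unexpressed
  genes are subdivided by whether the host gene is itself activated in the
  mutant, which is the control for the "TEs ride on activated genes"
  alternative explanation.
* `binDensity()` tiles chromosomes with fixed windows (default 100 kb) and
  assigns features by interval midpoint; a midpoint landing exactly on a
  window boundary belongs to the following window (half-open tiling).
  Midpoints avoid double counting across boundaries.

## piRNA cluster scoring

Precursors are assigned to clusters when at least half the precursor lies
inside the cluster (largest overlap wins; exact ties go to the
lexicographically smallest cluster id — both rules exist purely for
determinism). The cluster score for a condition is the mean over assigned
precursors of the per-precursor mean normalized count (replicate mean
first, then precursor mean), with a t-based 95% CI across precursors.
Folds over control are reported with one-decimal, half-away-from-zero
rounding: this convention reproduces, from published per-precursor cluster
means, every printed fold value in the corresponding study (e.g. 38.51
over 3.03 reports as 12.7) — base R's default ties-to-even rounding does
not.

## ChIP/input enrichment

Per-feature enrichment is
$((\mathrm{chip} + 0.5)/\mathrm{chipLib}) /
((\mathrm{input} + 0.5)/\mathrm{inputLib})$,
with replicate counts averaged *before* the ratio, and per-class means
with t-based 95% CIs across features (not replicates — the error bars of a
class profile describe feature-to-feature spread). Random 80-bp background
regions are sampled chromosome-proportionally and reproducibly under a
seed.

Two numerical facts matter for interpreting class profiles:

1. The mean of pseudocount ratios has an upward bias of order
   $1/(2\,\bar{c})$ for input mean count $\bar{c}$ (Jensen's inequality
   applied to $1/(\mathrm{input}+0.5)$). At shallow coverage this bias is
   comparable to a large class's CI, so "mean = 1 under uniform signal" is
   only a meaningful calibration check at coverage deep enough that
   $1/(2\bar{c})$ is negligible; the package's calibration tests run at 10
   reads/bp for this reason and add the analytic bias term to the
   tolerance.
2. A statement like "all class means equal 1 within their 95% CIs" over
   $K$ classes must be read simultaneously: $K$ independent unadjusted
   intervals jointly fail with probability $1 - 0.95^K$ (about half at
   $K = 15$) even for a perfect implementation. The calibration check
   therefore uses Bonferroni-adjusted intervals across the class/target
   grid.

The planted-enrichment recovery check (class mean relative to the random
class) is unaffected by both effects at standard coverage, since the bias
largely cancels in the ratio of class means.

## The synthetic-data generator

`simConfig()` fixes the study conditions the package is tested under:

* a 2.1 Mb four-chromosome genome whose distal 30% blocks stand in for
  repeat-dense pericentromeric heterochromatin;
* 600 repeats (140 LTR/Gypsy, 70 LTR/Pao, 50 LTR/Copia, 90 LINE/Jockey,
  250 Simple_repeat — transposons pericentromere-biased, simple repeats
  uniform), 100 genes (half expressed in wild type at NB mean 100), and
  2 dual- + 2 uni-strand piRNA clusters of 20 kb with 60 precursors each;
* five biological replicates per condition — wild type sequenced in two
  batches, a control genotype, the histone replacement and three
  methyltransferase knock-outs — matching the replication level of the
  study design emulated;
* NB counts at dispersion $\alpha = 0.1$ and TE baseline mean 50 with
  lognormal per-sample scale jitter; planted log2FC = 3 up-sets per mutant
  drawn with a 3:1 bias toward LTR/LINE elements; 30 features with a
  planted wild-type batch-2 effect (the double-control filter's targets);
  planted piRNA cluster folds of 8 (dual) and 1.5 (uni) over wild type in
  the replacement mutant, decreasing through the methyltransferase
  mutants;
* single-end 75-bp reads placed uniformly within features (clipped to
  short features), so that counting the emitted SAM over disjoint features
  reproduces the matrix exactly; paired-end handling is exercised by a
  handcrafted SAM fixture instead, keeping the round-trip oracle exact;
* Poisson ChIP/input coverage at 0.25 reads/bp with class multipliers
  (me2 doubled on LTR/LINE, me1 mildly elevated on simple repeats, me3 on
  exons).

Every stage derives an independent stream from the master seed and is
byte-reproducible. What the generator does *not* emulate — nucleotide
sequence, mappability structure, nested/fragmented repeat annotations,
empirical dispersion trends, batch effects beyond a planted mean shift —
bounds what green tests show about real data: they certify the
arithmetic and the statistical calibration of the pipeline, not robustness
to alignment artefacts or annotation noise. Absolute counts from the real
study (thousands of up-regulated elements, the 71.7% intergenic fraction,
the published membership-class sizes) require the real genome annotation
and deposited libraries and are deliberately not reproduction targets at
this scale.

## Problem sizes and runtime

The test-suite and acceptance simulations use 10,000 null features for
type-I calibration, 200 planted among 2,000 for recall, 1,000 features
with 50 batch-inconsistent for the filter, the 600-repeat synthetic study
end to end, 20 count-simulation replicates (over one fixed annotation, the
count draw being the stochastic stage under test) for cluster-fold
recovery, and 10,000 random 80-bp regions for ChIP profiles; the whole
suite runs in well under a minute on one CPU, and the acceptance script in
about one to two minutes.

## Known limitations

* No multi-mapper rescue: mapQ-0 reads are dropped, so young, highly
  identical TE families are under-counted (an inherent limit of the
  uniqueness criterion, noted rather than solved here).
* The dispersion estimator shares no information across features; at two
  or three replicates it is noisy and the t reference is what keeps the
  test calibrated.
* No shrinkage of fold changes; low-count features show inflated
  |log2FC| that the pseudocount only partly damps.
* Two-group contrasts only; no GLM designs, no batch covariates beyond
  the explicit two-batch control contrast.
* Cluster CIs treat precursors as independent, which overlapping precursor
  annotations within a cluster violate; the CI is descriptive.
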