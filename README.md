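# TEactivity

Transposable elements (TEs) are mobile DNA sequences kept transcriptionally
silent by chromatin marks; in *Drosophila melanogaster*, methylation of
lysine 36 on histone H3 (H3K36me, deposited by Set2, NSD and Ash1) is one of
the silencing layers, and piRNA clusters — the loci encoding the precursors
of the piRNA defence system — respond to its loss. **TEactivity** is an R
(Bioconductor-style) package for quantifying and testing this kind of
repeat transcription from RNA-seq alignments. It is aimed at genomicists
analysing TE and piRNA-cluster expression across mutant panels with
replicated designs and paired control comparisons.

The package covers the full chain:

* **Repeat-aware counting** — uniquely aligned reads (mapQ > 0) counted
  within RepeatMasker-style annotations (`.out`, BED with
  `name#order/family`, or GTF), with `every_overlap` or `largest_overlap`
  modes and paired-fragment collapsing (`readRepeatAnnotation`,
  `countFeatures`, `buildCountSet`).
* **Negative-binomial differential transcription** — median-of-ratios size
  factors, method-of-moments dispersion (variance = μ + αμ²), a Wald test
  on log₂ fold changes with Benjamini–Hochberg adjustment, and the strict
  up-set selection log₂FC > 2, *P* < 0.05 (`nbWaldTest`, `selectUp`).
* **Stringent double-control filtering** — features significantly changed
  between two independently sequenced wild-type runs *or* between a control
  genotype and wild type are excluded before any biological conclusion
  (`controlConsistencyFilter`).
* **Composition and context analyses** — observed vs genome-abundance
  repeat-class chi-square tests, membership partition of an up-set across
  mutants, classification of activated elements into
  intergenic / expressed-gene / unexpressed-gene contexts, and windowed
  genomic density tracks (`compositionChiSquare`, `partitionByMutants`,
  `classifyGenomicContext`, `binDensity`).
* **piRNA cluster scoring** — mean normalized reads per precursor for
  uni- and dual-strand clusters, 95% confidence intervals, and fold changes
  over control reported with one-decimal half-away-from-zero rounding
  (`summarizeClusters`, `foldOverControl`, `compareClusterTypes`).
* **ChIP/input enrichment profiling** — library-normalized,
  pseudocount-guarded sample/input ratios per feature class, including
  10,000 random 80-bp background regions (`featureRatio`, `classProfile`,
  `sampleRandomRegions`).
* **A seeded synthetic-data generator** — a small multi-chromosome genome
  with pericentromere-enriched repeats, genes with known expression states,
  2 dual- + 2 uni-strand piRNA clusters, NB counts with planted effects,
  SAM emission, and ChIP coverage with planted class enrichment, plus truth
  tables for oracle testing (`simConfig`, `simulateAnnotation`,
  `simulateCounts`, `simulateAlignments`, `simulateChip`).

The central statistic for a two-group contrast is the NB Wald test: with
group means μ̂ₜ, μ̂_c estimated on size-factor-normalized counts and fixed
dispersion α,

    log2FC = log2((μ̂_t + 0.5) / (μ̂_c + 0.5))
    se²    = (1/ln 2)² [ (1/n_t)(1/μ̂_t + α) + (1/n_c)(1/μ̂_c + α) ]

and log2FC/se is referred to a Student *t* with n_t + n_c − 2 df when α is
estimated from the data (see the methods vignette for why).

## Worked example

The whole chain on a synthetic study (five replicates each of a wild type
sequenced in two batches, a control genotype, the H3K36R histone
replacement and three methyltransferase knock-outs):

```r
library(TEactivity)
cfg <- simConfig(seed = 101)
ann <- simulateAnnotation(cfg)
sim <- simulateCounts(cfg, ann)
res <- runPipeline(sim, ann)

length(res$up$main)          # 133 up-regulated transposons (log2FC > 2, adj. p < 0.05)
res$filter$main$n_removed    # 31 removed by the double-control filter
res$composition
#> CompositionTable: n = 133, chi2 = 19.15 (df = 2), p = 6.96e-05
#>           class  observed  expected
#> 1          LINE 0.1729323 0.1500000
#> 2           LTR 0.5939850 0.4333333
#> 3 Simple_repeat 0.2330827 0.4166667
round(res$context$fractions, 3)
#>       intergenic   expressed_gene unexpressed_gene
#>            0.735            0.137            0.127
subset(res$clusters, condition == "H3K36R")[,
    c("cluster_id", "strand_mode", "mean_reads_per_precursor", "fold_reported")]
#>  cluster_id strand_mode mean_reads_per_precursor fold_reported
#>        42AB        dual                   27.035           8.4
#>         38C        dual                   27.526           8.7
#>         20A         uni                    4.619           1.6
#>    flamenco         uni                    4.944           1.5
```

Reading the output: the up-set is strongly LTR-enriched relative to genome
abundance (chi-square p ≪ 0.001), most activated elements are intergenic
(73.5%), and the dual-strand piRNA clusters respond far more strongly than
the uni-strand ones (estimated folds ≈ 8.4/8.7 vs 1.6/1.5 over wild type,
matching the planted simulation truth of 8 and 1.5).

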