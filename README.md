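# enhancerscape

Mapping active enhancer landscapes and classifying long non-coding RNAs
(lncRNAs) during the differentiation of embryonic stem cells (ESC)
toward mesendoderm — the transient precursor population, marked here by
Eomes expression (Eo&minus;/Eo&plus; sorted fractions), that gives rise
to mesoderm and definitive endoderm. The package reimplements the
computational core of this kind of study as tested, reusable R
(Bioconductor-style) components, together with a seeded synthetic-data
generator that plants known truth so the whole pipeline can be
exercised and benchmarked offline.

It is aimed at computational biologists who want the individual
statistical steps of an enhancer/lncRNA study as composable functions
(GRanges in, GRanges/DataFrame out) rather than a monolithic script.

## What it computes

**Enhancer calling.** Reads are extended to 200 bp from their 5' end
and allocated to 25-bp bins. A bin is enriched when its count *c*
satisfies the exact Poisson upper tail P(X ≥ c) &lt; 10⁻⁹ at the
genome-wide background rate λ (mean count/bin) *and* is at least
5-fold over the library-size-rescaled input. Replicates are combined
by intersection; maximal runs of positive bins, unioned over the three
cell populations and at least 200 bp long, are **constituent enhancers
(CEs)**.

**Super-enhancers.** CEs within 12.5 kb are stitched (ROSE
convention); stitched regions are ranked by input-corrected per-million
H3K27Ac signal, and the SE/TE threshold is placed where a slope-1 line
is tangent to the scaled rank–signal curve (the sorted index minimizing
scaled signal − scaled rank). A region is SE for a condition only when
both replicates put it above their own cutoff; the global SE list is
the union over conditions, and **typical enhancers (TEs)** are CEs not
overlapping any SE.

**lncRNA classification.** After filtering (mature length ≥ 200 bp and
≥ 2 exons for novel transcripts, external coding-potential score ≤ 4,
condition-mean FPKM &gt; 0.1 somewhere), each lncRNA gene gets exactly
one class, in precedence order: **plncRNA** (H3K4me3 within ±1 kb of a
TSS), **SE lncRNA** (any part of the gene in a super-enhancer), **TE
lncRNA**, or **unmarked**.

**Expression statistics.** Cell specificity is the normalized
difference ND(x) = (max(gₓ) − min(gₓ)) / mean(gₓ) over the three
populations (bounded [0, 3]); distributions are compared by one-tailed
Wilcoxon rank-sum tests (exact when tie-free and small). Heart
enrichment on a 12-tissue panel is HE = μ_cardiac / (μ_non-cardiac +
2·σ_non-cardiac), with a gene called enriched when HE &gt; 1, plus
per-tissue analogues and enrichment-percentage ratios between gene
sets. Panel preprocessing: strand sum → replicate mean →
median-of-ratios size factors → 0.1 expression floor.

**Conservation.** Fragment scores are per-base conservation summed
over the fragment and divided by its length (exons, introns, 1-kb
strand-aware promoters, and random intergenic fragments of
3400 bp ± 20%); phyloP-style TSS maxima scan a 600-bp window (−500/+100
around the TSS).

## Worked example

A small synthetic run, end to end (about 30 s):

```r
library(enhancerscape)

cfg <- syntheticConfig(
  seed = 42, chromSizes = c(chr1 = 1000000L, chr2 = 800000L),
  nPcg = 60L, nAnnotLnc = 20L, nNovelLnc = 30L,
  decoys = list(singleExon = 3L, short = 2L, highCoding = 3L),
  nIsolated = 8L, nClusters = 2L, readsPerReplicate = 300000L,
  expression = list(specificPerCondition = 5L),
  tissuePlan = list(nHeartEnriched = 12L),
  conservationPlan = list(nConserved = 25L))

runPipeline(cfg, "demo_out")
cat(readLines("demo_out/pipeline.log"), sep = "\n")
```

```
pipeline: binSize=25 extension=200 pThreshold=1e-09 minFold=5 minCeLength=200 stitchDistance=12500 promoterHalfwidth=1000 seed=42
simulate: 110 transcripts, 14 planted enhancer sites
callbins H3K27Ac: 14 regions
callbins H3K4me3: 66 regions
rose: 2 SE / 8 TE
classify: 42 lncRNA genes classified, 8 transcripts rejected
specificity: ND for 110 genes
tissue: 110 genes scored; 19 heart-enriched; |EoPos set|=5 |EoNeg set|=5
conserve: 110 genes scored; promoter-vs-intergenic p=1.55e-17
```

Reading the log: all 14 planted H3K27Ac sites come back as constituent
enhancers; the two planted clusters (3 constituents each) stitch into
the 2 called super-enhancers, and the 8 isolated sites are typical
enhancers. The 8 rejected transcripts are exactly the planted decoys
(single-exon, sub-200-bp, coding-score &gt; 4 novel lncRNAs). The
conservation stage confirms the planted promoter elevation against
sampled intergenic background:

```
nConservedPromoters  nIntergenic  meanPromoter  meanIntergenic  wilcoxonP
25                   500          0.402403      0.101923        1.54873e-17
```

(The 25 planted promoters average ~0.40 versus the ~0.10 background —
the configured 0.3 elevation.) Per-stage TSVs/BEDs (class assignments,
activity matrix, rank tables, HE scores, enrichment ratios) are written
next to the log, and a fixed seed reproduces every file byte for byte.

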