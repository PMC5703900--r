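---
title: "Methods: enhancer landscapes, lncRNA classes and enrichment statistics"
author: "enhancerscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enhancer landscapes, lncRNA classes and enrichment statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhancerscape)
```

This vignette is the package's own account of the models it
implements, the parameters that matter, the synthetic data it tests
itself on, and the numerical and design choices made along the way.

# The biological setting

During gastrulation, embryonic stem cells (ESC) pass through a
transient mesendoderm state before committing to mesoderm and
definitive endoderm. Sorting differentiating cells on an Eomes
reporter yields three populations — ESC, Eomes-negative (EoNeg) and
Eomes-positive (EoPos) — whose chromatin (H3K27Ac marking active
enhancers, H3K4me3 marking active promoters) and transcriptomes
(protein-coding genes, annotated and novel lncRNAs) can be compared.
The package implements the downstream computation of such a study:
enhancer calling, super-enhancer assignment, epigenomic lncRNA
classification, specificity and tissue-enrichment statistics, and
conservation scoring. Upstream steps (alignment, transcript
reconstruction, coding-potential scoring) are out of scope; their
outputs are inputs here.

# Poisson enrichment calling

Reads are extended from their 5' end to the fragment length
(`extension = 200` bp, matching sonicated single-end libraries) and
allocated to every `binSize = 25` bp bin their extended span overlaps.
A bin with count $c$ is enriched when

$$P(X \ge c \mid X \sim \mathrm{Pois}(\lambda)) < 10^{-9}
\quad\text{and}\quad
\frac{c}{\max(\hat c_{\mathrm{input}}, \varepsilon)} \ge 5,$$

where $\lambda$ is the genome-wide mean allocated count per bin of the
sample track, $\hat c_{\mathrm{input}}$ is the input count rescaled by
the ratio of library sizes, and $\varepsilon$ is the rescaled
genome-wide input mean — a floor that keeps the fold ratio defined on
zero-input bins. The tail is the exact Poisson survival function
(`ppois(c - 1, lower.tail = FALSE)`); no normal approximation is used,
and the test suite checks the decision against an independent
brute-force summation of the tail series on a thousand random
$(c, \lambda)$ pairs.

Two modelling choices deserve note. First, $\lambda$ is global: a
uniform background is the simplest model consistent with a
whole-genome Poisson test, and a per-chromosome rate is exposed via
`perChromosomeLambda = TRUE` for genomes with strong chromosome-scale
coverage differences. Second, the fold test uses library-size-rescaled
counts rather than raw counts; with equal library sizes the two
coincide, and rescaling is the only choice that makes the threshold
meaningful when they differ.

Replicates are combined by per-bin intersection — a bin counts for a
condition only if both biological replicates call it — and input
(whole-cell extract) replicates are pooled per condition before use.
Constituent enhancers (CEs) are maximal runs of positive bins, unioned
across the three populations with overlap merging, kept when at least
`minCeLength = 200` bp: an enhancer exists as soon as one population
supports it.

# Super-enhancers: stitching and the slope-1 cutoff

CEs within `stitchDistance = 12500` bp are merged transitively and the
stitched regions ranked by input-corrected per-million H3K27Ac signal
(no length normalization for ranking, following ROSE; a
length-normalized variant of `scoreRegion()` exists for size-matched
comparisons; no promoter exclusion is applied during stitching).
With ranks and signals rescaled to $[0,1]$, the SE threshold is the
signal at the sorted index minimizing
$\tilde y_i - \tilde x_i$ — the point where a line of slope 1 is
tangent to the ranked curve from below, i.e. where the curve starts
rising faster than the diagonal. Ties are resolved toward the higher
index (fewer super-enhancers), and degenerate inputs (all signals
equal, or an all-zero maximum) place the threshold at the maximum so
that nothing is "strictly above" it. Regions *strictly above* the
threshold are super-enhancers; a region sitting exactly at the cutoff
is typical. We chose the tangency formulation over a rule based on the
first discrete slope exceeding 1 because discrete slopes are noisy in
both tails: tied top signals create zero-slope plateaus, and the
near-zero tail of regions inactive in a condition can produce an early
spurious crossing.

A region is SE for a condition only when both replicates place it
above their own cutoff; the global SE list is the merged union over
conditions; TEs are the CEs with no SE overlap — so SE and TE
partition the constituent set by construction, which the tests verify.
The cross-condition activity matrix marks an enhancer active in a
condition on any-length overlap with that condition's list.

Because the replicate and condition comparisons all use any-length
overlap to identify "the same" region, the package stitches the global
CE list once and scores those fixed regions per condition and
replicate, rather than re-stitching per condition and matching regions
afterwards; under the any-overlap identity the two procedures agree,
and fixing the regions makes the replicate intersection exact.

# lncRNA filters and the four-way classification

Novel transcripts must have mature (exonic) length at least 200 bp and
at least 2 exons; every lncRNA must have an external coding-potential
score of at most 4 (strictly greater is discarded — a score of exactly
4 survives); and every transcript must exceed 0.1 FPKM as a condition
mean in at least one population. Filters are applied in that order and
the first failure is logged per transcript, so the rejection log is
order-independent and auditable.

Classification is a strict precedence cascade per gene, using
chromatin calls from any of the three conditions (the same union logic
as CE calling; a per-condition classification can be assembled from
the same functions if wanted):

1. **plncRNA** if any transcript's TSS ± 1 kb window overlaps an
   H3K4me3-positive region;
2. else **SE lncRNA** if any part of the gene span — exons and introns,
   since chromatin marks are not exon-restricted — overlaps a
   super-enhancer;
3. else **TE lncRNA** likewise versus typical enhancers;
4. else **unmarked**.

The tests enumerate all $2^3$ overlap combinations and check the
resulting class, plus the property that adding H3K4me3 at a TSS can
only move a gene toward plncRNA.

# Expression statistics

The **normalized difference** of a gene's condition means
$g_x$ is $\mathrm{ND}(x) = (\max g_x - \min g_x)/\overline{g_x}$: 0
for flat profiles, and at most $k$ for $k$ conditions (mean $\ge$
max$/k$), so 3 here, attained exactly when a gene is expressed in one
population only. ND is computed on replicate-collapsed condition
means; all-zero genes return `NA` rather than a value (they should
have been filtered). Distribution comparisons use the one-tailed
Wilcoxon rank-sum test, exact whenever the smaller group has at most
20 observations and the pooled values are tie-free, otherwise the
normal approximation with tie and continuity correction; the exact
path is validated against full enumeration of rank assignments for all
group sizes up to 6. Kernel-density summaries (Gaussian kernel,
Silverman's rule-of-thumb bandwidth) accompany the p-value for
plotting.

Fold-change-enriched sets use a pseudocount of 0.01 FPKM on both
means — the data's zero policy is otherwise undefined — with strict
`> 2` fold, optionally gated on Benjamini–Hochberg adjusted p below
0.05. `welchDE()` is explicitly plumbing: a per-gene Welch t-test on
log2(x + 0.01) so synthetic pipelines can produce p-values end to end;
it is not a substitute for a moderated count model on real data.
Between-sample normalization uses hand-implemented median-of-ratios
size factors (reference = per-gene geometric mean over samples,
excluding genes with any zero; factor = median ratio to the
reference), cross-checked in the test suite against an independent
reference implementation.

# Tissue enrichment

The 12-tissue panel is preprocessed by summing strands, averaging the
two replicates, dividing by size factors, and dropping genes that
never reach 0.1. The heart-enrichment score is

$$\mathrm{HE} = \frac{\mu_{\mathrm{cardiac}}}
{\mu_{\mathrm{non\text{-}cardiac}} + 2\,\sigma_{\mathrm{non\text{-}cardiac}}},$$

with $\sigma$ the sample (n−1) standard deviation over the 11
non-cardiac tissues — the population/sample choice is not dictated by
the formula, so the package states it and sticks to it. A gene is
enriched when HE is strictly above 1, i.e. its heart expression stands
two standard deviations above the non-cardiac mean; an all-zero
denominator with positive heart expression yields an `Inf` sentinel
(enriched), and scores are computed on linear expression, matching the
formula as written. Per-tissue scores reuse the identical code path,
so the heart column of `tissueEnrichmentScores()` is bit-identical to
`heScore()`. The enrichment *ratio* between two gene sets is the ratio
of the percentages of score-above-1 genes in each set (the
figure-legend definition; the per-gene score ratio would not be a
set-level summary), returned per tissue by
`tissueEnrichmentRatios()`.

# Conservation

Fragment scores are per-base track scores summed over a fragment and
divided by its full length; uncovered bases contribute 0 to the sum
but keep their place in the denominator, and a fully uncovered
fragment warns. Promoters are the 1000 bp immediately upstream of the
TSS, strand-aware (mirrored on the minus strand), merged per gene
before scoring so shared promoters are not double-counted. Background
comes from random intergenic fragments — uniform lengths in
3400 bp ± 20%, rejection-sampled (cap: 10 × n attempts) to avoid all
gene spans; regions may overlap each other, as a random background
sample legitimately can. phyloP-style TSS maxima scan a strand-aware
−500/+100 window; in phyloP mode uncovered bases are *excluded* from
the maximum, because a signed score's max must not be dragged toward 0
by missing data, whereas in phastCons mode missing means "no
conservation evidence" and scores 0.

# The synthetic-data generator

The generator is first-class, tested code, and its defaults define the
package's benchmark conditions: a 2 × 5 Mb toy genome carrying 50
planted H3K27Ac sites at 20-fold over background (35 isolated with
random non-empty condition activity; 5 clusters of 3 constituents
spaced 2–4 kb apart, all-condition active, so stitching at 12.5 kb is
exercised by construction), one million 50-bp single-end reads per
ChIP replicate, a 1000-gene complement (600 PCG / 150 annotated /
250 novel lncRNA, including single-exon, sub-200-bp and
coding-score-above-4 decoys for the filters), 100 heart-enriched genes
at 8-fold in the 12-tissue panel, and a +0.3 promoter conservation
elevation for 200 genes.

Reads are drawn from a piecewise-constant intensity (background rate
times the planted fold inside active sites; input sees background
only), with the read count Poisson around the target depth — so
per-bin background counts are Poisson-dispersed, which a test checks
via the variance/mean ratio. Expression noise is multiplicative
log-normal with unit mean and configured CV, so `cv = 0` reproduces
planted means exactly; strand counts are an exact split of each
replicate total. Conservation tracks are 100-bp tiles of Gaussian
noise (sd 0.05) around a 0.1 background, clamped to [0, 1], with the
planted delta added over conserved promoters. None of the noise
magnitudes are claims about any real dataset — the real studies
publish no such parameters — they are chosen once as plausible
desk-scale values and documented here. Everything derives from one
master seed through per-key sub-streams (hash of
mark/condition/replicate), so adding one track never perturbs another
and identical configurations give byte-identical files.

What the generator does *not* emulate: fragment-size distributions, GC
and mappability bias, duplicate reads, overdispersed (non-Poisson)
count noise, correlated replicates, isoform complexity (one transcript
per gene), or enhancers overlapping genes (transcripts are placed
clear of planted sites so enhancer truth and transcript truth stay
disentangled). Passing the planted-recovery benchmarks therefore shows
the *logic* is right at realistic signal-to-noise, not that the caller
is robust to every artefact of real ChIP-seq.

# Numerical and interface choices

- Internal coordinates are 1-based closed `GRanges` (the Bioconductor
  convention); BED (0-based half-open) and GTF (1-based closed) are
  converted at the `rtracklayer` boundary, and the bin index of a
  position is computed accordingly (`(pos - 1) %/% binSize`).
- Reads longer than the extension are kept unextended (with a
  warning); reads wholly outside their chromosome are dropped and
  counted.
- TSV outputs are written at 6 significant digits for diffability; GTF
  output drops the writer's date header line so equal data give equal
  bytes; coding scores are generated at limited precision so the GTF
  round trip is exact.
- The benchmark problem sizes used by the tests and the acceptance
  script (10⁶ reads/replicate, 10⁵ ND triples, 100 cutoff trials, 20
  heart-recovery seeds, 1000 intergenic fragments) are the package's
  chosen desk-scale study conditions; they run in a few minutes on one
  CPU.

# Known limitations

- The Poisson background is global and unimodal; regions of genuinely
  elevated background (e.g. copy-number gains) would inflate calls.
  The per-chromosome option is a coarse remedy only.
- `welchDE()` is deliberately naive; real differential expression
  should come from a moderated model upstream, with only the
  filtering thresholds applied here.
- The slope-1 cutoff, like ROSE's, is a geometric heuristic: with very
  few stitched regions (fewer than ~4) the tangency point is
  uninformative and no region clears the threshold.
- Classification uses marks unioned over conditions; genes switching
  classes between conditions are not resolved (the building blocks to
  do so per condition are exported).
- Real-data mode expects aligned reads as BED and conservation as
  bedGraph/wig; BAM and bigWig should be converted with standard
  tooling first.
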