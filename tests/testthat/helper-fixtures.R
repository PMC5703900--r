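## Shared fixtures, built in code.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

## A small, fast synthetic configuration for unit tests.
smallConfig <- function(seed = 11L, ...) {
  dots <- list(...)
  args <- list(
    seed = seed,
    chromSizes = c(chr1 = 400000L, chr2 = 300000L),
    nPcg = 30L, nAnnotLnc = 10L, nNovelLnc = 20L,
    decoys = list(singleExon = 3L, short = 2L, highCoding = 2L),
    nIsolated = 4L, nClusters = 1L,
    readsPerReplicate = 150000L,
    expression = list(specificPerCondition = 3L),
    tissuePlan = list(nHeartEnriched = 10L),
    conservationPlan = list(nConserved = 15L))
  for (nm in names(dots)) args[[nm]] <- dots[[nm]]   # wholesale override
  do.call(syntheticConfig, args)
}

## Build a BinnedTrack directly from per-chromosome count vectors.
manualTrack <- function(counts, binSize = 25L, seqlens = NULL,
                        totalMapped = sum(unlist(counts))) {
  if (is.null(seqlens))
    seqlens <- setNames(
      as.integer(vapply(counts, length, integer(1)) * binSize),
      names(counts))
  new("BinnedTrack", counts = lapply(counts, as.numeric),
      binSize = as.integer(binSize),
      seqlengths = setNames(as.integer(seqlens), names(seqlens)),
      totalMapped = as.numeric(totalMapped), nRejected = 0L)
}

## Build an EnrichedBinMask from logical vectors.
manualMask <- function(mask, binSize = 25L, seqlens = NULL,
                       mark = "H3K27Ac", condition = "ESC",
                       replicate = "intersection") {
  if (is.null(seqlens))
    seqlens <- setNames(
      as.integer(vapply(mask, length, integer(1)) * binSize),
      names(mask))
  new("EnrichedBinMask", mask = mask, binSize = as.integer(binSize),
      seqlengths = setNames(as.integer(seqlens), names(seqlens)),
      provenance = c(mark = mark, condition = condition,
                     replicate = replicate))
}

## Minimal TranscriptSet from a list of exon start/end matrices.
## spec: list(txId = list(chrom=, strand=, exons=matrix(start,end),
##            gene=, biotype=, coding=))
manualTxSet <- function(spec, seqlens = c(chr1 = 100000L)) {
  exl <- lapply(spec, function(s)
    GRanges(s$chrom, IRanges(s$exons[, 1], s$exons[, 2]),
            strand = s$strand))
  exons <- GRangesList(exl)
  names(exons) <- names(spec)
  seqlengths(exons) <- seqlens[seqlevels(exons)]
  info <- DataFrame(
    transcriptId = names(spec),
    geneId = vapply(spec, `[[`, character(1), "gene"),
    biotype = vapply(spec, `[[`, character(1), "biotype"),
    codingScore = vapply(spec, function(s)
      if (is.null(s$coding)) 1 else s$coding, numeric(1)))
  transcriptSet(exons, info)
}

## Independent brute-force Poisson upper-tail oracle: direct summation
## of the series P(X >= k) = sum_{j >= k} e^-lam lam^j / j!.
poissonTailOracle <- function(k, lam, terms = 3000L) {
  if (k <= 0) return(1)
  j <- k:(k + terms)
  sum(exp(-lam + j * log(lam) - lgamma(j + 1)))
}

## Independent Wilcoxon rank-sum oracle: full enumeration of all
## C(n+m, n) assignments of the pooled mid-ranks to group A.
wilcoxEnumOracle <- function(a, b, alternative = "greater") {
  pooled <- c(a, b)
  r <- rank(pooled)
  n <- length(a)
  obs <- sum(r[seq_len(n)])
  sums <- apply(utils::combn(length(pooled), n), 2,
                function(i) sum(r[i]))
  if (alternative == "greater") mean(sums >= obs) else mean(sums <= obs)
}
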