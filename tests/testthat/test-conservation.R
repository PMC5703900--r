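mkTrack <- function(runs, seqlens = c(chr1 = 100000L),
                    mode = "phastcons") {
  conservationTrack(runs, seqlens, mode = mode)
}

test_that("fragment score is the per-base sum over the full length", {
  const <- mkTrack(GRanges("chr1", IRanges(1, 100000), score = 0.5))
  iv <- GRanges("chr1", IRanges(c(11, 501), c(110, 4500)))
  expect_equal(fragmentScore(const, iv), c(0.5, 0.5))

  ## alternating 0/1 over 4 bp -> 0.5
  alt <- mkTrack(GRanges("chr1", IRanges(1:4, 1:4),
                         score = c(0, 1, 0, 1)))
  expect_equal(fragmentScore(alt, GRanges("chr1", IRanges(1, 4))), 0.5)

  ## uncovered bases contribute zero but count in the denominator
  half <- mkTrack(GRanges("chr1", IRanges(1, 50), score = 1))
  expect_equal(fragmentScore(half, GRanges("chr1", IRanges(1, 100))), 0.5)
  expect_warning(
    z <- fragmentScore(half, GRanges("chr1", IRanges(60001, 60100))),
    "uncovered")
  expect_equal(z, 0)
  expect_error(fragmentScore(half, GRanges("chr1", IRanges(99990, 100100))),
               "beyond chromosome")
})

test_that("fragment score of a concatenation is the length-weighted mean
           of the parts", {
  set.seed(14)
  runs <- GRanges("chr1", IRanges(seq(1, 99001, by = 1000),
                                  width = 1000),
                  score = runif(100))
  trk <- mkTrack(runs)
  a <- GRanges("chr1", IRanges(101, 1700))
  b <- GRanges("chr1", IRanges(1701, 5200))
  whole <- GRanges("chr1", IRanges(101, 5200))
  sA <- fragmentScore(trk, a); sB <- fragmentScore(trk, b)
  expect_equal(fragmentScore(trk, whole),
               (sA * width(a) + sB * width(b)) / width(whole))
})

test_that("feature scores use strand-aware promoters and per-transcript
           exon/intron structure", {
  ## high scores only in [4001,5000] (the + promoter of a TSS at 5001)
  runs <- GRanges("chr1", IRanges(c(1, 4001, 5001), c(4000, 5000, 100000)),
                  score = c(0.1, 0.9, 0.1))
  trk <- mkTrack(runs)
  txPlus <- manualTxSet(list(
    gp.t1 = list(chrom = "chr1", strand = "+",
                 exons = cbind(c(5001, 7001), c(5400, 7400)),
                 gene = "gp", biotype = "PCG")))
  fs <- featureScores(trk, txPlus)
  expect_equal(fs$promoterScore, 0.9)            # [4001,5000]
  expect_equal(fs$exonScore, 0.1)
  expect_equal(fs$intronScore, 0.1)              # gap [5401,7000]
  expect_false(fs$promoterClipped)

  ## minus strand: TSS at 5000 -> promoter [5001, 6000]
  runsM <- GRanges("chr1", IRanges(c(1, 5001, 6001), c(5000, 6000, 100000)),
                   score = c(0.1, 0.8, 0.1))
  trkM <- mkTrack(runsM)
  txMinus <- manualTxSet(list(
    gm.t1 = list(chrom = "chr1", strand = "-",
                 exons = cbind(c(3001, 4601), c(3400, 5000)),
                 gene = "gm", biotype = "PCG")))
  fsM <- featureScores(trkM, txMinus)
  expect_equal(fsM$promoterScore, 0.8)

  ## single-exon transcript: no intron score
  mono <- manualTxSet(list(
    gs.t1 = list(chrom = "chr1", strand = "+",
                 exons = cbind(20001, 20800),
                 gene = "gs", biotype = "novel_lnc")))
  expect_true(is.na(featureScores(trk, mono)$intronScore))
})

test_that("intergenic sampling respects length bounds and gene
           exclusion, deterministically", {
  sl <- c(chr1 = 2000000L, chr2 = 1500000L)
  set.seed(1)
  genes <- GRanges(sample(names(sl), 40, replace = TRUE),
                   IRanges(sample(10000:1400000, 40), width = 5000))
  ig <- sampleIntergenic(sl, genes, 300, seed = 42L)
  expect_length(ig, 300)
  expect_true(all(width(ig) >= 2720 & width(ig) <= 4080))
  expect_equal(sum(IRanges::overlapsAny(ig, genes)), 0)
  ig2 <- sampleIntergenic(sl, genes, 300, seed = 42L)
  expect_identical(ig, ig2)
  ## impossible request errors with the achieved count
  tiny <- c(chr1 = 10000L)
  dense <- GRanges("chr1", IRanges(1, 9000))
  expect_error(sampleIntergenic(tiny, dense, 5, seed = 1L),
               "insufficient intergenic space")
})

test_that("phyloP TSS maxima scan the strand-aware 600-bp window and
           ignore uncovered bases", {
  ## + strand TSS at 10001: window [9501, 10100]
  spike <- GRanges("chr1", IRanges(c(1, 9801), c(9800, 9801)),
                   score = c(0.1, 3.7))
  cover <- GRanges("chr1", IRanges(9802, 100000), score = 0.1)
  trk <- mkTrack(c(spike, cover), mode = "phylop")
  tx <- manualTxSet(list(
    g.t1 = list(chrom = "chr1", strand = "+",
                exons = cbind(c(10001, 12001), c(10400, 12400)),
                gene = "g", biotype = "PCG")))
  out <- phylopTssMax(trk, tx)
  expect_equal(out$maxScore, 3.7)          # spike at TSS-200 inside window

  ## spike at TSS-800 is outside the window
  far <- mkTrack(GRanges("chr1", IRanges(c(1, 9201, 9202), c(9200, 9201, 100000)),
                         score = c(0.1, 3.7, 0.1)), mode = "phylop")
  expect_equal(phylopTssMax(far, tx)$maxScore, 0.1)

  ## constant track returns the constant
  const <- mkTrack(GRanges("chr1", IRanges(1, 100000), score = 0.42),
                   mode = "phylop")
  expect_equal(phylopTssMax(const, tx)$maxScore, 0.42)

  ## uncovered bases are excluded from the max in phylop mode: a track
  ## of negative scores with a hole must not report 0
  neg <- mkTrack(GRanges("chr1", IRanges(c(1, 9700), c(9600, 100000)),
                         score = c(-2, -1)), mode = "phylop")
  expect_equal(phylopTssMax(neg, tx)$maxScore, -1)

  ## per-gene max over transcripts: adding a lower-scoring transcript
  ## does not change the gene value
  tx2 <- manualTxSet(list(
    g.t1 = list(chrom = "chr1", strand = "+",
                exons = cbind(c(10001, 12001), c(10400, 12400)),
                gene = "g", biotype = "PCG"),
    g.t2 = list(chrom = "chr1", strand = "+",
                exons = cbind(c(30001, 32001), c(30400, 32400)),
                gene = "g", biotype = "PCG")))
  expect_equal(phylopTssMax(trk, tx2)$maxScore, 3.7)

  ## minus strand mirror: TSS at 20000, window [19901, 20500]
  txm <- manualTxSet(list(
    m.t1 = list(chrom = "chr1", strand = "-",
                exons = cbind(c(18001, 19601), c(18400, 20000)),
                gene = "m", biotype = "PCG")))
  spikeM <- mkTrack(GRanges("chr1",
                            IRanges(c(1, 20400, 20401), c(20399, 20400, 100000)),
                            score = c(0.1, 2.5, 0.1)), mode = "phylop")
  expect_equal(phylopTssMax(spikeM, txm)$maxScore, 2.5)
})

test_that("planted promoter elevation separates promoters from
           intergenic background", {
  cfg <- smallConfig()
  g <- generateGenomeAndTranscripts(cfg)
  trk <- simulateConservation(cfg, g$truth, g$transcripts)
  fs <- featureScores(trk, g$transcripts)
  consProm <- fs$promoterScore[fs$geneId %in% g$truth@conservedPromoters]
  ig <- sampleIntergenic(cfg@chromSizes, geneSpans(g$transcripts), 100,
                         seed = 5L)
  igScore <- fragmentScore(trk, ig)
  p <- suppressWarnings(wilcox.test(consProm, igScore,
                                    alternative = "greater"))$p.value
  expect_lt(p, 0.01)
})
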