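mkLncFixture <- function() {
  manualTxSet(list(
    ok.t1 = list(chrom = "chr1", strand = "+",
                 exons = cbind(c(10001, 10601), c(10150, 10800)),
                 gene = "ok", biotype = "novel_lnc", coding = 1),
    short.t1 = list(chrom = "chr1", strand = "+",
                    exons = cbind(c(20001, 20201), c(20070, 20280)),
                    gene = "short", biotype = "novel_lnc", coding = 1),
    mono.t1 = list(chrom = "chr1", strand = "+",
                   exons = cbind(30001, 30800),
                   gene = "mono", biotype = "novel_lnc", coding = 1),
    coding4.t1 = list(chrom = "chr1", strand = "+",
                      exons = cbind(c(40001, 40601), c(40300, 40900)),
                      gene = "coding4", biotype = "annotated_lnc",
                      coding = 4),
    coding401.t1 = list(chrom = "chr1", strand = "+",
                        exons = cbind(c(50001, 50601), c(50300, 50900)),
                        gene = "coding401", biotype = "annotated_lnc",
                        coding = 4.01),
    silent.t1 = list(chrom = "chr1", strand = "+",
                     exons = cbind(c(60001, 60601), c(60300, 60900)),
                     gene = "silent", biotype = "annotated_lnc",
                     coding = 1)))
}

test_that("transcript filters apply length, exon, coding and expression
           rules in order", {
  tx <- mkLncFixture()
  genes <- unique(as.character(txInfo(tx)$geneId))
  fpkm <- matrix(5, nrow = length(genes), ncol = 3,
                 dimnames = list(genes, c("ESC", "EoNeg", "EoPos")))
  fpkm["silent", ] <- c(0.1, 0.05, 0)    # never strictly above 0.1
  filt <- filterTranscripts(tx, fpkm)
  rej <- as.data.frame(filt$rejected)
  expect_setequal(txInfo(filt$retained)$geneId, c("ok", "coding4"))
  expect_equal(rej$rule[rej$geneId == "short"], "length")    # 140 bp
  expect_equal(rej$rule[rej$geneId == "mono"], "exons")
  expect_equal(rej$rule[rej$geneId == "coding401"], "coding_score")
  expect_equal(rej$rule[rej$geneId == "silent"], "expression")

  ## a transcript missing from the matrix counts as unexpressed
  filt2 <- filterTranscripts(tx, fpkm[setdiff(genes, "ok"), ])
  expect_true("ok" %in% as.data.frame(filt2$rejected)$geneId)

  ## rejection set is order-invariant
  perm <- subsetTranscripts(tx, rev(txInfo(tx)$transcriptId))
  filt3 <- filterTranscripts(perm, fpkm)
  expect_setequal(as.data.frame(filt3$rejected)$transcriptId,
                  rej$transcriptId)
})

test_that("four-way classification follows the precedence order", {
  sl <- c(chr1 = 100000L)
  tx <- manualTxSet(list(
    g1.t1 = list(chrom = "chr1", strand = "+",
                 exons = cbind(c(10001, 12001), c(10300, 12400)),
                 gene = "g1", biotype = "novel_lnc")), seqlens = sl)
  se <- GRanges("chr1", IRanges(12000, 12100))     # inside the gene
  te <- GRanges("chr1", IRanges(11000, 11100))     # intron overlap
  k4AtTss <- GRanges("chr1", IRanges(9500, 9800))  # within TSS +/- 1 kb
  none <- GRanges()

  cl <- function(k4, s, t)
    as.character(classifyLncRNAs(tx, k4, s, t)$klass)
  ## all 2^3 overlap combinations map to the documented class
  expect_equal(cl(k4AtTss, se, te), "plncRNA")   # K4 wins over SE
  expect_equal(cl(k4AtTss, se, none), "plncRNA")
  expect_equal(cl(k4AtTss, none, te), "plncRNA")
  expect_equal(cl(k4AtTss, none, none), "plncRNA")
  expect_equal(cl(none, se, te), "SE_lncRNA")    # SE wins over TE
  expect_equal(cl(none, se, none), "SE_lncRNA")
  expect_equal(cl(none, none, te), "TE_lncRNA")
  expect_equal(cl(none, none, none), "unmarked")

  ## 1-bp overlap with an SE suffices ("any part of the transcript")
  se1 <- GRanges("chr1", IRanges(12400, 12400))
  expect_equal(cl(none, se1, none), "SE_lncRNA")
  ## an SE just outside the gene span does not
  seOut <- GRanges("chr1", IRanges(12401, 12600))
  expect_equal(cl(none, seOut, none), "unmarked")
  expect_error(classifyLncRNAs(manualTxSet(setNames(list(), character(0))),
                               none, none, none), "no transcripts")
})

test_that("multi-transcript genes take the highest-precedence transcript
           and minus-strand TSS windows are mirrored", {
  sl <- c(chr1 = 100000L)
  tx <- manualTxSet(list(
    g1.t1 = list(chrom = "chr1", strand = "-",
                 exons = cbind(c(20001, 22001), c(20300, 22400)),
                 gene = "g1", biotype = "annotated_lnc"),
    g1.t2 = list(chrom = "chr1", strand = "-",
                 exons = cbind(c(20001, 24001), c(20300, 24400)),
                 gene = "g1", biotype = "annotated_lnc")), seqlens = sl)
  ## minus-strand TSS of t2 = 24400; K4 at 25200 is within +/- 1 kb of
  ## t2's TSS but not of t1's (22400)
  k4 <- GRanges("chr1", IRanges(25200, 25300))
  out <- classifyLncRNAs(tx, k4, GRanges(), GRanges())
  expect_equal(as.character(out$klass), "plncRNA")
  ## moving the mark beyond both windows drops the class
  out2 <- classifyLncRNAs(tx, shift(k4, 300), GRanges(), GRanges())
  expect_equal(as.character(out2$klass), "unmarked")
})

test_that("adding H3K4me3 at a TSS can only promote toward plncRNA", {
  set.seed(12)
  sl <- c(chr1 = 1000000L)
  for (i in 1:25) {
    st <- sample(50000:900000, 1)
    tx <- manualTxSet(list(
      g.t1 = list(chrom = "chr1", strand = sample(c("+", "-"), 1),
                  exons = cbind(c(st, st + 2000), c(st + 300, st + 2400)),
                  gene = "g", biotype = "novel_lnc")), seqlens = sl)
    se <- if (runif(1) < 0.5)
      GRanges("chr1", IRanges(st + 100, st + 200)) else GRanges()
    te <- if (runif(1) < 0.5)
      GRanges("chr1", IRanges(st + 2100, st + 2200)) else GRanges()
    before <- as.character(classifyLncRNAs(tx, GRanges(), se, te)$klass)
    tssPos <- start(tssSites(tx))
    after <- as.character(classifyLncRNAs(
      tx, GRanges("chr1", IRanges(tssPos, tssPos)), se, te)$klass)
    expect_equal(after, "plncRNA")
    expect_true(before %in% c("SE_lncRNA", "TE_lncRNA", "unmarked"))
  }
})

test_that("class composition fractions sum to one per biotype", {
  cls <- DataFrame(
    geneId = paste0("g", 1:10),
    biotype = rep("novel_lnc", 10),
    klass = c(rep("TE_lncRNA", 6), "SE_lncRNA",
              rep("plncRNA", 2), "unmarked"))
  comp <- classComposition(cls)
  expect_equal(unname(comp["novel_lnc", ]),
               c(0.2, 0.1, 0.6, 0.1))   # plnc, SE, TE, unmarked
  expect_equal(sum(comp["novel_lnc", ]), 1, tolerance = 1e-12)

  one <- classComposition(cls[1, ])
  expect_equal(sum(one == 1), 1)        # degenerate one-hot

  empty <- classComposition(cls, biotypes = c("novel_lnc", "annotated_lnc"))
  expect_true(all(is.na(empty["annotated_lnc", ])))
})
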