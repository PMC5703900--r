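test_that("generator is deterministic and honours empty configs", {
  cfg0 <- smallConfig(nPcg = 0L, nAnnotLnc = 0L, nNovelLnc = 0L,
                      decoys = list())
  g0 <- generateGenomeAndTranscripts(cfg0)
  expect_length(g0$transcripts@exons, 0)

  cfg <- smallConfig()
  f1 <- tempfile(fileext = ".gtf"); f2 <- tempfile(fileext = ".gtf")
  writeGtfTranscripts(generateGenomeAndTranscripts(cfg)$transcripts, f1)
  writeGtfTranscripts(generateGenomeAndTranscripts(cfg)$transcripts, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("planted decoys are bookkept with their failing rule", {
  cfg <- smallConfig(nNovelLnc = 10L,
                     decoys = list(singleExon = 3L, short = 0L,
                                   highCoding = 0L))
  g <- generateGenomeAndTranscripts(cfg)
  dg <- g$truth@decoyGenes
  expect_equal(sum(dg$failingRule == "exons"), 3)
  ## and the filter rejects exactly those genes for that rule
  fpkm <- matrix(5, nrow = length(unique(txInfo(g$transcripts)$geneId)),
                 ncol = 3,
                 dimnames = list(unique(txInfo(g$transcripts)$geneId),
                                 c("ESC", "EoNeg", "EoPos")))
  filt <- filterTranscripts(g$transcripts, fpkm)
  expect_setequal(filt$rejected$geneId[filt$rejected$rule == "exons"],
                  dg$geneId[dg$failingRule == "exons"])
})

test_that("planted sites outside the genome raise a configuration error
           naming the site", {
  plan <- data.frame(chrom = "chr1", start = 390000L, width = 20000L,
                     fold = 20, seClusterId = NA_character_,
                     ESC = TRUE, EoNeg = TRUE, EoPos = TRUE)
  expect_error(smallConfig(enhancerPlan = plan),
               "outside chromosome.*chr1:390000")
})

test_that("simulated reads are reproducible and mark/condition checked", {
  cfg <- smallConfig(readsPerReplicate = 20000L)
  g <- generateGenomeAndTranscripts(cfg)
  r1 <- simulateChipReads(cfg, g$truth, "H3K27Ac", "ESC", 1)
  r2 <- simulateChipReads(cfg, g$truth, "H3K27Ac", "ESC", 1)
  expect_identical(r1, r2)
  rb <- simulateChipReads(cfg, g$truth, "H3K27Ac", "ESC", 2)
  expect_false(identical(length(r1), length(rb)) &&
               identical(granges(r1), granges(rb)))
  expect_error(simulateChipReads(cfg, g$truth, "H3K9me3", "ESC", 1),
               "unknown mark")
  expect_error(simulateChipReads(cfg, g$truth, "H3K27Ac", "mesoderm", 1),
               "unknown condition")
  expect_true(all(width(r1) <= 50))
})

test_that("background-only sampling is Poisson-dispersed per bin", {
  cfg <- smallConfig(seed = 99L, enhancerPlan = data.frame(
    chrom = character(0), start = integer(0), width = integer(0),
    fold = numeric(0), seClusterId = character(0),
    ESC = logical(0), EoNeg = logical(0), EoPos = logical(0)),
    readsPerReplicate = 400000L)
  g <- generateGenomeAndTranscripts(cfg)
  reads <- simulateChipReads(cfg, g$truth, "input", "ESC", 1)
  ## count 5' starts per 25-bp bin (no extension smoothing: dispersion
  ## is assessed on the raw sampling process)
  p5 <- ifelse(as.character(strand(reads)) == "+", start(reads),
               end(reads))
  chr1 <- p5[as.character(seqnames(reads)) == "chr1"]
  cnt <- tabulate((chr1 - 1) %/% 25 + 1, nbins = 16000)
  ratio <- var(cnt) / mean(cnt)
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.2)
})

test_that("planted sites dominate background by their fold", {
  cfg <- smallConfig(readsPerReplicate = 500000L)
  g <- generateGenomeAndTranscripts(cfg)
  reads <- simulateChipReads(cfg, g$truth, "H3K27Ac", "ESC", 1)
  trk <- binReads(reads, seqlens = cfg@chromSizes)
  active <- g$truth@enhancers[g$truth@enhancers$ESC]
  lam <- lambdaBg(trk)
  siteMeans <- vapply(seq_along(active), function(i) {
    chr <- as.character(seqnames(active))[i]
    b1 <- (start(active)[i] - 1) %/% 25 + 1
    b2 <- (end(active)[i] - 1) %/% 25 + 1
    mean(binCounts(trk)[[chr]][b1:b2])
  }, numeric(1))
  expect_true(all(siteMeans >= 10 * lam))
})

test_that("intensity function covers planted sites exactly in their
           active conditions", {
  cfg <- smallConfig()
  g <- generateGenomeAndTranscripts(cfg)
  enh <- g$truth@enhancers
  for (cond in c("ESC", "EoNeg", "EoPos")) {
    inten <- chipIntensity(cfg, g$truth, "H3K27Ac", cond, enh)
    active <- mcols(enh)[[cond]]
    expect_equal(inten[active] / cfg@backgroundRate,
                 mcols(enh)$fold[active], tolerance = 1e-12)
    expect_equal(inten[!active] / cfg@backgroundRate,
                 rep(1, sum(!active)), tolerance = 1e-12)
  }
  ## input sees background everywhere
  expect_equal(chipIntensity(cfg, g$truth, "input", "ESC", enh),
               rep(cfg@backgroundRate, length(enh)))
})

test_that("noiseless expression matches planted means exactly and
           specific genes reach ND = 3", {
  cfg <- smallConfig(expression = list(cv = 0, specificPerCondition = 3L),
                     tissuePlan = list(cv = 0, fold = 8,
                                       nonCardiacMean = 5,
                                       nHeartEnriched = 10L))
  g <- generateGenomeAndTranscripts(cfg)
  ex <- simulateExpression(cfg, g$truth, g$transcripts)

  ## tissue panel: heart value = 8 x 5 = 40 exactly for planted genes
  cnt <- SummarizedExperiment::assay(ex$tissue, "counts")
  cd <- SummarizedExperiment::colData(ex$tissue)
  heartCols <- cd$tissue == "heart"
  heartVal <- vapply(g$truth@heartEnriched, function(gid) {
    byRep <- tapply(cnt[gid, heartCols],
                    cd$replicate[heartCols], sum)   # strand sum
    mean(byRep)
  }, numeric(1))
  expect_equal(unname(heartVal), rep(40, 10))

  ## ESC-specific genes: zero elsewhere, ND = 3
  means <- collapseReplicates(ex$fpkm, ex$conditions)
  esc <- g$truth@specificGenes$ESC
  expect_true(all(means[esc, c("EoNeg", "EoPos")] == 0))
  expect_equal(unname(normalizedDifference(means[esc, , drop = FALSE])),
               rep(3, length(esc)))

  ## same seed, same TSV bytes
  f1 <- tempfile(); f2 <- tempfile()
  write.table(ex$fpkm, f1)
  write.table(simulateExpression(cfg, g$truth, g$transcripts)$fpkm, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("config YAML and truth JSON round-trip losslessly", {
  cfg <- smallConfig()
  fy <- tempfile(fileext = ".yaml")
  writeConfigYaml(cfg, fy)
  cfg2 <- readConfigYaml(fy)
  expect_equal(cfg2@chromSizes, cfg@chromSizes)
  expect_equal(cfg2@enhancerPlan, cfg@enhancerPlan)
  expect_equal(cfg2@expression, cfg@expression)
  expect_identical(cfg2@seed, cfg@seed)

  g <- generateGenomeAndTranscripts(cfg)
  fj <- tempfile(fileext = ".json")
  writeTruthJson(g$truth, fj)
  t2 <- readTruthJson(fj, cfg@chromSizes)
  expect_identical(granges(t2@enhancers), granges(g$truth@enhancers))
  expect_equal(as.data.frame(mcols(t2@enhancers)),
               as.data.frame(mcols(g$truth@enhancers)))
  expect_identical(t2@specificGenes, g$truth@specificGenes)
  expect_identical(t2@heartEnriched, g$truth@heartEnriched)
  expect_identical(t2@conservedPromoters, g$truth@conservedPromoters)
  expect_equal(as.data.frame(t2@decoyGenes),
               as.data.frame(g$truth@decoyGenes))

  ## unknown keys are rejected
  y <- yaml::read_yaml(fy)
  y$typo <- 1
  yaml::write_yaml(y, fy)
  expect_error(readConfigYaml(fy), "unknown configuration key")
})
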