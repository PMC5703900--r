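test_that("read extension and bin allocation follow the 5'-end rule", {
  sl <- c(chr1 = 10000L)
  ## + read with 5' at 1-based 101 (0-based 100): extended span covers
  ## 0-based bins 4..11
  plus <- GRanges("chr1", IRanges(101, 150), strand = "+")
  trk <- binReads(plus, seqlens = sl)
  expect_equal(which(binCounts(trk)$chr1 > 0), 5:12)   # 1-based indices
  expect_true(all(binCounts(trk)$chr1[5:12] == 1))
  expect_equal(totalMapped(trk), 1)

  ## - read aligned 0-based [280,330) = 1-based [281,330]: extended
  ## back to [131,330], bins 5..13 (0-based)
  minus <- GRanges("chr1", IRanges(281, 330), strand = "-")
  trk2 <- binReads(minus, seqlens = sl)
  expect_equal(which(binCounts(trk2)$chr1 > 0), 6:14)

  ## empty read set
  trk0 <- binReads(GRanges(seqlengths = sl), seqlens = sl)
  expect_equal(sum(binCounts(trk0)$chr1), 0)
  expect_equal(totalMapped(trk0), 0)
})

test_that("binReads rejects out-of-bounds reads and keeps long reads", {
  sl <- c(chr1 = 1000L)
  rd <- GRanges("chr1", IRanges(c(100, 2000), c(149, 2049)),
                strand = "+")
  expect_message(trk <- binReads(rd, seqlens = sl), "rejected")
  expect_equal(totalMapped(trk), 1)
  expect_equal(trk@nRejected, 1L)

  long <- GRanges("chr1", IRanges(101, 400), strand = "+")  # 300 bp
  expect_warning(trkL <- binReads(long, seqlens = sl), "unextended")
  expect_equal(which(binCounts(trkL)$chr1 > 0), 5:16)       # original span
})

test_that("Poisson caller matches the brute-force tail oracle at the
           p<1e-9 boundary", {
  ## at lambda = 1 the smallest count with tail < 1e-9 is 12
  n <- 10000L
  cnt <- rep(1, n)
  cnt[10] <- 12
  cnt[20] <- 11
  cnt[30:50] <- 0      # compensate: genome-wide mean stays exactly 1
  expect_equal(mean(cnt), 1)
  sample <- manualTrack(list(chr1 = cnt), totalMapped = n)
  input <- manualTrack(list(chr1 = rep(1, n)), totalMapped = n)
  m <- poissonEnrichedBins(sample, input)
  expect_true(m@mask$chr1[10])     # count 12: tail 8.3e-10 < 1e-9, fold 12
  expect_false(m@mask$chr1[20])    # count 11: tail 1.0e-8 fails
  expect_false(any(m@mask$chr1[cnt == 0]))  # zero bins never positive
})

test_that("enrichment decision equals the exact tail-sum oracle on
           random (count, lambda) pairs", {
  set.seed(402)
  nPair <- 1000L
  lam <- runif(nPair, 0.1, 50)
  cnt <- rpois(nPair, lam * sample(c(1, 2, 5, 20), nPair, replace = TRUE))
  agree <- vapply(seq_len(nPair), function(i) {
    viaPkg <- ppois(cnt[i] - 1, lam[i], lower.tail = FALSE) < 1e-9
    viaOracle <- poissonTailOracle(cnt[i], lam[i]) < 1e-9
    identical(viaPkg, viaOracle)
  }, logical(1))
  expect_true(all(agree))
})

test_that("fold-over-input rule vetoes Poisson-significant bins", {
  n <- 10000L
  cnt <- rep(1, n)
  cnt[100] <- 100
  cnt[1:88] <- 0                     # keep lambda ~ 1
  sample <- manualTrack(list(chr1 = cnt), totalMapped = n)
  inp <- rep(1, n); inp[100] <- 30   # rescaled input 30 -> fold 3.3
  input <- manualTrack(list(chr1 = inp), totalMapped = n)
  m <- poissonEnrichedBins(sample, input)
  expect_false(m@mask$chr1[100])
  ## with low input the same count passes
  inp2 <- rep(1, n)
  input2 <- manualTrack(list(chr1 = inp2), totalMapped = n)
  m2 <- poissonEnrichedBins(sample, input2)
  expect_true(m2@mask$chr1[100])
  ## zero-input library is an error
  input0 <- manualTrack(list(chr1 = rep(0, n)), totalMapped = 0)
  expect_error(poissonEnrichedBins(sample, input0), "undefined")
})

test_that("caller is monotone in count and in p threshold", {
  set.seed(77)
  n <- 2000L
  base <- rpois(n, 2)
  input <- manualTrack(list(chr1 = rep(2, n)), totalMapped = n)
  mk <- function(cnt, p = 1e-9) {
    s <- manualTrack(list(chr1 = cnt), totalMapped = n)
    poissonEnrichedBins(s, input, pThreshold = p)@mask$chr1
  }
  m1 <- mk(base)
  bumped <- base; bumped[m1] <- bumped[m1] + 5   # raise positive bins
  m2 <- mk(bumped)
  expect_true(all(m2[m1]))                        # no positive turns negative
  expect_true(all(mk(base, 1e-9) <= mk(base, 1e-6)))  # looser p grows set
})

test_that("replicate intersection is a per-bin AND with provenance", {
  mk <- function(idx) {
    v <- rep(FALSE, 20); v[idx] <- TRUE
    manualMask(list(chr1 = v), replicate = "1")
  }
  m1 <- mk(5:12); m2 <- mk(9:16)
  out <- intersectReplicates(m1, m2)
  expect_equal(which(out@mask$chr1), 9:12)
  expect_equal(unname(provenance(out)["replicate"]), "intersection")
  expect_equal(intersectReplicates(m1, m1)@mask, m1@mask)  # idempotent
  m3 <- mk(15:18)
  expect_equal(sum(intersectReplicates(mk(1:3), m3)@mask$chr1), 0)
  bad <- manualMask(list(chr1 = rep(FALSE, 20)), mark = "H3K4me3")
  expect_error(intersectReplicates(m1, bad), "same mark")
})

test_that("constituent enhancers merge across conditions and respect the
           200-bp floor", {
  mk <- function(idx, cond) {
    v <- rep(FALSE, 40)
    v[idx] <- TRUE
    manualMask(list(chr1 = v), condition = cond)
  }
  ## one condition, bins 4..11 (0-based) -> 1-based idx 5..12 -> CE
  ## [101,300], 200 bp, kept
  ce <- callConstituentEnhancers(list(ESC = mk(5:12, "ESC")))
  expect_equal(start(ce), 101)
  expect_equal(end(ce), 300)

  ## a 7-bin run (175 bp) is dropped
  ce2 <- callConstituentEnhancers(list(ESC = mk(5:11, "ESC")))
  expect_length(ce2, 0)

  ## overlapping runs from two conditions merge: [101,300] + [251,500]
  ce3 <- callConstituentEnhancers(list(A = mk(5:12, "ESC"),
                                       B = mk(11:20, "EoNeg")))
  expect_length(ce3, 1)
  expect_equal(c(start(ce3), end(ce3)), c(101, 500))

  ## order of conditions does not matter
  ce4 <- callConstituentEnhancers(list(B = mk(11:20, "EoNeg"),
                                       A = mk(5:12, "ESC")))
  expect_identical(granges(ce3), granges(ce4))
  expect_error(callConstituentEnhancers(list()), "at least one")
})

test_that("CE output is sorted and disjoint on random masks", {
  set.seed(5)
  for (i in 1:20) {
    masks <- lapply(1:3, function(j)
      manualMask(list(chr1 = runif(200) < 0.3,
                      chr2 = runif(150) < 0.3),
                 condition = paste0("c", j)))
    names(masks) <- paste0("c", 1:3)
    ce <- callConstituentEnhancers(masks)
    expect_true(GenomicRanges::isDisjoint(ce))
    expect_false(is.unsorted(ce))
  }
})
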