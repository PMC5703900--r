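#' Simulate one ChIP-seq read track
#'
#' Read 5' starts are drawn from a piecewise-constant intensity: the
#' background rate everywhere, multiplied by a site's fold inside
#' planted sites that are active in the requested condition and carry
#' the requested mark (planted enhancer sites for H3K27Ac, planted
#' promoters for H3K4me3 in every condition). The input track sees
#' background only. The number of reads is Poisson around
#' \code{readsPerReplicate}, read length is fixed (50 bp by default)
#' and strand is uniform. Each (mark, condition, replicate) triple has
#' its own random sub-stream, so simulating one track never perturbs
#' another.
#'
#' @param config a \code{\linkS4class{SyntheticConfig}}.
#' @param truth the matching \code{\linkS4class{PlantedTruth}}.
#' @param mark \code{"H3K27Ac"}, \code{"H3K4me3"} or \code{"input"}.
#' @param condition \code{"ESC"}, \code{"EoNeg"} or \code{"EoPos"}.
#' @param replicate 1 or 2.
#' @return \code{GRanges} of aligned reads (with seqlengths), ready
#'   for \code{\link{binReads}} or BED export.
#' @export
simulateChipReads <- function(config, truth, mark, condition, replicate) {
  .checkMark(mark)
  .checkCondition(condition)
  if (!replicate %in% 1:2) stop("replicate must be 1 or 2")
  sizes <- config@chromSizes

  sites <- switch(mark,
    H3K27Ac = {
      e <- truth@enhancers
      act <- mcols(e)[[condition]]
      s <- e[act]
      mcols(s)$intensityFold <- mcols(s)$fold
      s
    },
    H3K4me3 = {
      p <- truth@promoters
      if (length(p)) mcols(p)$intensityFold <- config@promoterFold
      p
    },
    input = GRanges())

  ## piecewise-constant intensity per chromosome as run-length runs
  segChrom <- character(0); segStart <- integer(0)
  segLen <- integer(0); segVal <- numeric(0)
  for (chr in names(sizes)) {
    mult <- Rle(1, sizes[[chr]])
    if (length(sites)) {
      sc <- sites[seqnames(sites) == chr]
      if (length(sc)) {
        cov <- GenomicRanges::coverage(
          GRanges(chr, ranges(sc)),
          weight = mcols(sc)$intensityFold - 1,
          width = stats::setNames(list(sizes[[chr]]), chr))[[chr]]
        mult <- mult + cov
      }
    }
    rl <- runLength(mult); rv <- runValue(mult)
    segChrom <- c(segChrom, rep(chr, length(rl)))
    segStart <- c(segStart, cumsum(c(1L, rl[-length(rl)])))
    segLen <- c(segLen, rl)
    segVal <- c(segVal, rv * config@backgroundRate)
  }
  w <- segVal * segLen

  .withSeed(.substream(config@seed,
                       paste("chip", mark, condition, replicate, sep = "|")), {
    nReads <- stats::rpois(1, config@readsPerReplicate)
    if (nReads == 0) {
      gr0 <- GRanges()
      seqlevels(gr0) <- names(sizes)
      seqlengths(gr0) <- sizes
      gr0
    } else {
    seg <- sample.int(length(w), nReads, replace = TRUE, prob = w)
    p5 <- segStart[seg] + floor(stats::runif(nReads) * segLen[seg])
    std <- sample(c("+", "-"), nReads, replace = TRUE)
    chr <- segChrom[seg]
    rl <- config@readLength
    s <- ifelse(std == "+", p5, p5 - rl + 1L)
    e <- s + rl - 1L
    lim <- sizes[chr]
    s <- pmax(s, 1L)
    e <- pmin(e, lim)
    gr <- GRanges(chr, IRanges(as.integer(s), as.integer(e)), strand = std)
    gr <- sort(gr)
    names(gr) <- sprintf("read%07d", seq_along(gr))
    seqlengths(gr) <- sizes[seqlevels(gr)]
    gr
    }
  })
}

#' Pool the two input replicates of a condition into one control track
#'
#' Whole-cell-extract controls are combined per condition before the
#' fold-over-input test.
#'
#' @param config,truth as in \code{\link{simulateChipReads}}.
#' @param condition cell population.
#' @param binSize,extension passed to \code{\link{binReads}}.
#' @return a pooled input \code{\linkS4class{BinnedTrack}}.
#' @export
simulatePooledInput <- function(config, truth, condition,
                                binSize = 25L, extension = 200L) {
  r1 <- simulateChipReads(config, truth, "input", condition, 1L)
  r2 <- simulateChipReads(config, truth, "input", condition, 2L)
  binReads(suppressWarnings(c(r1, r2)), seqlens = config@chromSizes,
           binSize = binSize, extension = extension)
}

#' Evaluate the planted ChIP intensity function directly
#'
#' The exact (noise-free) sampling intensity at given positions — the
#' object against which truth-consistency is checked without drawing
#' reads.
#'
#' @param config,truth,mark,condition as in
#'   \code{\link{simulateChipReads}}.
#' @param at \code{GRanges} of positions/intervals to evaluate (mean
#'   intensity over each interval is returned).
#' @return numeric vector of intensities (reads per bp, relative).
#' @export
chipIntensity <- function(config, truth, mark, condition, at) {
  .checkMark(mark)
  .checkCondition(condition)
  sites <- switch(mark,
    H3K27Ac = {
      e <- truth@enhancers
      s <- e[mcols(e)[[condition]]]
      mcols(s)$intensityFold <- mcols(s)$fold
      s
    },
    H3K4me3 = {
      p <- truth@promoters
      if (length(p)) mcols(p)$intensityFold <- config@promoterFold
      p
    },
    input = GRanges())
  out <- numeric(length(at))
  for (chr in unique(as.character(seqnames(at)))) {
    i <- which(as.character(seqnames(at)) == chr)
    mult <- Rle(1, config@chromSizes[[chr]])
    sc <- if (length(sites)) sites[seqnames(sites) == chr] else GRanges()
    if (length(sc)) {
      cov <- GenomicRanges::coverage(
        GRanges(chr, ranges(sc)),
        weight = mcols(sc)$intensityFold - 1,
        width = stats::setNames(list(config@chromSizes[[chr]]), chr))[[chr]]
      mult <- mult + cov
    }
    v <- Views(mult, start(at)[i], end(at)[i])
    out[i] <- viewSums(v) / width(at)[i] * config@backgroundRate
  }
  out
}
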