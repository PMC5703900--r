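#' Configure the synthetic-data generator
#'
#' Builds a \code{\linkS4class{SyntheticConfig}} describing a toy
#' genome with planted ground truth. The defaults define the
#' benchmark conditions used throughout the package's tests: a
#' 2 x 5 Mb genome carrying 50 planted constituent-enhancer sites at
#' 20-fold over background (35 isolated, plus 5 super-enhancer
#' clusters of 3 constituents within 12.5 kb), one million 50-bp
#' single-end reads per ChIP replicate, a 1000-gene transcript
#' complement, 100 heart-enriched genes (8-fold) in the 12-tissue
#' panel, and a 0.3 promoter conservation elevation for 200 genes.
#'
#' When \code{enhancerPlan} is \code{NULL} a plan is generated
#' deterministically from the seed: isolated sites get a random
#' non-empty subset of active conditions; cluster sites are active in
#' all three conditions so replicate-intersected super-enhancer calls
#' are exercised by construction.
#'
#' @param seed master seed; every generator output is a pure function
#'   of the configuration, and sub-streams are keyed per track.
#' @param chromSizes named integer vector of chromosome sizes (bp).
#' @param nPcg,nAnnotLnc,nNovelLnc gene counts per biotype.
#' @param decoys list with counts of planted novel-lncRNA decoys:
#'   \code{singleExon} (fail the exon-count filter), \code{short}
#'   (mature length below 200 bp) and \code{highCoding}
#'   (coding-potential score above 4).
#' @param enhancerPlan optional data.frame with columns \code{chrom},
#'   \code{start} (0-based), \code{width}, \code{fold},
#'   \code{seClusterId} (NA for isolated sites) and logical activity
#'   columns \code{ESC}, \code{EoNeg}, \code{EoPos}.
#' @param nIsolated,nClusters,clusterSize,enhancerFold,enhancerWidth
#'   parameters of the auto-generated plan (ignored when
#'   \code{enhancerPlan} is supplied).
#' @param backgroundRate background read-sampling intensity, reads per
#'   bp (relative weight; absolute depth is set by
#'   \code{readsPerReplicate}).
#' @param readsPerReplicate expected reads per simulated replicate.
#' @param readLength simulated read length in bp (50, matching
#'   single-end ChIP libraries).
#' @param promoterFold H3K4me3 intensity fold at planted promoters.
#' @param plncFraction fraction of (non-decoy) lncRNA genes given an
#'   H3K4me3-marked promoter.
#' @param expression list: \code{baselineFpkm} (named, \code{PCG} and
#'   \code{lnc}), \code{specificPerCondition},
#'   \code{specificMean}, \code{cv} (log-normal replicate noise).
#' @param tissuePlan list: \code{nHeartEnriched}, \code{fold},
#'   \code{nonCardiacMean}, \code{cv}.
#' @param conservationPlan list: \code{background}, \code{noiseSd},
#'   \code{delta} (promoter elevation), \code{nConserved},
#'   \code{tileWidth}.
#' @return a validated \code{\linkS4class{SyntheticConfig}}.
#' @export
syntheticConfig <- function(seed = 1L,
                            chromSizes = c(chr1 = 5000000L,
                                           chr2 = 5000000L),
                            nPcg = 600L, nAnnotLnc = 150L,
                            nNovelLnc = 250L,
                            decoys = list(singleExon = 8L, short = 5L,
                                          highCoding = 8L),
                            enhancerPlan = NULL,
                            nIsolated = 35L, nClusters = 5L,
                            clusterSize = 3L,
                            enhancerFold = 20, enhancerWidth = 600L,
                            backgroundRate = 0.1,
                            readsPerReplicate = 1000000L,
                            readLength = 50L,
                            promoterFold = 15,
                            plncFraction = 0.3,
                            expression = list(),
                            tissuePlan = list(),
                            conservationPlan = list()) {
  chromSizes <- stats::setNames(as.integer(chromSizes), names(chromSizes))
  expression <- utils::modifyList(
    list(baselineFpkm = c(PCG = 10, lnc = 2),
         specificPerCondition = 20L, specificMean = 40, cv = 0.2),
    expression)
  tissuePlan <- utils::modifyList(
    list(nHeartEnriched = 100L, fold = 8, nonCardiacMean = 5, cv = 0.2),
    tissuePlan)
  conservationPlan <- utils::modifyList(
    list(background = 0.1, noiseSd = 0.05, delta = 0.3,
         nConserved = 200L, tileWidth = 100L),
    conservationPlan)
  decoys <- utils::modifyList(
    list(singleExon = 0L, short = 0L, highCoding = 0L), decoys)

  if (is.null(enhancerPlan))
    enhancerPlan <- .autoEnhancerPlan(seed, chromSizes, nIsolated,
                                      nClusters, clusterSize,
                                      enhancerFold, enhancerWidth)
  new("SyntheticConfig",
      seed = as.integer(seed), chromSizes = chromSizes,
      nPcg = as.integer(nPcg), nAnnotLnc = as.integer(nAnnotLnc),
      nNovelLnc = as.integer(nNovelLnc), decoys = decoys,
      enhancerPlan = enhancerPlan,
      backgroundRate = backgroundRate,
      readsPerReplicate = as.integer(readsPerReplicate),
      readLength = as.integer(readLength),
      promoterFold = promoterFold, plncFraction = plncFraction,
      expression = expression, tissuePlan = tissuePlan,
      conservationPlan = conservationPlan)
}

## Deterministic enhancer plan: isolated sites scattered genome-wide,
## clusters laid out as `clusterSize` constituents with 2-4 kb gaps so
## every cluster fits within the 12.5-kb stitching distance.
.autoEnhancerPlan <- function(seed, chromSizes, nIsolated, nClusters,
                              clusterSize, fold, width) {
  .withSeed(.substream(seed, "enhancerPlan"), {
    rows <- list()
    margin <- 50000L
    clusterSpan <- clusterSize * width + (clusterSize - 1L) * 4000L
    ## lay candidate anchor positions on a jittered grid to keep sites
    ## well separated
    total <- nIsolated + nClusters
    chrom <- sample(names(chromSizes), total, replace = TRUE)
    anchors <- integer(total)
    for (chr in unique(chrom)) {
      i <- which(chrom == chr)
      lo <- margin
      hi <- chromSizes[[chr]] - margin - clusterSpan
      slots <- seq(lo, hi, length.out = length(i) + 2L)[-c(1L, length(i) + 2L)]
      anchors[i] <- as.integer(slots + stats::runif(length(i), -15000, 15000))
    }
    id <- 0L
    for (k in seq_len(total)) {
      isCluster <- k > nIsolated
      nSites <- if (isCluster) clusterSize else 1L
      gaps <- if (nSites > 1L)
        as.integer(stats::runif(nSites - 1L, 2000, 4000)) else integer(0)
      pos <- anchors[k] + cumsum(c(0L, gaps + width))
      act <- if (isCluster) c(TRUE, TRUE, TRUE) else {
        a <- stats::runif(3) < 0.6
        if (!any(a)) a[sample(3, 1)] <- TRUE
        a
      }
      for (p in pos) {
        id <- id + 1L
        rows[[id]] <- data.frame(
          chrom = chrom[k], start = p, width = width, fold = fold,
          seClusterId = if (isCluster)
            paste0("cluster", k - nIsolated) else NA_character_,
          ESC = act[1], EoNeg = act[2], EoPos = act[3],
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}
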