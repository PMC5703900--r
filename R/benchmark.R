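#' Planted-enhancer recovery benchmark
#'
#' Runs the full enhancer-calling chain (simulate reads, bin, Poisson
#' calls, replicate intersection, constituent assembly, stitching,
#' SE/TE calling) on a configuration with planted truth and measures
#' how well the planted landscape is recovered:
#' \describe{
#'   \item{ceRecovery}{fraction of planted constituent sites
#'     overlapping a called constituent enhancer.}
#'   \item{cePrecision}{fraction of called constituent-enhancer bp
#'     lying inside a planted site or its extension shadow (the
#'     planted interval widened by the read-extension length, where
#'     extended reads legitimately spill signal).}
#'   \item{clustersRecovered, nClusters}{planted super-enhancer
#'     clusters for which one called super-enhancer covers every
#'     constituent of the cluster.}
#'   \item{isolatedAsTe}{fraction of isolated planted sites (recovered
#'     as CEs) classified typical enhancer.}
#'   \item{backgroundSeCount}{super-enhancers called on a
#'     background-only control simulation (no planted sites); the
#'     correct value is 0.}
#' }
#'
#' @param config a \code{\linkS4class{SyntheticConfig}}; the default
#'   configuration is the package's benchmark condition (2 x 5 Mb
#'   genome, 50 constituents at 20-fold, 5 clusters of 3 within
#'   12.5 kb, 1e6 reads/replicate).
#' @param binSize,extension,pThreshold,minFold,minCeLength,
#'   stitchDistance calling parameters (pipeline defaults).
#' @return named list of the metrics above plus \code{nCes},
#'   \code{nSes}.
#' @export
enhancerRecoveryBenchmark <- function(config = syntheticConfig(),
                                      binSize = 25L, extension = 200L,
                                      pThreshold = 1e-9, minFold = 5,
                                      minCeLength = 200L,
                                      stitchDistance = 12500L) {
  g <- generateGenomeAndTranscripts(config)
  truth <- g$truth

  tracks <- stats::setNames(lapply(CONDITIONS, function(cond)
    lapply(1:2, function(r)
      binReads(simulateChipReads(config, truth, "H3K27Ac", cond, r),
               seqlens = config@chromSizes, binSize = binSize,
               extension = extension))), CONDITIONS)
  inputs <- stats::setNames(lapply(CONDITIONS, function(cond)
    simulatePooledInput(config, truth, cond, binSize, extension)),
    CONDITIONS)

  masks <- stats::setNames(lapply(CONDITIONS, function(cond) {
    m <- lapply(1:2, function(r)
      poissonEnrichedBins(tracks[[cond]][[r]], inputs[[cond]],
                          pThreshold, minFold,
                          provenance = c(mark = "H3K27Ac",
                                         condition = cond,
                                         replicate = as.character(r))))
    intersectReplicates(m[[1]], m[[2]])
  }), CONDITIONS)
  ces <- callConstituentEnhancers(masks, minCeLength)
  res <- callSuperEnhancers(ces, tracks, inputs, stitchDistance)

  enh <- truth@enhancers
  ceRecovery <- mean(IRanges::overlapsAny(enh, ces, ignore.strand = TRUE))
  shadow <- GenomicRanges::reduce(enh + extension, ignore.strand = TRUE)
  inShadow <- sum(width(GenomicRanges::intersect(
    ces, shadow, ignore.strand = TRUE)))
  cePrecision <- if (length(ces)) inShadow / sum(width(ces)) else NA_real_

  clusterIds <- unique(stats::na.omit(mcols(enh)$seClusterId))
  clustersRecovered <- sum(vapply(clusterIds, function(cid) {
    sites <- enh[!is.na(mcols(enh)$seClusterId) &
                   mcols(enh)$seClusterId == cid]
    any(vapply(seq_along(res$se), function(i)
      all(IRanges::overlapsAny(sites, res$se[i], ignore.strand = TRUE)),
      logical(1)))
  }, logical(1)))

  isolated <- enh[is.na(mcols(enh)$seClusterId)]
  isolatedCes <- isolated[IRanges::overlapsAny(isolated, ces,
                                               ignore.strand = TRUE)]
  isolatedAsTe <- if (length(isolatedCes))
    mean(IRanges::overlapsAny(isolatedCes, res$te, ignore.strand = TRUE) &
           !IRanges::overlapsAny(isolatedCes, res$se,
                                 ignore.strand = TRUE)) else NA_real_

  ## background-only control: same machinery, no planted sites
  emptyPlan <- config@enhancerPlan[integer(0), , drop = FALSE]
  cfg0 <- config
  cfg0@enhancerPlan <- emptyPlan
  truth0 <- truth
  truth0@enhancers <- truth@enhancers[integer(0)]
  t0 <- list(ESC = lapply(1:2, function(r)
    binReads(simulateChipReads(cfg0, truth0, "H3K27Ac", "ESC", r),
             seqlens = cfg0@chromSizes, binSize = binSize,
             extension = extension)))
  i0 <- list(ESC = simulatePooledInput(cfg0, truth0, "ESC", binSize,
                                       extension))
  m0 <- lapply(1:2, function(r)
    poissonEnrichedBins(t0$ESC[[r]], i0$ESC,
                        pThreshold, minFold,
                        provenance = c(mark = "H3K27Ac",
                                       condition = "ESC",
                                       replicate = as.character(r))))
  ce0 <- callConstituentEnhancers(
    list(ESC = intersectReplicates(m0[[1]], m0[[2]])), minCeLength)
  se0 <- callSuperEnhancers(ce0, t0, i0, stitchDistance)$se

  list(ceRecovery = ceRecovery, cePrecision = cePrecision,
       clustersRecovered = clustersRecovered,
       nClusters = length(clusterIds),
       isolatedAsTe = isolatedAsTe,
       backgroundSeCount = length(se0),
       nCes = length(ces), nSes = length(res$se))
}
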