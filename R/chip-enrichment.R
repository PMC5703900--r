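#' Call statistically enriched bins under a Poisson background model
#'
#' A bin is called enriched when two conditions hold jointly:
#' \enumerate{
#'   \item its count \eqn{c} is improbably large under a Poisson
#'     background, i.e. the exact upper tail
#'     \eqn{P(X \ge c)} at rate \eqn{\lambda} (the genome-wide mean
#'     count per bin of the sample track, or the per-chromosome mean
#'     with \code{perChromosomeLambda = TRUE}) is below
#'     \code{pThreshold}; and
#'   \item the count is at least \code{minFold} times the
#'     library-size-rescaled input count for the same bin. Zero-input
#'     bins are floored at the rescaled genome-wide input mean so the
#'     fold ratio is always defined.
#' }
#' The tail probability is the exact Poisson survival function; no
#' normal approximation is used.
#'
#' @param sample,input \code{\linkS4class{BinnedTrack}}s with identical
#'   bin size and chromosome set. The input track should be the pooled
#'   whole-cell-extract control for the condition.
#' @param pThreshold upper-tail probability cutoff (default
#'   \code{1e-9}).
#' @param minFold minimum sample/input fold (default 5).
#' @param perChromosomeLambda use per-chromosome background rates
#'   instead of one genome-wide rate.
#' @param provenance optional named character vector
#'   (\code{mark}, \code{condition}, \code{replicate}) recorded in the
#'   returned mask.
#' @return an \code{\linkS4class{EnrichedBinMask}}.
#'
#' @seealso \code{\link{intersectReplicates}},
#'   \code{\link{callConstituentEnhancers}}
#' @export
poissonEnrichedBins <- function(sample, input, pThreshold = 1e-9,
                                minFold = 5,
                                perChromosomeLambda = FALSE,
                                provenance = c(mark = "NA", condition = "NA",
                                               replicate = "NA")) {
  stopifnot(is(sample, "BinnedTrack"), is(input, "BinnedTrack"))
  if (sample@binSize != input@binSize ||
      !identical(sample@seqlengths, input@seqlengths))
    stop("sample and input tracks must share bin size and chromosome set")
  if (input@totalMapped == 0)
    stop("input track has no mapped reads; the fold-over-input test is undefined")

  ratio <- sample@totalMapped / input@totalMapped
  eps <- lambdaBg(input) * ratio      # floor against zero-input bins
  lam <- if (perChromosomeLambda) lambdaBg(sample, perChromosome = TRUE)
         else rep(lambdaBg(sample), length(sample@counts)) |>
           stats::setNames(names(sample@counts))

  mask <- stats::setNames(vector("list", length(sample@counts)),
                          names(sample@counts))
  for (chr in names(sample@counts)) {
    cnt <- sample@counts[[chr]]
    scaledInput <- input@counts[[chr]] * ratio
    ## exact survival function P(X >= c) = ppois(c - 1, lower.tail = FALSE)
    sig <- stats::ppois(cnt - 1, lam[[chr]], lower.tail = FALSE) < pThreshold
    fold <- cnt / pmax(scaledInput, eps) >= minFold
    mask[[chr]] <- sig & fold & cnt > 0
  }
  new("EnrichedBinMask", mask = mask, binSize = sample@binSize,
      seqlengths = sample@seqlengths,
      provenance = provenance[c("mark", "condition", "replicate")])
}

#' Combine replicate enrichment calls by intersection
#'
#' A bin is positive for a condition only when both biological
#' replicates call it positive.
#'
#' @param m1,m2 \code{\linkS4class{EnrichedBinMask}}s from the two
#'   replicates of one mark and condition.
#' @return an \code{\linkS4class{EnrichedBinMask}} with replicate
#'   provenance \code{"intersection"}.
#' @export
intersectReplicates <- function(m1, m2) {
  stopifnot(is(m1, "EnrichedBinMask"), is(m2, "EnrichedBinMask"))
  if (m1@binSize != m2@binSize || !identical(m1@seqlengths, m2@seqlengths))
    stop("replicate masks must have identical shape")
  p1 <- m1@provenance; p2 <- m2@provenance
  if (!identical(p1[["mark"]], p2[["mark"]]) ||
      !identical(p1[["condition"]], p2[["condition"]]))
    stop("replicate masks must come from the same mark and condition")
  mask <- Map(`&`, m1@mask, m2@mask)
  new("EnrichedBinMask", mask = mask, binSize = m1@binSize,
      seqlengths = m1@seqlengths,
      provenance = c(mark = p1[["mark"]], condition = p1[["condition"]],
                     replicate = "intersection"))
}

## Maximal runs of positive bins of one mask, as a GRanges (1-based).
.maskRuns <- function(mask) {
  bs <- mask@binSize
  pieces <- lapply(names(mask@mask), function(chr) {
    r <- rle(mask@mask[[chr]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (!any(keep)) return(GRanges())
    GRanges(chr, IRanges((starts[keep] - 1L) * bs + 1L,
                         pmin(ends[keep] * bs,
                              mask@seqlengths[[chr]])))
  })
  gr <- suppressWarnings(do.call(c, pieces))
  seqlengths(gr) <- mask@seqlengths[seqlevels(gr)]
  gr
}

#' Assemble constituent enhancers from per-condition bin calls
#'
#' Per condition, maximal runs of positive bins become candidate
#' intervals; intervals are merged across conditions (union with
#' overlap merging), and any merged interval shorter than
#' \code{minLength} bp is dropped. A constituent enhancer therefore
#' exists as soon as it is called in one condition.
#'
#' @param conditionMasks named list of replicate-intersected
#'   \code{\linkS4class{EnrichedBinMask}}s, one per condition.
#' @param minLength minimum constituent length in bp (default 200).
#' @return sorted, disjoint \code{GRanges} of constituent enhancers.
#' @export
callConstituentEnhancers <- function(conditionMasks, minLength = 200L) {
  if (length(conditionMasks) == 0L)
    stop("at least one condition mask is required")
  shapes <- lapply(conditionMasks, function(m) m@seqlengths)
  if (!all(vapply(shapes, identical, logical(1), y = shapes[[1]])))
    stop("condition masks must share the same genome")
  runs <- lapply(conditionMasks, .maskRuns)
  ce <- GenomicRanges::reduce(sort(suppressWarnings(
    do.call(c, unname(runs)))))
  ce[width(ce) >= minLength]
}
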