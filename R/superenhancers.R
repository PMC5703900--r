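#' Stitch constituent enhancers into candidate super-enhancer regions
#'
#' Consecutive constituents separated by at most \code{stitchDistance}
#' bp are merged transitively (the ROSE convention); each stitched
#' region spans from the first to the last constituent and records
#' which constituents it absorbed. No promoter exclusion is applied.
#'
#' @param ces sorted, disjoint \code{GRanges} of constituent enhancers
#'   (the output of \code{\link{callConstituentEnhancers}}).
#' @param stitchDistance maximum gap in bp to bridge (default 12500).
#' @return \code{GRanges} of stitched regions with metadata columns
#'   \code{constituentIds} (an \code{IntegerList} of indices into
#'   \code{ces}) and \code{nConstituents}.
#' @export
stitchEnhancers <- function(ces, stitchDistance = 12500L) {
  stopifnot(is(ces, "GRanges"))
  if (length(ces) > 1L &&
      (is.unsorted(order(as.factor(seqnames(ces)), start(ces))) ||
       !GenomicRanges::isDisjoint(ces)))
    stop("constituents must be sorted and disjoint; ",
         "merge them first (see callConstituentEnhancers)")
  st <- GenomicRanges::reduce(ces, min.gapwidth = stitchDistance + 1L,
                              with.revmap = TRUE)
  mcols(st)$constituentIds <- mcols(st)$revmap
  mcols(st)$revmap <- NULL
  mcols(st)$nConstituents <- lengths(mcols(st)$constituentIds)
  st
}

#' Input-corrected per-million ChIP signal of genomic regions
#'
#' For each region, the sample read count (per million mapped reads)
#' minus the pooled-input count (per million mapped reads), floored at
#' zero. With \code{lengthNormalized = TRUE} the difference is further
#' divided by the region length in kb — the variant used when comparing
#' regions of very different sizes.
#'
#' @param sample,input \code{\linkS4class{BinnedTrack}}s sharing bin
#'   size and genome.
#' @param regions \code{GRanges}; counts include every bin a region
#'   overlaps.
#' @param lengthNormalized divide by region length in kb.
#' @return numeric vector of signals, one per region.
#' @export
scoreRegion <- function(sample, input, regions, lengthNormalized = FALSE) {
  stopifnot(is(sample, "BinnedTrack"), is(input, "BinnedTrack"))
  if (length(regions) == 0L) stop("empty region set")
  if (sample@binSize != input@binSize ||
      !identical(sample@seqlengths, input@seqlengths))
    stop("sample and input tracks must share bin size and chromosome set")
  rpmS <- if (sample@totalMapped > 0)
    .regionBinSums(sample, regions) / sample@totalMapped * 1e6 else
      numeric(length(regions))
  rpmI <- if (input@totalMapped > 0)
    .regionBinSums(input, regions) / input@totalMapped * 1e6 else
      numeric(length(regions))
  sig <- pmax(0, rpmS - rpmI)
  if (lengthNormalized) sig <- sig / (width(regions) / 1000)
  sig
}

#' Slope-1 cutoff on the ranked signal curve
#'
#' Regions are sorted by ascending signal; ranks are rescaled to
#' \eqn{[0,1]} by \eqn{N-1} and signals to \eqn{[0,1]} by the maximum.
#' The threshold is the (unscaled) signal at the point where a line of
#' slope 1 is tangent to the ranked curve from below — the sorted
#' index minimizing (scaled signal − scaled rank), after which the
#' curve rises faster than the diagonal. This separates the long flat
#' tail of typical enhancers from the steep super-enhancer shoulder.
#' Regions with signal strictly above the threshold are
#' super-enhancers.
#'
#' @param signals numeric vector of non-negative region signals
#'   (length at least 2).
#' @return the threshold signal. Degenerate inputs (all signals equal,
#'   or a zero maximum) return the maximum signal, so that no region
#'   lies strictly above it.
#' @export
seCutoff <- function(signals) {
  if (length(signals) < 2L)
    stop("at least 2 signals are required to place a cutoff")
  if (any(signals < 0)) stop("signals must be non-negative")
  s <- sort(signals)
  n <- length(s)
  mx <- s[n]
  if (mx == 0 || s[1] == mx) return(mx)
  y <- s / mx
  x <- (seq_len(n) - 1) / (n - 1)
  ## tangency of the slope-1 line: past this point the curve rises
  ## faster than the diagonal; ties resolved upward (fewer SEs)
  d <- y - x
  s[max(which(d == min(d)))]
}

#' Rank-plot table for a set of region signals
#'
#' The table behind a ROSE-style hockey-stick plot: ascending rank,
#' signal, both rescaled to \eqn{[0,1]}, and the SE/TE class implied by
#' \code{\link{seCutoff}}.
#'
#' @param signals numeric vector of region signals.
#' @param cutoff optional precomputed threshold; computed when missing.
#' @return \code{data.frame} with columns \code{rank}, \code{signal},
#'   \code{scaledRank}, \code{scaledSignal}, \code{klass}.
#' @export
rankTable <- function(signals, cutoff = NULL) {
  if (is.null(cutoff)) cutoff <- seCutoff(signals)
  ord <- order(signals)
  s <- signals[ord]
  n <- length(s)
  data.frame(
    rank = seq_len(n),
    signal = s,
    scaledRank = if (n > 1) (seq_len(n) - 1) / (n - 1) else 0,
    scaledSignal = if (max(s) > 0) s / max(s) else s,
    klass = ifelse(s > cutoff, "SE", "TE")
  )
}

#' Call super-enhancers and typical enhancers across conditions
#'
#' The full SE/TE decision procedure: constituents are stitched
#' (\code{\link{stitchEnhancers}}); for every condition each replicate
#' ranks the stitched regions by input-corrected signal and flags those
#' above its own slope-1 cutoff; a region is a super-enhancer in a
#' condition only when both replicates flag it; the global
#' super-enhancer list is the merged union of the per-condition lists;
#' and typical enhancers are the constituents that do not overlap any
#' global super-enhancer.
#'
#' @param ces sorted, disjoint constituent-enhancer \code{GRanges}.
#' @param k27Tracks named list (one element per condition) of lists of
#'   two replicate \code{\linkS4class{BinnedTrack}}s of the enhancer
#'   mark.
#' @param inputTracks named list of pooled input
#'   \code{\linkS4class{BinnedTrack}}s, one per condition.
#' @param stitchDistance stitching gap in bp (default 12500).
#' @param subtractInput rank on input-corrected signal (default; set
#'   \code{FALSE} to rank on raw per-million counts).
#' @return list with elements \code{stitched} (annotated stitched
#'   regions with mean signal, rank and class), \code{se} (global SE
#'   \code{GRanges}), \code{te} (typical-enhancer \code{GRanges}),
#'   \code{perCondition} (named list of per-condition SE
#'   \code{GRanges}), and \code{rankTables} (per condition/replicate).
#' @export
callSuperEnhancers <- function(ces, k27Tracks, inputTracks,
                               stitchDistance = 12500L,
                               subtractInput = TRUE) {
  conds <- names(k27Tracks)
  if (is.null(conds) || !all(conds %in% names(inputTracks)))
    stop("k27Tracks and inputTracks must be named lists keyed by condition")
  nrep <- vapply(k27Tracks, length, integer(1))
  if (any(nrep < 2L))
    stop("missing replicate: every condition needs 2 replicate tracks (got ",
         paste(conds[nrep < 2L], collapse = ", "), ")")

  emptyOut <- function() {
    g <- GRanges()
    list(stitched = g, se = g, te = ces,
         perCondition = stats::setNames(rep(list(g), length(conds)), conds),
         rankTables = list())
  }
  if (length(ces) == 0L) return(emptyOut())

  stitched <- stitchEnhancers(ces, stitchDistance)
  perCondition <- stats::setNames(vector("list", length(conds)), conds)
  rankTables <- list()
  sigSum <- numeric(length(stitched))
  nSig <- 0L
  for (cond in conds) {
    flags <- matrix(FALSE, nrow = length(stitched), ncol = 2L)
    for (r in 1:2) {
      trk <- k27Tracks[[cond]][[r]]
      sig <- if (subtractInput)
        scoreRegion(trk, inputTracks[[cond]], stitched)
      else if (trk@totalMapped > 0)
        .regionBinSums(trk, stitched) / trk@totalMapped * 1e6
      else numeric(length(stitched))
      cut <- if (length(sig) >= 2L) seCutoff(sig) else max(sig)
      flags[, r] <- sig > cut
      rankTables[[paste(cond, r, sep = "_rep")]] <- rankTable(sig, cut)
      sigSum <- sigSum + sig
      nSig <- nSig + 1L
    }
    perCondition[[cond]] <- granges(stitched[flags[, 1] & flags[, 2]])
  }

  seGlobal <- GenomicRanges::reduce(sort(suppressWarnings(
    do.call(c, unname(perCondition)))))
  te <- ces[!IRanges::overlapsAny(ces, seGlobal)]

  meanSig <- sigSum / max(nSig, 1L)
  mcols(stitched)$signal <- meanSig
  mcols(stitched)$rank <- rank(meanSig, ties.method = "first")
  mcols(stitched)$klass <- ifelse(
    IRanges::overlapsAny(stitched, seGlobal), "SE", "TE")
  list(stitched = stitched, se = seGlobal, te = te,
       perCondition = perCondition, rankTables = rankTables)
}

#' Cross-condition enhancer activity matrix
#'
#' For each enhancer of the global list, whether it overlaps (by any
#' length) an enhancer of each condition's list — the boolean matrix
#' behind active/inactive enhancer heatmaps.
#'
#' @param globalList \code{GRanges} of the global (union) enhancer
#'   list.
#' @param perConditionLists named list of per-condition enhancer
#'   \code{GRanges}.
#' @return logical matrix, one row per global enhancer, one column per
#'   condition.
#' @export
activityMatrix <- function(globalList, perConditionLists) {
  m <- vapply(perConditionLists, function(g)
    IRanges::overlapsAny(globalList, g), logical(length(globalList)))
  if (length(globalList) == 1L) m <- matrix(m, nrow = 1L,
    dimnames = list(NULL, names(perConditionLists)))
  rownames(m) <- if (!is.null(names(globalList))) names(globalList) else
    paste0(seqnames(globalList), ":", start(globalList), "-", end(globalList))
  m
}
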