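#' @rdname BinnedTrack-class
#' @param object a \code{BinnedTrack} or \code{EnrichedBinMask}.
#' @export
setGeneric("binSize", function(object) standardGeneric("binSize"))

#' Genome-wide Poisson background rate of a binned track
#'
#' The mean allocated count per bin over all bins of the genome: the
#' \eqn{\lambda} of the Poisson enrichment test. With
#' \code{perChromosome = TRUE} a named vector of per-chromosome means is
#' returned instead (an alternative background model for genomes with
#' strong chromosome-level coverage differences).
#'
#' @param object a \code{BinnedTrack}.
#' @param perChromosome compute one rate per chromosome instead of a
#'   single genome-wide rate.
#' @return numeric scalar (or named vector).
#' @export
setGeneric("lambdaBg", function(object, perChromosome = FALSE)
  standardGeneric("lambdaBg"))

#' @rdname BinnedTrack-class
#' @export
setGeneric("totalMapped", function(object) standardGeneric("totalMapped"))

#' @rdname BinnedTrack-class
#' @export
setGeneric("binCounts", function(object) standardGeneric("binCounts"))

#' @rdname EnrichedBinMask-class
#' @param object an \code{EnrichedBinMask}.
#' @export
setGeneric("maskValues", function(object) standardGeneric("maskValues"))

#' @rdname EnrichedBinMask-class
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname TranscriptSet-class
#' @param object a \code{TranscriptSet}.
#' @export
setGeneric("txInfo", function(object) standardGeneric("txInfo"))

#' @rdname TranscriptSet-class
#' @export
setGeneric("exonsByTranscript", function(object)
  standardGeneric("exonsByTranscript"))

setMethod("binSize", "BinnedTrack", function(object) object@binSize)
setMethod("binSize", "EnrichedBinMask", function(object) object@binSize)
setMethod("totalMapped", "BinnedTrack", function(object) object@totalMapped)
setMethod("binCounts", "BinnedTrack", function(object) object@counts)
setMethod("maskValues", "EnrichedBinMask", function(object) object@mask)
setMethod("provenance", "EnrichedBinMask", function(object) object@provenance)
setMethod("txInfo", "TranscriptSet", function(object) object@info)
setMethod("exonsByTranscript", "TranscriptSet", function(object) object@exons)

setMethod("lambdaBg", "BinnedTrack", function(object, perChromosome = FALSE) {
  if (perChromosome) {
    vapply(object@counts, mean, numeric(1))
  } else {
    tot <- sum(vapply(object@counts, sum, numeric(1)))
    nb <- sum(vapply(object@counts, length, numeric(1)))
    tot / nb
  }
})

setMethod(GenomeInfoDb::seqlengths, "BinnedTrack", function(x) x@seqlengths)
setMethod(GenomeInfoDb::seqlengths, "EnrichedBinMask",
          function(x) x@seqlengths)
setMethod(GenomeInfoDb::seqlengths, "ConservationTrack",
          function(x) x@seqlengths)
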