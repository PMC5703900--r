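#' @import methods
#' @import BiocGenerics
#' @importFrom S4Vectors DataFrame Rle runValue runLength mcols mcols<-
#'   metadata metadata<-
#' @importFrom IRanges IRanges Views viewSums viewMaxs overlapsAny
#' @import GenomicRanges
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqnames seqlevels
#'   seqlevels<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' Fixed-width binned read counts for one ChIP-seq track
#'
#' A \code{BinnedTrack} holds, per chromosome, the number of (extended)
#' reads allocated to consecutive fixed-width bins, together with the
#' library size. The genome-wide mean count per bin is the background
#' rate of the Poisson enrichment model (see
#' \code{\link{poissonEnrichedBins}}).
#'
#' @slot counts named list of numeric vectors, one per chromosome; element
#'   \code{b} (1-based) counts reads whose extended span overlaps bin
#'   \code{b - 1} (0-based bin index, i.e. bases
#'   \code{[(b-1)*binSize, b*binSize)} in 0-based coordinates).
#' @slot binSize bin width in bp (default 25).
#' @slot seqlengths named integer vector of chromosome sizes in bp.
#' @slot totalMapped number of reads that were allocated (the library
#'   size used for per-million scaling).
#' @slot nRejected number of reads discarded for falling outside the
#'   genome.
#'
#' @seealso \code{\link{binReads}}, \code{\link{lambdaBg}}
#' @export
setClass("BinnedTrack",
  slots = c(
    counts      = "list",
    binSize     = "integer",
    seqlengths  = "integer",
    totalMapped = "numeric",
    nRejected   = "integer"
  )
)

setValidity("BinnedTrack", function(object) {
  msg <- NULL
  if (is.null(names(object@seqlengths)) || anyNA(object@seqlengths))
    msg <- c(msg, "'seqlengths' must be a named integer vector without NAs")
  if (!identical(names(object@counts), names(object@seqlengths)))
    msg <- c(msg, "'counts' and 'seqlengths' must have identical names")
  expected <- ceiling(object@seqlengths / object@binSize)
  got <- vapply(object@counts, length, integer(1))
  if (length(got) && any(got != expected))
    msg <- c(msg, "count vector lengths must equal ceiling(seqlength/binSize)")
  if (any(vapply(object@counts, function(x) any(x < 0), logical(1))))
    msg <- c(msg, "bin counts must be non-negative")
  if (object@binSize < 1L)
    msg <- c(msg, "'binSize' must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' Per-bin enrichment calls aligned to a BinnedTrack
#'
#' Boolean vectors, one per chromosome, marking bins called enriched.
#' \code{provenance} records which mark/condition/replicate the mask
#' came from ("intersection" once replicates have been combined).
#'
#' @slot mask named list of logical vectors (same shape as the track).
#' @slot binSize,seqlengths as in \code{\linkS4class{BinnedTrack}}.
#' @slot provenance named character vector with elements \code{mark},
#'   \code{condition} and \code{replicate}.
#' @export
setClass("EnrichedBinMask",
  slots = c(
    mask       = "list",
    binSize    = "integer",
    seqlengths = "integer",
    provenance = "character"
  )
)

setValidity("EnrichedBinMask", function(object) {
  msg <- NULL
  if (!identical(names(object@mask), names(object@seqlengths)))
    msg <- c(msg, "'mask' and 'seqlengths' must have identical names")
  expected <- ceiling(object@seqlengths / object@binSize)
  got <- vapply(object@mask, length, integer(1))
  if (length(got) && any(got != expected))
    msg <- c(msg, "mask vector lengths must equal ceiling(seqlength/binSize)")
  if (!all(c("mark", "condition", "replicate") %in% names(object@provenance)))
    msg <- c(msg, "'provenance' needs mark, condition and replicate entries")
  if (is.null(msg)) TRUE else msg
})

#' A set of transcript models with exon structure and metadata
#'
#' Exons are kept as a \code{GRangesList} named by transcript id;
#' per-transcript metadata (gene id, biotype, external coding-potential
#' score) lives in a parallel \code{DataFrame}. Biotypes are
#' \code{"PCG"} (protein-coding), \code{"annotated_lnc"} and
#' \code{"novel_lnc"}.
#'
#' @slot exons \code{GRangesList} of exons per transcript; exons of one
#'   transcript share chromosome and strand and are disjoint.
#' @slot info \code{DataFrame} with columns \code{transcriptId},
#'   \code{geneId}, \code{biotype}, \code{codingScore}; one row per
#'   element of \code{exons}, in the same order.
#' @seealso \code{\link{transcriptSet}}, \code{\link{tssSites}},
#'   \code{\link{filterTranscripts}}
#' @export
setClass("TranscriptSet",
  slots = c(exons = "GRangesList", info = "DataFrame")
)

setValidity("TranscriptSet", function(object) {
  msg <- NULL
  need <- c("transcriptId", "geneId", "biotype", "codingScore")
  if (!all(need %in% colnames(object@info)))
    msg <- c(msg, paste("'info' must have columns:", paste(need, collapse = ", ")))
  else {
    if (length(object@exons) != nrow(object@info))
      msg <- c(msg, "'exons' and 'info' must be parallel")
    else if (length(object@exons) &&
             !identical(names(object@exons),
                        as.character(object@info$transcriptId)))
      msg <- c(msg, "names(exons) must equal info$transcriptId")
    bad <- setdiff(unique(object@info$biotype),
                   c("PCG", "annotated_lnc", "novel_lnc"))
    if (length(bad))
      msg <- c(msg, paste("unknown biotype:", paste(bad, collapse = ", ")))
  }
  if (is.null(msg)) TRUE else msg
})

#' Per-base conservation scores stored as run-length runs
#'
#' Scores are held per chromosome as numeric \code{Rle}s, with a parallel
#' logical \code{Rle} flagging which bases the input track actually
#' covered. In \code{"phastcons"} mode uncovered bases contribute 0 to
#' fragment sums; in \code{"phylop"} mode (signed scores) uncovered
#' bases are excluded from window maxima so missing data cannot drag a
#' maximum toward 0.
#'
#' @slot scores named list of numeric \code{Rle}s, one per chromosome,
#'   each of length equal to the chromosome size.
#' @slot covered named list of logical \code{Rle}s, parallel to
#'   \code{scores}.
#' @slot seqlengths named integer chromosome sizes.
#' @slot mode \code{"phastcons"} or \code{"phylop"}.
#' @seealso \code{\link{conservationTrack}}, \code{\link{fragmentScore}}
#' @export
setClass("ConservationTrack",
  slots = c(
    scores     = "list",
    covered    = "list",
    seqlengths = "integer",
    mode       = "character"
  )
)

setValidity("ConservationTrack", function(object) {
  msg <- NULL
  if (!object@mode %in% c("phastcons", "phylop"))
    msg <- c(msg, "'mode' must be \"phastcons\" or \"phylop\"")
  if (!identical(names(object@scores), names(object@seqlengths)) ||
      !identical(names(object@covered), names(object@seqlengths)))
    msg <- c(msg, "'scores'/'covered' names must match 'seqlengths'")
  ls <- vapply(object@scores, length, numeric(1))
  lc <- vapply(object@covered, length, numeric(1))
  if (length(ls) && (any(ls != object@seqlengths) || any(lc != object@seqlengths)))
    msg <- c(msg, "Rle lengths must equal chromosome sizes")
  if (is.null(msg)) TRUE else msg
})

#' Configuration of the synthetic-data generator
#'
#' Bundles every knob of the seeded generator: the toy genome, the
#' transcript complement, planted enhancer sites with per-condition
#' activity, ChIP read-sampling parameters, expression/tissue-panel
#' parameters and the conservation-track plan. Identical configurations
#' produce bit-identical outputs; sub-streams of the master seed are
#' keyed by (mark, condition, replicate) so that adding one track never
#' perturbs another.
#'
#' @seealso \code{\link{syntheticConfig}} for the user constructor and
#'   the documented defaults.
#' @export
setClass("SyntheticConfig",
  slots = c(
    seed              = "integer",
    chromSizes        = "integer",
    nPcg              = "integer",
    nAnnotLnc         = "integer",
    nNovelLnc         = "integer",
    decoys            = "list",
    enhancerPlan      = "data.frame",
    backgroundRate    = "numeric",
    readsPerReplicate = "integer",
    readLength        = "integer",
    promoterFold      = "numeric",
    plncFraction      = "numeric",
    expression        = "list",
    tissuePlan        = "list",
    conservationPlan  = "list"
  )
)

setValidity("SyntheticConfig", function(object) {
  msg <- NULL
  if (length(object@chromSizes) == 0L || is.null(names(object@chromSizes)))
    msg <- c(msg, "'chromSizes' must be a non-empty named vector")
  if (any(object@chromSizes <= 0L))
    msg <- c(msg, "chromosome sizes must be positive")
  if (any(c(object@nPcg, object@nAnnotLnc, object@nNovelLnc) < 0L))
    msg <- c(msg, "transcript counts must be >= 0")
  ep <- object@enhancerPlan
  if (nrow(ep)) {
    need <- c("chrom", "start", "width", "fold", "seClusterId",
              "ESC", "EoNeg", "EoPos")
    if (!all(need %in% colnames(ep)))
      msg <- c(msg, paste("enhancerPlan needs columns:",
                          paste(need, collapse = ", ")))
    else {
      if (any(!ep$chrom %in% names(object@chromSizes)))
        msg <- c(msg, "enhancerPlan refers to unknown chromosomes")
      else {
        bad <- which(ep$start < 0 |
                     ep$start + ep$width > object@chromSizes[ep$chrom])
        if (length(bad))
          msg <- c(msg, paste0("planted site outside chromosome: ",
                               ep$chrom[bad[1]], ":", ep$start[bad[1]], "-",
                               ep$start[bad[1]] + ep$width[bad[1]]))
      }
      if (any(ep$fold <= 1))
        msg <- c(msg, "planted folds must be > 1")
    }
  }
  if (object@backgroundRate <= 0)
    msg <- c(msg, "'backgroundRate' must be > 0")
  if (object@readsPerReplicate < 0L)
    msg <- c(msg, "'readsPerReplicate' must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Record of what the synthetic generator planted
#'
#' The ground truth against which recovery of enhancers,
#' condition-specific transcripts, heart-enriched genes and conserved
#' promoters is judged. Serializes losslessly to JSON via
#' \code{\link{writeTruthJson}}.
#'
#' @slot enhancers planted constituent sites as a \code{GRanges} with
#'   columns \code{siteId}, \code{fold}, \code{seClusterId} (NA for
#'   isolated sites) and logical activity columns \code{ESC},
#'   \code{EoNeg}, \code{EoPos}.
#' @slot promoters H3K4me3-marked promoter intervals (\code{GRanges}
#'   with a \code{geneId} column).
#' @slot specificGenes list mapping condition to the gene ids planted as
#'   specific to it.
#' @slot heartEnriched gene ids planted heart-enriched in the tissue
#'   panel.
#' @slot conservedPromoters gene ids whose promoters carry elevated
#'   conservation.
#' @slot decoyGenes \code{DataFrame} (\code{geneId}, \code{failingRule})
#'   of novel-lncRNA decoys planted to fail a named transcript filter.
#' @export
setClass("PlantedTruth",
  slots = c(
    enhancers          = "GRanges",
    promoters          = "GRanges",
    specificGenes      = "list",
    heartEnriched      = "character",
    conservedPromoters = "character",
    decoyGenes         = "DataFrame"
  )
)

setMethod("show", "BinnedTrack", function(object) {
  cat("BinnedTrack:", length(object@counts), "chromosome(s),",
      object@binSize, "bp bins\n")
  cat("  total mapped reads:", format(object@totalMapped, big.mark = ","),
      " (", object@nRejected, "rejected )\n")
  cat("  background rate (lambda):",
      signif(lambdaBg(object), 4), "reads/bin\n")
})

setMethod("show", "EnrichedBinMask", function(object) {
  pos <- sum(vapply(object@mask, sum, numeric(1)))
  cat("EnrichedBinMask:", format(pos, big.mark = ","), "positive bins [",
      paste(names(object@provenance), object@provenance,
            sep = "=", collapse = ", "), "]\n")
})

setMethod("show", "TranscriptSet", function(object) {
  cat("TranscriptSet:", length(object@exons), "transcripts,",
      length(unique(object@info$geneId)), "genes\n")
  if (nrow(object@info))
    print(table(biotype = object@info$biotype))
})

setMethod("show", "ConservationTrack", function(object) {
  cat("ConservationTrack (", object@mode, "): ",
      length(object@scores), " chromosome(s)\n", sep = "")
})

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig: seed", object@seed, "\n")
  cat("  genome:", paste0(names(object@chromSizes), "=",
                          object@chromSizes, collapse = ", "), "\n")
  cat("  transcripts: PCG", object@nPcg, "/ annotated lnc",
      object@nAnnotLnc, "/ novel lnc", object@nNovelLnc, "\n")
  cat("  planted enhancer sites:", nrow(object@enhancerPlan), "\n")
  cat("  reads/replicate:", object@readsPerReplicate, "\n")
})

setMethod("show", "PlantedTruth", function(object) {
  cat("PlantedTruth:", length(object@enhancers), "enhancer sites,",
      length(object@promoters), "promoters\n")
  cat("  specific genes:",
      paste(names(object@specificGenes),
            lengths(object@specificGenes), sep = ":", collapse = " "), "\n")
  cat("  heart-enriched:", length(object@heartEnriched),
      "| conserved promoters:", length(object@conservedPromoters),
      "| decoys:", nrow(object@decoyGenes), "\n")
})
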