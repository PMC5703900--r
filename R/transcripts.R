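#' Construct a TranscriptSet
#'
#' @param exons \code{GRangesList} of exons, named by transcript id.
#' @param info data.frame or \code{DataFrame} with columns
#'   \code{transcriptId}, \code{geneId}, \code{biotype},
#'   \code{codingScore}, parallel to \code{exons}.
#' @return a \code{\linkS4class{TranscriptSet}}.
#' @export
transcriptSet <- function(exons, info) {
  info <- as(info, "DataFrame")
  exons <- as(exons, "GRangesList")
  ord <- order(as.character(info$transcriptId))
  have <- names(exons)
  if (!setequal(have, info$transcriptId))
    stop("exon list and info table name different transcripts")
  info <- info[ord, , drop = FALSE]
  exons <- exons[as.character(info$transcriptId)]
  new("TranscriptSet", exons = exons, info = info)
}

#' Transcription start sites of a TranscriptSet
#'
#' Strand-aware: the first transcribed base — the lowest exon start on
#' the plus strand, the highest exon end on the minus strand (1-based).
#'
#' @param txset a \code{\linkS4class{TranscriptSet}}.
#' @return \code{GRanges} of width-1 TSS positions, one per transcript,
#'   named by transcript id, with \code{geneId} in \code{mcols}.
#' @export
tssSites <- function(txset) {
  ex <- txset@exons
  rng <- unlist(range(ex), use.names = FALSE)
  plus <- as.character(strand(rng)) != "-"
  pos <- ifelse(plus, start(rng), end(rng))
  gr <- GRanges(seqnames(rng), IRanges(pos, pos), strand = strand(rng))
  seqlengths(gr) <- seqlengths(ex)[seqlevels(gr)]
  names(gr) <- names(ex)
  mcols(gr)$geneId <- txset@info$geneId
  gr
}

#' Genomic spans of genes (first to last exon over all transcripts)
#'
#' @param txset a \code{\linkS4class{TranscriptSet}}.
#' @return named \code{GRanges}, one span per gene.
#' @export
geneSpans <- function(txset) {
  rng <- unlist(range(txset@exons), use.names = FALSE)
  byGene <- split(rng, as.character(txset@info$geneId))
  sp <- unlist(range(byGene))
  seqlengths(sp) <- seqlengths(txset@exons)[seqlevels(sp)]
  sp
}

#' Mature (exonic) transcript lengths
#' @param txset a \code{\linkS4class{TranscriptSet}}.
#' @return named integer vector of summed exon widths.
#' @export
transcriptLengths <- function(txset) {
  stats::setNames(sum(width(txset@exons)), names(txset@exons))
}

#' Subset a TranscriptSet by transcript id
#' @param txset a \code{\linkS4class{TranscriptSet}}.
#' @param transcriptIds ids to keep.
#' @return a \code{\linkS4class{TranscriptSet}}.
#' @export
subsetTranscripts <- function(txset, transcriptIds) {
  keep <- txset@info$transcriptId %in% transcriptIds
  new("TranscriptSet", exons = txset@exons[keep],
      info = txset@info[keep, , drop = FALSE])
}
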