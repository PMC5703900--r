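#' Build a ConservationTrack from scored runs
#'
#' @param runs \code{GRanges} with a numeric \code{score} column;
#'   runs must not overlap. Bases not covered by any run are flagged
#'   uncovered (score 0 in phastCons mode, excluded from maxima in
#'   phyloP mode).
#' @param seqlens named integer chromosome sizes.
#' @param mode \code{"phastcons"} (probability-like scores) or
#'   \code{"phylop"} (signed scores).
#' @return a \code{\linkS4class{ConservationTrack}}.
#' @export
conservationTrack <- function(runs, seqlens, mode = c("phastcons", "phylop")) {
  mode <- match.arg(mode)
  if (!GenomicRanges::isDisjoint(runs))
    stop("score runs must be non-overlapping")
  seqlens <- stats::setNames(as.integer(seqlens), names(seqlens))
  gr <- runs
  seqlengths(gr) <- seqlens[seqlevels(gr)]
  scores <- stats::setNames(vector("list", length(seqlens)), names(seqlens))
  covered <- scores
  covAll <- GenomicRanges::coverage(gr, width = as.list(seqlens))
  scoAll <- GenomicRanges::coverage(gr, weight = gr$score,
                                    width = as.list(seqlens))
  for (chr in names(seqlens)) {
    if (chr %in% names(covAll)) {
      covered[[chr]] <- covAll[[chr]] > 0
      scores[[chr]] <- scoAll[[chr]]
    } else {
      covered[[chr]] <- Rle(FALSE, seqlens[[chr]])
      scores[[chr]] <- Rle(0, seqlens[[chr]])
    }
  }
  new("ConservationTrack", scores = scores, covered = covered,
      seqlengths = seqlens, mode = mode)
}

#' Mean per-base conservation score of genomic fragments
#'
#' Per-base scores summed over the fragment and divided by the
#' fragment length. Uncovered bases contribute 0 to the sum but full
#' weight to the denominator; a fragment with no covered base at all
#' scores 0 and triggers a coverage warning.
#'
#' @param track a \code{\linkS4class{ConservationTrack}}.
#' @param intervals \code{GRanges} of fragments (within chromosome
#'   bounds).
#' @return numeric vector of mean scores, one per fragment.
#' @export
fragmentScore <- function(track, intervals) {
  if (length(intervals) == 0L) stop("empty fragment set")
  chrom <- as.character(seqnames(intervals))
  if (any(!chrom %in% names(track@seqlengths)))
    stop("fragments on chromosomes absent from the track")
  if (any(start(intervals) < 1L |
          end(intervals) > track@seqlengths[chrom]))
    stop("fragment beyond chromosome bounds")
  out <- numeric(length(intervals))
  anyUncov <- FALSE
  for (chr in unique(chrom)) {
    i <- which(chrom == chr)
    v <- Views(track@scores[[chr]], start(intervals)[i], end(intervals)[i])
    out[i] <- viewSums(v) / width(intervals)[i]
    cv <- Views(track@covered[[chr]], start(intervals)[i],
                end(intervals)[i])
    if (any(viewSums(cv) == 0)) anyUncov <- TRUE
  }
  if (anyUncov)
    warning("some fragments are entirely uncovered by the track (score 0)")
  out
}

## Strand-aware promoter of width `len` immediately upstream of a TSS
## (1-based closed coordinates), clipped to the chromosome.
.promoterRanges <- function(tss, len = 1000L, seqlens = NULL) {
  plus <- as.character(strand(tss)) != "-"
  p <- start(tss)
  s <- ifelse(plus, p - len, p + 1L)
  e <- ifelse(plus, p - 1L, p + len)
  if (is.null(seqlens)) seqlens <- seqlengths(tss)
  lim <- seqlens[as.character(seqnames(tss))]
  clipped <- s < 1L | e > lim
  s <- pmin(pmax(s, 1L), lim)
  e <- pmax(pmin(e, lim), s)     # fully off-chromosome degrades to 1 bp
  gr <- GRanges(seqnames(tss), IRanges(s, e), strand = strand(tss))
  mcols(gr)$clipped <- clipped
  names(gr) <- names(tss)
  gr
}

#' Conservation scores of gene features
#'
#' Fragment scores (\code{\link{fragmentScore}}) of the exons, introns
#' and promoter of every gene. Exon/intron scores are computed per
#' transcript over the transcript's merged exon set (resp. the gaps
#' between its exons) and averaged over the gene's transcripts;
#' promoters — the \code{promoterLength} bp immediately upstream of
#' each TSS, strand-aware — are merged per gene before scoring so that
#' shared promoters are not double-counted. Promoters truncated at a
#' chromosome edge are scored over the clipped span and flagged.
#'
#' @param track a \code{\linkS4class{ConservationTrack}}.
#' @param txset a \code{\linkS4class{TranscriptSet}}.
#' @param promoterLength promoter length in bp (default 1000).
#' @return \code{DataFrame} with per-gene columns \code{exonScore},
#'   \code{intronScore} (\code{NA} when no transcript has an intron),
#'   \code{promoterScore} and \code{promoterClipped}.
#' @export
featureScores <- function(track, txset, promoterLength = 1000L) {
  ex <- txset@exons
  geneOf <- as.character(txset@info$geneId)

  exFlat <- unlist(ex, use.names = FALSE)
  exScore <- fragmentScore(track, exFlat)
  txOfExon <- rep(seq_along(ex), lengths(ex))
  exSum <- tapply(exScore * width(exFlat), txOfExon, sum)
  exLen <- tapply(width(exFlat), txOfExon, sum)
  txExon <- as.numeric(exSum / exLen)

  introns <- GenomicRanges::psetdiff(unlist(range(ex), use.names = FALSE),
                                     ex)
  hasIntron <- lengths(introns) > 0
  txIntron <- rep(NA_real_, length(ex))
  if (any(hasIntron)) {
    inFlat <- unlist(introns[hasIntron], use.names = FALSE)
    inScore <- fragmentScore(track, inFlat)
    txOfIn <- rep(which(hasIntron), lengths(introns[hasIntron]))
    inSum <- tapply(inScore * width(inFlat), txOfIn, sum)
    inLen <- tapply(width(inFlat), txOfIn, sum)
    txIntron[which(hasIntron)] <- as.numeric(inSum / inLen)
  }

  tss <- tssSites(txset)
  prom <- .promoterRanges(tss, promoterLength, track@seqlengths)
  promByGene <- GenomicRanges::reduce(split(prom, geneOf))
  clippedByGene <- tapply(mcols(prom)$clipped, geneOf, any)

  genes <- sort(unique(geneOf))
  promScore <- vapply(genes, function(g) {
    p <- promByGene[[g]]
    sum(fragmentScore(track, p) * width(p)) / sum(width(p))
  }, numeric(1))

  DataFrame(
    geneId = genes,
    exonScore = as.numeric(tapply(txExon, geneOf, mean)[genes]),
    intronScore = as.numeric(tapply(txIntron, geneOf,
                                    function(x) if (all(is.na(x))) NA_real_
                                    else mean(x, na.rm = TRUE))[genes]),
    promoterScore = unname(promScore),
    promoterClipped = as.logical(clippedByGene[genes])
  )
}

#' Sample random intergenic background regions
#'
#' Random fragments placed uniformly in the complement of the gene
#' spans, with lengths drawn uniformly from
#' \code{sizeMean * (1 - sizeJitter)} to
#' \code{sizeMean * (1 + sizeJitter)} — the background against which
#' genic conservation is judged. Regions never overlap a gene; they
#' may overlap each other. Placement is by rejection sampling with a
#' cap of \code{10 * n} attempts.
#'
#' @param seqlens named integer chromosome sizes.
#' @param genes \code{GRanges} of gene spans to avoid.
#' @param n number of regions.
#' @param sizeMean,sizeJitter fragment size model (defaults 3400 bp
#'   and 0.2, i.e. 3400 +/- 20\%).
#' @param seed integer seed; the same seed reproduces the same
#'   regions.
#' @return \code{GRanges} of \code{n} intergenic regions.
#' @export
sampleIntergenic <- function(seqlens, genes, n, sizeMean = 3400,
                             sizeJitter = 0.2, seed = 1L) {
  seqlens <- stats::setNames(as.integer(seqlens), names(seqlens))
  lo <- as.integer(ceiling(sizeMean * (1 - sizeJitter)))
  hi <- as.integer(floor(sizeMean * (1 + sizeJitter)))
  .withSeed(seed, {
    kept <- GRanges()
    attempts <- 0L
    maxAttempts <- 10L * n
    pChrom <- seqlens / sum(seqlens)
    while (length(kept) < n && attempts < maxAttempts) {
      batch <- min(n - length(kept), maxAttempts - attempts)
      attempts <- attempts + batch
      chr <- sample(names(seqlens), batch, replace = TRUE, prob = pChrom)
      len <- sample(lo:hi, batch, replace = TRUE)
      maxStart <- seqlens[chr] - len + 1L
      ok <- maxStart >= 1L
      if (!any(ok)) next
      st <- floor(stats::runif(sum(ok)) * maxStart[ok]) + 1L
      cand <- GRanges(chr[ok], IRanges(as.integer(st),
                                       width = len[ok]))
      cand <- cand[!IRanges::overlapsAny(cand, genes, ignore.strand = TRUE)]
      if (length(cand))
        kept <- c(kept, cand)
    }
    if (length(kept) < n)
      stop("insufficient intergenic space: only ", length(kept), " of ", n,
           " regions placed in ", maxAttempts, " attempts")
    kept <- kept[seq_len(n)]
    seqlengths(kept) <- seqlens[seqlevels(kept)]
    kept
  })
}

#' Maximum conservation score around transcription start sites
#'
#' Per transcript, the maximum per-base score over a strand-aware
#' window of \code{upstream} bp before and \code{downstream} bp after
#' the TSS (600 bp by default); per gene, the maximum over its
#' transcripts. In phyloP mode uncovered bases are excluded from the
#' maximum (signed scores must not be dragged toward 0 by missing
#' data); a window with no covered base yields \code{NA}. Windows
#' truncated at a chromosome edge are scored over the clipped span.
#'
#' @param track a \code{\linkS4class{ConservationTrack}}.
#' @param txset a \code{\linkS4class{TranscriptSet}}.
#' @param upstream,downstream window extent in bp (defaults 500 and
#'   100).
#' @return \code{DataFrame} with per-gene \code{maxScore} and
#'   \code{windowClipped}.
#' @export
phylopTssMax <- function(track, txset, upstream = 500L, downstream = 100L) {
  tss <- tssSites(txset)
  plus <- as.character(strand(tss)) != "-"
  p <- start(tss)
  s <- ifelse(plus, p - upstream, p - downstream + 1L)
  e <- ifelse(plus, p + downstream - 1L, p + upstream)
  lim <- track@seqlengths[as.character(seqnames(tss))]
  clipped <- s < 1L | e > lim
  s <- pmax(s, 1L); e <- pmin(e, lim)

  masked <- track@scores
  if (track@mode == "phylop")
    for (chr in names(masked))
      masked[[chr]][!track@covered[[chr]]] <- -Inf

  chrom <- as.character(seqnames(tss))
  txMax <- numeric(length(tss))
  for (chr in unique(chrom)) {
    i <- which(chrom == chr)
    txMax[i] <- viewMaxs(Views(masked[[chr]], s[i], e[i]))
  }
  txMax[is.infinite(txMax) & txMax < 0] <- NA_real_

  geneOf <- as.character(mcols(tss)$geneId)
  genes <- sort(unique(geneOf))
  DataFrame(
    geneId = genes,
    maxScore = as.numeric(tapply(txMax, geneOf, function(x)
      if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))[genes]),
    windowClipped = as.logical(tapply(clipped, geneOf, any)[genes])
  )
}
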