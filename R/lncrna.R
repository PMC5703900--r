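#' Filter transcripts by length, exon count, coding potential and
#' expression
#'
#' The reconstruction filters applied before lncRNA analysis:
#' \itemize{
#'   \item novel lncRNAs must have mature (exonic) length of at least
#'     \code{minLen} bp and at least \code{minExons} exons — single-exon
#'     reconstructed fragments are unreliable;
#'   \item every lncRNA (annotated or novel) must have an external
#'     coding-potential score of at most \code{maxCodingScore}
#'     (transcripts scoring strictly above are treated as unrecognized
#'     coding and discarded);
#'   \item every transcript must reach a condition-mean expression
#'     strictly above \code{minFpkm} in at least one condition.
#' }
#' Transcripts missing from the expression matrix are treated as
#' unexpressed. Filters are applied in the order above and the first
#' failed rule is logged per rejected transcript; the rejection set is
#' independent of input order.
#'
#' @param txset a \code{\linkS4class{TranscriptSet}}.
#' @param fpkm numeric matrix of condition-mean FPKM, rows named by
#'   gene id (or transcript id), one column per condition.
#' @param minLen minimum mature length in bp (default 200).
#' @param minExons minimum exon count for novel lncRNAs (default 2).
#' @param maxCodingScore maximum allowed coding-potential score
#'   (default 4; the cut is strict: a score of exactly 4 is retained).
#' @param minFpkm expression floor (default 0.1 FPKM, strict).
#' @return list with \code{retained} (a \code{TranscriptSet}) and
#'   \code{rejected} (\code{DataFrame} of \code{transcriptId},
#'   \code{geneId}, \code{rule}).
#' @export
filterTranscripts <- function(txset, fpkm, minLen = 200L, minExons = 2L,
                              maxCodingScore = 4, minFpkm = 0.1) {
  info <- txset@info
  n <- nrow(info)
  rule <- rep(NA_character_, n)
  isLnc <- info$biotype %in% c("annotated_lnc", "novel_lnc")
  isNovel <- info$biotype == "novel_lnc"

  len <- unname(sum(width(txset@exons)))
  nEx <- unname(lengths(txset@exons))
  fail <- isNovel & len < minLen
  rule[fail & is.na(rule)] <- "length"
  fail <- isNovel & nEx < minExons
  rule[fail & is.na(rule)] <- "exons"
  fail <- isLnc & info$codingScore > maxCodingScore
  rule[fail & is.na(rule)] <- "coding_score"

  key <- ifelse(info$geneId %in% rownames(fpkm),
                info$geneId,
                ifelse(info$transcriptId %in% rownames(fpkm),
                       info$transcriptId, NA_character_))
  maxExpr <- rep(0, n)
  hit <- !is.na(key)
  if (any(hit))
    maxExpr[hit] <- apply(fpkm[key[hit], , drop = FALSE], 1, max)
  rule[maxExpr <= minFpkm & is.na(rule)] <- "expression"

  rejected <- DataFrame(transcriptId = info$transcriptId[!is.na(rule)],
                        geneId = info$geneId[!is.na(rule)],
                        rule = rule[!is.na(rule)])
  keep <- is.na(rule)
  list(retained = new("TranscriptSet", exons = txset@exons[keep],
                      info = info[keep, , drop = FALSE]),
       rejected = rejected)
}

#' Four-way epigenomic classification of lncRNA genes
#'
#' Each lncRNA gene receives exactly one class, evaluated in strict
#' precedence order:
#' \enumerate{
#'   \item \strong{plncRNA} — the window of \code{promoterHalfwidth} bp
#'     on either side of any of the gene's TSSs overlaps an
#'     H3K4me3-positive region (an active promoter signature);
#'   \item \strong{SE_lncRNA} — otherwise, any part of the gene span
#'     (exons and introns) overlaps a super-enhancer;
#'   \item \strong{TE_lncRNA} — otherwise, likewise versus the typical
#'     enhancers;
#'   \item \strong{unmarked} — no chromatin mark on the gene.
#' }
#' With multiple transcripts per gene, a transcript qualifying at a
#' higher-precedence rule sets the gene class.
#'
#' @param txset \code{\linkS4class{TranscriptSet}} of the (already
#'   filtered) lncRNAs to classify; genes of other biotypes present in
#'   the set are classified too and can be dropped downstream.
#' @param h3k4me3Regions \code{GRanges} of H3K4me3-positive regions
#'   (typically \code{\link{callConstituentEnhancers}} output on the
#'   promoter mark, union over conditions).
#' @param seList,teList super-enhancer and typical-enhancer
#'   \code{GRanges}.
#' @param promoterHalfwidth half-width of the TSS window in bp
#'   (default 1000).
#' @return \code{DataFrame} with one row per gene: \code{geneId},
#'   \code{biotype}, \code{klass}.
#' @export
classifyLncRNAs <- function(txset, h3k4me3Regions, seList, teList,
                            promoterHalfwidth = 1000L) {
  if (length(txset@exons) == 0L)
    stop("no transcripts to classify")
  tss <- tssSites(txset)
  win <- GRanges(seqnames(tss),
                 IRanges(pmax(start(tss) - promoterHalfwidth, 1L),
                         end(tss) + promoterHalfwidth))
  promHit <- IRanges::overlapsAny(win, h3k4me3Regions, ignore.strand = TRUE)
  promByGene <- tapply(promHit, as.character(txset@info$geneId), any)

  spans <- geneSpans(txset)
  seHit <- IRanges::overlapsAny(spans, seList, ignore.strand = TRUE)
  teHit <- IRanges::overlapsAny(spans, teList, ignore.strand = TRUE)

  genes <- names(spans)
  klass <- ifelse(promByGene[genes], "plncRNA",
           ifelse(seHit, "SE_lncRNA",
           ifelse(teHit, "TE_lncRNA", "unmarked")))
  biotype <- txInfo(txset)$biotype[match(genes,
                                         as.character(txInfo(txset)$geneId))]
  DataFrame(geneId = genes, biotype = biotype, klass = unname(klass))
}

#' Class composition per biotype
#'
#' Fractions of the four epigenomic classes within each biotype (the
#' numbers behind stacked class-composition barplots).
#'
#' @param classes the \code{DataFrame} returned by
#'   \code{\link{classifyLncRNAs}}.
#' @param biotypes biotypes to tabulate (default: those present).
#' @return numeric matrix, rows = biotypes, columns = the four classes;
#'   rows for biotypes with no genes are all \code{NA}. Each populated
#'   row sums to 1.
#' @export
classComposition <- function(classes,
                             biotypes = unique(as.character(classes$biotype))) {
  lev <- c("plncRNA", "SE_lncRNA", "TE_lncRNA", "unmarked")
  out <- matrix(NA_real_, nrow = length(biotypes), ncol = length(lev),
                dimnames = list(biotypes, lev))
  for (b in biotypes) {
    k <- as.character(classes$klass[classes$biotype == b])
    if (length(k))
      out[b, ] <- as.numeric(table(factor(k, levels = lev))) / length(k)
  }
  out
}
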