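## Readers and writers for the standard formats at the package
## boundary. Internally everything is 1-based GRanges; rtracklayer
## does the 0-based BED conversion.

#' @importFrom rtracklayer import export
NULL

#' Write/read aligned-read intervals as BED6
#'
#' @param reads \code{GRanges} (names become the BED name field).
#' @param path file path.
#' @return \code{writeReadsBed} the path invisibly;
#'   \code{readReadsBed} a \code{GRanges}.
#' @export
writeReadsBed <- function(reads, path) {
  if (is.null(names(reads)) && length(reads))
    names(reads) <- sprintf("read%07d", seq_along(reads))
  rtracklayer::export(reads, path, format = "BED")
  invisible(path)
}

#' @rdname writeReadsBed
#' @param seqlens optional named chromosome sizes to attach.
#' @export
readReadsBed <- function(path, seqlens = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(seqlens)) {
    seqlens <- stats::setNames(as.integer(seqlens), names(seqlens))
    seqlengths(gr) <- seqlens[seqlevels(gr)]
  }
  gr
}

#' Write/read generic genomic intervals as BED
#' @param gr a \code{GRanges}.
#' @param path file path.
#' @export
writeRegionsBed <- function(gr, path) {
  rtracklayer::export(granges(gr), path, format = "BED")
  invisible(path)
}

#' @rdname writeRegionsBed
#' @param seqlens optional named chromosome sizes to attach.
#' @export
readRegionsBed <- function(path, seqlens = NULL) readReadsBed(path, seqlens)

#' Write/read a TranscriptSet as GTF
#'
#' Exon records with attributes \code{gene_id}, \code{transcript_id},
#' \code{biotype} and \code{coding_score}. GTF is 1-based inclusive;
#' the conversion from the package's GRanges representation is
#' handled by \pkg{rtracklayer}.
#'
#' @param txset a \code{\linkS4class{TranscriptSet}}.
#' @param path file path.
#' @export
writeGtfTranscripts <- function(txset, path) {
  ex <- txset@exons
  flat <- unlist(ex, use.names = FALSE)
  i <- rep(seq_along(ex), lengths(ex))
  mcols(flat) <- DataFrame(
    source = factor("enhancerscape"), type = factor("exon"),
    gene_id = as.character(txset@info$geneId)[i],
    transcript_id = as.character(txset@info$transcriptId)[i],
    biotype = as.character(txset@info$biotype)[i],
    coding_score = txset@info$codingScore[i])
  rtracklayer::export(flat, path, format = "gtf")
  ## drop the volatile date header so identical data give identical files
  ln <- readLines(path)
  writeLines(ln[!startsWith(ln, "##date")], path)
  invisible(path)
}

#' @rdname writeGtfTranscripts
#' @param seqlens optional named chromosome sizes to attach.
#' @export
readGtfTranscripts <- function(path, seqlens = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (!is.null(seqlens)) {
    seqlens <- stats::setNames(as.integer(seqlens), names(seqlens))
    seqlengths(gr) <- seqlens[seqlevels(gr)]
  }
  txid <- as.character(gr$transcript_id)
  exons <- split(granges(gr), txid)
  first <- !duplicated(txid)
  info <- DataFrame(
    transcriptId = txid[first],
    geneId = as.character(gr$gene_id)[first],
    biotype = as.character(gr$biotype)[first],
    codingScore = as.numeric(gr$coding_score)[first])
  transcriptSet(exons, info)
}

#' Export a binned track as bedGraph
#'
#' One record per bin; values are scaled per million mapped reads by
#' default (the convention for genome-browser tracks).
#'
#' @param track a \code{\linkS4class{BinnedTrack}}.
#' @param path file path.
#' @param perMillion scale counts by 1e6 / totalMapped.
#' @export
writeTrackBedGraph <- function(track, path, perMillion = TRUE) {
  pieces <- lapply(names(track@counts), function(chr) {
    cnt <- track@counts[[chr]]
    nb <- length(cnt)
    ends <- pmin(seq_len(nb) * track@binSize, track@seqlengths[[chr]])
    GRanges(chr, IRanges((seq_len(nb) - 1L) * track@binSize + 1L, ends),
            score = if (perMillion && track@totalMapped > 0)
              cnt / track@totalMapped * 1e6 else cnt)
  })
  gr <- suppressWarnings(do.call(c, pieces))
  gr <- gr[gr$score != 0]          # bedGraph convention: sparse
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph/wig conservation track
#'
#' @param path bedGraph or wig file of per-base (or run-level) scores.
#' @param seqlens named chromosome sizes.
#' @param mode score semantics, \code{"phastcons"} or \code{"phylop"}.
#' @return a \code{\linkS4class{ConservationTrack}}.
#' @export
readConservationBedGraph <- function(path, seqlens,
                                     mode = c("phastcons", "phylop")) {
  gr <- rtracklayer::import(path)
  conservationTrack(gr, seqlens, mode = match.arg(mode))
}

#' Serialize planted truth to JSON (lossless round trip)
#'
#' @param truth a \code{\linkS4class{PlantedTruth}}.
#' @param path file path.
#' @export
writeTruthJson <- function(truth, path) {
  grDf <- function(g, cols) {
    d <- data.frame(chrom = as.character(seqnames(g)),
                    start = start(g) - 1L, end = end(g),
                    stringsAsFactors = FALSE)
    for (cc in cols) d[[cc]] <- mcols(g)[[cc]]
    d
  }
  obj <- list(
    enhancers = grDf(truth@enhancers,
                     c("siteId", "fold", "seClusterId",
                       "ESC", "EoNeg", "EoPos")),
    promoters = grDf(truth@promoters, "geneId"),
    specificGenes = truth@specificGenes,
    heartEnriched = truth@heartEnriched,
    conservedPromoters = truth@conservedPromoters,
    decoyGenes = as.data.frame(truth@decoyGenes))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE,
                       null = "list", na = "null")
  invisible(path)
}

#' @rdname writeTruthJson
#' @param seqlens named chromosome sizes to attach to the intervals.
#' @export
readTruthJson <- function(path, seqlens) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  seqlens <- stats::setNames(as.integer(seqlens), names(seqlens))
  dfGr <- function(d, cols) {
    if (is.null(d) || !length(d) || !nrow(as.data.frame(d))) {
      g <- GRanges()
      for (cc in names(cols)) mcols(g)[[cc]] <- vector(cols[[cc]], 0)
      return(g)
    }
    d <- as.data.frame(d)
    g <- .grFrom0(d$chrom, d$start, d$end, seqlen = seqlens)
    for (cc in names(cols)) {
      v <- d[[cc]]
      mcols(g)[[cc]] <- if (cols[[cc]] == "character") as.character(v)
        else if (cols[[cc]] == "logical") as.logical(v) else as.numeric(v)
    }
    g
  }
  chr <- function(x) if (is.null(x)) character(0) else as.character(x)
  dec <- if (is.null(obj$decoyGenes) || !length(obj$decoyGenes))
    DataFrame(geneId = character(0), failingRule = character(0))
  else DataFrame(as.data.frame(obj$decoyGenes))
  new("PlantedTruth",
      enhancers = dfGr(obj$enhancers,
                       c(siteId = "character", fold = "numeric",
                         seClusterId = "character", ESC = "logical",
                         EoNeg = "logical", EoPos = "logical")),
      promoters = dfGr(obj$promoters, c(geneId = "character")),
      specificGenes = lapply(obj$specificGenes, chr),
      heartEnriched = chr(obj$heartEnriched),
      conservedPromoters = chr(obj$conservedPromoters),
      decoyGenes = dec)
}

#' Serialize a SyntheticConfig to/from YAML
#'
#' @param config a \code{\linkS4class{SyntheticConfig}}.
#' @param path file path.
#' @export
writeConfigYaml <- function(config, path) {
  obj <- list(
    seed = config@seed,
    chromSizes = as.list(config@chromSizes),
    nPcg = config@nPcg, nAnnotLnc = config@nAnnotLnc,
    nNovelLnc = config@nNovelLnc,
    decoys = config@decoys,
    enhancerPlan = as.list(config@enhancerPlan),
    backgroundRate = config@backgroundRate,
    readsPerReplicate = config@readsPerReplicate,
    readLength = config@readLength,
    promoterFold = config@promoterFold,
    plncFraction = config@plncFraction,
    expression = c(config@expression[setdiff(names(config@expression),
                                             "baselineFpkm")],
                   list(baselineFpkm = as.list(
                     config@expression$baselineFpkm))),
    tissuePlan = config@tissuePlan,
    conservationPlan = config@conservationPlan)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname writeConfigYaml
#' @export
readConfigYaml <- function(path) {
  obj <- yaml::read_yaml(path)
  known <- c("seed", "chromSizes", "nPcg", "nAnnotLnc", "nNovelLnc",
             "decoys", "enhancerPlan", "backgroundRate",
             "readsPerReplicate", "readLength", "promoterFold",
             "plncFraction", "expression", "tissuePlan",
             "conservationPlan")
  bad <- setdiff(names(obj), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  ep <- as.data.frame(obj$enhancerPlan, stringsAsFactors = FALSE)
  ex <- obj$expression
  if (!is.null(ex$baselineFpkm)) ex$baselineFpkm <- unlist(ex$baselineFpkm)
  syntheticConfig(
    seed = obj$seed, chromSizes = unlist(obj$chromSizes),
    nPcg = obj$nPcg, nAnnotLnc = obj$nAnnotLnc,
    nNovelLnc = obj$nNovelLnc, decoys = obj$decoys,
    enhancerPlan = ep,
    backgroundRate = obj$backgroundRate,
    readsPerReplicate = obj$readsPerReplicate,
    readLength = obj$readLength,
    promoterFold = obj$promoterFold, plncFraction = obj$plncFraction,
    expression = ex, tissuePlan = obj$tissuePlan,
    conservationPlan = obj$conservationPlan)
}
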