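#' Generate the toy genome: transcript models and planted truth
#'
#' Lays out the configured gene complement along the toy genome,
#' avoiding the planted enhancer sites (so enhancer and transcript
#' truth stay disentangled), and records every planted feature in a
#' \code{\linkS4class{PlantedTruth}} object: enhancer sites with their
#' active conditions, H3K4me3-marked promoters (all protein-coding
#' genes plus a configured fraction of lncRNA genes),
#' condition-specific genes, heart-enriched genes, conserved-promoter
#' genes, and the novel-lncRNA decoys planted to fail a named
#' transcript filter (single-exon, sub-200-bp, or coding-score above
#' 4).
#'
#' All randomness derives from the configuration seed; the same
#' configuration always yields byte-identical transcripts and truth.
#'
#' @param config a \code{\linkS4class{SyntheticConfig}}.
#' @return list with \code{transcripts} (a
#'   \code{\linkS4class{TranscriptSet}}, one transcript per gene) and
#'   \code{truth} (a \code{\linkS4class{PlantedTruth}}).
#' @export
generateGenomeAndTranscripts <- function(config) {
  validObject(config)
  sizes <- config@chromSizes
  dk <- config@decoys
  nNovel <- config@nNovelLnc
  nDecoy <- dk$singleExon + dk$short + dk$highCoding
  if (nDecoy > nNovel)
    stop("more decoys configured than novel lncRNAs")

  plan <- config@enhancerPlan
  enh <- if (nrow(plan)) .grFrom0(plan$chrom, plan$start,
                                  plan$start + plan$width,
                                  seqlen = sizes) else GRanges()
  if (length(enh)) {
    mcols(enh) <- DataFrame(siteId = sprintf("site%03d", seq_len(nrow(plan))),
                            fold = plan$fold,
                            seClusterId = plan$seClusterId,
                            ESC = plan$ESC, EoNeg = plan$EoNeg,
                            EoPos = plan$EoPos)
  }
  avoid <- if (length(enh))
    GenomicRanges::reduce(enh + 5000L, ignore.strand = TRUE) else GRanges()

  n <- config@nPcg + config@nAnnotLnc + config@nNovelLnc
  out <- .withSeed(.substream(config@seed, "genome"), {
    biotype <- rep(c("PCG", "annotated_lnc", "novel_lnc"),
                   c(config@nPcg, config@nAnnotLnc, config@nNovelLnc))
    geneId <- character(n)
    geneId[biotype == "PCG"] <- sprintf("pcg%04d", seq_len(config@nPcg))
    geneId[biotype == "annotated_lnc"] <-
      sprintf("lnc%04d", seq_len(config@nAnnotLnc))
    geneId[biotype == "novel_lnc"] <-
      sprintf("nov%04d", seq_len(config@nNovelLnc))

    ## decoy roles among the novel lncRNAs
    novelIdx <- which(biotype == "novel_lnc")
    role <- rep("normal", n)
    if (nDecoy > 0) {
      pick <- novelIdx[sample.int(length(novelIdx), nDecoy)]
      role[pick] <- rep(c("singleExon", "short", "highCoding"),
                        c(dk$singleExon, dk$short, dk$highCoding))
    }

    ## per-gene structure
    strandOf <- sample(c("+", "-"), n, replace = TRUE)
    exonW <- vector("list", n)
    intronW <- vector("list", n)
    for (i in seq_len(n)) {
      nEx <- switch(role[i],
        singleExon = 1L,
        short = 2L,
        sample(2:6, 1))
      exonW[[i]] <- switch(role[i],
        singleExon = sample(400:900, 1),
        short = sample(60:90, 2, replace = TRUE),
        sample(150:400, nEx, replace = TRUE))
      intronW[[i]] <- if (nEx > 1)
        sample(300:1500, nEx - 1L, replace = TRUE) else integer(0)
    }
    span <- vapply(seq_len(n), function(i)
      sum(exonW[[i]]) + sum(intronW[[i]]), numeric(1))

    ## assign genes to chromosomes proportionally to size, then walk a
    ## cursor along each chromosome, skipping planted-enhancer buffers
    ord <- sample.int(n)
    chromOf <- character(n)
    startOf <- integer(n)      # 1-based gene start
    share <- round(n * as.numeric(sizes) / sum(as.numeric(sizes)))
    share[length(share)] <- n - sum(share[-length(share)])
    splits <- split(ord, rep(names(sizes), share))
    for (chr in names(sizes)) {
      ids <- splits[[chr]]
      av <- avoid[seqnames(avoid) == chr]
      cursor <- 20000L
      lim <- sizes[[chr]] - 20000L
      for (i in ids) {
        cursor <- cursor + sample(500:2000, 1)
        repeat {
          cand <- IRanges(cursor, cursor + span[i] - 1L)
          hit <- which(start(av) <= end(cand) & end(av) >= start(cand))
          if (!length(hit)) break
          cursor <- max(end(av)[hit]) + 1000L
        }
        if (cursor + span[i] - 1L > lim)
          stop("insufficient genome space to place all genes on ", chr)
        chromOf[i] <- chr
        startOf[i] <- cursor
        cursor <- cursor + span[i]
      }
    }

    codingScore <- numeric(n)
    codingScore[biotype == "PCG"] <- stats::runif(sum(biotype == "PCG"),
                                                  10, 60)
    isLnc <- biotype != "PCG"
    codingScore[isLnc] <- stats::runif(sum(isLnc), 0, 4)
    codingScore[role == "highCoding"] <-
      stats::runif(sum(role == "highCoding"), 4.5, 15)

    ## H3K4me3 promoters: all PCGs plus a fraction of non-decoy lncRNAs
    lncNormal <- which(isLnc & role == "normal")
    nPlnc <- round(config@plncFraction * length(lncNormal))
    promGenes <- c(which(biotype == "PCG"),
                   if (nPlnc > 0) lncNormal[sample.int(length(lncNormal), nPlnc)])

    nonDecoy <- geneId[role == "normal"]
    pool <- sample(nonDecoy)
    ## degrade gracefully on tiny gene complements
    spc <- min(config@expression$specificPerCondition,
               length(pool) %/% 3L)
    specific <- list(ESC = pool[seq_len(spc)],
                     EoNeg = pool[spc + seq_len(spc)],
                     EoPos = pool[2 * spc + seq_len(spc)])
    heart <- sample(nonDecoy, min(config@tissuePlan$nHeartEnriched,
                                  length(nonDecoy)))
    conserved <- sample(geneId, min(config@conservationPlan$nConserved, n))

    list(biotype = biotype, geneId = geneId, role = role,
         strandOf = strandOf, exonW = exonW, intronW = intronW,
         chromOf = chromOf, startOf = startOf, codingScore = codingScore,
         promGenes = promGenes, specific = specific, heart = heart,
         conserved = conserved)
  })

  ## assemble exon GRanges (genomic layout is strand-independent; the
  ## TSS convention handles orientation)
  exList <- vector("list", n)
  for (i in seq_len(n)) {
    w <- out$exonW[[i]]
    iw <- out$intronW[[i]]
    starts <- out$startOf[i] +
      cumsum(c(0L, if (length(w) > 1) w[-length(w)] + iw else integer(0)))
    exList[[i]] <- GRanges(out$chromOf[i],
                           IRanges(starts, width = w),
                           strand = out$strandOf[i])
  }
  txIds <- if (n) paste0(out$geneId, ".t1") else character(0)
  exons <- GRangesList(exList)
  names(exons) <- txIds
  seqlengths(exons) <- sizes[seqlevels(exons)]
  info <- DataFrame(transcriptId = txIds, geneId = out$geneId,
                    biotype = out$biotype,
                    codingScore = out$codingScore)
  txset <- transcriptSet(exons, info)

  tss <- tssSites(txset)
  geneOfTss <- mcols(tss)$geneId
  promIdx <- if (length(out$promGenes))
    match(paste0(out$geneId[out$promGenes], ".t1"), names(tss)) else
      integer(0)
  promoters <- GRanges(
    seqnames(tss)[promIdx],
    IRanges(pmax(start(tss)[promIdx] - 500L, 1L),
            pmin(start(tss)[promIdx] + 500L,
                 sizes[as.character(seqnames(tss)[promIdx])])))
  mcols(promoters)$geneId <- geneOfTss[promIdx]
  seqlengths(promoters) <- sizes[seqlevels(promoters)]

  ruleOf <- c(singleExon = "exons", short = "length",
              highCoding = "coding_score")
  decoyGenes <- DataFrame(
    geneId = out$geneId[out$role != "normal"],
    failingRule = unname(ruleOf[out$role[out$role != "normal"]]))

  truth <- new("PlantedTruth", enhancers = enh, promoters = promoters,
               specificGenes = out$specific, heartEnriched = out$heart,
               conservedPromoters = out$conserved, decoyGenes = decoyGenes)
  list(transcripts = txset, truth = truth)
}
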