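## Mean-corrected log-normal noise factor: E[factor] = 1, coefficient
## of variation = cv. cv = 0 degenerates to exactly 1.
.lnNoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(stats::rnorm(n, -s2 / 2, sqrt(s2)))
}

#' Simulate the expression data: FPKM matrix and 12-tissue count panel
#'
#' Two planted-truth expression datasets over the toy genome's genes:
#' \itemize{
#'   \item an FPKM matrix over the three cell populations (ESC, EoNeg,
#'     EoPos) with 4 replicates each. Baseline genes draw a biotype
#'     baseline mean; condition-specific genes (from the truth) are
#'     expressed at \code{specificMean} in their own population and 0
#'     elsewhere, so their normalized difference is exactly 3.
#'   \item a stranded 12-tissue count panel with 2 replicates per
#'     tissue. All genes share a non-cardiac baseline mean;
#'     heart-enriched genes (from the truth) have a heart mean of
#'     \code{fold} times the baseline. Per-gene strand fractions split
#'     each replicate total so the two strands always sum back to it.
#' }
#' Replicate noise is multiplicative log-normal with the configured
#' coefficient of variation and unit mean, so with \code{cv = 0}
#' values equal their planted means exactly.
#'
#' @param config a \code{\linkS4class{SyntheticConfig}}.
#' @param truth the matching \code{\linkS4class{PlantedTruth}}.
#' @param txset the matching \code{\linkS4class{TranscriptSet}}.
#' @return list with \code{fpkm} (matrix, genes x 12 samples, column
#'   names like \code{ESC_1}), \code{conditions} (column-to-condition
#'   map), and \code{tissue} (a \code{SummarizedExperiment} of counts
#'   with colData \code{tissue}, \code{replicate}, \code{strand}).
#' @export
simulateExpression <- function(config, truth, txset) {
  genes <- sort(unique(as.character(txInfo(txset)$geneId)))
  biotype <- as.character(txInfo(txset)$biotype)[
    match(genes, as.character(txInfo(txset)$geneId))]
  ex <- config@expression
  tp <- config@tissuePlan
  nG <- length(genes)

  .withSeed(.substream(config@seed, "expression"), {
    base <- ifelse(biotype == "PCG", ex$baselineFpkm[["PCG"]],
                   ex$baselineFpkm[["lnc"]])
    meanMat <- matrix(base, nrow = nG, ncol = 3,
                      dimnames = list(genes, CONDITIONS))
    for (cond in CONDITIONS) {
      sp <- intersect(truth@specificGenes[[cond]], genes)
      meanMat[sp, ] <- 0
      meanMat[sp, cond] <- ex$specificMean
    }
    fpkm <- matrix(0, nrow = nG, ncol = 12,
                   dimnames = list(genes, paste(rep(CONDITIONS, each = 4),
                                                1:4, sep = "_")))
    conditions <- rep(CONDITIONS, each = 4)
    for (j in seq_len(12))
      fpkm[, j] <- meanMat[, conditions[j]] * .lnNoise(nG, ex$cv)

    tissues <- c("thymus", "liver", "stomach", "colon", "ovary", "spleen",
                 "heart", "kidney", "mammary", "frontal_lobe", "cortex",
                 "cerebellum")
    heartSet <- genes %in% truth@heartEnriched
    strandFrac <- stats::runif(nG, 0.3, 0.7)
    nCol <- length(tissues) * 2L * 2L
    counts <- matrix(0, nrow = nG, ncol = nCol)
    cd <- expand.grid(strand = c("+", "-"), replicate = 1:2,
                      tissue = tissues, stringsAsFactors = FALSE)
    cd <- cd[, c("tissue", "replicate", "strand")]
    colnames(counts) <- paste(cd$tissue, cd$replicate, cd$strand, sep = "_")
    for (tt in tissues) {
      mu <- rep(tp$nonCardiacMean, nG)
      if (tt == "heart") mu[heartSet] <- tp$fold * tp$nonCardiacMean
      for (rr in 1:2) {
        tot <- mu * .lnNoise(nG, tp$cv)
        counts[, cd$tissue == tt & cd$replicate == rr & cd$strand == "+"] <-
          tot * strandFrac
        counts[, cd$tissue == tt & cd$replicate == rr & cd$strand == "-"] <-
          tot * (1 - strandFrac)
      }
    }
    rownames(counts) <- genes
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = counts),
      colData = DataFrame(cd, row.names = colnames(counts)))
    list(fpkm = fpkm, conditions = conditions, tissue = se)
  })
}

#' Simulate a per-base conservation track with planted promoter
#' elevation
#'
#' The genome is tiled in \code{tileWidth}-bp windows whose scores are
#' Gaussian noise around the background level (clamped to [0, 1] in
#' phastCons mode); tiles overlapping the 1000-bp promoter of a
#' conserved-promoter gene (from the truth) are elevated by
#' \code{delta}. In phyloP mode scores are signed (background 0) and
#' conserved promoters receive the same additive elevation scaled by
#' 10, mimicking the larger dynamic range of -log p scores.
#'
#' @param config a \code{\linkS4class{SyntheticConfig}}.
#' @param truth the matching \code{\linkS4class{PlantedTruth}}.
#' @param txset the matching \code{\linkS4class{TranscriptSet}}.
#' @param mode \code{"phastcons"} or \code{"phylop"}.
#' @return a \code{\linkS4class{ConservationTrack}}.
#' @export
simulateConservation <- function(config, truth, txset,
                                 mode = c("phastcons", "phylop")) {
  mode <- match.arg(mode)
  cp <- config@conservationPlan
  sizes <- config@chromSizes

  tiles <- unlist(GenomicRanges::tileGenome(sizes,
                                            tilewidth = cp$tileWidth))
  tss <- tssSites(txset)
  keep <- mcols(tss)$geneId %in% truth@conservedPromoters
  prom <- .promoterRanges(tss[keep], 1000L, sizes)

  .withSeed(.substream(config@seed, paste0("conservation|", mode)), {
    bg <- if (mode == "phastcons") cp$background else 0
    val <- stats::rnorm(length(tiles), bg, cp$noiseSd)
    delta <- if (mode == "phastcons") cp$delta else 10 * cp$delta
    hit <- IRanges::overlapsAny(tiles, prom, ignore.strand = TRUE)
    val[hit] <- val[hit] + delta
    if (mode == "phastcons") val <- pmin(pmax(val, 0), 1)
    mcols(tiles)$score <- val
    conservationTrack(tiles, sizes, mode = mode)
  })
}
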