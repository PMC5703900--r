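## End-to-end orchestration over a synthetic configuration. Every
## stage writes plain-text outputs (TSV/BED/GTF/JSON) into `outDir`;
## numbers in TSVs are fixed at 6 significant digits for diffability,
## and no output carries a timestamp, so identical configurations give
## byte-identical output trees.

.PIPELINE_STAGES <- c("simulate", "callbins", "rose", "classify",
                      "specificity", "tissue", "conserve")

.need <- function(outDir, file, producer, stage) {
  p <- file.path(outDir, file)
  if (!file.exists(p))
    stop("stage '", stage, "' requires output of stage '", producer,
         "': ", file, " not found in ", outDir)
  p
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the stages in dependency order — simulate the planted
#' datasets, bin reads and call enriched bins, assemble constituent
#' enhancers, call super-/typical enhancers, classify lncRNAs, compute
#' specificity (ND) statistics, tissue-enrichment scores and ratios,
#' and conservation scores — writing per-stage TSV/BED/GTF/JSON
#' outputs plus the resolved configuration and a structured log.
#'
#' With \code{only}, a single stage is re-run against the text outputs
#' of the earlier stages already present in \code{outDir}; a missing
#' prerequisite raises an error naming the stage that must run first.
#'
#' @param config a \code{\linkS4class{SyntheticConfig}}.
#' @param outDir output directory (created if needed).
#' @param only optional single stage name to re-run.
#' @param binSize,extension,pThreshold,minFold,minCeLength,
#'   stitchDistance,promoterHalfwidth tuning parameters with the
#'   pipeline defaults (25, 200, 1e-9, 5, 200, 12500, 1000).
#' @param nIntergenic intergenic background regions for the
#'   conservation comparison (default 500).
#' @param writeReads also write the simulated reads as BED6 (off by
#'   default; read sets are large and regenerable from the seed).
#' @return the output directory, invisibly.
#' @export
runPipeline <- function(config, outDir, only = NULL,
                        binSize = 25L, extension = 200L,
                        pThreshold = 1e-9, minFold = 5,
                        minCeLength = 200L, stitchDistance = 12500L,
                        promoterHalfwidth = 1000L,
                        nIntergenic = 500L, writeReads = FALSE) {
  validObject(config)
  if (!is.null(only) && !only %in% .PIPELINE_STAGES)
    stop("unknown stage '", only, "'; stages are: ",
         paste(.PIPELINE_STAGES, collapse = ", "))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logLines <- character(0)
  note <- function(...) logLines <<- c(logLines, paste0(...))
  note("pipeline: binSize=", binSize, " extension=", extension,
       " pThreshold=", pThreshold, " minFold=", minFold,
       " minCeLength=", minCeLength, " stitchDistance=", stitchDistance,
       " promoterHalfwidth=", promoterHalfwidth, " seed=", config@seed)

  stages <- if (is.null(only)) .PIPELINE_STAGES else only
  state <- new.env(parent = emptyenv())

  loadSim <- function(stage) {
    state$truth <- readTruthJson(
      .need(outDir, "truth.json", "simulate", stage), config@chromSizes)
    state$txset <- readGtfTranscripts(
      .need(outDir, "transcripts.gtf", "simulate", stage),
      config@chromSizes)
  }
  loadFpkm <- function(stage) {
    d <- .readTsv(.need(outDir, "fpkm.tsv", "simulate", stage))
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d[[1]]
    state$fpkm <- m
    state$conditions <- sub("_[0-9]+$", "", colnames(m))
  }

  if ("simulate" %in% stages) {
    g <- generateGenomeAndTranscripts(config)
    state$truth <- g$truth; state$txset <- g$transcripts
    expr <- simulateExpression(config, g$truth, g$transcripts)
    state$fpkm <- expr$fpkm; state$conditions <- expr$conditions
    state$tissueSe <- expr$tissue
    writeConfigYaml(config, file.path(outDir, "config.yaml"))
    writeGtfTranscripts(g$transcripts, file.path(outDir, "transcripts.gtf"))
    writeTruthJson(g$truth, file.path(outDir, "truth.json"))
    .writeTsv(data.frame(geneId = rownames(expr$fpkm), expr$fpkm,
                         check.names = FALSE),
              file.path(outDir, "fpkm.tsv"))
    cnt <- SummarizedExperiment::assay(expr$tissue, "counts")
    .writeTsv(data.frame(geneId = rownames(cnt), cnt, check.names = FALSE),
              file.path(outDir, "tissue_counts.tsv"))
    if (writeReads)
      for (mark in c("H3K27Ac", "H3K4me3", "input"))
        for (cond in CONDITIONS)
          for (r in 1:2)
            writeReadsBed(
              simulateChipReads(config, g$truth, mark, cond, r),
              file.path(outDir, sprintf("reads_%s_%s_rep%d.bed",
                                        mark, cond, r)))
    note("simulate: ", length(g$transcripts@exons), " transcripts, ",
         length(g$truth@enhancers), " planted enhancer sites")
  }

  needsTracks <- any(c("callbins", "rose") %in% stages)
  if (needsTracks) {
    if (is.null(state$truth)) loadSim(stages[1])
    ## tracks are regenerated deterministically from the seed
    state$inputs <- stats::setNames(lapply(CONDITIONS, function(cond)
      simulatePooledInput(config, state$truth, cond, binSize, extension)),
      CONDITIONS)
    for (mark in c("H3K27Ac", "H3K4me3")) {
      tr <- lapply(CONDITIONS, function(cond) lapply(1:2, function(r)
        binReads(simulateChipReads(config, state$truth, mark, cond, r),
                 seqlens = config@chromSizes, binSize = binSize,
                 extension = extension)))
      names(tr) <- CONDITIONS
      state[[paste0("tracks_", mark)]] <- tr
    }
  }

  if ("callbins" %in% stages) {
    for (mark in c("H3K27Ac", "H3K4me3")) {
      masks <- stats::setNames(lapply(CONDITIONS, function(cond) {
        tr <- state[[paste0("tracks_", mark)]][[cond]]
        m <- lapply(1:2, function(r)
          poissonEnrichedBins(tr[[r]], state$inputs[[cond]],
                              pThreshold, minFold,
                              provenance = c(mark = mark,
                                             condition = cond,
                                             replicate = as.character(r))))
        intersectReplicates(m[[1]], m[[2]])
      }), CONDITIONS)
      ce <- callConstituentEnhancers(masks, minCeLength)
      state[[paste0("ce_", mark)]] <- ce
      fn <- if (mark == "H3K27Ac") "constituent_enhancers.bed" else
        "h3k4me3_regions.bed"
      writeRegionsBed(ce, file.path(outDir, fn))
      note("callbins ", mark, ": ", length(ce), " regions")
    }
  }

  if ("rose" %in% stages) {
    ce <- state$ce_H3K27Ac
    if (is.null(ce))
      ce <- readRegionsBed(.need(outDir, "constituent_enhancers.bed",
                                 "callbins", "rose"), config@chromSizes)
    res <- callSuperEnhancers(ce, state$tracks_H3K27Ac, state$inputs,
                              stitchDistance)
    state$se <- res$se; state$te <- res$te
    writeRegionsBed(res$se, file.path(outDir, "superenhancers.bed"))
    writeRegionsBed(res$te, file.path(outDir, "typical_enhancers.bed"))
    for (cond in names(res$perCondition))
      writeRegionsBed(res$perCondition[[cond]],
                      file.path(outDir, sprintf("superenhancers_%s.bed",
                                                cond)))
    am <- activityMatrix(res$se, res$perCondition)
    .writeTsv(data.frame(enhancer = rownames(am), am, check.names = FALSE),
              file.path(outDir, "activity_matrix.tsv"))
    for (nm in names(res$rankTables))
      .writeTsv(res$rankTables[[nm]],
                file.path(outDir, sprintf("rank_%s.tsv", nm)))
    note("rose: ", length(res$se), " SE / ", length(res$te), " TE")
  }

  if ("classify" %in% stages) {
    if (is.null(state$txset)) loadSim("classify")
    if (is.null(state$fpkm)) loadFpkm("classify")
    se <- state$se
    if (is.null(se))
      se <- readRegionsBed(.need(outDir, "superenhancers.bed", "rose",
                                 "classify"), config@chromSizes)
    te <- state$te
    if (is.null(te))
      te <- readRegionsBed(.need(outDir, "typical_enhancers.bed", "rose",
                                 "classify"), config@chromSizes)
    k4 <- state$ce_H3K4me3
    if (is.null(k4))
      k4 <- readRegionsBed(.need(outDir, "h3k4me3_regions.bed", "callbins",
                                 "classify"), config@chromSizes)
    means <- collapseReplicates(state$fpkm, state$conditions)
    filt <- filterTranscripts(state$txset, means)
    state$retained <- filt$retained
    lnc <- subsetTranscripts(filt$retained,
      txInfo(filt$retained)$transcriptId[
        txInfo(filt$retained)$biotype != "PCG"])
    cls <- classifyLncRNAs(lnc, k4, se, te, promoterHalfwidth)
    state$classes <- cls
    .writeTsv(as.data.frame(cls), file.path(outDir, "lncrna_classes.tsv"))
    .writeTsv(as.data.frame(filt$rejected),
              file.path(outDir, "rejected_transcripts.tsv"))
    comp <- classComposition(cls)
    .writeTsv(data.frame(biotype = rownames(comp), comp,
                         check.names = FALSE),
              file.path(outDir, "class_composition.tsv"))
    note("classify: ", nrow(cls), " lncRNA genes classified, ",
         nrow(filt$rejected), " transcripts rejected")
  }

  if ("specificity" %in% stages) {
    if (is.null(state$fpkm)) loadFpkm("specificity")
    cls <- state$classes
    if (is.null(cls)) {
      d <- .readTsv(.need(outDir, "lncrna_classes.tsv", "classify",
                          "specificity"))
      cls <- DataFrame(d)
    }
    if (is.null(state$txset)) loadSim("specificity")
    means <- collapseReplicates(state$fpkm, state$conditions)
    nd <- normalizedDifference(means)
    info <- txInfo(state$txset)
    biotype <- as.character(info$biotype)[match(rownames(means),
                                                as.character(info$geneId))]
    out <- data.frame(geneId = rownames(means), biotype = biotype,
                      nd = nd,
                      klass = as.character(cls$klass)[
                        match(rownames(means), as.character(cls$geneId))])
    .writeTsv(out, file.path(outDir, "specificity.tsv"))
    ok <- !is.na(nd)
    tests <- list()
    for (bt in c("annotated_lnc", "novel_lnc")) {
      a <- nd[ok & biotype == bt]; b <- nd[ok & biotype == "PCG"]
      if (length(a) && length(b)) {
        cmp <- compareNdDistributions(a, b, "greater")
        tests[[bt]] <- data.frame(groupA = bt, groupB = "PCG",
                                  alternative = "greater",
                                  p = cmp$p.value, method = cmp$method)
      }
    }
    if (length(tests))
      .writeTsv(do.call(rbind, tests), file.path(outDir, "nd_tests.tsv"))
    note("specificity: ND for ", sum(ok), " genes")
  }

  if ("tissue" %in% stages) {
    tse <- state$tissueSe
    if (is.null(tse)) {
      d <- .readTsv(.need(outDir, "tissue_counts.tsv", "simulate",
                          "tissue"))
      m <- as.matrix(d[, -1, drop = FALSE]); rownames(m) <- d[[1]]
      parts <- do.call(rbind, strsplit(colnames(m), "_(?=[^_]+_[^_]+$)",
                                       perl = TRUE))
      rp <- do.call(rbind, strsplit(parts[, 2], "_"))
      tse <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = m),
        colData = DataFrame(tissue = parts[, 1], replicate = rp[, 1],
                            strand = rp[, 2]))
    }
    if (is.null(state$fpkm)) loadFpkm("tissue")
    panel <- preprocessPanel(tse)
    scores <- tissueEnrichmentScores(panel)
    he <- heScore(panel)
    .writeTsv(data.frame(geneId = rownames(scores), heScore = he,
                         heEnriched = he > 1, scores, check.names = FALSE),
              file.path(outDir, "tissue_scores.tsv"))
    de <- welchDE(state$fpkm, which(state$conditions == "EoPos"),
                  which(state$conditions == "EoNeg"))
    means <- collapseReplicates(state$fpkm, state$conditions)
    p <- stats::setNames(de$p, de$geneId)
    upPos <- enrichedSet(means, "EoPos", "EoNeg", p = p)
    upNeg <- enrichedSet(means, "EoNeg", "EoPos", p = p)
    if (length(upPos) && length(upNeg)) {
      ratios <- tissueEnrichmentRatios(upPos, upNeg, panel)
      .writeTsv(data.frame(tissue = names(ratios), ratio = ratios),
                file.path(outDir, "tissue_enrichment_ratios.tsv"))
    }
    note("tissue: ", nrow(scores), " genes scored; ",
         sum(he > 1), " heart-enriched; |EoPos set|=", length(upPos),
         " |EoNeg set|=", length(upNeg))
  }

  if ("conserve" %in% stages) {
    if (is.null(state$txset) || is.null(state$truth)) loadSim("conserve")
    trk <- simulateConservation(config, state$truth, state$txset)
    fs <- featureScores(trk, state$txset)
    .writeTsv(as.data.frame(fs), file.path(outDir, "conservation_scores.tsv"))
    ig <- sampleIntergenic(config@chromSizes, geneSpans(state$txset),
                           nIntergenic,
                           seed = .substream(config@seed, "intergenic"))
    igScore <- fragmentScore(trk, ig)
    consProm <- fs$promoterScore[fs$geneId %in% state$truth@conservedPromoters]
    wt <- suppressWarnings(stats::wilcox.test(consProm, igScore,
                                              alternative = "greater"))
    .writeTsv(data.frame(nConservedPromoters = length(consProm),
                         nIntergenic = length(igScore),
                         meanPromoter = mean(consProm),
                         meanIntergenic = mean(igScore),
                         wilcoxonP = wt$p.value),
              file.path(outDir, "conservation_test.tsv"))
    note("conserve: ", nrow(fs), " genes scored; promoter-vs-intergenic p=",
         format(wt$p.value, digits = 3))
  }

  writeLines(logLines, file.path(outDir, "pipeline.log"))
  invisible(outDir)
}
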