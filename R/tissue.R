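#' Preprocess a stranded, replicated tissue count panel
#'
#' The standard preparation of a multi-tissue expression panel:
#' per-gene counts on plus and minus strands are summed, the two
#' replicates of each tissue are averaged, samples are normalized with
#' median-of-ratios size factors
#' (\code{\link{medianRatioSizeFactors}}), and genes that never reach
#' \code{minExpr} in any tissue are dropped.
#'
#' @param se \code{SummarizedExperiment} with a \code{counts} assay and
#'   \code{colData} columns \code{tissue}, \code{replicate},
#'   \code{strand}; every tissue needs both strands of both
#'   replicates.
#' @param minExpr expression floor (default 0.1; genes are kept when
#'   at least one tissue reaches it).
#' @return \code{SummarizedExperiment} with one column per tissue, a
#'   single \code{expr} assay of normalized values, and
#'   \code{metadata()} entries \code{sizeFactors} and
#'   \code{droppedGenes}.
#' @export
preprocessPanel <- function(se, minExpr = 0.1) {
  cd <- SummarizedExperiment::colData(se)
  need <- c("tissue", "replicate", "strand")
  if (!all(need %in% colnames(cd)))
    stop("colData needs columns: ", paste(need, collapse = ", "))
  counts <- SummarizedExperiment::assay(se, "counts")
  tissues <- unique(as.character(cd$tissue))

  perTissue <- vapply(tissues, function(tt) {
    repVals <- vapply(sort(unique(cd$replicate[cd$tissue == tt])),
      function(rr) {
        sel <- cd$tissue == tt & cd$replicate == rr
        if (length(unique(cd$strand[sel])) < 2L)
          stop("missing strand for tissue ", tt, " replicate ", rr)
        rowSums(counts[, sel, drop = FALSE])        # strand sum
      }, numeric(nrow(counts)))
    if (ncol(repVals) < 2L)
      stop("missing replicate for tissue ", tt)
    rowMeans(repVals)                               # replicate mean
  }, numeric(nrow(counts)))
  colnames(perTissue) <- tissues
  rownames(perTissue) <- rownames(counts)

  sf <- medianRatioSizeFactors(perTissue)
  norm <- sweep(perTissue, 2, sf, "/")
  keep <- apply(norm, 1, max) >= minExpr
  out <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = norm[keep, , drop = FALSE]),
    colData = DataFrame(tissue = tissues, row.names = tissues))
  S4Vectors::metadata(out)$sizeFactors <- sf
  S4Vectors::metadata(out)$droppedGenes <- rownames(norm)[!keep]
  out
}

.panelMatrix <- function(panel) {
  if (is(panel, "SummarizedExperiment"))
    SummarizedExperiment::assay(panel, 1) else as.matrix(panel)
}

## Enrichment score of one tissue column against the others:
## value / (mean(others) + 2 * sd(others)), sample (n-1) sd. The same
## code path serves heScore and tissueEnrichmentScores so the heart
## column of the latter is bit-identical to the former.
.enrichScore <- function(mat, col) {
  x <- mat[, col]
  others <- mat[, setdiff(colnames(mat), col), drop = FALSE]
  mu <- rowMeans(others)
  sd <- apply(others, 1, stats::sd)
  den <- mu + 2 * sd
  ifelse(den > 0, x / den, ifelse(x > 0, Inf, 0))
}

#' Heart-Enrichment (HE) score
#'
#' Per gene, heart expression divided by the mean plus two (sample)
#' standard deviations of the 11 non-cardiac tissues:
#' \deqn{HE = \mu_{cardiac} / (\mu_{non\text{-}cardiac} +
#'   2\,\sigma_{non\text{-}cardiac}).}
#' A gene is heart-enriched when its score is strictly above 1 — its
#' heart expression stands two standard deviations above the
#' non-cardiac mean. A gene expressed in heart only (all non-cardiac
#' values zero) scores \code{Inf} and is enriched; a gene silent in
#' heart scores 0. The score is invariant to rescaling the gene's row.
#'
#' @param panel normalized tissue panel: matrix (genes x tissues, one
#'   column named as \code{heartLabel}) or the
#'   \code{SummarizedExperiment} from \code{\link{preprocessPanel}}.
#' @param heartLabel name of the cardiac column (default
#'   \code{"heart"}).
#' @return named numeric vector of HE scores.
#' @export
heScore <- function(panel, heartLabel = "heart") {
  mat <- .panelMatrix(panel)
  if (!heartLabel %in% colnames(mat))
    stop("no '", heartLabel, "' column in the panel")
  if (ncol(mat) < 3L) stop("at least 2 non-cardiac tissues are required")
  .enrichScore(mat, heartLabel)
}

#' Tissue-enrichment scores for every tissue
#'
#' The HE-score construction applied to each tissue in turn: for
#' tissue \eqn{t}, \eqn{x_t / (\mu_{\neq t} + 2\sigma_{\neq t})}. The
#' column for the cardiac tissue equals \code{\link{heScore}} exactly.
#'
#' @inheritParams heScore
#' @return numeric matrix, genes x tissues, of enrichment scores.
#' @export
tissueEnrichmentScores <- function(panel) {
  mat <- .panelMatrix(panel)
  if (ncol(mat) < 3L) stop("at least 3 tissues are required")
  out <- vapply(colnames(mat), function(tt) .enrichScore(mat, tt),
                numeric(nrow(mat)))
  if (!is.matrix(out))
    out <- matrix(out, nrow = 1L, dimnames = list(NULL, colnames(mat)))
  rownames(out) <- rownames(mat)
  out
}

#' Ratio of tissue-enrichment percentages between two gene sets
#'
#' The fraction of genes in set A with tissue score above 1, divided by
#' the same fraction in set B — e.g. the HE ratio comparing
#' heart-enrichment of the genes upregulated in one cell population
#' versus another.
#'
#' @param genesA,genesB nonempty character vectors of gene ids (rows of
#'   the panel; ids absent from the panel count as not enriched).
#' @param panel normalized tissue panel (matrix or
#'   \code{SummarizedExperiment}).
#' @param tissue tissue whose enrichment is compared (default
#'   \code{"heart"}).
#' @return the ratio (numeric). When no gene of B is enriched the
#'   ratio is undefined and \code{NA} is returned with a warning.
#' @export
enrichmentRatio <- function(genesA, genesB, panel, tissue = "heart") {
  if (!length(genesA) || !length(genesB))
    stop("both gene sets must be nonempty")
  mat <- .panelMatrix(panel)
  scores <- .enrichScore(mat, tissue)
  pct <- function(g) {
    hit <- intersect(g, rownames(mat))
    100 * sum(scores[hit] > 1) / length(g)
  }
  pA <- pct(genesA); pB <- pct(genesB)
  if (pB == 0) {
    warning("no gene of set B is ", tissue, "-enriched; ratio undefined")
    return(NA_real_)
  }
  pA / pB
}

#' Per-tissue enrichment-ratio profile of two gene sets
#'
#' \code{\link{enrichmentRatio}} applied to every tissue of the panel.
#'
#' @inheritParams enrichmentRatio
#' @return named numeric vector, one ratio per tissue.
#' @export
tissueEnrichmentRatios <- function(genesA, genesB, panel) {
  mat <- .panelMatrix(panel)
  vapply(colnames(mat), function(tt)
    suppressWarnings(enrichmentRatio(genesA, genesB, mat, tissue = tt)),
    numeric(1))
}
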