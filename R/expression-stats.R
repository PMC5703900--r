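#' Collapse replicate columns to condition means
#'
#' @param mat numeric matrix, genes in rows, samples in columns.
#' @param conditions character vector assigning each column to a
#'   condition.
#' @return matrix of per-condition means (columns in first-appearance
#'   order of \code{conditions}).
#' @export
collapseReplicates <- function(mat, conditions) {
  if (length(conditions) != ncol(mat))
    stop("'conditions' must have one entry per column")
  lev <- unique(conditions)
  out <- vapply(lev, function(cc)
    rowMeans(mat[, conditions == cc, drop = FALSE]), numeric(nrow(mat)))
  if (nrow(mat) == 1L) out <- matrix(out, nrow = 1L,
    dimnames = list(rownames(mat), lev))
  colnames(out) <- lev
  out
}

#' Normalized Difference (ND): expression specificity across conditions
#'
#' For a gene with condition-mean expression \eqn{g_x} over the three
#' cell populations,
#' \deqn{ND(x) = \frac{\max(g_x) - \min(g_x)}{\mathrm{mean}(g_x)}.}
#' ND is 0 for a constant profile and reaches its maximum of 3 (for
#' three conditions) when a gene is expressed in exactly one
#' population; it is invariant to rescaling the profile. Genes with an
#' all-zero profile have no defined ND and return \code{NA} (they
#' should have been removed by the expression filter).
#'
#' @param x numeric vector of condition means (one gene), or a matrix
#'   with one row per gene and one column per condition.
#' @return numeric scalar or per-gene vector of ND values.
#' @export
normalizedDifference <- function(x) {
  if (is.matrix(x)) {
    m <- rowMeans(x)
    nd <- (apply(x, 1, max) - apply(x, 1, min)) / m
    nd[m == 0] <- NA_real_
    return(nd)
  }
  if (any(x < 0)) stop("expression values must be non-negative")
  m <- mean(x)
  if (m == 0) return(NA_real_)
  (max(x) - min(x)) / m
}

#' Compare two ND distributions by one-tailed Wilcoxon rank-sum test
#'
#' Tests whether group A's specificity values are stochastically
#' greater (or less) than group B's. The exact rank-sum distribution is
#' used whenever the smaller group has at most 20 observations and the
#' pooled data are tie-free; otherwise the normal approximation with
#' tie correction and continuity correction is used. Gaussian kernel
#' density estimates (Silverman's rule-of-thumb bandwidth) of both
#' groups are returned alongside for distribution plots.
#'
#' @param groupA,groupB numeric vectors of ND values (nonempty).
#' @param alternative \code{"greater"} (A stochastically above B) or
#'   \code{"less"}.
#' @return list with \code{p.value}, \code{method} (\code{"exact"} or
#'   \code{"normal_approx"}), \code{densityA}, \code{densityB}.
#' @export
compareNdDistributions <- function(groupA, groupB,
                                   alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (!length(groupA) || !length(groupB))
    stop("both groups must be nonempty")
  ties <- anyDuplicated(c(groupA, groupB)) > 0
  exact <- min(length(groupA), length(groupB)) <= 20 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(groupA, groupB, alternative = alternative,
                       exact = exact, correct = TRUE))
  dens <- function(v) if (length(v) >= 2 && stats::sd(v) > 0)
    stats::density(v, kernel = "gaussian", bw = "nrd0") else NULL
  list(p.value = wt$p.value,
       method = if (exact) "exact" else "normal_approx",
       densityA = dens(groupA), densityB = dens(groupB))
}

#' Fold-change-enriched gene set between two conditions
#'
#' Genes whose mean expression in \code{condA} exceeds \code{minFold}
#' times the mean in \code{condB}. A pseudocount is added to both means
#' so that zeros cannot produce infinite folds. When raw p-values are
#' supplied they are Benjamini-Hochberg adjusted and genes must
#' additionally reach adjusted p below \code{alpha}; pre-adjusted
#' p-values can be passed via \code{adjP} instead.
#'
#' @param means numeric matrix of condition means (genes x conditions,
#'   rownames = gene ids).
#' @param condA,condB column names of the numerator and denominator
#'   conditions.
#' @param minFold fold threshold (default 2, strict).
#' @param pseudocount added to both means (default 0.01 FPKM).
#' @param p optional named vector of raw p-values (BH-adjusted here).
#' @param adjP optional named vector of already-adjusted p-values.
#' @param alpha adjusted-p cutoff (default 0.05).
#' @return character vector of enriched gene ids.
#' @export
enrichedSet <- function(means, condA, condB, minFold = 2,
                        pseudocount = 0.01, p = NULL, adjP = NULL,
                        alpha = 0.05) {
  if (!all(c(condA, condB) %in% colnames(means)))
    stop("unknown condition: ",
         paste(setdiff(c(condA, condB), colnames(means)), collapse = ", "))
  fold <- (means[, condA] + pseudocount) / (means[, condB] + pseudocount)
  keep <- fold > minFold
  if (!is.null(p) && is.null(adjP))
    adjP <- stats::p.adjust(p, method = "BH")
  if (!is.null(adjP)) {
    a <- adjP[rownames(means)]
    keep <- keep & !is.na(a) & a < alpha
  }
  rownames(means)[keep]
}

#' Median-of-ratios size factors
#'
#' Between-sample normalization factors computed with the
#' median-of-ratios algorithm: the reference profile is the per-gene
#' geometric mean over samples (genes with any zero count are excluded
#' from the reference), and each sample's factor is the median over
#' genes of its counts divided by the reference.
#'
#' @param counts numeric matrix, genes x samples (at least 2 samples).
#' @return named numeric vector of size factors, one per sample.
#' @export
medianRatioSizeFactors <- function(counts) {
  if (ncol(counts) < 2L) stop("at least 2 samples are required")
  allPos <- rowSums(counts <= 0) == 0
  if (!any(allPos))
    stop("no gene has positive counts in every sample; ",
         "size factors are undefined")
  lc <- log(counts[allPos, , drop = FALSE])
  ref <- rowMeans(lc)                       # log geometric mean
  apply(lc, 2, function(x) exp(stats::median(x - ref)))
}

#' Per-gene Welch t-test on log expression
#'
#' A plumbing differential-expression test for synthetic pipelines:
#' Welch's two-sample t-test on \code{log2(x + pseudocount)} per gene,
#' with the log2 fold change of condition means. Not a replacement for
#' a moderated count model on real data.
#'
#' @param mat numeric matrix, genes x samples.
#' @param colsA,colsB column indices (or names) of the two groups, each
#'   of size at least 2.
#' @param pseudocount added before logging (default 0.01).
#' @return \code{data.frame} with \code{geneId}, \code{log2FC}
#'   (A over B), \code{p} (raw), \code{adjP} (Benjamini-Hochberg).
#' @export
welchDE <- function(mat, colsA, colsB, pseudocount = 0.01) {
  a <- mat[, colsA, drop = FALSE]
  b <- mat[, colsB, drop = FALSE]
  if (ncol(a) < 2L || ncol(b) < 2L)
    stop("each group needs at least 2 replicates")
  la <- log2(a + pseudocount); lb <- log2(b + pseudocount)
  na <- ncol(la); nb <- ncol(lb)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- apply(la, 1, stats::var); vb <- apply(lb, 1, stats::var)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  p[se2 == 0] <- 1        # identical constant groups carry no evidence
  lfc <- log2(rowMeans(a) + pseudocount) - log2(rowMeans(b) + pseudocount)
  data.frame(geneId = rownames(mat), log2FC = lfc, p = p,
             adjP = stats::p.adjust(p, method = "BH"),
             row.names = NULL)
}
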