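## Internal helpers shared across modules.

CONDITIONS <- c("ESC", "EoNeg", "EoPos")
CHIP_MARKS <- c("H3K27Ac", "H3K4me3", "input")

## Deterministic 31-bit sub-seed from a master seed and a string key.
## Polynomial rolling hash; all arithmetic stays below 2^53 so doubles
## are exact. Keying by e.g. "chip|H3K27Ac|ESC|1" gives every simulated
## track its own stream: adding a track never perturbs the others.
.substream <- function(seed, key) {
  h <- 7
  for (code in utf8ToInt(key)) h <- (h * 131 + code) %% 2147483647
  as.integer((h + (as.numeric(seed) %% 2147483647) * 48271) %% 2147483647)
}

## Evaluate expr under a local RNG state; the caller's .Random.seed is
## untouched.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

.checkCondition <- function(condition) {
  if (!condition %in% CONDITIONS)
    stop("unknown condition '", condition, "'; expected one of ",
         paste(CONDITIONS, collapse = ", "))
  condition
}

.checkMark <- function(mark) {
  if (!mark %in% CHIP_MARKS)
    stop("unknown mark '", mark, "'; expected one of ",
         paste(CHIP_MARKS, collapse = ", "))
  mark
}

## GRanges from 0-based half-open triples (the generator plans and BED
## think in 0-based coordinates; GRanges is 1-based closed).
.grFrom0 <- function(chrom, start0, end0, strand = "*", seqlen = NULL) {
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0), strand = strand)
  if (!is.null(seqlen)) seqlengths(gr) <- seqlen[seqlevels(gr)]
  gr
}

## Format a numeric data.frame column-wise at 6 significant digits for
## diffable TSV output (integers and characters pass through).
.writeTsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.readTsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
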