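## internal helpers shared across modules

geometricMean <- function(x) exp(mean(log(x)))

## z-score with the n-1 (sample SD) denominator; errors on zero variance
zstd <- function(x, what = "variable") {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop(sprintf("zero-variance %s cannot be standardized", what), call. = FALSE)
  (x - mean(x)) / s
}

## validate a genes x samples count matrix; returns it as a base matrix
asCountMatrix <- function(counts, minSamples = 2L, minGenes = 2L) {
  if (is(counts, "SenescenceCohort"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  if (is(counts, "Matrix")) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric genes x samples matrix", call. = FALSE)
  if (nrow(counts) < minGenes || ncol(counts) < minSamples)
    stop(sprintf("count matrix must have at least %d genes and %d samples",
                 minGenes, minSamples), call. = FALSE)
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("counts must be nonnegative integers; first violation at gene row %d, sample column %d",
                 bad[1, 1], bad[1, 2]), call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene identifiers in count matrix", call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample identifiers in count matrix", call. = FALSE)
  counts
}

## deterministic child seed, kept within 32-bit integer range
childSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * offset) %% 2147483646L) + 1L
}
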