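#' Relative-log-expression (median-ratio) scale factors
#'
#' For each gene the reference is the geometric mean of its counts across all
#' samples (genes with any zero count have reference 0 and are excluded).
#' Each sample's raw factor is the median over the remaining genes of
#' count/reference; even-length medians are the mean of the two central order
#' statistics.  Raw factors are rescaled so their geometric mean is 1, and
#' the effective library size is the raw library size times the factor.
#'
#' @param counts genes x samples matrix of nonnegative integers (or a
#'   [SenescenceCohort-class]); at least 2 genes and 2 samples.
#' @return a [NormFactors-class] object.
#' @examples
#' m <- matrix(c(10, 20, 30, 40, 20, 40, 60, 80), ncol = 2,
#'             dimnames = list(paste0("g", 1:4), c("A", "B")))
#' normFactors(rleScaleFactors(m))  # (2^-1/2, 2^1/2)
#' @export
rleScaleFactors <- function(counts) {
  counts <- asCountMatrix(counts)
  ref <- exp(rowMeans(log(counts)))
  keep <- is.finite(ref) & ref > 0
  if (!any(keep))
    stop(paste("no gene has strictly positive counts in every sample;",
               "filter all-zero-containing genes before RLE normalization"),
         call. = FALSE)
  ratios <- counts[keep, , drop = FALSE] / ref[keep]
  raw <- apply(ratios, 2, stats::median)
  if (!all(is.finite(raw)) || any(raw <= 0))
    stop("median-ratio factors are not finite and positive", call. = FALSE)
  factors <- raw / geometricMean(raw)
  lib <- colSums(counts)
  nm <- colnames(counts)
  if (!is.null(nm)) {
    names(factors) <- nm
    names(lib) <- nm
  }
  new("NormFactors", factors = factors, libSizes = lib,
      effectiveLibSizes = lib * factors, nGenesUsed = sum(keep))
}

#' Log2 counts-per-million with a library-size-scaled prior count
#'
#' For sample j with effective library size \eqn{L_j} and mean effective
#' library size \eqn{\bar L}, the scaled prior is
#' \eqn{p_j = \mathrm{priorCount} \cdot L_j / \bar L} and
#' \deqn{\mathrm{value}(g,j) = \log_2\!\big((c_{gj} + p_j) / (L_j + 2 p_j)
#'   \times 10^6\big).}
#' Zero counts map to finite values for any positive prior, and values are
#' strictly increasing in the count within a sample.
#'
#' @param counts genes x samples matrix of nonnegative integers.
#' @param factors a [NormFactors-class] from [rleScaleFactors()], or a numeric
#'   vector of per-sample factors (effective library = column sum x factor).
#'   Ignored when \code{effectiveLibSizes} is given.
#' @param priorCount positive prior count (default 2).
#' @param effectiveLibSizes optional per-sample effective library sizes,
#'   overriding \code{factors}.
#' @return numeric matrix of log2-CPM values with attribute
#'   \code{"priorCount"}.
#' @examples
#' m <- matrix(c(998, 2), ncol = 1, dimnames = list(c("g1", "g2"), "A"))
#' log2Cpm(m, effectiveLibSizes = 1e6)["g1", ]  # log2(1000/1000004 * 1e6)
#' @export
log2Cpm <- function(counts, factors = NULL, priorCount = 2,
                    effectiveLibSizes = NULL) {
  if (is(counts, "SenescenceCohort"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  counts <- asCountMatrix(counts, minSamples = 1L, minGenes = 1L)
  if (!is.numeric(priorCount) || length(priorCount) != 1L || priorCount <= 0)
    stop("priorCount must be a single positive number", call. = FALSE)
  if (is.null(effectiveLibSizes)) {
    if (is(factors, "NormFactors")) {
      effectiveLibSizes <- factors@effectiveLibSizes
    } else if (is.numeric(factors)) {
      effectiveLibSizes <- colSums(counts) * factors
    } else {
      stop("supply RLE factors or effectiveLibSizes", call. = FALSE)
    }
  }
  if (length(effectiveLibSizes) != ncol(counts))
    stop("effective library sizes do not align with samples", call. = FALSE)
  if (any(!is.finite(effectiveLibSizes)) || any(effectiveLibSizes <= 0))
    stop("effective library sizes must be positive and finite", call. = FALSE)
  p <- priorCount * effectiveLibSizes / mean(effectiveLibSizes)
  out <- log2(sweep(sweep(counts, 2, p, "+"), 2,
                    effectiveLibSizes + 2 * p, "/") * 1e6)
  dimnames(out) <- dimnames(counts)
  structure(out, priorCount = priorCount)
}

#' Normalize a cohort to log2-CPM
#'
#' Convenience wrapper: computes RLE factors on the cohort's counts and
#' returns the cohort with a \code{"log2cpm"} assay added; the
#' [NormFactors-class] object is stored in \code{metadata(x)$normFactors}.
#'
#' @param cohort a [SenescenceCohort-class].
#' @param priorCount positive prior count (default 2).
#' @return the cohort with assay \code{"log2cpm"}.
#' @export
normalizeCohort <- function(cohort, priorCount = 2) {
  stopifnot(is(cohort, "SenescenceCohort"))
  counts <- SummarizedExperiment::assay(cohort, "counts")
  nf <- rleScaleFactors(counts)
  expr <- log2Cpm(counts, nf, priorCount = priorCount)
  SummarizedExperiment::assay(cohort, "log2cpm") <- expr
  S4Vectors::metadata(cohort)$normFactors <- nf
  cohort
}
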