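#' Per-gene z-score standardization of an expression matrix
#'
#' Each retained gene's log2-CPM values are centered and scaled across
#' samples with the sample-SD (n-1) denominator, so every retained row has
#' mean 0 and SD 1.  Genes with zero variance are excluded (never divided by
#' zero) and listed with a reason.
#'
#' @param expr genes x samples numeric matrix of log2-CPM values.
#' @return list with \code{values} (standardized matrix over retained genes)
#'   and \code{excluded} (data.frame with columns \code{gene}, \code{reason}).
#' @examples
#' z <- zscoreGenes(matrix(1:6, 2, 3, dimnames = list(c("a", "b"), NULL)))
#' z$values["a", ]  # (-1, 0, 1)
#' @export
zscoreGenes <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expr must be a numeric genes x samples matrix", call. = FALSE)
  if (ncol(expr) < 2L)
    stop("z-scoring requires at least 2 samples", call. = FALSE)
  m <- rowMeans(expr)
  sds <- apply(expr, 1, stats::sd)
  keep <- is.finite(sds) & sds > 0
  excluded <- data.frame(gene = rownames(expr)[!keep],
                         reason = rep("zero variance", sum(!keep)),
                         stringsAsFactors = FALSE)
  if (!any(keep))
    stop("no scoreable genes: every gene has zero variance", call. = FALSE)
  values <- (expr[keep, , drop = FALSE] - m[keep]) / sds[keep]
  list(values = values, excluded = excluded)
}

#' Composite score over one gene set
#'
#' The per-sample score is the unweighted mean of the z-scored log2-CPM
#' values of the set's member genes,
#' \eqn{\mathrm{Score}_i = G^{-1} \sum_g z(g, i)}; higher values indicate a
#' stronger senescence expression signal.  Under the default
#' \code{missingPolicy = "error"}, any member absent from the matrix or
#' excluded as zero-variance aborts with the offending gene names; under
#' \code{"drop"} such members are skipped and the genes actually averaged
#' are recorded.
#'
#' @param std result of [zscoreGenes()] (or a bare standardized matrix).
#' @param geneSet character vector of member gene ids.
#' @param missingPolicy \code{"error"} (default) or \code{"drop"}.
#' @return numeric per-sample score vector with attribute \code{"gUsed"}.
#' @examples
#' z <- zscoreGenes(matrix(rnorm(40), 4, 10,
#'                  dimnames = list(paste0("g", 1:4), NULL)))
#' s <- compositeScore(z, c("g1", "g2"))
#' attr(s, "gUsed")
#' @export
compositeScore <- function(std, geneSet, missingPolicy = c("error", "drop")) {
  missingPolicy <- match.arg(missingPolicy)
  z <- if (is.list(std)) std$values else std
  geneSet <- trimws(geneSet)
  if (anyDuplicated(geneSet))
    stop("gene set contains duplicate members", call. = FALSE)
  present <- geneSet[geneSet %in% rownames(z)]
  missing <- setdiff(geneSet, present)
  if (missingPolicy == "error" && length(missing))
    stop(sprintf("gene set members missing or excluded from the expression matrix: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (!length(present))
    stop("no gene set members present in the expression matrix", call. = FALSE)
  score <- colMeans(z[present, , drop = FALSE])
  structure(score, gUsed = length(present))
}

#' @describeIn scoreAll score a log2-CPM matrix with every set in a
#'   collection.  Z-scoring is applied once; each configured score is the
#'   mean of the standardized values over its member genes (the summary
#'   score averages over the deduplicated union, not the three sub-scores).
#' @param collection a [SenGeneSetCollection-class].
#' @param missingPolicy passed to [compositeScore()].
#' @export
setMethod("scoreAll", "matrix", function(x, collection,
                                         missingPolicy = c("error", "drop")) {
  missingPolicy <- match.arg(missingPolicy)
  stopifnot(is(collection, "SenGeneSetCollection"))
  std <- zscoreGenes(x)
  cols <- lapply(names(collection), function(nm)
    compositeScore(std, collection[[nm]], missingPolicy))
  out <- data.frame(sample_id = colnames(x), stringsAsFactors = FALSE)
  if (is.null(out$sample_id)) out$sample_id <- sprintf("S%05d", seq_len(ncol(x)))
  for (i in seq_along(cols)) out[[names(collection)[i]]] <- as.numeric(cols[[i]])
  rownames(out) <- out$sample_id
  structure(out,
            gUsed = stats::setNames(vapply(cols, attr, integer(1), "gUsed"),
                                    names(collection)),
            excludedGenes = std$excluded)
})

#' @describeIn scoreAll normalize a cohort (RLE + log2-CPM) and score it with
#'   its own gene-set collection.
#' @param priorCount prior count for [log2Cpm()].
#' @export
setMethod("scoreAll", "SenescenceCohort",
          function(x, missingPolicy = c("error", "drop"), priorCount = 2) {
  expr <- if ("log2cpm" %in% SummarizedExperiment::assayNames(x))
    SummarizedExperiment::assay(x, "log2cpm")
  else
    SummarizedExperiment::assay(normalizeCohort(x, priorCount), "log2cpm")
  scoreAll(expr, geneSets(x), missingPolicy = missingPolicy)
})

#' Overlap report for a gene-set collection
#'
#' Thin wrapper over [overlapMatrix()] returning a tidy data.frame of the
#' pairwise intersection counts (diagonal = set sizes).
#'
#' @param collection a [SenGeneSetCollection-class] with at least 2 sets.
#' @return data.frame with columns \code{set1}, \code{set2}, \code{overlap}.
#' @export
overlapReport <- function(collection) {
  stopifnot(is(collection, "SenGeneSetCollection"))
  if (length(collection) < 2L)
    stop("overlap report needs at least 2 sets", call. = FALSE)
  m <- overlapMatrix(collection)
  idx <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE)
  data.frame(set1 = rownames(m)[idx[, 1]], set2 = colnames(m)[idx[, 2]],
             overlap = m[idx], stringsAsFactors = FALSE)
}
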