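#' @include AllClasses.R
NULL

#' Pairwise gene-set overlap table
#'
#' Symmetric matrix of pairwise intersection sizes between all sets in a
#' collection; the diagonal holds set sizes.
#'
#' @param object a [SenGeneSetCollection-class] (or object carrying one).
#' @return integer matrix, sets x sets.
#' @examples
#' gsc <- SenGeneSetCollection(list(A = c("x", "y"), B = c("y", "z")))
#' overlapMatrix(gsc)
#' @export
setGeneric("overlapMatrix", function(object) standardGeneric("overlapMatrix"))

#' Extract the gene-set collection
#' @param object a [SenescenceCohort-class].
#' @return a [SenGeneSetCollection-class].
#' @export
setGeneric("geneSets", function(object) standardGeneric("geneSets"))

#' Extract the generator truth record
#' @param object a [SenescenceCohort-class].
#' @return list with latent factor, programmed effects, loadings, batch shifts.
#' @export
setGeneric("truthRecord", function(object) standardGeneric("truthRecord"))

#' Extract the phenotype table
#' @param object a [SenescenceCohort-class].
#' @return base data.frame of per-sample covariates, outcomes and weights.
#' @export
setGeneric("phenotypes", function(object) standardGeneric("phenotypes"))

#' Compute all composite scores
#'
#' @param x an expression matrix (genes x samples, log2-CPM) or a
#'   [SenescenceCohort-class] (normalized internally).
#' @param ... passed to methods; see [scoreAll,matrix-method].
#' @return data.frame of per-sample scores, one column per gene set.
#' @export
setGeneric("scoreAll", function(x, ...) standardGeneric("scoreAll"))
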