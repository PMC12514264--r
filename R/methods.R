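#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn overlapMatrix pairwise intersections of a collection.
#' @export
setMethod("overlapMatrix", "SenGeneSetCollection", function(object) {
  nms <- names(object@sets)
  out <- matrix(0L, length(nms), length(nms), dimnames = list(nms, nms))
  for (i in seq_along(nms))
    for (j in seq_along(nms))
      out[i, j] <- length(intersect(object@sets[[i]], object@sets[[j]]))
  out
})

#' @describeIn overlapMatrix overlaps of a cohort's gene sets.
#' @export
setMethod("overlapMatrix", "SenescenceCohort",
          function(object) overlapMatrix(object@geneSets))

#' Set names in a collection
#' @param x a SenGeneSetCollection.
#' @export
setMethod("names", "SenGeneSetCollection", function(x) names(x@sets))

#' Number of sets
#' @param x a SenGeneSetCollection.
#' @export
setMethod("length", "SenGeneSetCollection", function(x) length(x@sets))

#' Extract one gene set's members
#' @param x a SenGeneSetCollection.
#' @param i set name or index.
#' @export
setMethod("[[", "SenGeneSetCollection", function(x, i) x@sets[[i]])

#' Roles of the sets in a collection
#' @param object a SenGeneSetCollection.
#' @return named character vector of roles.
#' @export
geneSetRoles <- function(object) object@roles

setMethod("show", "SenGeneSetCollection", function(object) {
  cat("SenGeneSetCollection with", length(object@sets), "sets\n")
  sizes <- vapply(object@sets, length, integer(1))
  for (nm in names(object@sets))
    cat(sprintf("  %-10s role=%-8s %d genes\n", nm, object@roles[[nm]], sizes[[nm]]))
})

setMethod("show", "NormFactors", function(object) {
  cat("NormFactors for", length(object@factors), "samples;",
      object@nGenesUsed, "reference genes\n")
  cat("  factor range: [", format(min(object@factors), digits = 4), ",",
      format(max(object@factors), digits = 4), "]\n")
})

#' @describeIn SenescenceCohort-class gene-set accessor.
#' @param object a SenescenceCohort.
#' @export
setMethod("geneSets", "SenescenceCohort", function(object) object@geneSets)

#' @describeIn SenescenceCohort-class truth-record accessor.
#' @export
setMethod("truthRecord", "SenescenceCohort", function(object) object@truth)

#' @describeIn SenescenceCohort-class phenotype table as a data.frame.
#' @export
setMethod("phenotypes", "SenescenceCohort", function(object) {
  as.data.frame(SummarizedExperiment::colData(object))
})

setMethod("show", "SenescenceCohort", function(object) {
  cat("SenescenceCohort:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("  gene sets:", paste(names(object@geneSets), collapse = ", "), "\n")
  cat("  phenotype columns:",
      paste(utils::head(colnames(SummarizedExperiment::colData(object)), 8),
            collapse = ", "),
      if (ncol(SummarizedExperiment::colData(object)) > 8) "..." else "", "\n")
})

#' Per-sample factors from a NormFactors object
#' @param object a [NormFactors-class].
#' @return named numeric vector of factors (geometric mean 1).
#' @export
normFactors <- function(object) {
  stopifnot(is(object, "NormFactors"))
  object@factors
}

#' Effective library sizes from a NormFactors object
#' @param object a [NormFactors-class].
#' @return named numeric vector, \code{libSizes * factors}.
#' @export
effectiveLibSizes <- function(object) {
  stopifnot(is(object, "NormFactors"))
  object@effectiveLibSizes
}
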