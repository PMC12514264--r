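#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.VALID_ROLES <- c("CSP", "SIP", "SRP", "summary", "SenMayo", "custom")

#' Collection of named senescence gene sets
#'
#' Holds the gene lists the composite scores are computed over: the canonical
#' senescence pathway (CSP, cell-cycle arrest), the senescence-initiating
#' pathway (SIP, macromolecular damage), the senescence response pathway
#' (SRP, SASP), their deduplicated union ("summary") and a SenMayo-style SASP
#' list.  Each set carries a role so downstream code can locate the summary
#' union and report pairwise overlaps.
#'
#' @slot sets named list of character vectors (unique, nonempty gene ids).
#' @slot roles named character vector, one of \code{CSP, SIP, SRP, summary,
#'   SenMayo, custom}, parallel to \code{sets}.
#'
#' @seealso [generateGeneSets()], [overlapMatrix()], [readGmt()]
#' @export
setClass("SenGeneSetCollection",
         representation(sets = "list", roles = "character"))

setValidity("SenGeneSetCollection", function(object) {
  msgs <- character()
  sets <- object@sets
  if (length(sets) == 0L) msgs <- c(msgs, "collection is empty")
  nms <- names(sets)
  if (is.null(nms) || anyNA(nms) || any(nms == ""))
    msgs <- c(msgs, "all gene sets must be named")
  if (anyDuplicated(nms)) msgs <- c(msgs, "duplicate gene-set names")
  for (nm in nms) {
    members <- sets[[nm]]
    if (!is.character(members) || length(members) == 0L)
      msgs <- c(msgs, sprintf("set '%s' must be a nonempty character vector", nm))
    else {
      if (anyDuplicated(members))
        msgs <- c(msgs, sprintf("set '%s' contains duplicate members", nm))
      if (anyNA(members) || any(members == ""))
        msgs <- c(msgs, sprintf("set '%s' contains missing/empty gene ids", nm))
    }
  }
  if (!identical(sort(names(object@roles)), sort(nms)))
    msgs <- c(msgs, "roles must be named parallel to sets")
  if (!all(object@roles %in% .VALID_ROLES))
    msgs <- c(msgs, sprintf("roles must be among: %s",
                            paste(.VALID_ROLES, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Construct a SenGeneSetCollection
#'
#' @param sets named list of character vectors of gene ids.
#' @param roles optional named character vector of roles; when missing, roles
#'   are inferred from set names that match a known role (case-insensitive),
#'   with everything else marked \code{"custom"}.
#' @return a [SenGeneSetCollection-class] object.
#' @examples
#' gsc <- SenGeneSetCollection(list(CSP = c("A", "B"), SIP = c("B", "C")))
#' overlapMatrix(gsc)
#' @export
SenGeneSetCollection <- function(sets, roles = NULL) {
  sets <- lapply(sets, function(m) trimws(as.character(m)))
  if (is.null(roles)) {
    roles <- vapply(names(sets), function(nm) {
      hit <- match(tolower(nm), tolower(.VALID_ROLES))
      if (is.na(hit)) "custom" else .VALID_ROLES[hit]
    }, character(1))
  }
  if (is.null(names(roles))) names(roles) <- names(sets)
  new("SenGeneSetCollection", sets = sets, roles = roles)
}

#' Relative-log-expression scale factors
#'
#' Per-sample scale factors from the median-ratio (RLE) rule: each gene's
#' reference is the geometric mean of its counts across samples, a sample's
#' raw factor is the median across usable genes of count/reference, and the
#' raw factors are rescaled to geometric mean 1.  The effective library size
#' is the raw library size multiplied by the factor.
#'
#' @slot factors per-sample positive factors, geometric mean 1.
#' @slot libSizes per-sample raw library sizes (column sums).
#' @slot effectiveLibSizes \code{libSizes * factors}.
#' @slot nGenesUsed number of genes with a positive geometric-mean reference.
#' @seealso [rleScaleFactors()], [log2Cpm()]
#' @export
setClass("NormFactors",
         representation(factors = "numeric", libSizes = "numeric",
                        effectiveLibSizes = "numeric", nGenesUsed = "integer"))

setValidity("NormFactors", function(object) {
  msgs <- character()
  f <- object@factors
  if (length(f) != length(object@libSizes) ||
      length(f) != length(object@effectiveLibSizes))
    msgs <- c(msgs, "factors, libSizes, effectiveLibSizes lengths differ")
  if (!all(is.finite(f)) || any(f <= 0))
    msgs <- c(msgs, "all factors must be finite and > 0")
  else if (abs(exp(mean(log(f))) - 1) > 1e-10)
    msgs <- c(msgs, "geometric mean of factors must be 1 (+/- 1e-10)")
  if (length(msgs)) msgs else TRUE
})

#' Synthetic senescence cohort container
#'
#' A \code{SummarizedExperiment} carrying the raw count matrix (assay
#' \code{"counts"}, genes x samples) with per-sample phenotypes in
#' \code{colData}, plus the gene-set collection used for scoring and the
#' generator's truth record (latent senescence factor, programmed effects,
#' gene loadings, batch shifts) for parameter-recovery tests.
#'
#' @slot geneSets a [SenGeneSetCollection-class].
#' @slot truth list with elements \code{latent}, \code{covariateEffects},
#'   \code{outcomeEffects}, \code{loadings}, \code{batchShifts}, \code{seed}.
#' @seealso [generateCohort()], [scoreAll()], [runModelGrid()]
#' @export
setClass("SenescenceCohort",
         contains = "SummarizedExperiment",
         representation(geneSets = "SenGeneSetCollection", truth = "list"))

setValidity("SenescenceCohort", function(object) {
  msgs <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'counts' is required")
  else {
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(cnt < 0) || any(cnt != round(cnt)))
      msgs <- c(msgs, "counts must be nonnegative integers")
  }
  lat <- object@truth$latent
  if (!is.null(lat) && length(lat) != ncol(object))
    msgs <- c(msgs, "truth$latent length must equal the number of samples")
  if (length(msgs)) msgs else TRUE
})
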