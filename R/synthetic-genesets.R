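## Deterministic allocation of gene-set membership over the gene universe.
## Pairwise overlaps are realised as disjoint shared blocks (no triple
## intersections), so every configured pairwise count is met exactly.
allocateGeneSets <- function(cfg) {
  sizes <- cfg$geneSetSizes
  ov <- cfg$overlaps
  setNames <- names(sizes)
  universe <- sprintf("GENE%05d", seq_len(cfg$nGenes))

  shared <- vapply(setNames, function(nm) {
    sum(vapply(names(ov), function(p) {
      pair <- strsplit(p, ".", fixed = TRUE)[[1]]
      if (nm %in% pair) as.integer(ov[[p]]) else 0L
    }, integer(1)))
  }, integer(1))
  over <- shared > sizes[setNames]
  if (any(over))
    stop(sprintf("infeasible overlap geometry: set '%s' needs %d shared genes but has size %d",
                 setNames[over][1], shared[over][1],
                 sizes[setNames[over][1]]), call. = FALSE)
  nDistinct <- sum(sizes) - sum(ov)
  if (nDistinct > cfg$nGenes)
    stop(sprintf("infeasible overlap geometry: %d distinct set genes exceed the %d-gene universe",
                 nDistinct, cfg$nGenes), call. = FALSE)

  members <- stats::setNames(vector("list", length(setNames)), setNames)
  for (nm in setNames) members[[nm]] <- integer(0)
  cursor <- 1L
  take <- function(k) {
    idx <- seq.int(cursor, length.out = k)
    cursor <<- cursor + k
    idx
  }
  for (p in names(ov)) {
    k <- as.integer(ov[[p]])
    if (k == 0L) next
    pair <- strsplit(p, ".", fixed = TRUE)[[1]]
    block <- take(k)
    ## the SIP/SRP shared genes are the two sentinel identifiers that the
    ## summary union must deduplicate
    if (setequal(pair, c("SIP", "SRP")) && k >= 1L) {
      sentinels <- c("IGFBP7", "AKT1")
      universe[block[seq_len(min(k, 2L))]] <- sentinels[seq_len(min(k, 2L))]
    }
    for (nm in pair) members[[nm]] <- c(members[[nm]], block)
  }
  for (nm in setNames)
    members[[nm]] <- sort(c(members[[nm]], take(sizes[[nm]] - length(members[[nm]]))))

  list(universe = universe,
       sets = lapply(members, function(ix) universe[ix]))
}

#' Generate the senescence gene-set collection
#'
#' Builds named gene sets with exactly the configured sizes and pairwise
#' overlaps over the configured gene universe, plus the deduplicated
#' CSP/SIP/SRP union as the summary set.  With the defaults this reproduces
#' the published geometry: sets of 22/48/44/125 genes, the two sentinel genes
#' (IGFBP7, AKT1) shared between SIP and SRP, a 112-gene summary union, and
#' SenMayo overlapping CSP/SIP/SRP by 1/4/22 genes.
#'
#' @param config a [cohortConfig()] object.
#' @return a [SenGeneSetCollection-class] including the \code{summary} set.
#' @examples
#' gsc <- generateGeneSets(cohortConfig())
#' length(gsc[["summary"]])  # 112
#' overlapMatrix(gsc)["SenMayo", c("CSP", "SIP", "SRP")]
#' @export
generateGeneSets <- function(config) {
  validateCohortConfig(config)
  alloc <- allocateGeneSets(config)
  sets <- alloc$sets
  if (all(c("CSP", "SIP", "SRP") %in% names(sets)))
    sets$summary <- buildSummarySet(sets$CSP, sets$SIP, sets$SRP)
  roles <- vapply(names(sets), function(nm)
    if (nm %in% .VALID_ROLES) nm else "custom", character(1))
  SenGeneSetCollection(sets, roles)
}

#' Deduplicated union of the three pathway sets
#'
#' The summary score averages each gene once: genes appearing in more than
#' one of CSP/SIP/SRP (the sentinel pair IGFBP7/AKT1 under the defaults)
#' enter the union a single time.
#'
#' @param csp,sip,srp character vectors of gene ids.
#' @return character vector, the deduplicated union in first-appearance order.
#' @examples
#' buildSummarySet(c("a", "b"), c("b", "c"), "d")
#' @export
buildSummarySet <- function(csp, sip, srp) {
  stopifnot(is.character(csp), is.character(sip), is.character(srp))
  unique(c(csp, sip, srp))
}
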