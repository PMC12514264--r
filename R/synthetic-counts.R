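#' Generate negative-binomial RNA-seq counts
#'
#' Counts for gene g in sample j are drawn from a negative binomial with
#' dispersion \eqn{\theta} and log-mean
#' \deqn{\log\mu_{gj} = b_g + o_j + \delta_{batch(j)} + \lambda_g s_j,}
#' where \eqn{b_g} is a per-gene baseline, \eqn{o_j} a log-normal library
#' offset, \eqn{\delta} an additive gene-independent batch shift and
#' \eqn{\lambda_g} a loading that is nonzero only on genes belonging to the
#' senescence gene sets, multiplying the sample's latent factor \eqn{s_j}.
#'
#' @param config a [cohortConfig()] object.
#' @param phenotypes phenotype data.frame from [generatePhenotypes()] (needs
#'   \code{sample_id} and \code{batch}).
#' @param truth truth record from [generatePhenotypes()]; must contain the
#'   latent factor.  Pre-existing \code{loadings}/\code{batchShifts} entries
#'   are reused, otherwise they are drawn here.
#' @param geneSets optional [SenGeneSetCollection-class]; regenerated from
#'   \code{config} when missing (needed to place the loadings).
#' @param seed integer seed (derived from \code{config$seed} by default so
#'   phenotype and count draws do not share a stream).
#' @return integer matrix, genes x samples, with attributes \code{loadings},
#'   \code{batchShifts}, \code{baselines} and \code{libOffsets}.
#' @examples
#' cfg <- cohortConfig(nSamples = 20, nGenes = 300, seed = 5)
#' ph <- generatePhenotypes(cfg)
#' cnt <- generateCounts(cfg, ph$phenotypes, ph$truth)
#' dim(cnt)
#' @export
generateCounts <- function(config, phenotypes, truth,
                           geneSets = NULL, seed = childSeed(config$seed, 1L)) {
  validateCohortConfig(config)
  if (is.null(truth$latent))
    stop("truth record must contain the latent factor", call. = FALSE)
  if (is.null(geneSets)) geneSets <- generateGeneSets(config)
  set.seed(seed)

  n <- nrow(phenotypes)
  universe <- allocateGeneSets(config)$universe
  G <- length(universe)
  s <- as.numeric(truth$latent)
  if (length(s) != n)
    stop("latent factor length does not match the phenotype table", call. = FALSE)

  baselines <- truth$baselines
  if (is.null(baselines))
    baselines <- stats::setNames(
      stats::runif(G, config$baselineLogMeanRange[1],
                   config$baselineLogMeanRange[2]), universe)
  libOffsets <- stats::rnorm(n, 0, config$libSizeLogSd)
  batchLevels <- levels(phenotypes$batch)
  batchShifts <- truth$batchShifts
  if (is.null(batchShifts))
    batchShifts <- stats::setNames(
      stats::rnorm(length(batchLevels), 0, config$batchEffectSd), batchLevels)
  loadings <- truth$loadings
  if (is.null(loadings)) {
    loadings <- stats::setNames(numeric(G), universe)
    scored <- intersect(universe,
                        unique(unlist(geneSets@sets[geneSets@roles != "summary"])))
    loadings[scored] <- stats::runif(length(scored), config$loadingRange[1],
                                     config$loadingRange[2])
  }

  logMu <- outer(baselines, libOffsets + batchShifts[as.character(phenotypes$batch)],
                 "+") + outer(loadings, s)
  if (!all(is.finite(logMu)))
    stop("non-finite log-means in count generation; check config scales",
         call. = FALSE)
  counts <- matrix(stats::rnbinom(G * n, mu = exp(logMu),
                                  size = config$nbDispersion),
                   nrow = G, ncol = n,
                   dimnames = list(universe, phenotypes$sample_id))
  storage.mode(counts) <- "integer"
  structure(counts, loadings = loadings, batchShifts = batchShifts,
            baselines = baselines, libOffsets = libOffsets)
}

#' Generate a complete synthetic cohort
#'
#' Composes [generateGeneSets()], [generatePhenotypes()] and
#' [generateCounts()] into a consistent [SenescenceCohort-class]: sample ids
#' agree between counts and phenotypes, gene-set members are rows of the
#' count matrix, and the truth record stores the latent factor, programmed
#' effects, gene loadings and batch shifts.
#'
#' @param config a [cohortConfig()] object.
#' @return a [SenescenceCohort-class].
#' @examples
#' coh <- generateCohort(cohortConfig(nSamples = 30, nGenes = 300, seed = 11))
#' coh
#' @export
generateCohort <- function(config) {
  validateCohortConfig(config)
  gs <- generateGeneSets(config)
  ph <- generatePhenotypes(config, seed = config$seed)
  counts <- generateCounts(config, ph$phenotypes, ph$truth, geneSets = gs,
                           seed = childSeed(config$seed, 1L))
  truth <- ph$truth
  truth$loadings <- attr(counts, "loadings")
  truth$batchShifts <- attr(counts, "batchShifts")
  for (a in c("loadings", "batchShifts", "baselines", "libOffsets"))
    attr(counts, a) <- NULL
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(ph$phenotypes,
                                   row.names = ph$phenotypes$sample_id))
  new("SenescenceCohort", se, geneSets = gs, truth = truth)
}
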