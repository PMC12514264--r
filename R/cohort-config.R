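.COVARIATE_KEYS <- c("age_group", "female", "race", "education", "bmi_class",
                     "pack_years", "weekly_drinks", "insomnia")
.OUTCOME_KEYS <- c("pace", "clock_aa", "bioage_aa", "cognition",
                   "multimorbidity", "mortality")

#' Configuration for the synthetic-cohort generator
#'
#' Bundles every population parameter of the generator.  The defaults emulate
#' the cohort the scoring pipeline targets: 3580 older adults with
#' negative-binomial bulk RNA-seq counts, four senescence gene lists sized
#' 22 (CSP), 48 (SIP), 44 (SRP) and 125 (SenMayo) with 2 genes shared between
#' SIP and SRP and SenMayo overlapping CSP/SIP/SRP by 1/4/22, 46 batch plates,
#' a 6-year mortality rate of 16.2\%, and a latent senescence factor loading
#' on the senescence genes and linked to covariates and aging outcomes.
#'
#' @param nSamples number of samples (default 3580).
#' @param nGenes size of the gene universe (default 1000); must exceed the
#'   number of distinct senescence genes.
#' @param geneSetSizes named integer vector of set sizes for
#'   \code{CSP, SIP, SRP, SenMayo}.
#' @param overlaps named integer vector of pairwise shared-gene counts, names
#'   of the form \code{"SET1.SET2"}; pairs not listed are disjoint.  Triple
#'   intersections are not generated.
#' @param nbDispersion negative-binomial dispersion \eqn{\theta}
#'   (variance \eqn{\mu + \mu^2/\theta}); default 10.
#' @param baselineLogMeanRange range (natural-log scale) of per-gene baseline
#'   expected counts; default \code{log(c(5, 500))}.
#' @param libSizeLogSd SD of the per-sample log library-size offset.
#' @param nBatches number of batch plates (default 46).
#' @param batchEffectSd SD of additive per-batch log-scale shifts, shared by
#'   all genes in a sample.
#' @param loadingRange range of per-gene loadings of senescence-set genes on
#'   the latent factor (log scale per SD of the factor).
#' @param covariateEffects named numeric vector of standardized effects of
#'   covariates on the latent senescence factor.  Allowed names:
#'   \code{age_group, female, race, education, bmi_class, pack_years,
#'   weekly_drinks, insomnia}.
#' @param outcomeEffects named numeric vector of standardized effects of the
#'   latent factor on outcomes (\code{pace, clock_aa, bioage_aa, cognition,
#'   multimorbidity}); for \code{mortality} the value is the log-odds per SD
#'   of the factor.
#' @param mortalityRate marginal 6-year mortality probability (default 0.162).
#' @param presumedAliveFraction fraction of survivors recorded as "presumed
#'   alive" (vital status 2) rather than contacted alive (status 1).
#' @param missingVitalFraction fraction of samples with missing vital status.
#' @param missingBioageFraction fraction of samples with missing biological
#'   age (default matches 2660 observed of 3580).
#' @param weightAgeLink logical; tilt survey weights by age group so that
#'   weighting is consequential, then rescale to mean 1.
#' @param seed integer seed; every generator consumes it deterministically.
#'
#' @return a validated list of class \code{"CohortConfig"}.
#' @examples
#' cfg <- cohortConfig(nSamples = 200, nGenes = 300, seed = 7)
#' cfg$geneSetSizes
#' @export
cohortConfig <- function(nSamples = 3580L,
                         nGenes = 1000L,
                         geneSetSizes = c(CSP = 22L, SIP = 48L, SRP = 44L,
                                          SenMayo = 125L),
                         overlaps = c(SIP.SRP = 2L, CSP.SenMayo = 1L,
                                      SIP.SenMayo = 4L, SRP.SenMayo = 22L),
                         nbDispersion = 10,
                         baselineLogMeanRange = log(c(5, 500)),
                         libSizeLogSd = 0.2,
                         nBatches = 46L,
                         batchEffectSd = 0.1,
                         loadingRange = c(0.15, 0.35),
                         covariateEffects = c(age_group = 0.12, female = 0.05,
                                              bmi_class = 0.06,
                                              weekly_drinks = 0.03),
                         outcomeEffects = c(pace = 0.24, clock_aa = 0.20,
                                            bioage_aa = 0.20,
                                            cognition = -0.07,
                                            multimorbidity = 0.35,
                                            mortality = log(1.52)),
                         mortalityRate = 0.162,
                         presumedAliveFraction = 0.1,
                         missingVitalFraction = 26 / 3580,
                         missingBioageFraction = 1 - 2660 / 3580,
                         weightAgeLink = TRUE,
                         seed = 1L) {
  cfg <- list(nSamples = as.integer(nSamples), nGenes = as.integer(nGenes),
              geneSetSizes = geneSetSizes, overlaps = overlaps,
              nbDispersion = nbDispersion,
              baselineLogMeanRange = baselineLogMeanRange,
              libSizeLogSd = libSizeLogSd, nBatches = as.integer(nBatches),
              batchEffectSd = batchEffectSd, loadingRange = loadingRange,
              covariateEffects = covariateEffects,
              outcomeEffects = outcomeEffects,
              mortalityRate = mortalityRate,
              presumedAliveFraction = presumedAliveFraction,
              missingVitalFraction = missingVitalFraction,
              missingBioageFraction = missingBioageFraction,
              weightAgeLink = isTRUE(weightAgeLink),
              seed = as.integer(seed))
  class(cfg) <- "CohortConfig"
  validateCohortConfig(cfg)
  cfg
}

validateCohortConfig <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$nSamples < 1L || cfg$nGenes < 1L)
    stop("nSamples and nGenes must be positive", call. = FALSE)
  sizes <- cfg$geneSetSizes
  if (is.null(names(sizes)) || any(sizes < 1))
    stop("geneSetSizes must be a named vector of positive sizes", call. = FALSE)
  ov <- cfg$overlaps
  if (length(ov)) {
    if (is.null(names(ov)) || any(ov < 0))
      stop("overlaps must be named nonnegative counts", call. = FALSE)
    for (nm in names(ov)) {
      pair <- strsplit(nm, ".", fixed = TRUE)[[1]]
      if (length(pair) != 2L || !all(pair %in% names(sizes)))
        stop(sprintf("overlap '%s' does not name two known sets", nm),
             call. = FALSE)
      if (ov[[nm]] > min(sizes[pair]))
        stop(sprintf("overlap '%s' (%d) exceeds the smaller set size (%d)",
                     nm, ov[[nm]], min(sizes[pair])), call. = FALSE)
    }
  }
  for (p in c("mortalityRate", "presumedAliveFraction",
              "missingVitalFraction", "missingBioageFraction"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop(sprintf("%s must lie in [0, 1]", p), call. = FALSE)
  if (cfg$mortalityRate <= 0 || cfg$mortalityRate >= 1)
    stop("mortalityRate must lie strictly in (0, 1)", call. = FALSE)
  if (cfg$nbDispersion <= 0) stop("nbDispersion must be positive", call. = FALSE)
  if (cfg$libSizeLogSd < 0 || cfg$batchEffectSd < 0)
    stop("libSizeLogSd and batchEffectSd must be nonnegative", call. = FALSE)
  if (diff(cfg$baselineLogMeanRange) < 0)
    stop("baselineLogMeanRange must be an increasing interval", call. = FALSE)
  ce <- cfg$covariateEffects
  if (length(ce)) {
    bad <- setdiff(names(ce), .COVARIATE_KEYS)
    if (length(bad))
      stop(sprintf("unknown covariate effect(s): %s (allowed: %s)",
                   paste(bad, collapse = ", "),
                   paste(.COVARIATE_KEYS, collapse = ", ")), call. = FALSE)
    if (sum(ce^2) >= 1)
      stop("sum of squared covariate effects must be < 1 so the latent factor has unit variance",
           call. = FALSE)
  }
  oe <- cfg$outcomeEffects
  if (length(oe)) {
    bad <- setdiff(names(oe), .OUTCOME_KEYS)
    if (length(bad))
      stop(sprintf("unknown outcome effect(s): %s (allowed: %s)",
                   paste(bad, collapse = ", "),
                   paste(.OUTCOME_KEYS, collapse = ", ")), call. = FALSE)
    cont <- setdiff(names(oe), "mortality")
    if (any(abs(oe[cont]) >= 1))
      stop("standardized continuous outcome effects must have |effect| < 1",
           call. = FALSE)
  }
  invisible(cfg)
}
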