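.AGE_LEVELS <- c("55-64", "65-74", "75-84", "85+")
.RACE_LEVELS <- c("NH White", "NH Black", "Hispanic", "NH Other")
.EDU_LEVELS <- c("Less than HS", "High School", "Some College", "College+")
.BMI_LEVELS <- c("Not Overweight/Obese", "Overweight", "Obesity I", "Obesity II")

## numeric encoding of a covariate for the latent-factor linear combination
.covariateNumeric <- function(ph, key) {
  switch(key,
         age_group = as.numeric(ph$age_group),
         female = ph$female,
         race = as.numeric(ph$race),
         education = as.numeric(ph$education),
         bmi_class = as.numeric(ph$bmi_class),
         pack_years = ph$pack_years,
         weekly_drinks = ph$weekly_drinks,
         insomnia = ph$insomnia,
         stop(sprintf("unknown covariate '%s'", key), call. = FALSE))
}

## standardized latent factor s_i = sum_c beta_c z(x_c) + noise, Var ~ 1
.latentFactor <- function(ph, effects) {
  n <- nrow(ph)
  lin <- numeric(n)
  for (key in names(effects))
    lin <- lin + effects[[key]] * zstd(.covariateNumeric(ph, key), key)
  resid <- 1 - sum(effects^2)
  lin + stats::rnorm(n, 0, sqrt(resid))
}

## gamma survey weights, mean 1; optionally tilted by age group
.surveyWeights <- function(ph, ageLink) {
  w <- stats::rgamma(nrow(ph), shape = 4, rate = 4)
  if (ageLink) {
    tilt <- c(0.85, 0.95, 1.1, 1.3)[as.numeric(ph$age_group)]
    w <- w * tilt
  }
  w / mean(w)
}

#' Generate the per-sample phenotype table and truth record
#'
#' Draws demographics and behaviors with marginals patterned on a
#' population-representative cohort of US adults aged 56+ (four age groups,
#' 54\% women, four race/ethnicity and education and BMI classes, pack-years,
#' weekly drinks, insomnia), assigns batch plates and gamma survey weights
#' (mean 1), builds a standardized latent senescence factor as a linear
#' combination of the configured covariates plus noise, and generates
#' outcomes linked to the factor at the programmed standardized effects:
#' a pace-of-aging measure (mean 1, SD 0.1), an epigenetic-clock age
#' acceleration (SD 4 years), biological age (chronological age plus an
#' 8.1-year-SD acceleration), cognition (0-27, rounded), multimorbidity
#' (binomial on 5 conditions with a logit link), and 4-category vital status
#' from which 6-year mortality is coded (statuses 3/4 deceased, 1/2 alive).
#'
#' @param config a [cohortConfig()] object.
#' @param seed integer seed (defaults to \code{config$seed}).
#' @return list with elements \code{phenotypes} (data.frame) and \code{truth}
#'   (list with \code{latent}, \code{covariateEffects}, \code{outcomeEffects},
#'   \code{seed}).
#' @examples
#' ph <- generatePhenotypes(cohortConfig(nSamples = 50, seed = 3))
#' table(ph$phenotypes$vital_status, useNA = "ifany")
#' @export
generatePhenotypes <- function(config, seed = config$seed) {
  validateCohortConfig(config)
  set.seed(seed)
  n <- config$nSamples
  ph <- data.frame(
    sample_id = sprintf("S%05d", seq_len(n)),
    age_group = factor(sample(.AGE_LEVELS, n, TRUE,
                              prob = c(0.405, 0.352, 0.172, 0.071)),
                       levels = .AGE_LEVELS),
    female = stats::rbinom(n, 1, 0.544),
    race = factor(sample(.RACE_LEVELS, n, TRUE,
                         prob = c(0.775, 0.102, 0.089, 0.034)),
                  levels = .RACE_LEVELS),
    education = factor(sample(.EDU_LEVELS, n, TRUE,
                              prob = c(0.140, 0.299, 0.259, 0.302)),
                       levels = .EDU_LEVELS),
    bmi_class = factor(sample(.BMI_LEVELS, n, TRUE,
                              prob = c(0.238, 0.374, 0.227, 0.161)),
                       levels = .BMI_LEVELS),
    stringsAsFactors = FALSE)
  ## continuous age consistent with the group (85+ capped at 95)
  lo <- c(56, 65, 75, 85)[as.numeric(ph$age_group)]
  hi <- c(64, 74, 84, 95)[as.numeric(ph$age_group)]
  ph$age_years <- round(stats::runif(n, lo, hi + 1 - 1e-9))
  ## zero-inflated exposures: never-users at 0, gamma among users
  smoker <- stats::rbinom(n, 1, 0.57)
  ph$pack_years <- smoker * stats::rgamma(n, shape = 1, scale = 23)
  drinker <- stats::rbinom(n, 1, 0.45)
  ph$weekly_drinks <- drinker * stats::rgamma(n, shape = 1, scale = 6.4)
  ph$insomnia <- stats::rbinom(n, 1, 0.204)
  ph$batch <- factor(sprintf("B%02d", sample.int(config$nBatches, n, TRUE)),
                     levels = sprintf("B%02d", seq_len(config$nBatches)))
  ph$weight <- .surveyWeights(ph, config$weightAgeLink)

  s <- .latentFactor(ph, config$covariateEffects)
  oe <- config$outcomeEffects
  eff <- function(key) if (key %in% names(oe)) oe[[key]] else 0
  mix <- function(g) g * s + sqrt(1 - g^2) * stats::rnorm(n)

  ph$pace <- 1 + 0.1 * mix(eff("pace"))
  ph$clock_aa <- 4.0 * mix(eff("clock_aa"))
  ph$bioage <- ph$age_years + 8.1 * mix(eff("bioage_aa"))
  ph$cognition <- pmin(27, pmax(0, round(15.5 + 4.3 * mix(eff("cognition")))))
  pMM <- stats::plogis(stats::qlogis(0.16) + eff("multimorbidity") * s)
  ph$multimorbidity <- stats::rbinom(n, 5, pMM)

  ## marginal mortality rate is calibrated by solving for the intercept
  gM <- eff("mortality")
  alpha <- stats::uniroot(function(a) mean(stats::plogis(a + gM * s)) -
                            config$mortalityRate,
                          interval = c(-30, 30))$root
  dead <- stats::rbinom(n, 1, stats::plogis(alpha + gM * s))
  vital <- ifelse(dead == 1,
                  sample(c(3L, 4L), n, TRUE),
                  ifelse(stats::runif(n) < config$presumedAliveFraction, 2L, 1L))
  vital[stats::runif(n) < config$missingVitalFraction] <- NA_integer_
  ph$vital_status <- vital
  ph$mortality <- ifelse(is.na(vital), NA_integer_,
                         as.integer(vital %in% c(3L, 4L)))
  ph$bioage[stats::runif(n) < config$missingBioageFraction] <- NA_real_

  ## immune cell-type proportions (logistic-normal around typical blood
  ## composition, mildly tilted by the latent factor)
  base <- c(prop_gran = 58, prop_nk = 4, prop_b = 4,
            prop_cd4 = 17, prop_cd8 = 9, prop_mono = 8)
  tilt <- c(0.25, -0.2, -0.2, -0.25, -0.15, 0.1)
  g <- matrix(stats::rgamma(n * 6L,
                            shape = rep(base, each = n) *
                              exp(outer(s, tilt)) * 2),
              nrow = n)
  props <- g / rowSums(g)
  colnames(props) <- names(base)
  ph <- cbind(ph, as.data.frame(props))
  rownames(ph) <- ph$sample_id

  truth <- list(latent = stats::setNames(s, ph$sample_id),
                covariateEffects = config$covariateEffects,
                outcomeEffects = config$outcomeEffects,
                mortalityIntercept = alpha,
                seed = seed)
  list(phenotypes = ph, truth = truth)
}
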