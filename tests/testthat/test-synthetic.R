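test_that("identical config and seed reproduce the cohort bit for bit", {
  cfg <- smallConfig(n = 60, genes = 250, seed = 42)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(SummarizedExperiment::assay(a, "counts"),
                   SummarizedExperiment::assay(b, "counts"))
  expect_identical(phenotypes(a), phenotypes(b))
  expect_identical(truthRecord(a)$latent, truthRecord(b)$latent)
  # different seeds give different counts
  c2 <- generateCohort(smallConfig(n = 60, genes = 250, seed = 43))
  expect_false(identical(SummarizedExperiment::assay(a, "counts"),
                         SummarizedExperiment::assay(c2, "counts")))
})

test_that("cohort components are mutually consistent", {
  coh <- generateCohort(smallConfig(n = 50, genes = 250, seed = 3))
  cnt <- SummarizedExperiment::assay(coh, "counts")
  ph <- phenotypes(coh)
  expect_identical(colnames(cnt), ph$sample_id)
  expect_identical(names(truthRecord(coh)$latent), ph$sample_id)
  expect_true(all(cnt >= 0) && all(cnt == round(cnt)))
  expect_true(all(unlist(geneSets(coh)@sets) %in% rownames(cnt)))
  expect_identical(truthRecord(coh)$covariateEffects,
                   smallConfig(n = 50)$covariateEffects)
})

test_that("requested sample size is honored", {
  ph <- generatePhenotypes(cohortConfig(nSamples = 3580, seed = 1))
  expect_equal(nrow(ph$phenotypes), 3580L)
})

test_that("with zero loadings and batch effects, gene means match the NB expectation", {
  cfg <- cohortConfig(nSamples = 400, nGenes = 150, nBatches = 3,
                      geneSetSizes = c(CSP = 3, SIP = 4, SRP = 5,
                                       SenMayo = 6),
                      overlaps = integer(0),
                      batchEffectSd = 0, loadingRange = c(0, 0), seed = 9)
  ph <- generatePhenotypes(cfg)
  cnt <- generateCounts(cfg, ph$phenotypes, ph$truth)
  mu <- exp(outer(attr(cnt, "baselines"), attr(cnt, "libOffsets"), "+"))
  expMean <- rowMeans(mu)
  # NB variance mu + mu^2/theta; Monte-Carlo SE of the per-gene mean
  mcSe <- sqrt(rowSums(mu + mu^2 / cfg$nbDispersion)) / ncol(cnt)
  dev <- abs(rowMeans(cnt) - expMean)
  expect_true(mean(dev <= 3 * mcSe) > 0.97)
})

test_that("large dispersion approaches the Poisson variance/mean limit", {
  cfg <- cohortConfig(nSamples = 2000, nGenes = 60, nBatches = 2,
                      geneSetSizes = c(CSP = 3, SIP = 4, SRP = 5,
                                       SenMayo = 6),
                      overlaps = integer(0),
                      nbDispersion = 1e8, libSizeLogSd = 0,
                      batchEffectSd = 0, loadingRange = c(0, 0), seed = 5)
  ph <- generatePhenotypes(cfg)
  cnt <- generateCounts(cfg, ph$phenotypes, ph$truth)
  ratio <- apply(cnt, 1, var) / rowMeans(cnt)
  expect_true(all(abs(ratio - 1) < 0.15))
  expect_lt(abs(median(ratio) - 1), 0.05)
})

test_that("mortality is coded from vital status (3/4 deceased, 1/2 alive)", {
  ph <- generatePhenotypes(smallConfig(n = 2000, seed = 8))$phenotypes
  ok <- !is.na(ph$vital_status)
  expect_setequal(unique(ph$vital_status[ok]), 1:4)
  expect_equal(ph$mortality[ok], as.integer(ph$vital_status[ok] %in% 3:4))
  expect_true(all(is.na(ph$mortality[!ok])))
})

test_that("phenotype ranges and weights respect their invariants", {
  ph <- generatePhenotypes(smallConfig(n = 1500, seed = 21))$phenotypes
  expect_true(all(ph$cognition >= 0 & ph$cognition <= 27))
  expect_true(all(ph$multimorbidity %in% 0:5))
  expect_true(all(ph$weight > 0))
  expect_equal(mean(ph$weight), 1, tolerance = 1e-12)
  expect_true(all(ph$pack_years >= 0) && all(ph$weekly_drinks >= 0))
  expect_equal(nlevels(ph$age_group), 4L)
  props <- as.matrix(ph[, grep("^prop_", names(ph))])
  expect_equal(unname(rowSums(props)), rep(1, nrow(ph)), tolerance = 1e-12)
})

test_that("unknown effect keys are a configuration error", {
  expect_error(cohortConfig(covariateEffects = c(shoe_size = 0.2)),
               "unknown covariate")
  expect_error(cohortConfig(outcomeEffects = c(happiness = 0.2)),
               "unknown outcome")
})

test_that("with all effects zero the latent factor is uncorrelated with outcomes", {
  cfg <- nullConfig(n = 3000, seed = 13)
  ph <- generatePhenotypes(cfg)
  s <- ph$truth$latent
  bound <- 3 / sqrt(cfg$nSamples)
  for (v in c("pace", "clock_aa", "cognition", "multimorbidity"))
    expect_lt(abs(cor(s, ph$phenotypes[[v]])), bound)
})

test_that("programmed standardized effects are present in the generated outcomes", {
  # Monte-Carlo over seeds: empirical standardized association of a
  # continuous outcome with the latent factor recovers the programmed 0.25
  est <- vapply(1:50, function(sd) {
    cfg <- cohortConfig(nSamples = 3000, seed = sd,
                        outcomeEffects = c(clock_aa = 0.25))
    ph <- generatePhenotypes(cfg)
    cor(ph$truth$latent, ph$phenotypes$clock_aa)
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.25), 0.05)
})

test_that("marginal mortality rate is calibrated to the configured value", {
  cfg <- cohortConfig(nSamples = 20000, seed = 77)
  ph <- generatePhenotypes(cfg)$phenotypes
  expect_lt(abs(mean(ph$mortality, na.rm = TRUE) - 0.162), 0.01)
})
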