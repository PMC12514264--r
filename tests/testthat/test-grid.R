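fakeScoredTable <- function(n = 250, seed = 1, nScores = 5) {
  ph <- generatePhenotypes(smallConfig(n = n, batches = 4, seed = seed))
  tab <- ph$phenotypes
  s <- ph$truth$latent
  set.seed(seed + 1000)
  for (i in seq_len(nScores))
    tab[[paste0("score", i)]] <- 0.8 * s + 0.6 * rnorm(n)
  attr(tab, "latent") <- s
  tab
}

test_that("grid cardinality: each outcome family fits one model per outcome x score", {
  tab <- fakeScoredTable(n = 250, seed = 2)
  res <- runModelGrid(tab, scoreNames = paste0("score", 1:5),
                      families = "outcomes",
                      linearOutcomes = c("pace", "clock_aa", "cognition",
                                         "multimorbidity"),
                      logisticOutcomes = character(0))
  focal <- res[res$focal, ]
  expect_equal(nrow(focal), 20L)
  expect_equal(sort(unique(focal$outcome)),
               c("clock_aa", "cognition", "multimorbidity", "pace"))
  # deterministic ordering
  res2 <- runModelGrid(tab, scoreNames = paste0("score", 1:5),
                       families = "outcomes",
                       linearOutcomes = c("pace", "clock_aa", "cognition",
                                          "multimorbidity"),
                       logisticOutcomes = character(0))
  expect_identical(res, res2)
})

test_that("FDR adjustment is applied within outcome families and respects invariants", {
  tab <- fakeScoredTable(n = 250, seed = 5)
  res <- runModelGrid(tab, scoreNames = paste0("score", 1:5),
                      families = c("scores", "outcomes"),
                      linearOutcomes = c("pace", "clock_aa"),
                      logisticOutcomes = "mortality")
  focal <- res[res$focal, ]
  expect_true(all(focal$fdr.p >= focal$p.value - 1e-14))
  expect_true(all(focal$fdr.p <= 1))
  oneFam <- focal[focal$family == "outcomes" & focal$outcome == "pace", ]
  expect_equal(oneFam$fdr.p, bhFdr(oneFam$p.value), tolerance = 1e-14)
  byTerm <- focal[focal$family == "scores" & focal$term == "female", ]
  expect_equal(byTerm$fdr.p, bhFdr(byTerm$p.value), tolerance = 1e-14)
})

test_that("mortality models in the grid use logistic regression with ORs", {
  tab <- fakeScoredTable(n = 500, seed = 7)
  res <- runModelGrid(tab, scoreNames = "score1", families = "outcomes",
                      linearOutcomes = character(0),
                      logisticOutcomes = "mortality")
  focal <- res[res$focal, ]
  expect_equal(nrow(focal), 1L)
  expect_true(is.finite(focal$or) && focal$or > 0)
  expect_equal(focal$or, exp(focal$estimate))
})

test_that("adding a mediating pace covariate attenuates the focal coefficient", {
  fitFocal <- function(tab, spec) {
    d <- standardizeVariables(buildAnalysisSample(tab, spec), spec)
    f <- fitLinearWeighted(d$y, d$X, d$weights)
    f$estimate[f$term == "score1"]
  }
  deltas <- vapply(1:20, function(sd) {
    set.seed(sd)
    n <- 800
    s <- rnorm(n)
    tab <- data.frame(
      score1 = 0.8 * s + 0.6 * rnorm(n),
      pace = 1 + 0.1 * (0.6 * s + 0.8 * rnorm(n)),
      clock_aa = 4 * (0.3 * s + sqrt(1 - 0.09) * rnorm(n)),
      weight = 1)
    spec0 <- modelSpec("clock_aa", "linear", focal = "score1", batch = FALSE)
    spec1 <- modelSpec("clock_aa", "linear", focal = "score1", batch = FALSE,
                       extra = "pace")
    b0 <- fitFocal(tab, spec0)
    b1 <- fitFocal(tab, spec1)
    abs(b0) - abs(b1)
  }, numeric(1))
  expect_gt(mean(deltas), 0)
  expect_gt(mean(deltas > 0), 0.9)
})

test_that("per-model failures are recorded and the run continues", {
  tab <- fakeScoredTable(n = 200, seed = 9)
  tab$broken <- NA_real_
  res <- runModelGrid(tab, scoreNames = "score1", families = "outcomes",
                      linearOutcomes = c("pace", "broken"),
                      logisticOutcomes = character(0))
  expect_equal(sum(res$focal), 1L)
  fails <- attr(res, "failures")
  expect_equal(nrow(fails), 1L)
  expect_equal(fails$outcome, "broken")
})

test_that("a cohort is scored and modeled end to end", {
  coh <- generateCohort(smallConfig(n = 150, genes = 1000, batches = 3,
                                    seed = 12))
  res <- runModelGrid(coh, families = "outcomes",
                      linearOutcomes = "clock_aa",
                      logisticOutcomes = character(0))
  focal <- res[res$focal, ]
  expect_equal(nrow(focal), 5L)  # CSP, SIP, SRP, SenMayo, summary
  expect_setequal(focal$score, c("CSP", "SIP", "SRP", "SenMayo", "summary"))
  expect_true(all(focal$n == 150))
})
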