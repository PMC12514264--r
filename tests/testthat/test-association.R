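makePhen <- function() {
  data.frame(sample_id = paste0("s", 1:4),
             vital_status = c(1L, 2L, 3L, 4L),
             score = c(0.1, -0.2, 0.3, 0),
             weight = 1, stringsAsFactors = FALSE)
}

test_that("mortality is derived from vital status and presumed-alive can be excluded", {
  spec <- modelSpec("mortality", "logistic", focal = "score", batch = FALSE)
  tab <- buildAnalysisSample(makePhen(), spec)
  expect_equal(tab$mortality, c(0L, 0L, 1L, 1L))
  spec2 <- modelSpec("mortality", "logistic", focal = "score", batch = FALSE,
                     excludePresumedAlive = TRUE)
  tab2 <- buildAnalysisSample(makePhen(), spec2)
  expect_equal(nrow(tab2), 3L)
  expect_false(2L %in% tab2$vital_status)
  expect_error(buildAnalysisSample(transform(makePhen(), vital_status = 5L),
                                   spec), "unknown vital-status")
})

test_that("complete-case filtering is model-specific", {
  ph <- data.frame(y = c(1, 2, 3, 4), a = c(1, NA, 3, 4), b = 1:4,
                   weight = 1)
  specA <- modelSpec("y", "linear", focal = "a", batch = FALSE)
  specB <- modelSpec("y", "linear", focal = "b", batch = FALSE)
  expect_equal(attr(buildAnalysisSample(ph, specA), "n"), 3L)
  expect_equal(attr(buildAnalysisSample(ph, specB), "n"), 4L)
  expect_error(buildAnalysisSample(ph[0, ], specB), "empty")
})

test_that("standardization z-scores continuous variables and expands dummies", {
  ph <- generatePhenotypes(smallConfig(n = 300, batches = 46, seed = 4))$phenotypes
  ph$score <- rnorm(300)
  spec <- modelSpec("pace", "linear", focal = "score",
                    covariates = c("age_group", "female"), batch = TRUE)
  d <- standardizeVariables(buildAnalysisSample(ph, spec), spec)
  expect_equal(mean(d$X[, "score"]), 0, tolerance = 1e-10)
  expect_equal(sd(d$X[, "score"]), 1, tolerance = 1e-10)
  expect_equal(mean(d$y), 0, tolerance = 1e-10)
  expect_length(grep("^age_group", colnames(d$X)), 3L)
  expect_length(grep("^batch", colnames(d$X)), 45L)
  # 0/1 indicators are left binary
  expect_setequal(unique(d$X[, "female"]), c(0, 1))
  # toy z-score
  toy <- data.frame(y = c(1, 5, 9), x = c(2, 4, 6), weight = 1)
  spec2 <- modelSpec("y", "linear", focal = "x", batch = FALSE)
  d2 <- standardizeVariables(buildAnalysisSample(toy, spec2), spec2)
  expect_equal(unname(d2$X[, "x"]), c(-1, 0, 1))
  toy$x <- 3
  expect_error(standardizeVariables(buildAnalysisSample(toy, spec2), spec2),
               "zero-variance.*x")
})

test_that("weighted least squares recovers a perfect fit and flags collinearity", {
  x <- rnorm(40)
  fit <- fitLinearWeighted(x, cbind(x = x))
  expect_equal(fit$estimate[fit$term == "x"], 1, tolerance = 1e-10)
  expect_equal(attr(fit, "r.squared"), 1, tolerance = 1e-10)
  X <- cbind(a = x, b = 2 * x)
  expect_error(fitLinearWeighted(rnorm(40), X), "collinear.*b")
})

test_that("null focal effects are rejected at close to the nominal rate", {
  set.seed(31)
  hits <- vapply(1:100, function(i) {
    y <- rnorm(400)
    x <- rnorm(400)
    fit <- fitLinearWeighted(y, cbind(x = x), weights = rgamma(400, 4, 4))
    abs(fit$statistic[fit$term == "x"]) > 3
  }, logical(1))
  expect_gte(mean(!hits), 0.95)
})

test_that("frequency-weight equivalence holds exactly for linear and logistic fits", {
  set.seed(17)
  n <- 60
  X <- cbind(x = rnorm(n), z = rnorm(n))
  y <- rbinom(n, 1, plogis(0.5 * X[, "x"]))
  w <- rep(1, n); w[1:30] <- 2
  Xexp <- X[c(1:n, 1:30), ]
  yexp <- y[c(1:n, 1:30)]
  lin <- fitLinearWeighted(y, X, weights = w)
  linExp <- fitLinearWeighted(yexp, Xexp)
  expect_equal(lin$estimate, linExp$estimate, tolerance = 1e-10)
  log1 <- fitLogisticWeighted(y, X, weights = w)
  log2 <- fitLogisticWeighted(yexp, Xexp)
  expect_equal(log1$estimate, log2$estimate, tolerance = 1e-8)
})

test_that("logistic fit reports ORs and guards against degenerate outcomes", {
  set.seed(23)
  x <- rnorm(500)
  y <- rbinom(500, 1, plogis(-1 + 0.5 * x))
  fit <- fitLogisticWeighted(y, cbind(x = x))
  expect_equal(fit$or[fit$term == "x"], exp(fit$estimate[fit$term == "x"]))
  expect_true(all(fit$or > 0))
  expect_error(fitLogisticWeighted(rep(1, 10), cbind(x = rnorm(10))),
               "single class")
  # complete separation
  xs <- c(rnorm(20, -3), rnorm(20, 3))
  ys <- rep(c(0, 1), each = 20)
  expect_error(fitLogisticWeighted(ys, cbind(x = xs)), "separation")
})

test_that("null logistic confidence intervals cover OR = 1 at about 95%", {
  set.seed(41)
  covered <- vapply(1:100, function(i) {
    y <- rbinom(400, 1, 0.3)
    x <- rnorm(400)
    fit <- fitLogisticWeighted(y, cbind(x = x))
    fit$or.low[1] <= 1 && fit$or.high[1] >= 1
  }, logical(1))
  expect_gte(mean(covered), 0.90)
})

test_that("age-acceleration residuals behave like OLS residuals", {
  age <- c(60, 65, 70, 80, 90)
  expect_equal(ageAccelResiduals(age, age), rep(0, 5), tolerance = 1e-12)
  expect_equal(ageAccelResiduals(age + 7, age), rep(0, 5), tolerance = 1e-12)
  set.seed(2)
  bio <- age + rnorm(5, 0, 3)
  r <- ageAccelResiduals(bio, age)
  expect_lt(abs(mean(r)), 1e-10)
  # missing inputs propagate, fit uses complete pairs
  r2 <- ageAccelResiduals(c(bio, NA), c(age, 70))
  expect_true(is.na(r2[6]))
  expect_equal(r2[1:5], r, tolerance = 1e-12)
  expect_error(ageAccelResiduals(bio, rep(70, 5)), "constant")
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bhFdr(0.03), 0.03)
  expect_equal(bhFdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)),
               bruteBhStepUp(c(0.01, 0.02, 0.03, 0.04)), tolerance = 1e-14)
  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    adj <- bhFdr(p)
    expect_equal(adj, bruteBhStepUp(p), tolerance = 1e-13)
    expect_true(all(adj >= p) && all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
  expect_error(bhFdr(c(0.2, 1.3)), "\\[0, 1\\]")
  expect_error(bhFdr(c(0.2, NA)), "finite")
})

test_that("BH adjustment preserves p-value ordering and is idempotent on rejection sets", {
  set.seed(10)
  p <- runif(30)
  adj <- bhFdr(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  adj2 <- bhFdr(adj)
  for (alpha in c(0.05, 0.1, 0.25))
    expect_identical(which(adj2 <= alpha), which(bhFdr(p) <= alpha))
})

test_that("cross-validation is seeded, exact on noiseless data, and honest on noise", {
  n <- 200
  tab <- data.frame(y = NA, x = rnorm(n), weight = 1)
  tab$y <- 2 * tab$x + 1
  spec <- modelSpec("y", "linear", focal = "x", batch = FALSE)
  cv <- kfoldCv(spec, tab, k = 5, seed = 3)
  expect_equal(cv$cvR2, 1, tolerance = 1e-8)
  expect_equal(cv$fullR2, 1, tolerance = 1e-8)
  cv2 <- kfoldCv(spec, tab, k = 5, seed = 3)
  expect_identical(cv$perFold, cv2$perFold)
  # pure noise: out-of-sample R^2 hovers at or below zero
  set.seed(6)
  r2s <- vapply(1:50, function(i) {
    tabN <- data.frame(y = rnorm(500), x = rnorm(500), weight = 1)
    kfoldCv(spec, tabN, k = 5, seed = i)$cvR2
  }, numeric(1))
  expect_lte(mean(r2s), 0.02)
})

test_that("logistic cross-validation stratifies folds on the outcome", {
  set.seed(44)
  n <- 300
  tab <- data.frame(vital_status = sample(c(1L, 1L, 1L, 3L), n, TRUE),
                    x = rnorm(n), weight = 1)
  spec <- modelSpec("mortality", "logistic", focal = "x", batch = FALSE)
  cv <- kfoldCv(spec, tab, k = 5, seed = 2)
  expect_equal(cv$k, 5L)
  expect_true(all(is.finite(cv$perFold$rmse)))
  # a class smaller than k cannot be stratified
  tab2 <- tab
  tab2$vital_status <- c(rep(3L, 3), rep(1L, n - 3))
  expect_error(kfoldCv(spec, tab2, k = 5, seed = 2), "stratified")
})
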