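test_that("identical columns give unit factors", {
  m <- matrix(rep(c(5L, 10L, 20L, 40L), 3), ncol = 3,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  nf <- rleScaleFactors(m)
  expect_equal(unname(normFactors(nf)), rep(1, 3), tolerance = 1e-12)
  expect_equal(unname(effectiveLibSizes(nf)), unname(colSums(m)),
               tolerance = 1e-12)
})

test_that("a gene-wise doubled sample yields factors (2^-1/2, 2^1/2)", {
  a <- c(10L, 25L, 40L, 100L)
  m <- cbind(A = a, B = 2L * a)
  rownames(m) <- paste0("g", 1:4)
  expect_equal(unname(normFactors(rleScaleFactors(m))),
               c(2^-0.5, 2^0.5), tolerance = 1e-12)
})

test_that("factors match the brute-force median-ratio oracle", {
  set.seed(101)
  for (i in 1:25) {
    m <- randomCountMatrix(10, 5)
    expect_equal(unname(normFactors(rleScaleFactors(m))),
                 bruteRleFactors(m), tolerance = 1e-12)
  }
  # a toy matrix with an even number of usable genes exercises the
  # mean-of-central-order-statistics median
  m <- matrix(c(2L, 4L, 8L, 16L,
                3L, 5L, 9L, 15L,
                4L, 8L, 16L, 40L), nrow = 4,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  expect_equal(unname(normFactors(rleScaleFactors(m))), bruteRleFactors(m),
               tolerance = 1e-12)
})

test_that("raw median ratios agree with edgeR's RLE factors after convention change", {
  skip_if_not_installed("edgeR")
  set.seed(7)
  m <- randomCountMatrix(40, 6, lambda = 120)
  mine <- normFactors(rleScaleFactors(m))
  # edgeR stores factor = median-ratio / library size, geometric mean 1
  converted <- (mine / colSums(m))
  converted <- converted / exp(mean(log(converted)))
  theirs <- edgeR::calcNormFactors(m, method = "RLE")
  expect_equal(unname(converted), unname(theirs), tolerance = 1e-10)
})

test_that("scale equivariance: scaling one sample scales only its raw factor", {
  set.seed(11)
  m <- randomCountMatrix(12, 4)
  rawFactors <- function(x) {
    ref <- exp(rowMeans(log(x)))
    apply(x[ref > 0, ] / ref[ref > 0], 2, median)
  }
  m2 <- m
  m2[, 2] <- m2[, 2] * 3L
  r1 <- rawFactors(m)
  r2 <- rawFactors(m2)
  scale1 <- (3)^(1 / ncol(m))  # reference shifts by 3^(1/n) for every gene
  expect_equal(unname(r2[2] / r1[2]), 3 / scale1, tolerance = 1e-12)
  expect_equal(unname(r2[-2] / r1[-2]), rep(1 / scale1, 3), tolerance = 1e-12)
})

test_that("RLE errors are informative", {
  m <- matrix(c(0L, 5L, 3L, 0L), 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_error(rleScaleFactors(m), "filter")
  expect_error(rleScaleFactors(matrix(1:4, ncol = 1)), "at least")
})

test_that("log2-CPM follows the scaled-prior formula", {
  m <- matrix(c(998L, 2L), ncol = 1, dimnames = list(c("g1", "g2"), "A"))
  out <- log2Cpm(m, effectiveLibSizes = 1e6, priorCount = 2)
  expect_equal(unname(out["g1", 1]), log2((998 + 2) / (1e6 + 4) * 1e6),
               tolerance = 1e-12)
  # scaled prior: p_j = prior * L_j / mean(L)
  m2 <- matrix(c(10L, 30L, 20L, 60L), 2,
               dimnames = list(c("g1", "g2"), c("a", "b")))
  L <- c(100, 300)
  out2 <- log2Cpm(m2, effectiveLibSizes = L, priorCount = 2)
  p <- 2 * L / mean(L)
  expect_equal(unname(out2[1, ]),
               log2((c(10, 20) + p) / (L + 2 * p) * 1e6), tolerance = 1e-12)
})

test_that("log2-CPM matches edgeR's cpm on shared effective library sizes", {
  skip_if_not_installed("edgeR")
  set.seed(21)
  m <- randomCountMatrix(30, 5)
  eff <- colSums(m) * runif(5, 0.8, 1.2)
  mine <- log2Cpm(m, effectiveLibSizes = eff, priorCount = 2)
  theirs <- edgeR::cpm(m, lib.size = eff, log = TRUE, prior.count = 2)
  expect_equal(unname(mine), unname(theirs), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("log2-CPM is symmetric, monotone and finite on zeros", {
  m <- matrix(5L, 4, 3, dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  out <- log2Cpm(m, rep(1, 3))
  expect_equal(max(out) - min(out), 0)
  set.seed(3)
  m2 <- randomCountMatrix(20, 3)
  m2[1, 1] <- 0L
  out2 <- log2Cpm(m2, rleScaleFactors(m2[-1, ]))
  expect_true(all(is.finite(out2)))
  # non-decreasing in count within a sample, strict for distinct counts
  ord <- order(m2[, 2])
  expect_true(all(diff(out2[ord, 2]) >= 0))
  a <- which(m2[, 3] == max(m2[, 3]))[1]
  b <- which(m2[, 3] == min(m2[, 3]))[1]
  expect_gt(out2[a, 3], out2[b, 3])
})

test_that("prior and library-size validation", {
  m <- randomCountMatrix(4, 2)
  expect_error(log2Cpm(m, rep(1, 2), priorCount = 0), "positive")
  expect_error(log2Cpm(m, effectiveLibSizes = c(0, 10)), "positive")
  expect_error(log2Cpm(m, effectiveLibSizes = 1), "align")
})

test_that("normalizeCohort adds a log2cpm assay and stores factors", {
  coh <- generateCohort(smallConfig(n = 25, genes = 300, seed = 2))
  coh <- normalizeCohort(coh)
  expect_true("log2cpm" %in% SummarizedExperiment::assayNames(coh))
  nf <- S4Vectors::metadata(coh)$normFactors
  expect_s4_class(nf, "NormFactors")
  expect_equal(exp(mean(log(normFactors(nf)))), 1, tolerance = 1e-10)
})
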