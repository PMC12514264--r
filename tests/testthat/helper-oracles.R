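# Independent brute-force oracles, written straight from the definitions and
# kept free of any package internals.

# median-ratio (RLE) factors: per-gene geometric-mean reference, per-sample
# median of count/reference over genes with a positive reference, rescaled to
# geometric mean 1
bruteRleFactors <- function(counts) {
  ref <- apply(counts, 1, function(g) exp(mean(log(g))))
  usable <- which(is.finite(ref) & ref > 0)
  raw <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    ratios <- sort(counts[usable, j] / ref[usable])
    n <- length(ratios)
    raw[j] <- if (n %% 2 == 1) ratios[(n + 1) / 2]
              else (ratios[n / 2] + ratios[n / 2 + 1]) / 2
  }
  raw / exp(mean(log(raw)))
}

# Benjamini-Hochberg step-up by definition: sort ascending,
# adj_(i) = min_{j >= i} p_(j) * m / j, capped at 1, back to input order
bruteBhStepUp <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    candidates <- sorted[i:m] * m / (i:m)
    adj[i] <- min(1, min(candidates))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# composite score by definition: per-gene z with the n-1 SD denominator,
# then the per-sample mean over the set's genes, via explicit loops
bruteCompositeScore <- function(expr, members) {
  n <- ncol(expr)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (g in members) {
      v <- expr[g, ]
      acc <- acc + (expr[g, i] - mean(v)) / sd(v)
    }
    scores[i] <- acc / length(members)
  }
  scores
}

# small fast generator configuration shared across tests
smallConfig <- function(n = 80, genes = 300, batches = 4, seed = 1, ...) {
  cohortConfig(nSamples = n, nGenes = genes, nBatches = batches,
               seed = seed, ...)
}

# null configuration: no covariate or outcome effects
nullConfig <- function(n = 400, genes = 250, batches = 5, seed = 1) {
  cohortConfig(nSamples = n, nGenes = genes, nBatches = batches, seed = seed,
               covariateEffects = numeric(0),
               outcomeEffects = numeric(0))
}

randomCountMatrix <- function(genes, samples, lambda = 50) {
  matrix(rpois(genes * samples, lambda) + 1L, nrow = genes,
         dimnames = list(paste0("g", seq_len(genes)),
                         paste0("s", seq_len(samples))))
}
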