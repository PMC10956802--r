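# Independent oracles used to cross-check the implementation.

# partial correlation via residual regression: correlate the residuals of
# y on z with the residuals of x on z
oraclePartial <- function(x, y, z) {
  rx <- residuals(lm(x ~ z))
  ry <- residuals(lm(y ~ z))
  r <- cor(rx, ry)
  n <- length(x)
  t <- r * sqrt((n - 3) / (1 - r^2))
  list(r = r, p = 2 * pt(abs(t), df = n - 3, lower.tail = FALSE))
}

# Benjamini-Hochberg step-up by the textbook definition
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- prev
  }
  pmin(adj, 1)
}

# exact hypergeometric upper tail P(X >= k) by log-space tail summation
oracleHyperTail <- function(N, K, n, k) {
  if (k <= 0) return(1)
  j <- k:min(K, n)
  j <- j[n - j <= N - K]
  if (!length(j)) return(0)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

# small helper: matrix with dimnames
namedMatrix <- function(vals, features, samples) {
  matrix(vals, nrow = length(features),
         dimnames = list(features, samples))
}

# a tiny aligned dataset with deterministic values
toyDataset <- function(nGenes = 3, nMirnas = 2, n = 8, seed = 7) {
  set.seed(seed)
  s <- sprintf("S%d", seq_len(n))
  g <- sprintf("G%d", seq_len(nGenes))
  mi <- sprintf("miR-%d", seq_len(nMirnas))
  new("OmicsDataset",
      mrna = namedMatrix(rnorm(nGenes * n), g, s),
      protein = namedMatrix(rnorm(nGenes * n), g, s),
      mirna = namedMatrix(rnorm(nMirnas * n), mi, s))
}

# standard study-condition dataset used by the recovery checks
studyDataset <- function(seed, b = 1.5) {
  generateDataset(synthSpec(nSamples = 100L, nGenes = 50L, nMirnas = 10L,
                            planted = 20L, b = b, noiseSd = 0.5,
                            missingRate = 0.05, seed = seed))
}

runSelection <- function(ds, quartile = 0.75) {
  dset <- suppressMessages(
    preprocessDataset(ds$M, ds$P, ds$MI, pseudocount = 0))
  grid <- suppressMessages(computeGrid(dset))
  list(grid = grid, table = selectInteractions(grid, quartile = quartile),
       dataset = dset)
}
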