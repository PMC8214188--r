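# small fixtures shared across test files -------------------------------

geomean <- function(x) exp(mean(log(x)))

# deterministic Poisson-ish matrix with named dims
tinyCounts <- function(G = 8, n1 = 3, n2 = 3, seed = 42, lambda = 50) {
  set.seed(seed)
  m <- matrix(rpois(G * (n1 + n2), lambda), G, n1 + n2,
              dimnames = list(paste0("g", seq_len(G)),
                              paste0("s", seq_len(n1 + n2))))
  m
}

tinySet <- function(G = 8, n1 = 3, n2 = 3, seed = 42, lambda = 50) {
  DGECountSet(tinyCounts(G, n1, n2, seed, lambda),
              condition = rep(c("A", "B"), c(n1, n2)))
}

# a DGECountSet where both groups are the same constant matrix
constantSet <- function(G = 10, n = 3, value = 20) {
  m <- matrix(value, G, 2 * n,
              dimnames = list(paste0("g", seq_len(G)),
                              paste0("s", seq_len(2 * n))))
  DGECountSet(m, condition = rep(c("A", "B"), each = n))
}

# default simulation used by several engine tests (kept small for speed)
simMedium <- function(seed = 101, ...) {
  simulateCounts(simParams(n_genes = 400, n_samples_per_group = c(10, 10),
                           seed = seed, ...))
}

# independent brute-force conditional exact test: enumerate every split of
# the total, conditional NB (or binomial when phi = 0) probabilities
oracleExactP <- function(t1, T, n1, n2, phi) {
  probs <- vapply(0:T, function(t) {
    if (phi <= 0) {
      exp(lchoose(T, t) + t * log(n1 / (n1 + n2)) +
            (T - t) * log(n2 / (n1 + n2)))
    } else {
      mu <- T / (n1 + n2)
      dnbinom(t, size = n1 / phi, mu = n1 * mu) *
        dnbinom(T - t, size = n2 / phi, mu = n2 * mu)
    }
  }, numeric(1))
  probs <- probs / sum(probs)
  pobs <- probs[t1 + 1]
  min(1, sum(probs[probs <= pobs * (1 + 1e-12)]))
}

# brute-force noise-cloud posterior (double loop)
oracleNoiseqPosterior <- function(noiseM, noiseD, m, d) {
  vapply(seq_along(m), function(g) {
    hits <- 0L
    for (i in seq_along(noiseM)) {
      if (noiseM[i] < m[g] && noiseD[i] < d[g]) hits <- hits + 1L
    }
    hits / length(noiseM)
  }, numeric(1))
}
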