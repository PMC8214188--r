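#' Exact conditional NB test for one gene
#'
#' Conditions on the total count across both groups (after the engine has
#' scaled all samples to a common library size): if the group sums are
#' \eqn{Y_1 \sim NB(n_1/\phi,\ n_1\mu)} and \eqn{Y_2 \sim NB(n_2/\phi,\
#' n_2\mu)}, the two-sided p-value is the sum, over all splits
#' \eqn{(t, T-t)} of the observed total \eqn{T}, of the conditional
#' probabilities no larger than that of the observed split.  Probabilities
#' equal up to a relative 1e-12 are counted into the sum, which makes the
#' test deterministic and conservative at ties.  With \eqn{\phi = 0} the
#' conditional distribution is Binomial(\eqn{T}, \eqn{n_1/(n_1+n_2)}).
#'
#' @param counts_g per-sample counts for one gene (non-negative, assumed
#'   depth-equalized).
#' @param groups two-level factor.
#' @param phi NB dispersion (>= 0).
#' @return two-sided p-value in (0, 1\].
#' @examples
#' nbExactTest(c(6, 0), factor(c("a", "b")), phi = 0)  # 2/64
#' @export
nbExactTest <- function(counts_g, groups, phi) {
  if (any(counts_g < 0)) stop("negative counts")
  if (phi < 0) stop("dispersion must be >= 0")
  groups <- as.factor(groups)
  lev <- levels(groups)
  if (length(lev) != 2L) stop("exactly two groups required")
  n1 <- sum(groups == lev[1]); n2 <- sum(groups == lev[2])
  t1 <- round(sum(counts_g[groups == lev[1]]))
  T <- t1 + round(sum(counts_g[groups == lev[2]]))
  .exactCondP(t1, T, n1, n2, phi)
}

# conditional two-sided p for group-1 total t1 out of total T
.exactCondP <- function(t1, T, n1, n2, phi) {
  if (T == 0) return(1)
  mu <- T / (n1 + n2) # common per-sample mean under the null
  t <- 0:T
  if (phi <= 0) {
    logp <- stats::dbinom(t, T, n1 / (n1 + n2), log = TRUE)
  } else {
    size1 <- n1 / phi; size2 <- n2 / phi
    logp <- stats::dnbinom(t, size = size1, mu = n1 * mu, log = TRUE) +
      stats::dnbinom(T - t, size = size2, mu = n2 * mu, log = TRUE)
  }
  logp <- logp - max(logp)
  p <- exp(logp)
  p <- p / sum(p)
  pobs <- p[t1 + 1]
  min(1, sum(p[p <= pobs * (1 + 1e-12)]))
}
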