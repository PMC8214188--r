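#' Per-gene NB dispersion by pooled method of moments
#'
#' For each gene the within-group method-of-moments estimate
#' \eqn{\hat\phi_k = (v_k - m_k)/m_k^2} (from Var = \eqn{\mu + \phi\mu^2})
#' is pooled across the two groups with weights \eqn{n_k - 1}, clamped at
#' zero, and shrunk toward the 10%-trimmed mean of all gene dispersions:
#' \deqn{\tilde\phi_g = (\hat\phi_g + w\,\bar\phi) / (1 + w).}
#' Moment estimators at small n are noisy; the shrinkage stabilises them
#' the way the compared tools borrow information across genes.
#'
#' @param norm_counts matrix of normalized counts (counts divided by size
#'   factors), genes x samples.
#' @param groups two-level factor of group labels, >= 2 samples per group.
#' @param shrinkage_weight non-negative shrinkage weight `w`; 0 disables
#'   shrinkage.
#' @return numeric vector of per-gene dispersions, all >= 0.
#' @export
estimateNbDispersion <- function(norm_counts, groups, shrinkage_weight = 1) {
  groups <- as.factor(groups)
  .assertTwoGroups(groups)
  if (shrinkage_weight < 0) stop("shrinkage_weight must be >= 0")
  lev <- levels(groups)
  num <- den <- 0
  for (k in lev) {
    x <- norm_counts[, groups == k, drop = FALSE]
    nk <- ncol(x)
    m <- rowMeans(x)
    v <- apply(x, 1, var)
    contrib <- (v - m) / pmax(m, .Machine$double.eps)^2
    num <- num + (nk - 1) * contrib
    den <- den + (nk - 1)
  }
  phi <- pmax(num / den, 0)
  if (shrinkage_weight > 0) {
    center <- mean(phi, trim = 0.1)
    phi <- (phi + shrinkage_weight * center) / (1 + shrinkage_weight)
  }
  pmax(phi, 0)
}

# fit the trend phi(mu) = a0 + a1/mu by least squares on per-gene MoM
# dispersions, coefficients clamped at >= 0
.dispersionTrend <- function(phi, mu) {
  use <- is.finite(phi) & is.finite(mu) & mu > 0
  x <- 1 / mu[use]; y <- phi[use]
  if (sum(use) < 2L) return(c(a0 = mean(y), a1 = 0))
  fit <- stats::lm.fit(cbind(1, x), y)$coefficients
  fit[is.na(fit)] <- 0 # collinear design (e.g. constant means)
  a0 <- max(fit[1], 0); a1 <- max(fit[2], 0)
  if (a0 == 0 && a1 == 0) a0 <- max(mean(y), 0)
  c(a0 = a0, a1 = a1)
}
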