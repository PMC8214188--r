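#' Leave-one-out population of datasets
#'
#' Builds the population used for the slope comparison: `reps` datasets
#' each missing one sample (the group it is removed from and the sample
#' within it are chosen uniformly at random, seeded), plus the unmodified
#' base dataset, giving `reps + 1` datasets in total.
#'
#' @param base a [DGECountSet-class] with >= 3 samples per group (so a
#'   removal leaves >= 2).
#' @param reps number of leave-one-out replicates (default 10, i.e. 11
#'   datasets including the base).
#' @param seed integer seed.
#' @return named list of `DGECountSet`s; element `"base"` is the
#'   unmodified dataset, elements `"loo_<i>"` each lack one sample.
#' @export
makePopulation <- function(base, reps = 10L, seed = 1L) {
  stopifnot(is(base, "DGECountSet"))
  cond <- condition(base)
  if (reps > 0L && any(tabulate(cond) < 3L))
    stop("each group needs >= 3 samples to remove one")
  out <- vector("list", reps + 1L)
  out[[1]] <- base
  nm <- c("base", if (reps > 0L) sprintf("loo_%02d", seq_len(reps)))
  for (i in seq_len(reps)) {
    set.seed(deriveSeed(seed, i))
    g <- sample(levels(cond), 1L)
    victim <- sample(which(cond == g), 1L)
    out[[i + 1L]] <- base[, -victim]
  }
  names(out) <- nm
  out
}

#' OLS slope of relative FDR against retention fraction
#'
#' @param points data.frame (or list) with components `f` and `rel_fdr`;
#'   at least two distinct `f` values.
#' @return list of class `"SlopeRecord"`: `slope`, `intercept`, `points`.
#' @examples
#' fitFdrSlope(data.frame(f = c(0.8, 0.85, 0.9, 0.95, 0.99),
#'                        rel_fdr = c(0.020, 0.015, 0.010, 0.005, 0.001)))
#' @export
fitFdrSlope <- function(points) {
  f <- points$f; y <- points$rel_fdr
  if (length(unique(f)) < 2L) stop("need at least two distinct f values")
  co <- stats::lm.fit(cbind(intercept = 1, f = f), y)$coefficients
  structure(list(slope = unname(co["f"]), intercept = unname(co["intercept"]),
                 points = data.frame(f = f, rel_fdr = y)),
            class = "SlopeRecord")
}

#' Tie-corrected Friedman rank test
#'
#' Ranks treatments within each block (average ranks at ties) and forms
#' the tie-corrected chi-squared statistic
#' \deqn{Q = (k-1) \sum_j (R_j - n(k+1)/2)^2 / (A_1 - C_1),}
#' with \eqn{A_1} the sum of squared ranks and \eqn{C_1 = nk(k+1)^2/4};
#' it reduces to the classic statistic when no ties occur.  When every
#' rank is tied (\eqn{A_1 = C_1}) the statistic is 0 and p = 1.
#'
#' @param values blocks x treatments numeric matrix (no missing cells).
#' @return a [FriedmanResult-class].
#' @export
friedmanTest <- function(values) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("missing cells not supported")
  n <- nrow(values); k <- ncol(values)
  if (n < 2L || k < 2L) stop("need >= 2 blocks and >= 2 treatments")
  rk <- t(apply(values, 1, rank, ties.method = "average"))
  Rj <- colSums(rk)
  A1 <- sum(rk^2)
  C1 <- n * k * (k + 1)^2 / 4
  S <- sum((Rj - n * (k + 1) / 2)^2)
  stat <- if (A1 > C1) (k - 1) * S / (A1 - C1) else 0
  df <- k - 1L
  p <- chi2Sf(stat, df)
  nm <- colnames(values)
  if (is.null(nm)) nm <- paste0("T", seq_len(k))
  new("FriedmanResult", statistic = stat, df = as.integer(df), p.value = p,
      meanRanks = setNames(Rj / n, nm),
      rankMatrix = `colnames<-`(rk, nm), tieCorrected = TRUE)
}

#' Chi-squared survival function
#'
#' Upper-tail probability of the chi-squared distribution (the
#' regularized upper incomplete gamma function); for df = 4 it equals
#' the closed form \eqn{e^{-x/2}(1 + x/2)}.
#'
#' @param x non-negative quantile.
#' @param df positive degrees of freedom.
#' @return p in (0, 1\].
#' @examples
#' chi2Sf(6, 2)       # exp(-3)
#' chi2Sf(34.545, 4)  # ~5.76e-07
#' @export
chi2Sf <- function(x, df) {
  if (any(x < 0)) stop("x must be >= 0")
  if (any(df <= 0)) stop("df must be positive")
  pchisq(x, df, lower.tail = FALSE)
}

.rankSetup <- function(values) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("missing cells not supported")
  n <- nrow(values); k <- ncol(values)
  if (n < 2L || k < 2L) stop("need >= 2 blocks and >= 2 treatments")
  rk <- t(apply(values, 1, rank, ties.method = "average"))
  nm <- colnames(values)
  if (is.null(nm)) nm <- paste0("T", seq_len(k))
  list(rk = rk, n = n, k = k, nm = nm, Rj = colSums(rk))
}

.pairApply <- function(k, nm, fn) {
  p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    p[i, j] <- p[j, i] <- fn(i, j)
  }
  p
}

#' Conover post-hoc test after Friedman
#'
#' Pairwise comparisons of treatment rank sums with the pooled-variance
#' denominator \eqn{\sqrt{2n(A - B)/((n-1)(k-1))}}, where \eqn{A} is the
#' sum of squared ranks and \eqn{B = \sum_j R_j^2 / n}; the statistic is
#' referred two-sided to Student's t with \eqn{(n-1)(k-1)} df.  When all
#' blocks rank the treatments identically the denominator is exactly
#' zero; the result is flagged `degenerate` and unequal rank sums get
#' p = 0 explicitly rather than silently.
#'
#' @param values blocks x treatments numeric matrix.
#' @return a [PosthocMatrix-class].
#' @export
conoverPosthoc <- function(values) {
  s <- .rankSetup(values)
  A <- sum(s$rk^2)
  B <- sum(s$Rj^2) / s$n
  dfree <- (s$n - 1) * (s$k - 1)
  denom2 <- 2 * s$n * (A - B) / dfree
  degenerate <- denom2 <= .Machine$double.eps
  p <- .pairApply(s$k, s$nm, function(i, j) {
    dR <- abs(s$Rj[i] - s$Rj[j])
    if (degenerate) return(if (dR > 0) 0 else 1)
    tstat <- dR / sqrt(denom2)
    2 * pt(-tstat, df = dfree)
  })
  new("PosthocMatrix", method = "conover", p.matrix = p,
      degenerate = degenerate)
}

#' Nemenyi post-hoc test after Friedman
#'
#' Pairwise comparisons of mean ranks referred to the studentized range
#' distribution: \eqn{q = |\bar R_i - \bar R_j| / \sqrt{k(k+1)/(12n)}}
#' against the range of k means with infinite df.
#'
#' @param values blocks x treatments numeric matrix.
#' @return a [PosthocMatrix-class].
#' @export
nemenyiPosthoc <- function(values) {
  s <- .rankSetup(values)
  se <- sqrt(s$k * (s$k + 1) / (12 * s$n))
  p <- .pairApply(s$k, s$nm, function(i, j) {
    q <- abs(s$Rj[i] - s$Rj[j]) / s$n / se
    ptukey(q, nmeans = s$k, df = Inf, lower.tail = FALSE)
  })
  new("PosthocMatrix", method = "nemenyi", p.matrix = p,
      degenerate = FALSE)
}
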