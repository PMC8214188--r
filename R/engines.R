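#' Engine parameters
#'
#' Tuning knobs shared by the DGE engines.  Defaults reproduce each
#' engine's published low-count filter: the exact-test engine requires
#' CPM > 1 in at least min-group-size samples; the precision-weight
#' engine additionally requires a total of >= 10 reads across samples;
#' the noise-cloud engine requires mean CPM > 1 in every condition; the
#' empirical-Bayes NB engine applies no filter.
#'
#' @param normalization override of the engine's default normalization
#'   (`NULL` keeps the engine's own choice).
#' @param dispersion_shrinkage_weight shrinkage weight passed to
#'   [estimateNbDispersion()] (exact-test engine) or toward the fitted
#'   mean-dispersion trend (Wald engine).
#' @param low_count_filter apply the engine's low-count filter.
#' @param pseudocount pseudocount added to normalized group means before
#'   taking log2 fold changes.
#' @param seed seed for engines with internal sampling (noise-cloud pair
#'   selection).
#' @param max_noise_pairs cap on within-condition sample pairs per
#'   condition contributing to the noise cloud (seeded, order-invariant
#'   selection when the cap binds).
#' @param em_tol,em_maxit EM convergence tolerance (on the log-likelihood)
#'   and iteration cap for the empirical-Bayes NB engine.
#' @param independent_filter Wald engine only: scan base-mean cutoffs and
#'   keep the one maximizing BH discoveries (DESeq2-style independent
#'   filtering).
#' @return a list of class `"EngineParams"`.
#' @export
engineParams <- function(normalization = NULL,
                         dispersion_shrinkage_weight = 1,
                         low_count_filter = TRUE,
                         pseudocount = 0.5,
                         seed = 1L,
                         max_noise_pairs = 30L,
                         em_tol = 1e-6,
                         em_maxit = 500L,
                         independent_filter = TRUE) {
  stopifnot(pseudocount > 0, dispersion_shrinkage_weight >= 0)
  structure(list(normalization = normalization,
                 dispersion_shrinkage_weight = dispersion_shrinkage_weight,
                 low_count_filter = low_count_filter,
                 pseudocount = pseudocount,
                 seed = as.integer(seed),
                 max_noise_pairs = as.integer(max_noise_pairs),
                 em_tol = em_tol, em_maxit = as.integer(em_maxit),
                 independent_filter = independent_filter),
            class = "EngineParams")
}

.engineInput <- function(object) {
  stopifnot(is(object, "DGECountSet"))
  cond <- condition(object)
  list(counts = assay(object, "counts"), cond = cond,
       lev = levels(cond), gene_id = rownames(object))
}

.groupMeans <- function(norm, cond, lev) {
  list(m1 = rowMeans(norm[, cond == lev[1], drop = FALSE]),
       m2 = rowMeans(norm[, cond == lev[2], drop = FALSE]))
}

.makeResult <- function(engine, gene_id, base_mean, log2fc, p_value = NULL,
                        posterior_de = NULL, keep, params, extra = list()) {
  G <- length(gene_id)
  p <- rep(NA_real_, G); q <- rep(NA_real_, G); padj <- rep(NA_real_, G)
  if (!is.null(p_value)) {
    p[keep] <- p_value
    padj[keep] <- bhAdjust(p_value)
  }
  if (!is.null(posterior_de)) q[keep] <- posterior_de
  tab <- data.frame(gene_id = gene_id, base_mean = base_mean,
                    log2fc = log2fc, p_value = p, posterior_de = q,
                    p_adjusted = padj, filtered = !keep,
                    row.names = NULL)
  EngineResult(engine, tab, c(unclass(params), extra))
}

# CPM > 1 in at least min-group-size samples
.cpmFilter <- function(counts, cond) {
  cpm <- cpmMatrix(counts)
  rowSums(cpm > 1) >= min(tabulate(cond))
}

#' Exact-test NB engine (TMM normalized)
#'
#' TMM normalization, pooled method-of-moments dispersion with shrinkage,
#' then the exact conditional NB test of [nbExactTest()] per gene on
#' counts scaled to a common library size.  Low-count filter: CPM > 1 in
#' at least min-group-size samples.
#'
#' @param object a [DGECountSet-class] with >= 2 samples per group.
#' @param params an [engineParams()] list.
#' @return an [EngineResult-class] with p-values.
#' @export
engineNbExact <- function(object, params = engineParams()) {
  inp <- .engineInput(object)
  .assertTwoGroups(inp$cond)
  cts <- inp$counts
  sf <- sizeFactorsFrom(tmmFactors(cts), cts)
  norm <- sweep(cts, 2, sf, "/")
  keep <- if (params$low_count_filter) .cpmFilter(cts, inp$cond)
          else rep(TRUE, nrow(cts))
  gm <- .groupMeans(norm, inp$cond, inp$lev)
  lfc <- log2((gm$m2 + params$pseudocount) / (gm$m1 + params$pseudocount))

  phi <- estimateNbDispersion(norm, inp$cond,
                              params$dispersion_shrinkage_weight)
  # equalized pseudo-counts: dividing by the depth-absorbing size factors
  # scales every sample to the geometric-mean effective depth; the exact
  # test conditions on integer totals, hence the rounding
  eq <- round(norm)
  g1 <- inp$cond == inp$lev[1]; g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  kidx <- which(keep)
  pv <- vapply(kidx, function(g) {
    t1 <- sum(eq[g, g1]); T <- t1 + sum(eq[g, g2])
    .exactCondP(t1, T, n1, n2, phi[g])
  }, numeric(1))
  .makeResult("nb_exact", inp$gene_id, rowMeans(norm), lfc,
              p_value = pv, keep = keep, params = params,
              extra = list(dispersion = phi))
}

#' Wald NB engine (RLE normalized)
#'
#' RLE (median-of-ratios) size factors; per-gene moment dispersions are
#' shrunk toward a fitted trend \eqn{\phi(\mu) = a_0 + a_1/\mu}; the Wald
#' statistic is the log2 fold change over its delta-method standard
#' error, referred to a standard normal.  Optional DESeq2-style
#' independent filtering scans base-mean cutoffs for the one maximizing
#' BH discoveries at 0.05.
#'
#' @inheritParams engineNbExact
#' @return an [EngineResult-class] with p-values.
#' @export
engineNbWald <- function(object, params = engineParams()) {
  inp <- .engineInput(object)
  .assertTwoGroups(inp$cond)
  cts <- inp$counts
  sf <- sizeFactorsFrom(rleSizeFactors(cts), cts)
  norm <- sweep(cts, 2, sf, "/")
  gm <- .groupMeans(norm, inp$cond, inp$lev)
  base_mean <- rowMeans(norm)
  pc <- params$pseudocount
  lfc <- log2((gm$m2 + pc) / (gm$m1 + pc))

  phi_raw <- estimateNbDispersion(norm, inp$cond, shrinkage_weight = 0)
  tr <- .dispersionTrend(phi_raw, base_mean)
  trend <- tr["a0"] + tr["a1"] / pmax(base_mean, .Machine$double.eps)
  w <- params$dispersion_shrinkage_weight
  phi <- pmax((phi_raw + w * trend) / (1 + w), 0)

  g1 <- inp$cond == inp$lev[1]; g2 <- !g1
  vlog2 <- function(m, idx) {
    n <- sum(idx)
    vm <- (m * sum(1 / sf[idx]) / n^2) + phi * m^2 / n
    vm / ((m + pc)^2 * log(2)^2)
  }
  se <- sqrt(vlog2(gm$m1, g1) + vlog2(gm$m2, g2))
  z <- ifelse(lfc == 0, 0, lfc / pmax(se, .Machine$double.eps))
  pv <- 2 * pnorm(-abs(z))

  keep <- rep(TRUE, nrow(cts))
  if (params$low_count_filter && params$independent_filter) {
    cuts <- quantile(base_mean, seq(0, 0.9, by = 0.05), names = FALSE)
    rej <- vapply(cuts, function(cc) {
      k <- base_mean >= cc
      sum(bhAdjust(pv[k]) < 0.05)
    }, numeric(1))
    keep <- base_mean >= cuts[which.max(rej)]
  }
  .makeResult("nb_wald", inp$gene_id, base_mean, lfc,
              p_value = pv[keep], keep = keep, params = params,
              extra = list(dispersion = phi, trend = tr))
}

# moment fit of a scaled F prior to sample variances (log-scale moments)
.fitFDistMoments <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) return(list(df_prior = Inf, var_prior = mean(s2)))
  z <- log(s2[ok])
  evar <- var(z) - trigamma(df / 2)
  if (evar > 0) {
    d0 <- 2 * .trigammaInverse(evar)
    s02 <- exp(mean(z) - digamma(df / 2) + digamma(d0 / 2) + log(df / d0))
  } else {
    d0 <- Inf
    s02 <- exp(mean(z) - digamma(df / 2) + log(df / 2))
  }
  list(df_prior = d0, var_prior = s02)
}

.trigammaInverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (-dif / x < 1e-8) break
  }
  x
}

#' Precision-weighted moderated-t engine (quantile normalized log-CPM)
#'
#' Quantile-normalizes log2-CPM, estimates the mean-variance trend by
#' lowess of sqrt residual standard deviations against average log
#' counts, converts the interpolated trend into observation weights
#' (trend^-4), refits the two-group model by weighted least squares and
#' moderates the variances with an empirical-Bayes scaled-F prior fitted
#' by moments, giving a moderated t with residual + prior df.  Filter:
#' total count >= 10 and CPM > 1 in at least min-group-size samples.
#'
#' @inheritParams engineNbExact
#' @return an [EngineResult-class] with p-values.
#' @export
engineVoomLite <- function(object, params = engineParams()) {
  inp <- .engineInput(object)
  .assertTwoGroups(inp$cond)
  cts <- inp$counts
  lib <- colSums(cts)
  keep <- if (params$low_count_filter)
    rowSums(cts) >= 10 & .cpmFilter(cts, inp$cond)
  else rep(TRUE, nrow(cts))
  if (!any(keep)) stop("all genes filtered")

  y <- quantileNormalize(cpmMatrix(cts, log = TRUE,
                                   prior_count = params$pseudocount))
  g1 <- inp$cond == inp$lev[1]; g2 <- !g1
  n <- ncol(y); dfres <- n - 2L
  yk <- y[keep, , drop = FALSE]
  m1 <- rowMeans(yk[, g1, drop = FALSE])
  m2 <- rowMeans(yk[, g2, drop = FALSE])
  fitted <- outer(m1, as.numeric(g1)) + outer(m2, as.numeric(g2))
  res <- yk - fitted
  s <- sqrt(rowSums(res^2) / dfres)

  # mean-variance trend on the log-count scale
  amean <- rowMeans(yk) + mean(log2(lib + 1)) - log2(1e6)
  lo <- lowess(amean, sqrt(s), f = 0.5)
  lambda <- sweep(fitted, 2, log2(lib + 1) - log2(1e6), "+")
  sqsd <- if (length(unique(lo$x)) < 2L)
    rep(mean(sqrt(s)), length(lambda)) # flat trend (degenerate input)
  else approx(lo$x, lo$y, xout = as.vector(lambda), rule = 2,
              ties = mean)$y
  w <- matrix(pmax(sqsd, 1e-6)^(-4), nrow(yk), n)

  sw1 <- rowSums(w[, g1, drop = FALSE])
  sw2 <- rowSums(w[, g2, drop = FALSE])
  b1 <- rowSums((w * yk)[, g1, drop = FALSE]) / sw1
  b2 <- rowSums((w * yk)[, g2, drop = FALSE]) / sw2
  fittedw <- outer(b1, as.numeric(g1)) + outer(b2, as.numeric(g2))
  s2w <- rowSums(w * (yk - fittedw)^2) / dfres

  pri <- .fitFDistMoments(s2w, dfres)
  s2post <- if (is.finite(pri$df_prior))
    (pri$df_prior * pri$var_prior + dfres * s2w) / (pri$df_prior + dfres)
  else rep(pri$var_prior, length(s2w))
  dft <- dfres + pri$df_prior
  diff <- b2 - b1
  denom <- sqrt(s2post * (1 / sw1 + 1 / sw2))
  tstat <- ifelse(diff == 0, 0, diff / pmax(denom, .Machine$double.eps))
  pv <- 2 * pt(-abs(tstat), df = dft)

  # report fold changes for every gene from unweighted group means
  M1 <- rowMeans(y[, g1, drop = FALSE]); M2 <- rowMeans(y[, g2, drop = FALSE])
  .makeResult("voom_lite", inp$gene_id, rowMeans(2^y), M2 - M1,
              p_value = pv, keep = keep, params = params,
              extra = list(df_prior = pri$df_prior,
                           var_prior = pri$var_prior))
}

# canonical (order-invariant) seeded choice of within-condition pairs;
# the selection tag derives from the member sample ids, so it is invariant
# to column permutations and to swapping the condition labels
.noisePairs <- function(idx, sample_ids, max_pairs, seed) {
  if (length(idx) < 2L) return(NULL)
  pr <- t(utils::combn(idx, 2L))
  if (nrow(pr) > max_pairs) {
    chars <- utf8ToInt(paste(sort(sample_ids[idx]), collapse = "|"))
    tag <- sum(chars * seq_along(chars)) %% 2147483647
    set.seed(deriveSeed(seed, tag))
    pr <- pr[sample.int(nrow(pr), max_pairs), , drop = FALSE]
  }
  pr
}

#' Non-parametric noise-cloud engine (upper-quartile normalized)
#'
#' For each gene the signal statistics are M (log2 ratio of group means,
#' with pseudocount) and D (absolute difference of group means) on
#' upper-quartile-normalized counts.  A noise cloud of (|M*|, D*) pairs
#' is pooled over all genes and within-condition sample pairs; the
#' posterior probability of differential expression is the fraction of
#' noise points strictly dominated by the gene's (|M|, D).  Filter: mean
#' CPM > 1 in every condition.
#'
#' @inheritParams engineNbExact
#' @return an [EngineResult-class] with posterior probabilities.
#' @export
engineNoiseqLike <- function(object, params = engineParams()) {
  inp <- .engineInput(object)
  cts <- inp$counts
  cond <- inp$cond
  if (max(tabulate(cond)) < 2L)
    stop("no within-condition sample pair available")
  sf <- sizeFactorsFrom(quantileScaleFactors(cts, q = 0.75), cts)
  norm <- sweep(cts, 2, sf, "/")
  pc <- params$pseudocount
  gm <- .groupMeans(norm, cond, inp$lev)
  M <- log2((gm$m2 + pc) / (gm$m1 + pc))
  D <- abs(gm$m2 - gm$m1)

  keep <- if (params$low_count_filter) {
    cpm <- cpmMatrix(cts)
    rowMeans(cpm[, cond == inp$lev[1], drop = FALSE]) > 1 &
      rowMeans(cpm[, cond == inp$lev[2], drop = FALSE]) > 1
  } else rep(TRUE, nrow(cts))

  # noise cloud: canonical sample order makes pair selection invariant to
  # column permutations within a condition
  ord <- order(colnames(cts))
  noiseM <- noiseD <- list()
  for (k in seq_along(inp$lev)) {
    idx <- ord[cond[ord] == inp$lev[k]]
    pr <- .noisePairs(idx, colnames(cts), params$max_noise_pairs,
                      params$seed)
    if (is.null(pr)) next
    a <- norm[keep, pr[, 1], drop = FALSE]
    b <- norm[keep, pr[, 2], drop = FALSE]
    noiseM[[k]] <- as.vector(abs(log2((a + pc) / (b + pc))))
    noiseD[[k]] <- as.vector(abs(a - b))
  }
  nM <- unlist(noiseM); nD <- unlist(noiseD)
  post <- countDominatedNoise(nM, nD, abs(M[keep]), D[keep]) / length(nM)

  .makeResult("noiseq_like", inp$gene_id, rowMeans(norm), M,
              posterior_de = post, keep = keep, params = params,
              extra = list(n_noise = length(nM)))
}

# beta-NB marginal machinery for the empirical-Bayes NB engine ----------

.ebnbStats <- function(cts, cond, lev, sf) {
  norm <- sweep(cts, 2, sf, "/")
  g1 <- cond == lev[1]; g2 <- !g1
  m <- rowMeans(norm)
  v1 <- apply(norm[, g1, drop = FALSE], 1, var)
  v2 <- apply(norm[, g2, drop = FALSE], 1, var)
  n1 <- sum(g1); n2 <- sum(g2)
  v <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  r0 <- pmin(pmax(m^2 / pmax(v - m, 1e-8), 1e-3), 1e6)
  rj <- outer(r0, sf)                   # per-sample NB size r_gj = r_g0 s_j
  list(norm = norm, r0 = r0,
       R = rowSums(rj), R1 = rowSums(rj[, g1, drop = FALSE]),
       R2 = rowSums(rj[, g2, drop = FALSE]),
       X = rowSums(cts), X1 = rowSums(cts[, g1, drop = FALSE]),
       X2 = rowSums(cts[, g2, drop = FALSE]),
       phat = rowSums(rj) / (rowSums(rj) + rowSums(cts)))
}

# log marginal likelihoods under equal-expression / differential models,
# up to the alpha/beta-free constant shared by both
.ebnbLogLik <- function(st, alpha, beta) {
  l0 <- lbeta(alpha + st$R, beta + st$X) - lbeta(alpha, beta)
  l1 <- lbeta(alpha + st$R1, beta + st$X1) +
    lbeta(alpha + st$R2, beta + st$X2) - 2 * lbeta(alpha, beta)
  list(l0 = l0, l1 = l1)
}

#' Empirical-Bayes NB mixture engine (median normalized)
#'
#' Assumes counts are NB with a beta prior on the probability parameter;
#' each gene is either equally expressed (one shared prior draw) or
#' differentially expressed (independent draws per condition).  The
#' beta hyperparameters and the DE mixture weight are estimated by EM
#' (method-of-moments initialization, mixture weight 0.1, tolerance 1e-6
#' on the log-likelihood, at most `em_maxit` iterations); each gene's
#' `posterior_de` is its posterior DE membership probability, and the EE
#' and DE posteriors sum to one by construction.  No low-count filter.
#'
#' @inheritParams engineNbExact
#' @return an [EngineResult-class] with posterior probabilities; the
#'   fitted mixture weight, hyperparameters and convergence flag are in
#'   the result's `params`.
#' @export
engineEbNb <- function(object, params = engineParams()) {
  inp <- .engineInput(object)
  .assertTwoGroups(inp$cond)
  cts <- inp$counts
  sf <- sizeFactorsFrom(quantileScaleFactors(cts, q = 0.5), cts)
  st <- .ebnbStats(cts, inp$cond, inp$lev, sf)

  # method-of-moments beta fit to the implied per-gene probabilities
  mp <- mean(st$phat); vp <- max(var(st$phat), 1e-6)
  conc <- max(mp * (1 - mp) / vp - 1, 0.1)
  alpha <- max(mp * conc, 0.01); beta <- max((1 - mp) * conc, 0.01)
  w <- 0.1
  ll_old <- -Inf; converged <- FALSE; iter <- 0L
  for (iter in seq_len(params$em_maxit)) {
    lk <- .ebnbLogLik(st, alpha, beta)
    a <- log(w) + lk$l1; b <- log1p(-w) + lk$l0
    mx <- pmax(a, b)
    ll <- sum(mx + log(exp(a - mx) + exp(b - mx)))
    z <- 1 / (1 + exp(b - a))
    if (is.finite(ll_old) && abs(ll - ll_old) < params$em_tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    w <- min(max(mean(z), 1e-6), 1 - 1e-6)
    opt <- optim(log(c(alpha, beta)), function(par) {
      ab <- exp(par)
      lk2 <- .ebnbLogLik(st, ab[1], ab[2])
      -sum((1 - z) * lk2$l0 + z * lk2$l1)
    }, method = "Nelder-Mead", control = list(maxit = 25))
    alpha <- exp(opt$par[1]); beta <- exp(opt$par[2])
  }
  if (!converged)
    warning("EM did not converge within ", params$em_maxit,
            " iterations; returning partial results")

  gm <- .groupMeans(st$norm, inp$cond, inp$lev)
  pcnt <- params$pseudocount
  lfc <- log2((gm$m2 + pcnt) / (gm$m1 + pcnt))
  .makeResult("eb_nb", inp$gene_id, rowMeans(st$norm), lfc,
              posterior_de = z, keep = rep(TRUE, nrow(cts)),
              params = params,
              extra = list(mixture_weight = w, alpha = alpha, beta = beta,
                           em_iterations = iter, em_converged = converged,
                           log_likelihood = ll))
}

#' Load an externally computed DGE result table
#'
#' Lets result tables produced by other tools flow through the same
#' evaluation stack.  The TSV must have columns `gene_id`, `log2fc`, and
#' at least one of `p_value` / `posterior_de`; `p_adjusted` is computed
#' by BH when absent; unknown columns are ignored.
#'
#' @param path TSV file path.
#' @param engine_label label stored as the engine name.
#' @return an [EngineResult-class].
#' @export
loadExternalResults <- function(path, engine_label = "external") {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "log2fc") %in% names(tab)))
    stop("mandatory columns 'gene_id' and 'log2fc' missing")
  has_p <- "p_value" %in% names(tab)
  has_q <- "posterior_de" %in% names(tab)
  if (!has_p && !has_q)
    stop("table must carry 'p_value' or 'posterior_de'")
  p <- if (has_p) tab$p_value else rep(NA_real_, nrow(tab))
  q <- if (has_q) tab$posterior_de else rep(NA_real_, nrow(tab))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p_value outside [0,1]")
  if (any(q < 0 | q > 1, na.rm = TRUE)) stop("posterior_de outside [0,1]")
  padj <- if ("p_adjusted" %in% names(tab)) tab$p_adjusted
          else if (has_p) bhAdjust(p) else rep(NA_real_, nrow(tab))
  filtered <- if ("filtered" %in% names(tab)) as.logical(tab$filtered)
              else (is.na(p) & is.na(q))
  out <- data.frame(gene_id = as.character(tab$gene_id),
                    base_mean = if ("base_mean" %in% names(tab))
                      tab$base_mean else NA_real_,
                    log2fc = tab$log2fc,
                    p_value = p, posterior_de = q, p_adjusted = padj,
                    filtered = filtered)
  EngineResult(engine_label, out, list(source = path))
}

#' Available engine names
#' @return character vector of registered engine names.
#' @export
listEngines <- function() {
  c("nb_exact", "nb_wald", "voom_lite", "noiseq_like", "eb_nb")
}

#' Run a DGE engine by name
#'
#' @param object a [DGECountSet-class].
#' @param engine one of [listEngines()], or `"external:<label>=<path>"` to
#'   load a result table from disk.
#' @param params an [engineParams()] list.
#' @return an [EngineResult-class].
#' @export
runEngine <- function(object, engine, params = engineParams()) {
  if (startsWith(engine, "external:")) {
    spec <- sub("^external:", "", engine)
    parts <- strsplit(spec, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("use external:<label>=<path>")
    return(loadExternalResults(parts[2], parts[1]))
  }
  fn <- switch(engine,
               nb_exact = engineNbExact,
               nb_wald = engineNbWald,
               voom_lite = engineVoomLite,
               noiseq_like = engineNoiseqLike,
               eb_nb = engineEbNb,
               stop("unknown engine: ", engine))
  fn(object, params)
}
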