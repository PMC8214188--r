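#' Counts per million
#'
#' @param counts count matrix, or a [DGECountSet-class].
#' @param log return log2 values.
#' @param prior_count prior count used for the log transform; following
#'   the usual precision-weighting convention it is scaled per sample by
#'   the library size relative to the mean library size before being
#'   added, so the offset is constant on the CPM scale.
#' @return a numeric matrix of (log-)CPM values.
#' @export
cpmMatrix <- function(counts, log = FALSE, prior_count = 0.5) {
  if (is(counts, "DGECountSet")) counts <- assay(counts, "counts")
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("zero-depth sample")
  if (!log) return(sweep(counts, 2, lib, "/") * 1e6)
  # sample-specific prior keeps the offset constant on the CPM scale
  pc <- prior_count * lib / mean(lib)
  adj <- sweep(counts, 2, pc, "+")
  log2(sweep(adj, 2, lib + 2 * pc, "/") * 1e6)
}

.normFactorsObj <- function(factors, method, sample_ids) {
  data.frame(sample_id = sample_ids, method = method,
             factor = unname(factors), row.names = NULL)
}

# TMM weighted trimmed mean of M-values for one sample vs reference
.tmmPair <- function(obs, ref, libObs, libRef,
                     logratioTrim = 0.3, sumTrim = 0.05) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (!length(obs)) stop("sample shares no expressed genes with reference")
  m <- log2((obs / libObs) / (ref / libRef))
  a <- (log2(obs / libObs) + log2(ref / libRef)) / 2
  # asymptotic inverse variance of M under binomial sampling
  w <- (libObs - obs) / (libObs * obs) + (libRef - ref) / (libRef * ref)
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  loM <- floor(n * logratioTrim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * sumTrim) + 1;      hiA <- n + 1 - loA
  keep2 <- rank(m) >= loM & rank(m) <= hiM &
           rank(a) >= loA & rank(a) <= hiA
  f <- 2^(sum(m[keep2] / w[keep2]) / sum(1 / w[keep2]))
  if (!is.finite(f)) f <- 1
  f
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values: for each sample a doubly-trimmed (30% on the
#' log-ratios M, 5% on the average log-abundances A), inverse-variance
#' weighted mean of M-values against a reference sample, exponentiated
#' and rescaled so the factors have geometric mean 1.  Genes with a zero
#' count in either the sample or the reference are excluded.  Factors
#' multiply library sizes (effective library size = factor x depth).
#'
#' @param counts count matrix or [DGECountSet-class]; at least 2 samples.
#' @param ref_sample optional sample id/index used as reference; by
#'   default the sample whose upper quartile of scaled counts is closest
#'   to the mean upper quartile.
#' @return data.frame with columns `sample_id`, `method`, `factor`.
#' @export
tmmFactors <- function(counts, ref_sample = NULL) {
  if (is(counts, "DGECountSet")) counts <- assay(counts, "counts")
  if (ncol(counts) < 2L) stop("TMM needs at least two samples")
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("zero-depth sample")
  if (is.null(ref_sample)) {
    uq <- apply(counts, 2, function(x) quantile(x / sum(x), 0.75))
    ref <- which.min(abs(uq - mean(uq)))
  } else {
    ref <- if (is.character(ref_sample)) match(ref_sample, colnames(counts))
           else as.integer(ref_sample)
    if (is.na(ref) || ref < 1 || ref > ncol(counts))
      stop("unknown reference sample")
  }
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    .tmmPair(counts[, j], counts[, ref], lib[j], lib[ref])
  }, numeric(1))
  f <- f / geomean(f)
  .normFactorsObj(f, "tmm", colnames(counts))
}

#' RLE (median-of-ratios) size factors
#'
#' Each sample's factor is the median over genes of its count divided by
#' the gene's geometric mean across samples; genes with any zero count
#' are excluded.  These are depth-absorbing size factors (counts are
#' divided by them directly).
#'
#' @param counts count matrix or [DGECountSet-class].
#' @return data.frame with columns `sample_id`, `method`, `factor`.
#' @examples
#' rleSizeFactors(cbind(s1 = c(2, 4, 8), s2 = c(4, 8, 16)))
#' @export
rleSizeFactors <- function(counts) {
  if (is(counts, "DGECountSet")) counts <- assay(counts, "counts")
  logg <- rowMeans(log(counts))
  use <- is.finite(logg)
  if (!any(use)) stop("no gene has positive counts in all samples")
  f <- apply(counts, 2, function(x) exp(median(log(x[use]) - logg[use])))
  .normFactorsObj(f, "rle", colnames(counts))
}

#' Quantile-based scale factors (median / upper-quartile normalization)
#'
#' Per-sample quantile `q` of the counts (non-zero counts by default),
#' scaled by library size and rescaled so the factors have geometric mean
#' 1.  `q = 0.5` gives median normalization, `q = 0.75` upper-quartile.
#' Quantiles use linear interpolation (type 7).  Factors multiply library
#' sizes, like [tmmFactors()].
#'
#' @param counts count matrix or [DGECountSet-class].
#' @param q quantile in (0,1).
#' @param nonzero_only compute the quantile on non-zero counts only
#'   (default); set `FALSE` to include zeros.
#' @return data.frame with columns `sample_id`, `method`, `factor`.
#' @export
quantileScaleFactors <- function(counts, q = 0.75, nonzero_only = TRUE) {
  if (is(counts, "DGECountSet")) counts <- assay(counts, "counts")
  if (q <= 0 || q >= 1) stop("'q' must lie in (0,1)")
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("zero-depth sample")
  f <- vapply(seq_len(ncol(counts)), function(j) {
    x <- counts[, j]
    if (nonzero_only) x <- x[x > 0]
    if (!length(x)) stop("all-zero sample")
    quantile(x, q, type = 7, names = FALSE) / lib[j]
  }, numeric(1))
  f <- f / geomean(f)
  method <- if (isTRUE(all.equal(q, 0.5))) "median"
            else if (isTRUE(all.equal(q, 0.75))) "upper_quartile"
            else sprintf("quantile_%g", q)
  .normFactorsObj(f, method, colnames(counts))
}

#' Library-size-only factors
#'
#' @param counts count matrix or [DGECountSet-class].
#' @return data.frame with columns `sample_id`, `method`, `factor`; the
#'   factors are all 1 (normalization by depth alone).
#' @export
librarySizeFactors <- function(counts) {
  if (is(counts, "DGECountSet")) counts <- assay(counts, "counts")
  .normFactorsObj(rep(1, ncol(counts)), "library_size", colnames(counts))
}

#' Convert norm factors to depth-absorbing size factors
#'
#' Multiplies each factor by its library size and rescales to geometric
#' mean 1, giving size factors `s_j` such that `counts / s_j` are
#' comparable across samples.  RLE factors already absorb depth and are
#' only rescaled.
#'
#' @param factors data.frame from one of the factor functions.
#' @param counts the matrix (or [DGECountSet-class]) the factors belong to.
#' @return named numeric vector of size factors with geometric mean 1.
#' @export
sizeFactorsFrom <- function(factors, counts) {
  if (is(counts, "DGECountSet")) counts <- assay(counts, "counts")
  stopifnot(identical(factors$sample_id, colnames(counts)))
  s <- if (factors$method[1] == "rle") factors$factor
       else factors$factor * colSums(counts)
  s <- s / geomean(s)
  setNames(s, factors$sample_id)
}

#' Quantile normalization of a numeric matrix
#'
#' Forces every column to share the same distribution: the k-th largest
#' value in each column is replaced by the mean of the k-th largest
#' values across columns; ties within a column receive the mean of their
#' target values.
#'
#' @param x numeric matrix without missing values.
#' @return matrix of the same shape with identical sorted columns.
#' @examples
#' quantileNormalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
quantileNormalize <- function(x) {
  if (!is.matrix(x) || nrow(x) == 0L || ncol(x) == 0L) stop("empty matrix")
  if (anyNA(x)) stop("missing values not supported")
  target <- rowMeans(apply(x, 2, sort))
  out <- apply(x, 2, function(col) {
    rk <- rank(col, ties.method = "average")
    # average rank -> mean of the corresponding target values
    lo <- floor(rk); hi <- ceiling(rk)
    (target[lo] + target[hi]) / 2
  })
  dimnames(out) <- dimnames(x)
  out
}
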