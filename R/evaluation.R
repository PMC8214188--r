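# thin R-level wrapper over the compiled noise-cloud dominance counter
countDominatedNoise <- function(noiseM, noiseD, m, d) {
  .countDominatedNoise(as.numeric(noiseM), as.numeric(noiseD),
                       as.numeric(m), as.numeric(d))
}

#' Benjamini-Hochberg adjustment
#'
#' Validated front end to the step-up false discovery rate adjustment
#' (delegates to [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p_values numeric vector of raw p-values in \[0,1\] (`NA`s pass
#'   through).
#' @return adjusted p-values, monotone in the raw values and each >= its
#'   raw value.
#' @examples
#' bhAdjust(c(0.01, 0.04, 0.03, 0.002))
#' @export
bhAdjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0,1]")
  p.adjust(p_values, method = "BH")
}

#' Call differentially expressed genes from an engine result
#'
#' P-value engines: genes with BH-adjusted p below `alpha`.  Posterior
#' engines: the empirical-Bayes NB engine is thresholded on the posterior
#' FDR -- genes are ranked by decreasing `posterior_de` and the largest
#' prefix whose mean miss-probability `1 - posterior_de` stays at or
#' below `alpha` is called (a hard posterior cutoff is available via
#' `posterior_cutoff`); the noise-cloud engine is called at
#' `posterior_de >= q`.
#'
#' @param result an [EngineResult-class].
#' @param alpha significance / posterior-FDR threshold in (0,1).
#' @param q hard posterior threshold for the noise-cloud engine family
#'   (engines whose name contains "noiseq").
#' @param posterior_cutoff optional hard posterior cutoff overriding the
#'   posterior-FDR rule for posterior engines.
#' @param f,r,regime bookkeeping stored in the returned set.
#' @return a [DEGSet-class].
#' @export
callDegs <- function(result, alpha = 0.05, q = 0.95,
                     posterior_cutoff = NULL,
                     f = 1, r = 1L, regime = "no_fold") {
  stopifnot(is(result, "EngineResult"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)")
  tab <- resultTable(result)
  use_p <- any(!is.na(tab$p_value))
  if (use_p) {
    sel <- !is.na(tab$p_adjusted) & tab$p_adjusted < alpha
  } else if (grepl("noiseq", engineName(result), fixed = TRUE)) {
    sel <- !is.na(tab$posterior_de) & tab$posterior_de >= q
  } else if (!is.null(posterior_cutoff)) {
    sel <- !is.na(tab$posterior_de) & tab$posterior_de >= posterior_cutoff
  } else {
    # posterior-FDR: largest prefix (by decreasing posterior) whose mean
    # miss-probability stays within alpha
    sel <- rep(FALSE, nrow(tab))
    ok <- which(!is.na(tab$posterior_de))
    ord <- ok[order(tab$posterior_de[ok], decreasing = TRUE)]
    miss <- cumsum(1 - tab$posterior_de[ord]) / seq_along(ord)
    nsel <- max(c(0L, which(miss <= alpha)))
    if (nsel > 0L) sel[ord[seq_len(nsel)]] <- TRUE
  }
  DEGSet(engineName(result), tab$gene_id[sel], f = f, r = r, regime = regime)
}

#' Fold-change filtering of a DEG set
#'
#' Keeps genes whose absolute log2 fold change exceeds `c` (the study's
#' "two-fold" regime uses `c = 2`, i.e. |log2FC| > 2).
#'
#' @param degs a [DEGSet-class] derived from `result`.
#' @param result the [EngineResult-class] the set came from.
#' @param c log2-scale threshold.
#' @return a [DEGSet-class] with `regime = "two_fold"` (subset of the
#'   input set).
#' @export
foldFilter <- function(degs, result, c = 2) {
  stopifnot(is(degs, "DEGSet"), is(result, "EngineResult"))
  tab <- resultTable(result)
  idx <- match(geneIds(degs), tab$gene_id)
  if (anyNA(idx)) stop("gene in DEG set missing from result")
  keep <- abs(tab$log2fc[idx]) > c
  DEGSet(degs@engine, geneIds(degs)[keep], f = degs@f, r = degs@r,
         regime = "two_fold")
}

#' Relative FDR of a subsampled DEG set against the full-depth set
#'
#' Treats the full-depth (f = 1) DEG set as the truth of record: genes
#' found in both are TP, genes found only at reduced depth are FP, and
#' full-depth genes missed at reduced depth are miss-detected (MD).
#' Relative FDR = FP/(FP+TP) (0 when both are 0; 1 when TP = 0 but
#' FP > 0), PC = 100 (FP+MD)/TP and MDR = MD/TP (both `NA` with
#' `undefined = TRUE` when TP = 0).
#'
#' @param sub [DEGSet-class] from a subsampled dataset.
#' @param full [DEGSet-class] from the full dataset (same engine and
#'   regime, f = 1).
#' @return one-row data.frame: engine, f, r, regime, tp, fp, md, rel_fdr,
#'   pc, mdr, undefined.
#' @export
relativeFdr <- function(sub, full) {
  stopifnot(is(sub, "DEGSet"), is(full, "DEGSet"))
  if (sub@engine != full@engine || sub@regime != full@regime)
    stop("mismatched engine or filtering regime")
  s <- geneIds(sub); fl <- geneIds(full)
  tp <- length(intersect(s, fl))
  fp <- length(setdiff(s, fl))
  md <- length(setdiff(fl, s))
  rel <- if (tp + fp == 0) 0 else fp / (fp + tp)
  if (tp == 0) {
    pc <- NA_real_; mdr <- NA_real_; undef <- TRUE
    if (fp > 0) rel <- 1
  } else {
    pc <- 100 * (fp + md) / tp; mdr <- md / tp; undef <- FALSE
  }
  data.frame(engine = sub@engine, f = sub@f, r = sub@r, regime = sub@regime,
             tp = tp, fp = fp, md = md, rel_fdr = rel, pc = pc, mdr = mdr,
             undefined = undef)
}

#' Split genes into low/high expression strata
#'
#' Using the normalized expression of the control samples (the first
#' condition level), each gene's mean is compared with the median of
#' those means: means at or below the median go to the low stratum, the
#' rest to the high stratum (ties to low, a deterministic policy).
#'
#' @param object a [DGECountSet-class].
#' @param normalization `"cpm"` (default), `"tmm"`, `"rle"`,
#'   `"upper_quartile"`, `"median"` or `"library_size"`.
#' @return list with character vectors `low` and `high`; their union is
#'   all genes and they are disjoint.
#' @export
expressionStrata <- function(object, normalization = "cpm") {
  stopifnot(is(object, "DGECountSet"))
  cond <- condition(object)
  ctrl <- assay(object, "counts")[, cond == levels(cond)[1], drop = FALSE]
  if (ncol(ctrl) < 1L) stop("no control samples")
  norm <- switch(normalization,
                 cpm = cpmMatrix(ctrl),
                 tmm = sweep(ctrl, 2, sizeFactorsFrom(tmmFactors(ctrl),
                                                      ctrl), "/"),
                 rle = sweep(ctrl, 2, sizeFactorsFrom(rleSizeFactors(ctrl),
                                                      ctrl), "/"),
                 upper_quartile = sweep(ctrl, 2,
                   sizeFactorsFrom(quantileScaleFactors(ctrl, 0.75), ctrl),
                   "/"),
                 median = sweep(ctrl, 2,
                   sizeFactorsFrom(quantileScaleFactors(ctrl, 0.5), ctrl),
                   "/"),
                 library_size = sweep(ctrl, 2,
                                      colSums(ctrl) / mean(colSums(ctrl)),
                                      "/"),
                 stop("unknown normalization: ", normalization))
  m <- rowMeans(norm)
  med <- median(m)
  list(low = rownames(ctrl)[m <= med], high = rownames(ctrl)[m > med])
}

#' Concordance of gene sets over the full inclusion-exclusion lattice
#'
#' For every non-empty combination of the input sets, counts the genes
#' belonging to exactly that combination (the numbers a Venn diagram would
#' display).  Region labels join set names with `"&"`.
#'
#' @param sets named list of >= 2 character vectors.
#' @return list with `regions` (data.frame: region, count), `uniques`
#'   (per-set exclusive counts) and `union_size`; region counts sum to
#'   the union size.
#' @export
concordance <- function(sets) {
  if (length(sets) < 2L) stop("need at least two sets")
  if (is.null(names(sets)) || anyDuplicated(names(sets)) ||
      any(names(sets) == ""))
    stop("sets must have unique non-empty names")
  nm <- names(sets)
  univ <- unique(unlist(sets))
  memb <- vapply(sets, function(s) univ %in% s, logical(length(univ)))
  if (length(univ) == 1L) memb <- matrix(memb, nrow = 1)
  key <- apply(memb, 1, function(b) paste(nm[b], collapse = "&"))
  counts <- table(key)
  k <- length(nm)
  combos <- unlist(lapply(seq_len(k), function(i)
    utils::combn(nm, i, paste, collapse = "&")))
  regions <- data.frame(region = combos,
                        count = as.integer(counts[combos]))
  regions$count[is.na(regions$count)] <- 0L
  uniques <- setNames(regions$count[match(nm, regions$region)], nm)
  list(regions = regions, uniques = uniques,
       union_size = length(univ))
}
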