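#' DEG sets for both filtering regimes from one engine run
#'
#' @param result an [EngineResult-class].
#' @param alpha,q,posterior_cutoff passed to [callDegs()].
#' @param fold_threshold log2-scale threshold for the two-fold regime.
#' @param f,r bookkeeping.
#' @return list with elements `no_fold` and `two_fold` ([DEGSet-class]).
#' @export
degSetsBothRegimes <- function(result, alpha = 0.05, q = 0.95,
                               posterior_cutoff = NULL, fold_threshold = 2,
                               f = 1, r = 1L) {
  nf <- callDegs(result, alpha = alpha, q = q,
                 posterior_cutoff = posterior_cutoff, f = f, r = r)
  tf <- foldFilter(nf, result, c = fold_threshold)
  list(no_fold = nf, two_fold = tf)
}

#' Relative-FDR sweep over a thinning grid
#'
#' For each engine: run once at full depth (the truth of record), then on
#' every thinned instance of the grid, call DEGs under both filtering
#' regimes, and record TP/FP/MD and the relative FDR, PC and MDR per
#' (engine, f, r, regime).
#'
#' @param object the full-depth [DGECountSet-class].
#' @param spec a [subsampleSpec()] describing fractions and iterations.
#' @param engines character vector of engine names ([listEngines()]).
#' @param params an [engineParams()] list shared by all engines.
#' @param alpha,q,fold_threshold DEG-calling parameters.
#' @param verbose print progress.
#' @return data.frame with one row per (engine, f, r, regime).
#' @export
depthRelFdr <- function(object, spec = subsampleSpec(),
                        engines = listEngines(),
                        params = engineParams(),
                        alpha = 0.05, q = 0.95, fold_threshold = 2,
                        verbose = FALSE) {
  full <- lapply(engines, function(e) {
    res <- runEngine(object, e, params)
    degSetsBothRegimes(res, alpha = alpha, q = q,
                       fold_threshold = fold_threshold, f = 1, r = 0L)
  })
  names(full) <- engines
  rows <- list()
  for (f in spec$fractions) {
    for (r in seq_len(spec$iterations)) {
      thin <- thinCounts(object, f, seed = thinningSeed(spec, f, r))
      for (e in engines) {
        res <- runEngine(thin, e, params)
        ds <- degSetsBothRegimes(res, alpha = alpha, q = q,
                                 fold_threshold = fold_threshold,
                                 f = f, r = r)
        rows[[length(rows) + 1L]] <- rbind(
          relativeFdr(ds$no_fold, full[[e]]$no_fold),
          relativeFdr(ds$two_fold, full[[e]]$two_fold))
      }
      if (verbose)
        message(sprintf("f=%g r=%d done", f, r))
    }
  }
  do.call(rbind, rows)
}

#' Population-of-slopes robustness comparison
#'
#' Implements the slope-based robustness measure: a leave-one-out
#' population of datasets is built with [makePopulation()]; each member
#' is thinned over the slope fraction grid (default
#' `{0.8, 0.85, 0.9, 0.95, 0.99}`) with `iterations` draws per fraction;
#' relative FDRs (two-fold regime by default, as in the study design) are
#' averaged over iterations per fraction and an OLS line is fitted,
#' giving one slope per (engine, dataset).
#'
#' @param base full-depth [DGECountSet-class].
#' @param engines engine names.
#' @param reps leave-one-out replicates (default 10 -> 11 datasets).
#' @param f_grid fractions used for the regression.
#' @param iterations thinning iterations per fraction (averaged before
#'   the fit; default 5).
#' @param params,alpha,q,fold_threshold as in [depthRelFdr()].
#' @param regime which filtering regime feeds the regression.
#' @param seed master seed (population sampling and thinning).
#' @param per_iteration if `TRUE`, fit on per-iteration points instead of
#'   per-fraction means.
#' @param verbose print progress.
#' @return list with `slopes` (data.frame: engine, dataset_id, slope,
#'   intercept, n_points) and `slope_matrix` (datasets x engines, ready
#'   for [friedmanTest()]).
#' @export
populationSlopes <- function(base, engines = listEngines(),
                             reps = 10L,
                             f_grid = c(0.8, 0.85, 0.9, 0.95, 0.99),
                             iterations = 5L,
                             params = engineParams(),
                             alpha = 0.05, q = 0.95, fold_threshold = 2,
                             regime = c("two_fold", "no_fold"),
                             seed = 1L, per_iteration = FALSE,
                             verbose = FALSE) {
  regime <- match.arg(regime)
  pop <- makePopulation(base, reps = reps, seed = deriveSeed(seed, 104729))
  rows <- list()
  for (d in names(pop)) {
    spec <- subsampleSpec(fractions = f_grid, iterations = iterations,
                          master_seed = deriveSeed(seed, match(d, names(pop))))
    rel <- depthRelFdr(pop[[d]], spec, engines = engines, params = params,
                       alpha = alpha, q = q, fold_threshold = fold_threshold)
    rel <- rel[rel$regime == regime, ]
    for (e in engines) {
      sub <- rel[rel$engine == e, ]
      pts <- if (per_iteration) data.frame(f = sub$f, rel_fdr = sub$rel_fdr)
      else {
        agg <- tapply(sub$rel_fdr, sub$f, mean)
        data.frame(f = as.numeric(names(agg)), rel_fdr = as.numeric(agg))
      }
      sl <- fitFdrSlope(pts)
      rows[[length(rows) + 1L]] <-
        data.frame(engine = e, dataset_id = d, slope = sl$slope,
                   intercept = sl$intercept, n_points = nrow(pts))
    }
    if (verbose) message("dataset ", d, " done")
  }
  slopes <- do.call(rbind, rows)
  mat <- matrix(NA_real_, length(pop), length(engines),
                dimnames = list(names(pop), engines))
  for (i in seq_len(nrow(slopes)))
    mat[slopes$dataset_id[i], slopes$engine[i]] <- slopes$slope[i]
  list(slopes = slopes, slope_matrix = mat)
}

#' Omnibus + post-hoc comparison of a slope matrix
#'
#' @param slope_matrix datasets x engines matrix (e.g. from
#'   [populationSlopes()]).
#' @param posthoc which post-hoc procedures to run.
#' @return list with `friedman` ([FriedmanResult-class]) and the
#'   requested [PosthocMatrix-class] objects.
#' @export
compareEngines <- function(slope_matrix,
                           posthoc = c("conover", "nemenyi")) {
  posthoc <- match.arg(posthoc, several.ok = TRUE)
  out <- list(friedman = friedmanTest(slope_matrix))
  if ("conover" %in% posthoc) out$conover <- conoverPosthoc(slope_matrix)
  if ("nemenyi" %in% posthoc) out$nemenyi <- nemenyiPosthoc(slope_matrix)
  out
}
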