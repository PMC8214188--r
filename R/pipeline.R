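#' Pipeline configuration
#'
#' One structured configuration for the end-to-end experiment: simulate
#' (or load) counts, thin over a fraction grid, run engines, evaluate
#' relative FDR and concordance, fit the slope population and compare
#' engines.  Round-trips losslessly through YAML; every random stage
#' derives its seed from `master_seed` via [deriveSeed()].
#'
#' @param simulation a `SimulationConfig` from [simParams()], or a list
#'   `list(counts = <tsv path>, sample_sheet = <tsv path>)` to load real
#'   data.
#' @param subsample a [subsampleSpec()].
#' @param engines engine names ([listEngines()] and/or
#'   `"external:<label>=<path>"`).
#' @param alpha,q,fold_threshold DEG-calling parameters.
#' @param strata_normalization normalization for [expressionStrata()].
#' @param population_reps leave-one-out replicates for the slope stage.
#' @param slope_f_grid fractions for the slope regressions.
#' @param slope_iterations thinning iterations per slope fraction.
#' @param posthoc post-hoc methods to run after the Friedman test.
#' @param output_dir output directory.
#' @param master_seed master seed.
#' @return a list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(simulation = simParams(),
                           subsample = subsampleSpec(),
                           engines = listEngines(),
                           alpha = 0.05, q = 0.95, fold_threshold = 2,
                           strata_normalization = "cpm",
                           population_reps = 10L,
                           slope_f_grid = c(0.8, 0.85, 0.9, 0.95, 0.99),
                           slope_iterations = 5L,
                           posthoc = c("conover", "nemenyi"),
                           output_dir = "depthdge_run",
                           master_seed = 1L) {
  structure(list(simulation = simulation, subsample = subsample,
                 engines = engines, alpha = alpha, q = q,
                 fold_threshold = fold_threshold,
                 strata_normalization = strata_normalization,
                 population_reps = as.integer(population_reps),
                 slope_f_grid = slope_f_grid,
                 slope_iterations = as.integer(slope_iterations),
                 posthoc = posthoc, output_dir = output_dir,
                 master_seed = as.integer(master_seed)),
            class = "PipelineConfig")
}

#' @rdname pipelineConfig
#' @param config a `PipelineConfig`.
#' @param path YAML file path.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(rapply(config, unclass, how = "replace")), path)
  invisible(path)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- raw$simulation
  if (!is.null(sim$n_genes)) sim <- do.call(simParams, sim)
  cfg <- pipelineConfig(simulation = sim,
                        subsample = do.call(subsampleSpec, raw$subsample),
                        engines = unlist(raw$engines),
                        alpha = raw$alpha, q = raw$q,
                        fold_threshold = raw$fold_threshold,
                        strata_normalization = raw$strata_normalization,
                        population_reps = raw$population_reps,
                        slope_f_grid = unlist(raw$slope_f_grid),
                        slope_iterations = raw$slope_iterations,
                        posthoc = unlist(raw$posthoc),
                        output_dir = raw$output_dir,
                        master_seed = raw$master_seed)
  cfg
}

.logLine <- function(logfile, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
  message(msg)
  cat(msg, "\n", file = logfile, append = TRUE)
}

#' Run the end-to-end experiment
#'
#' Stages: simulate/load counts; thin over the grid; run engines on every
#' instance; evaluate relative FDR under both filtering regimes;
#' concordance of full-depth DEG sets (overall and within low/high
#' expression strata); leave-one-out slope population; Friedman and
#' post-hoc comparison.  Every stage writes its TSV artifacts under
#' `output_dir` along with a manifest, the config snapshot, and a run
#' log.  Stages already on disk are reused when `resume = TRUE`, and the
#' per-stage seeds recorded in the manifest make any instance
#' reproducible in isolation.
#'
#' @param config a [pipelineConfig()].
#' @param resume reuse stage outputs already present in `output_dir`.
#' @return (invisibly) a list with the counts object, the relative-FDR
#'   table, concordance reports, the slope table and the comparison
#'   results; the same information is on disk under `output_dir`.
#' @export
runExperiment <- function(config, resume = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(config$output_dir, "run.log")
  if (!resume && file.exists(logfile)) file.remove(logfile)
  writePipelineConfig(config, file.path(config$output_dir, "config.yaml"))
  .logLine(logfile, "depthDGE ", as.character(utils::packageVersion("depthDGE")),
           " master_seed=", config$master_seed)

  # stage 1: counts
  counts_tsv <- file.path(config$output_dir, "counts.tsv")
  sheet_tsv <- file.path(config$output_dir, "samples.tsv")
  if (resume && file.exists(counts_tsv) && file.exists(sheet_tsv)) {
    dat <- readCountsTSV(counts_tsv, sheet_tsv)
    .logLine(logfile, "stage simulate: reused ", counts_tsv)
  } else if (inherits(config$simulation, "SimulationConfig")) {
    sim <- config$simulation
    sim$seed <- deriveSeed(config$master_seed, 1L, sim$seed)
    dat <- simulateCounts(sim)
    writeCountsTSV(dat, counts_tsv)
    writeSampleSheet(dat, sheet_tsv)
    writeTruthTable(dat, file.path(config$output_dir, "truth.tsv"))
    .logLine(logfile, "stage simulate: ", nrow(dat), " genes x ",
             ncol(dat), " samples (seed ", sim$seed, ")")
  } else {
    dat <- readCountsTSV(config$simulation$counts,
                         config$simulation$sample_sheet)
    .logLine(logfile, "stage load: ", config$simulation$counts)
  }

  engines <- config$engines
  params <- engineParams(seed = deriveSeed(config$master_seed, 2L))
  spec <- config$subsample
  spec$master_seed <- deriveSeed(config$master_seed, 3L)

  # stage 2+3+4: thinning grid, engines, relative FDR
  rel_tsv <- file.path(config$output_dir, "rel_fdr.tsv")
  if (resume && file.exists(rel_tsv)) {
    rel <- read.delim(rel_tsv)
    .logLine(logfile, "stage rel_fdr: reused ", rel_tsv)
  } else {
    rel <- depthRelFdr(dat, spec, engines = engines, params = params,
                       alpha = config$alpha, q = config$q,
                       fold_threshold = config$fold_threshold)
    write.table(rel, rel_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    .logLine(logfile, "stage rel_fdr: ", nrow(rel), " records")
  }
  manifest <- do.call(rbind, lapply(spec$fractions, function(f)
    data.frame(f = f, r = seq_len(spec$iterations),
               seed = vapply(seq_len(spec$iterations), function(r)
                 thinningSeed(spec, f, r), numeric(1)))))
  write.table(manifest, file.path(config$output_dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # per-f means, both regimes
  agg <- stats::aggregate(rel_fdr ~ engine + f + regime, data = rel, FUN = mean)
  write.table(agg, file.path(config$output_dir, "rel_fdr_means.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # stage 5: full-depth DEG sets, concordance, expression strata
  full_sets <- lapply(engines, function(e) {
    res <- runEngine(dat, e, params)
    writeEngineResult(res, file.path(config$output_dir,
                                     paste0("engine_", gsub("[:=/]", "_", e),
                                            "_full.tsv")))
    degSetsBothRegimes(res, alpha = config$alpha, q = config$q,
                       fold_threshold = config$fold_threshold)
  })
  names(full_sets) <- engines
  conc <- list()
  if (length(engines) >= 2L) {
    for (regime in c("no_fold", "two_fold")) {
      sets <- lapply(full_sets, function(s) geneIds(s[[regime]]))
      conc[[regime]] <- concordance(sets)
      writeConcordance(conc[[regime]],
                       file.path(config$output_dir,
                                 paste0("concordance_", regime, ".tsv")))
    }
    strata <- expressionStrata(dat, config$strata_normalization)
    for (st in c("low", "high")) {
      sets <- lapply(full_sets, function(s)
        intersect(geneIds(s$two_fold), strata[[st]]))
      if (all(lengths(sets) == 0)) next
      conc[[paste0("two_fold_", st)]] <- concordance(sets)
      writeConcordance(conc[[paste0("two_fold_", st)]],
                       file.path(config$output_dir,
                                 paste0("concordance_two_fold_", st, ".tsv")))
    }
  }
  .logLine(logfile, "stage concordance: ", length(conc), " reports")

  # stage 6: slope population + comparison
  slopes_tsv <- file.path(config$output_dir, "slopes.tsv")
  if (resume && file.exists(slopes_tsv)) {
    slopes <- read.delim(slopes_tsv)
    mat <- matrix(NA_real_, length(unique(slopes$dataset_id)),
                  length(unique(slopes$engine)),
                  dimnames = list(unique(slopes$dataset_id),
                                  unique(slopes$engine)))
    for (i in seq_len(nrow(slopes)))
      mat[slopes$dataset_id[i], slopes$engine[i]] <- slopes$slope[i]
    pop <- list(slopes = slopes, slope_matrix = mat)
    .logLine(logfile, "stage slopes: reused ", slopes_tsv)
  } else {
    pop <- populationSlopes(dat, engines = engines,
                            reps = config$population_reps,
                            f_grid = config$slope_f_grid,
                            iterations = config$slope_iterations,
                            params = params, alpha = config$alpha,
                            q = config$q,
                            fold_threshold = config$fold_threshold,
                            seed = deriveSeed(config$master_seed, 4L))
    write.table(pop$slopes, slopes_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
    .logLine(logfile, "stage slopes: ", nrow(pop$slopes), " slopes")
  }

  cmp <- NULL
  if (nrow(pop$slope_matrix) >= 2L && ncol(pop$slope_matrix) >= 2L) {
    cmp <- compareEngines(pop$slope_matrix, posthoc = config$posthoc)
    fr <- cmp$friedman
    write.table(data.frame(chi_squared = fr@statistic, df = fr@df,
                           p_value = fr@p.value),
                file.path(config$output_dir, "friedman.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    for (m in intersect(names(cmp), c("conover", "nemenyi"))) {
      pm <- pValues(cmp[[m]])
      write.table(data.frame(engine = rownames(pm), pm, check.names = FALSE),
                  file.path(config$output_dir, paste0("posthoc_", m, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    .logLine(logfile, "stage compare: Friedman chi2=",
             sprintf("%.4f", fr@statistic), " df=", fr@df,
             " p=", format(fr@p.value, digits = 3))
  } else {
    .logLine(logfile, "stage compare: skipped (needs >= 2 datasets and",
             " >= 2 engines)")
  }

  invisible(list(counts = dat, rel_fdr = rel, rel_fdr_means = agg,
                 concordance = conc, slopes = pop$slopes,
                 slope_matrix = pop$slope_matrix, comparison = cmp))
}
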