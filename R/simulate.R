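#' Simulation parameters for a two-condition negative-binomial dataset
#'
#' Builds and validates the parameter list consumed by
#' [simulateCounts()].  Counts for gene g in sample j are drawn from a
#' negative binomial with mean
#' \deqn{s_j \mu_g 2^{\delta_g [j \in \mathrm{group 2}]}}
#' and variance \eqn{\mu + \phi \mu^2}, where \eqn{s_j} is a per-sample
#' library size factor, \eqn{\mu_g} a log-normal baseline mean and
#' \eqn{\delta_g} the true log2 fold change (non-zero for the configured
#' fraction of DE genes, split evenly between up- and down-regulation).
#'
#' @param n_genes number of genes.
#' @param n_samples_per_group integer pair: samples in group 1 (reference)
#'   and group 2.
#' @param de_fraction proportion of genes that are truly DE, in \[0,1\];
#'   the realised number is `floor(de_fraction * n_genes)`.
#' @param log2fc_magnitude magnitude of the true log2 fold change of DE
#'   genes; either a single value or a length-2 range sampled uniformly.
#' @param baseline_mean_log_params `c(location, scale)` of the log-normal
#'   distribution of baseline gene means.  The default
#'   (meanlog 4, sdlog 1.2, i.e. a median mean of ~55 counts) emulates a
#'   moderately deep bulk library once multiplied by size factors.
#' @param dispersion per-gene NB dispersion \eqn{\phi}; scalar (recycled)
#'   or one value per gene.
#' @param library_size_factors per-sample positive factors, or `NULL` to
#'   sample them log-normally around 1 (sdlog `library_size_sdlog`),
#'   emulating inter-sample variability in sequencing depth.
#' @param library_size_sdlog sdlog of sampled size factors.
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @return a validated list of class `"SimulationConfig"`.
#' @seealso [presetContrast()] for study-like presets.
#' @export
simParams <- function(n_genes = 2000L,
                      n_samples_per_group = c(20L, 20L),
                      de_fraction = 0.2,
                      log2fc_magnitude = 2,
                      baseline_mean_log_params = c(4, 1.2),
                      dispersion = 0.2,
                      library_size_factors = NULL,
                      library_size_sdlog = 0.3,
                      seed = 1L) {
  if (length(n_samples_per_group) != 2L ||
      any(n_samples_per_group != round(n_samples_per_group)))
    stop("n_samples_per_group must be a pair of positive integers")
  cfg <- list(n_genes = as.integer(n_genes),
              n_samples_per_group = as.integer(n_samples_per_group),
              de_fraction = de_fraction,
              log2fc_magnitude = log2fc_magnitude,
              baseline_mean_log_params = baseline_mean_log_params,
              dispersion = dispersion,
              library_size_factors = library_size_factors,
              library_size_sdlog = library_size_sdlog,
              seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  validateSimParams(cfg)
  cfg
}

#' @rdname simParams
#' @param config a `SimulationConfig` list.
#' @export
validateSimParams <- function(config) {
  with(config, {
    if (n_genes < 1L) stop("n_genes must be positive")
    if (length(n_samples_per_group) != 2L || any(n_samples_per_group < 1L) ||
        any(n_samples_per_group != round(n_samples_per_group)))
      stop("n_samples_per_group must be a pair of positive integers")
    if (de_fraction < 0 || de_fraction > 1)
      stop("de_fraction must lie in [0,1]")
    if (any(log2fc_magnitude <= 0) || length(log2fc_magnitude) > 2L)
      stop("log2fc_magnitude must be a positive value or range")
    if (baseline_mean_log_params[2] < 0)
      stop("baseline mean log-scale must be non-negative")
    if (any(dispersion < 0)) stop("dispersion must be non-negative")
    if (!is.null(library_size_factors) && any(library_size_factors <= 0))
      stop("library size factors must be positive")
    if (library_size_sdlog < 0) stop("library_size_sdlog must be >= 0")
  })
  invisible(config)
}

#' Study-like contrast presets
#'
#' Presets mirroring the benchmark's contrast designs: a triple-negative
#' breast cancer-like contrast (42 tumours vs 21 uninvolved tissues), an
#' ER-positive-like contrast (42 vs 30), and the small balanced subset
#' design (5 vs 5).  All other parameters take the documented
#' [simParams()] defaults.
#'
#' @param name one of `"tnbc_like"`, `"erpos_like"`, `"subset_like"`.
#' @param ... overrides passed on to [simParams()].
#' @return a `SimulationConfig`.
#' @export
presetContrast <- function(name = c("tnbc_like", "erpos_like", "subset_like"),
                           ...) {
  name <- match.arg(name)
  sizes <- switch(name,
                  tnbc_like = c(42L, 21L),
                  erpos_like = c(42L, 30L),
                  subset_like = c(5L, 5L))
  simParams(n_samples_per_group = sizes, ...)
}

#' Simulate a two-condition NB count matrix with ground truth
#'
#' @param config a `SimulationConfig` from [simParams()].
#' @return a [DGECountSet-class] whose `rowData` holds the truth table
#'   (`isDE`, `trueLog2FC`) and whose `metadata()$sim_config` records the
#'   parameters.
#' @examples
#' dcs <- simulateCounts(simParams(n_genes = 100, seed = 7))
#' head(truthTable(dcs))
#' @export
simulateCounts <- function(config) {
  validateSimParams(config)
  set.seed(config$seed)
  G <- config$n_genes
  n1 <- config$n_samples_per_group[1]
  n2 <- config$n_samples_per_group[2]
  N <- n1 + n2

  mu <- rlnorm(G, config$baseline_mean_log_params[1],
               config$baseline_mean_log_params[2])
  phi <- rep_len(config$dispersion, G)

  n_de <- floor(config$de_fraction * G)
  is_de <- rep(FALSE, G)
  if (n_de > 0) is_de[sample.int(G, n_de)] <- TRUE
  lfc <- numeric(G)
  if (n_de > 0) {
    mag <- if (length(config$log2fc_magnitude) == 2L)
      runif(n_de, config$log2fc_magnitude[1], config$log2fc_magnitude[2])
    else rep(config$log2fc_magnitude, n_de)
    # split evenly between up- and down-regulation
    sgn <- rep(c(1, -1), length.out = n_de)
    lfc[is_de] <- sgn * mag
  }

  s <- config$library_size_factors
  if (is.null(s)) s <- rlnorm(N, 0, config$library_size_sdlog)
  s <- rep_len(s, N)

  grp2 <- c(rep(0, n1), rep(1, n2))
  mean_mat <- outer(mu, s) * 2^(outer(lfc, grp2))
  # phi = 0 is the Poisson limit; a huge size is numerically equivalent
  size_mat <- matrix(ifelse(phi > 0, 1 / phi, 1e12), G, N)
  counts <- matrix(rnbinom(G * N, size = size_mat, mu = mean_mat), G, N)
  dimnames(counts) <- list(sprintf("gene_%05d", seq_len(G)),
                           c(sprintf("ctrl_%03d", seq_len(n1)),
                             sprintf("case_%03d", seq_len(n2))))

  truth <- data.frame(gene_id = rownames(counts), is_de = is_de,
                      true_log2fc = lfc)
  DGECountSet(counts,
              condition = factor(rep(c("group1", "group2"), c(n1, n2)),
                                 levels = c("group1", "group2")),
              truth = truth,
              metadata = list(sim_config = config,
                              size_factors = s, baseline_mean = mu,
                              dispersion = phi))
}
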