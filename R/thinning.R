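#' Binomial thinning of a count matrix
#'
#' Simulates a shallower sequencing run by keeping each original count
#' independently with probability `f`: every cell becomes
#' `Binomial(count, f)`.  Under multinomial allocation of reads to genes,
#' keeping each read with probability `f` induces exactly this
#' distribution per cell, so count-level thinning is the count-matrix
#' equivalent of subsampling the read alignments.
#'
#' @param object a [DGECountSet-class].
#' @param f retention fraction in \[0,1\]; `f = 1` returns the parent
#'   counts unchanged.
#' @param seed integer seed for the draw.
#' @return a `DGECountSet` with thinned counts; all metadata, truth and
#'   condition information is preserved, and `metadata()$thinning` records
#'   `(f, seed)`.
#' @examples
#' dcs <- simulateCounts(simParams(n_genes = 50, seed = 1))
#' thin <- thinCounts(dcs, 0.5, seed = 99)
#' all(assay(thin) <= assay(dcs))
#' @export
thinCounts <- function(object, f, seed = 1L) {
  stopifnot(is(object, "DGECountSet"))
  if (length(f) != 1L || is.na(f) || f < 0 || f > 1)
    stop("'f' must be a single fraction in [0,1]")
  cts <- assay(object, "counts")
  if (f == 1) {
    out <- object
  } else if (f == 0) {
    out <- object
    assays(out)$counts <- matrix(0, nrow(cts), ncol(cts),
                                 dimnames = dimnames(cts))
  } else {
    set.seed(seed)
    thinned <- matrix(rbinom(length(cts), size = as.integer(cts), prob = f),
                      nrow(cts), ncol(cts), dimnames = dimnames(cts))
    out <- object
    assays(out)$counts <- thinned
  }
  metadata(out)$thinning <- list(f = f, seed = as.integer(seed))
  out
}

#' Subsampling grid specification
#'
#' The default fraction grid is the benchmark's 17 values
#' `{1, 0.99, 0.95, 0.9, 0.85, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.25, 0.2,
#' 0.15, 0.1, 0.05, 0.01}` with 25 iterations per fraction.
#'
#' @param fractions retention fractions, all in (0,1\].
#' @param iterations iterations R per fraction.
#' @param master_seed master seed from which every (f, r) draw derives its
#'   own seed via [deriveSeed()].
#' @return a list of class `"SubsampleSpec"`.
#' @export
subsampleSpec <- function(fractions = c(1, 0.99, 0.95, 0.9, 0.85, 0.8, 0.7,
                                        0.6, 0.5, 0.4, 0.3, 0.25, 0.2, 0.15,
                                        0.1, 0.05, 0.01),
                          iterations = 25L,
                          master_seed = 1L) {
  if (length(fractions) == 0L) stop("empty fraction list")
  if (any(fractions <= 0 | fractions > 1))
    stop("all fractions must lie in (0,1]")
  if (iterations < 1L) stop("iterations must be positive")
  structure(list(fractions = as.numeric(fractions),
                 iterations = as.integer(iterations),
                 master_seed = as.integer(master_seed)),
            class = "SubsampleSpec")
}

#' Seed for one (fraction, iteration) thinning draw
#'
#' @param spec a `SubsampleSpec`.
#' @param f fraction (must be one of `spec$fractions`).
#' @param r iteration index.
#' @return integer seed, independent of evaluation order.
#' @export
thinningSeed <- function(spec, f, r) {
  deriveSeed(spec$master_seed, .fractionTag(f), as.integer(r))
}

#' Generate the full subsampling grid
#'
#' One thinned dataset per (fraction, iteration) pair; the default spec
#' yields 17 x 25 = 425 instances.  Each draw is seeded independently via
#' [thinningSeed()], so any single instance can be regenerated in
#' isolation and results do not depend on evaluation order.
#'
#' @param object parent [DGECountSet-class].
#' @param spec a [subsampleSpec()].
#' @return a list of `DGECountSet`s with names `"f<frac>_r<iter>"`; each
#'   element's `metadata()$thinning` holds `(f, r, seed)`.
#' @export
thinningGrid <- function(object, spec = subsampleSpec()) {
  stopifnot(inherits(spec, "SubsampleSpec"))
  out <- vector("list", length(spec$fractions) * spec$iterations)
  nm <- character(length(out))
  k <- 0L
  for (f in spec$fractions) {
    for (r in seq_len(spec$iterations)) {
      k <- k + 1L
      sd <- thinningSeed(spec, f, r)
      thin <- thinCounts(object, f, seed = sd)
      metadata(thin)$thinning <- list(f = f, r = r, seed = sd)
      out[[k]] <- thin
      nm[k] <- sprintf("f%s_r%d", format(f, trim = TRUE), r)
    }
  }
  names(out) <- nm
  out
}
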