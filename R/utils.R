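#' @importFrom methods is new validObject slot
#' @importFrom stats median quantile var sd lowess approx optim pchisq pnorm
#'   pt ptukey rbinom rlnorm rnbinom runif setNames p.adjust cor complete.cases
#' @importFrom utils read.delim write.table head tail
NULL

# geometric mean of strictly positive values
geomean <- function(x) exp(mean(log(x)))

#' Derive a child seed from a master seed and integer tags
#'
#' Deterministic Lehmer-style hash used to give every (fraction, iteration)
#' pair -- and any other keyed random stage -- its own reproducible seed,
#' independent of the order in which stages are evaluated.  All arithmetic
#' stays below 2^53 so the result is exact in double precision.
#'
#' @param master integer master seed.
#' @param ... further non-negative integer tags (e.g. fraction index,
#'   iteration index).
#' @return an integer seed in `[1, 2147483646]`.
#' @export
deriveSeed <- function(master, ...) {
  stopifnot(length(master) == 1L, is.finite(master))
  m <- 2147483647 # 2^31 - 1, prime
  h <- (abs(as.numeric(master)) %% m)
  for (v in c(...)) {
    h <- (h * 48271 + (abs(as.numeric(v)) %% m) + 1) %% m
    h <- (h * 16807 + 11) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

# single place where fractions are mapped to stable integer tags for seeding
.fractionTag <- function(f) as.integer(round(f * 1e6))

.assertCounts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("'counts' must be a numeric matrix")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("'counts' must contain non-negative integers")
  invisible(TRUE)
}

.assertTwoGroups <- function(condition, min_per_group = 2L) {
  lev <- levels(condition)
  if (length(lev) != 2L)
    stop("'condition' must have exactly two levels")
  n <- table(condition)
  if (any(n < min_per_group))
    stop("each condition level needs at least ", min_per_group, " samples")
  invisible(lev)
}
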