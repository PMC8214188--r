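test_that("CPM matches its definition", {
  m <- matrix(c(5, 999995, 50, 499950), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  cpm <- cpmMatrix(m)
  expect_equal(cpm["g1", "s1"], 5)        # 5 in a library of 1e6
  expect_equal(cpm["g1", "s2"], 100)      # 50 / 5e5 * 1e6
  # identical columns give identical CPM columns
  mm <- cbind(a = c(3, 7, 10), b = c(3, 7, 10))
  rownames(mm) <- paste0("g", 1:3)
  expect_equal(cpmMatrix(mm)[, 1], cpmMatrix(mm)[, 2])
  expect_error(cpmMatrix(cbind(a = c(0, 0))), "zero-depth")
})

test_that("TMM factors: identity, pure depth scaling, and inflated sample", {
  m <- tinyCounts(G = 200, seed = 1, lambda = 100)[, 1:2]
  same <- cbind(a = m[, 1], b = m[, 1])
  expect_equal(tmmFactors(same)$factor, c(1, 1))
  doubled <- cbind(a = m[, 1], b = 2 * m[, 1])
  expect_equal(tmmFactors(doubled)$factor, c(1, 1), tolerance = 1e-12)

  set.seed(2)
  base <- matrix(rpois(4000, 50), 1000, 4,
                 dimnames = list(paste0("g", 1:1000), paste0("s", 1:4)))
  base[1:50, 4] <- base[1:50, 4] * 10
  f <- tmmFactors(base)$factor
  # the sample with a few highly inflated genes gets a shrunken factor
  # (its non-inflated genes look diluted relative to the others)
  expect_lt(f[4], 1)
  expect_true(all(f[1:3] > 1))
  expect_equal(geomean(tmmFactors(base)$factor), 1, tolerance = 1e-12)
})

test_that("TMM agrees with the edgeR reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(8)
  m <- matrix(rnbinom(600 * 6, mu = 60, size = 2), 600, 6,
              dimnames = list(paste0("g", 1:600), paste0("s", 1:6)))
  ours <- tmmFactors(m)$factor
  ref <- edgeR::calcNormFactors(m, method = "TMM")
  expect_equal(ours, unname(ref), tolerance = 1e-6)
})

test_that("RLE size factors match the hand-derived example and DESeq2", {
  m <- cbind(s1 = c(2, 4, 8), s2 = c(4, 8, 16))
  rownames(m) <- paste0("g", 1:3)
  f <- rleSizeFactors(m)$factor
  expect_equal(f, c(1 / sqrt(2), sqrt(2)), tolerance = 1e-6)
  # identical samples and single-sample edge cases
  expect_equal(rleSizeFactors(cbind(a = m[, 1], b = m[, 1]))$factor, c(1, 1))
  expect_equal(rleSizeFactors(m[, 1, drop = FALSE])$factor, 1)

  skip_if_not_installed("DESeq2")
  set.seed(3)
  big <- matrix(rnbinom(2000, mu = 100, size = 1), 500, 4,
                dimnames = list(paste0("g", 1:500), paste0("s", 1:4)))
  big <- big + 1 # DESeq2 drops genes with zeros, as we do; +1 avoids them
  expect_equal(rleSizeFactors(big)$factor,
               unname(DESeq2::estimateSizeFactorsForMatrix(big)),
               tolerance = 1e-8)
})

test_that("quantile scale factors use type-7 quantiles on non-zero counts", {
  x <- c(1, 2, 3, 4, 100)
  # (n-1) q = 3 for q = 0.75 -> exactly the 4th order statistic
  expect_equal(unname(quantile(x, 0.75, type = 7)), 4)
  m <- cbind(a = c(0, x), b = c(0, x))
  rownames(m) <- paste0("g", 1:6)
  expect_equal(quantileScaleFactors(m, 0.75)$factor, c(1, 1))
  # one sample 3x the other: depth scaling equalises the factors
  m3 <- cbind(a = c(10, 20, 30, 40), b = 3 * c(10, 20, 30, 40))
  rownames(m3) <- paste0("g", 1:4)
  expect_equal(quantileScaleFactors(m3, 0.75)$factor, c(1, 1),
               tolerance = 1e-12)
  expect_equal(quantileScaleFactors(m3, 0.5)$method[1], "median")
  expect_error(quantileScaleFactors(cbind(a = c(0, 0)), 0.75))
})

test_that("factor methods are invariant to global library rescaling", {
  m <- tinyCounts(G = 300, n1 = 2, n2 = 2, seed = 4, lambda = 80)
  for (fn in list(tmmFactors,
                  function(x) quantileScaleFactors(x, 0.75),
                  function(x) quantileScaleFactors(x, 0.5))) {
    expect_equal(fn(m)$factor, fn(m * 5)$factor, tolerance = 1e-9)
    expect_equal(geomean(fn(m)$factor), 1, tolerance = 1e-12)
  }
  # RLE (median of ratios) is also invariant: the geometric means rescale
  # with the counts, so the ratios do not move
  expect_equal(rleSizeFactors(m * 5)$factor, rleSizeFactors(m)$factor,
               tolerance = 1e-9)
})

test_that("quantile normalization forces shared column distributions", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  qn <- quantileNormalize(m)
  expect_equal(unname(qn[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, 2]), c(2.5, 3.5, 4.5))
  # identical columns unchanged
  same <- cbind(a = c(2, 9, 4), b = c(2, 9, 4))
  expect_equal(quantileNormalize(same), same)
  # rank order within each column preserved
  set.seed(5)
  r <- matrix(rnorm(200), 40, 5)
  qr <- quantileNormalize(r)
  for (j in 1:5) expect_equal(order(qr[, j]), order(r[, j]))
  expect_error(quantileNormalize(matrix(numeric(0), 0, 0)), "empty")

  skip_if_not_installed("limma")
  expect_equal(unname(quantileNormalize(r)),
               unname(limma::normalizeQuantiles(r)), tolerance = 1e-10)
})

test_that("size-factor conversion has geometric mean one", {
  m <- tinyCounts(G = 100, seed = 6)
  for (f in list(tmmFactors(m), rleSizeFactors(m),
                 quantileScaleFactors(m, 0.75))) {
    s <- sizeFactorsFrom(f, m)
    expect_equal(geomean(s), 1, tolerance = 1e-12)
  }
})
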