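test_that("BH adjustment matches the hand-computed step-up example", {
  expect_equal(bhAdjust(c(0.01, 0.04, 0.03, 0.002)),
               c(0.02, 0.04, 0.04, 0.008))
  expect_equal(bhAdjust(rep(0.03, 5)), rep(0.03, 5))
  expect_equal(bhAdjust(0.2), 0.2)
  p <- bhAdjust(runif(50))
  expect_true(all(p >= 0 & p <= 1))
  expect_error(bhAdjust(c(0.1, 1.3)), "0,1")
})

test_that("DEG calling thresholds adjusted p-values and posteriors", {
  mk <- function(engine, p = NA, q = NA) {
    n <- max(length(p), length(q))
    tab <- data.frame(gene_id = paste0("g", seq_len(n)), base_mean = 10,
                      log2fc = 0, p_value = rep(NA_real_, n),
                      posterior_de = rep(NA_real_, n),
                      p_adjusted = rep(NA_real_, n), filtered = FALSE)
    if (!all(is.na(p))) { tab$p_value <- p / 2; tab$p_adjusted <- p }
    if (!all(is.na(q))) tab$posterior_de <- q
    new("EngineResult", engine = engine, table = tab, params = list())
  }
  # p-value engine: adjusted p below alpha
  s <- callDegs(mk("nb_exact", p = c(0.01, 0.2, 0.049)), alpha = 0.05)
  expect_setequal(geneIds(s), c("g1", "g3"))
  # empty result
  expect_length(geneIds(callDegs(mk("nb_exact", p = numeric(0)))), 0)
  # posterior-FDR rule: mean miss-probability of the called prefix <= alpha
  s2 <- callDegs(mk("eb_nb", q = c(0.99, 0.98, 0.6)), alpha = 0.05)
  expect_setequal(geneIds(s2), c("g1", "g2"))
  # hard posterior cutoff override
  s3 <- callDegs(mk("eb_nb", q = c(0.99, 0.98, 0.6)), posterior_cutoff = 0.5)
  expect_setequal(geneIds(s3), c("g1", "g2", "g3"))
  # noiseq family: hard q threshold
  s4 <- callDegs(mk("noiseq_like", q = c(0.99, 0.95, 0.6)), q = 0.95)
  expect_setequal(geneIds(s4), c("g1", "g2"))
  expect_error(callDegs(mk("nb_exact", p = 0.01), alpha = 0), "alpha")
})

test_that("fold filtering keeps genes beyond the log2 threshold", {
  tab <- data.frame(gene_id = c("A", "B", "C"), base_mean = 1,
                    log2fc = c(2.5, 1.0, -3.0), p_value = 0.001,
                    posterior_de = NA_real_, p_adjusted = 0.001,
                    filtered = FALSE)
  res <- new("EngineResult", engine = "nb_exact", table = tab, params = list())
  degs <- DEGSet("nb_exact", c("A", "B", "C"))
  expect_setequal(geneIds(foldFilter(degs, res, c = 2)), c("A", "C"))
  expect_setequal(geneIds(foldFilter(degs, res, c = 0)), c("A", "B", "C"))
  tab0 <- transform(tab, log2fc = 0)
  res0 <- new("EngineResult", engine = "nb_exact", table = tab0,
              params = list())
  expect_length(geneIds(foldFilter(degs, res0, c = 0)), 0)
  expect_error(foldFilter(DEGSet("nb_exact", "missing"), res), "missing")
})

test_that("relative FDR bookkeeping follows the TP/FP/MD definitions", {
  full <- DEGSet("e", c("A", "B", "C", "D"))
  sub <- DEGSet("e", c("A", "B", "E"), f = 0.5)
  r <- relativeFdr(sub, full)
  expect_equal(r$tp, 2); expect_equal(r$fp, 1); expect_equal(r$md, 2)
  expect_equal(r$rel_fdr, 1 / 3)
  expect_equal(r$mdr, 1.0)
  expect_equal(r$pc, 150.0)
  # identity
  same <- relativeFdr(DEGSet("e", c("A", "B")), DEGSet("e", c("A", "B")))
  expect_equal(same$rel_fdr, 0); expect_equal(same$pc, 0)
  expect_equal(same$mdr, 0)
  # disjoint
  dis <- relativeFdr(DEGSet("e", c("X", "Y")), DEGSet("e", c("A")))
  expect_equal(dis$rel_fdr, 1)
  expect_true(dis$undefined)
  # empty sub and empty full
  r0 <- relativeFdr(DEGSet("e", character(0)), DEGSet("e", character(0)))
  expect_equal(r0$rel_fdr, 0)
  expect_error(relativeFdr(DEGSet("a", "X"), DEGSet("b", "X")), "mismatch")
})

test_that("expression strata split at the median of control means", {
  cts <- matrix(c(1, 5, 10, 20), 4, 3,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  cts <- cbind(cts, c(50, 50, 50, 50))
  colnames(cts) <- paste0("s", 1:4)
  # first factor level is the control group
  d <- DGECountSet(cts, condition = factor(c("ctrl", "ctrl", "ctrl", "case"),
                                           levels = c("ctrl", "case")))
  st <- expressionStrata(d, normalization = "library_size")
  expect_setequal(st$low, c("g1", "g2"))
  expect_setequal(st$high, c("g3", "g4"))
  expect_length(intersect(st$low, st$high), 0)

  # ties go to the low stratum
  dall <- constantSet(G = 5, n = 2, value = 7)
  st2 <- expressionStrata(dall)
  expect_length(st2$high, 0)
  expect_length(st2$low, 5)

  # single gene: its mean equals the median -> low
  one <- DGECountSet(matrix(5, 1, 4, dimnames = list("g1", paste0("s", 1:4))),
                     condition = c("a", "a", "b", "b"))
  expect_equal(expressionStrata(one)$low, "g1")
})

test_that("concordance enumerates the full region lattice", {
  rep1 <- concordance(list(x = c("A", "B", "C"), y = c("B", "C", "D"),
                           z = c("C", "E")))
  counts <- setNames(rep1$regions$count, rep1$regions$region)
  expect_equal(unname(counts["x&y&z"]), 1)        # {C}
  expect_equal(unname(counts["x"]), 1)            # {A}
  expect_equal(unname(counts["y"]), 1)            # {D}
  expect_equal(unname(counts["z"]), 1)            # {E}
  expect_equal(sum(rep1$regions$count), rep1$union_size)

  same <- concordance(list(a = c("A", "B"), b = c("A", "B")))
  cts <- setNames(same$regions$count, same$regions$region)
  expect_equal(unname(cts["a&b"]), 2)
  expect_equal(unname(same$uniques), c(0L, 0L))

  set.seed(13)
  rand <- lapply(1:4, function(i) sample(letters, sample(5:20, 1)))
  names(rand) <- paste0("s", 1:4)
  rep2 <- concordance(rand)
  expect_equal(sum(rep2$regions$count), length(unique(unlist(rand))))
  expect_error(concordance(list(a = "X")), "two sets")
  expect_error(concordance(list(a = "X", a = "Y")), "unique")
})
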