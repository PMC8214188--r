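test_that("dispersion estimator recovers Poisson and NB truth", {
  d0 <- simulateCounts(simParams(n_genes = 300,
                                 n_samples_per_group = c(100, 100),
                                 de_fraction = 0, dispersion = 1e-8,
                                 baseline_mean_log_params = c(log(500), 0.1),
                                 library_size_factors = 1, seed = 41))
  phi0 <- estimateNbDispersion(assay(d0), condition(d0), shrinkage_weight = 0)
  expect_lt(median(phi0), 0.02)

  d2 <- simulateCounts(simParams(n_genes = 300,
                                 n_samples_per_group = c(100, 100),
                                 de_fraction = 0, dispersion = 0.2,
                                 baseline_mean_log_params = c(log(300), 0.2),
                                 library_size_factors = 1, seed = 42))
  phi2 <- estimateNbDispersion(assay(d2), condition(d2), shrinkage_weight = 0)
  expect_gt(mean(phi2), 0.15)
  expect_lt(mean(phi2), 0.25)

  # a gene with variance below its mean clamps to zero
  m <- rbind(g1 = rep(c(10, 11), 5), g2 = c(0, 40, 3, 80, 1, 9, 100, 2, 5, 60))
  colnames(m) <- paste0("s", 1:10)
  phi <- estimateNbDispersion(m, rep(c("A", "B"), each = 5),
                              shrinkage_weight = 0)
  expect_equal(phi[["g1"]], 0)
  expect_error(estimateNbDispersion(m, rep(c("A", "B"), c(9, 1))), "2 samples")
})

test_that("identical constant groups give null results in every engine", {
  d <- constantSet(G = 12, n = 4, value = 30)
  for (e in c("nb_exact", "nb_wald")) {
    tab <- resultTable(runEngine(d, e))
    expect_true(all(tab$log2fc == 0), info = e)
    expect_true(all(tab$p_value[!tab$filtered] == 1), info = e)
  }
  tabv <- resultTable(runEngine(d, "voom_lite"))
  expect_true(all(abs(tabv$log2fc) < 1e-10))
  expect_true(all(tabv$p_value[!tabv$filtered] == 1))
  tabn <- resultTable(runEngine(d, "noiseq_like"))
  expect_true(all(tabn$log2fc == 0))
  expect_true(all(tabn$posterior_de[!tabn$filtered] == 0))
})

test_that("engines are invariant to sample permutation within groups", {
  d <- simMedium(seed = 55)
  perm <- c(sample(1:10), sample(11:20))
  dp <- d[, perm]
  for (e in listEngines()) {
    a <- resultTable(runEngine(d, e))
    b <- resultTable(runEngine(dp, e))
    expect_equal(a$log2fc, b$log2fc, tolerance = 1e-9, info = e)
    score_a <- ifelse(is.na(a$p_value), a$posterior_de, a$p_value)
    score_b <- ifelse(is.na(b$p_value), b$posterior_de, b$p_value)
    expect_equal(score_a, score_b, tolerance = 1e-9, info = e)
  }
})

test_that("swapping group labels negates fold changes, preserves scores", {
  d <- simMedium(seed = 56)
  cts <- assay(d)
  swapped <- DGECountSet(cts, condition = factor(
    ifelse(condition(d) == "group1", "group2", "group1"),
    levels = c("group1", "group2")))
  for (e in listEngines()) {
    a <- resultTable(runEngine(d, e))
    b <- resultTable(runEngine(swapped, e))
    expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-9, info = e)
    score_a <- ifelse(is.na(a$p_value), a$posterior_de, a$p_value)
    score_b <- ifelse(is.na(b$p_value), b$posterior_de, b$p_value)
    expect_equal(score_a, score_b, tolerance = 1e-9, info = e)
  }
})

test_that("engines separate true DE genes from the rest (ROC)", {
  d <- simulateCounts(simParams(n_genes = 600, n_samples_per_group = c(20, 20),
                                de_fraction = 0.2, log2fc_magnitude = 2,
                                seed = 57))
  tt <- truthTable(d)
  auc <- function(score) {
    ok <- !is.na(score)
    r <- rank(score[ok]); lab <- tt$is_de[ok]
    (sum(r[lab]) - sum(lab) * (sum(lab) + 1) / 2) / (sum(lab) * sum(!lab))
  }
  for (e in listEngines()) {
    tab <- resultTable(runEngine(d, e))
    score <- if (any(!is.na(tab$p_value))) 1 - tab$p_value else tab$posterior_de
    expect_gt(auc(score), 0.90, label = paste("AUC for", e))
  }
})

test_that("raw p-values are calibrated under the null", {
  d <- simulateCounts(simParams(de_fraction = 0, seed = 58))
  pe <- resultTable(runEngine(d, "nb_exact"))$p_value
  pe <- pe[!is.na(pe)]
  expect_gt(mean(pe < 0.05), 0.03)
  expect_lt(mean(pe < 0.05), 0.07)
  pw <- resultTable(runEngine(d, "nb_wald"))$p_value
  ks <- suppressWarnings(ks.test(pw, "punif")$statistic)
  expect_lt(unname(ks), 0.05)
  # no engine should call more than 1% of genes under the null
  for (e in listEngines()) {
    res <- runEngine(d, e)
    expect_lt(length(geneIds(callDegs(res))), 0.01 * nrow(d), label = e)
  }
})

test_that("noise-cloud posterior matches the brute-force double loop", {
  d <- simulateCounts(simParams(n_genes = 50, n_samples_per_group = c(5, 5),
                                seed = 59))
  res <- runEngine(d, "noiseq_like", engineParams(low_count_filter = FALSE))
  tab <- resultTable(res)
  # rebuild the identical noise cloud by the same public conventions
  cts <- assay(d)
  sf <- sizeFactorsFrom(quantileScaleFactors(cts, 0.75), cts)
  norm <- sweep(cts, 2, sf, "/")
  cond <- condition(d)
  ord <- order(colnames(cts))
  nM <- c(); nD <- c()
  for (lv in levels(cond)) {
    idx <- ord[cond[ord] == lv]
    pr <- t(combn(idx, 2))
    a <- norm[, pr[, 1], drop = FALSE]; b <- norm[, pr[, 2], drop = FALSE]
    nM <- c(nM, as.vector(abs(log2((a + 0.5) / (b + 0.5)))))
    nD <- c(nD, as.vector(abs(a - b)))
  }
  m1 <- rowMeans(norm[, cond == "group1"]); m2 <- rowMeans(norm[, cond == "group2"])
  M <- log2((m2 + 0.5) / (m1 + 0.5)); D <- abs(m2 - m1)
  expect_equal(tab$posterior_de,
               unname(oracleNoiseqPosterior(nM, nD, abs(M), D)),
               tolerance = 1e-12)
})

test_that("noise-cloud boundary cases: nothing beats nothing, domination", {
  d <- constantSet(G = 6, n = 3, value = 25)
  cts <- assay(d)
  cts["g1", 4:6] <- 2500L # strictly dominates every noise point
  d2 <- DGECountSet(cts, condition = condition(d))
  tab <- resultTable(runEngine(d2, "noiseq_like",
                               engineParams(low_count_filter = FALSE)))
  expect_equal(tab$posterior_de[tab$gene_id == "g1"], 1)
  expect_true(all(tab$posterior_de[tab$gene_id != "g1"] == 0))
})

test_that("empirical-Bayes NB posteriors are proper and recover the DE weight", {
  d <- simMedium(seed = 60) # 20% DE
  res <- runEngine(d, "eb_nb")
  tab <- resultTable(res)
  expect_true(all(tab$posterior_de >= 0 & tab$posterior_de <= 1))
  # EE and DE posteriors are complementary by mixture normalization
  expect_equal(tab$posterior_de + (1 - tab$posterior_de), rep(1, nrow(tab)),
               tolerance = 1e-10)
  expect_true(res@params$em_converged)
  expect_gt(res@params$mixture_weight, 0.1)
  expect_lt(res@params$mixture_weight, 0.3)

  null <- simulateCounts(simParams(n_genes = 400,
                                   n_samples_per_group = c(10, 10),
                                   de_fraction = 0, seed = 61))
  tabn <- resultTable(runEngine(null, "eb_nb"))
  expect_lt(mean(tabn$posterior_de), 0.1)
})

test_that("external result tables load, validate, and get BH adjusted", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(gene_id = c("a", "b", "c"), log2fc = c(1, -2, 0),
                   p_value = c(0.01, 0.5, 0.04), note = "ignored")
  write.table(df, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  res <- loadExternalResults(tf, "ext")
  tab <- resultTable(res)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$p_adjusted, p.adjust(df$p_value, "BH"))
  expect_equal(order(tab$p_adjusted), order(tab$p_value))

  bad <- df[, c("gene_id", "log2fc")]
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(bad, tf2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(loadExternalResults(tf2), "p_value")

  # runEngine round trip via the external:<label>=<path> syntax
  res2 <- runEngine(tinySet(), paste0("external:ext=", tf))
  expect_equal(engineName(res2), "ext")
})

test_that("engine results validate their structural invariants", {
  d <- simMedium(seed = 62)
  for (e in listEngines()) {
    res <- runEngine(d, e)
    tab <- resultTable(res)
    has_p <- !is.na(tab$p_value); has_q <- !is.na(tab$posterior_de)
    expect_false(any(has_p & has_q), info = e)
    expect_false(any(tab$filtered & (has_p | has_q)), info = e)
    expect_true(validObject(res), info = e)
  }
})
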