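---
title: "Benchmarking depth robustness of differential-expression pipelines"
author: "depthDGE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking depth robustness of differential-expression pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depthDGE)
```

## The question the package answers

When an RNA-seq experiment is sequenced more shallowly — fewer reads per
library — how much does the set of genes a differential-expression (DGE)
pipeline calls significant change, and do pipelines differ in how fast they
degrade?  `depthDGE` turns that question into a controlled computational
experiment:

1. fix a gene × sample count matrix with a two-level condition;
2. simulate shallower libraries by *binomial thinning*: each count cell is
   replaced by a draw from Binomial(count, *f*), for retention fractions
   *f* on a grid;
3. run one or more two-group DGE engines on every thinned instance;
4. score each instance against the engine's own full-depth result by the
   **relative false discovery rate**: with the full-depth DEG set taken as
   the truth of record, rel FDR = FP/(FP+TP), where TP are genes found at
   both depths and FP only at reduced depth (full-depth genes missed at
   reduced depth are "miss-detected", MD; the package also reports
   PC = 100·(FP+MD)/TP and MDR = MD/TP);
5. regress rel FDR on *f* over a near-full-depth grid
   ({0.8, 0.85, 0.9, 0.95, 0.99}) for a leave-one-out population of
   datasets, giving a *population of slopes* per engine; flat slopes mean
   a depth-robust pipeline, steep negative slopes a fragile one;
6. compare engines by the tie-corrected Friedman rank test over the slope
   matrix (datasets × engines), with Conover and Nemenyi post hocs.

Why thinning at the count level is the right surrogate for read-level
subsampling: if each mapped read is kept independently with probability
*f*, and reads are allocated to genes multinomially, the retained count of
every cell is exactly Binomial(count, *f*).  Count-level thinning therefore
reproduces the sampling distribution of read subsampling without touching
alignments, and composes: thinning by *f₁* then *f₂* is distributionally
identical to thinning once by *f₁·f₂* (a property the test suite checks).

## The synthetic data generator

`simulateCounts()` draws counts for gene *g*, sample *j* from a negative
binomial with mean

$$ s_j \, \mu_g \, 2^{\delta_g\,[j \in \text{group 2}]} $$

and variance $\mu + \phi\mu^2$ (the mean–dispersion parameterisation used
by the count-based DGE tools).  Defaults, chosen once as a plausible
moderate-depth bulk RNA-seq contrast and documented rather than fitted to
any particular dataset:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 2000 | genes |
| `n_samples_per_group` | (20, 20) | balanced two-group design |
| `de_fraction` | 0.2 | fraction of genes truly DE (floor rule) |
| `log2fc_magnitude` | 2 | true \|log2FC\| of DE genes, split 50/50 up/down |
| `baseline_mean_log_params` | (4, 1.2) | log-normal gene means (median ≈ 55 counts) |
| `dispersion` | 0.2 | NB dispersion φ (biological-replicate scale) |
| `library_size_sdlog` | 0.3 | log-normal spread of library size factors |

The even split of DE genes between up- and down-regulation avoids
confounding differential expression with library size.
`presetContrast()` provides study-like designs: `tnbc_like` (42 vs 21),
`erpos_like` (42 vs 30) and `subset_like` (5 vs 5).

What the generator deliberately does **not** emulate: transcript/isoform
structure, GC and length bias, batch effects, outlier samples, or
correlated genes.  Passing tests therefore demonstrate that the metrics
and engines behave as designed under a clean NB world; they do not certify
behaviour under real-data artefacts such as batch structure or mapping
ambiguity.

## The engines

The five engines are *method-inspired simplifications* of the model
families used by popular pipelines — an exact conditional NB test on
TMM-scaled counts, an NB Wald test on median-of-ratios-scaled counts, a
precision-weighted moderated *t* on quantile-normalized log-CPM, a
non-parametric noise-cloud posterior on upper-quartile-scaled counts, and
an empirical-Bayes NB mixture on median-scaled counts.  They are authored
here and make no claim of numerical agreement with any Bioconductor
package; the benchmark's metrics treat every engine symmetrically, and
externally computed result tables can be injected with
`loadExternalResults()` to run real pipelines through the identical
evaluation stack.

Engine specifics worth knowing:

* **nb_exact** — pooled method-of-moments dispersion shrunk toward the
  10 %-trimmed mean of all gene dispersions (weight 1 by default); the
  test conditions on the rounded total of size-factor-equalized counts and
  sums all split probabilities no larger than the observed one
  (probabilities tied within a relative 1e-12 are counted in, which makes
  the two-sided sum deterministic and conservative).  Low-count filter:
  CPM > 1 in at least min-group-size samples.
* **nb_wald** — gene dispersions shrunk toward a fitted trend
  φ(μ) = a₀ + a₁/μ (coefficients clamped at ≥ 0); the Wald *z* uses a
  delta-method standard error of the pseudocounted log2 fold change;
  DESeq2-style independent filtering scans base-mean quantile cutoffs
  (0–90 % in 5 % steps) and keeps the one maximizing BH discoveries at
  0.05.
* **voom_lite** — the lowess mean–variance trend of √(residual SD) against
  average log-count is inverted into observation weights (trend⁻⁴); the
  empirical-Bayes prior (d₀, s₀²) is fitted by the log-scale moment method
  (trigamma inversion by Newton iteration); a degenerate all-constant
  input falls back to a flat trend.  Filter: total ≥ 10 reads and the
  CPM > 1 rule.
* **noiseq_like** — posterior DE probability is the fraction of
  noise-cloud points (|M\*|, D\*) from within-condition sample pairs that
  the gene's (|M|, D) strictly dominates.  With many replicates the pair
  count explodes, so at most 30 pairs per condition enter the cloud (a
  seeded, order- and label-invariant selection; all pairs are used when
  fewer exist).  The dominance count is computed in C++; a brute-force R
  double loop serves as its oracle in the tests.  Filter: mean CPM > 1 in
  every condition.
* **eb_nb** — beta prior on the NB probability parameter, two-hypothesis
  EE/DE mixture; per-gene NB sizes come from pooled within-group moments
  (clamped to [1e-3, 1e6]); EM with method-of-moments initialisation,
  mixture weight 0.1, tolerance 1e-6 on the log-likelihood, at most 500
  iterations (non-convergence is reported, with partial results flagged).
  No low-count filter.

## DEG calling and filtering regimes

P-value engines are thresholded at BH-adjusted *p* < 0.05.  The
empirical-Bayes engine is thresholded on the *posterior FDR*: genes ranked
by posterior, the largest prefix whose mean miss-probability
(1 − posterior) stays at or below 0.05 is called — the soft analogue of
"FDR = 0.05"; a hard posterior cutoff is available.  The noise-cloud
engine uses a hard posterior threshold, default q = 0.95.  No
authoritative value for q exists for this benchmark design; 0.95 is a
documented assumption, and with it the engine calls few, very stable
genes — which is exactly why its depth-degradation profile is nearly
flat.  Every DEG set also exists in a "two-fold" variant keeping only
|log2FC| > 2, always a subset of the unfiltered set.

Other documented conventions: fold changes use a pseudocount of 0.5 on
normalized group means (second condition level over the first); quantiles
are type-7 (linear interpolation); TMM trims 30 % on M and 5 % on A with
inverse-variance weights and rescales factors to geometric mean 1; the
expression strata split control-sample means at their median with ties
going to the *low* stratum; when TP = 0, rel FDR is defined as 1 if
FP > 0 and 0 otherwise, with PC and MDR flagged undefined.

## Seeding and reproducibility

Every random stage derives its seed from a master seed through a
deterministic integer hash (`deriveSeed()`), keyed by stage and by
(fraction, iteration).  Any thinned instance can therefore be regenerated
in isolation, results do not depend on evaluation order, and a repeated
run with the same configuration is byte-identical.  The noise-cloud pair
selection keys its seed to the member sample ids, so it is invariant to
column permutations and to swapping the condition labels.

## The slope population and its comparison

`makePopulation()` removes one uniformly chosen sample (group chosen at
random, seeded) per replicate, default ten times, keeping the original —
11 datasets.  For each dataset and engine, relative FDRs on the
{0.8, 0.85, 0.9, 0.95, 0.99} grid (two-fold regime by default, 5 thinning
iterations per fraction averaged before the fit; a per-iteration mode
exists) give an OLS slope.  The Friedman statistic is always computed in
its tie-corrected form, which reduces to the classic statistic without
ties; a fully tied matrix returns statistic 0 and p = 1.  The Conover
post hoc refers rank-sum differences to Student's *t* with (n−1)(k−1) df;
identical rankings in every block make its pooled denominator exactly
zero, which is reported as a degenerate flag rather than a silent p = 0.
The Nemenyi post hoc uses the studentized range with infinite df and is
the more conservative of the two.

## Problem sizes used by the shipped checks

The test-suite and the acceptance script keep the experiment at sizes a
single core handles in minutes, chosen as the package's own defaults for
routine verification: the depth-degradation check runs the default
2000-gene, 20 vs 20 preset over f ∈ {1, 0.5, 0.25, 0.1} with 10
iterations; the slope-population check uses 5 leave-one-out datasets with
2 iterations per fraction (the package default for production runs is 10
datasets and 5 iterations); oracle equivalence for the exact test is
exhaustive for conditional totals up to 200.  Monte-Carlo checks use
fixed seeds and tolerance bands stated next to each test.

## Known limitations

* Engines are two-group only: no GLMs, covariates, or multi-factor
  designs.
* The Wald engine's normal reference is an approximation; its null
  calibration is checked by simulation, not guaranteed analytically.
* The relative-FDR framework measures *stability under depth reduction*,
  not biological accuracy; an engine that calls a tiny, stable set (the
  noise-cloud engine at q = 0.95) can look maximally robust while being
  insensitive.
* Simulated data are clean NB; conclusions about real tissue contrasts
  require running the real pipelines (via `loadExternalResults()`) on
  real counts.
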