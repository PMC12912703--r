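---
title: "Differential expression testing under spatial correlation: models, simulator and benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential expression testing under spatial correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stgee)
```

## The problem

Spatial transcriptomics (ST) platforms such as 10x Visium measure genome-wide
expression at thousands of spatially indexed tissue spots. A routine analysis
question is which genes are differentially expressed (DE) between two
predefined pathology regions — say invasive carcinoma versus fibrous tissue.
The default tool for this comparison in common pipelines is the Wilcoxon
rank-sum test, with the two-sample z-test as the large-sample parametric
alternative. Both assume independent observations. Spots are not independent:
expression is spatially correlated, and depending on the strength and range
of that correlation the tests' type I error can be inflated or deflated,
sometimes badly.

`stgee` implements a family of estimating-equation (GEE) tests that stay
valid under spatial correlation, together with the two classical tests, a
spatially correlated count simulator, and a benchmark harness that measures
type I error and power of all five tests under controlled conditions.

## Models and tests

### Marginal Poisson model

For one gene, let $Y_i$ be the count at spot $i$ ($i = 1, \dots, n$),
$X_i \in \{0, 1\}$ the grade indicator, and
$$\log E(Y_i) = \log \mu_i = \beta_0 + \beta_1 X_i .$$
$\beta_1$ is the grade-B log fold change; DE testing is
$H_0\colon \beta_1 = 0$. The coefficients solve the estimating equations
$\sum_{i=1}^m D_i^\top V_i^{-1} (Y_i - \mu_i) = 0$, where $i$ now indexes
working clusters of spots, $D_i = \partial \mu_i / \partial \beta$, and
$V_i$ is the working covariance. `stgee` uses the independence working
correlation with $V_i = \mathrm{diag}(\mu_i)$ and scale fixed at 1; the
solution then coincides with the Poisson GLM maximum-likelihood estimate and
does not depend on the clustering (`fit_poisson_ee()`). The sandwich
estimator is invariant to any scalar working-variance factor, which is why
no dispersion parameter is estimated.

### Cluster-robust inference

Working clusters are spatially contiguous groups of spots obtained by
K-means on the raw coordinates (`kmeans_spatial()`); they are an inference
device, not a biological segmentation. Inference uses the sandwich
covariance
$$\widehat{\mathrm{Var}}(\hat\beta) = B^{-1} M B^{-1}, \qquad
B = \sum_i D_i^\top V_i^{-1} D_i, \quad
M = \sum_i D_i^\top V_i^{-1} (Y_i - \mu_i)(Y_i - \mu_i)^\top V_i^{-1} D_i ,$$
which is consistent as the number of clusters $m$ grows even when the
working independence assumption is wrong. Three tests are built on this:

* **Robust Wald** (`robust_wald_test()`):
  $W = \hat\beta_1 / \widehat{se}(\hat\beta_1)$, standard normal reference.
* **Generalized score test, GST** (`generalized_score_test()`): only the
  null (intercept-only) model is fitted; the $\beta_1$ component of the
  score at the null fit, $U = \sum_{i: X_i = 1}(Y_i - \bar Y)$, is
  standardized by a robust variance assembled from per-cluster
  contributions. Because the intercept is estimated, each cluster's
  $\beta_1$-score contribution is orthogonalized against its
  intercept-score contribution through the bread blocks
  ($e_c = U_c^{(1)} - B_{10} B_{00}^{-1} U_c^{(0)}$,
  $\widehat{\mathrm{Var}}(U) = \sum_c e_c^2$). Without this nuisance
  adjustment the test is anti-conservative; the adjusted form is the
  standard generalized score construction. The GST needs no alternative
  fit, so it remains defined when one grade is all zeros and $\hat\beta_1$
  would diverge.
* **Independent GEE** (`independent_gee_test()`): the $m = n$ special case
  — every spot its own cluster — i.e. Poisson regression with
  heteroskedasticity-robust (HC0) standard errors. No pre-clustering is
  needed.

### Classical tests

`wilcoxon_rank_sum()` implements the rank-sum normal approximation:
mid-ranks over the pooled sample, $W_X$ standardized by
$\mu_W = n_X (N + 1)/2$ and $\sigma^2_W = n_X n_Y (N+1)/12$. Count data tie
heavily, so the variance applies the standard tie correction by default (a
flag restores the uncorrected formula). A continuity-correction flag exists
for small samples; it is off by default because ST comparisons have hundreds
of spots per group. We standardize $W_X$ directly (the equivalent
Mann–Whitney form); the two-sided p-value is identical to standardizing
$W_Y$. `two_sample_z()` is the Welch-variance z-test
$z = (\bar X - \bar Y)/\sqrt{s^2_X/n_X + s^2_Y/n_Y}$.

## The simulator

`st_scenario()` defines a Poisson log-normal spatial generative model on a
hex lattice (`generate_visium_lattice()`, unit nearest-neighbour spacing):
$$Y_i \mid \varepsilon \sim \mathrm{Poisson}\!\big(\exp(\beta_0 + \beta_1 X_i + \varepsilon_i)\big),
\qquad \varepsilon \sim N(0, \Sigma), \quad
\Sigma_{ii'} = \sigma^2 \exp(-\tau_{ii'}/\kappa),$$
with $\tau$ the Euclidean inter-spot distance. The exponential kernel is
the Matérn family at smoothness $\nu = 0.5$. $\sigma^2$ controls the
marginal overdispersion ($E[Y] = e^{\beta_0 + \beta_1 X + \sigma^2/2}$,
$\mathrm{Var}[Y] = E[Y] + (e^{\sigma^2} - 1) E[Y]^2$), $\kappa$ the
correlation range in spot units. A small intercept ($\beta_0 = -2.5$ in the
presets) reproduces the extreme sparsity of spot-level counts: under the
null of the weak preset over 90% of entries are zero. Grades default to a
contiguous half-slide split (`assign_grades()`), mimicking two adjacent
pathology regions; a randomized balanced scheme is also provided (under
random labels all marginal tests are essentially exchangeability-protected,
so the half split is the interesting default).

Counts are drawn by inverse-CDF Poisson sampling from per-replicate seeded
streams, so any block of replicates is reproducible independently of chunk
size.

### What the simulator does and does not emulate

It reproduces the sparsity, overdispersion and spatial correlation of
spot-level ST counts for a single gene at a time, on a regular full
lattice. It does not emulate irregular tissue boundaries, library-size
variation between spots, multi-gene correlation, or cell-type composition
effects. Benchmarks on it therefore speak to the calibration of the tests
under spatial correlation — the property at issue — and not to every
feature of real slides.

### Frozen scenario presets and how they were calibrated

The benchmark scenarios (`scenario_preset()`) fix $(\sigma^2, \kappa)$ at

| preset | $\sigma^2$ | $\kappa$ (spot units) |
|---|---|---|
| independent | 0 | — |
| weak | 0.25 | 0.5 |
| moderate | 0.5 | 0.75 |
| strong | 4 | 0.4 |

These were calibrated once, by a grid search over $(\sigma^2, \kappa)$
spanning five orders of magnitude in $\kappa$ and both grade layouts, on
the 59×59 lattice with 10,000 null replicates per candidate, scored by
closeness of the seven per-method rejection rates to the reference type I
error pattern the package documents; the winning values were frozen before
any acceptance measurement. The pattern the frozen presets reproduce:

* **weak** ($\sigma^2 = 0.25$, $\kappa = 0.5$; nearest-neighbour latent
  correlation $0.25\,e^{-2} \approx 0.03$): every test close to nominal,
  except the $m = 25$ clustered Wald test, which is anti-conservative for
  the few-cluster reason alone (its normal reference ignores the
  variability of a 25-term sandwich; it sits near 0.02 at $\alpha = 0.01$
  even under fully independent data).
* **moderate** ($\sigma^2 = 0.5$, $\kappa = 0.75$): mild inflation of the
  marginal tests (z-test near 0.002 at $\alpha = 0.001$), with the
  clustered GST still conservative.
* **strong** ($\sigma^2 = 4$, $\kappa = 0.4$): the rank-sum test clearly
  inflated (about $2\times$ nominal at $\alpha = 0.01$) — ranks of heavily
  zero-inflated counts feel the spatial correlation of the nonzero-count
  indicator strongly — while the z-test turns conservative (its variance
  estimate co-moves with the heavy-tailed sample mean), the clustered GST
  deflates (roughly half nominal), and the Independent GEE stays closest
  to nominal among the marginal tests.

Calibration exposed two structural facts about this generative model that
are worth recording, because they bound what any preset can show. First,
with contiguous grade regions, an exponential field whose range is
comparable to the region size ($\kappa$ between roughly 2 and 200 spot
units on this lattice — the linear variogram of the $\nu = 0.5$ kernel
decays very slowly) acts as a group-level random confounder that inflates
*every* marginal test severalfold, the Independent GEE included: no
variance estimator built from marginal residuals can see the covariance
between the two region means. Rejection rates of 0.3–0.8 at
$\alpha = 0.01$ for all marginal tests are typical in that regime. Second,
order-of-magnitude *deflation* of the clustered tests (sandwich variance
far above the truth) requires within-cluster covariance that survives
group-mean centring yet cancels in the group-mean difference; with
contiguous half-slide regions those two requirements conflict — the same
mid-range field that fills the cluster blocks also confounds the group
contrast — and with scattered (randomized) grade labels, where the
cancellation does hold, the rank-sum and z-tests become exactly
calibrated by exchangeability and show no inflation at all. The frozen
presets therefore live in the short-range regime, where the qualitative
ordering of the methods (rank-sum inflated, Independent GEE closest to
nominal, GST conservative, few-cluster Wald anti-conservative) is stable
and reproducible; the extreme collapse of the clustered tests reported for
real-data-derived parameters is not attainable simultaneously with
calibrated marginal tests under this model family, and the package
documents that tension rather than engineering around it.

## Benchmarks

`run_type1_experiment()` simulates replicate genes under $\beta_1 = 0$ and
tabulates rejection fractions at $\alpha \in \{0.01, 0.001, 0.0001\}$, with
Monte-Carlo standard errors $\sqrt{r(1-r)/\text{reps}}$; the K-means
partition is computed once per $m$ and reused. Replicates whose fit fails
(all-zero gene, or a grade entirely zero for Wald-type tests) are excluded
from the denominator and reported, with a flag to count them as
non-rejections instead. `run_power_experiment()` sweeps a $\beta_1$ grid
(default $\{0, 0.25, 0.5, 0.75, 1, 1.5\}$, a plausible log-fold-change
range) at a single level, default $\alpha = 0.001$.

Default problem sizes are 10,000 replicates for type I error (MC-SE about
0.001 at $\alpha = 0.01$) and 1,000 for power, on the 3,481-spot lattice;
both are configurable upward. The test suite runs reduced lattices for the
purely structural checks and the full benchmark for pattern checks.

```{r, eval = FALSE}
sc <- scenario_preset("strong")
run_type1_experiment(sc, methods = c("independent-gee", "wilcoxon"),
                     reps = 10000, seed = 1)
```

## Genome-wide scans

`scan_genes()` applies any of the five tests gene-by-gene to an
`st_dataset` (from `read_visium()` or built in memory) and reports BH-FDR
and Bonferroni-FWER adjusted p-values; missing p-values (failed genes) are
excluded from the number of tests rather than imputed. `qq_data()` and
`stratified_summary()` provide the calibration diagnostics — genome-wide
QQ coordinates and sparsity-stratified QQ/histogram tables — that localize
rank-sum miscalibration to non-sparse genes. `spatial_split()` builds
negative-control pseudo-grades (control-vs-control comparisons within one
histological region), in which any significant gene is a presumptive false
positive.

## Preprocessing choices

`read_visium()` accepts the MatrixMarket + TSV triplet with either
tissue-positions dialect (headerless v1 or headered v2). Quality control
follows convention: spots under 500 total counts and genes detected in
fewer than 10 spots are dropped (both thresholds exposed in
`preprocess_config()`; these values are conventional Visium QC, the
upstream provenance of any given public dataset's exact thresholds being
unknowable). Highly variable gene selection keeps the 3,000 genes with the
largest variance of `log1p`(median-depth-normalized counts) — a documented,
reproducible stand-in for pipeline-specific HVG selection; exact
replication of any particular toolkit's variance stabilization is a
non-goal. Filters apply sequentially, in the documented order, each to the
current matrix. The GEE tests always consume raw counts (they are count
models); the rank-sum and z-test default to raw counts with an option to
supply a transformed matrix.

## Numerical details and edge cases

* IRLS starts at $(\log \bar y, 0)$, stops at $\max|\Delta\beta| < 10^{-8}$
  or 25 iterations; the two-group model converges in a handful of steps.
* An all-zero gene is `degenerate_input`; a gene with one grade entirely
  zero is `nonconvergence` for Wald-type tests ($\hat\beta_1$ infinite)
  while the GST still returns a finite statistic.
* A zero robust variance with a zero statistic yields $p = 1$ (no
  evidence); with a nonzero statistic it is reported as nonconvergence.
* The covariance Cholesky adds a $10^{-10}$ jitter (escalating to
  $10^{-6}$) only if the kernel matrix is numerically semidefinite.
* K-means uses k-means++ seeding, 10 restarts, Lloyd iterations to a
  $10^{-8}$ relative WSS change, farthest-point re-seeding of emptied
  clusters, and a fixed seed: partitions are bit-reproducible, which the
  cluster-dependent tests require. Coordinates are not standardized (both
  axes already share units on a lattice).
* QQ plots cap $-\log_{10} p$ at 320 to avoid underflow infinities.
* Ties in the median split go to the lower half, making the two
  pseudo-groups differ by at most one spot.

## Known limitations

* Only the independence working correlation is implemented; exchangeable
  or AR(1) structures are out of scope, as are small-sample sandwich
  corrections (Mancl–DeRouen type), which would temper the $m = 25$ Wald
  inflation.
* Grades are binary; multi-group comparisons and multi-slide designs are
  not supported.
* The likelihood-based spatial GLMM is used only as a generative model;
  fitting it per gene is numerically fragile on zero-inflated counts and
  is deliberately not provided.
* With contiguous regions and mid-range spatial correlation (the
  confounding regime described above), no test in this family — nor any
  marginal two-sample test — controls type I error; detecting that regime
  from a single gene is an open problem, and negative-control splits
  (`spatial_split()`) are the practical diagnostic.
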