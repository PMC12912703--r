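test_that("scan equals per-gene test calls and flags flat genes", {
  ds <- make_test_dataset(n_genes = 8, n_spots = 32, seed = 19)
  # add one flat gene (equal counts everywhere) and one all-zero gene
  counts <- rbind(as.matrix(ds$counts), flat = 2L, zero = 0L)
  ds2 <- st_dataset(counts, ds$coords, ds$labels)
  scan <- scan_genes(ds2, method = "independent-gee")
  expect_equal(nrow(scan), 10)
  single <- purrr::map_dfr(seq_len(10), function(j) {
    y <- as.numeric(counts[j, ])
    independent_gee_test(y, ds2$labels)
  })
  expect_equal(scan$p_value, single$p_value, tolerance = 1e-12)
  expect_equal(scan$status, single$status)
  expect_equal(scan$p_value[9], 1) # flat gene: equal group means
  expect_equal(scan$status[10], "degenerate_input")

  # clustered scan with m computed internally is deterministic given seed
  s1 <- scan_genes(ds2, method = "gee-gst", m = 4, seed = 2)
  s2 <- scan_genes(ds2, method = "gee-gst", m = 4, seed = 2)
  expect_identical(s1$p_value, s2$p_value)
  expect_error(scan_genes(ds2, method = "gee-wald"), class = "stgee_value_error")
})

test_that("BH and Bonferroni adjustments match brute-force step-up arithmetic", {
  expect_equal(
    adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "BH"),
    rep(0.04, 4)
  )
  expect_equal(adjust_pvalues(rep(0.01, 3), "bonferroni"), rep(0.03, 3))
  expect_equal(adjust_pvalues(c(1e-5, 0.5), "bonferroni"), c(2e-5, 1))
  set.seed(40)
  for (rep in 1:10) {
    p <- runif(sample(5:50, 1))
    expect_equal(adjust_pvalues(p, "BH"), brute_bh(p), tolerance = 1e-12)
    expect_equal(adjust_pvalues(p, "bonferroni"), pmin(p * length(p), 1))
  }
  expect_error(adjust_pvalues(c(0.5, 1.2)), class = "stgee_value_error")
})

test_that("missing p-values are excluded from M and propagated", {
  p <- c(0.01, NA, 0.04)
  bh <- adjust_pvalues(p, "BH")
  expect_true(is.na(bh[2]))
  expect_equal(bh[c(1, 3)], brute_bh(c(0.01, 0.04)))
  bon <- adjust_pvalues(p, "bonferroni")
  expect_equal(bon[c(1, 3)], pmin(c(0.01, 0.04) * 2, 1)) # M = 2, not 3
})

test_that("scan-level adjustments respect the rowwise ordering invariants", {
  ds <- make_test_dataset(n_genes = 10, n_spots = 40, seed = 23)
  scan <- scan_genes(ds, method = "wilcoxon")
  ok <- !is.na(scan$p_value)
  expect_true(all(scan$p_bh[ok] >= scan$p_value[ok]))
  expect_true(all(scan$p_bonferroni[ok] >= scan$p_value[ok]))
  expect_true(all(scan$p_bh[ok] <= 1 & scan$p_bonferroni[ok] <= 1))
  # BH monotone in raw p
  o <- order(scan$p_value[ok])
  expect_true(!is.unsorted(scan$p_bh[ok][o]))
})

test_that("qq_data pairs sorted observed with uniform order statistics", {
  m <- 99
  p <- (1:m) / (m + 1)
  qq <- qq_data(sample(p))
  expect_equal(qq$observed, qq$expected, tolerance = 1e-12)
  one <- qq_data(0.5)
  expect_equal(one$expected, -log10(1 / 2))
  expect_equal(one$observed, -log10(0.5))
  capped <- qq_data(c(0, 0.5))
  expect_equal(max(capped$observed), 320)
})

test_that("stratified summary bins genes by zero fraction with an elementwise oracle", {
  ds <- make_test_dataset(n_genes = 12, n_spots = 36, seed = 29)
  scan <- scan_genes(ds, method = "ztest")
  strat <- stratified_summary(scan)
  expect_equal(nrow(strat), 4)
  expect_equal(sum(strat$n_genes), sum(!is.na(scan$p_value)))
  br <- c(0, 0.25, 0.5, 0.75, 1)
  for (k in 1:4) {
    zf <- scan$zero_fraction
    in_bin <- if (k < 4) zf >= br[k] & zf < br[k + 1] else zf >= br[4] & zf <= 1
    expect_equal(strat$n_genes[k], sum(in_bin & !is.na(scan$p_value)))
  }
  # a single all-covering bin reproduces the global QQ data
  all_in <- stratified_summary(scan, c(0, 1))
  expect_equal(all_in$qq[[1]], qq_data(scan$p_value))
  expect_error(stratified_summary(scan, c(0.1, 1)), class = "stgee_value_error")
})

test_that("plot constructors return ggplot objects", {
  ds <- make_test_dataset(n_genes = 6, n_spots = 24, seed = 31)
  scan <- scan_genes(ds, method = "wilcoxon")
  expect_s3_class(plot_qq(scan), "ggplot")
  expect_s3_class(ggplot2::autoplot(scan), "ggplot")
})
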