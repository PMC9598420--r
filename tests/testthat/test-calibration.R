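test_that("random track generator is seeded, bounded and uniform", {
  tr1 <- generate_random_track_pair(n_a = 200, n_b = 100, seed = 5)
  tr2 <- generate_random_track_pair(n_a = 200, n_b = 100, seed = 5)
  expect_identical(tr1$A$elements, tr2$A$elements)
  expect_identical(tr1$B$elements, tr2$B$elements)
  expect_equal(nrow(tr1$A$elements), 200L)
  len <- tr1$A$elements$length
  expect_true(all(len >= 1 & len <= 1e4))
  # centers uniform on the span: chi-square GOF
  tr <- generate_random_track_pair(n_a = 1000, n_b = 1, seed = 9)
  ctr <- tr$A$elements$center
  obs <- table(cut(ctr, breaks = seq(0, 2e8, length.out = 21)))
  p <- suppressWarnings(stats::chisq.test(obs)$p.value)
  expect_gt(p, 0.001)
  expect_error(generate_random_track_pair(max_length = 0), "max_length")
})

test_that("element-count tuning reaches the target pair count", {
  n <- tune_element_count(200, seed = 31)
  ks <- vapply(1:5, function(i) {
    tr <- generate_random_track_pair(n_a = n, n_b = n, seed = 100 + i)
    sum(track_pairs(tr$A, tr$B)$pair_class == "ABA_BAB")
  }, numeric(1))
  expect_lt(abs(mean(ks) - 200) / 200, 0.1)
})

test_that("null zeta sampling is reproducible under a fixed seed", {
  z1 <- null_zeta_sample(60, 25, seed = 77)
  z2 <- null_zeta_sample(60, 25, seed = 77)
  expect_identical(as.numeric(z1), as.numeric(z2))
})

test_that("calibrated thresholds are ordered across levels and interpolate", {
  tb <- test_thresholds()
  expect_true(all(tb$thresholds["p0.01", ] > tb$thresholds["p0.05", ]))
  # interpolation reproduces grid values within Monte-Carlo error
  for (lv in c(0.05, 0.01)) {
    i <- match(lv, tb$levels)
    at_grid <- vapply(tb$k_grid, threshold_at, numeric(1), table = tb,
                      level = lv)
    emp <- tb$thresholds[i, ]
    expect_true(all(abs(at_grid - emp) / emp < 0.1))
  }
  expect_error(threshold_at(tb, 10, 0.05), "below calibrated range")
  expect_error(threshold_at(tb, 100, 0.5), "not calibrated")
})

test_that("saturating curve fit recovers known parameters on a clean grid", {
  k <- c(50, 100, 200, 400, 800, 1600)
  true <- list(z_min = 0, z_max = 1.4, b = -20, k_min = -60)
  thr <- true$z_min + (true$z_max - true$z_min) * (1 + true$b / (k - true$k_min))
  fit <- fit_threshold_curve(k, thr)
  expect_true(fit$converged)
  expect_lt(abs(fit$z_max - true$z_max) / true$z_max, 0.01)
  expect_lt(abs(fit$b - true$b) / abs(true$b), 0.01)
  # fitted curve is monotone over the grid range
  grid <- seq(min(k), max(k), length.out = 200)
  vals <- trackcoloc:::.curve_eval(fit, grid)
  expect_true(all(diff(vals) > 0) || all(diff(vals) < 0))
  expect_error(fit_threshold_curve(c(50, 100, 200), thr[1:3]), "length")
})

test_that("threshold tables survive a JSON round trip exactly", {
  tb <- test_thresholds()
  path <- tempfile(fileext = ".json")
  save_threshold_table(tb, path)
  tb2 <- load_threshold_table(path)
  expect_equal(tb2$thresholds, tb$thresholds)
  for (K in c(60, 150, 500, 800))
    expect_equal(threshold_at(tb2, K, 0.05), threshold_at(tb, K, 0.05),
                 tolerance = 1e-12)
})

test_that("Gaussian mapping turns thresholds into calibrated p-values", {
  tb <- test_thresholds()
  thr <- threshold_at(tb, 100, 0.05)
  pv <- approx_pvalue(tb, 100, -thr * (1 + 1e-9))
  expect_equal(pv$lambda_zeta, 1.96, tolerance = 1e-6)
  expect_equal(pv$p, 0.05, tolerance = 1e-3)
  expect_equal(pv$significant_at, "0.05")
  expect_equal(pv$direction, "colocalized")
  pv0 <- approx_pvalue(tb, 100, 0)
  expect_equal(pv0$p, 1)
  expect_equal(pv0$significant_at, "none")
  thr01 <- threshold_at(tb, 100, 0.01)
  pv1 <- approx_pvalue(tb, 100, thr01 * 1.01)
  expect_equal(pv1$significant_at, "0.01")
  expect_equal(pv1$direction, "anti_colocalized")
})

test_that("thresholds depend only weakly on the mean index regime", {
  # same K, very different density regimes: mean IO near 0 vs near -0.5
  th_mid <- empirical_threshold(150, 0.05, 1200, seed = 51,
                                max_length = 3e5)
  th_dense <- empirical_threshold(150, 0.05, 1200, seed = 52,
                                  max_length = 9e5)
  expect_lt(abs(th_mid - th_dense) / ((th_mid + th_dense) / 2), 0.2)
})
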