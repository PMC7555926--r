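test_that("metabolic index formulas are exact", {
  expect_equal(homa_ir(22.5, 1), 1)
  expect_equal(homa_ir(0, 7), 0)
  expect_equal(homa_ir(15, 5.5), 15 * 5.5 / 22.5)
  expect_error(homa_ir(-1, 5), "non-negative")

  expect_equal(tyg_index(2, 1), 0)
  expect_equal(tyg_index(116, 86.4), log(116 * 86.4 / 2))
  # strictly increasing in each argument
  expect_true(tyg_index(120, 86.4) > tyg_index(116, 86.4))
  expect_true(tyg_index(116, 90) > tyg_index(116, 86.4))
  expect_error(tyg_index(0, 5), "positive")

  expect_equal(lee_index(1, 1), 1)
  expect_equal(lee_index(8^3, 2), 4)
  expect_equal(lee_index(548, 26.7), 548^(1 / 3) / 26.7)
  # rounded-exponent variant differs by ~2% at physiological weights
  expect_lt(abs(lee_index(548, 26.7, exponent = 0.33) /
                  lee_index(548, 26.7) - 1), 0.03)
})

test_that("GTT AUC is the trapezoidal area", {
  expect_equal(gtt_auc(c(0, 180), c(5, 5)), 900)
  expect_equal(gtt_auc(c(0, 180), c(4, 6)), 900)
  # oracle: fine-grid integral of the linear interpolant
  minutes <- c(0, 15, 30, 45, 60, 90, 120, 180)
  glucose <- c(4.8, 9.5, 11.2, 10.1, 8.9, 7.2, 6.0, 5.1)
  grid <- seq(0, 180, by = 0.001)
  fine <- approx(minutes, glucose, xout = grid)$y
  oracle <- sum((head(fine, -1) + tail(fine, -1)) / 2) * 0.001
  expect_equal(gtt_auc(minutes, glucose), oracle, tolerance = 1e-9)
  expect_error(gtt_auc(c(0, 10, 5), c(1, 2, 3)), "increasing")
})

test_that("correlation p-values follow the exact t-transform", {
  # perfectly linear data
  x <- 1:10
  expect_equal(pearson_test(x, 2 * x + 1)$r, 1)
  # agreement with the independent stats::cor.test implementation
  set.seed(11)
  for (i in 1:5) {
    x <- rnorm(20)
    y <- 0.5 * x + rnorm(20)
    ours <- pearson_test(x, y)
    ref <- cor.test(x, y)
    expect_equal(ours$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
  # spearman equals pearson on ranks
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  y <- c(2, 7, 1, 8, 2.8, 1.8, 2.9)
  expect_equal(spearman_test(x, y)$r, cor(rank(x), rank(y)))
})

test_that("pearson p-values match a permutation oracle", {
  set.seed(23)
  n <- 20
  n_perm <- 4000
  for (rep in 1:3) {
    x <- rnorm(n)
    y <- 0.4 * x + rnorm(n)
    res <- pearson_test(x, y)
    robs <- abs(res$r)
    perm <- replicate(n_perm, abs(cor(x, sample(y))))
    p_perm <- (sum(perm >= robs) + 1) / (n_perm + 1)
    mc_err <- 4 * sqrt(p_perm * (1 - p_perm) / n_perm) + 2 / n_perm
    expect_lt(abs(res$p - p_perm), mc_err + 0.01)
  }
})

test_that("group comparison is gated on Shapiro-Wilk normality", {
  # identical tied groups: rank test via midranks, p = 1
  a <- rep(c(1, 1, 2, 2, 3), 3)
  res <- compare_groups(a, a)
  expect_equal(res$p, 1, tolerance = 1e-9)

  # normal shifted data selects the t branch in most seeded replicates
  picks_t <- vapply(1:40, function(i) {
    set.seed(100 + i)
    a <- rnorm(14)
    b <- rnorm(14, mean = 1.5)
    compare_groups(a, b)$test == "t"
  }, logical(1))
  expect_gte(mean(picks_t), 0.9)

  # heavy-tailed data routes to Mann-Whitney in the majority of replicates
  picks_mw <- vapply(1:40, function(i) {
    set.seed(200 + i)
    a <- exp(rnorm(14, sd = 1.5))
    b <- exp(rnorm(14, sd = 1.5))
    compare_groups(a, b)$test == "mann-whitney"
  }, logical(1))
  expect_gt(mean(picks_mw), 0.5)
})
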