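test_that("an empty configuration yields an empty cohort", {
  co <- generate_cohort(cohort_config(n_per_group = 0))
  expect_equal(nrow(co), 0)
})

test_that("cohort generation is deterministic per seed", {
  a <- generate_cohort(cohort_config(n_per_group = 5, seed = 42))
  b <- generate_cohort(cohort_config(n_per_group = 5, seed = 42))
  c <- generate_cohort(cohort_config(n_per_group = 5, seed = 43))
  expect_identical(a$fat_mass, b$fat_mass)
  expect_identical(a$vonfrey[[1]], b$vonfrey[[1]])
  expect_false(identical(a$fat_mass, c$fat_mass))
})

test_that("group means and configured effect directions are reproduced", {
  set.seed(1)
  n_rep <- 60
  dirs <- matrix(NA, n_rep, 4)
  bw <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    co <- generate_cohort(cohort_config(seed = 1000 + i))
    m <- function(f, g) mean(co[[f]][co$group == g])
    dirs[i, ] <- c(m("body_weight", "caf") > m("body_weight", "chow"),
                   m("FBG", "caf") > m("FBG", "chow"),
                   m("triglycerides", "caf") > m("triglycerides", "chow"),
                   m("HDL", "caf") < m("HDL", "chow"))
    bw[i] <- m("body_weight", "chow")
  }
  expect_gte(mean(dirs[, 1]), 0.95)
  expect_gte(mean(dirs[, 2]), 0.95)
  expect_gte(mean(dirs[, 3]), 0.95)
  expect_gte(mean(dirs[, 4]), 0.95)
  expect_lt(abs(mean(bw) - 548) / 548, 0.01)
})

test_that("GTT curves start at the configured fasting glucose and CAF has larger AUC", {
  cfg <- cohort_config()
  set.seed(2)
  auc_chow <- replicate(100, {
    g <- generate_gtt(cfg, "chow")
    gtt_auc(g$minute, g$glucose)
  })
  set.seed(2)
  auc_caf <- replicate(100, {
    g <- generate_gtt(cfg, "caf")
    gtt_auc(g$minute, g$glucose)
  })
  expect_gte(mean(auc_caf > auc_chow), 0.95)
  g <- generate_gtt(cfg, "chow")
  expect_equal(g$glucose[1], cfg$gtt$baseline[["chow"]])

  # zero noise and zero excursion amplitude give a flat curve
  cfg0 <- cohort_config(gtt = list(baseline = c(chow = 5, caf = 5),
                                   A = c(chow = 0, caf = 0),
                                   t_peak = c(chow = 30, caf = 45),
                                   noise_sd = 0))
  g0 <- generate_gtt(cfg0, "chow")
  expect_equal(g0$glucose, rep(5, 8))
})

test_that("degenerate psychometric functions hit the boundary rules", {
  cfg <- cohort_config(vonfrey = list(theta_g = c(chow = 3, caf = 4),
                                      log10_sd = 0, sigma = 1e-12))
  set.seed(3)
  s_low <- generate_vonfrey_sequence(cfg, theta = 0.01)
  expect_equal(vonfrey_50pwt(s_low), 0.4)
  s_high <- generate_vonfrey_sequence(cfg, theta = 100)
  expect_equal(vonfrey_50pwt(s_high), 15)
})

test_that("generator reproduces the configured pooled correlation structure", {
  set.seed(4)
  n_rep <- 300
  rs <- vapply(seq_len(n_rep), function(i) {
    co <- generate_cohort(cohort_config(seed = 5000 + i))
    cor(co$superexcitability, co$fat_mass)
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.497), 0.03)
})

test_that("cohort analysis recovers the built-in group effects and correlations", {
  co <- generate_cohort(cohort_config(n_per_group = 14, seed = 77))
  gt <- cohort_group_tests(co, c("body_weight", "HDL", "superexcitability"))
  expect_equal(nrow(gt), 3)
  expect_true(all(gt$test %in% c("t", "mann-whitney")))
  # configured large effects are detected
  expect_lt(gt$p[gt$field == "body_weight"], 0.001)
  expect_gt(gt$caf_mean[gt$field == "body_weight"],
            gt$chow_mean[gt$field == "body_weight"])
  cc <- cohort_correlations(co, fields = c("fat_mass", "HDL"))
  expect_equal(cc$method, rep("pearson", 2))
  expect_true(all(abs(cc$r) <= 1))
  expect_true(all(cc$n == 28))
  sp <- cohort_correlations(co, fields = "HOMA_IR", method = "spearman")
  expect_equal(sp$method, "spearman")
})
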