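test_that("boundary rules assign the edge filament forces", {
  all_pos <- data.frame(filament_g = c(2, 1.4, 1, 0.6, 0.4),
                        response = rep("+", 5))
  expect_equal(vonfrey_50pwt(all_pos), 0.4)
  all_neg <- data.frame(filament_g = c(2, 4, 6, 8, 10, 15),
                        response = rep("-", 6))
  expect_equal(vonfrey_50pwt(all_neg), 15)
})

test_that("sequences violating the up-down rule are rejected", {
  bad_start <- data.frame(filament_g = c(4, 6), response = c("-", "-"))
  expect_error(vonfrey_50pwt(bad_start), "start at the 2")
  wrong_step <- data.frame(filament_g = c(2, 6), response = c("-", "-"))
  expect_error(vonfrey_50pwt(wrong_step), "up-down rule violated")
  off_set <- data.frame(filament_g = c(2, 3), response = c("-", "+"))
  expect_error(vonfrey_50pwt(off_set), "not in the filament set")
})

test_that("interior patterns match the probit-MLE oracle", {
  # several mixed sequences; the estimator's k table is generated by the
  # same oracle, so agreement must be exact up to optimizer tolerance
  cases <- list(
    data.frame(filament_g = c(2, 4, 2, 4),
               response = c("-", "+", "-", "+")),
    data.frame(filament_g = c(2, 1.4, 2, 1.4, 2, 4),
               response = c("+", "-", "+", "-", "-", "+")),
    data.frame(filament_g = c(2, 4, 6, 4, 6, 8),
               response = c("-", "-", "+", "-", "-", "-"))
  )
  delta <- mean(diff(log10(vf_filament_set())))
  for (s in cases) {
    pat <- paste(s$response, collapse = "")
    mle <- vonfrey_probit_mle(pat, final_g = s$filament_g[nrow(s)],
                              delta = delta)
    expect_equal(vonfrey_50pwt(s), mle$threshold_g, tolerance = 1e-6)
  }
})

test_that("the packaged k table reproduces the oracle", {
  path <- system.file("extdata", "vonfrey_k_table.csv",
                      package = "axotrace")
  expect_true(nzchar(path))
  tab <- read.csv(path, stringsAsFactors = FALSE)
  expect_gt(nrow(tab), 50)
  set.seed(5)
  pick <- sample(nrow(tab), 12)
  for (i in pick) {
    expect_equal(tab$k[i], vonfrey_probit_mle(tab$pattern[i])$k,
                 tolerance = 1e-6, label = tab$pattern[i])
  }
})

test_that("estimates always lie inside the filament range", {
  set.seed(9)
  cfg <- cohort_config()
  for (i in 1:50) {
    theta <- 10^runif(1, log10(0.1), log10(40))
    s <- generate_vonfrey_sequence(cfg, theta)
    pwt <- vonfrey_50pwt(s)
    expect_gte(pwt, 0.4)
    expect_lte(pwt, 15)
  }
})

test_that("up-down estimator is consistent for the latent threshold", {
  set.seed(31)
  cfg <- cohort_config()
  theta <- 4
  est <- replicate(400, {
    vonfrey_50pwt(generate_vonfrey_sequence(cfg, theta))
  })
  expect_lt(abs(mean(est) - theta) / theta, 0.10)
})
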