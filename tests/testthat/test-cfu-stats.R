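test_that("CFU/ml follows the hand-computed dilution arithmetic", {
  # 34 colonies at 10^4 from a 10 ul droplet: 34 x 1e4 / 0.01 = 3.4e7
  s <- tibble::tibble(dilution = 1e4, count = 34)
  est <- cfu_per_ml(s, plated_ul = 10, countable_range = c(3, 50))
  expect_equal(est$cfu_per_ml, 3.4e7)
  expect_equal(est$n_countable_rows, 1L)
  expect_false(est$discordant)

  # only the countable row is used: 1 colony at 1e4 is below range
  s2 <- tibble::tibble(dilution = c(1e3, 1e4), count = c(10, 1))
  expect_equal(cfu_per_ml(s2)$cfu_per_ml, 10 * 1e3 / 0.01)

  # concordant multi-row series pool colonies Poisson-optimally
  s3 <- tibble::tibble(dilution = c(1e2, 1e3), count = c(30, 3))
  est3 <- cfu_per_ml(s3)
  expect_equal(est3$cfu_per_ml, 33 / (0.01 / 1e2 + 0.01 / 1e3))
  expect_false(est3$discordant)

  # > 2x disagreement between countable rows is flagged
  s4 <- tibble::tibble(dilution = c(1e2, 1e3), count = c(10, 25))
  expect_true(cfu_per_ml(s4)$discordant)

  # sterile series: zero with a below-detection flag, not an error
  s5 <- tibble::tibble(dilution = 10^(0:6), count = rep(0L, 7))
  est5 <- cfu_per_ml(s5)
  expect_equal(est5$cfu_per_ml, 0)
  expect_true(est5$below_detection)

  expect_error(cfu_per_ml(tibble::tibble(dilution = 1e2, count = 100)),
               "above")
  expect_error(cfu_per_ml(tibble::tibble(dilution = 1e6, count = 1)),
               "below")
  expect_error(cfu_per_ml(s, plated_ul = 0), "positive")
  expect_error(cfu_per_ml(tibble::tibble(dilution = c(10, 10),
                                         count = c(5, 6))), "unique")
  # exactly linear in colony count at fixed dilution
  e1 <- cfu_per_ml(tibble::tibble(dilution = 1e3, count = 5))$cfu_per_ml
  e2 <- cfu_per_ml(tibble::tibble(dilution = 1e3, count = 25))$cfu_per_ml
  expect_equal(e2, 5 * e1)
})

test_that("survival normalizes to the matched control", {
  expect_equal(survival_fraction(3e6, 3e6)$survival, 1)
  s0 <- survival_fraction(0, 1e7)
  expect_equal(s0$survival, 0)
  expect_match(s0$flag, "below detection")
  expect_equal(survival_fraction(2e7, 1e7)$survival, 2)  # growth allowed
  expect_error(survival_fraction(1e5, 0), "not positive")
})

test_that("survival estimation is unbiased in Poisson simulation", {
  set.seed(123)
  n_rep <- 200
  est <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    treated <- make_cfu_counts(0.1, 1e8, condition = "treated")
    control <- make_cfu_counts(1, 1e8, condition = "untreated")
    t_est <- cfu_per_ml(treated)$cfu_per_ml
    c_est <- cfu_per_ml(control)$cfu_per_ml
    est[i] <- survival_fraction(t_est, c_est)$survival
  }
  se <- sd(est) / sqrt(n_rep)
  expect_lt(abs(mean(est) - 0.1), 3 * se)
})

test_that("Welch t matches the closed-form oracle to 1e-10", {
  # x = {1,2,3,4}, y = {2,4,6,8}: by hand, s2x = 5/3, s2y = 20/3,
  # se^2 = 25/12, t = -2.5 / sqrt(25/12) = -sqrt(3),
  # df = (25/12)^2 / ((5/12)^2/3 + (20/12)^2/3) = 75/17;
  # p frozen from an independent implementation (scipy.stats).
  tt <- welch_ttest(c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_equal(tt$t_statistic, -sqrt(3), tolerance = 1e-12)
  expect_equal(tt$df, 75 / 17, tolerance = 1e-12)
  expect_equal(tt$p_two_sided, 0.15158050484530375, tolerance = 1e-10)
  expect_equal(tt$mean_x, 2.5)
  expect_equal(tt$n_y, 4L)
})

test_that("Welch t agrees with stats::t.test on random samples", {
  set.seed(31)
  for (i in 1:25) {
    x <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1),
               sd = runif(1, 0.5, 3))
    tt <- welch_ttest(x, y)
    ref <- t.test(x, y, var.equal = FALSE)
    expect_equal(tt$t_statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(tt$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(tt$p_two_sided, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Welch t edge cases follow the documented contract", {
  x <- c(1.5, 2.5, 3.5)
  tt <- welch_ttest(x, x)
  expect_equal(tt$t_statistic, 0)
  expect_equal(tt$p_two_sided, 1)
  # antisymmetry
  y <- c(2, 3, 9)
  a <- welch_ttest(x, y); b <- welch_ttest(y, x)
  expect_equal(a$t_statistic, -b$t_statistic)
  expect_equal(a$p_two_sided, b$p_two_sided)
  expect_equal(sign(a$t_statistic), sign(a$mean_x - a$mean_y))
  # zero-variance degeneracies
  d1 <- welch_ttest(c(2, 2, 2), c(2, 2, 2))
  expect_equal(d1$p_two_sided, 1)
  d2 <- welch_ttest(c(2, 2, 2), c(3, 3, 3))
  expect_equal(d2$p_two_sided, 0)
  expect_true(d2$degenerate)
  expect_error(welch_ttest(1, c(1, 2)), "at least 2")
  expect_error(welch_ttest(c(1, NA, 3), c(1, 2, 3)), "finite")
  # equal variances and sizes reduce to the pooled-t df
  e <- welch_ttest(c(1, 2, 3), c(5, 6, 7))
  expect_equal(e$df, 4)
})

test_that("tidy and glance return broom-shaped rows", {
  tt <- welch_ttest(c(1, 2, 3, 4), c(2, 4, 6, 8))
  td <- tidy(tt)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$estimate, -2.5)
  expect_equal(td$statistic, tt$t_statistic)
  expect_equal(td$parameter, tt$df)
  expect_equal(glance(tt)$p.value, tt$p_two_sided)
})

test_that("condition comparisons label significance like the figures", {
  tbl <- tibble::tibble(
    condition = rep(c("treated", "untreated", "same"), each = 3),
    replicate = rep(1:3, 3),
    value = c(0.60, 0.67, 0.62, 0.055, 0.062, 0.060, 0.60, 0.67, 0.62))
  res <- compare_conditions(tbl, list(c("treated", "untreated"),
                                      c("treated", "same")))
  expect_equal(nrow(res), 2L)
  expect_lt(res$p_value[1], 0.05)
  expect_false(res$label[1] == "ns")
  expect_equal(res$label[2], "ns")
  expect_equal(res$fold[1], mean(c(0.60, 0.67, 0.62)) /
                 mean(c(0.055, 0.062, 0.060)))
  # empty pair list and lookup errors
  expect_equal(nrow(compare_conditions(tbl, list())), 0L)
  expect_error(compare_conditions(tbl, list(c("treated", "ghost"))),
               "not found")
  # Holm flag adjusts p-values monotonically
  res_h <- compare_conditions(tbl, list(c("treated", "untreated"),
                                        c("treated", "same")), holm = TRUE)
  expect_gte(res_h$p_value[1], res$p_value[1])
})
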