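test_that("single-observation fixed-slope fit has the closed-form intercept", {
  f <- fit_loglog_glm(data.frame(cells_per_well = 2, n_wells = 4, n_negative = 2),
                      slope_fixed = TRUE)
  expect_equal(f$alpha, log(-log(0.5)) - log(2), tolerance = 1e-8)
  expect_identical(f$b, 1)
  expect_true(f$slope_fixed)
  expect_equal(f$n_params, 1L)
  expect_equal(dim(f$cov), c(1L, 1L))
})

test_that("free-slope fit equals a complementary log-log regression on successes", {
  for (seed in c(2, 17, 31, 58)) {
    d <- random_small_dataset(seed)
    mine <- fit_loglog_glm(d)
    oracle <- suppressWarnings(glm(
      cbind(n_wells - n_negative, n_negative) ~ log(cells_per_well),
      family = binomial("cloglog"), data = d,
      control = glm.control(epsilon = 1e-12, maxit = 100)))
    expect_equal(unname(coef(mine)), unname(coef(oracle)), tolerance = 1e-6)
    expect_equal(unname(vcov(mine)), unname(vcov(oracle)), tolerance = 1e-5)
    expect_equal(mine$deviance, deviance(oracle), tolerance = 1e-6)
    expect_equal(mine$aic, AIC(oracle), tolerance = 1e-6)
    expect_equal(mine$aic, -2 * mine$log_likelihood + 2 * mine$n_params)
  }
})

test_that("rescaling the dilution ladder shifts alpha by -b log(c) and leaves b alone", {
  d <- random_small_dataset(7)
  f0 <- fit_loglog_glm(d)
  for (c_scale in c(0.25, 3)) {
    d2 <- d
    d2$cells_per_well <- d$cells_per_well * c_scale
    f2 <- fit_loglog_glm(d2)
    expect_equal(f2$b, f0$b, tolerance = 1e-6)
    expect_equal(f2$alpha, f0$alpha - f0$b * log(c_scale), tolerance = 1e-6)
  }
})

test_that("degenerate data are refused or flagged rather than estimated", {
  all_neg <- data.frame(cells_per_well = c(1, 2, 4), n_wells = 12,
                        n_negative = 12)
  expect_error(fit_loglog_glm(all_neg), class = "lda_estimation_error",
               regexp = "clonogenic growth")

  all_pos <- data.frame(cells_per_well = c(1, 2, 4), n_wells = 12,
                        n_negative = 0)
  expect_warning(f <- fit_loglog_glm(all_pos), regexp = "boundary")
  expect_false(f$converged)

  one_s <- data.frame(cells_per_well = c(2, 2), n_wells = 12,
                      n_negative = c(3, 5))
  expect_error(fit_loglog_glm(one_s), class = "lda_input_error",
               regexp = "distinct")
})

test_that("predicted failure fraction follows the inverse link and decreases in S", {
  # alpha = 0, b = 1 at S = 1 means lambda = 1: mu = exp(-1)
  d <- random_small_dataset(3)
  f <- fit_loglog_glm(d)
  f$alpha <- 0; f$b <- 1
  expect_equal(predict_failure_fraction(f, 1)$mu, exp(-1), tolerance = 1e-12)

  # inverse of the saturated two-point example
  f2 <- fit_loglog_glm(data.frame(cells_per_well = c(1, 4), n_wells = 4,
                                  n_negative = c(2, 1)))
  expect_equal(predict_failure_fraction(f2, 4)$mu, 0.25, tolerance = 1e-6)

  S <- 2^seq(-3, 10, by = 0.5)
  pr <- predict_failure_fraction(fit_loglog_glm(d), S)
  expect_true(all(diff(pr$mu) < 0))
  expect_true(all(pr$lower <= pr$mu & pr$mu <= pr$upper))
  expect_true(all(pr$lower >= 0 & pr$upper <= 1))
  expect_error(predict_failure_fraction(f, -1), class = "lda_input_error")
})

test_that("model comparison is a chi-squared(1) test on the deviance gap", {
  d <- random_small_dataset(12)
  ff <- fit_loglog_glm(d)
  fx <- fit_loglog_glm(d, slope_fixed = TRUE)
  cm <- compare_models(ff, fx)
  expect_gte(cm$delta_deviance, 0)
  expect_equal(cm$lrt_p, pchisq(cm$delta_deviance, 1, lower.tail = FALSE))
  expect_equal(cm$delta_aic, fx$aic - ff$aic)

  # saturated two-point free fit: nesting keeps delta deviance >= 0
  d2 <- data.frame(cells_per_well = c(1, 4), n_wells = 4, n_negative = c(2, 1))
  cm2 <- compare_models(fit_loglog_glm(d2), fit_loglog_glm(d2, slope_fixed = TRUE))
  expect_equal(cm2$delta_deviance,
               fit_loglog_glm(d2, slope_fixed = TRUE)$deviance)

  # mismatched data are rejected
  expect_error(compare_models(ff, fit_loglog_glm(d2, slope_fixed = TRUE)),
               class = "lda_input_error")
  expect_error(compare_models(fx, ff), class = "lda_input_error")
})

test_that("fit_table reports one row per group with standard errors", {
  sim <- simulate_lda(p = 0.12, b = 1.2, n_replicates = 2,
                      treatments = c(ctrl = 1, trt = 0.5), seed = 9)
  tab_pooled <- fit_table(sim, mode = "pooled")
  expect_equal(nrow(tab_pooled), 2)
  tab_rep <- fit_table(sim, mode = "per_replicate")
  expect_equal(nrow(tab_rep), 4)
  expect_true(all(c("alpha", "b", "se_alpha", "se_b", "cov_ab",
                    "deviance", "aic", "converged") %in% names(tab_rep)))
  expect_true(all(tab_rep$se_alpha > 0))
})
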