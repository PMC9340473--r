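linear_dataset <- function(a = 100, b = 3, sigma = 6, n = 100,
                           doses = c(0, 1, 2, 4, 8)) {
  # group means exactly on the line, group SDs exactly sigma: the ML
  # residual SD is then sigma * sqrt((n-1)/n) and BMD = sigma_hat / b
  tibble::tibble(dose = doses, mean = a - b * doses, sd = sigma, n = n)
}

test_that("linear-model BMD matches the closed form sigma/b within 1%", {
  d <- linear_dataset()
  f <- fit_bmd(d, model_family = "linear")
  closed <- 6 * sqrt(99 / 100) / 3
  expect_equal(f$bmd, closed, tolerance = 0.01)
  expect_true(f$bmdl < f$bmd && f$bmd < f$bmdu)
  expect_equal(f$response_direction, "decrease")
})

test_that("BMD estimates are scale-equivariant in dose", {
  d <- generate_dose_response(list(family = "exponential",
                                   params = c(100, -0.3)),
                              doses = c(0, 0.5, 1, 2, 4), sd = 4,
                              n_per_group = 8, seed = 11)
  f1 <- fit_bmd(d, model_family = "exponential")
  d10 <- dplyr::mutate(d, dose = dose * 10)
  f10 <- fit_bmd(d10, model_family = "exponential")
  expect_equal(f10$bmd, 10 * f1$bmd, tolerance = 1e-4)
  expect_equal(f10$bmdl, 10 * f1$bmdl, tolerance = 1e-3)
  expect_equal(f10$bmdu, 10 * f1$bmdu, tolerance = 1e-3)
})

test_that("a larger benchmark response never gives a smaller BMD", {
  d <- generate_dose_response(list(family = "exponential",
                                   params = c(100, -0.3)),
                              doses = c(0, 0.5, 1, 2, 4), sd = 4,
                              n_per_group = 8, seed = 21)
  f1 <- fit_bmd(d, model_family = "exponential", bmr_factor = 1)
  f2 <- fit_bmd(d, model_family = "exponential", bmr_factor = 2)
  expect_gte(f2$bmd, f1$bmd)
})

test_that("flat responses are rejected as unidentifiable", {
  flat <- tibble::tibble(dose = c(0, 1, 2, 4), mean = 100, sd = 5, n = 6)
  expect_error(fit_bmd(flat, model_family = "linear"), "not identifiable")
})

test_that("a BMD above the tested range is flagged as extrapolated", {
  d <- linear_dataset(b = 0.3, sigma = 6, doses = c(0, 1, 2, 4))
  expect_warning(f <- fit_bmd(d, model_family = "linear"), "extrapolated")
  expect_true(f$extrapolated)
  expect_gt(f$bmd, 4)
})

test_that("model selection picks the better-fitting family by AIC", {
  d <- generate_dose_response(list(family = "exponential",
                                   params = c(100, -0.6)),
                              doses = c(0, 0.5, 1, 2, 4), sd = 2,
                              n_per_group = 10, seed = 5)
  f <- fit_bmd(d, model_family = c("exponential", "hill", "linear"))
  expect_true(f$model_name %in% c("exponential", "hill"))
})

test_that("true BMD recovery on generated data is unbiased in the median", {
  true_model <- list(family = "exponential", params = c(100, -0.25))
  doses <- c(0, 0.5, 1, 2, 4)
  bmds <- vapply(1:40, function(r) {
    d <- generate_dose_response(true_model, doses, sd = 4, n_per_group = 6,
                                seed = 1000 + r)
    suppressWarnings(fit_bmd(d, model_family = "exponential")$bmd)
  }, numeric(1))
  true_bmd <- attr(generate_dose_response(true_model, doses, 4, 6, 1),
                   "true_bmd")
  expect_lt(abs(stats::median(bmds) - true_bmd) / true_bmd, 0.25)
})

test_that("lognormal fits require positive means and run end to end", {
  d <- generate_dose_response(list(family = "exponential",
                                   params = c(100, -0.3)),
                              doses = c(0, 0.5, 1, 2, 4), sd = 4,
                              n_per_group = 8, seed = 31)
  f <- fit_bmd(d, model_family = "exponential", distribution = "lognormal")
  expect_true(f$bmd > 0 && f$bmdl <= f$bmd && f$bmd <= f$bmdu)
  bad <- dplyr::mutate(d, mean = mean - 200)
  expect_error(fit_bmd(bad, distribution = "lognormal"), "positive")
})

test_that("quality diagnostics report interval width and distance to data", {
  d <- linear_dataset()
  f <- fit_bmd(d, model_family = "linear")
  q1 <- assess_bmd_quality(f)
  expect_true(q1$acceptable)
  expect_equal(q1$bmdu_bmdl_ratio, f$bmdu / f$bmdl)
  expect_equal(q1$bmdl_to_lowest_dose_ratio, f$bmdl / 1)
  # threshold sweeps change only the flag, never the ratios
  q2 <- assess_bmd_quality(f, max_bmdu_bmdl_ratio = 1.0000001,
                           min_bmdl_fraction_of_lowest_dose = 10)
  expect_false(q2$acceptable)
  expect_equal(q2$bmdu_bmdl_ratio, q1$bmdu_bmdl_ratio)
  expect_equal(q2$bmdl_to_lowest_dose_ratio, q1$bmdl_to_lowest_dose_ratio)
})

test_that("dataset validation enforces the summary-data contract", {
  expect_error(fit_bmd(tibble::tibble(dose = c(0, 1), mean = c(1, 2),
                                      sd = 1, n = 5)), "3 dose groups")
  expect_error(fit_bmd(tibble::tibble(dose = c(1, 2, 3), mean = 1:3,
                                      sd = 1, n = 5)), "control")
  expect_error(fit_bmd(tibble::tibble(dose = c(0, 1, 2), mean = 1:3,
                                      sd = 0, n = 5)), "sd")
  expect_error(fit_bmd(tibble::tibble(dose = c(0, 1, 2), mean = 1:3,
                                      sd = 1, n = 1)), "n >= 2")
})
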