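test_that("the in vitro simulator conserves mass between medium changes", {
  sys <- in_vitro_system(v_medium_ml = 2, v_cells_ml = 0.01,
                         kp_cell_medium = 8, cl_ml_h = 0, nominal_um = 10,
                         n_doses = 3, mw = 206.29)
  s <- simulate_in_vitro(sys, duration_h = 72)
  expect_lt(max(abs(s$balance$rel_error)), 0.005)
  # zero clearance: nothing metabolized, steady cell/medium ratio -> Kp
  expect_equal(max(s$balance$metabolized_ug), 0)
  late <- tail(s$data, 1)
  expect_equal(kp_from_in_vitro(late$cell_conc, late$medium_conc), 8,
               tolerance = 0.02)
})

test_that("single-dose linear depletion decays at CL over total capacity", {
  v_med <- 2; v_cell <- 0.01; kp <- 5; cl <- 0.2
  sys <- in_vitro_system(v_med, v_cell, kp, cl_ml_h = cl, nominal_um = 50,
                         n_doses = 1, mw = 200,
                         cl_exchange_ml_h = 500)
  s <- simulate_in_vitro(sys, duration_h = 48, grid_h = 0.1)
  # with instant partitioning, total amount decays mono-exponentially with
  # rate CL * kp / (v_med + kp * v_cell)
  k_theory <- cl * kp / (v_med + kp * v_cell)
  k_obs <- in_vitro_apparent_depletion(s, 2)
  expect_equal(k_obs, k_theory, tolerance = 0.01)
})

test_that("metabolite product inhibition slows depletion across 14 days", {
  mp <- metabolic_params(4.12, 38.85, "nmol/h/mg", ki_product = 12.1)
  sys <- in_vitro_system(2, 0.01, kp_cell_medium = 50, clearance = mp,
                         protein_mg = 1, nominal_um = 2.5, n_doses = 14,
                         mw = 645.31)
  s <- simulate_in_vitro(sys)
  k1 <- in_vitro_apparent_depletion(s, 1)
  k14 <- in_vitro_apparent_depletion(s, 14)
  expect_lt(k14, k1)
  # without inhibition the day-14 rate does not collapse
  mp0 <- metabolic_params(4.12, 38.85, "nmol/h/mg")
  s0 <- simulate_in_vitro(in_vitro_system(2, 0.01, 50, clearance = mp0,
                                          protein_mg = 1, nominal_um = 2.5,
                                          n_doses = 14, mw = 645.31))
  expect_gt(in_vitro_apparent_depletion(s0, 14) / in_vitro_apparent_depletion(s0, 1),
            k14 / k1)
})

test_that("measurement noise is unbiased, reproducible, and off at cv 0", {
  sys <- in_vitro_system(2, 0.01, 8, cl_ml_h = 0.1, nominal_um = 10,
                         n_doses = 2, mw = 200)
  s <- simulate_in_vitro(sys, duration_h = 48, grid_h = 1)
  expect_identical(add_noise(s, 0, seed = 1), s$data)
  n1 <- add_noise(s, 0.1, seed = 7)
  n2 <- add_noise(s, 0.1, seed = 7)
  expect_identical(n1, n2)
  expect_false(identical(n1, add_noise(s, 0.1, seed = 8)))
  # empirical CV of the multiplicative factors ~ 0.1
  set.seed(99)
  base <- rep(10, 4000)
  noisy <- add_noise(tibble::tibble(time = seq_along(base),
                                    medium_conc = base), 0.1, seed = 3)
  cv_emp <- stats::sd(noisy$medium_conc) / mean(noisy$medium_conc)
  expect_equal(cv_emp, 0.1, tolerance = 0.1)
})

test_that("dose-response generation collapses to the true curve as sd -> 0", {
  tm <- list(family = "exponential", params = c(100, -0.3))
  doses <- c(0, 0.312, 0.625, 1.25, 2.5)
  d <- generate_dose_response(tm, doses, sd = 1e-9, n_per_group = 6,
                              seed = 4)
  expect_equal(d$mean, 100 * exp(-0.3 * doses), tolerance = 1e-6)
  expect_equal(nrow(d), 5)
  expect_true(0 %in% d$dose)
  expect_true(is.finite(attr(d, "true_bmd")))
})
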