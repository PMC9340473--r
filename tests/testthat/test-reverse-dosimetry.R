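# The toy model here is the fast-mixing near-one-compartment fixture, so
# each objective evaluation is cheap and the dose-metric relation is known
# (AUC inf = dose / CL).

test_that("a forward-simulated profile target recovers its generating dose", {
  m <- standard_test_model()
  D_star <- 600
  fwd <- simulate_pbk(m, dosing_regimen("oral", D_star), duration = 12)
  t_obs <- c(0.5, 1, 2, 4, 8)
  liver <- dplyr::filter(tidy(fwd), compartment == "liver",
                         round(time, 9) %in% t_obs)
  target <- target_exposure("profile", "liver",
                            profile = tibble::tibble(time = liver$time,
                                                     conc = liver$conc_ug_ml))
  ds <- optimize_dose_profile(m, dosing_regimen("oral", 1), target,
                              dose_step = 10,
                              sim_args = list(fine_h = 0.05))
  expect_equal(ds$optimized_dose, D_star, tolerance = 1e-9)
  expect_lte(ds$objective, min(ds$trace$objective))
})

test_that("scaling a profile target scales the dose under linear kinetics", {
  m <- standard_test_model()
  fwd <- simulate_pbk(m, dosing_regimen("oral", 300), duration = 8)
  liver <- dplyr::filter(tidy(fwd), compartment == "liver",
                         round(time, 9) %in% c(1, 2, 4, 8))
  prof <- tibble::tibble(time = liver$time, conc = liver$conc_ug_ml)
  step <- 10
  d1 <- optimize_dose_profile(m, dosing_regimen("oral", 1),
                              target_exposure("profile", "liver",
                                              profile = prof),
                              dose_step = step,
                              sim_args = list(fine_h = 0.05))
  prof2 <- dplyr::mutate(prof, conc = conc * 2)
  d2 <- optimize_dose_profile(m, dosing_regimen("oral", 1),
                              target_exposure("profile", "liver",
                                              profile = prof2),
                              dose_step = step,
                              sim_args = list(fine_h = 0.05))
  expect_lte(abs(d2$optimized_dose - 2 * d1$optimized_dose), step)
})

test_that("metric targets solve the linear dose-AUC relation within one step", {
  m <- near_one_compartment_model(cl_L_h = 2, v_central = 10)
  # AUC over a long window ~ dose / CL: target 30 -> dose ~ 60
  target <- target_exposure("auc", "venous", value = 30, window = c(0, 240))
  ds <- optimize_dose_metric(m, dosing_regimen("iv_bolus", 1), target,
                             dose_step = 0.05,
                             sim_args = list(grid_h = 0.5, fine_h = 0.02,
                                             fine_window_h = 0.1))
  expect_lte(abs(ds$achieved_metric - 30), 30 * 0.01)
  expect_equal(ds$optimized_dose, 60, tolerance = 0.02)
  # grid-search optimality against the step-aligned neighbours
  tr <- ds$trace
  neigh <- dplyr::filter(tr,
                         abs(dose - ds$optimized_dose) <= 0.05 * 1.001,
                         abs(dose / 0.05 - round(dose / 0.05)) < 1e-9,
                         dose != ds$optimized_dose)
  expect_gt(nrow(neigh), 0)
  expect_true(all(neigh$objective >= ds$objective))
})

test_that("doubled targets double the optimized dose (linearity sweep)", {
  m <- near_one_compartment_model(cl_L_h = 2, v_central = 10)
  sim_args <- list(grid_h = 0.5, fine_h = 0.02, fine_window_h = 0.1)
  step <- 0.05
  d <- function(v) {
    optimize_dose_metric(m, dosing_regimen("iv_bolus", 1),
                         target_exposure("auc", "venous", value = v,
                                         window = c(0, 240)),
                         dose_step = step, sim_args = sim_args)$optimized_dose
  }
  d1 <- d(10); d2 <- d(20)
  expect_lte(abs(d2 - 2 * d1), 2 * step)
})

test_that("unreachable targets report the nearest achievable metric", {
  m <- near_one_compartment_model(cl_L_h = 2, v_central = 10)
  target <- target_exposure("auc", "venous", value = 50, window = c(0, 24))
  expect_error(
    optimize_dose_metric(m, dosing_regimen("iv_bolus", 1), target,
                         dose_step = 0.5, bounds = c(0, 2),
                         sim_args = list(grid_h = 0.5, fine_h = 0.05,
                                         fine_window_h = 0.1)),
    "nearest achieved"
  )
})

test_that("target validation catches malformed inputs", {
  expect_error(target_exposure("profile",
                               profile = data.frame(time = numeric(),
                                                    conc = numeric())),
               "non-empty")
  expect_error(target_exposure("profile",
                               profile = data.frame(time = c(2, 1),
                                                    conc = c(1, 2))),
               "increasing")
  expect_error(target_exposure("auc", value = 0), "value")
})

test_that("concentration-response tables re-index on optimized doses", {
  tab <- tibble::tibble(dose = c(0, 0.312, 0.625, 1.25, 2.5),
                        mean = c(100, 90, 80, 60, 40), sd = 5, n = 6)
  # identity mapping: table unchanged except relabeled units
  out <- concentration_response_to_dose_response(tab, tab$dose, "mg")
  expect_equal(out$dose, tab$dose)
  expect_equal(out$in_vitro_conc, tab$dose)
  expect_equal(out$mean, tab$mean)
  expect_equal(nrow(out), 5)
  # monotone function mapping
  out2 <- concentration_response_to_dose_response(tab, function(cc) 3 * cc)
  expect_equal(out2$dose, 3 * tab$dose)
  # non-monotone mapping is an internal-consistency error
  expect_error(
    concentration_response_to_dose_response(tab, c(0, 2, 1, 3, 4)),
    "Non-monotone")
})
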