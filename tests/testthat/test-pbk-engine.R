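test_that("a degenerate one-compartment model matches the closed form", {
  V <- 10; CL <- 2; D <- 100
  m <- near_one_compartment_model(cl_L_h = CL, v_central = V)
  sim <- simulate_pbk(m, dosing_regimen("iv_bolus", D), duration = 24)
  prof <- dplyr::filter(tidy(sim), compartment == "venous", time >= 0.5)
  expected <- (D / V) * exp(-CL / V * prof$time)
  expect_lt(max(abs(prof$conc_ug_ml - expected) / expected), 1e-3)
})

test_that("flow-limited kinetics agree with a matrix-exponential oracle", {
  m <- standard_test_model(cl_L_h = 4.38)
  M <- flow_limited_matrix(m)
  D <- 100
  sim <- simulate_pbk(m, dosing_regimen("iv_bolus", D), duration = 12)
  a0 <- setNames(numeric(nrow(M)), rownames(M))
  a0["venous"] <- D
  for (t_chk in c(1, 4, 12)) {
    oracle <- drop(mat_exp(M * t_chk) %*% a0)
    row <- dplyr::filter(tidy(sim), time == t_chk)
    amounts <- setNames(row$amount_mg, row$compartment)[rownames(M)]
    expect_equal(unname(amounts), unname(oracle), tolerance = 1e-6)
  }
})

test_that("with zero clearance the administered dose is conserved", {
  m <- standard_test_model(cl_L_h = 0)
  sim <- simulate_pbk(m, dosing_regimen("iv_bolus", 50), duration = 48)
  bal <- sim$balance[sim$balance$time > 0, ]
  expect_equal(bal$in_body_mg, rep(50, nrow(bal)), tolerance = 1e-8)
})

test_that("mass balance holds within 0.5% for all routes and repeated doses", {
  m <- standard_test_model()
  regs <- list(
    dosing_regimen("iv_bolus", 100, n_doses = 3, interval_h = 8),
    dosing_regimen("oral", 600, n_doses = 2, interval_h = 12),
    dosing_regimen("oral", 600, fa = 0.3),
    dosing_regimen("iv_infusion", 100, infusion_duration_h = 4)
  )
  for (reg in regs) {
    sim <- simulate_pbk(m, reg, duration = 30)
    expect_lt(max(abs(sim$balance$rel_error)), 0.005)
  }
})

test_that("state variables stay non-negative", {
  m <- standard_test_model()
  sim <- simulate_pbk(m, dosing_regimen("oral", 600, n_doses = 3,
                                        interval_h = 8), duration = 36)
  expect_gte(min(sim$profile$conc_ug_ml), -1e-9)
})

test_that("linear kinetics are dose-proportional", {
  m <- standard_test_model()
  base <- compute_metrics(
    simulate_pbk(m, dosing_regimen("oral", 100), duration = 24), "venous")
  for (k in c(0.5, 2, 10)) {
    scaled <- compute_metrics(
      simulate_pbk(m, dosing_regimen("oral", 100 * k), duration = 24),
      "venous")
    expect_equal(scaled$auc_ug_h_ml, k * base$auc_ug_h_ml, tolerance = 1e-8)
    expect_equal(scaled$cmax_ug_ml, k * base$cmax_ug_ml, tolerance = 1e-8)
  }
})

test_that("repeated doses superpose shifted single doses (linear case)", {
  m <- standard_test_model()
  tau <- 8; n <- 3; D <- 200
  grid <- seq(0, 40, by = 0.25)
  multi <- simulate_pbk(m, dosing_regimen("iv_bolus", D, n_doses = n,
                                          interval_h = tau),
                        duration = 40, times = grid)
  single <- simulate_pbk(m, dosing_regimen("iv_bolus", D), duration = 40,
                         times = grid)
  cv <- function(s) {
    p <- dplyr::filter(tidy(s), compartment == "venous")
    approxfun(p$time, p$conc_ug_ml, rule = 2)
  }
  f1 <- cv(single)
  f3 <- cv(multi)
  t_chk <- c(20, 30, 40)
  super <- f1(t_chk) + f1(t_chk - tau) + f1(t_chk - 2 * tau)
  expect_equal(f3(t_chk), super, tolerance = 1e-4)
})

test_that("permeability-limited PS->infinity recovers the flow-limited profile", {
  fu_t <- 0.01
  perm <- standard_test_model(
    driving = "blood",
    tissue_kinetics = list(liver = permeability_limited(
      ps_L_h = 1e4 * 84, fu_tissue = fu_t)))
  flow <- standard_test_model(driving = "blood")
  flow$partition_set$kp[flow$partition_set$tissue == "liver"] <-
    flow$compound$fu_plasma / fu_t
  reg <- dosing_regimen("iv_bolus", 100)
  a <- compute_metrics(simulate_pbk(perm, reg, 24), "venous")$auc_ug_h_ml
  b <- compute_metrics(simulate_pbk(flow, reg, 24), "venous")$auc_ug_h_ml
  expect_equal(a, b, tolerance = 0.01)
})

test_that("a sealed tissue (PS = 0) receives no drug", {
  m <- standard_test_model(
    tissue_kinetics = list(brain = permeability_limited(ps_L_h = 0,
                                                        fu_tissue = 0.1)))
  sim <- simulate_pbk(m, dosing_regimen("iv_bolus", 100), duration = 12)
  tis <- dplyr::filter(tidy(sim), compartment == "brain_tissue")
  expect_equal(max(abs(tis$conc_ug_ml)), 0)
})

test_that("structural validation names the offending tissue", {
  phys <- load_reference_physiology("adult_male")
  cpd <- case_study_compound("ibuprofen")
  ps <- predict_partition_set(cpd, phys)
  ps <- ps[ps$tissue != "brain", ]
  expect_error(
    build_model(phys, cpd, ps, clearance_spec("linear", cl_L_h = 1)),
    "brain")
})

test_that("exposure metrics behave on analytic cases", {
  # constant concentration: AUC = c * T
  m <- standard_test_model(cl_L_h = 0)
  sim <- simulate_pbk(m, dosing_regimen("iv_infusion", 0,
                                        infusion_duration_h = 1),
                      duration = 10)
  expect_equal(compute_metrics(sim, "venous")$auc_ug_h_ml, 0)
  # one-compartment iv bolus: AUC_0-inf = Dose / CL
  V <- 10; CL <- 2; D <- 100
  m1 <- near_one_compartment_model(cl_L_h = CL, v_central = V)
  s1 <- simulate_pbk(m1, dosing_regimen("iv_bolus", D), duration = 24 * 15)
  auc <- compute_metrics(s1, "venous")$auc_ug_h_ml
  expect_equal(auc, D / CL, tolerance = 0.002)
  # grid refinement changes AUC by < 0.1%
  s2 <- simulate_pbk(m1, dosing_regimen("iv_bolus", D), duration = 24 * 15,
                     grid_h = 0.05, fine_h = 0.005)
  auc2 <- compute_metrics(s2, "venous")$auc_ug_h_ml
  expect_lt(abs(auc2 - auc) / auc2, 1e-3)
  expect_error(compute_metrics(s1, "venous", window = c(5, 5)), "Empty")
  expect_error(compute_metrics(s1, "venous", window = c(0, 1e4)), "span")
  expect_error(compute_metrics(s1, "spleen"), "not present")
})
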