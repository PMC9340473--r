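test_that("microsomal scaling reproduces the benchmark organ clearance", {
  mp <- metabolic_params(4.12, 38.85, "nmol/h/mg")
  cl <- scale_intrinsic_clearance(mp, mppgl = 32, liver_mass_g = 1493)
  expect_equal(round(cl, 2), 5.07)
})

test_that("clearance scaling follows exact unit reduction", {
  # 1 nmol/h/mg over 1 uM = 1 mL/h/mg; x 10 mg/g x 1000 g = 10 L/h
  expect_equal(scale_intrinsic_clearance(
    metabolic_params(1, 1, "nmol/h/mg"), 10, 1000), 10)
  expect_equal(scale_intrinsic_clearance(
    metabolic_params(0, 1, "nmol/h/mg"), 32, 1500), 0)
  # per-minute rates are converted, never guessed
  expect_equal(scale_intrinsic_clearance(
    metabolic_params(1, 1, "nmol/min/mg"), 10, 1000), 600)
  expect_error(metabolic_params(1, 1), "vmax_unit")
})

test_that("scaling is linear in vmax and liver mass, inverse in km", {
  base <- scale_intrinsic_clearance(metabolic_params(2, 10, "nmol/h/mg"),
                                    32, 1000)
  expect_equal(scale_intrinsic_clearance(
    metabolic_params(4, 10, "nmol/h/mg"), 32, 1000), 2 * base)
  expect_equal(scale_intrinsic_clearance(
    metabolic_params(2, 10, "nmol/h/mg"), 32, 2000), 2 * base)
  expect_equal(scale_intrinsic_clearance(
    metabolic_params(2, 5, "nmol/h/mg"), 32, 1000), 2 * base)
})

test_that("linear elimination rate is CL x concentration", {
  spec <- clearance_spec("linear", cl_L_h = 4.38)
  expect_equal(hepatic_elimination_rate(1, spec), 4.38)
  expect_equal(hepatic_elimination_rate(c(0, 2), spec), c(0, 8.76))
})

test_that("Michaelis-Menten elimination has the right limits and bounds", {
  mw <- 645.31
  mp <- metabolic_params(4.12, 38.85, "nmol/h/mg", ki_product = 12.1)
  spec <- clearance_spec("michaelis_menten", pathways = mp,
                         mppgl = 32, liver_mass_g = 1493)
  # first-order limit c << Km matches the scaled linear clearance
  c_lo <- 1e-4 # ug/mL -> ~1.5e-4 uM, far below Km
  lin <- scale_intrinsic_clearance(mp, 32, 1493) * c_lo
  expect_equal(hepatic_elimination_rate(c_lo, spec, mw = mw), lin,
               tolerance = 1e-4)
  # competitive inhibition at I = Ki doubles apparent Km: low-c rate halves
  r0 <- hepatic_elimination_rate(c_lo, spec, mw = mw)
  ri <- hepatic_elimination_rate(c_lo, spec, mw = mw, inhibitor_um = 12.1)
  expect_equal(ri / r0, 0.5, tolerance = 1e-4)
  # monotone non-decreasing in c, bounded by organ-scaled Vmax
  cs <- c(0.1, 1, 10, 100, 1000, 1e5)
  rates <- hepatic_elimination_rate(cs, spec, mw = mw)
  expect_true(all(diff(rates) >= 0))
  vmax_org_mg_h <- 4.12 * 32 * 1493 * mw / 1e6
  expect_true(all(rates <= vmax_org_mg_h))
  expect_equal(rates[length(rates)], vmax_org_mg_h, tolerance = 0.01)
})

test_that("an inhibitor without a Ki is rejected", {
  mp <- metabolic_params(4.12, 38.85, "nmol/h/mg")
  spec <- clearance_spec("michaelis_menten", pathways = mp,
                         mppgl = 32, liver_mass_g = 1493)
  expect_error(hepatic_elimination_rate(1, spec, mw = 645, inhibitor_um = 5),
               "ki_product")
})

test_that("clearance beyond hepatic blood flow warns but builds", {
  phys <- load_reference_physiology("adult_male")
  cpd <- case_study_compound("ibuprofen")
  ps <- predict_partition_set(cpd, phys)
  expect_warning(
    build_model(phys, cpd, ps, clearance_spec("linear", cl_L_h = 5000)),
    "exceeds hepatic blood flow"
  )
})
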