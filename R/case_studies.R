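# The three end-to-end case studies, shipped as runnable parameterized
# pipelines. Each returns a report tibble placing computed quantities next
# to their printed benchmark values with a status:
#   reproducible - recomputed from packaged inputs, expected to match
#   ratio_only   - only the ratio is desk-reproducible (absolute values
#                  depend on unpublished raw data or software internals)
#   qualitative  - a direction/ordering reproduced, not a number
#   context      - a printed value carried for comparison only
# All in-vitro-dependent stages run on synthetic stand-ins generated by the
# synthetic-data module.

.report_row <- function(case, quantity, value, unit, anchor = NA_real_,
                        status = "reproducible", note = "") {
  tibble(case = case, quantity = quantity, value = value, unit = unit,
         anchor = anchor, status = status, note = note)
}

# Synthetic stand-in tissue:blood partition set for the lipophilic
# antiarrhythmic (the original model's rodent-derived values are not
# published); magnitudes chosen as plausible for a highly lipophilic base.
.ami_partition_set <- function() {
  tibble(
    tissue = c("lung", "liver", "gut", "brain", "kidney", "adipose",
               "muscle", "skin", "rest"),
    kp = c(10, 25, 20, 15, 25, 100, 20, 15, 20),
    provenance = "synthetic_stand_in"
  )
}

.ami_brain_model <- function() {
  ami <- case_study_compound("amiodarone")
  phys <- load_reference_physiology("adult_male")
  build_model(
    phys, ami, .ami_partition_set(),
    clearance_spec("linear", cl_L_h = 5.068 + 0.096, driving = "blood"),
    tissue_kinetics = list(
      liver = permeability_limited(ps_L_h = 5, fu_tissue = 0.006)
    )
  )
}

.case_ibu <- function(dose_step = 10, seed = 1) {
  ibu <- case_study_compound("ibuprofen")
  phys <- load_reference_physiology("adult_male")
  kp_liver <- predict_kp_schmitt(ibu, "liver")

  # in-vitro-derived liver Kp from a synthetic hepatocyte culture at
  # near-steady state (generating ratio 11.1)
  sys <- in_vitro_system(v_medium_ml = 2, v_cells_ml = 0.01,
                         kp_cell_medium = 11.1, cl_ml_h = 0.05,
                         nominal_um = 100, n_doses = 1, mw = ibu$mw,
                         cl_exchange_ml_h = 100)
  iv <- simulate_in_vitro(sys, duration_h = 24, grid_h = 0.5)
  late <- tail(iv$data, 1)
  kp_vitro <- kp_from_in_vitro(late$cell_conc, late$medium_conc)

  ps_a <- predict_partition_set(ibu, phys)
  model_a <- build_model(phys, ibu, ps_a,
                         clearance_spec("linear", cl_L_h = 4.38))
  reg <- dosing_regimen("oral", 600)
  sim <- simulate_pbk(model_a, reg, duration = 24)
  met <- compute_metrics(sim, "venous")

  # reverse-dosimetry self-consistency at the 10 mg grid step: a forward-
  # simulated liver profile is recovered as a dose
  t_obs <- c(0.5, 1, 2, 3, 4, 6, 8)
  liver <- dplyr::filter(sim$profile, .data$compartment == "liver",
                         round(.data$time, 9) %in% round(t_obs, 9))
  target <- target_exposure("profile", compartment = "liver",
                            profile = tibble(time = liver$time,
                                             conc = liver$conc_ug_ml))
  ds <- optimize_dose_profile(model_a, dosing_regimen("oral", 1), target,
                              dose_step = dose_step,
                              sim_args = list(fine_h = 0.05))

  dplyr::bind_rows(
    .report_row("ibu", "kp_liver_predicted", kp_liver, "unitless", 3.01,
                "reproducible", "composition-based prediction"),
    .report_row("ibu", "kp_liver_in_vitro", kp_vitro, "unitless", 11.1,
                "reproducible", "cell:medium ratio, synthetic culture"),
    .report_row("ibu", "kp_liver_postmortem", NA_real_, "unitless", 2.7,
                "context", "printed benchmark, not computed"),
    .report_row("ibu", "clearance_in_vivo", 4.38, "L/h", 4.38, "context",
                "model input"),
    .report_row("ibu", "cmax_600mg_oral", met$cmax_ug_ml, "ug/mL", NA_real_,
                "qualitative", "order-of-magnitude envelope vs clinical data"),
    .report_row("ibu", "auc24_600mg_oral", met$auc_ug_h_ml, "ug*h/mL",
                NA_real_, "qualitative", ""),
    .report_row("ibu", "reverse_dose_recovered", ds$optimized_dose, "mg", 600,
                "reproducible", "self-consistency at 10 mg grid step"),
    .report_row("ibu", "dose_low_toxicity_in_vitro_kp", NA_real_, "mg", 1790,
                "context", "depends on unpublished raw profiles"),
    .report_row("ibu", "dose_low_toxicity_predicted_kp", NA_real_, "mg", 3560,
                "context", "depends on unpublished raw profiles")
  )
}

.case_ami_liver <- function(seed = 1) {
  phys <- load_reference_physiology("adult_male")
  mp <- metabolic_params(4.12, 38.85, "nmol/h/mg", ki_product = 12.1)
  clint <- scale_intrinsic_clearance(mp, mppgl = phys$mppgl,
                                     liver_mass_g = phys$liver_mass_g)

  # repeated-dose hepatocyte culture: metabolite product inhibition
  # collapses the apparent clearance between day 1 and day 14
  sys <- in_vitro_system(v_medium_ml = 2, v_cells_ml = 0.01,
                         kp_cell_medium = 50, clearance = mp,
                         protein_mg = 1, nominal_um = 2.5, n_doses = 14,
                         mw = 645.31)
  s <- simulate_in_vitro(sys)
  k1 <- in_vitro_apparent_depletion(s, 1)
  k14 <- in_vitro_apparent_depletion(s, 14)

  dplyr::bind_rows(
    .report_row("ami-liver", "clint_scaled_microsomal", clint, "L/h", 5.07,
                "reproducible", "Vmax/Km x MPPGL x liver mass"),
    .report_row("ami-liver", "clint_phh_culture", NA_real_, "L/h", 0.002,
                "context", "printed benchmark from inhibited culture"),
    .report_row("ami-liver", "clint_other_metabolites", NA_real_, "L/h",
                0.096, "context", "model input"),
    .report_row("ami-liver", "depletion_day1", k1, "1/h", NA_real_,
                "qualitative", "synthetic hepatocyte culture, Ki 12.1 uM"),
    .report_row("ami-liver", "depletion_day14", k14, "1/h", NA_real_,
                "qualitative",
                "product inhibition: day-14 rate below day-1"),
    .report_row("ami-liver", "depletion_ratio_day14_day1", k14 / k1,
                "unitless", NA_real_, "qualitative", "< 1 expected")
  )
}

.case_ami_brain <- function(dose_step = 0.01, seed = 1) {
  model <- .ami_brain_model()
  bw <- model$physiology$body_weight
  reg <- dosing_regimen("iv_bolus", 1)
  sim_args <- list(grid_h = 0.1, fine_h = 0.05, fine_window_h = 0.2)

  find_dose <- function(auc_target) {
    optimize_dose_metric(
      model, reg,
      target_exposure("auc", compartment = "brain", value = auc_target,
                      window = c(0, 24)),
      dose_step = dose_step, sim_args = sim_args
    )
  }
  ds1 <- find_dose(1.00)
  ds2 <- find_dose(1.99)

  # in vitro concentration-response for the neurotoxicity marker on the
  # four-concentration panel; per-concentration exposure targets scale with
  # the printed day-14 AUC at the top concentration (linear in vitro range)
  panel_um <- c(0.312, 0.625, 1.25, 2.5)
  auc_at <- function(c_um) 1.99 * c_um / 2.5
  doses <- c(0, purrr::map_dbl(panel_um, function(cc) {
    find_dose(auc_at(cc))$optimized_dose
  }))
  chat <- generate_dose_response(
    list(family = "exponential", params = c(100, -log(2) / 2.5)),
    doses = c(0, panel_um), sd = 6, n_per_group = 6, seed = seed
  )
  dr <- concentration_response_to_dose_response(chat, doses,
                                                dose_unit = "mg")
  bmd_fit <- fit_bmd(dr, model_family = c("exponential", "hill"))

  oral_nominal <- iv_to_oral_dose(0.058, 0.65, bw)
  oral_corrected <- unbound_fraction_dose_correction(6.5, 0.06)

  dplyr::bind_rows(
    .report_row("ami-brain", "dose_auc_1.00", ds1$optimized_dose / bw,
                "mg/kg", 3.83, "ratio_only",
                "absolute depends on unpublished tissue permeability data"),
    .report_row("ami-brain", "dose_auc_1.99", ds2$optimized_dose / bw,
                "mg/kg", 7.68, "ratio_only", ""),
    .report_row("ami-brain", "dose_ratio_auc",
                ds2$optimized_dose / ds1$optimized_dose, "unitless", 1.99,
                "reproducible", "dose-AUC linearity under linear clearance"),
    .report_row("ami-brain", "bmdu_in_vivo_dose", bmd_fit$bmdu, "mg",
                NA_real_, "qualitative",
                "synthetic stand-in response; printed 5.28 mg/kg is a context anchor"),
    .report_row("ami-brain", "oral_dose_from_nominal_bmdu", oral_nominal,
                "mg", 6.5, "reproducible",
                "0.058 mg/kg / F 0.65 x 70 kg; printed value carries rounding"),
    .report_row("ami-brain", "oral_dose_nominal_corrected", oral_corrected,
                "mg", 10833.3, "reproducible", "100/fu correction, fu 0.06"),
    .report_row("ami-brain", "oral_dose_bmdu_auc", NA_real_, "mg", 593,
                "context", "depends on unpublished raw data")
  )
}

.case_cpf <- function(seed = 1) {
  cpf <- case_study_compound("chlorpyrifos")
  phys_f <- load_reference_physiology("adult_female")
  phys_p <- apply_pregnancy(phys_f)
  paths <- list(
    metabolic_params(14.04, 4.33, "nmol/min/mg", pathway = "dearylation"),
    metabolic_params(9.36, 28.5, "nmol/min/mg", pathway = "desulfuration")
  )
  cl <- clearance_spec("michaelis_menten", pathways = paths,
                       mppgl = phys_f$mppgl,
                       liver_mass_g = phys_f$liver_mass_g)
  ps_f <- predict_partition_set(cpf, phys_f)
  ps_p <- predict_partition_set(cpf, phys_p)
  m_f <- build_model(phys_f, cpf, ps_f, cl)
  m_p <- build_model(phys_p, cpf, ps_p, cl)

  reg_oral <- dosing_regimen("oral", 2, dose_unit = "mg_per_kg")
  s_f <- simulate_pbk(m_f, reg_oral, duration = 48)
  s_p <- simulate_pbk(m_p, reg_oral, duration = 48)
  cmax_f <- compute_metrics(s_f, "venous")$cmax_ug_ml
  cmax_p <- compute_metrics(s_p, "venous")$cmax_ug_ml

  # fetal:maternal concentration ratio under sustained maternal exposure
  ratio <- cpf_fetal_maternal_ratio(m_p)

  # conversion chain from nominal in vitro BMDUs to actual intracellular
  # concentrations (conversion factors from the printed measured pairs)
  bmdu_um <- c(neurites_per_neuron = 29.5, synapses = 25.7)
  bmdu_ugml <- molar_to_mass_conc(bmdu_um, cpf$mw)
  factors <- c(neurites_per_neuron = 11.7 / 10.3, synapses = 10.2 / 9.0)
  bmdu_actual <- nominal_to_actual(bmdu_ugml, 1) * factors

  maternal_ng_ml <- c(7.33, 5.29, 0.011) # printed maternal exposure maxima
  fetal_ng_ml <- ratio * maternal_ng_ml
  margin <- min(bmdu_actual) * 1000 / max(fetal_ng_ml)

  dplyr::bind_rows(
    .report_row("cpf", "cmax_nonpregnant_2mgkg", cmax_f, "ug/mL", NA_real_,
                "qualitative", ""),
    .report_row("cpf", "cmax_pregnant_2mgkg", cmax_p, "ug/mL", NA_real_,
                "qualitative", "below non-pregnant (larger distribution volume)"),
    .report_row("cpf", "fetal_maternal_ratio", ratio, "unitless", 1.46,
                "reproducible", "sustained-exposure simulation"),
    .report_row("cpf", "bmdu_nominal_neurites", bmdu_ugml[[1]], "ug/mL",
                10.3, "reproducible", "29.5 uM x MW / 1000"),
    .report_row("cpf", "bmdu_actual_neurites", bmdu_actual[[1]], "ug/mL",
                11.7, "reproducible", "nominal-to-actual conversion"),
    .report_row("cpf", "bmdu_nominal_synapses", bmdu_ugml[[2]], "ug/mL",
                9.0, "reproducible", ""),
    .report_row("cpf", "bmdu_actual_synapses", bmdu_actual[[2]], "ug/mL",
                10.2, "reproducible", ""),
    .report_row("cpf", "fetal_conc_highest_exposure", max(fetal_ng_ml),
                "ng/mL", 10.7, "reproducible",
                "printed maternal 7.33 ng/mL as input"),
    .report_row("cpf", "margin_bmdu_over_fetal", margin, "fold", NA_real_,
                "reproducible", ">= 100-fold expected (orders of magnitude)")
  )
}

#' Fetal:maternal concentration ratio under sustained exposure
#'
#' Simulates a long constant-rate i.v. infusion in a pregnancy-extended
#' model and returns the fetal-to-arterial concentration ratio once the
#' fetal compartment tracks maternal blood (the ratio converges long before
#' whole-body steady state).
#'
#' @param model A pregnancy-extended [build_model()] object containing a
#'   `fetus` compartment.
#' @param duration Infusion span, h (default 240).
#' @return The fetal:maternal (arterial blood) concentration ratio.
#' @export
cpf_fetal_maternal_ratio <- function(model, duration = 240) {
  stopifnot(inherits(model, "qivive_pbk_model"))
  if (!"fetus" %in% model$physiology$organs$organ) {
    abort("Model has no fetal compartment; apply a pregnancy extension first.")
  }
  reg <- dosing_regimen("iv_infusion", 1, infusion_duration_h = duration)
  sim <- simulate_pbk(model, reg, duration = duration,
                      times = seq(0, duration, by = 1))
  last <- dplyr::filter(sim$profile, .data$time == duration)
  c_fet <- last$conc_ug_ml[last$compartment == "fetus"]
  c_mat <- last$conc_ug_ml[last$compartment == "arterial"]
  c_fet / c_mat
}

#' Run a packaged case study end to end
#'
#' Chains model building, simulation, reverse dosimetry, BMD fitting and
#' unit conversions for one of the three shipped scenarios, and returns a
#' report table of computed values next to printed benchmark values. Runs
#' are deterministic for a fixed seed.
#'
#' @param name `"ibu"` (hepatotoxicity, flow-limited model, profile-matching
#'   reverse dosimetry), `"ami-liver"` (clearance scaling and in vitro
#'   product inhibition), `"ami-brain"` (permeability-limited liver, AUC
#'   reverse dosimetry, BMD chain, nominal-concentration corrections) or
#'   `"cpf"` (pregnancy extension, fetal exposure margin).
#' @param seed Integer seed for the synthetic in vitro stand-ins.
#' @return A `qivive_case_report` tibble (case, quantity, value, unit,
#'   anchor, status, note).
#' @examples
#' \donttest{
#' run_case_study("ami-liver")
#' }
#' @export
run_case_study <- function(name = c("ibu", "ami-liver", "ami-brain", "cpf"),
                           seed = 1) {
  name <- match.arg(name)
  report <- switch(name,
                   "ibu" = .case_ibu(seed = seed),
                   "ami-liver" = .case_ami_liver(seed = seed),
                   "ami-brain" = .case_ami_brain(seed = seed),
                   "cpf" = .case_cpf(seed = seed))
  class(report) <- c("qivive_case_report", class(report))
  report
}

#' Write a case-study report as a delimited table
#'
#' @param report A [run_case_study()] result.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_case_report <- function(report, path) {
  write.table(as.data.frame(report), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
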