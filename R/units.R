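#' Convert a molar concentration to a mass concentration
#'
#' In vitro effect concentrations are usually reported in µM while kinetic
#' models and exposure data work in µg/mL; the conversion is
#' `conc_um * mw / 1000`.
#'
#' @param conc_um Concentration in µM (numeric vector, values >= 0).
#' @param mw Molecular weight in g/mol (> 0).
#' @return Concentration in µg/mL, full precision (round only for reporting).
#' @examples
#' molar_to_mass_conc(29.5, 350.57) # ~10.3 ug/mL
#' @seealso [mass_to_molar_conc()], [nominal_to_actual()]
#' @export
molar_to_mass_conc <- function(conc_um, mw) {
  assert_numeric_vec(conc_um, "conc_um", lower = 0)
  assert_number(mw, "mw", lower = 0, strict_lower = TRUE)
  conc_um * mw / 1000
}

#' Convert a mass concentration to a molar concentration
#'
#' Inverse of [molar_to_mass_conc()].
#'
#' @param conc_ug_ml Concentration in µg/mL (>= 0).
#' @param mw Molecular weight in g/mol (> 0).
#' @return Concentration in µM.
#' @export
mass_to_molar_conc <- function(conc_ug_ml, mw) {
  assert_numeric_vec(conc_ug_ml, "conc_ug_ml", lower = 0)
  assert_number(mw, "mw", lower = 0, strict_lower = TRUE)
  conc_ug_ml * 1000 / mw
}

#' Convert a nominal in vitro concentration to an actual concentration
#'
#' Nominal (applied) concentrations overstate or understate the concentration
#' that cells actually experience; where measured actual/nominal pairs exist
#' for a test system, their ratio is a per-dataset conversion factor applied
#' multiplicatively.
#'
#' @param conc_nominal Nominal concentration (any concentration unit, >= 0).
#' @param conversion_factor Measured actual/nominal ratio for the dataset
#'   (> 0).
#' @return Actual concentration in the same unit as `conc_nominal`.
#' @examples
#' nominal_to_actual(10.3, 11.7 / 10.3)
#' @export
nominal_to_actual <- function(conc_nominal, conversion_factor) {
  assert_numeric_vec(conc_nominal, "conc_nominal", lower = 0)
  assert_number(conversion_factor, "conversion_factor",
                lower = 0, strict_lower = TRUE)
  conc_nominal * conversion_factor
}

#' Correct a dose derived from nominal concentrations for plasma binding
#'
#' When an in vitro point of departure was expressed on nominal (free)
#' concentrations, the equivalent in vivo dose must be inflated for plasma
#' protein binding. The default `method = "percent"` multiplies by `100 / fu`,
#' the convention used in reverse-dosimetry practice when fu is quoted as a
#' fraction but the correction is stated "per 100"; `method = "fraction"` is
#' the dimensionally plain `dose / fu`.
#'
#' @param dose Dose in mg (>= 0).
#' @param fu Unbound fraction in plasma (> 0).
#' @param method `"percent"` (`dose * 100 / fu`, default) or `"fraction"`
#'   (`dose / fu`).
#' @return Corrected dose in mg.
#' @examples
#' unbound_fraction_dose_correction(6.5, 0.06) # 10833.3 mg
#' @export
unbound_fraction_dose_correction <- function(dose, fu,
                                             method = c("percent", "fraction")) {
  method <- match.arg(method)
  assert_numeric_vec(dose, "dose", lower = 0)
  assert_number(fu, "fu", lower = 0, strict_lower = TRUE)
  if (method == "percent") dose * 100 / fu else dose / fu
}

#' Convert an intravenous dose per kg to an absolute oral dose
#'
#' Divides by oral bioavailability F and scales by body weight:
#' `dose_iv_per_kg * body_weight / F`.
#'
#' @param dose_iv_per_kg i.v. dose in mg/kg (>= 0).
#' @param F Oral bioavailability, in (0, 1].
#' @param body_weight Body weight in kg (> 0).
#' @return Oral dose in mg.
#' @examples
#' iv_to_oral_dose(0.058, 0.65, 70)
#' @export
iv_to_oral_dose <- function(dose_iv_per_kg, F, body_weight) {
  assert_numeric_vec(dose_iv_per_kg, "dose_iv_per_kg", lower = 0)
  assert_number(F, "F", lower = 0, upper = 1, strict_lower = TRUE)
  assert_number(body_weight, "body_weight", lower = 0, strict_lower = TRUE)
  dose_iv_per_kg * body_weight / F
}
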