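# Whole-body PBK model assembly. A model is a validated bundle of
# physiology, compound, partition set, clearance spec and per-tissue kinetics
# flags from which the ODE right-hand side is fully determined. The
# circulation is closed: venous blood -> lung -> arterial blood -> tissues ->
# venous blood, with the gut draining through the portal vein into the liver
# and oral absorption entering the portal inflow.

#' Describe a dosing regimen
#'
#' @param route `"iv_bolus"`, `"iv_infusion"` or `"oral"`.
#' @param dose Dose per administration (>= 0).
#' @param dose_unit `"mg"` or `"mg_per_kg"`; mg/kg doses are resolved
#'   against the model physiology's body weight at simulation time.
#' @param n_doses Number of repeated administrations (>= 1).
#' @param interval_h Dosing interval, h (> 0 when `n_doses` > 1).
#' @param infusion_duration_h Infusion duration, h (i.v. infusion only).
#' @param ka,fa Optional overrides of the compound's first-order absorption
#'   rate constant (1/h) and fraction absorbed (oral route).
#' @return A `qivive_regimen` list.
#' @export
dosing_regimen <- function(route = c("iv_bolus", "iv_infusion", "oral"),
                           dose, dose_unit = c("mg", "mg_per_kg"),
                           n_doses = 1, interval_h = 24,
                           infusion_duration_h = 1,
                           ka = NULL, fa = NULL) {
  route <- match.arg(route)
  dose_unit <- match.arg(dose_unit)
  assert_number(dose, "dose", lower = 0)
  assert_number(n_doses, "n_doses", lower = 1)
  if (n_doses > 1) assert_number(interval_h, "interval_h", lower = 0, strict_lower = TRUE)
  if (route == "iv_infusion") {
    assert_number(infusion_duration_h, "infusion_duration_h",
                  lower = 0, strict_lower = TRUE)
  }
  structure(
    list(route = route, dose = dose, dose_unit = dose_unit,
         n_doses = as.integer(n_doses), interval_h = interval_h,
         infusion_duration_h = infusion_duration_h, ka = ka, fa = fa),
    class = "qivive_regimen"
  )
}

#' Flag a tissue as permeability-limited
#'
#' Splits the tissue into a vascular and an extravascular sub-compartment
#' separated by a diffusional barrier with permeability-surface-area product
#' `ps_L_h`; exchange is driven by the unbound concentration gradient
#' `fu_plasma * C_vascular - fu_tissue * C_tissue`.
#'
#' @param ps_L_h Permeability-surface area product, L/h (>= 0).
#' @param fu_tissue Unbound fraction in the tissue sub-compartment, (0, 1].
#' @param vascular_fraction Fraction of the tissue volume that is vascular
#'   (default 0.1).
#' @return A kinetics flag consumed by [build_model()].
#' @export
permeability_limited <- function(ps_L_h, fu_tissue, vascular_fraction = 0.1) {
  assert_number(ps_L_h, "ps_L_h", lower = 0)
  assert_number(fu_tissue, "fu_tissue", lower = 0, upper = 1,
                strict_lower = TRUE)
  assert_number(vascular_fraction, "vascular_fraction", lower = 0, upper = 0.9,
                strict_lower = TRUE)
  list(kind = "permeability_limited", ps_L_h = ps_L_h,
       fu_tissue = fu_tissue, vascular_fraction = vascular_fraction)
}

#' Assemble a whole-body PBK model
#'
#' Validates the components against each other and wires the circulation:
#' every perfused tissue needs either a partition coefficient (flow-limited)
#' or a [permeability_limited()] flag; the gut drains into the liver (portal
#' vein); elimination sits in the liver per the clearance spec.
#'
#' @param physiology A [load_reference_physiology()] (optionally
#'   [apply_pregnancy()]-extended) object.
#' @param compound A [compound()].
#' @param partition_set Tibble from [predict_partition_set()] or any data
#'   frame with columns `tissue` and `kp`.
#' @param clearance A [clearance_spec()].
#' @param tissue_kinetics Named list of [permeability_limited()] flags;
#'   tissues not listed are flow-limited.
#' @return A `qivive_pbk_model`.
#' @export
build_model <- function(physiology, compound, partition_set, clearance,
                        tissue_kinetics = list()) {
  stopifnot(inherits(physiology, "qivive_physiology"),
            inherits(compound, "qivive_compound"),
            inherits(clearance, "qivive_clearance"))
  validate_physiology(physiology)
  ps_df <- as.data.frame(partition_set)
  stopifnot(all(c("tissue", "kp") %in% names(ps_df)))

  org <- physiology$organs
  tissues <- setdiff(org$organ, c("lung", "arterial", "venous"))
  for (t in c("lung", tissues)) {
    perm <- t %in% names(tissue_kinetics)
    has_kp <- t %in% ps_df$tissue
    if (t == "lung" && perm) abort("The lung compartment must be flow-limited.")
    if (!perm && !has_kp) {
      abort(sprintf("Tissue '%s' has neither a partition coefficient nor a permeability-limited spec.", t))
    }
  }
  if (any(ps_df$kp[ps_df$tissue %in% c("lung", tissues)] <= 0)) {
    abort("Partition coefficients must be > 0.")
  }
  # Well-stirred sanity: hepatic clearance beyond hepatic blood flow cannot
  # be expressed as extraction; warn, do not error.
  q_liver <- org$flow_L_h[org$organ == "liver"] +
    org$flow_L_h[org$organ == "gut"]
  if (clearance$kind == "linear" && clearance$cl_L_h > q_liver) {
    warn(sprintf(paste0("Hepatic clearance (%.3g L/h) exceeds hepatic blood ",
                        "flow (%.3g L/h); effective extraction is flow-limited."),
                 clearance$cl_L_h, q_liver))
  }
  structure(
    list(physiology = physiology, compound = compound,
         partition_set = as_tibble(ps_df), clearance = clearance,
         tissue_kinetics = tissue_kinetics),
    class = "qivive_pbk_model"
  )
}

#' @export
print.qivive_pbk_model <- function(x, ...) {
  n_perm <- length(x$tissue_kinetics)
  cat(sprintf("<qivive_pbk_model> %s in %s\n", x$compound$name,
              x$physiology$profile))
  cat(sprintf("  %d perfused tissues (%d permeability-limited), clearance: %s\n",
              nrow(x$physiology$organs) - 2, n_perm, x$clearance$kind))
  invisible(x)
}
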