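# Hepatic elimination: scaling of in vitro metabolic parameters (microsomal
# or hepatocyte Vmax/Km) to whole-organ intrinsic clearance, and the rate
# laws (linear or Michaelis-Menten with optional competitive product
# inhibition) used inside the PBK engine and the in vitro simulator.

#' Describe one metabolic pathway measured in vitro
#'
#' @param vmax Maximal rate per mg of (microsomal) protein. The unit tag is
#'   mandatory: rates are never guessed between per-minute and per-hour.
#' @param km Michaelis constant, µM (> 0).
#' @param vmax_unit `"nmol/h/mg"` or `"nmol/min/mg"`.
#' @param ki_product Competitive product-inhibition constant, µM (optional).
#' @param pathway Pathway label.
#' @return A `qivive_metabolic_params` list with `vmax_per_h` normalized to
#'   nmol/h/mg.
#' @examples
#' metabolic_params(4.12, 38.85, "nmol/h/mg")
#' @export
metabolic_params <- function(vmax, km, vmax_unit, ki_product = NA_real_,
                             pathway = "metabolism") {
  if (missing(vmax_unit)) {
    abort("`vmax_unit` is required ('nmol/h/mg' or 'nmol/min/mg'); units are never guessed.")
  }
  assert_choice(vmax_unit, "vmax_unit", c("nmol/h/mg", "nmol/min/mg"))
  assert_number(vmax, "vmax", lower = 0)
  assert_number(km, "km", lower = 0, strict_lower = TRUE)
  assert_number(ki_product, "ki_product", lower = 0, strict_lower = TRUE,
                allow_na = TRUE)
  structure(
    list(vmax = vmax, vmax_unit = vmax_unit,
         vmax_per_h = if (vmax_unit == "nmol/min/mg") vmax * 60 else vmax,
         km = km, ki_product = ki_product, pathway = pathway),
    class = "qivive_metabolic_params"
  )
}

#' Scale in vitro metabolic parameters to whole-organ intrinsic clearance
#'
#' In the linear range the per-mg intrinsic clearance is Vmax/Km
#' (nmol/h/mg over µM gives mL/h/mg); multiplying by MPPGL (mg microsomal
#' protein per g liver) and liver mass (g) and reducing units yields the
#' organ intrinsic clearance in L/h.
#'
#' @param params A [metabolic_params()] object, or a list of them (pathway
#'   clearances are summed).
#' @param mppgl Milligrams of microsomal protein per gram liver (> 0).
#' @param liver_mass_g Liver mass, g (> 0).
#' @return Intrinsic clearance, L/h.
#' @examples
#' scale_intrinsic_clearance(metabolic_params(4.12, 38.85, "nmol/h/mg"),
#'                           mppgl = 32, liver_mass_g = 1493) # ~5.07 L/h
#' @export
scale_intrinsic_clearance <- function(params, mppgl, liver_mass_g) {
  assert_number(mppgl, "mppgl", lower = 0, strict_lower = TRUE)
  assert_number(liver_mass_g, "liver_mass_g", lower = 0, strict_lower = TRUE)
  if (inherits(params, "qivive_metabolic_params")) params <- list(params)
  stopifnot(all(purrr::map_lgl(params, inherits, "qivive_metabolic_params")))
  sum(purrr::map_dbl(params, function(p) {
    (p$vmax_per_h / p$km) * mppgl * liver_mass_g / 1000
  }))
}

#' Specify hepatic elimination for a PBK model
#'
#' Either a linear clearance (`cl_L_h`) or Michaelis-Menten kinetics from
#' one or more [metabolic_params()] pathways scaled to the organ with MPPGL
#' and liver mass. `driving` selects the concentration that drives
#' elimination: `"blood"` (liver venous-equilibrium concentration, the
#' conventional well-stirred choice), `"tissue"` (total liver tissue
#' concentration) or `"unbound_tissue"` (fu_tissue-weighted, for
#' permeability-limited livers).
#'
#' @param kind `"linear"` or `"michaelis_menten"`.
#' @param cl_L_h Linear clearance, L/h (required for `"linear"`).
#' @param pathways A [metabolic_params()] or list of them (required for
#'   `"michaelis_menten"`).
#' @param mppgl,liver_mass_g Organ scaling factors for Michaelis-Menten
#'   kinetics.
#' @param driving Driving-concentration scope (see above).
#' @return A `qivive_clearance` list.
#' @export
clearance_spec <- function(kind = c("linear", "michaelis_menten"),
                           cl_L_h = NULL, pathways = NULL,
                           mppgl = NULL, liver_mass_g = NULL,
                           driving = c("blood", "tissue", "unbound_tissue")) {
  kind <- match.arg(kind)
  driving <- match.arg(driving)
  if (kind == "linear") {
    assert_number(cl_L_h, "cl_L_h", lower = 0)
    spec <- list(kind = kind, cl_L_h = cl_L_h, driving = driving)
  } else {
    if (inherits(pathways, "qivive_metabolic_params")) pathways <- list(pathways)
    if (is.null(pathways) || !length(pathways)) {
      abort("Michaelis-Menten clearance needs at least one `pathways` entry.")
    }
    assert_number(mppgl, "mppgl", lower = 0, strict_lower = TRUE)
    assert_number(liver_mass_g, "liver_mass_g", lower = 0, strict_lower = TRUE)
    spec <- list(kind = kind, pathways = pathways, mppgl = mppgl,
                 liver_mass_g = liver_mass_g, driving = driving)
  }
  structure(spec, class = "qivive_clearance")
}

#' Hepatic elimination rate at a given driving concentration
#'
#' Linear: `CL * c` (µg/mL read as mg/L, so the rate is mg/h). Michaelis-
#' Menten: the organ-scaled `Vmax * c / (Km * (1 + I/Ki) + c)` evaluated in
#' molar units, with optional competitive product inhibition by an inhibitor
#' at concentration `inhibitor_um`.
#'
#' @param conc Driving concentration, µg/mL (>= 0; vectorized).
#' @param spec A [clearance_spec()].
#' @param mw Compound molecular weight, g/mol (required for
#'   Michaelis-Menten).
#' @param inhibitor_um Inhibitor (metabolite) concentration, µM. Requires
#'   `ki_product` on the pathway(s).
#' @return Elimination rate, mg/h.
#' @export
hepatic_elimination_rate <- function(conc, spec, mw = NULL,
                                     inhibitor_um = NULL) {
  stopifnot(inherits(spec, "qivive_clearance"))
  assert_numeric_vec(conc, "conc", lower = 0)
  if (spec$kind == "linear") {
    if (!is.null(inhibitor_um)) {
      abort("Inhibitor supplied but linear clearance has no `ki_product`.")
    }
    return(spec$cl_L_h * conc)
  }
  if (is.null(mw)) abort("`mw` is required for Michaelis-Menten elimination.")
  c_um <- conc * 1000 / mw
  rate_nmol_h <- 0
  for (p in spec$pathways) {
    km_app <- p$km
    if (!is.null(inhibitor_um)) {
      if (is.na(p$ki_product)) {
        abort("Inhibitor concentration given but pathway has no `ki_product`.")
      }
      km_app <- p$km * (1 + inhibitor_um / p$ki_product)
    }
    vmax_org <- p$vmax_per_h * spec$mppgl * spec$liver_mass_g # nmol/h
    rate_nmol_h <- rate_nmol_h + vmax_org * c_um / (km_app + c_um)
  }
  rate_nmol_h * mw / 1e6 # nmol/h -> mg/h
}
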