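#' Define a compound
#'
#' A compound bundles the physicochemical and binding parameters every other
#' module consumes: molecular weight, lipophilicity, ionization, plasma
#' protein binding, solubility and (optionally) oral absorption parameters.
#'
#' At least one absorption parameterization (`ka` + `fa`, or `peff`) must be
#' present before the compound can be used with an oral dosing regimen;
#' i.v.-only use needs none.
#'
#' @param name Compound name.
#' @param mw Molecular weight, g/mol (> 0).
#' @param log_p Octanol-water log partition coefficient.
#' @param ionization One of `"acid"`, `"base"`, `"neutral"`.
#' @param pka Acid/base dissociation constant; required unless neutral.
#' @param fu_plasma Unbound fraction in plasma, in \[0, 1].
#' @param solubility Aqueous solubility, mg/mL (optional).
#' @param ka First-order absorption rate constant, 1/h (optional).
#' @param fa Fraction absorbed, in \[0, 1] (optional).
#' @param peff Specific intestinal permeability, cm/s (optional). When `ka`
#'   is absent it is derived via [ka_from_peff()] at model build time.
#' @param oral_bioavailability_f Oral bioavailability F, in (0, 1] (optional).
#' @return An object of class `qivive_compound` (a named list).
#' @examples
#' compound("ibuprofen-like", mw = 206.29, log_p = 2.23,
#'          ionization = "acid", pka = 4.5, fu_plasma = 0.01,
#'          ka = 2.1, fa = 1)
#' @export
compound <- function(name, mw, log_p, ionization = c("neutral", "acid", "base"),
                     pka = NA_real_, fu_plasma = 1, solubility = NA_real_,
                     ka = NA_real_, fa = NA_real_, peff = NA_real_,
                     oral_bioavailability_f = NA_real_) {
  ionization <- match.arg(ionization)
  assert_number(mw, "mw", lower = 0, strict_lower = TRUE)
  assert_number(log_p, "log_p")
  assert_number(fu_plasma, "fu_plasma", lower = 0, upper = 1)
  assert_number(pka, "pka", allow_na = TRUE)
  assert_number(solubility, "solubility", lower = 0, allow_na = TRUE)
  assert_number(ka, "ka", lower = 0, allow_na = TRUE)
  assert_number(fa, "fa", lower = 0, upper = 1, allow_na = TRUE)
  assert_number(peff, "peff", lower = 0, allow_na = TRUE)
  assert_number(oral_bioavailability_f, "oral_bioavailability_f",
                lower = 0, upper = 1, allow_na = TRUE)
  if (ionization != "neutral" && is.na(pka)) {
    abort("`pka` is required for acids and bases.")
  }
  structure(
    list(name = name, mw = mw, log_p = log_p, ionization = ionization,
         pka = pka, fu_plasma = fu_plasma, solubility = solubility,
         ka = ka, fa = fa, peff = peff,
         oral_bioavailability_f = oral_bioavailability_f),
    class = "qivive_compound"
  )
}

#' @export
print.qivive_compound <- function(x, ...) {
  cat(sprintf("<qivive_compound> %s\n", x$name))
  cat(sprintf("  MW %g g/mol, logP %g, %s (pKa %s), fu %g\n",
              x$mw, x$log_p, x$ionization,
              ifelse(is.na(x$pka), "-", format(x$pka)), x$fu_plasma))
  if (!is.na(x$ka) || !is.na(x$peff)) {
    cat(sprintf("  absorption: ka %s 1/h, fa %s, Peff %s cm/s\n",
                format(x$ka), format(x$fa), format(x$peff)))
  }
  invisible(x)
}

#' Derive a first-order absorption rate constant from intestinal permeability
#'
#' Smooth-tube reduction of effective-permeability absorption:
#' `ka = 2 * peff / radius`, converted from per-second to per-hour.
#'
#' @param peff Effective intestinal permeability, cm/s (> 0).
#' @param radius_cm Small-intestinal radius, cm (default 1.75).
#' @return ka in 1/h.
#' @export
ka_from_peff <- function(peff, radius_cm = 1.75) {
  assert_number(peff, "peff", lower = 0, strict_lower = TRUE)
  assert_number(radius_cm, "radius_cm", lower = 0, strict_lower = TRUE)
  2 * peff / radius_cm * 3600
}

#' Read compound definitions from a YAML configuration file
#'
#' The file holds one section per compound; numeric keys carry explicit unit
#' suffixes (`mw_g_per_mol`, `ka_per_h`, `peff_cm_per_s`, ...). See
#' `system.file("extdata", "compounds.yaml", package = "qivive")` for the
#' packaged example with the three case-study compounds.
#'
#' @param path Path to the YAML file.
#' @return A named list of [compound()] objects.
#' @export
read_compound_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- purrr::imap(cfg, function(entry, nm) {
    compound(
      name = nm,
      mw = entry$mw_g_per_mol,
      log_p = entry$log_p,
      ionization = entry$ionization %||% "neutral",
      pka = entry$pka %||% NA_real_,
      fu_plasma = entry$fu_plasma,
      solubility = entry$solubility_mg_per_ml %||% NA_real_,
      ka = entry$ka_per_h %||% NA_real_,
      fa = entry$fa %||% NA_real_,
      peff = entry$peff_cm_per_s %||% NA_real_,
      oral_bioavailability_f = entry$oral_bioavailability_f %||% NA_real_
    )
  })
  out
}

#' Packaged case-study compounds
#'
#' Reference parameterizations of the three demonstration compounds: an NSAID
#' (`"ibuprofen"`), a lipophilic antiarrhythmic (`"amiodarone"`) and an
#' organophosphate pesticide (`"chlorpyrifos"`), read from the packaged
#' configuration file.
#'
#' @param name Compound name (one of the above).
#' @return A [compound()] object.
#' @examples
#' case_study_compound("ibuprofen")
#' @export
case_study_compound <- function(name = c("ibuprofen", "amiodarone", "chlorpyrifos")) {
  name <- match.arg(name)
  path <- system.file("extdata", "compounds.yaml", package = "qivive")
  read_compound_config(path)[[name]]
}
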