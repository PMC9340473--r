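# Reference human physiology: ICRP-style organ volumes and blood flows for a
# 70 kg adult male and a 60 kg adult female, packaged as delimited text under
# inst/extdata. The liver row also carries liver mass and MPPGL (microsomal
# protein per gram liver), the scaling factors for microsomal clearance.

#' Load a reference human physiology
#'
#' Returns a complete, internally consistent physiological parameter set:
#' body weight, cardiac output, per-organ volumes and blood flows (a closed
#' circulation: organ flows sum exactly to cardiac output, with a lumped
#' `rest` compartment carrying the residual), liver mass and MPPGL.
#'
#' @param profile `"adult_male"` or `"adult_female"`.
#' @return An object of class `qivive_physiology`: a list with elements
#'   `profile`, `sex`, `body_weight` (kg), `cardiac_output` (L/h), `organs`
#'   (tibble: organ, volume_L, flow_L_h), `liver_mass_g`, `mppgl`
#'   (mg microsomal protein / g liver), `hematocrit`, and `pregnancy`
#'   (NULL until [apply_pregnancy()]).
#' @examples
#' phys <- load_reference_physiology("adult_male")
#' phys$organs
#' @export
load_reference_physiology <- function(profile = c("adult_male", "adult_female")) {
  available <- c("adult_male", "adult_female")
  if (!is.character(profile) || !profile[1] %in% available) {
    abort(sprintf("Unknown physiology profile. Available: %s.",
                  paste(available, collapse = ", ")))
  }
  profile <- profile[1]
  organs <- as_tibble(read.delim(
    system.file("extdata", "physiology_organs.tsv", package = "qivive")
  ))
  scalars <- read.delim(
    system.file("extdata", "physiology_scalars.tsv", package = "qivive")
  )
  organs <- dplyr::filter(organs, .data$profile == !!profile)
  organs$profile <- NULL
  sc <- scalars[scalars$profile == profile, ]
  phys <- structure(
    list(profile = profile, sex = sc$sex,
         body_weight = sc$body_weight_kg,
         cardiac_output = sc$cardiac_output_L_h,
         organs = organs,
         liver_mass_g = sc$liver_mass_g,
         mppgl = sc$mppgl_mg_per_g,
         hematocrit = sc$hematocrit,
         pregnancy = NULL),
    class = "qivive_physiology"
  )
  validate_physiology(phys)
  phys
}

validate_physiology <- function(phys) {
  org <- phys$organs
  required <- c("lung", "arterial", "venous", "liver", "gut", "brain",
                "kidney", "adipose", "muscle", "skin")
  missing <- setdiff(required, org$organ)
  if (length(missing)) {
    abort(sprintf("Physiology is missing organ(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  if (any(org$volume_L <= 0)) abort("All organ volumes must be > 0.")
  flows <- org$flow_L_h[!org$organ %in% c("lung", "arterial", "venous")]
  if (any(is.na(flows)) || any(flows <= 0)) {
    abort("All tissue blood flows must be > 0.")
  }
  if (sum(flows) > phys$cardiac_output * (1 + 1e-8)) {
    abort("Sum of organ blood flows exceeds cardiac output.")
  }
  invisible(phys)
}

#' @export
print.qivive_physiology <- function(x, ...) {
  cat(sprintf("<qivive_physiology> %s (%s, %g kg, CO %g L/h%s)\n",
              x$profile, x$sex, x$body_weight, x$cardiac_output,
              if (!is.null(x$pregnancy)) ", pregnant" else ""))
  print(x$organs)
  invisible(x)
}

#' Describe a pregnancy extension
#'
#' Physiological changes applied on top of an adult female physiology:
#' expanded plasma volume, increased cardiac output and a flow-limited fetal
#' compartment exchanging with maternal arterial blood. Defaults describe the
#' end of the first trimester (week 13): +40\% plasma volume, +20\% cardiac
#' output, a 0.05 L fetal compartment and a fetal:maternal partition of 1.46.
#'
#' @param gestational_week Gestational week (informational).
#' @param plasma_volume_expansion Fractional increase of the blood pools.
#' @param cardiac_output_increase Fractional increase of cardiac output.
#' @param fetal_volume_L Fetal compartment volume, L (> 0).
#' @param fetal_flow_L_h Placental blood flow to the fetal compartment, L/h.
#' @param fetal_maternal_partition Steady-state fetal:maternal concentration
#'   ratio, used as the fetal compartment's partition coefficient.
#' @return A `qivive_pregnancy_extension` list.
#' @export
pregnancy_extension <- function(gestational_week = 13,
                                plasma_volume_expansion = 0.4,
                                cardiac_output_increase = 0.2,
                                fetal_volume_L = 0.05,
                                fetal_flow_L_h = 2,
                                fetal_maternal_partition = 1.46) {
  assert_number(plasma_volume_expansion, "plasma_volume_expansion", lower = 0)
  assert_number(cardiac_output_increase, "cardiac_output_increase", lower = 0)
  assert_number(fetal_volume_L, "fetal_volume_L", lower = 0, strict_lower = TRUE)
  assert_number(fetal_flow_L_h, "fetal_flow_L_h", lower = 0, strict_lower = TRUE)
  assert_number(fetal_maternal_partition, "fetal_maternal_partition",
                lower = 0, strict_lower = TRUE)
  structure(
    list(gestational_week = gestational_week,
         plasma_volume_expansion = plasma_volume_expansion,
         cardiac_output_increase = cardiac_output_increase,
         fetal_volume_L = fetal_volume_L,
         fetal_flow_L_h = fetal_flow_L_h,
         fetal_maternal_partition = fetal_maternal_partition),
    class = "qivive_pregnancy_extension"
  )
}

#' Extend a female physiology with pregnancy
#'
#' Increases the blood-pool volumes and cardiac output, adds a flow-limited
#' fetal compartment, and re-balances flows so venous return still equals
#' cardiac output (the cardiac-output increment beyond the placental flow is
#' routed through the lumped `rest` compartment). Total distribution volume
#' never decreases.
#'
#' @param physiology A female [load_reference_physiology()] object.
#' @param ext A [pregnancy_extension()].
#' @return A `qivive_physiology` with a `fetus` organ row and the extension
#'   stored in `$pregnancy`.
#' @export
apply_pregnancy <- function(physiology, ext = pregnancy_extension()) {
  stopifnot(inherits(physiology, "qivive_physiology"))
  stopifnot(inherits(ext, "qivive_pregnancy_extension"))
  if (!identical(physiology$sex, "female")) {
    abort("Pregnancy extension requires a female physiology profile.")
  }
  extra_co <- physiology$cardiac_output * ext$cardiac_output_increase
  if (ext$fetal_flow_L_h > extra_co) {
    abort("Fetal blood flow exceeds the cardiac output increment; raise `cardiac_output_increase`.")
  }
  org <- physiology$organs
  pool <- org$organ %in% c("arterial", "venous")
  org$volume_L[pool] <- org$volume_L[pool] * (1 + ext$plasma_volume_expansion)
  org$flow_L_h[org$organ == "rest"] <-
    org$flow_L_h[org$organ == "rest"] + (extra_co - ext$fetal_flow_L_h)
  org$flow_L_h[org$organ == "lung"] <- physiology$cardiac_output + extra_co
  org <- dplyr::bind_rows(
    org,
    tibble(organ = "fetus", volume_L = ext$fetal_volume_L,
           flow_L_h = ext$fetal_flow_L_h)
  )
  physiology$organs <- org
  physiology$cardiac_output <- physiology$cardiac_output + extra_co
  physiology$pregnancy <- ext
  validate_physiology(physiology)
  physiology
}
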