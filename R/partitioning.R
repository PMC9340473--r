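# Tissue:blood partition coefficients, either predicted mechanistically from
# compound properties and tissue composition, or measured as in vitro
# cell:medium concentration ratios.
#
# The mechanistic route is a four-constituent composition-based algorithm in
# the tradition of tissue-composition Kp predictors: a tissue's capacity for
# a compound is the sum of contributions from tissue water (all species, with
# Henderson-Hasselbalch ionization at intracellular pH), neutral lipid
# (neutral species only, affinity 10^logP), phospholipid membranes (both
# species, affinity from a membrane-affinity regression on logP) and tissue
# protein (both species, association constant by ionization class). The
# blood-side denominator is the aqueous capacity of plasma at blood pH
# divided by the unbound fraction, so predicted Kp is proportional to fu.

# Membrane affinity (phospholipid:water) regressed on lipophilicity.
.log_membrane_affinity <- function(log_p) 0.81 * log_p + 0.98

# Tissue-protein association constants by ionization class. The acid value
# was fixed once against hepatic tissue-distribution data for an acidic
# NSAID; acids bind intracellular/interstitial albumin-like proteins far more
# strongly than bases or neutrals.
.protein_affinity <- c(acid = 3700, base = 200, neutral = 60)

# Total:neutral ratio in aqueous solution at a given pH.
.ionization_ratio <- function(ionization, pka, ph) {
  switch(ionization,
         acid = 1 + 10^(ph - pka),
         base = 1 + 10^(pka - ph),
         neutral = 1)
}

#' Load the packaged tissue-composition table
#'
#' Volume fractions of water, neutral lipid, phospholipid and protein plus
#' intracellular pH for the standard organ set, as delimited text.
#'
#' @return A tibble with columns `tissue`, `f_water`, `f_neutral_lipid`,
#'   `f_phospholipid`, `f_protein`, `intracellular_ph`.
#' @export
tissue_composition <- function() {
  as_tibble(read.delim(
    system.file("extdata", "tissue_composition.tsv", package = "qivive")
  ))
}

#' Predict a tissue:blood partition coefficient from composition
#'
#' Mechanistic composition-based prediction (see the package vignette for the
#' equation set). Deterministic for fixed inputs; strictly increasing in the
#' plasma unbound fraction and, for lipid-containing tissues, in logP.
#'
#' @param compound A [compound()].
#' @param tissue A tissue name from [tissue_composition()], or a one-row data
#'   frame with the same columns for a custom composition.
#' @param fu Plasma unbound fraction driving the blood-side binding term;
#'   defaults to the compound's `fu_plasma`. Must be in (0, 1].
#' @param blood_ph Blood/plasma pH (default 7.4).
#' @param blood_plasma_ratio Blood:plasma concentration ratio (default 1:
#'   red-cell partitioning neglected, so tissue:plasma and tissue:blood
#'   coincide).
#' @return Kp, the predicted tissue:blood concentration ratio (> 0).
#' @examples
#' ibu <- case_study_compound("ibuprofen")
#' predict_kp_schmitt(ibu, "liver") # ~3
#' @export
predict_kp_schmitt <- function(compound, tissue, fu = compound$fu_plasma,
                               blood_ph = 7.4, blood_plasma_ratio = 1) {
  stopifnot(inherits(compound, "qivive_compound"))
  assert_number(fu, "fu", lower = 0, upper = 1, strict_lower = TRUE)
  assert_number(blood_plasma_ratio, "blood_plasma_ratio",
                lower = 0, strict_lower = TRUE)
  if (compound$ionization != "neutral" && is.na(compound$pka)) {
    abort("Ionizable compound needs `pka` for partition prediction.")
  }
  if (is.character(tissue)) {
    comp <- tissue_composition()
    row <- comp[comp$tissue == tissue, ]
    if (nrow(row) != 1) {
      abort(sprintf("Unknown tissue '%s'; see tissue_composition().", tissue))
    }
  } else {
    row <- as.data.frame(tissue)
    stopifnot(nrow(row) == 1)
  }
  a_blood <- .ionization_ratio(compound$ionization, compound$pka, blood_ph)
  a_tis <- .ionization_ratio(compound$ionization, compound$pka,
                             row$intracellular_ph)
  k_nl <- 10^compound$log_p
  k_pl <- 10^.log_membrane_affinity(compound$log_p)
  k_prot <- .protein_affinity[[compound$ionization]]
  capacity <- row$f_water * a_tis +
    row$f_neutral_lipid * k_nl +
    row$f_phospholipid * k_pl * a_tis +
    row$f_protein * k_prot * a_tis
  fu * capacity / a_blood / blood_plasma_ratio
}

#' Build a full partition set for a model
#'
#' Predicts Kp for every tissue in a physiology with [predict_kp_schmitt()],
#' then applies any per-tissue overrides (e.g. an in-vitro-derived liver Kp,
#' or a fetal:maternal ratio). Provenance is recorded per tissue.
#'
#' @param compound A [compound()].
#' @param physiology A [load_reference_physiology()] object.
#' @param overrides Named numeric vector of Kp overrides by tissue.
#' @param overrides_provenance Provenance label for overridden tissues
#'   (default `"override"`; use e.g. `"in_vitro"` or `"literature"`).
#' @param fu Plasma unbound fraction for the blood-side term (defaults to the
#'   compound's).
#' @return A tibble with columns `tissue`, `kp`, `provenance` covering every
#'   perfused compartment (including `lung`, excluding the blood pools).
#' @export
predict_partition_set <- function(compound, physiology, overrides = NULL,
                                  overrides_provenance = "override",
                                  fu = compound$fu_plasma) {
  stopifnot(inherits(physiology, "qivive_physiology"))
  tissues <- setdiff(physiology$organs$organ, c("arterial", "venous"))
  kp <- purrr::map_dbl(tissues, function(t) {
    if (!is.null(physiology$pregnancy) && t == "fetus") {
      physiology$pregnancy$fetal_maternal_partition
    } else {
      predict_kp_schmitt(compound, t, fu = fu)
    }
  })
  prov <- rep("predicted", length(tissues))
  prov[tissues == "fetus"] <- "literature"
  out <- tibble(tissue = tissues, kp = kp, provenance = prov)
  if (!is.null(overrides)) {
    stopifnot(!is.null(names(overrides)))
    unknown <- setdiff(names(overrides), out$tissue)
    if (length(unknown)) {
      abort(sprintf("Override for unknown tissue(s): %s.",
                    paste(unknown, collapse = ", ")))
    }
    idx <- match(names(overrides), out$tissue)
    out$kp[idx] <- unname(overrides)
    out$provenance[idx] <- overrides_provenance
  }
  if (any(out$kp <= 0)) abort("All partition coefficients must be > 0.")
  out
}

#' Partition coefficient from in vitro cell and medium concentrations
#'
#' The empirical route: the ratio of the concentration measured in the cell
#' lysate to the concentration in the culture medium at (near-)steady state.
#'
#' @param cell_conc Cell-lysate concentration, µg/mL (>= 0).
#' @param medium_conc Medium concentration, µg/mL (> 0).
#' @return Kp = `cell_conc / medium_conc`.
#' @examples
#' kp_from_in_vitro(11.1, 1.0)
#' @export
kp_from_in_vitro <- function(cell_conc, medium_conc) {
  assert_numeric_vec(cell_conc, "cell_conc", lower = 0)
  if (!is.numeric(medium_conc) || any(medium_conc <= 0)) {
    abort("`medium_conc` must be > 0.")
  }
  cell_conc / medium_conc
}
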