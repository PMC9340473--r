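# Synthetic in vitro data: a two-compartment (medium <-> cell) biokinetic
# simulator with repeated-dosing medium replacement and optional metabolite
# product inhibition, plus generators for noisy measurements and continuous
# dose-response tables. These emulate the structure of long-term repeated-
# dose in vitro biokinetic experiments (14 daily administrations, sampling
# in medium and cell lysate) so the full pipeline is testable without
# laboratory data.

#' Describe an in vitro test system
#'
#' @param v_medium_ml Culture-medium volume, mL (> 0).
#' @param v_cells_ml Cell (lysate) volume, mL (> 0).
#' @param kp_cell_medium Cell:medium partition coefficient at equilibrium
#'   (> 0), for free medium compound (the realized equilibrium ratio is
#'   `kp_cell_medium * fu_medium`).
#' @param clearance Metabolic loss from the cell compartment: either a
#'   linear intrinsic clearance in mL/h (`cl_ml_h`), or [metabolic_params()]
#'   (possibly with `ki_product`) together with `protein_mg`.
#' @param cl_ml_h Linear in vitro clearance, mL/h (alternative to
#'   `clearance`).
#' @param protein_mg Protein amount scaling Michaelis-Menten Vmax to the
#'   whole well, mg.
#' @param fu_medium Unbound fraction in the medium (1 for protein-free
#'   medium).
#' @param nominal_um Nominal concentration applied at each medium change,
#'   µM.
#' @param redose_interval_h Medium-replacement interval, h (default 24).
#' @param n_doses Number of administrations (default 14, one per day).
#' @param mw Compound molecular weight, g/mol (for µM <-> µg conversions).
#' @param cl_exchange_ml_h Medium-cell exchange clearance, mL/h. Default
#'   `10 * v_cells_ml * kp_cell_medium`, fast relative to metabolism
#'   (equilibration well under 1 h).
#' @return A `qivive_invitro_system` list.
#' @export
in_vitro_system <- function(v_medium_ml, v_cells_ml, kp_cell_medium,
                            clearance = NULL, cl_ml_h = NULL,
                            protein_mg = NULL, fu_medium = 1,
                            nominal_um, redose_interval_h = 24, n_doses = 14,
                            mw, cl_exchange_ml_h = NULL) {
  assert_number(v_medium_ml, "v_medium_ml", lower = 0, strict_lower = TRUE)
  assert_number(v_cells_ml, "v_cells_ml", lower = 0, strict_lower = TRUE)
  assert_number(kp_cell_medium, "kp_cell_medium", lower = 0, strict_lower = TRUE)
  assert_number(fu_medium, "fu_medium", lower = 0, upper = 1, strict_lower = TRUE)
  assert_number(nominal_um, "nominal_um", lower = 0)
  assert_number(mw, "mw", lower = 0, strict_lower = TRUE)
  if (is.null(cl_exchange_ml_h)) {
    cl_exchange_ml_h <- 10 * v_cells_ml * kp_cell_medium
  }
  if (!is.null(clearance) && inherits(clearance, "qivive_metabolic_params")) {
    assert_number(protein_mg, "protein_mg", lower = 0, strict_lower = TRUE)
    met <- list(kind = "mm", params = clearance, protein_mg = protein_mg)
  } else if (!is.null(cl_ml_h)) {
    assert_number(cl_ml_h, "cl_ml_h", lower = 0)
    met <- list(kind = "linear", cl_ml_h = cl_ml_h)
  } else {
    met <- list(kind = "linear", cl_ml_h = 0)
  }
  structure(
    list(v_medium = v_medium_ml, v_cells = v_cells_ml,
         kp = kp_cell_medium, fu_medium = fu_medium, met = met,
         nominal_um = nominal_um, redose_interval_h = redose_interval_h,
         n_doses = as.integer(n_doses), mw = mw,
         cl_exchange = cl_exchange_ml_h),
    class = "qivive_invitro_system"
  )
}

#' Simulate noise-free in vitro biokinetics
#'
#' Integrates the medium/cell exchange (`CL_ex * (fu_medium * C_med -
#' C_cell / Kp)`) with intracellular metabolic loss; each re-dose replaces
#' the medium (medium amount reset to the nominal dose, cell-associated
#' amounts retained). With `ki_product` on the metabolic parameters the
#' accumulating metabolite competitively inhibits the parent's metabolism,
#' so the apparent depletion rate declines over repeated doses.
#'
#' @param system An [in_vitro_system()].
#' @param duration_h Simulated span (default covers all doses).
#' @param grid_h Output-grid spacing, h.
#' @return A `qivive_invitro_sim`: `$data` (tibble: time, medium_conc,
#'   cell_conc, metabolite_conc, all µg/mL), `$balance` (mass audit),
#'   `$system`.
#' @export
simulate_in_vitro <- function(system, duration_h = NULL, grid_h = 0.25) {
  stopifnot(inherits(system, "qivive_invitro_system"))
  if (is.null(duration_h)) {
    duration_h <- system$n_doses * system$redose_interval_h
  }
  dose_ug <- system$nominal_um * system$mw / 1000 * system$v_medium
  dose_times <- (seq_len(system$n_doses) - 1) * system$redose_interval_h
  dose_times <- dose_times[dose_times < duration_h]

  # states (ug): medium, cell, metabolite-in-cell, cumulative metabolized,
  # removed by medium changes, administered
  rhs <- function(t, y, p) {
    c_med <- y[1] / system$v_medium
    c_cell <- y[2] / system$v_cells
    flux <- system$cl_exchange *
      (system$fu_medium * c_med - c_cell / system$kp)
    met <- system$met
    if (met$kind == "linear") {
      vmet <- met$cl_ml_h * c_cell
    } else {
      c_um <- c_cell * 1000 / system$mw
      i_um <- (y[3] / system$v_cells) * 1000 / system$mw
      km_app <- met$params$km
      if (!is.na(met$params$ki_product)) {
        km_app <- km_app * (1 + i_um / met$params$ki_product)
      }
      vmet <- met$params$vmax_per_h * met$protein_mg * c_um /
        (km_app + c_um) * system$mw / 1e6 * 1000 # nmol/h -> ug/h
    }
    list(c(-flux, flux - vmet, vmet, vmet, 0, 0))
  }
  event_fun <- function(t, y, p) {
    y[5] <- y[5] + y[1] # discarded medium
    y[1] <- dose_ug
    y[6] <- y[6] + dose_ug
    y
  }
  times <- sort(unique(c(seq(0, duration_h, by = grid_h), dose_times,
                         duration_h)))
  y0 <- c(medium = 0, cell = 0, metabolite = 0, metabolized = 0,
          removed = 0, administered = 0)
  out <- as.data.frame(deSolve::ode(
    y0, times, rhs, parms = NULL, method = "lsoda",
    rtol = 1e-10, atol = 1e-12,
    events = list(func = event_fun, time = dose_times)
  ))
  data <- tibble(
    time = out$time,
    medium_conc = out$medium / system$v_medium,
    cell_conc = out$cell / system$v_cells,
    metabolite_conc = out$metabolite / system$v_cells
  )
  balance <- tibble(
    time = out$time, administered_ug = out$administered,
    in_system_ug = out$medium + out$cell,
    metabolized_ug = out$metabolized, removed_ug = out$removed,
    rel_error = ifelse(out$administered > 0,
                       (out$administered - out$medium - out$cell -
                          out$metabolized - out$removed) / out$administered,
                       0)
  )
  structure(list(data = data, balance = balance, system = system),
            class = "qivive_invitro_sim")
}

#' @export
print.qivive_invitro_sim <- function(x, ...) {
  cat(sprintf("<qivive_invitro_sim> %d doses of %g uM, %g h\n",
              x$system$n_doses, x$system$nominal_um, max(x$data$time)))
  invisible(x)
}

#' @export
tidy.qivive_invitro_sim <- function(x, ...) x$data

#' @export
autoplot.qivive_invitro_sim <- function(object, ...) {
  long <- tidyr::pivot_longer(object$data, -"time",
                              names_to = "series", values_to = "conc")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$conc,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "concentration (µg/mL)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Apparent depletion rate of parent compound within one dosing day
#'
#' Log-linear decline rate of the total parent amount (medium + cell)
#' between two consecutive medium changes: a simple apparent-clearance
#' readout whose decline over repeated doses reveals product inhibition.
#'
#' @param sim A [simulate_in_vitro()] result.
#' @param day Dosing day (1-based).
#' @return Apparent first-order depletion rate constant, 1/h.
#' @export
in_vitro_apparent_depletion <- function(sim, day) {
  stopifnot(inherits(sim, "qivive_invitro_sim"))
  sys <- sim$system
  t0 <- (day - 1) * sys$redose_interval_h
  t1 <- t0 + sys$redose_interval_h
  d <- dplyr::filter(sim$data, .data$time > t0 + 1e-9, .data$time <= t1 + 1e-9)
  total <- d$medium_conc * sys$v_medium + d$cell_conc * sys$v_cells
  if (any(total <= 0)) abort("Non-positive amounts; cannot fit depletion rate.")
  fit <- stats::lm(log(total) ~ d$time)
  -unname(stats::coef(fit)[2])
}

#' Add multiplicative lognormal measurement noise
#'
#' Mean-unbiased lognormal noise with coefficient of variation `cv`,
#' reproducible under a fixed seed; `cv = 0` returns the dataset unchanged.
#'
#' @param sim A [simulate_in_vitro()] result (or its `$data` tibble).
#' @param cv Coefficient of variation (>= 0).
#' @param seed Integer seed.
#' @return The dataset with noisy concentration columns.
#' @export
add_noise <- function(sim, cv, seed) {
  assert_number(cv, "cv", lower = 0)
  data <- if (inherits(sim, "qivive_invitro_sim")) sim$data else as_tibble(sim)
  if (cv == 0) return(data)
  sdlog <- sqrt(log(1 + cv^2))
  cols <- intersect(c("medium_conc", "cell_conc", "metabolite_conc"),
                    names(data))
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed({
    for (cl in cols) {
      data[[cl]] <- data[[cl]] *
        exp(rnorm(nrow(data), 0, sdlog) - sdlog^2 / 2)
    }
  })
  data
}

#' Generate a continuous dose-response table from a known true curve
#'
#' Group means are the true curve plus normal error with standard error
#' `sd / sqrt(n)`; group SDs are drawn from the scaled chi-square sampling
#' distribution of a sample SD, so the table has exactly the summary-data
#' structure the BMD likelihood assumes. The design true BMD (at
#' `bmr_factor` SD of background) is carried in the `true_bmd` attribute
#' for recovery studies.
#'
#' @param true_model List with `family` (`"linear"`, `"exponential"` or
#'   `"hill"`) and `params` (see [fit_bmd()] parameterizations).
#' @param doses Dose vector including 0 (control).
#' @param sd True residual SD (> 0).
#' @param n_per_group Group size (>= 2).
#' @param seed Integer seed.
#' @param bmr_factor BMR in SDs used for the recorded true BMD (default 1).
#' @return A dose-response tibble (`dose`, `mean`, `sd`, `n`) with
#'   attributes `true_bmd` and `true_model`.
#' @export
generate_dose_response <- function(true_model, doses, sd, n_per_group, seed,
                                   bmr_factor = 1) {
  stopifnot(0 %in% doses)
  assert_number(sd, "sd", lower = 0, strict_lower = TRUE)
  assert_number(n_per_group, "n_per_group", lower = 2)
  mu <- .bmd_mu(true_model$family, true_model$params, doses)
  mu0 <- .bmd_mu(true_model$family, true_model$params, 0)
  g <- function(d) abs(.bmd_mu(true_model$family, true_model$params, d) - mu0) -
    bmr_factor * sd
  true_bmd <- tryCatch(
    uniroot(g, c(0, 100 * max(doses)), tol = 1e-10)$root,
    error = function(e) NA_real_
  )
  set.seed(seed)
  means <- mu + rnorm(length(doses), 0, sd / sqrt(n_per_group))
  sds <- sd * sqrt(stats::rchisq(length(doses), n_per_group - 1) /
                     (n_per_group - 1))
  out <- tibble(dose = doses, mean = means, sd = sds, n = n_per_group)
  attr(out, "true_bmd") <- true_bmd
  attr(out, "true_model") <- true_model
  out
}

#' Read / write dose-response tables as delimited text
#'
#' Tab-separated tables with header columns `dose`, `mean`, `sd`, `n`.
#'
#' @param path File path.
#' @return `read_dose_response`: a validated tibble.
#' @export
read_dose_response <- function(path) {
  .validate_dose_response(read.delim(path))
}

#' @rdname read_dose_response
#' @param data A dose-response data frame.
#' @export
write_dose_response <- function(data, path) {
  write.table(as.data.frame(data), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
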