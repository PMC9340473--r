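# Reverse dosimetry: find the external dose whose simulated internal
# exposure matches an in vitro target. The search is a deterministic grid
# search refined hierarchically down to a user-stated dose step, mirroring
# iterative fixed-increment dose finding; ties at equal objective break
# toward the lower (conservative) dose.

#' Describe a target exposure for reverse dosimetry
#'
#' @param mode `"profile"` (match a full concentration-time profile by sum
#'   of squared differences), `"auc"` or `"cmax"` (match a scalar metric).
#' @param compartment Model compartment the target refers to.
#' @param profile For `mode = "profile"`: data frame with columns `time`
#'   (h, sorted) and `conc` (µg/mL).
#' @param value For scalar modes: the target AUC (µg·h/mL) or Cmax (µg/mL),
#'   > 0.
#' @param window For scalar modes: `c(t0, t1)` evaluation window in h.
#' @return A `qivive_target` list.
#' @export
target_exposure <- function(mode = c("profile", "auc", "cmax"),
                            compartment = "venous", profile = NULL,
                            value = NULL, window = c(0, 24)) {
  mode <- match.arg(mode)
  if (mode == "profile") {
    stopifnot(is.data.frame(profile), all(c("time", "conc") %in% names(profile)))
    if (!nrow(profile)) abort("Target profile must be non-empty.")
    if (is.unsorted(profile$time, strictly = TRUE)) {
      abort("Target profile times must be strictly increasing.")
    }
  } else {
    assert_number(value, "value", lower = 0, strict_lower = TRUE)
  }
  structure(
    list(mode = mode, compartment = compartment,
         profile = if (!is.null(profile)) as_tibble(profile),
         value = value, window = window),
    class = "qivive_target"
  )
}

# Objective for one candidate dose. Returns the scalar objective plus the
# achieved metric.
.dose_objective <- function(dose, model, regimen_template, target, sim_args) {
  reg <- regimen_template
  reg$dose <- dose
  if (target$mode == "profile") {
    dur <- max(target$profile$time)
    times <- sort(unique(c(seq(0, dur, by = 0.1), target$profile$time)))
    sim <- do.call(simulate_pbk,
                   c(list(model = model, regimen = reg, duration = dur,
                          times = times), sim_args))
    prof <- dplyr::filter(sim$profile,
                          .data$compartment == target$compartment)
    csim <- prof$conc_ug_ml[match(round(target$profile$time, 9),
                                  round(prof$time, 9))]
    ssq <- sum((csim - target$profile$conc)^2)
    list(objective = ssq, achieved = NA_real_)
  } else {
    dur <- target$window[2]
    sim <- do.call(simulate_pbk,
                   c(list(model = model, regimen = reg, duration = dur),
                     sim_args))
    met <- compute_metrics(sim, target$compartment, target$window)
    achieved <- if (target$mode == "auc") met$auc_ug_h_ml else met$cmax_ug_ml
    list(objective = abs(achieved - target$value), achieved = achieved)
  }
}

.search_grid <- function(lo, hi, step, n_coarse = 21) {
  if ((hi - lo) / step + 1 <= n_coarse * 2) {
    seq(ceiling(lo / step) * step, hi, by = step)
  } else {
    seq(lo, hi, length.out = n_coarse)
  }
}

#' Find the dose matching a target exposure (grid search)
#'
#' Searches dose space for the administration whose simulated exposure best
#' matches `target`. The objective is evaluated on successively refined
#' grids until the stated `dose_step` resolution is reached; the final grid
#' is aligned to multiples of `dose_step`, reproducing a fixed-increment
#' iterative search. If several grid doses tie at the minimum the lowest
#' dose is returned with a warning.
#'
#' @param model A [build_model()] object.
#' @param regimen_template A [dosing_regimen()] whose `dose` field is the
#'   placeholder varied by the search (its unit defines the search unit).
#' @param target A [target_exposure()].
#' @param dose_step Grid resolution in the regimen's dose unit (> 0).
#' @param bounds Search interval `c(lo, hi)`. Default: `c(0, 100 * d1)`
#'   where `d1` is a first-guess dose from the linear relation between dose
#'   and the target metric.
#' @param sim_args Extra arguments passed to [simulate_pbk()] (e.g. coarser
#'   output grids for speed).
#' @return A `qivive_dose_search`: `optimized_dose`, `achieved_metric`,
#'   `objective` (SSQ or |metric difference|), `trace` (tibble of every
#'   evaluated dose and objective), `dose_step`, `mode`.
#' @export
optimize_dose <- function(model, regimen_template, target, dose_step,
                          bounds = NULL, sim_args = list()) {
  stopifnot(inherits(model, "qivive_pbk_model"),
            inherits(regimen_template, "qivive_regimen"),
            inherits(target, "qivive_target"))
  assert_number(dose_step, "dose_step", lower = 0, strict_lower = TRUE)

  # zero target -> zero dose, no search needed
  if (target$mode != "profile" && target$value == 0) {
    abort("Scalar targets must be > 0; a zero target maps to dose 0.")
  }

  obj_fun <- function(d) .dose_objective(d, model, regimen_template, target,
                                         sim_args)
  trace <- tibble(dose = numeric(), objective = numeric(),
                  achieved = numeric())
  evaluate <- function(doses) {
    res <- purrr::map(doses, obj_fun)
    new <- tibble(dose = doses,
                  objective = purrr::map_dbl(res, "objective"),
                  achieved = purrr::map_dbl(res, "achieved"))
    trace <<- dplyr::bind_rows(trace, new)
    new
  }

  if (is.null(bounds)) {
    d0 <- if (regimen_template$dose > 0) regimen_template$dose else 1
    probe <- evaluate(d0)
    scale_ratio <- if (target$mode == "profile") {
      # ratio of target to simulated profile magnitude at the probe dose
      reg <- regimen_template; reg$dose <- d0
      dur <- max(target$profile$time)
      times <- sort(unique(c(seq(0, dur, by = 0.1), target$profile$time)))
      sim <- do.call(simulate_pbk,
                     c(list(model = model, regimen = reg, duration = dur,
                            times = times), sim_args))
      prof <- dplyr::filter(sim$profile,
                            .data$compartment == target$compartment)
      csim <- prof$conc_ug_ml[match(round(target$profile$time, 9),
                                    round(prof$time, 9))]
      sum(target$profile$conc * csim) / max(sum(csim^2), 1e-300)
    } else {
      target$value / max(probe$achieved, 1e-300)
    }
    d1 <- max(d0 * scale_ratio, dose_step)
    bounds <- c(0, 100 * d1)
  }
  lo <- max(bounds[1], 0)
  hi <- bounds[2]
  if (hi <= lo) abort("Invalid dose bounds.")

  repeat {
    grid <- .search_grid(lo, hi, dose_step)
    res <- evaluate(grid)
    i <- which.min(res$objective)
    spacing <- if (length(grid) > 1) grid[2] - grid[1] else dose_step
    if (spacing <= dose_step * (1 + 1e-9)) {
      ties <- which(abs(res$objective - res$objective[i]) <=
                      1e-12 * max(res$objective[i], 1e-300))
      if (length(ties) > 1) {
        warn("Multiple grid doses tie at the minimum objective; returning the lowest.")
        i <- min(ties)
      }
      best <- res[i, ]
      break
    }
    lo <- max(lo, grid[i] - 2 * spacing)
    hi <- min(hi, grid[i] + 2 * spacing)
  }

  if (target$mode != "profile" &&
      best$objective > 0.5 * target$value) {
    abort(sprintf(paste0("No dose within the bounds achieves the target ",
                         "metric; nearest achieved value: %.4g."),
                  best$achieved))
  }
  structure(
    list(optimized_dose = best$dose, achieved_metric = best$achieved,
         objective = best$objective,
         trace = dplyr::arrange(dplyr::distinct(trace, .data$dose,
                                                .keep_all = TRUE), .data$dose),
         dose_step = dose_step, mode = target$mode,
         dose_unit = regimen_template$dose_unit, target = target),
    class = "qivive_dose_search"
  )
}

#' @rdname optimize_dose
#' @export
optimize_dose_profile <- function(model, regimen_template, target, dose_step,
                                  bounds = NULL, sim_args = list()) {
  if (target$mode != "profile") abort("`target` must have mode 'profile'.")
  optimize_dose(model, regimen_template, target, dose_step, bounds, sim_args)
}

#' @rdname optimize_dose
#' @export
optimize_dose_metric <- function(model, regimen_template, target, dose_step,
                                 bounds = NULL, sim_args = list()) {
  if (!target$mode %in% c("auc", "cmax")) {
    abort("`target` must have mode 'auc' or 'cmax'.")
  }
  optimize_dose(model, regimen_template, target, dose_step, bounds, sim_args)
}

#' @export
print.qivive_dose_search <- function(x, ...) {
  cat(sprintf("<qivive_dose_search> %s target: dose %g %s (objective %.4g, %d evaluations)\n",
              x$mode, x$optimized_dose, x$dose_unit, x$objective,
              nrow(x$trace)))
  invisible(x)
}

#' @export
tidy.qivive_dose_search <- function(x, ...) x$trace

#' @export
glance.qivive_dose_search <- function(x, ...) {
  tibble(optimized_dose = x$optimized_dose, dose_unit = x$dose_unit,
         achieved_metric = x$achieved_metric, objective = x$objective,
         dose_step = x$dose_step, mode = x$mode, n_evaluations = nrow(x$trace))
}

#' @export
autoplot.qivive_dose_search <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(.data$dose, .data$objective)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$optimized_dose,
                        linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = sprintf("dose (%s)", object$dose_unit),
                  y = "objective") +
    ggplot2::theme_minimal()
}

#' Translate an in vitro concentration-response table to an in vivo
#' dose-response table
#'
#' Re-indexes a concentration-response dataset on the in vivo doses obtained
#' by reverse dosimetry for each tested concentration. The mapping must be
#' monotone non-decreasing (it always is under linear kinetics); a
#' non-monotone mapping raises an internal-consistency error.
#'
#' @param conc_response Data frame with columns `dose` (the tested in vitro
#'   concentrations), `mean`, `sd`, `n`.
#' @param doses Numeric vector of optimized in vivo doses, one per row
#'   (e.g. `optimized_dose` from [optimize_dose()] runs), or a function
#'   mapping a concentration to a dose.
#' @param dose_unit Unit label for the new dose column.
#' @return The table re-indexed on in vivo doses (response columns
#'   untouched).
#' @export
concentration_response_to_dose_response <- function(conc_response, doses,
                                                    dose_unit = "mg") {
  conc_response <- as_tibble(conc_response)
  stopifnot(all(c("dose", "mean") %in% names(conc_response)))
  if (is.function(doses)) {
    doses <- purrr::map_dbl(conc_response$dose, doses)
  }
  stopifnot(length(doses) == nrow(conc_response))
  ord <- order(conc_response$dose)
  if (is.unsorted(doses[ord])) {
    abort("Non-monotone concentration-to-dose mapping; check the kinetic model.")
  }
  out <- conc_response
  out$in_vitro_conc <- out$dose
  out$dose <- doses
  attr(out, "dose_unit") <- dose_unit
  out
}
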