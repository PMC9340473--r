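# Numerical integration of a PBK model. State variables are compartment
# amounts in mg (so repeated doses are additive solver events); profiles are
# reported as concentrations in ug/mL (== mg/L). Mass-balance bookkeeping
# (administered = in body + eliminated + unabsorbed) is carried along as
# extra states and checked on output.

# Precompute everything the right-hand side needs from a model.
.compile_model <- function(model) {
  org <- model$physiology$organs
  tissues <- setdiff(org$organ, c("lung", "arterial", "venous"))
  kp <- setNames(model$partition_set$kp, model$partition_set$tissue)
  vol <- setNames(org$volume_L, org$organ)
  flow <- setNames(org$flow_L_h, org$organ)
  perm <- model$tissue_kinetics

  state_names <- c("arterial", "venous", "lung")
  tinfo <- list()
  for (t in tissues) {
    if (t %in% names(perm)) {
      pk <- perm[[t]]
      v_vas <- vol[[t]] * pk$vascular_fraction
      tinfo[[t]] <- list(kind = "perm", q = flow[[t]], v_vas = v_vas,
                         v_tis = vol[[t]] - v_vas, ps = pk$ps_L_h,
                         fu_t = pk$fu_tissue,
                         i_vas = length(state_names) + 1L,
                         i_tis = length(state_names) + 2L)
      state_names <- c(state_names, paste0(t, "_vas"), paste0(t, "_tis"))
    } else {
      tinfo[[t]] <- list(kind = "flow", q = flow[[t]], v = vol[[t]],
                         kp = kp[[t]], i = length(state_names) + 1L)
      state_names <- c(state_names, t)
    }
  }
  state_names <- c(state_names, "depot", "eliminated", "unabsorbed")
  list(
    tissues = tissues, tinfo = tinfo, state_names = state_names,
    n_state = length(state_names),
    i_art = 1L, i_ven = 2L, i_lung = 3L,
    i_depot = length(state_names) - 2L,
    i_elim = length(state_names) - 1L,
    i_unabs = length(state_names),
    v_art = vol[["arterial"]], v_ven = vol[["venous"]],
    v_lung = vol[["lung"]], kp_lung = kp[["lung"]],
    co = model$physiology$cardiac_output,
    fu_plasma = model$compound$fu_plasma,
    mw = model$compound$mw,
    clearance = model$clearance
  )
}

.liver_driving_conc <- function(cmp, li, y) {
  if (li$kind == "flow") {
    c_liv <- y[li$i] / li$v
    switch(cmp$clearance$driving,
           blood = c_liv / li$kp,
           tissue = c_liv,
           unbound_tissue = abort("`unbound_tissue` driving requires a permeability-limited liver."))
  } else {
    switch(cmp$clearance$driving,
           blood = y[li$i_vas] / li$v_vas,
           tissue = y[li$i_tis] / li$v_tis,
           unbound_tissue = li$fu_t * y[li$i_tis] / li$v_tis)
  }
}

.make_rhs <- function(cmp, ka, infusions) {
  force(cmp); force(ka); force(infusions)
  function(t, y, parms) {
    dy <- numeric(cmp$n_state)
    c_art <- y[cmp$i_art] / cmp$v_art
    c_ven <- y[cmp$i_ven] / cmp$v_ven
    c_lung_out <- y[cmp$i_lung] / cmp$v_lung / cmp$kp_lung

    dy[cmp$i_lung] <- cmp$co * (c_ven - c_lung_out)
    dy[cmp$i_art] <- cmp$co * (c_lung_out - c_art)

    venous_in <- 0
    gi <- cmp$tinfo[["gut"]]
    c_gut_out <- y[gi$i] / gi$v / gi$kp
    dy[gi$i] <- gi$q * (c_art - c_gut_out)

    absorbed <- ka * y[cmp$i_depot]
    dy[cmp$i_depot] <- -absorbed

    for (t_name in cmp$tissues) {
      ti <- cmp$tinfo[[t_name]]
      if (t_name == "gut") next
      if (t_name == "liver") {
        inflow <- ti$q * c_art + gi$q * c_gut_out + absorbed
        q_out <- ti$q + gi$q
        c_drive <- .liver_driving_conc(cmp, ti, y)
        elim <- if (cmp$clearance$kind == "linear") {
          cmp$clearance$cl_L_h * c_drive
        } else {
          hepatic_elimination_rate(c_drive, cmp$clearance, mw = cmp$mw)
        }
        if (ti$kind == "flow") {
          c_out <- y[ti$i] / ti$v / ti$kp
          dy[ti$i] <- inflow - q_out * c_out - elim
          venous_in <- venous_in + q_out * c_out
        } else {
          c_vas <- y[ti$i_vas] / ti$v_vas
          c_tis <- y[ti$i_tis] / ti$v_tis
          flux <- ti$ps * (cmp$fu_plasma * c_vas - ti$fu_t * c_tis)
          dy[ti$i_vas] <- inflow - q_out * c_vas - flux
          dy[ti$i_tis] <- flux - elim
          venous_in <- venous_in + q_out * c_vas
        }
        dy[cmp$i_elim] <- elim
      } else if (ti$kind == "flow") {
        c_out <- y[ti$i] / ti$v / ti$kp
        dy[ti$i] <- ti$q * (c_art - c_out)
        venous_in <- venous_in + ti$q * c_out
      } else {
        c_vas <- y[ti$i_vas] / ti$v_vas
        c_tis <- y[ti$i_tis] / ti$v_tis
        flux <- ti$ps * (cmp$fu_plasma * c_vas - ti$fu_t * c_tis)
        dy[ti$i_vas] <- ti$q * (c_art - c_vas) - flux
        dy[ti$i_tis] <- flux
        venous_in <- venous_in + ti$q * c_vas
      }
    }

    inf_rate <- 0
    if (nrow(infusions)) {
      on <- infusions$start <= t & t < infusions$end
      if (any(on)) inf_rate <- sum(infusions$rate[on])
    }
    dy[cmp$i_ven] <- venous_in - cmp$co * c_ven + inf_rate
    list(dy)
  }
}

.resolve_dose_mg <- function(regimen, physiology) {
  if (regimen$dose_unit == "mg_per_kg") {
    regimen$dose * physiology$body_weight
  } else {
    regimen$dose
  }
}

.resolve_absorption <- function(model, regimen) {
  cpd <- model$compound
  ka <- regimen$ka %||% cpd$ka
  if (is.null(ka) || is.na(ka)) {
    if (!is.na(cpd$peff)) ka <- ka_from_peff(cpd$peff) else {
      abort("Oral dosing requested but the compound has neither `ka` nor `peff`.")
    }
  }
  fa <- regimen$fa %||% cpd$fa
  if (is.null(fa) || is.na(fa)) fa <- 1
  list(ka = ka, fa = fa)
}

#' Simulate a PBK model under a dosing regimen
#'
#' Integrates the model ODEs with a stiff-capable solver (deSolve, `lsoda`).
#' Repeated doses are solver events (the integrator is re-initialized at dose
#' times); i.v. infusions are constant-rate inputs into venous blood. Output
#' is deterministic for fixed inputs and tolerances.
#'
#' @param model A [build_model()] object.
#' @param regimen A [dosing_regimen()].
#' @param duration Simulated span, h (> 0).
#' @param times Optional explicit output grid (h). Defaults to a `grid_h`
#'   spaced grid refined to `fine_h` for `fine_window_h` after each dose.
#' @param grid_h,fine_h,fine_window_h Output-grid controls (see `times`).
#' @param rtol,atol Solver tolerances (defaults 1e-8, 1e-10 mg).
#' @return A `qivive_pbk_sim`: `$profile` (tibble: time, compartment,
#'   conc_ug_ml, amount_mg), `$balance` (mass-balance audit per output time),
#'   `$dose_mg` (per administration), plus the model and regimen.
#' @export
simulate_pbk <- function(model, regimen, duration, times = NULL,
                         grid_h = 0.1, fine_h = 0.01, fine_window_h = 0.5,
                         rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "qivive_pbk_model"),
            inherits(regimen, "qivive_regimen"))
  assert_number(duration, "duration", lower = 0, strict_lower = TRUE)
  cmp <- .compile_model(model)
  dose_mg <- .resolve_dose_mg(regimen, model$physiology)
  dose_times <- (seq_len(regimen$n_doses) - 1) * regimen$interval_h
  dose_times <- dose_times[dose_times < duration]

  ka <- 0
  fa <- 1
  events <- NULL
  infusions <- data.frame(start = numeric(), end = numeric(), rate = numeric())
  if (regimen$route == "oral") {
    ab <- .resolve_absorption(model, regimen)
    ka <- ab$ka; fa <- ab$fa
    events <- rbind(
      data.frame(var = "depot", time = dose_times, value = fa * dose_mg,
                 method = "add"),
      if (fa < 1) data.frame(var = "unabsorbed", time = dose_times,
                             value = (1 - fa) * dose_mg, method = "add")
    )
  } else if (regimen$route == "iv_bolus") {
    events <- data.frame(var = "venous", time = dose_times, value = dose_mg,
                         method = "add")
  } else {
    infusions <- data.frame(
      start = dose_times,
      end = pmin(dose_times + regimen$infusion_duration_h, duration),
      rate = dose_mg / regimen$infusion_duration_h
    )
  }

  if (is.null(times)) {
    times <- seq(0, duration, by = grid_h)
    fine <- unlist(lapply(dose_times, function(td) {
      seq(td, min(td + fine_window_h, duration), by = fine_h)
    }))
    times <- c(times, fine, duration)
  }
  times <- sort(unique(round(
    c(times, dose_times, infusions$start, infusions$end), 9
  )))
  times <- times[times <= duration + 1e-12]

  y0 <- setNames(numeric(cmp$n_state), cmp$state_names)
  rhs <- .make_rhs(cmp, ka, infusions)
  out <- deSolve::ode(
    y = y0, times = times, func = rhs, parms = NULL, method = "lsoda",
    rtol = rtol, atol = atol,
    events = if (!is.null(events)) list(data = events) else NULL
  )
  if (attr(out, "istate")[1] < 0) {
    abort("ODE solver failed to converge; see diagnostics with deSolve::diagnostics().")
  }
  out <- as.data.frame(out)

  # concentrations per reported compartment
  prof <- list(
    tibble(time = out$time, compartment = "arterial",
           conc_ug_ml = out$arterial / cmp$v_art, amount_mg = out$arterial),
    tibble(time = out$time, compartment = "venous",
           conc_ug_ml = out$venous / cmp$v_ven, amount_mg = out$venous),
    tibble(time = out$time, compartment = "lung",
           conc_ug_ml = out$lung / cmp$v_lung, amount_mg = out$lung)
  )
  for (t_name in cmp$tissues) {
    ti <- cmp$tinfo[[t_name]]
    if (ti$kind == "flow") {
      amt <- out[[t_name]]
      prof[[length(prof) + 1]] <- tibble(
        time = out$time, compartment = t_name,
        conc_ug_ml = amt / ti$v, amount_mg = amt)
    } else {
      a_vas <- out[[paste0(t_name, "_vas")]]
      a_tis <- out[[paste0(t_name, "_tis")]]
      prof[[length(prof) + 1]] <- tibble(
        time = out$time, compartment = t_name,
        conc_ug_ml = (a_vas + a_tis) / (ti$v_vas + ti$v_tis),
        amount_mg = a_vas + a_tis)
      prof[[length(prof) + 1]] <- tibble(
        time = out$time, compartment = paste0(t_name, "_vascular"),
        conc_ug_ml = a_vas / ti$v_vas, amount_mg = a_vas)
      prof[[length(prof) + 1]] <- tibble(
        time = out$time, compartment = paste0(t_name, "_tissue"),
        conc_ug_ml = a_tis / ti$v_tis, amount_mg = a_tis)
    }
  }
  profile <- dplyr::bind_rows(prof)

  body_cols <- setdiff(cmp$state_names, c("eliminated", "unabsorbed"))
  in_body <- rowSums(out[, body_cols, drop = FALSE])
  # A bolus/oral event at time t is visible in output rows strictly after t
  # (the row at t itself records the pre-event state), hence the strict
  # inequality.
  administered <- vapply(out$time, function(t) {
    bol <- if (regimen$route != "iv_infusion") {
      sum(dose_mg * (dose_times < t - 1e-9))
    } else 0
    inf <- if (nrow(infusions)) {
      sum(infusions$rate * pmax(0, pmin(t, infusions$end) - infusions$start))
    } else 0
    bol + inf
  }, numeric(1))
  balance <- tibble(
    time = out$time, administered_mg = administered, in_body_mg = in_body,
    eliminated_mg = out$eliminated, unabsorbed_mg = out$unabsorbed,
    rel_error = ifelse(administered > 0,
                       (administered - in_body - out$eliminated - out$unabsorbed) /
                         administered, 0)
  )

  structure(
    list(profile = profile, balance = balance, model = model,
         regimen = regimen, dose_mg = dose_mg, times = out$time),
    class = "qivive_pbk_sim"
  )
}

#' Exposure metrics from a simulated profile
#'
#' AUC by the trapezoidal rule on the output grid, plus Cmax and Tmax from
#' the grid maximum, for one compartment over a time window.
#'
#' @param sim A [simulate_pbk()] result.
#' @param compartment Compartment name (default `"venous"`).
#' @param window `c(t0, t1)` in h; must lie within the simulated span.
#' @return A one-row tibble: compartment, t0, t1, auc_ug_h_ml, cmax_ug_ml,
#'   tmax_h.
#' @export
compute_metrics <- function(sim, compartment = "venous", window = NULL) {
  stopifnot(inherits(sim, "qivive_pbk_sim"))
  prof <- dplyr::filter(sim$profile, .data$compartment == !!compartment)
  if (!nrow(prof)) {
    abort(sprintf("Compartment '%s' not present in the simulation.", compartment))
  }
  span <- range(prof$time)
  if (is.null(window)) window <- span
  if (window[1] >= window[2]) abort("Empty metrics window.")
  if (window[1] < span[1] - 1e-9 || window[2] > span[2] + 1e-9) {
    abort("Metrics window lies outside the simulated span.")
  }
  keep <- prof$time >= window[1] - 1e-12 & prof$time <= window[2] + 1e-12
  tt <- prof$time[keep]
  cc <- prof$conc_ug_ml[keep]
  tibble(
    compartment = compartment, t0 = window[1], t1 = window[2],
    auc_ug_h_ml = trapz(tt, cc),
    cmax_ug_ml = max(cc), tmax_h = tt[which.max(cc)]
  )
}
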