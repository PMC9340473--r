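#' @export
print.qivive_pbk_sim <- function(x, ...) {
  cat(sprintf("<qivive_pbk_sim> %s, %s %g mg x %d, %g h\n",
              x$model$compound$name, x$regimen$route, x$dose_mg,
              x$regimen$n_doses, max(x$times)))
  worst <- max(abs(x$balance$rel_error))
  cat(sprintf("  %d output times, %d compartments, mass-balance |rel err| <= %.2g\n",
              length(x$times), dplyr::n_distinct(x$profile$compartment), worst))
  invisible(x)
}

#' Tidy a PBK simulation into its concentration-time table
#'
#' @param x A [simulate_pbk()] result.
#' @param ... Unused.
#' @return Tibble with columns time, compartment, conc_ug_ml, amount_mg.
#' @export
tidy.qivive_pbk_sim <- function(x, ...) x$profile

#' One-row-per-compartment exposure summary of a PBK simulation
#'
#' @param x A [simulate_pbk()] result.
#' @param ... Unused.
#' @return Tibble with auc_ug_h_ml, cmax_ug_ml, tmax_h per compartment over
#'   the full simulated span.
#' @export
glance.qivive_pbk_sim <- function(x, ...) {
  comps <- unique(x$profile$compartment)
  dplyr::bind_rows(purrr::map(comps, function(cp) compute_metrics(x, cp)))
}

#' Plot simulated concentration-time profiles
#'
#' @param object A [simulate_pbk()] result.
#' @param compartments Compartments to show (default: venous and liver).
#' @param log_y Log-scale the concentration axis (default TRUE).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qivive_pbk_sim <- function(object, compartments = c("venous", "liver"),
                                    log_y = TRUE, ...) {
  dat <- dplyr::filter(object$profile, .data$compartment %in% compartments)
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$time, .data$conc_ug_ml,
                                         colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "concentration (µg/mL)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Write a simulated profile as a tidy delimited table
#'
#' @param sim A [simulate_pbk()] result.
#' @param path Output file path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_simulation <- function(sim, path) {
  stopifnot(inherits(sim, "qivive_pbk_sim"))
  prof <- sim$profile
  prof$units <- "ug_per_ml"
  write.table(prof, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
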