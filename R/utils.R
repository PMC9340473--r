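# Internal validation helpers. All user-facing errors funnel through these so
# messages carry the offending argument name.

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          allow_na = FALSE, strict_lower = FALSE) {
  if (allow_na && (is.null(x) || (length(x) == 1 && is.na(x)))) {
    return(invisible(x))
  }
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  if (strict_lower) {
    if (x <= lower) {
      abort(sprintf("`%s` must be > %g (got %g).", name, lower, x))
    }
  } else if (x < lower) {
    abort(sprintf("`%s` must be >= %g (got %g).", name, lower, x))
  }
  if (x > upper) {
    abort(sprintf("`%s` must be <= %g (got %g).", name, upper, x))
  }
  invisible(x)
}

assert_numeric_vec <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) == 0 || anyNA(x)) {
    abort(sprintf("`%s` must be a non-empty numeric vector without NAs.", name))
  }
  if (any(x < lower)) {
    abort(sprintf("`%s` must be >= %g throughout.", name, lower))
  }
  invisible(x)
}

assert_choice <- function(x, name, choices) {
  if (!is.character(x) || length(x) != 1 || !x %in% choices) {
    abort(sprintf("`%s` must be one of: %s.", name,
                  paste(choices, collapse = ", ")))
  }
  invisible(x)
}

# Trapezoidal integral on an (unevenly spaced) grid.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}
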