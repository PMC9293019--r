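# Pseudo-first-order rate extraction from internal-referenced 19F NMR
# integral time courses. Under a large excess of the nucleophile the
# electrophile decays as d[E]/dt = -k_obs [E]; for each fluorine signal i the
# log-ratio transform y_i(t) = ln(I_t^i / I_t^ref) - ln(I_0^i / I_0^ref)
# is linear in t with slope -k_obs, and the per-signal slopes are averaged.

#' Construct a kinetic trace from a data frame
#'
#' @param data Data frame with a `time_s` column (seconds, strictly
#'   increasing, first row is t0), one column per signal and one column for
#'   the internal-reference integral.
#' @param signals Character vector of signal column names (e.g.
#'   `c("Fo", "Fm", "Fp")` for the ortho/meta/para fluorines).
#' @param reference Name of the internal-reference column (default "TFA").
#' @return An object of class `kinetic_trace` (a validated tibble).
#' @export
kinetic_trace <- function(data, signals, reference = "TFA") {
  df <- as_tibble(data)
  needed <- c("time_s", signals, reference)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    abort(paste0("trace is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "enaminekin_parse_error")
  }
  df <- df[, needed]
  for (cl in needed) {
    if (!is.numeric(df[[cl]]) || any(!is.finite(df[[cl]]))) {
      abort(paste0("column '", cl, "' must be finite numeric."),
            class = "enaminekin_parse_error")
    }
  }
  if (nrow(df) < 2L) {
    abort("a kinetic trace needs at least 2 time points.",
          class = "enaminekin_invalid_data")
  }
  if (any(diff(df$time_s) <= 0)) {
    abort("time_s must be strictly increasing.",
          class = "enaminekin_invalid_data")
  }
  for (cl in c(signals, reference)) {
    bad <- which(df[[cl]] <= 0)
    if (length(bad) > 0L) {
      abort(paste0("non-positive integral in column '", cl, "' at row(s) ",
                   paste(bad, collapse = ", "), "."),
            class = "enaminekin_invalid_data")
    }
  }
  structure(df, class = c("kinetic_trace", class(df)),
            signals = signals, reference = reference)
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat("<kinetic_trace> ", nrow(x), " points over ",
      max(x$time_s) - min(x$time_s), " s; signals: ",
      paste(attr(x, "signals"), collapse = ", "),
      "; reference: ", attr(x, "reference"), "\n", sep = "")
  NextMethod()
}

#' Log-ratio transform of one signal of a kinetic trace
#'
#' Computes y(t) = ln(I_t / I_t_ref) - ln(I_0 / I_0_ref), which is zero at t0
#' by construction and equals -k_obs t for a clean exponential decay against
#' a stable internal reference.
#'
#' @param trace A [kinetic_trace()].
#' @param signal Name of the signal to transform.
#' @return A tibble with columns `time_s`, `y`.
#' @export
log_ratio_transform <- function(trace, signal) {
  stopifnot(inherits(trace, "kinetic_trace"))
  sigs <- attr(trace, "signals")
  if (!signal %in% sigs) {
    abort(paste0("unknown signal '", signal, "'; trace has: ",
                 paste(sigs, collapse = ", ")),
          class = "enaminekin_invalid_data")
  }
  ref <- trace[[attr(trace, "reference")]]
  r <- trace[[signal]] / ref
  tibble(time_s = trace$time_s, y = log(r) - log(r[1]))
}

#' Fit the observed pseudo-first-order rate constant
#'
#' Regresses the log-ratio transform of every signal against time by
#' ordinary least squares and averages the per-signal slopes:
#' k_obs = -mean(slopes). The reported uncertainty is the cross-signal
#' standard deviation of the per-signal constants (the regression slope
#' standard error for a single-signal trace).
#'
#' @param trace A [kinetic_trace()] with at least 3 time points.
#' @param intercept "free" (default; robust to an error in the t0 integrals)
#'   or "anchored" (regression through the origin, as the transform itself
#'   anchors y(t0) = 0).
#' @param reference_floor Points whose reference integral falls below this
#'   fraction of the maximum reference integral are excluded (default 1e-6).
#' @return An object of class `kobs_fit` with elements `k_obs` (s^-1),
#'   `per_signal_k`, `stderr`, `r_squared`, `n_points`, `intercept`.
#' @export
fit_kobs <- function(trace, intercept = c("free", "anchored"),
                     reference_floor = 1e-6) {
  stopifnot(inherits(trace, "kinetic_trace"))
  intercept <- match.arg(intercept)
  ref <- trace[[attr(trace, "reference")]]
  keep <- ref >= reference_floor * max(ref)
  if (!all(keep)) {
    warn(paste0("excluding ", sum(!keep),
                " point(s) with reference integral below the floor."))
    trace <- kinetic_trace(trace[keep, ], attr(trace, "signals"),
                           attr(trace, "reference"))
  }
  if (nrow(trace) < 3L) {
    abort("at least 3 usable time points are required to fit k_obs.",
          class = "enaminekin_insufficient_data")
  }
  sigs <- attr(trace, "signals")
  fits <- lapply(sigs, function(s) {
    d <- log_ratio_transform(trace, s)
    fit <- if (intercept == "free") lm(y ~ time_s, data = d)
           else lm(y ~ 0 + time_s, data = d)
    slope <- coef(fit)[["time_s"]]
    # summary.lm warns on a noiseless (perfect) fit; the values are still valid
    sm <- suppressWarnings(summary(fit))
    list(k = -slope,
         se = sm$coefficients["time_s", "Std. Error"],
         r2 = sm$r.squared)
  })
  per_k <- setNames(vapply(fits, `[[`, numeric(1), "k"), sigs)
  if (any(per_k < 0)) {
    warn(paste0("negative fitted rate constant for signal(s): ",
                paste(sigs[per_k < 0], collapse = ", ")))
  }
  k_obs <- mean(per_k)
  stderr <- if (length(per_k) >= 2L) stats::sd(per_k) else fits[[1]]$se
  structure(
    list(k_obs = k_obs, per_signal_k = per_k, stderr = stderr,
         r_squared = setNames(vapply(fits, `[[`, numeric(1), "r2"), sigs),
         n_points = nrow(trace), intercept = intercept),
    class = "kobs_fit"
  )
}

#' @export
print.kobs_fit <- function(x, ...) {
  # report in the conventional 1e-4 s^-1 units of kinetics tables
  cat(sprintf("k_obs = %.2f (+/- %.2f) x 10^-4 s^-1  [%d signals, %d points, %s intercept]\n",
              1e4 * x$k_obs, 1e4 * x$stderr, length(x$per_signal_k),
              x$n_points, x$intercept))
  for (s in names(x$per_signal_k)) {
    cat(sprintf("  %-4s k = %.3e s^-1  (R^2 = %.5f)\n",
                s, x$per_signal_k[[s]], x$r_squared[[s]]))
  }
  invisible(x)
}

#' @describeIn fit_kobs Per-signal estimates as a tibble.
#' @param x A `kobs_fit`.
#' @param ... Unused.
#' @method tidy kobs_fit
#' @export
tidy.kobs_fit <- function(x, ...) {
  tibble(signal = names(x$per_signal_k),
         k = unname(x$per_signal_k),
         r_squared = unname(x$r_squared[names(x$per_signal_k)]))
}

#' @describeIn fit_kobs One-row fit summary.
#' @method glance kobs_fit
#' @export
glance.kobs_fit <- function(x, ...) {
  tibble(k_obs = x$k_obs, stderr = x$stderr,
         n_signals = length(x$per_signal_k), n_points = x$n_points,
         intercept = x$intercept)
}
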