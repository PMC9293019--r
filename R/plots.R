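# ggplot2 views of the main result types.

#' @method autoplot kin_trajectory
#' @export
autoplot.kin_trajectory <- function(object, species = NULL, log_time = TRUE,
                                    ...) {
  d <- tidy(object)
  if (!is.null(species)) d <- d[d$species %in% species, ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$conc_M,
                                       colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "concentration (M)")
  if (log_time) p <- p + ggplot2::scale_x_log10()
  p
}

#' @method autoplot kinetic_trace
#' @export
autoplot.kinetic_trace <- function(object, ...) {
  sigs <- c(attr(object, "signals"), attr(object, "reference"))
  d <- tidyr::pivot_longer(as_tibble(object), dplyr::all_of(sigs),
                           names_to = "signal", values_to = "integral")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$integral,
                                  colour = .data$signal)) +
    ggplot2::geom_point() + ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "time (s)", y = "integral (a.u.)")
}

#' @method autoplot selectivity_result
#' @export
autoplot.selectivity_result <- function(object, ...) {
  d <- tidy(object)
  d$channel <- paste(d$cycle, d$product_config, d$conformer)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$channel, y = .data$yield,
                                  fill = .data$diastereo_class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "product yield (M)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Log-ratio plot of a kinetic trace with fitted slopes
#'
#' The linearised view used for pseudo-first-order fitting: the log-ratio
#' transform of every signal against time, with the per-signal least-squares
#' lines.
#'
#' @param trace A [kinetic_trace()].
#' @param fit Optional [fit_kobs()] result; computed when missing.
#' @return A ggplot object.
#' @export
plot_log_ratio <- function(trace, fit = NULL) {
  stopifnot(inherits(trace, "kinetic_trace"))
  sigs <- attr(trace, "signals")
  d <- purrr::map_dfr(sigs, function(s) {
    out <- log_ratio_transform(trace, s)
    out$signal <- s
    out
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$y,
                                  colour = .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::labs(x = "time (s)",
                  y = "ln(I/I_ref) - ln(I0/I0_ref)")
}

#' Conformer ensemble scatter plot
#'
#' Energy against the marker dihedral, coloured by the distal/proximal
#' classification.
#'
#' @param ensemble Data frame with `omega` and `energy` columns.
#' @return A ggplot object.
#' @export
plot_conformer_ensemble <- function(ensemble) {
  d <- as_tibble(ensemble)
  d$conformer <- classify_conformer(d$omega)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$omega, y = .data$energy,
                                  colour = .data$conformer)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = 90, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "|omega| (deg)", y = "relative energy (kcal/mol)")
}
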