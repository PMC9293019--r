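# Mass-action ODE assembly, stiff integration and selectivity analysis
# (diastereomeric ratio, enantiomeric excess, per-cycle flux partition).

#' Assemble the mass-action rate function of a network
#'
#' Builds the right-hand side d\[conc\]/dt = S (rate_fwd - rate_rev) with
#' elementary mass-action rates. The returned function is deterministic and
#' side-effect free, in the signature expected by [deSolve::ode()].
#'
#' @param net A validated `reaction_network`; refused if
#'   [validate_network()] fails.
#' @return A function `f(t, y, parms)` returning `list(dy)`.
#' @export
assemble_rate_function <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  diag <- validate_network(net)
  if (!diag$pass) {
    abort("network failed validation; run validate_network() for diagnostics.",
          class = "enaminekin_validation_error")
  }
  sp_names <- net$species$name
  n_sp <- length(sp_names)
  n_rx <- nrow(net$reactions)
  re_idx <- lapply(net$reactions$reactants, match, table = sp_names)
  pr_idx <- lapply(net$reactions$products, match, table = sp_names)
  k_f <- net$reactions$k_fwd
  k_r <- net$reactions$k_rev

  # stoichiometry matrix: species x reactions (net, forward direction)
  S <- matrix(0, n_sp, n_rx)
  for (j in seq_len(n_rx)) {
    for (i in re_idx[[j]]) S[i, j] <- S[i, j] - 1
    for (i in pr_idx[[j]]) S[i, j] <- S[i, j] + 1
  }

  function(t, y, parms) {
    v <- numeric(n_rx)
    for (j in seq_len(n_rx)) {
      v[j] <- k_f[j] * prod(y[re_idx[[j]]])
      if (k_r[j] > 0) v[j] <- v[j] - k_r[j] * prod(y[pr_idx[[j]]])
    }
    list(as.vector(S %*% v))
  }
}

#' Integrate a reaction network in time
#'
#' Stiff-capable integration of the mass-action ODEs with [deSolve::ode()]
#' (lsoda). The output grid is geometric (dense at early times, where the
#' fast lumped steps relax) plus t = 0.
#'
#' @param net A validated `reaction_network`.
#' @param t_end End time in seconds; must be finite and > 0.
#' @param n_steps Number of output points (default 400).
#' @param rtol,atol Relative/absolute integration tolerances
#'   (defaults 1e-8, 1e-12).
#' @param init Optional named replacement/override of initial concentrations.
#' @return An object of class `kin_trajectory` with fields `time` (s), `conc`
#'   (time x species matrix, M), `net` and `conservation` (relative drift of
#'   each material tag total).
#' @export
simulate_network <- function(net, t_end, n_steps = 400, rtol = 1e-8,
                             atol = 1e-12, init = NULL) {
  stopifnot(inherits(net, "reaction_network"))
  if (!is.numeric(t_end) || length(t_end) != 1L || !is.finite(t_end) ||
      t_end <= 0) {
    abort("`t_end` must be a single finite value > 0 (seconds).",
          class = "enaminekin_invalid_parameter")
  }
  y0 <- net$init
  if (!is.null(init)) {
    unknown <- setdiff(names(init), names(y0))
    if (length(unknown) > 0L) {
      abort(paste0("unknown species in `init`: ",
                   paste(unknown, collapse = ", ")),
            class = "enaminekin_invalid_parameter")
    }
    y0[names(init)] <- init
  }
  f <- assemble_rate_function(net)
  times <- c(0, exp(seq(log(t_end) - log(1e4), log(t_end),
                        length.out = n_steps)))
  sol <- deSolve::ode(y = y0, times = times, func = f, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    abort("ODE integration failed; last valid state attached.",
          class = "enaminekin_integrator_error",
          last_state = sol[nrow(sol), ])
  }
  conc <- unname(as.matrix(sol[, -1, drop = FALSE]))
  colnames(conc) <- names(y0)

  tags <- c("catalyst", "ketone", "electrophile", "acid_proton")
  tag_m <- as.matrix(net$species[, tags])
  totals <- conc %*% tag_m
  drift <- vapply(seq_along(tags), function(k) {
    tot0 <- totals[1, k]
    if (tot0 == 0) return(0)
    max(abs(totals[, k] - tot0)) / tot0
  }, numeric(1))
  names(drift) <- tags

  structure(
    list(time = sol[, 1], conc = conc, net = net, conservation = drift),
    class = "kin_trajectory"
  )
}

#' @export
print.kin_trajectory <- function(x, ...) {
  cat("<kin_trajectory> ", length(x$time), " time points to ",
      max(x$time), " s, ", ncol(x$conc), " species; max mass drift ",
      format(max(x$conservation), digits = 3), "\n", sep = "")
  invisible(x)
}

#' @describeIn simulate_network Tidy trajectory: one row per (time, species).
#' @param x A `kin_trajectory`.
#' @param ... Unused.
#' @method tidy kin_trajectory
#' @export
tidy.kin_trajectory <- function(x, ...) {
  out <- as_tibble(as.data.frame(x$conc))
  out$time_s <- x$time
  tidyr::pivot_longer(out, -"time_s", names_to = "species",
                      values_to = "conc_M")
}

.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

#' Selectivity outputs of a simulated trajectory
#'
#' Computes the per-channel product yields, the diastereomeric ratio (from
#' yields summed by diastereomer class), the enantiomeric excess of the major
#' diastereomer pair, ee = 100 (y(2R,1'S) - y(2S,1'R)) / (y(2R,1'S) +
#' y(2S,1'R)) (positive when (2R,1'S) is major), and the partition of flux
#' between catalytic cycles A and B. The cycle partition integrates each
#' channel's instantaneous C-C rate over the trajectory, so it remains
#' well-defined even when cycles share product states.
#'
#' @param traj A `kin_trajectory`.
#' @param net The network it came from; defaults to the one stored in `traj`.
#' @return An object of class `selectivity_result`.
#' @export
selectivity <- function(traj, net = traj$net) {
  stopifnot(inherits(traj, "kin_trajectory"),
            inherits(net, "reaction_network"))
  conc_end <- traj$conc[nrow(traj$conc), ]
  e0 <- net$init["E"]
  conversion <- 1 - conc_end["E"] / e0
  if (conversion < 0.99) {
    warn(sprintf("electrophile conversion is only %.1f%%; selectivity may not be terminal.",
                 100 * conversion))
  }

  ch <- net$channels
  ch$yield <- conc_end[ch$product_species]
  # channel flux: integral of k_cc * [RC] over the trajectory
  ch$flux <- vapply(seq_len(nrow(ch)), function(i) {
    rc_sp <- paste0("RC_", ch$cycle[i], "_", ch$conformer[i])
    .trapz(traj$time, ch$k_cc[i] * traj$conc[, rc_sp])
  }, numeric(1))

  total <- sum(ch$yield)
  if (total <= 0) {
    abort("no product was formed; selectivity is undefined.",
          class = "enaminekin_undefined_selectivity")
  }

  dr <- dplyr::summarise(dplyr::group_by(ch, .data$diastereo_class),
                         yield = sum(.data$yield), .groups = "drop")
  dr$pct <- 100 * dr$yield / sum(dr$yield)
  # conventional ordering: major-class-first label per reaction type
  first <- if (net$reaction_type == "aldol") "anti" else "syn"
  dr <- dr[order(dr$diastereo_class != first), ]

  y_cfg <- function(cfg) sum(ch$yield[ch$product_config == cfg])
  pair <- y_cfg("RS") + y_cfg("SR")
  ee <- if (pair > 0) 100 * (y_cfg("RS") - y_cfg("SR")) / pair else NA_real_

  part <- dplyr::summarise(dplyr::group_by(ch, .data$cycle),
                           flux = sum(.data$flux), .groups = "drop")
  part$pct <- 100 * part$flux / sum(part$flux)

  structure(
    list(channel_yields = ch, dr = dr, ee = ee, cycle_partition = part,
         conversion = unname(conversion), reaction_type = net$reaction_type),
    class = "selectivity_result"
  )
}

#' @export
print.selectivity_result <- function(x, ...) {
  cat(report_selectivity(x), sep = "\n")
  invisible(x)
}

#' @describeIn selectivity Per-channel yields and fluxes as a tibble.
#' @param x A `selectivity_result`.
#' @param ... Unused.
#' @method tidy selectivity_result
#' @export
tidy.selectivity_result <- function(x, ...) {
  x$channel_yields[, c("ts_name", "cycle", "conformer", "product_config",
                       "diastereo_class", "yield", "flux")]
}

#' @describeIn selectivity One-row summary (dr, ee, cycle partition,
#'   conversion).
#' @method glance selectivity_result
#' @export
glance.selectivity_result <- function(x, ...) {
  dr <- setNames(x$dr$pct, paste0(x$dr$diastereo_class, "_pct"))
  part <- setNames(x$cycle_partition$pct,
                   paste0("cycle_", x$cycle_partition$cycle, "_pct"))
  dplyr::bind_cols(
    tibble(reaction_type = x$reaction_type),
    as_tibble(as.list(dr)), tibble(ee = x$ee),
    as_tibble(as.list(part)), tibble(conversion = x$conversion)
  )
}
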