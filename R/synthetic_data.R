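# Generators for all test inputs: noisy internal-referenced NMR traces,
# free-energy landscapes with the dual-cycle topology, and conformer
# ensembles. All generators are pure functions of (spec, seed).

.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Specification of a synthetic kinetic trace
#'
#' Emulates the decay of the fluorine integrals of the electrophile against a
#' stable internal-reference signal: I_t^i / I_t^ref =
#' (I_0^i / I_0^ref) exp(-k_true t), with multiplicative lognormal noise on
#' every integral (NMR integral error scales with the signal) or optional
#' additive noise.
#'
#' @param k_true True decay constant (s^-1).
#' @param times Sampling grid (s), strictly increasing; default 12 points
#'   over 3000 s, the hour-scale of the aldol runs.
#' @param signals Signal names; default the ortho/meta/para fluorines.
#' @param signal_levels Initial integrals per signal; default 2:2:1,
#'   the fluorine multiplicities of a pentafluorophenyl group.
#' @param reference_level Internal-reference integral level (default 1).
#' @param noise_sd Relative noise (sdlog of the lognormal factor, or the sd
#'   of the additive term as a fraction of each level). Default 0.02.
#' @param noise_model "multiplicative" (default) or "additive".
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return A list of class `trace_spec`.
#' @export
trace_spec <- function(k_true, times = seq(0, 3000, length.out = 12),
                       signals = c("Fo", "Fm", "Fp"),
                       signal_levels = NULL, reference_level = 1,
                       noise_sd = 0.02,
                       noise_model = c("multiplicative", "additive"),
                       seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(is.numeric(k_true), length(k_true) == 1L, is.finite(k_true),
            k_true >= 0, noise_sd >= 0, length(times) >= 2L,
            all(diff(times) > 0))
  if (is.null(signal_levels)) {
    signal_levels <- setNames(rep(c(2, 1), length.out = length(signals)),
                              signals)
    if (identical(signals, c("Fo", "Fm", "Fp"))) {
      signal_levels <- c(Fo = 2, Fm = 2, Fp = 1)
    }
  }
  structure(list(k_true = k_true, times = times, signals = signals,
                 signal_levels = signal_levels,
                 reference_level = reference_level, noise_sd = noise_sd,
                 noise_model = noise_model, seed = seed),
            class = "trace_spec")
}

#' Generate a synthetic kinetic trace
#'
#' @param spec A [trace_spec()].
#' @return A [kinetic_trace()]; with `noise_sd = 0` the exact exponential.
#' @export
generate_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_spec"))
  n <- length(spec$times)
  .with_seed(spec$seed, {
    noisy <- function(level) {
      if (spec$noise_sd == 0) return(level)
      if (spec$noise_model == "multiplicative") {
        level * exp(rnorm(length(level), 0, spec$noise_sd))
      } else {
        pmax(level + rnorm(length(level), 0, spec$noise_sd * max(level)),
             .Machine$double.eps)
      }
    }
    df <- tibble(time_s = spec$times)
    decay <- exp(-spec$k_true * spec$times)
    for (s in spec$signals) {
      df[[s]] <- noisy(spec$signal_levels[[s]] * decay)
    }
    df$TFA <- noisy(rep(spec$reference_level, n))
    kinetic_trace(df, signals = spec$signals, reference = "TFA")
  })
}

#' Specification of a synthetic free-energy landscape
#'
#' Parameterizes landscapes with the dual-cycle topology: enamine
#' intermediates and reactive complexes per (cycle, conformer) and one C-C
#' transition state per stereochannel, all as Gibbs energies relative to a
#' single zero-reference intermediate.
#'
#' @param reaction_type "aldol" or "michael".
#' @param intermediates Tibble `cycle`, `conformer`, `g_rel` for the enamine
#'   intermediates (exactly one row must have `g_rel == 0`).
#' @param complexes Tibble `cycle`, `conformer`, `g_rel` for the reactive
#'   complexes.
#' @param channels Tibble `cycle`, `conformer`, `product_config`, `g_ts`
#'   (absolute TS energy on the landscape scale, kcal/mol).
#' @param temperature Kelvin.
#' @param jitter_sd Optional Gaussian jitter (kcal/mol) applied to TS
#'   energies, for robustness experiments. Default 0.
#' @param seed Seed for the jitter.
#' @return A list of class `landscape_spec`.
#' @export
landscape_spec <- function(reaction_type, intermediates, complexes, channels,
                           temperature = 298.15, jitter_sd = 0, seed = 1L) {
  structure(list(reaction_type = reaction_type,
                 intermediates = as_tibble(intermediates),
                 complexes = as_tibble(complexes),
                 channels = as_tibble(channels),
                 temperature = temperature, jitter_sd = jitter_sd,
                 seed = seed),
            class = "landscape_spec")
}

#' Built-in landscape specifications
#'
#' Three presets with the topology of the dual-cycle mechanism:
#'
#' * `"two-channel"`: a single cycle with one enamine, one reactive complex
#'   and two C-C channels separated by `ddg` kcal/mol; the minimal
#'   Curtin-Hammett benchmark. The default `ddg = 1.447` corresponds to a
#'   92:8 product ratio at 298.15 K.
#' * `"dual-cycle-aldol"`: two cycles x two conformers x four stereochannels
#'   per cycle, with transition-state energies chosen so that the
#'   fast-pre-equilibrium limit gives an anti:syn ratio of 92:8, an ee of
#'   +85% on the anti pair and an A:B flux partition of 58:42 - the headline
#'   selectivity of the aldol system. The energies themselves are synthetic
#'   stand-ins (no quantum-chemical data ships with the package).
#' * `"dual-cycle-michael"`: the conjugate-addition analogue targeting
#'   syn:anti 90:10, ee +87% and a strongly A-dominated partition (85:15),
#'   with the cycle-B reactive complex 7 kcal/mol above its A analogue.
#'
#' @param name Preset name.
#' @param ddg Barrier difference (kcal/mol) for the two-channel preset.
#' @param base_g_ts Energy of the most stable transition state (kcal/mol);
#'   defaults pick C-C rates well below the lumped-step scale.
#' @param jitter_sd,seed Passed to [landscape_spec()].
#' @return A `landscape_spec`.
#' @export
landscape_preset <- function(name = c("two-channel", "dual-cycle-aldol",
                                      "dual-cycle-michael"),
                             ddg = 1.447, base_g_ts = NULL,
                             jitter_sd = 0, seed = 1L) {
  name <- match.arg(name)
  RT <- .R_kcal * 298.15
  ts_from_weights <- function(df, base) {
    df$g_ts <- base + RT * log(max(df$weight) / df$weight)
    df$weight <- NULL
    df
  }
  if (name == "two-channel") {
    base <- base_g_ts %||% 19
    spec <- landscape_spec(
      "aldol",
      intermediates = tibble(cycle = "A", conformer = NA_character_,
                             g_rel = 0),
      complexes = tibble(cycle = "A", conformer = NA_character_, g_rel = 1),
      channels = tibble(cycle = "A", conformer = NA_character_,
                        product_config = c("RS", "RR"),
                        g_ts = c(base, base + ddg)),
      jitter_sd = jitter_sd, seed = seed)
  } else if (name == "dual-cycle-aldol") {
    base <- base_g_ts %||% 18
    # channel weights realizing anti:syn 92:8, ee(anti) +85, A:B 58:42
    ch <- tibble(
      cycle = rep(c("A", "B"), each = 4),
      conformer = rep(c("proximal", "distal"), each = 4),
      product_config = rep(c("RS", "SR", "RR", "SS"), 2),
      weight = c(0.58 * c(0.851, 0.069, 0.060, 0.020),
                 0.42 * c(0.851, 0.069, 0.060, 0.020)))
    spec <- landscape_spec(
      "aldol",
      intermediates = tibble(
        cycle = c("A", "A", "B", "B"),
        conformer = c("distal", "proximal", "distal", "proximal"),
        g_rel = c(0, 0.3, -0.5, 0.2)),
      complexes = tibble(cycle = c("A", "B"),
                         conformer = c("proximal", "distal"),
                         g_rel = c(1.0, 1.5)),
      channels = ts_from_weights(ch, base),
      jitter_sd = jitter_sd, seed = seed)
  } else {
    base <- base_g_ts %||% 21
    # weights realizing syn:anti 90:10, ee(syn) +87, A:B 85:15
    ch <- tibble(
      cycle = rep(c("A", "B"), each = 4),
      conformer = rep(c("proximal", "distal"), each = 4),
      product_config = rep(c("RS", "SR", "RR", "SS"), 2),
      weight = c(0.85 * c(0.8415, 0.0585, 0.070, 0.030),
                 0.15 * c(0.8415, 0.0585, 0.070, 0.030)))
    spec <- landscape_spec(
      "michael",
      intermediates = tibble(
        cycle = c("A", "A", "B", "B"),
        conformer = c("distal", "proximal", "distal", "proximal"),
        g_rel = c(0, 0.3, -0.5, 0.2)),
      complexes = tibble(cycle = c("A", "B"),
                         conformer = c("proximal", "distal"),
                         g_rel = c(1.0, 8.0)),
      channels = ts_from_weights(ch, base),
      jitter_sd = jitter_sd, seed = seed)
  }
  spec
}

#' Generate a free-energy landscape from a specification
#'
#' @param spec A [landscape_spec()], e.g. from [landscape_preset()].
#' @return A [landscape()] that passes network construction unchanged.
#' @export
generate_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  ch <- spec$channels
  if (spec$jitter_sd > 0) {
    ch$g_ts <- .with_seed(spec$seed,
                          ch$g_ts + rnorm(nrow(ch), 0, spec$jitter_sd))
  }
  rc_key <- paste(spec$complexes$cycle, .conf_key(spec$complexes$conformer))
  g_rc <- spec$complexes$g_rel[match(paste(ch$cycle, .conf_key(ch$conformer)),
                                     rc_key)]
  if (any(is.na(g_rc))) {
    abort("every channel needs a reactive complex in its cycle/conformer.",
          class = "enaminekin_spec_error")
  }
  if (any(ch$g_ts < g_rc)) {
    abort("negative activation barrier: a TS lies below its reactive complex.",
          class = "enaminekin_spec_error")
  }
  cyc_tag <- c(A = "a", B = "b")
  int_no <- if (spec$reaction_type == "aldol") "1" else "1"
  ts_no <- if (spec$reaction_type == "aldol") "1" else "2"
  ints <- spec$intermediates
  rcs <- spec$complexes
  pts <- dplyr::bind_rows(
    tibble(name = paste0("INT", int_no, cyc_tag[ints$cycle],
                         ifelse(is.na(ints$conformer), "",
                                paste0("_", ints$conformer))),
           role = "intermediate", cycle = ints$cycle,
           conformer = ints$conformer, g_rel = ints$g_rel,
           product_config = NA_character_),
    tibble(name = paste0("RC", cyc_tag[rcs$cycle],
                         ifelse(is.na(rcs$conformer), "",
                                paste0("_", rcs$conformer))),
           role = "reactive_complex", cycle = rcs$cycle,
           conformer = rcs$conformer, g_rel = rcs$g_rel,
           product_config = NA_character_),
    tibble(name = paste0("TS", ts_no, cyc_tag[ch$cycle], "_",
                         ch$product_config,
                         ifelse(is.na(ch$conformer), "",
                                paste0("_", ch$conformer))),
           role = "transition_state", cycle = ch$cycle,
           conformer = ch$conformer, g_rel = ch$g_ts,
           product_config = ch$product_config)
  )
  landscape(pts, spec$reaction_type, spec$temperature)
}

#' Generate a synthetic conformer ensemble
#'
#' Samples an ensemble of enamine conformations in two clusters of the
#' marker dihedral - distal near |omega| = 180 deg and proximal near 0 deg -
#' with a designed energy offset between the clusters, emulating a
#' force-field Monte-Carlo conformational search.
#'
#' @param n Number of conformers (>= 1).
#' @param gap Energy offset (kcal/mol) of the disfavoured cluster.
#' @param widths Within-cluster energy spread (kcal/mol), recycled to length
#'   2 (distal, proximal). Equal widths leave the designed Boltzmann split
#'   intact in expectation.
#' @param seed Integer seed.
#' @param favour Which cluster sits at the lower base energy ("distal" or
#'   "proximal").
#' @param omega_sd Angular spread of each cluster (degrees).
#' @return A tibble with columns `omega` (deg, in \[0, 180\]) and `energy`
#'   (kcal/mol, minimum 0).
#' @export
generate_conformer_ensemble <- function(n, gap = 0.41, widths = c(0.3, 0.3),
                                        seed = 1L,
                                        favour = c("distal", "proximal"),
                                        omega_sd = 15) {
  favour <- match.arg(favour)
  stopifnot(n >= 1, gap >= 0, all(widths >= 0))
  widths <- rep(widths, length.out = 2)
  .with_seed(seed, {
    is_distal <- stats::runif(n) < 0.5
    omega <- ifelse(is_distal,
                    180 - abs(rnorm(n, 0, omega_sd)),
                    abs(rnorm(n, 0, omega_sd)))
    omega <- pmin(pmax(omega, 0), 180)
    base <- ifelse(is_distal == (favour == "distal"), 0, gap)
    width <- ifelse(is_distal, widths[1], widths[2])
    tibble(omega = omega, energy = base + width * abs(rnorm(n)))
  })
}
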