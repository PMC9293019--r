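# Shared fixtures, all built in code.

# Minimal single-cycle, single-TS landscape (linear 4-step network).
minimal_landscape <- function(g_ts = 19, g_rc = 1) {
  landscape(
    tibble::tibble(
      name = c("EN", "RC", "TS"),
      role = c("intermediate", "reactive_complex", "transition_state"),
      cycle = "A",
      conformer = NA_character_,
      product_config = c(NA, NA, "RS"),
      g_rel = c(0, g_rc, g_ts)),
    reaction_type = "aldol")
}

# Dual-cycle landscape with 2 conformers per cycle, 4 stereochannels in
# cycle A (on the proximal conformer) and 2 in cycle B (distal).
six_channel_landscape <- function() {
  pts <- dplyr::bind_rows(
    tibble::tibble(name = c("ENa_d", "ENa_p", "ENb_d", "ENb_p"),
                   role = "intermediate",
                   cycle = c("A", "A", "B", "B"),
                   conformer = c("distal", "proximal", "distal", "proximal"),
                   product_config = NA_character_,
                   g_rel = c(0, 0.3, -0.5, 0.2)),
    tibble::tibble(name = c("RCa_p", "RCb_d"),
                   role = "reactive_complex",
                   cycle = c("A", "B"),
                   conformer = c("proximal", "distal"),
                   product_config = NA_character_,
                   g_rel = c(1, 1.5)),
    tibble::tibble(name = paste0("TSa_", c("RS", "SR", "RR", "SS")),
                   role = "transition_state", cycle = "A",
                   conformer = "proximal",
                   product_config = c("RS", "SR", "RR", "SS"),
                   g_rel = c(18, 19.5, 19.6, 20.2)),
    tibble::tibble(name = paste0("TSb_", c("RS", "SR")),
                   role = "transition_state", cycle = "B",
                   conformer = "distal",
                   product_config = c("RS", "SR"),
                   g_rel = c(18.2, 19.7)))
  landscape(pts, "aldol")
}

# Hand-built network for rate-function unit tests. `reactions` is a list of
# lists with fields reactants, products, k_fwd, k_rev.
toy_network <- function(species, reactions, init,
                        roles = NULL, catalyst = NULL,
                        reaction_type = "aldol") {
  roles <- roles %||% rlang::rep_named(species, "intermediate")
  catalyst <- catalyst %||% rlang::rep_named(species, 0)
  sp <- tibble::tibble(name = species, role = unname(roles[species]),
                       catalyst = unname(catalyst[species]), ketone = 0,
                       electrophile = 0, acid_proton = 0, product = 0)
  rx <- purrr::imap_dfr(reactions, function(r, i) {
    tibble::tibble(id = i, step = "toy",
                   reactants = list(r$reactants), products = list(r$products),
                   k_fwd = r$k_fwd, k_rev = r$k_rev %||% 0,
                   cycle = NA_character_, conformer = NA_character_,
                   product_config = NA_character_,
                   diastereo_class = NA_character_, ts_name = NA_character_)
  })
  structure(
    list(species = sp, reactions = rx,
         channels = tibble::tibble(), init = init,
         reaction_type = reaction_type, temperature = 298.15,
         options = network_options()),
    class = "reaction_network")
}

`%||%` <- rlang::`%||%`

expect_equal_rel <- function(object, expected, tol) {
  expect_lt(abs(object / expected - 1), tol)
}
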