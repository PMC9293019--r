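# Construction of mass-action reaction networks for the dual-cycle
# catalytic mechanism: acid partition between the two pyrrolidine sites,
# enamine formation per conformer, electrophile binding, irreversible C-C
# bond formation per stereochannel, and hydrolytic catalyst release.

#' Options controlling network construction
#'
#' Steps not resolved on the DFT landscape (protonation, enamine formation,
#' hydrolysis) are modelled as fast lumped steps; their defaults are large
#' relative to typical C-C rates so that selectivity is controlled by the
#' landscape (Curtin-Hammett regime). All reversible pre-C-C steps obey
#' detailed balance against the landscape energies, so relative pool
#' populations are thermodynamically consistent.
#'
#' @param k_lump First-order rate scale (s^-1) for lumped steps: effective
#'   enamine formation, acid protonation and hydrolysis. Default 1e3.
#' @param k_conf Base rate (s^-1) for distal/proximal enamine interconversion
#'   (downhill direction); lower it to approach the frozen-conformer limit.
#'   Default 1e4.
#' @param k_bind Bimolecular electrophile binding constant (M^-1 s^-1) for
#'   reactive-complex formation. Default 1e4.
#' @param protonation_bias Multiplier on the cycle-A protonation rate;
#'   1 means the two pyrrolidine units have identical basicity.
#' @param g_precursor Free energy (kcal/mol, landscape scale) assigned to the
#'   protonated catalyst + ketone state, fixing the absolute enamine-formation
#'   equilibrium; only shifts how much catalyst is enamine-bound, never the
#'   selectivity. Default 0.
#' @param electrophile_conc Initial electrophile concentration (M). Default 0.1.
#' @param nucleophile_equiv Ketone equivalents relative to electrophile;
#'   default 60 (aldol) or 8 (Michael) when NULL.
#' @param catalyst_equiv,acid_equiv Catalyst and acid loadings as equivalents
#'   of electrophile. Defaults 0.3 each.
#' @return A list of class `network_options`.
#' @export
network_options <- function(k_lump = 1e3, k_conf = 1e4, k_bind = 1e4,
                            protonation_bias = 1, g_precursor = 0,
                            electrophile_conc = 0.1,
                            nucleophile_equiv = NULL,
                            catalyst_equiv = 0.3, acid_equiv = 0.3) {
  stopifnot(k_lump > 0, k_conf > 0, k_bind > 0, protonation_bias > 0,
            electrophile_conc > 0, catalyst_equiv > 0, acid_equiv > 0)
  structure(list(k_lump = k_lump, k_conf = k_conf, k_bind = k_bind,
                 protonation_bias = protonation_bias,
                 g_precursor = g_precursor,
                 electrophile_conc = electrophile_conc,
                 nucleophile_equiv = nucleophile_equiv,
                 catalyst_equiv = catalyst_equiv, acid_equiv = acid_equiv),
            class = "network_options")
}

.conf_key <- function(conformer) ifelse(is.na(conformer), "nc", conformer)

#' Build the dual-cycle catalytic network from a free-energy landscape
#'
#' Translates a landscape into an executable mass-action network. Per cycle
#' present in the landscape the builder adds: acid protonation of the site
#' (only when both cycles are present, so the acid partitions between them),
#' reversible enamine formation per conformer, distal/proximal interconversion
#' when both conformers exist, reversible electrophile binding per reactive
#' complex, one irreversible C-C bond-forming step per transition state (rate
#' from [eyring_rate()] on the TS energy relative to its reactive complex) and
#' a hydrolytic product-release step regenerating the catalyst. Each
#' stereochannel gets its own iminium intermediate and product species, tagged
#' with the channel's cycle, conformer and product configuration.
#'
#' @param landscape A [landscape()] object.
#' @param options A [network_options()] list.
#' @return An object of class `reaction_network` with fields `species`
#'   (tibble with composition tags), `reactions` (tibble with list-columns of
#'   reactant/product names and rate constants), `channels` (one row per C-C
#'   channel), `init` (named initial concentrations, M), `reaction_type` and
#'   `temperature`.
#' @export
build_dual_cycle_network <- function(landscape, options = network_options()) {
  stopifnot(inherits(landscape, "fe_landscape"),
            inherits(options, "network_options"))
  pts <- landscape$points
  temp <- landscape$temperature
  RT <- .R_kcal * temp
  opt <- options
  if (is.null(opt$nucleophile_equiv)) {
    opt$nucleophile_equiv <- if (landscape$reaction_type == "aldol") 60 else 8
  }

  en <- pts[pts$role == "intermediate", ]
  rc <- pts[pts$role == "reactive_complex", ]
  ts <- pts[pts$role == "transition_state", ]
  en_key <- paste(en$cycle, .conf_key(en$conformer))
  rc_key <- paste(rc$cycle, .conf_key(rc$conformer))
  ts_key <- paste(ts$cycle, .conf_key(ts$conformer))
  if (anyDuplicated(en_key) || anyDuplicated(rc_key)) {
    abort("at most one intermediate and one reactive complex per (cycle, conformer).",
          class = "enaminekin_validation_error")
  }
  orphan_ts <- !(ts_key %in% rc_key)
  if (any(orphan_ts)) {
    abort(paste0("transition state(s) without a preceding reactive complex ",
                 "in the same cycle/conformer: ",
                 paste(ts$name[orphan_ts], collapse = ", ")),
          class = "enaminekin_malformed_landscape")
  }
  orphan_rc <- !(rc_key %in% en_key)
  if (any(orphan_rc)) {
    abort(paste0("reactive complex(es) without a preceding enamine ",
                 "intermediate: ", paste(rc$name[orphan_rc], collapse = ", ")),
          class = "enaminekin_malformed_landscape")
  }

  cycles <- sort(unique(en$cycle))
  multi <- length(cycles) > 1L
  im_prefix <- if (landscape$reaction_type == "aldol") "INT2" else "INT3"

  e0 <- opt$electrophile_conc
  ket0 <- opt$nucleophile_equiv * e0
  acid0 <- opt$acid_equiv * e0

  species <- list()
  add_sp <- function(name, role, catalyst = 0, ketone = 0, electrophile = 0,
                     acid_proton = 0, product = 0) {
    tibble(name = name, role = role, catalyst = catalyst, ketone = ketone,
           electrophile = electrophile, acid_proton = acid_proton,
           product = product)
  }
  species$cat <- add_sp("cat", "catalyst", catalyst = 1)
  species$ketone <- add_sp("ketone", "nucleophile", ketone = 1)
  species$E <- add_sp("E", "electrophile", electrophile = 1)
  if (multi) {
    species$acid <- add_sp("acid", "acid", acid_proton = 1)
    for (cy in cycles) {
      species[[paste0("catH_", cy)]] <-
        add_sp(paste0("catH_", cy), "protonated_catalyst",
               catalyst = 1, acid_proton = 1)
    }
  }
  h <- as.integer(multi) # acid proton carried through the cycle species

  reactions <- list()
  rid <- 0L
  add_rx <- function(step, reactants, products, k_fwd, k_rev = 0,
                     cycle = NA_character_, conformer = NA_character_,
                     product_config = NA_character_,
                     diastereo_class = NA_character_, ts_name = NA_character_) {
    rid <<- rid + 1L
    reactions[[rid]] <<- tibble(
      id = rid, step = step,
      reactants = list(reactants), products = list(products),
      k_fwd = k_fwd, k_rev = k_rev, cycle = cycle, conformer = conformer,
      product_config = product_config, diastereo_class = diastereo_class,
      ts_name = ts_name)
  }

  cat_sp <- function(cy) if (multi) paste0("catH_", cy) else "cat"
  if (multi) {
    for (cy in cycles) {
      bias <- if (cy == "A") opt$protonation_bias else 1
      add_rx("protonation", c("cat", "acid"), cat_sp(cy),
             k_fwd = bias * opt$k_lump / acid0, k_rev = opt$k_lump,
             cycle = cy)
    }
  }

  en_name <- function(cy, cf) paste0("EN_", cy, "_", cf)
  rc_name <- function(cy, cf) paste0("RC_", cy, "_", cf)
  g_of <- function(df, cy, cf) df$g_rel[paste(df$cycle, .conf_key(df$conformer)) == paste(cy, cf)]

  for (i in seq_len(nrow(en))) {
    cy <- en$cycle[i]; cf <- .conf_key(en$conformer[i])
    nm <- en_name(cy, cf)
    species[[nm]] <- add_sp(nm, "enamine", catalyst = 1, ketone = 1,
                            acid_proton = h)
    k_eq <- exp(-(en$g_rel[i] - opt$g_precursor) / RT) # M^-1, 1 M standard
    k_f <- opt$k_lump / ket0                           # effective k_lump at ket0
    add_rx("enamine_formation", c(cat_sp(cy), "ketone"), nm,
           k_fwd = k_f, k_rev = k_f * ket0 / k_eq,
           cycle = cy, conformer = cf)
  }

  for (cy in cycles) {
    here <- en[en$cycle == cy, ]
    cfs <- .conf_key(here$conformer)
    if (all(c("distal", "proximal") %in% cfs)) {
      gd <- g_of(en, cy, "distal"); gp <- g_of(en, cy, "proximal")
      add_rx("conformer_exchange", en_name(cy, "distal"), en_name(cy, "proximal"),
             k_fwd = opt$k_conf * exp(-max(0, gp - gd) / RT),
             k_rev = opt$k_conf * exp(-max(0, gd - gp) / RT),
             cycle = cy)
    }
  }

  for (i in seq_len(nrow(rc))) {
    cy <- rc$cycle[i]; cf <- .conf_key(rc$conformer[i])
    nm <- rc_name(cy, cf)
    species[[nm]] <- add_sp(nm, "reactive_complex", catalyst = 1, ketone = 1,
                            electrophile = 1, acid_proton = h)
    g_en <- g_of(en, cy, cf)
    k_eq <- exp(-(rc$g_rel[i] - g_en) / RT) # M^-1
    add_rx("complex_formation", c(en_name(cy, cf), "E"), nm,
           k_fwd = opt$k_bind, k_rev = opt$k_bind / k_eq,
           cycle = cy, conformer = cf)
  }

  channels <- list()
  for (i in seq_len(nrow(ts))) {
    cy <- ts$cycle[i]; cf <- .conf_key(ts$conformer[i])
    cfg <- ts$product_config[i]
    g_rc <- g_of(rc, cy, cf)
    barrier <- ts$g_rel[i] - g_rc
    if (barrier < 0) {
      warn(paste0("transition state ", ts$name[i],
                  " lies below its reactive complex; using a barrierless rate."))
      barrier <- 0
    }
    k_cc <- eyring_rate(barrier, temp)
    im <- paste0(im_prefix, "_", ts$name[i])
    pr <- paste0("P_", cy, "_", cfg, "_", cf)
    species[[im]] <- add_sp(im, "iminium", catalyst = 1, ketone = 1,
                            electrophile = 1, acid_proton = h, product = 1)
    species[[pr]] <- add_sp(pr, "product", ketone = 1, electrophile = 1,
                            product = 1)
    add_rx("cc_bond", rc_name(cy, cf), im, k_fwd = k_cc,
           cycle = cy, conformer = cf, product_config = cfg,
           diastereo_class = ts$diastereo_class[i], ts_name = ts$name[i])
    add_rx("hydrolysis", im, c(pr, cat_sp(cy)), k_fwd = opt$k_lump,
           cycle = cy, conformer = cf, product_config = cfg,
           diastereo_class = ts$diastereo_class[i], ts_name = ts$name[i])
    channels[[i]] <- tibble(
      ts_name = ts$name[i], cycle = cy, conformer = cf,
      product_config = cfg, diastereo_class = ts$diastereo_class[i],
      g_ts = ts$g_rel[i], barrier = barrier, k_cc = k_cc,
      iminium_species = im, product_species = pr)
  }

  species <- dplyr::bind_rows(species)
  reactions <- dplyr::bind_rows(reactions)
  channels <- dplyr::bind_rows(channels)

  init <- setNames(numeric(nrow(species)), species$name)
  init["E"] <- e0
  init["ketone"] <- ket0
  init["cat"] <- opt$catalyst_equiv * e0
  if (multi) init["acid"] <- acid0

  structure(
    list(species = species, reactions = reactions, channels = channels,
         init = init, reaction_type = landscape$reaction_type,
         temperature = temp, options = opt),
    class = "reaction_network"
  )
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> ", x$reaction_type, ": ", nrow(x$species),
      " species, ", nrow(x$reactions), " reactions (",
      nrow(x$channels), " C-C channels)\n", sep = "")
  print(dplyr::count(x$reactions, .data$step))
  invisible(x)
}

#' Validate a reaction network
#'
#' Checks per-reaction conservation of the material composition tags
#' (catalyst, ketone, electrophile, acid-proton; the `product` tag is a
#' marker created at the C-C step and is excluded), species reachability
#' (every species takes part in at least one reaction) and exit paths (every
#' species that is produced is either consumed somewhere or a terminal
#' product).
#'
#' @param net A `reaction_network`.
#' @return A list of class `network_diagnostics` with fields `balance`
#'   (tibble of per-reaction tag imbalances), `unreachable`, `no_exit`
#'   (character vectors) and `pass` (logical).
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  tags <- c("catalyst", "ketone", "electrophile", "acid_proton")
  sp <- net$species
  tag_of <- function(names, tag) {
    m <- sp[[tag]][match(names, sp$name)]
    sum(m)
  }
  rows <- purrr::pmap_dfr(
    net$reactions[, c("id", "reactants", "products")],
    function(id, reactants, products) {
      unknown <- setdiff(c(reactants, products), sp$name)
      if (length(unknown) > 0L) {
        abort(paste0("reaction ", id, " references undeclared species: ",
                     paste(unknown, collapse = ", ")),
              class = "enaminekin_validation_error")
      }
      tibble(id = id, tag = tags,
             delta = vapply(tags, function(tg) {
               tag_of(products, tg) - tag_of(reactants, tg)
             }, numeric(1)))
    })
  imbalance <- rows[rows$delta != 0, ]

  all_re <- unlist(net$reactions$reactants)
  all_pr <- unlist(net$reactions$products)
  rev <- net$reactions$k_rev > 0
  consumed <- union(all_re, unlist(net$reactions$products[rev]))
  touched <- union(all_re, all_pr)
  unreachable <- setdiff(sp$name, touched)
  produced <- unique(all_pr)
  terminal_ok <- sp$name[sp$role %in% c("product", "nucleophile")]
  no_exit <- setdiff(setdiff(produced, consumed), terminal_ok)

  structure(
    list(balance = imbalance, unreachable = unreachable, no_exit = no_exit,
         pass = nrow(imbalance) == 0L && length(unreachable) == 0L &&
           length(no_exit) == 0L),
    class = "network_diagnostics"
  )
}

#' @export
print.network_diagnostics <- function(x, ...) {
  cat("<network_diagnostics> ", if (x$pass) "PASS" else "FAIL", "\n", sep = "")
  if (nrow(x$balance) > 0) {
    cat("  unbalanced reactions:\n"); print(x$balance)
  }
  if (length(x$unreachable) > 0)
    cat("  unreachable species:", paste(x$unreachable, collapse = ", "), "\n")
  if (length(x$no_exit) > 0)
    cat("  species with no exit path:", paste(x$no_exit, collapse = ", "), "\n")
  invisible(x)
}
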