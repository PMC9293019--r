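# Free-energy landscapes: named stationary points with relative Gibbs
# energies and stereochemical labels, the input to network construction.

.roles <- c("intermediate", "reactive_complex", "transition_state")
.cycles <- c("A", "B")
.conformers <- c("distal", "proximal")
.configs <- c("RS", "SR", "RR", "SS")
.faces <- c("Si,Si", "Re,Re", "Re,Si", "Si,Re")

#' Stereochemical label table for a reaction type
#'
#' Maps the four product configurations to prochiral-face combinations,
#' Seebach-Prelog topology (lk when both faces match, ul otherwise) and the
#' diastereomer class. Configurations are coded by the descriptors at C2 and
#' C1': "RS" = (2R,1'S), "SR" = (2S,1'R), "RR" = (2R,1'R), "SS" = (2S,1'S).
#' In the aldol reaction (2R,1'S)/(2S,1'R) are the anti pair; in the Michael
#' reaction the same pair is syn.
#'
#' @param reaction_type "aldol" or "michael".
#' @return A tibble with columns `product_config`, `face_pair`, `topology`,
#'   `diastereo_class`.
#' @export
stereo_table <- function(reaction_type = c("aldol", "michael")) {
  reaction_type <- match.arg(reaction_type)
  if (reaction_type == "aldol") {
    tibble(
      product_config = c("RS", "SR", "RR", "SS"),
      face_pair = c("Si,Si", "Re,Re", "Re,Si", "Si,Re"),
      topology = c("lk", "lk", "ul", "ul"),
      diastereo_class = c("anti", "anti", "syn", "syn")
    )
  } else {
    tibble(
      product_config = c("RS", "SR", "RR", "SS"),
      face_pair = c("Re,Si", "Si,Re", "Re,Re", "Si,Si"),
      topology = c("ul", "ul", "lk", "lk"),
      diastereo_class = c("syn", "syn", "anti", "anti")
    )
  }
}

#' Pretty label for a product configuration code
#' @param config Character vector of codes ("RS", "SR", "RR", "SS").
#' @return Labels such as "(2R,1'S)".
#' @export
config_label <- function(config) {
  map <- c(RS = "(2R,1'S)", SR = "(2S,1'R)", RR = "(2R,1'R)", SS = "(2S,1'S)")
  unname(map[config])
}

.mirror_config <- c(RS = "SR", SR = "RS", RR = "SS", SS = "RR")
.mirror_face <- c("Si,Si" = "Re,Re", "Re,Re" = "Si,Si",
                  "Re,Si" = "Si,Re", "Si,Re" = "Re,Si")

#' Construct a free-energy landscape
#'
#' A landscape is the executable description of the competing catalytic
#' cycles: enamine intermediates, reactive complexes and C-C bond-forming
#' transition states, each with a Gibbs energy relative to a single zero
#' reference (conventionally the separated enamine intermediate plus free
#' electrophile).
#'
#' @param points Data frame with columns `name`, `role` (one of
#'   "intermediate", "reactive_complex", "transition_state"), `cycle` ("A" or
#'   "B"), `conformer` ("distal", "proximal" or NA), `g_rel` (kcal/mol) and,
#'   for transition states, `product_config` (one of "RS", "SR", "RR", "SS");
#'   `face_pair` is optional and filled from [stereo_table()] when absent.
#' @param reaction_type "aldol" or "michael".
#' @param temperature Kelvin; default 298.15.
#' @return An object of class `fe_landscape`.
#' @export
landscape <- function(points, reaction_type = c("aldol", "michael"),
                      temperature = 298.15) {
  reaction_type <- match.arg(reaction_type)
  .check_temperature(temperature)
  pts <- as_tibble(points)
  required <- c("name", "role", "cycle", "conformer", "g_rel")
  missing_cols <- setdiff(required, names(pts))
  if (length(missing_cols) > 0L) {
    abort(paste0("landscape points are missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "enaminekin_parse_error")
  }
  if (!"product_config" %in% names(pts)) pts$product_config <- NA_character_
  if (!"face_pair" %in% names(pts)) pts$face_pair <- NA_character_

  pts$conformer[pts$conformer %in% c("n/a", "na", "")] <- NA_character_
  pts$product_config[pts$product_config %in% c("n/a", "na", "")] <- NA_character_

  if (anyDuplicated(pts$name)) {
    abort(paste0("duplicate stationary-point name(s): ",
                 paste(unique(pts$name[duplicated(pts$name)]), collapse = ", ")),
          class = "enaminekin_validation_error")
  }
  .check_enum(pts$role, .roles, "role")
  .check_enum(pts$cycle, .cycles, "cycle")
  .check_enum(pts$conformer[!is.na(pts$conformer)], .conformers, "conformer")
  if (!is.numeric(pts$g_rel) || any(!is.finite(pts$g_rel))) {
    abort("every stationary point needs a finite g_rel (kcal/mol).",
          class = "enaminekin_validation_error")
  }

  is_ts <- pts$role == "transition_state"
  if (!any(is_ts)) {
    abort("a landscape needs at least one transition_state point.",
          class = "enaminekin_validation_error")
  }
  if (any(is.na(pts$product_config[is_ts]))) {
    abort("every transition_state point must carry a product_config.",
          class = "enaminekin_validation_error")
  }
  .check_enum(pts$product_config[!is.na(pts$product_config)], .configs,
              "product_config")
  if (sum(pts$g_rel == 0) != 1L) {
    abort("exactly one stationary point must sit at the zero reference (g_rel = 0).",
          class = "enaminekin_validation_error")
  }

  st <- stereo_table(reaction_type)
  idx <- match(pts$product_config, st$product_config)
  pts$diastereo_class <- st$diastereo_class[idx]
  pts$topology <- st$topology[idx]
  fill <- is.na(pts$face_pair) & !is.na(pts$product_config)
  pts$face_pair[fill] <- st$face_pair[idx[fill]]
  pts <- pts[, c("name", "role", "cycle", "conformer", "face_pair",
                 "product_config", "g_rel", "diastereo_class", "topology")]

  structure(
    list(reaction_type = reaction_type, temperature = temperature,
         points = pts),
    class = "fe_landscape"
  )
}

.check_enum <- function(x, allowed, what) {
  bad <- setdiff(unique(x), allowed)
  if (length(bad) > 0L) {
    abort(paste0("unknown ", what, " value(s): ",
                 paste(bad, collapse = ", "),
                 " (allowed: ", paste(allowed, collapse = ", "), ")"),
          class = "enaminekin_enum_error")
  }
  invisible(x)
}

#' @export
print.fe_landscape <- function(x, ...) {
  cat("<fe_landscape> ", x$reaction_type, " at ", x$temperature, " K, ",
      nrow(x$points), " stationary points (",
      sum(x$points$role == "transition_state"), " TS)\n", sep = "")
  print(x$points, n = 8)
  invisible(x)
}

#' @method tidy fe_landscape
#' @export
tidy.fe_landscape <- function(x, ...) x$points

#' Mirror-swap the stereochemical labels of a landscape
#'
#' Exchanges each product configuration for its enantiomer
#' (RS <-> SR, RR <-> SS, faces Si <-> Re) while leaving all energies
#' untouched. A network built from the mirrored landscape yields the exactly
#' negated enantiomeric excess with an unchanged diastereomeric ratio.
#'
#' @param x A `fe_landscape`.
#' @return The mirrored `fe_landscape`.
#' @export
mirror_landscape <- function(x) {
  stopifnot(inherits(x, "fe_landscape"))
  pts <- x$points
  has_cfg <- !is.na(pts$product_config)
  pts$product_config[has_cfg] <- .mirror_config[pts$product_config[has_cfg]]
  has_face <- !is.na(pts$face_pair)
  pts$face_pair[has_face] <- .mirror_face[pts$face_pair[has_face]]
  pts$diastereo_class <- NULL
  pts$topology <- NULL
  landscape(pts, x$reaction_type, x$temperature)
}

#' Read a free-energy landscape from a YAML file
#'
#' The file is a nested key-value document with top-level fields
#' `reaction_type`, `temperature` and `points` (a sequence of maps with
#' `name`, `role`, `cycle`, `conformer`, `g_rel` and, for transition states,
#' `product_config`).
#'
#' @param path File path.
#' @return A `fe_landscape`.
#' @export
read_landscape <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("landscape file not found: ", path),
          class = "enaminekin_parse_error")
  }
  doc <- yaml::read_yaml(path)
  for (field in c("reaction_type", "points")) {
    if (is.null(doc[[field]])) {
      abort(paste0("landscape file is missing field: ", field),
            class = "enaminekin_parse_error")
    }
  }
  pts <- purrr::map_dfr(doc$points, function(p) {
    if (is.null(p$g_rel)) {
      abort(paste0("stationary point '", p$name %||% "<unnamed>",
                   "' is missing field: g_rel"),
            class = "enaminekin_parse_error")
    }
    tibble(
      name = as.character(p$name),
      role = as.character(p$role),
      cycle = as.character(p$cycle),
      conformer = as.character(p$conformer %||% NA_character_),
      face_pair = as.character(p$face_pair %||% NA_character_),
      product_config = as.character(p$product_config %||% NA_character_),
      g_rel = as.numeric(p$g_rel)
    )
  })
  landscape(pts, reaction_type = doc$reaction_type,
            temperature = doc$temperature %||% 298.15)
}

#' Write a free-energy landscape to a YAML file
#' @param x A `fe_landscape`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(x, path) {
  stopifnot(inherits(x, "fe_landscape"))
  pts <- purrr::pmap(x$points[, c("name", "role", "cycle", "conformer",
                                  "face_pair", "product_config", "g_rel")],
    function(name, role, cycle, conformer, face_pair, product_config, g_rel) {
      p <- list(name = name, role = role, cycle = cycle, g_rel = g_rel)
      if (!is.na(conformer)) p$conformer <- conformer
      if (!is.na(product_config)) {
        p$product_config <- product_config
        p$face_pair <- face_pair
      }
      p
    })
  yaml::write_yaml(
    list(reaction_type = x$reaction_type, temperature = x$temperature,
         points = pts),
    path
  )
  invisible(path)
}
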