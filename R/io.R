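# Readers, writers and report formatting for the tabular formats used by
# the other modules: trace CSVs and selectivity reports. Landscape YAML IO
# lives next to the landscape constructor.

#' Read a kinetic trace from a CSV file
#'
#' Expects a header with `time_s`, one column per signal and the
#' internal-reference column. Malformed cells are reported with their row
#' number.
#'
#' @param path File path.
#' @param signals Signal column names (default `c("Fo", "Fm", "Fp")`).
#' @param reference Reference column name (default "TFA").
#' @return A [kinetic_trace()].
#' @export
read_trace_csv <- function(path, signals = c("Fo", "Fm", "Fp"),
                           reference = "TFA") {
  if (!file.exists(path)) {
    abort(paste0("trace file not found: ", path),
          class = "enaminekin_parse_error")
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("time_s", signals, reference)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L) {
    abort(paste0("trace file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "enaminekin_parse_error")
  }
  for (cl in needed) {
    v <- suppressWarnings(as.numeric(raw[[cl]]))
    bad <- which(is.na(v) & !is.na(raw[[cl]]))
    if (length(bad) > 0L) {
      abort(paste0("non-numeric value in column '", cl, "' at data row(s) ",
                   paste(bad, collapse = ", "), "."),
            class = "enaminekin_parse_error")
    }
    raw[[cl]] <- v
  }
  kinetic_trace(raw, signals = signals, reference = reference)
}

#' Write a kinetic trace to CSV
#' @param trace A [kinetic_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "kinetic_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Write a trajectory to a tidy CSV
#'
#' One row per (time, species): columns `time_s`, `species`, `conc_M`.
#'
#' @param traj A `kin_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "kin_trajectory"))
  utils::write.csv(as.data.frame(tidy(traj)), path, row.names = FALSE)
  invisible(path)
}

.fmt_ratio <- function(a, b, digits) {
  paste0(formatC(a, format = "f", digits = digits), " : ",
         formatC(b, format = "f", digits = digits))
}

#' Format a selectivity result as text
#'
#' @param result A `selectivity_result`.
#' @param style "decimal" (percentages to 1 decimal), "paper" (ratios rounded
#'   to integers, as selectivities are conventionally printed) or "machine"
#'   (key,value CSV lines).
#' @return A character vector of report lines.
#' @export
report_selectivity <- function(result,
                               style = c("decimal", "paper", "machine")) {
  stopifnot(inherits(result, "selectivity_result"))
  style <- match.arg(style)
  dr <- result$dr
  part <- result$cycle_partition
  if (style == "machine") {
    g <- glance(result)
    lines <- c("key,value",
               paste0(names(g)[-1], ",",
                      vapply(g[-1], function(v) format(v, digits = 15),
                             character(1))))
    ch <- result$channel_yields
    lines <- c(lines,
               paste0("yield_", ch$cycle, "_", ch$product_config, "_",
                      ch$conformer, ",", format(ch$yield, digits = 15)))
    return(lines)
  }
  digits <- if (style == "paper") 0L else 1L
  dr_line <- paste0(paste(dr$diastereo_class, collapse = ":"), " ",
                    .fmt_ratio(dr$pct[1], dr$pct[2], digits))
  ee_line <- if (style == "paper") {
    sprintf("ee %+d%%", round(result$ee))
  } else {
    sprintf("ee %+.1f%%", result$ee)
  }
  part_line <- if (nrow(part) == 2L) {
    paste0(paste(part$cycle, collapse = " : "), " = ",
           .fmt_ratio(part$pct[1], part$pct[2], digits))
  } else NULL
  c(paste0(dr_line, ", ", ee_line),
    part_line,
    sprintf("conversion %.1f%%", 100 * result$conversion))
}
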