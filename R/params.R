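#' Physical constants used by the classical backend
#'
#' Coulomb constant in kcal*Angstrom/(mol*e^2), the hartree-to-kcal/mol
#' conversion, and the molar gas constant in kcal/(mol*K).
#'
#' @keywords internal
#' @name constants
NULL

.ke_coulomb <- 332.0637
.hartree_kcal <- 627.5095
.r_gas <- 1.98720425864083e-3

#' Default per-element nonbonded and Born parameters
#'
#' Fallback table used when an atom has no explicit Lennard-Jones or Born
#' parameters. Values are generic force-field-scale defaults: well depths and
#' diameters on the Amber/OPLS order of magnitude, Born radii the usual
#' intrinsic radii (H 1.2, C 1.7, N 1.55, O 1.52, S 1.8 Angstrom). An explicit
#' parameter table (see [read_parameter_table()]) overrides these.
#'
#' @return A data.frame with columns `element`, `lj_epsilon` (kcal/mol),
#'   `lj_sigma` (Angstrom), `born_radius` (Angstrom).
#' @export
#' @examples
#' default_element_params()
default_element_params <- function() {
  data.frame(
    element     = c("H",    "C",    "N",    "O",    "S",    "P",    "F",    "CL",   "BR",   "I"),
    lj_epsilon  = c(0.0157, 0.0860, 0.1700, 0.2100, 0.2500, 0.2000, 0.0610, 0.2650, 0.3200, 0.4000),
    lj_sigma    = c(2.471,  3.400,  3.250,  2.960,  3.564,  3.742,  3.118,  3.471,  3.599,  3.830),
    born_radius = c(1.20,   1.70,   1.55,   1.52,   1.80,   1.80,   1.47,   1.75,   1.85,   1.98),
    stringsAsFactors = FALSE
  )
}

#' Read a per-element parameter table
#'
#' Plain-text key-value table mapping an element symbol to its Lennard-Jones
#' well depth (kcal/mol), diameter (Angstrom) and Born radius (Angstrom).
#' Whitespace-separated columns `element epsilon sigma born_radius`; lines
#' starting with `#` are comments. Entries override the shipped defaults.
#'
#' @param path Path to the table.
#' @return data.frame in the same layout as [default_element_params()].
#' @export
read_parameter_table <- function(path) {
  if (!file.exists(path)) {
    stop_pocketedda(sprintf("parameter table not found: %s", path), "io_error")
  }
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE,
                           col.names = c("element", "lj_epsilon", "lj_sigma", "born_radius"))
  tab$element <- toupper(tab$element)
  bad <- !is.finite(tab$lj_epsilon) | tab$lj_epsilon < 0 |
    !is.finite(tab$lj_sigma) | tab$lj_sigma <= 0 |
    !is.finite(tab$born_radius) | tab$born_radius <= 0
  if (any(bad)) {
    stop_pocketedda(sprintf("invalid parameter row(s) for element(s): %s",
                            paste(tab$element[bad], collapse = ", ")),
                    "parameter_error")
  }
  tab
}

#' Resolve missing atom parameters from an element table
#'
#' Fills `lj_epsilon`, `lj_sigma` and `born_radius` of atoms that carry `NA`
#' values from `table`, falling back to [default_element_params()]. Explicit
#' per-atom values already present are kept.
#'
#' @param fragment A [fragment()].
#' @param table Optional data.frame from [read_parameter_table()].
#' @return The fragment with all parameters resolved.
#' @export
resolve_parameters <- function(fragment, table = NULL) {
  stopifnot(inherits(fragment, "fragment"))
  at <- fragment$atoms
  defaults <- default_element_params()
  if (!is.null(table)) {
    keep <- !(defaults$element %in% table$element)
    defaults <- rbind(table, defaults[keep, , drop = FALSE])
  }
  idx <- match(toupper(at$element), defaults$element)
  for (col in c("lj_epsilon", "lj_sigma", "born_radius")) {
    miss <- is.na(at[[col]])
    at[[col]][miss] <- defaults[[col]][idx[miss]]
  }
  unresolved <- is.na(at$lj_epsilon) | is.na(at$lj_sigma) | is.na(at$born_radius)
  if (any(unresolved)) {
    stop_pocketedda(sprintf("no parameters for atom(s): %s (element %s) in fragment %s",
                            paste(at$name[unresolved], collapse = ", "),
                            paste(unique(at$element[unresolved]), collapse = ", "),
                            fragment$label),
                    "parameter_error")
  }
  fragment$atoms <- at
  fragment
}

# Condition helper: all package errors are classed conditions so callers and
# tests can dispatch on the failure kind rather than on message text.
stop_pocketedda <- function(message, class, ...) {
  stop(errorCondition(message,
                      class = c(paste0("pocketedda_", class), "pocketedda_error"),
                      ...))
}
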