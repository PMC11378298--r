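#' Binding free-energy breakdown
#'
#' Container for the terms of the binding Gibbs energy bookkeeping:
#' gas-phase binding energy, deformation penalty, translational-rotational-
#' vibrational enthalpy, solvation Gibbs energy, and the two entropy terms
#' (translational-rotational-vibrational and conformational). Terms that are
#' not available are left `NA` and tracked explicitly -- they are never
#' silently zeroed. Entropies are in kcal/(mol*K); everything else in
#' kcal/mol.
#'
#' @param e_bind Gas-phase binding energy, kcal/mol.
#' @param e_def Deformation energy, kcal/mol.
#' @param h_trv Translation-rotation-vibration enthalpy contribution,
#'   kcal/mol.
#' @param g_solv Solvation Gibbs energy, kcal/mol.
#' @param s_trv,s_conf Entropy terms, kcal/(mol*K); accepted only as inputs
#'   (e.g. from an external conformer-ensemble tool), never computed here.
#' @param temperature Kelvin (default 298.15).
#' @return Object of class `binding_energy_breakdown`.
#' @export
binding_energy_breakdown <- function(e_bind = NA_real_, e_def = NA_real_,
                                     h_trv = NA_real_, g_solv = NA_real_,
                                     s_trv = NA_real_, s_conf = NA_real_,
                                     temperature = 298.15) {
  if (!is.finite(temperature) || temperature <= 0) {
    stop_pocketedda("temperature must be positive", "argument_error")
  }
  structure(list(e_bind = e_bind, e_def = e_def, h_trv = h_trv,
                 g_solv = g_solv, s_trv = s_trv, s_conf = s_conf,
                 temperature = temperature),
            class = "binding_energy_breakdown")
}

#' Assemble the binding Gibbs energy from its breakdown
#'
#' Sums the available terms of the bookkeeping expression
#' `e_bind + e_def + h_trv + g_solv - T * (s_trv + s_conf)` and reports which
#' terms were omitted. The minimum usable breakdown is `e_bind + g_solv`
#' (binding energy plus solvation Gibbs energy, the pair the decomposition
#' reports carry); with terms omitted the value is a relative quantity, not
#' an absolute binding free energy.
#'
#' @param b A [binding_energy_breakdown()].
#' @return List with `value` (kcal/mol), `included` and `omitted` term names,
#'   and `temperature`.
#' @export
#' @examples
#' b <- binding_energy_breakdown(e_bind = -53.1, g_solv = 10)
#' assemble_binding_energy(b)
assemble_binding_energy <- function(b) {
  stopifnot(inherits(b, "binding_energy_breakdown"))
  if (is.na(b$e_bind)) {
    stop_pocketedda("incomplete breakdown: e_bind is unset", "incomplete_breakdown")
  }
  if (is.na(b$g_solv)) {
    stop_pocketedda("incomplete breakdown: g_solv is unset", "incomplete_breakdown")
  }
  enthalpic <- c(e_bind = b$e_bind, e_def = b$e_def, h_trv = b$h_trv,
                 g_solv = b$g_solv)
  entropic <- c(s_trv = b$s_trv, s_conf = b$s_conf)
  value <- sum(enthalpic, na.rm = TRUE) -
    b$temperature * sum(entropic, na.rm = TRUE)
  included <- c(names(enthalpic)[!is.na(enthalpic)], names(entropic)[!is.na(entropic)])
  omitted <- setdiff(c(names(enthalpic), names(entropic)), included)
  list(value = value, included = included, omitted = omitted,
       temperature = b$temperature)
}

#' Conformer ensemble
#'
#' Energies (kcal/mol) of an ensemble of conformers together with a parallel
#' vector of property values to be averaged.
#'
#' @param energies Numeric conformer energies, kcal/mol.
#' @param values Property values, one per conformer.
#' @param temperature Kelvin.
#' @return Object of class `conformer_ensemble`.
#' @export
conformer_ensemble <- function(energies, values, temperature = 298.15) {
  if (length(energies) == 0 || length(energies) != length(values)) {
    stop_pocketedda("energies and values must be non-empty parallel vectors",
                    "argument_error")
  }
  if (!is.finite(temperature) || temperature <= 0) {
    stop_pocketedda("temperature must be positive", "argument_error")
  }
  structure(list(energies = as.numeric(energies), values = as.numeric(values),
                 temperature = temperature),
            class = "conformer_ensemble")
}

#' Boltzmann weights of a conformer ensemble
#'
#' `w_i = exp(-(E_i - E_min)/RT) / Z` with
#' `R = 1.98720425864083e-3 kcal/(mol*K)`; energies are shifted by the
#' ensemble minimum before exponentiation for overflow safety, which leaves
#' the weights unchanged.
#'
#' @param ensemble A [conformer_ensemble()].
#' @return Numeric weights summing to 1.
#' @export
boltzmann_weights <- function(ensemble) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  rt <- .r_gas * ensemble$temperature
  w <- exp(-(ensemble$energies - min(ensemble$energies)) / rt)
  w / sum(w)
}

#' Boltzmann-averaged property over a conformer ensemble
#'
#' Population-weighted expectation `sum_i w_i x_i` with the weights of
#' [boltzmann_weights()].
#'
#' @param ensemble A [conformer_ensemble()].
#' @return The averaged property value.
#' @export
#' @examples
#' ens <- conformer_ensemble(c(0, 0.5), c(1, 3), temperature = 300)
#' boltzmann_average(ens)
boltzmann_average <- function(ensemble) {
  sum(boltzmann_weights(ensemble) * ensemble$values)
}

#' Free-energy difference from an affinity ratio
#'
#' Textbook conversion between relative experimental affinities and a
#' calculated free-energy difference (1 M standard state):
#' `ddG(A - B) = R T ln(k_a / k_b)`, negative when A binds tighter (smaller
#' affinity value). IC50 ratios serve as affinity-ratio proxies when no
#' dissociation constants are available; the result is labeled accordingly.
#'
#' @param k_a,k_b Affinities of A and B (same units, any concentration
#'   scale; only the ratio enters).
#' @param temperature Kelvin (default 298.15).
#' @return ddG in kcal/mol, with attribute `convention`.
#' @export
#' @examples
#' ddg_from_affinity_ratio(70e-9, 185e-9)  # tighter binder A -> negative
ddg_from_affinity_ratio <- function(k_a, k_b, temperature = 298.15) {
  if (!is.finite(k_a) || !is.finite(k_b) || k_a <= 0 || k_b <= 0) {
    stop_pocketedda("affinities must be positive", "argument_error")
  }
  if (!is.finite(temperature) || temperature <= 0) {
    stop_pocketedda("temperature must be positive", "argument_error")
  }
  structure(.r_gas * temperature * log(k_a / k_b),
            convention = "relative, IC50-proxy; ddG = RT ln(kA/kB), 1 M standard state")
}
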