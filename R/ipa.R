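new_interaction_map <- function(mode_label, pairs, summed) {
  structure(list(mode_label = mode_label, pairs = pairs, summed = summed),
            class = "interaction_map")
}

#' @export
print.interaction_map <- function(x, ...) {
  cat(sprintf("<interaction_map> %s: %d residue pair(s), summed total %.4f kcal/mol\n",
              x$mode_label, nrow(x$pairs), x$summed[["total"]]))
  if (nrow(x$pairs) > 0) {
    show <- x$pairs[, c("label", "total", "electrostatic", "dispersion", "repulsion",
                        "hbond", "desolvation", "closest_contact")]
    print(utils::head(show, 12), row.names = FALSE, digits = 5)
  }
  invisible(x)
}

#' Relax hydrogen positions with heavy atoms fixed
#'
#' Local minimization of the backend total energy over the Cartesian
#' coordinates of mobile hydrogens only. Heavy atoms (and any hydrogen not
#' flagged `mobile`) are bitwise unchanged. The optimizer is deterministic
#' gradient descent with a backtracking (Armijo) line search: the energy is
#' non-increasing across accepted steps, and iteration stops when the energy
#' improvement falls below `tol` or after `max_iter` accepted steps.
#' Gradients are analytic for the classical backend and central finite
#' differences (step 1e-4 A) for the external engine.
#'
#' @param geometry A [fragment()] (typically a ligand-residue union from
#'   [merge_fragments()]) with at least one mobile hydrogen.
#' @param config A [backend_config()].
#' @param tol Convergence threshold on the energy change, kcal/mol.
#' @param max_iter Maximum number of accepted descent steps.
#' @return List of class `refine_result`: `fragment` (refined geometry),
#'   `energy_initial`, `energy_final` (kcal/mol), `accepted_steps`,
#'   `converged`.
#' @export
refine_hydrogens <- function(geometry, config = backend_config(),
                             tol = 1e-6, max_iter = 500) {
  stopifnot(inherits(geometry, "fragment"))
  mob <- which(geometry$atoms$mobile)
  if (length(mob) == 0) {
    stop_pocketedda(sprintf("fragment %s has no mobile hydrogens", geometry$label),
                    "argument_error")
  }
  atoms <- geometry$atoms
  if (config$engine == "classical") {
    check_params_resolved(geometry)
    eg <- function(at) classical_energy_gradient(at, geometry$bonds, config, free = mob)
  } else {
    fd_step <- 1e-4
    eg <- function(at) {
      f <- geometry; f$atoms <- at
      e0 <- external_engine_energy(f, config)
      g <- matrix(0, length(mob), 3)
      cols <- c("x", "y", "z")
      for (k in seq_along(mob)) for (c3 in 1:3) {
        ap <- at; ap[mob[k], cols[c3]] <- ap[mob[k], cols[c3]] + fd_step
        am <- at; am[mob[k], cols[c3]] <- am[mob[k], cols[c3]] - fd_step
        fp <- geometry; fp$atoms <- ap
        fm <- geometry; fm$atoms <- am
        g[k, c3] <- (external_engine_energy(fp, config) -
                       external_engine_energy(fm, config)) / (2 * fd_step)
      }
      list(energy = e0, gradient = g)
    }
  }
  cur <- eg(atoms)
  if (!is.finite(cur$energy)) {
    stop_pocketedda(sprintf("non-finite starting energy for %s", geometry$label),
                    "geometry_error")
  }
  e0 <- cur$energy
  accepted <- 0L
  converged <- FALSE
  cols <- c("x", "y", "z")
  for (it in seq_len(max_iter)) {
    g <- cur$gradient
    gnorm2 <- sum(g^2)
    if (sqrt(gnorm2) < 1e-12) { converged <- TRUE; break }
    # Initial step scaled so the largest atom displacement is ~0.05 A.
    step <- 0.05 / max(sqrt(rowSums(g^2)))
    improved <- FALSE
    repeat {
      trial <- atoms
      trial[mob, cols] <- as.matrix(atoms[mob, cols]) - step * g
      nxt <- eg(trial)
      if (is.finite(nxt$energy) && nxt$energy <= cur$energy - 1e-4 * step * gnorm2) {
        improved <- TRUE
        break
      }
      step <- step / 2
      if (step < 1e-12) break
    }
    if (!improved) { converged <- TRUE; break }
    accepted <- accepted + 1L
    delta <- cur$energy - nxt$energy
    atoms <- trial
    cur <- nxt
    if (delta < tol) { converged <- TRUE; break }
  }
  out <- geometry
  out$atoms <- atoms
  structure(list(fragment = out, energy_initial = e0, energy_final = cur$energy,
                 accepted_steps = accepted, converged = converged),
            class = "refine_result")
}

#' @export
print.refine_result <- function(x, ...) {
  cat(sprintf("<refine_result> %s: E %.6f -> %.6f kcal/mol in %d step(s)%s\n",
              x$fragment$label, x$energy_initial, x$energy_final,
              x$accepted_steps, if (x$converged) " (converged)" else ""))
  invisible(x)
}

sum_components <- function(pairs) {
  if (nrow(pairs) == 0) return(energy_components())
  energy_components(electrostatic = sum(pairs$electrostatic),
                    dispersion = sum(pairs$dispersion),
                    repulsion = sum(pairs$repulsion),
                    hbond = sum(pairs$hbond),
                    desolvation = sum(pairs$desolvation),
                    bonded = 0,
                    total = sum(pairs$total), check = FALSE)
}

#' In-pocket analysis: per-residue interaction map
#'
#' For every ligand-residue pair of the pocket (in closest-contact order),
#' optionally relaxes the pair's hydrogen positions (each pair independently,
#' starting from the original pocket geometry; the monomers keep the
#' pair-refined hydrogen positions in the supermolecule formula), computes
#' the pair interaction energy, and assembles the per-residue records with
#' componentwise sums.
#'
#' @param pocket A [pocket_model()].
#' @param config A [backend_config()].
#' @param refine Relax hydrogens before each pair energy. Defaults to `TRUE`
#'   for the external engine and `FALSE` for the classical backend, whose
#'   closed-form reference values assume the input geometry.
#' @param tol,max_iter Passed to [refine_hydrogens()].
#' @return An `interaction_map`: `mode_label`, `pairs` (one row per residue
#'   with components, closest contact and the `refined` flag), `summed`
#'   ([energy_components()]).
#' @export
in_pocket_analysis <- function(pocket, config = backend_config(),
                               refine = (config$engine == "external"),
                               tol = 1e-6, max_iter = 500) {
  stopifnot(inherits(pocket, "pocket_model"))
  pairs <- enumerate_pairs(pocket)
  rows <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    res <- pocket$residues[[pairs$index[k]]]
    lig <- pocket$ligand
    did_refine <- FALSE
    result <- tryCatch({
      if (refine) {
        un <- merge_fragments(lig, res)
        if (any(un$atoms$mobile)) {
          ref <- refine_hydrogens(un, config, tol = tol, max_iter = max_iter)
          nl <- nrow(lig$atoms)
          lig$atoms <- ref$fragment$atoms[seq_len(nl), , drop = FALSE]
          res$atoms <- ref$fragment$atoms[-seq_len(nl), , drop = FALSE]
          did_refine <- TRUE
        }
      }
      pair_interaction_energy(lig, res, config)
    }, pocketedda_error = function(e) {
      stop_pocketedda(sprintf("[%s] %s", res$label, conditionMessage(e)),
                      sub("^pocketedda_", "", class(e)[1]))
    })
    srid <- res$source_residue_ids
    rows[[k]] <- data.frame(
      chain = if (nrow(srid) > 0) srid$chain[1] else "",
      resnum = if (nrow(srid) > 0) srid$resnum[1] else NA_integer_,
      label = res$label,
      electrostatic = result[["electrostatic"]],
      dispersion = result[["dispersion"]],
      repulsion = result[["repulsion"]],
      hbond = result[["hbond"]],
      desolvation = result[["desolvation"]],
      total = result[["total"]],
      closest_contact = pairs$closest_contact[k],
      refined = did_refine,
      stringsAsFactors = FALSE
    )
  }
  p <- if (length(rows)) do.call(rbind, rows)
       else data.frame(chain = character(), resnum = integer(), label = character(),
                       electrostatic = numeric(), dispersion = numeric(),
                       repulsion = numeric(), hbond = numeric(),
                       desolvation = numeric(), total = numeric(),
                       closest_contact = numeric(), refined = logical())
  new_interaction_map(pocket$ligand$label, p, sum_components(p))
}
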