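#' Binding mode: one ligand pose in a shared pocket
#'
#' A labeled (pose, pocket) pair. Modes under comparison must share their
#' residue fragments atom-for-atom; only the ligand pose differs (e.g. the
#' two 180-degree-flipped orientations of a planar ring).
#'
#' @param label Mode label, e.g. `"N-C"` or `"N-O"`.
#' @param pocket A [pocket_model()] holding the pose.
#' @return Object of class `binding_mode`.
#' @export
binding_mode <- function(label, pocket) {
  stopifnot(inherits(pocket, "pocket_model"))
  structure(list(label = as.character(label), pocket = pocket),
            class = "binding_mode")
}

#' @export
print.binding_mode <- function(x, ...) {
  cat(sprintf("<binding_mode> %s\n", x$label))
  print(x$pocket)
  invisible(x)
}

# Minimize a fragment with every atom mobile (classical backend): reference
# conformer for the deformation energy when none is supplied.
minimize_fragment <- function(frag, config, tol = 1e-6, max_iter = 500) {
  atoms <- frag$atoms
  free <- seq_len(nrow(atoms))
  cols <- c("x", "y", "z")
  cur <- classical_energy_gradient(atoms, frag$bonds, config, free = free)
  for (it in seq_len(max_iter)) {
    g <- cur$gradient
    gnorm2 <- sum(g^2)
    if (sqrt(gnorm2) < 1e-12) break
    step <- 0.05 / max(sqrt(rowSums(g^2)))
    improved <- FALSE
    repeat {
      trial <- atoms
      trial[free, cols] <- as.matrix(atoms[free, cols]) - step * g
      nxt <- classical_energy_gradient(trial, frag$bonds, config, free = free)
      if (is.finite(nxt$energy) && nxt$energy <= cur$energy - 1e-4 * step * gnorm2) {
        improved <- TRUE; break
      }
      step <- step / 2
      if (step < 1e-12) break
    }
    if (!improved) break
    delta <- cur$energy - nxt$energy
    atoms <- trial; cur <- nxt
    if (delta < tol) break
  }
  out <- frag
  out$atoms <- atoms
  list(fragment = out, energy = cur$energy)
}

intra_energy <- function(frag, config) {
  if (config$engine == "external") external_engine_energy(frag, config)
  else fragment_energy(frag, config)[["total"]]
}

#' Ligand deformation (strain) energy
#'
#' Intramolecular energy of the bound conformation minus that of a relaxed
#' reference conformer: `E_intra(bound) - E_intra(reference)`. When no
#' reference is supplied the classical backend generates one by minimizing
#' the bound conformer with all atoms mobile, which makes the result
#' non-negative by construction.
#'
#' @param bound_conformer Bound-pose [fragment()].
#' @param reference_conformer Optional relaxed [fragment()] with the same
#'   atoms in the same order (e.g. from an external conformer search).
#' @param config A [backend_config()].
#' @return Deformation energy, kcal/mol.
#' @export
deformation_energy <- function(bound_conformer, reference_conformer = NULL,
                               config = backend_config()) {
  if (is.null(reference_conformer)) {
    if (config$engine != "classical") {
      stop_pocketedda("reference conformer required for the external engine",
                      "argument_error")
    }
    reference_conformer <- minimize_fragment(bound_conformer, config)$fragment
  }
  if (nrow(bound_conformer$atoms) != nrow(reference_conformer$atoms) ||
      !identical(bound_conformer$atoms$element, reference_conformer$atoms$element)) {
    stop_pocketedda("bound and reference conformers must have the same atoms in the same order",
                    "argument_error")
  }
  intra_energy(bound_conformer, config) - intra_energy(reference_conformer, config)
}

# Pocket-level generalized-Born desolvation: supermolecule polarization of
# the whole pocket minus all monomers, i.e. every cross-fragment GB term
# (ligand-residue and residue-residue). Returned per residue using the share
# rule: residue r gets its full ligand-r term plus half of each r-r' term,
# which sums exactly to the pocket total.
pocket_desolvation <- function(pocket, config) {
  frags <- c(list(pocket$ligand), pocket$residues)
  nf <- length(frags)
  tau <- gb_tau(config)
  cross <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1)) for (j in seq((i + 1), nf)) {
    a <- frags[[i]]$atoms; b <- frags[[j]]$atoms
    d <- cross_distances(a, b)
    ab <- outer(a$born_radius, b$born_radius)
    qq <- outer(a$charge, b$charge)
    cross[i, j] <- cross[j, i] <-
      -config$coulomb_constant * tau * sum(qq / sqrt(d^2 + ab * exp(-d^2 / (4 * ab))))
  }
  nres <- nf - 1
  per_res <- numeric(nres)
  for (r in seq_len(nres)) {
    per_res[r] <- cross[1, r + 1] + 0.5 * sum(cross[r + 1, -c(1, r + 1)])
  }
  list(total = sum(cross[upper.tri(cross)]), per_residue = per_res)
}

#' Single-mode energy decomposition report
#'
#' Runs [in_pocket_analysis()], replaces the pairwise desolvation entries by
#' the pocket-level generalized-Born desolvation (whole-pocket supermolecule
#' minus monomers, distributed across residues by their GB cross-term share
#' -- an approximate attribution, flagged in the report), and adds the ligand
#' deformation energy. The score is the summed interaction energy plus
#' desolvation plus deformation, and always equals the component sum.
#'
#' @param mode A [binding_mode()].
#' @param config A [backend_config()].
#' @param refine,tol,max_iter Passed to [in_pocket_analysis()].
#' @param reference_conformer Optional reference for
#'   [deformation_energy()].
#' @return Object of class `edda_report` with fields `mode_label`, `map`
#'   (pocket-level desolvation substituted), `interaction` (gas-phase
#'   ligand-residue sum), `desolvation`, `deformation`, `score`, `components`
#'   (named vector), `unavailable` (components the backend cannot supply),
#'   `notes`.
#' @export
edda_decompose <- function(mode, config = backend_config(),
                           refine = (config$engine == "external"),
                           reference_conformer = NULL,
                           tol = 1e-6, max_iter = 500) {
  stopifnot(inherits(mode, "binding_mode"))
  pocket <- mode$pocket
  map <- in_pocket_analysis(pocket, config, refine = refine, tol = tol,
                            max_iter = max_iter)
  unavailable <- character(0)
  if (config$engine == "classical") {
    ds <- pocket_desolvation(pocket, config)
    if (nrow(map$pairs) > 0) {
      map$pairs$desolvation <- ds$per_residue[map$pairs$label |>
        match(vapply(pocket$residues, function(f) f$label, ""))]
      map$pairs$total <- map$pairs$electrostatic + map$pairs$dispersion +
        map$pairs$repulsion + map$pairs$hbond + map$pairs$desolvation
    }
    map$summed <- sum_components(map$pairs)
    desolvation <- ds$total
    interaction <- map$summed[["total"]] - desolvation
    deformation <- deformation_energy(pocket$ligand, reference_conformer, config)
    components <- c(electrostatic = map$summed[["electrostatic"]],
                    dispersion = map$summed[["dispersion"]],
                    repulsion = map$summed[["repulsion"]],
                    hbond = map$summed[["hbond"]],
                    desolvation = desolvation,
                    deformation = deformation)
  } else {
    desolvation <- NA_real_
    interaction <- map$summed[["total"]]
    deformation <- if (!is.null(reference_conformer)) {
      deformation_energy(pocket$ligand, reference_conformer, config)
    } else NA_real_
    unavailable <- c("electrostatic", "dispersion", "repulsion", "hbond",
                     "desolvation",
                     if (is.na(deformation)) "deformation")
    components <- c(interaction = interaction, deformation = deformation)
  }
  score <- sum(c(interaction, desolvation, deformation), na.rm = config$engine != "classical")
  structure(list(mode_label = mode$label, map = map,
                 interaction = interaction, desolvation = desolvation,
                 deformation = deformation, score = score,
                 components = components, unavailable = unavailable,
                 notes = c("per-residue desolvation is an approximate share of the pocket-level GB term",
                           if (length(unavailable))
                             "component breakdown unavailable for the external engine")),
            class = "edda_report")
}

#' @export
print.edda_report <- function(x, ...) {
  cat(sprintf("<edda_report> mode %s\n", x$mode_label))
  cat(sprintf("  interaction %10.4f kcal/mol\n", x$interaction))
  cat(sprintf("  desolvation %10.4f kcal/mol\n", x$desolvation))
  cat(sprintf("  deformation %10.4f kcal/mol\n", x$deformation))
  cat(sprintf("  score       %10.4f kcal/mol\n", x$score))
  if (length(x$unavailable)) {
    cat("  unavailable:", paste(x$unavailable, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Compare two binding modes
#'
#' Decomposes both modes, forms per-residue and per-component deltas
#' (mode A minus mode B) and a total delta, and issues a qualitative verdict:
#' `"dual"` when the absolute total delta is within the near-degeneracy
#' threshold, otherwise the label of the preferred (lower-score) mode. Deltas
#' are antisymmetric under swapping the modes.
#'
#' @param mode_a,mode_b [binding_mode()]s sharing identical residue
#'   fragments.
#' @param config A [backend_config()].
#' @param threshold Near-degeneracy threshold on the absolute total delta,
#'   kcal/mol (default 0.5).
#' @param refine,tol,max_iter Passed to [edda_decompose()].
#' @param reference_conformer Optional shared deformation reference.
#' @return Object of class `edda_comparison`: reports for both modes, a
#'   `delta` data.frame (per residue, per component, A - B), `total_delta`,
#'   `threshold`, `verdict`.
#' @export
compare_binding_modes <- function(mode_a, mode_b, config = backend_config(),
                                  threshold = 0.5,
                                  refine = (config$engine == "external"),
                                  reference_conformer = NULL,
                                  tol = 1e-6, max_iter = 500) {
  ra <- mode_a$pocket$residues; rb <- mode_b$pocket$residues
  mismatch <- character(0)
  if (length(ra) != length(rb)) {
    mismatch <- "residue counts differ"
  } else {
    for (k in seq_along(ra)) {
      same <- identical(ra[[k]]$label, rb[[k]]$label) &&
        nrow(ra[[k]]$atoms) == nrow(rb[[k]]$atoms) &&
        identical(ra[[k]]$atoms$element, rb[[k]]$atoms$element) &&
        max(abs(coords_of(ra[[k]]$atoms) - coords_of(rb[[k]]$atoms))) <= 1e-9 &&
        max(abs(ra[[k]]$atoms$charge - rb[[k]]$atoms$charge)) <= 1e-9
      if (!same) mismatch <- c(mismatch, ra[[k]]$label)
    }
  }
  if (length(mismatch)) {
    stop_pocketedda(sprintf("modes do not share identical residue fragments: %s",
                            paste(mismatch, collapse = ", ")), "comparison_error")
  }
  rep_a <- edda_decompose(mode_a, config, refine = refine,
                          reference_conformer = reference_conformer,
                          tol = tol, max_iter = max_iter)
  rep_b <- edda_decompose(mode_b, config, refine = refine,
                          reference_conformer = reference_conformer,
                          tol = tol, max_iter = max_iter)
  comp_cols <- c("electrostatic", "dispersion", "repulsion", "hbond",
                 "desolvation", "total")
  pa <- rep_a$map$pairs; pb <- rep_b$map$pairs
  delta <- pa[, c("chain", "resnum", "label"), drop = FALSE]
  ib <- match(pa$label, pb$label)
  for (col in comp_cols) delta[[col]] <- pa[[col]] - pb[[col]][ib]
  total_delta <- rep_a$score - rep_b$score
  verdict <- if (is.finite(total_delta) && abs(total_delta) <= threshold) "dual"
             else if (total_delta < 0) mode_a$label else mode_b$label
  structure(list(mode_a = rep_a, mode_b = rep_b, delta = delta,
                 total_delta = total_delta, threshold = threshold,
                 verdict = verdict),
            class = "edda_comparison")
}

#' @export
print.edda_comparison <- function(x, ...) {
  cat(sprintf("<edda_comparison> %s vs %s: total delta %+.4f kcal/mol (threshold %.2f) -> %s\n",
              x$mode_a$mode_label, x$mode_b$mode_label, x$total_delta,
              x$threshold, x$verdict))
  invisible(x)
}
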