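#' Energy backend configuration
#'
#' Parameters of the energy contract shared by the in-pocket analysis and the
#' decomposition stages. The classical backend evaluates exact double sums of
#' Coulomb and Lennard-Jones terms (no cutoffs or neighbor lists: pockets are
#' small and the numbers must be bit-stable), a geometric hydrogen-bond
#' reattribution, and generalized-Born polarization. The external backend
#' exchanges XYZ files with a user-configured engine command and parses a
#' single total energy.
#'
#' @param coulomb_constant Coulomb constant, kcal*A/(mol*e^2).
#' @param interior_dielectric Dielectric inside the solute (>= 1).
#' @param solvent_dielectric Solvent dielectric (>= 1); 78.5 is water at
#'   room temperature. Setting it equal to `interior_dielectric` switches
#'   solvation off (gas phase).
#' @param hbond_distance Maximum H...acceptor distance for the hydrogen-bond
#'   gate, Angstrom.
#' @param hbond_angle Minimum donor-H...acceptor angle, degrees.
#' @param engine `"classical"` or `"external"`.
#' @param external_command Command template for the external engine; the
#'   placeholders `{xyz}` and `{charge}` are substituted before the shell
#'   call.
#' @param external_pattern Regular expression with one capture group that
#'   extracts the total energy, in hartree, from the engine output.
#' @return Object of class `backend_config`.
#' @export
#' @examples
#' backend_config()                       # aqueous classical backend
#' backend_config(solvent_dielectric = 1) # gas phase
backend_config <- function(coulomb_constant = 332.0637,
                           interior_dielectric = 1.0,
                           solvent_dielectric = 78.5,
                           hbond_distance = 2.5,
                           hbond_angle = 120,
                           engine = c("classical", "external"),
                           external_command = NULL,
                           external_pattern = "TOTAL ENERGY\\s+(-?[0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?)") {
  engine <- match.arg(engine)
  if (interior_dielectric < 1 || solvent_dielectric < 1) {
    stop_pocketedda("dielectric constants must be >= 1", "argument_error")
  }
  if (hbond_distance <= 0) {
    stop_pocketedda("hbond_distance must be positive", "argument_error")
  }
  structure(list(coulomb_constant = coulomb_constant,
                 interior_dielectric = interior_dielectric,
                 solvent_dielectric = solvent_dielectric,
                 hbond_distance = hbond_distance,
                 hbond_angle = hbond_angle,
                 engine = engine,
                 external_command = external_command,
                 external_pattern = external_pattern),
            class = "backend_config")
}

#' Energy component vector
#'
#' Named numeric vector with the component set reported by the classical
#' backend: electrostatic, dispersion, repulsion, hydrogen-bond, desolvation
#' and bonded terms plus their total, all in kcal/mol. The total always
#' equals the component sum; components unavailable for a backend are `NA`.
#'
#' @param electrostatic,dispersion,repulsion,hbond,desolvation,bonded,total
#'   Component values in kcal/mol.
#' @param check Verify the total against the component sum.
#' @return Object of class `energy_components`.
#' @export
energy_components <- function(electrostatic = 0, dispersion = 0, repulsion = 0,
                              hbond = 0, desolvation = 0, bonded = 0,
                              total = NULL, check = TRUE) {
  parts <- c(electrostatic = electrostatic, dispersion = dispersion,
             repulsion = repulsion, hbond = hbond, desolvation = desolvation,
             bonded = bonded)
  if (is.null(total)) total <- sum(parts, na.rm = TRUE)
  out <- structure(c(parts, total = total), class = "energy_components")
  if (check && !anyNA(parts) && abs(sum(parts) - total) > 1e-9) {
    stop_pocketedda(sprintf("component sum %.12g != total %.12g", sum(parts), total),
                    "argument_error")
  }
  out
}

#' @export
print.energy_components <- function(x, ...) {
  cat("<energy_components> kcal/mol\n")
  print(round(unclass(x), 6))
  invisible(x)
}

# Generalized-Born pairwise screening function (Still's interpolation):
# f = sqrt(r^2 + a_i a_j exp(-r^2 / (4 a_i a_j))); f -> a at r = 0.
gb_f <- function(r, ai, aj) {
  ab <- ai * aj
  sqrt(r^2 + ab * exp(-r^2 / (4 * ab)))
}

# tau = 1/eps_in - 1/eps_out, the GB polarization prefactor.
gb_tau <- function(config) 1 / config$interior_dielectric - 1 / config$solvent_dielectric

# Hydrogen-bond gate: for each hydrogen in `atoms_h` (with donor coordinates
# provided) and each acceptor row in `atoms_acc`, TRUE where the H...A
# distance and D-H...A angle gates are both met. Returns a logical matrix
# (hydrogens x acceptors). Hydrogens without a resolvable donor never gate.
hbond_gate <- function(h_xyz, d_xyz, has_donor, acc_xyz, config) {
  nh <- nrow(h_xyz); na_ <- nrow(acc_xyz)
  gate <- matrix(FALSE, nh, na_)
  if (nh == 0 || na_ == 0) return(gate)
  for (i in seq_len(nh)) {
    if (!has_donor[i]) next
    va <- sweep(acc_xyz, 2, h_xyz[i, ])          # H -> A vectors
    da <- sqrt(rowSums(va^2))
    vd <- d_xyz[i, ] - h_xyz[i, ]                # H -> D vector
    dd <- sqrt(sum(vd^2))
    cosang <- (va %*% vd) / (da * dd)
    ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    gate[i, ] <- da <= config$hbond_distance & ang >= config$hbond_angle
  }
  gate
}

# Donor lookup: for each hydrogen index, the nearest heavy atom of the same
# fragment within 1.6 A (covalent range); prefers an explicit bond topology.
find_donors <- function(atoms, bonds = NULL) {
  h_idx <- which(atoms$is_hydrogen)
  donor <- rep(NA_integer_, length(h_idx))
  if (length(h_idx) == 0) return(list(h_idx = h_idx, donor = donor))
  heavy <- which(!atoms$is_hydrogen)
  for (k in seq_along(h_idx)) {
    i <- h_idx[k]
    if (!is.null(bonds) && nrow(bonds) > 0) {
      nb <- c(bonds$j[bonds$i == i], bonds$i[bonds$j == i])
      nb <- nb[!atoms$is_hydrogen[nb]]
      if (length(nb) > 0) { donor[k] <- nb[1]; next }
    }
    if (length(heavy) > 0) {
      d <- sqrt((atoms$x[heavy] - atoms$x[i])^2 + (atoms$y[heavy] - atoms$y[i])^2 +
                  (atoms$z[heavy] - atoms$z[i])^2)
      j <- which.min(d)
      if (d[j] <= 1.6) donor[k] <- heavy[j]
    }
  }
  list(h_idx = h_idx, donor = donor)
}

check_params_resolved <- function(frag) {
  at <- frag$atoms
  bad <- !is.finite(at$lj_epsilon) | !is.finite(at$lj_sigma) | !is.finite(at$born_radius)
  if (any(bad)) {
    stop_pocketedda(sprintf("unresolved parameters for atom(s) %s of fragment %s",
                            paste(at$name[bad], collapse = ", "), frag$label),
                    "parameter_error")
  }
  if (any(at$lj_epsilon < 0) || any(at$lj_sigma <= 0) || any(at$born_radius <= 0)) {
    stop_pocketedda(sprintf("out-of-range parameters in fragment %s", frag$label),
                    "parameter_error")
  }
  invisible(frag)
}

# Bond-graph exclusion mask for one fragment: TRUE where the pair is closer
# than 3 bonds (1-2 or 1-3) and therefore excluded from Coulomb/LJ. With no
# topology all pairs interact.
exclusion_mask <- function(n, bonds) {
  excl <- matrix(FALSE, n, n)
  if (is.null(bonds) || nrow(bonds) == 0) return(excl)
  adj <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds$i[b]; j <- bonds$j[b]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    excl[i, j] <- excl[j, i] <- TRUE
  }
  for (i in seq_len(n)) {          # 1-3 neighbors
    for (j in adj[[i]]) {
      for (k in adj[[j]]) if (k != i) excl[i, k] <- excl[k, i] <- TRUE
    }
  }
  excl
}

#' Intrafragment (monomer) energy, classical backend
#'
#' Nonbonded energy over intramolecular atom pairs separated by at least
#' three bonds (all pairs when the fragment has no topology): Coulomb
#' `k_e q_i q_j / (eps_in r)` and Lennard-Jones
#' `4 eps [(sigma/r)^12 - (sigma/r)^6]` with Lorentz-Berthelot combining;
#' harmonic bond terms `1/2 k (r - r0)^2` for topology bonds carrying
#' parameters; and the generalized-Born polarization energy (self plus pair
#' terms over all atoms, no topology exclusions), reported under
#' `desolvation`. The hydrogen-bond component is only populated for
#' cross-fragment interactions and is 0 here.
#'
#' @param fragment A [fragment()] with parameters resolved.
#' @param config A [backend_config()].
#' @return An [energy_components()] vector.
#' @export
fragment_energy <- function(fragment, config = backend_config()) {
  if (config$engine == "external") {
    tot <- external_engine_energy(fragment, config)
    return(energy_components(electrostatic = NA_real_, dispersion = NA_real_,
                             repulsion = NA_real_, hbond = NA_real_,
                             desolvation = NA_real_, bonded = NA_real_,
                             total = tot, check = FALSE))
  }
  check_params_resolved(fragment)
  at <- fragment$atoms
  n <- nrow(at)
  ke <- config$coulomb_constant / config$interior_dielectric
  tau <- gb_tau(config)
  elec <- disp <- rep_ <- bonded <- 0
  desolv <- -0.5 * config$coulomb_constant * tau * sum(at$charge^2 / at$born_radius)
  if (n > 1) {
    d <- cross_distances(at, at)
    qq <- tcrossprod(at$charge)
    sig <- outer(at$lj_sigma, at$lj_sigma, "+") / 2
    eps <- sqrt(tcrossprod(at$lj_epsilon))
    excl <- exclusion_mask(n, fragment$bonds)
    ut <- upper.tri(d)
    pair_on <- ut & !excl
    r <- d[pair_on]
    if (any(r < 1e-12)) {
      stop_pocketedda(sprintf("coincident atoms in fragment %s", fragment$label),
                      "geometry_error")
    }
    elec <- sum(ke * qq[pair_on] / r)
    sr6 <- (sig[pair_on] / r)^6
    disp <- sum(-4 * eps[pair_on] * sr6)
    rep_ <- sum(4 * eps[pair_on] * sr6^2)
    ab <- tcrossprod(at$born_radius)
    fgb <- sqrt(d^2 + ab * exp(-d^2 / (4 * ab)))
    desolv <- desolv - config$coulomb_constant * tau * sum(qq[ut] / fgb[ut])
  }
  if (!is.null(fragment$bonds) && nrow(fragment$bonds) > 0) {
    b <- fragment$bonds
    has_k <- is.finite(b$k)
    if (any(has_k)) {
      dx <- at$x[b$i] - at$x[b$j]; dy <- at$y[b$i] - at$y[b$j]; dz <- at$z[b$i] - at$z[b$j]
      rb <- sqrt(dx^2 + dy^2 + dz^2)
      bonded <- sum(0.5 * b$k[has_k] * (rb[has_k] - b$r0[has_k])^2)
    }
  }
  energy_components(electrostatic = elec, dispersion = disp, repulsion = rep_,
                    hbond = 0, desolvation = desolv, bonded = bonded)
}

#' Ligand-residue interaction energy (supermolecule definition)
#'
#' `E_int = E(A union B) - E(A) - E(B)` per component. For the pairwise
#' classical backend this reduces to the direct cross-fragment atom-pair
#' sums: Coulomb and Lennard-Jones over every (i in A, j in B) pair, and the
#' generalized-Born cross terms for desolvation. Coulomb and Lennard-Jones
#' contributions of H...acceptor pairs that satisfy the hydrogen-bond gates
#' (H...A distance and donor-H...A angle, acceptor N/O/S) are reported under
#' `hbond` instead of their parent components, so the total is independent of
#' the gates. With the external engine, three engine calls implement the
#' supermolecule formula and only the total is available.
#'
#' @param ligand,residue Atom-disjoint [fragment()]s.
#' @param config A [backend_config()].
#' @return An [energy_components()] vector.
#' @export
pair_interaction_energy <- function(ligand, residue, config = backend_config()) {
  if (config$engine == "external") {
    e_ab <- external_engine_energy(merge_fragments(ligand, residue), config)
    e_a <- external_engine_energy(ligand, config)
    e_b <- external_engine_energy(residue, config)
    return(energy_components(electrostatic = NA_real_, dispersion = NA_real_,
                             repulsion = NA_real_, hbond = NA_real_,
                             desolvation = NA_real_, bonded = NA_real_,
                             total = e_ab - e_a - e_b, check = FALSE))
  }
  check_params_resolved(ligand); check_params_resolved(residue)
  a <- ligand$atoms; b <- residue$atoms
  d <- cross_distances(a, b)
  if (any(d < 0.1)) {
    stop_pocketedda(sprintf("overlapping atoms (r < 0.1 A) between %s and %s",
                            ligand$label, residue$label), "geometry_error")
  }
  ke <- config$coulomb_constant / config$interior_dielectric
  tau <- gb_tau(config)
  qq <- outer(a$charge, b$charge)
  elec_m <- ke * qq / d
  sig <- outer(a$lj_sigma, b$lj_sigma, "+") / 2
  eps <- sqrt(outer(a$lj_epsilon, b$lj_epsilon))
  sr6 <- (sig / d)^6
  disp_m <- -4 * eps * sr6
  rep_m <- 4 * eps * sr6^2
  ab <- outer(a$born_radius, b$born_radius)
  desolv <- -config$coulomb_constant * tau * sum(qq / sqrt(d^2 + ab * exp(-d^2 / (4 * ab))))

  # Hydrogen-bond reattribution: move the H...acceptor pair terms into hbond.
  hb_mask <- matrix(FALSE, nrow(a), nrow(b))
  acc_elements <- c("N", "O", "S")
  don_a <- find_donors(a, ligand$bonds)
  acc_b <- which(b$element %in% acc_elements & !b$is_hydrogen)
  if (length(don_a$h_idx) && length(acc_b)) {
    g <- hbond_gate(coords_of(a)[don_a$h_idx, , drop = FALSE],
                    coords_of(a)[ifelse(is.na(don_a$donor), don_a$h_idx, don_a$donor), ,
                                 drop = FALSE],
                    !is.na(don_a$donor),
                    coords_of(b)[acc_b, , drop = FALSE], config)
    hb_mask[don_a$h_idx, acc_b] <- hb_mask[don_a$h_idx, acc_b] | g
  }
  don_b <- find_donors(b, residue$bonds)
  acc_a <- which(a$element %in% acc_elements & !a$is_hydrogen)
  if (length(don_b$h_idx) && length(acc_a)) {
    g <- hbond_gate(coords_of(b)[don_b$h_idx, , drop = FALSE],
                    coords_of(b)[ifelse(is.na(don_b$donor), don_b$h_idx, don_b$donor), ,
                                 drop = FALSE],
                    !is.na(don_b$donor),
                    coords_of(a)[acc_a, , drop = FALSE], config)
    hb_mask[acc_a, don_b$h_idx] <- hb_mask[acc_a, don_b$h_idx] | t(g)
  }
  hbond <- sum(elec_m[hb_mask]) + sum(disp_m[hb_mask]) + sum(rep_m[hb_mask])
  energy_components(electrostatic = sum(elec_m[!hb_mask]),
                    dispersion = sum(disp_m[!hb_mask]),
                    repulsion = sum(rep_m[!hb_mask]),
                    hbond = hbond, desolvation = desolv, bonded = 0)
}

#' Total energy via an external engine
#'
#' File-exchange adapter: writes the fragment as an XYZ file (total charge in
#' the comment line), substitutes `{xyz}` and `{charge}` into the configured
#' command template, runs it, and extracts the total energy (hartree) from
#' the output with the configured pattern's first capture group. The value is
#' returned in kcal/mol (1 hartree = 627.5095 kcal/mol). Component fields are
#' not available through this route.
#'
#' @param fragment A [fragment()].
#' @param config A [backend_config()] with `engine = "external"` and a
#'   command template set.
#' @return Total energy, kcal/mol.
#' @export
external_engine_energy <- function(fragment, config) {
  if (is.null(config$external_command)) {
    stop_pocketedda("no external engine command configured", "engine_error")
  }
  xyz <- tempfile(fileext = ".xyz")
  on.exit(unlink(xyz), add = TRUE)
  write_xyz(fragment, xyz)
  cmd <- gsub("{charge}", as.character(fragment$formal_charge),
              gsub("{xyz}", xyz, config$external_command, fixed = TRUE),
              fixed = TRUE)
  out <- suppressWarnings(system(cmd, intern = TRUE, ignore.stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop_pocketedda(sprintf("engine command failed (exit %d): %s", status, cmd),
                    "engine_error", output = out)
  }
  m <- regmatches(out, regexec(config$external_pattern, out, perl = TRUE))
  hits <- Filter(function(v) length(v) >= 2, m)
  if (length(hits) == 0) {
    stop_pocketedda(sprintf("energy pattern '%s' not found in engine output",
                            config$external_pattern),
                    "engine_error", output = out)
  }
  hartree <- as.numeric(hits[[length(hits)]][2])
  hartree * .hartree_kcal
}

# Total classical energy (elec + LJ + GB + bonded, gate-independent) and its
# analytic gradient. `free` selects the atoms whose gradient is needed; the
# returned gradient is a length(free) x 3 matrix. Used by the hydrogen
# refiner and the reference-conformer minimizer.
classical_energy_gradient <- function(atoms, bonds, config, free = seq_len(nrow(atoms))) {
  n <- nrow(atoms)
  xyz <- coords_of(atoms)
  q <- atoms$charge
  ke <- config$coulomb_constant / config$interior_dielectric
  tau <- gb_tau(config)
  excl <- exclusion_mask(n, bonds)
  energy <- -0.5 * config$coulomb_constant * tau * sum(q^2 / atoms$born_radius)
  grad <- matrix(0, length(free), 3)
  if (n > 1) {
    d <- cross_distances(atoms, atoms); diag(d) <- Inf
    qq <- tcrossprod(q)
    sig <- outer(atoms$lj_sigma, atoms$lj_sigma, "+") / 2
    eps <- sqrt(tcrossprod(atoms$lj_epsilon))
    ab <- tcrossprod(atoms$born_radius)
    inc <- !excl; diag(inc) <- FALSE
    ut <- upper.tri(d)
    r_ut <- d[ut & inc]
    energy <- energy + sum(ke * qq[ut & inc] / r_ut)
    sr6 <- (sig[ut & inc] / r_ut)^6
    energy <- energy + sum(4 * eps[ut & inc] * (sr6^2 - sr6))
    expo <- exp(-d^2 / (4 * ab))
    fgb <- sqrt(d^2 + ab * expo)
    energy <- energy - config$coulomb_constant * tau * sum(qq[ut] / fgb[ut])
    # Pairwise dE/dr assembled per free atom.
    for (gi in seq_along(free)) {
      i <- free[gi]
      js <- setdiff(seq_len(n), i)
      rij <- d[i, js]
      dEdr <- numeric(length(js))
      on_ <- inc[i, js]
      if (any(on_)) {
        dEdr[on_] <- dEdr[on_] - ke * qq[i, js][on_] / rij[on_]^2
        s6 <- (sig[i, js][on_] / rij[on_])^6
        dEdr[on_] <- dEdr[on_] + 4 * eps[i, js][on_] * (-12 * s6^2 + 6 * s6) / rij[on_]
      }
      e_ij <- expo[i, js]
      f_ij <- fgb[i, js]
      fp <- rij * (1 - e_ij / 4) / f_ij
      dEdr <- dEdr + config$coulomb_constant * tau * qq[i, js] * fp / f_ij^2
      uv <- sweep(xyz[js, , drop = FALSE], 2, xyz[i, ], "-") / rij  # i -> j unit
      grad[gi, ] <- grad[gi, ] - colSums(uv * dEdr)
    }
  }
  if (!is.null(bonds) && nrow(bonds) > 0) {
    has_k <- which(is.finite(bonds$k))
    for (b in has_k) {
      i <- bonds$i[b]; j <- bonds$j[b]
      v <- xyz[i, ] - xyz[j, ]
      rb <- sqrt(sum(v^2))
      energy <- energy + 0.5 * bonds$k[b] * (rb - bonds$r0[b])^2
      dEdr <- bonds$k[b] * (rb - bonds$r0[b])
      if (i %in% free) grad[match(i, free), ] <- grad[match(i, free), ] + dEdr * v / rb
      if (j %in% free) grad[match(j, free), ] <- grad[match(j, free), ] - dEdr * v / rb
    }
  }
  list(energy = energy, gradient = grad)
}
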