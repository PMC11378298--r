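# Run code with a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-6) return(v / n)
  }
}

random_rotation <- function() {
  # QR of a Gaussian matrix; sign-fixed to a proper rotation.
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Specification of a synthetic pocket fixture
#'
#' Desk-scale pocket with closed-form energetics: a planar five-site ring
#' ligand surrounded by a few small residue-like probes placed at given
#' radial distances in seeded random directions. Residue archetypes are 1-4
#' atoms so every reference energy stays hand-checkable: `"point-ion"` (one
#' charged atom), `"water-like"` (O + 2 H), `"methylamine-like"` (protonated
#' N + 3 H + C analog of a lysine ammonium head, 4 sites, charge +1).
#'
#' The ring is a regular pentagon in the z = 0 plane with one vertex on the
#' x axis; its site coordinates and the default charge pattern are exactly
#' mirror-symmetric under the in-plane flip `(y, z) -> (-y, -z)`, so the
#' flipped pose is energetically identical at `asymmetry = 0`. The
#' `asymmetry` offset is added to one off-axis ring site and subtracted from
#' its mirror image, giving the flip a closed-form energy difference.
#'
#' @param n_residues Number of residue probes.
#' @param distances Radial placement distances, Angstrom (recycled).
#' @param archetypes Residue archetypes (recycled over
#'   `c("point-ion", "water-like", "methylamine-like")` choices).
#' @param ion_charges Charges for point-ion probes, e (recycled; default
#'   alternates -1, +1).
#' @param ligand_charges Five per-site ring charges, e; the default
#'   `c(0.3, -0.15, 0, 0, -0.15)` is mirror-symmetric and sums to 0.
#' @param asymmetry Charge offset epsilon applied as `q2 + eps`, `q5 - eps`
#'   to the mirror-paired ring sites; must satisfy `|asymmetry| <= 0.5`.
#' @param lj Include Lennard-Jones parameters (`FALSE` keeps the fixture
#'   Coulomb/GB-only, the closed-form regime).
#' @param ring_radius Pentagon circumradius, Angstrom.
#' @param seed Integer seed fixing all placements (default 20240819).
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_residues = 3,
                         distances = 3.5 + 1.5 * seq_len(max(n_residues, 1)) - 1.5,
                         archetypes = "point-ion",
                         ion_charges = c(-1, 1),
                         ligand_charges = c(0.3, -0.15, 0, 0, -0.15),
                         asymmetry = 0, lj = FALSE,
                         ring_radius = 1.2, seed = 20240819) {
  if (abs(asymmetry) > 0.5) {
    stop_pocketedda("|asymmetry| must be <= 0.5 e", "spec_error")
  }
  if (length(ligand_charges) != 5) {
    stop_pocketedda("ligand_charges must have five entries", "spec_error")
  }
  archetypes <- match.arg(archetypes,
                          c("point-ion", "water-like", "methylamine-like"),
                          several.ok = TRUE)
  structure(list(n_residues = as.integer(n_residues),
                 distances = rep_len(distances, max(n_residues, 1)),
                 archetypes = rep_len(archetypes, max(n_residues, 1)),
                 ion_charges = ion_charges,
                 ligand_charges = ligand_charges,
                 asymmetry = asymmetry, lj = lj,
                 ring_radius = ring_radius, seed = as.integer(seed)),
            class = "fixture_spec")
}

# The five ring sites: regular pentagon, z = 0, one vertex on +x. Angles are
# written as +/- pairs so the two off-axis pairs are bitwise mirror images
# under y -> -y.
ring_sites <- function(radius) {
  ang <- c(0, 72, 144, -144, -72) * pi / 180
  cbind(x = radius * cos(ang), y = radius * sin(ang), z = 0)
}

build_ring_ligand <- function(spec) {
  xyz <- ring_sites(spec$ring_radius)
  q <- spec$ligand_charges
  q[2] <- q[2] + spec$asymmetry
  q[5] <- q[5] - spec$asymmetry
  elements <- c("C", "N", "C", "C", "N")
  at <- atom_table(elements, xyz[, 1], xyz[, 2], xyz[, 3],
                   name = paste0("R", 1:5), charge = q)
  side <- 2 * spec$ring_radius * sin(pi / 5)
  bonds <- data.frame(i = 1:5, j = c(2:5, 1), k = 300, r0 = side)
  frag <- fragment("LIG", at,
                   formal_charge = as.integer(round(sum(spec$ligand_charges))),
                   bonds = bonds)
  frag <- resolve_parameters(frag)
  if (!spec$lj) frag$atoms$lj_epsilon <- 0
  frag
}

build_archetype <- function(kind, charge) {
  if (kind == "point-ion") {
    el <- if (charge >= 0) "N" else "O"
    at <- atom_table(el, 0, 0, 0, name = "ION", charge = charge)
    return(fragment("ION", at, formal_charge = as.integer(round(charge))))
  }
  if (kind == "water-like") {
    r_oh <- 0.9572; half <- 104.52 / 2 * pi / 180
    at <- atom_table(c("O", "H", "H"),
                     x = c(0, r_oh * cos(half), r_oh * cos(half)),
                     y = c(0, r_oh * sin(half), -r_oh * sin(half)),
                     z = c(0, 0, 0),
                     name = c("O", "H1", "H2"),
                     charge = c(-0.834, 0.417, 0.417))
    return(fragment("WTR", at, formal_charge = 0L,
                    bonds = data.frame(i = c(1, 1), j = c(2, 3),
                                       k = 450, r0 = r_oh)))
  }
  # methylamine-like: ammonium-methyl head, +1, 4 heavy/hydrogen sites.
  r_nh <- 1.01; r_nc <- 1.47
  tet <- acos(-1 / 3)
  hs <- t(vapply(0:2, function(k) {
    phi <- 2 * pi * k / 3
    c(r_nh * sin(tet) * cos(phi), r_nh * sin(tet) * sin(phi), r_nh * cos(tet))
  }, numeric(3)))
  at <- atom_table(c("N", "H", "H", "H", "C"),
                   x = c(0, hs[, 1], 0), y = c(0, hs[, 2], 0),
                   z = c(0, hs[, 3], -r_nc),
                   name = c("NZ", "HZ1", "HZ2", "HZ3", "CE"),
                   charge = c(-0.30, 0.33, 0.33, 0.33, 0.31))
  fragment("AMN", at, formal_charge = 1L,
           bonds = data.frame(i = c(1, 1, 1, 1), j = c(2, 3, 4, 5),
                              k = c(434, 434, 434, 337),
                              r0 = c(r_nh, r_nh, r_nh, r_nc)))
}

translate_rotate <- function(frag, rotation, translation) {
  xyz <- coords_of(frag$atoms) %*% t(rotation)
  frag$atoms$x <- xyz[, 1] + translation[1]
  frag$atoms$y <- xyz[, 2] + translation[2]
  frag$atoms$z <- xyz[, 3] + translation[3]
  frag
}

# Closed-form pairwise Coulomb + GB cross energy between two atom tables,
# written as scalar sums straight from the defining formulas.
closed_form_cross <- function(atoms_a, atoms_b, config) {
  ke <- config$coulomb_constant / config$interior_dielectric
  tau <- gb_tau(config)
  e <- 0
  for (i in seq_len(nrow(atoms_a))) for (j in seq_len(nrow(atoms_b))) {
    dx <- atoms_a$x[i] - atoms_b$x[j]
    dy <- atoms_a$y[i] - atoms_b$y[j]
    dz <- atoms_a$z[i] - atoms_b$z[j]
    r <- sqrt(dx^2 + dy^2 + dz^2)
    qq <- atoms_a$charge[i] * atoms_b$charge[j]
    e <- e + ke * qq / r -
      config$coulomb_constant * tau * qq / gb_f(r, atoms_a$born_radius[i],
                                                atoms_b$born_radius[j])
  }
  e
}

#' Build a deterministic toy pocket
#'
#' Generates the pocket described by a [fixture_spec()]: ring ligand at the
#' origin, residue probes at the specified radial distances in seeded random
#' directions (random orientation for multi-atom probes). Placements that
#' would put any probe atom within 1.5 A of a ligand atom are redrawn. The
#' returned model carries an `expected` attribute: per-residue closed-form
#' Coulomb energies (scalar sums of `k_e q_i q_j / r`, gas phase, computed
#' inside the generator) for cross-checking the analysis path.
#'
#' @param spec A [fixture_spec()].
#' @return A [pocket_model()] with attribute `expected`
#'   (data.frame `label`, `coulomb` in kcal/mol).
#' @export
make_toy_pocket <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  ligand <- build_ring_ligand(spec)
  residues <- list()
  expected <- data.frame(label = character(), coulomb = numeric())
  ke <- .ke_coulomb
  if (spec$n_residues > 0) {
    with_seed(spec$seed, {
      ion_i <- 0
      for (r in seq_len(spec$n_residues)) {
        kind <- spec$archetypes[r]
        chg <- if (kind == "point-ion") {
          ion_i <- ion_i + 1
          spec$ion_charges[(ion_i - 1) %% length(spec$ion_charges) + 1]
        } else 0
        proto <- build_archetype(kind, chg)
        placed <- NULL
        for (try_ in 1:200) {
          dir <- random_unit_vector()
          rot <- if (nrow(proto$atoms) > 1) random_rotation() else diag(3)
          cand <- translate_rotate(proto, rot, dir * spec$distances[r])
          if (min(cross_distances(ligand$atoms, cand$atoms)) > 1.5) {
            placed <- cand
            break
          }
        }
        if (is.null(placed)) {
          stop_pocketedda(sprintf("cannot place residue %d without overlap", r),
                          "spec_error")
        }
        placed$label <- sprintf("%s%d", placed$label, r)
        placed$source_residue_ids <- data.frame(chain = "A", resnum = r)
        placed <- resolve_parameters(placed)
        if (!spec$lj) placed$atoms$lj_epsilon <- 0
        residues[[r]] <- placed
        # Closed-form gas-phase Coulomb reference, scalar double sum.
        e <- 0
        for (i in seq_len(nrow(ligand$atoms))) for (j in seq_len(nrow(placed$atoms))) {
          dx <- ligand$atoms$x[i] - placed$atoms$x[j]
          dy <- ligand$atoms$y[i] - placed$atoms$y[j]
          dz <- ligand$atoms$z[i] - placed$atoms$z[j]
          e <- e + ke * ligand$atoms$charge[i] * placed$atoms$charge[j] /
            sqrt(dx^2 + dy^2 + dz^2)
        }
        expected <- rbind(expected,
                          data.frame(label = placed$label, coulomb = e))
      }
    })
  }
  pocket <- pocket_model(ligand = ligand, residues = residues,
                         cutoff = max(spec$distances) + 1,
                         source_id = sprintf("fixture(seed=%d)", spec$seed))
  attr(pocket, "expected") <- expected
  pocket
}

# In-plane 180-degree flip of the ring ligand about its x axis: exact sign
# negation of y and z, so flipping twice is a bitwise involution.
flip_ligand <- function(frag) {
  frag$atoms$y <- -frag$atoms$y
  frag$atoms$z <- -frag$atoms$z
  frag
}

#' Dual-orientation flip fixture
#'
#' Builds two binding modes of the same pocket that differ only by a
#' 180-degree in-plane flip of the ring ligand, mimicking the two
#' orientations of a planar heteroaromatic group that low-resolution
#' electron density cannot distinguish. With `asymmetry = 0` the ring charge
#' pattern is mirror-symmetric and the two modes are energetically
#' identical; with asymmetry `eps`, the mirror-paired ring sites carry
#' `q +/- eps` and the inter-mode energy difference has a closed form
#' (difference of two scalar Coulomb + generalized-Born cross sums under
#' `config`), recorded in the result.
#'
#' @param asymmetry Charge offset, e (`|asymmetry| <= 0.5`).
#' @param seed Placement seed.
#' @param config [backend_config()] under which the closed-form delta is
#'   evaluated.
#' @param n_residues,distances,archetypes Passed to [fixture_spec()].
#' @return List of class `flip_fixture`: `mode_a`, `mode_b`
#'   ([binding_mode()]s labeled `"N-C analog"` / `"N-O analog"`),
#'   `expected_total_delta` (kcal/mol, A - B), `asymmetry`, `seed`.
#' @export
make_flip_fixture <- function(asymmetry = 0, seed = 20240819,
                              config = backend_config(),
                              n_residues = 1, distances = 4.0,
                              archetypes = "point-ion") {
  spec <- fixture_spec(n_residues = n_residues, distances = distances,
                       archetypes = archetypes, asymmetry = asymmetry,
                       seed = seed)
  pocket_a <- make_toy_pocket(spec)
  lig_b <- flip_ligand(pocket_a$ligand)
  pocket_b <- pocket_model(ligand = lig_b, residues = pocket_a$residues,
                           cutoff = pocket_a$cutoff,
                           source_id = pocket_a$source_id)
  delta <- 0
  for (res in pocket_a$residues) {
    delta <- delta + closed_form_cross(pocket_a$ligand$atoms, res$atoms, config) -
      closed_form_cross(lig_b$atoms, res$atoms, config)
  }
  structure(list(mode_a = binding_mode("N-C analog", pocket_a),
                 mode_b = binding_mode("N-O analog", pocket_b),
                 expected_total_delta = delta,
                 asymmetry = asymmetry, seed = seed),
            class = "flip_fixture")
}

#' Brute-force pair interaction oracle
#'
#' Naive scalar double loop over all cross-fragment atom pairs, written
#' independently of the vectorized backend: Coulomb, split Lennard-Jones,
#' generalized-Born cross terms, and the hydrogen-bond gate evaluated
#' triple-by-triple. Serves as the independent reference for
#' [pair_interaction_energy()] (classical backend only).
#'
#' @param a,b [fragment()]s.
#' @param config A [backend_config()] (classical).
#' @return An [energy_components()] vector.
#' @export
brute_force_pair_energy <- function(a, b, config = backend_config()) {
  if (config$engine != "classical") {
    stop_pocketedda("the brute-force oracle is classical-only", "argument_error")
  }
  ke <- config$coulomb_constant / config$interior_dielectric
  tau <- gb_tau(config)
  at_a <- a$atoms; at_b <- b$atoms
  if (nrow(at_a) == 0 || nrow(at_b) == 0) return(energy_components())

  donor_of <- function(atoms, bonds, i) {
    if (!is.null(bonds) && nrow(bonds) > 0) {
      for (r in seq_len(nrow(bonds))) {
        if (bonds$i[r] == i && !atoms$is_hydrogen[bonds$j[r]]) return(bonds$j[r])
        if (bonds$j[r] == i && !atoms$is_hydrogen[bonds$i[r]]) return(bonds$i[r])
      }
    }
    best <- NA_integer_; best_d <- 1.6
    for (j in seq_len(nrow(atoms))) {
      if (j == i || atoms$is_hydrogen[j]) next
      d <- sqrt((atoms$x[i] - atoms$x[j])^2 + (atoms$y[i] - atoms$y[j])^2 +
                  (atoms$z[i] - atoms$z[j])^2)
      if (d <= best_d) { best <- j; best_d <- d }
    }
    best
  }
  angle_deg <- function(p_d, p_h, p_a) {
    v1 <- p_d - p_h; v2 <- p_a - p_h
    c_ <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    acos(min(max(c_, -1), 1)) * 180 / pi
  }
  is_gated <- function(atoms_h, bonds_h, i_h, atoms_x, i_x) {
    if (!atoms_h$is_hydrogen[i_h]) return(FALSE)
    if (atoms_x$is_hydrogen[i_x] || !(atoms_x$element[i_x] %in% c("N", "O", "S")))
      return(FALSE)
    d <- sqrt((atoms_h$x[i_h] - atoms_x$x[i_x])^2 +
                (atoms_h$y[i_h] - atoms_x$y[i_x])^2 +
                (atoms_h$z[i_h] - atoms_x$z[i_x])^2)
    if (d > config$hbond_distance) return(FALSE)
    don <- donor_of(atoms_h, bonds_h, i_h)
    if (is.na(don)) return(FALSE)
    ang <- angle_deg(c(atoms_h$x[don], atoms_h$y[don], atoms_h$z[don]),
                     c(atoms_h$x[i_h], atoms_h$y[i_h], atoms_h$z[i_h]),
                     c(atoms_x$x[i_x], atoms_x$y[i_x], atoms_x$z[i_x]))
    ang >= config$hbond_angle
  }

  elec <- disp <- rep_ <- hb <- desolv <- 0
  for (i in seq_len(nrow(at_a))) for (j in seq_len(nrow(at_b))) {
    dx <- at_a$x[i] - at_b$x[j]; dy <- at_a$y[i] - at_b$y[j]; dz <- at_a$z[i] - at_b$z[j]
    r <- sqrt(dx^2 + dy^2 + dz^2)
    if (r < 0.1) {
      stop_pocketedda(sprintf("overlapping atoms (r < 0.1 A) between %s and %s",
                              a$label, b$label), "geometry_error")
    }
    qq <- at_a$charge[i] * at_b$charge[j]
    e_c <- ke * qq / r
    sg <- (at_a$lj_sigma[i] + at_b$lj_sigma[j]) / 2
    ep <- sqrt(at_a$lj_epsilon[i] * at_b$lj_epsilon[j])
    sr6 <- (sg / r)^6
    e_d <- -4 * ep * sr6
    e_r <- 4 * ep * sr6^2
    desolv <- desolv - config$coulomb_constant * tau * qq /
      gb_f(r, at_a$born_radius[i], at_b$born_radius[j])
    gated <- is_gated(at_a, a$bonds, i, at_b, j) ||
      is_gated(at_b, b$bonds, j, at_a, i)
    if (gated) hb <- hb + e_c + e_d + e_r
    else { elec <- elec + e_c; disp <- disp + e_d; rep_ <- rep_ + e_r }
  }
  energy_components(electrostatic = elec, dispersion = disp, repulsion = rep_,
                    hbond = hb, desolvation = desolv, bonded = 0)
}
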