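test_that("Coulomb, Lennard-Jones and Born terms match their closed forms", {
  cfg <- gas_config()
  # two +1 charges at k_e/100 A apart -> exactly +100 kcal/mol
  a <- ion_fragment(1)
  b <- ion_fragment(1, x = 3.320637)
  expect_equal(pair_interaction_energy(a, b, cfg)[["electrostatic"]], 100,
               tolerance = 1e-12)
  bm <- ion_fragment(-1, x = 3.320637, element = "O")
  expect_equal(pair_interaction_energy(a, bm, cfg)[["total"]], -100,
               tolerance = 1e-12)
  # LJ: zero at r = sigma, minimum -eps at r = 2^(1/6) sigma
  lj <- function(r) {
    f1 <- resolve_parameters(fragment("A", atom_table("C", 0, 0, 0)))
    f2 <- resolve_parameters(fragment("B", atom_table("C", r, 0, 0)))
    e <- pair_interaction_energy(f1, f2, cfg)
    e[["dispersion"]] + e[["repulsion"]]
  }
  sigma <- default_element_params()$lj_sigma[2]
  eps <- default_element_params()$lj_epsilon[2]
  expect_equal(lj(sigma), 0, tolerance = 1e-12)
  rmin <- 2^(1/6) * sigma
  expect_equal(lj(rmin), -eps, tolerance = 1e-12)
  expect_true(lj(rmin - 1e-4) > lj(rmin) && lj(rmin + 1e-4) > lj(rmin))
  # Born self term: q = +1, a = 2 A, eps_out = 78.5
  solv <- backend_config()
  ion <- ion_fragment(1, born_radius = 2)
  want <- -0.5 * 332.0637 * (1 - 1 / 78.5) * 1 / 2
  got <- fragment_energy(ion, solv)[["desolvation"]]
  expect_equal(got, want, tolerance = 1e-12)
  expect_lt(abs(got - want) / abs(want), 1e-4)
})

test_that("single neutral atoms and far-apart fragments have no energy", {
  cfg <- backend_config()
  lone <- resolve_parameters(fragment("A", atom_table("C", 0, 0, 0)))
  e <- fragment_energy(lone, cfg)
  expect_equal(unclass(e), unclass(energy_components()), tolerance = 1e-15)
  a <- resolve_parameters(fragment("A", atom_table(c("C", "O"), c(0, 1.2), c(0, 0), c(0, 0))))
  b <- resolve_parameters(fragment("B", atom_table(c("N", "H"), c(1000, 1001), c(0, 0), c(0, 0))))
  expect_lt(abs(pair_interaction_energy(a, b, cfg)[["total"]]), 1e-6)
})

test_that("pair energies are symmetric and rigid-motion invariant", {
  cfg <- backend_config()
  set.seed(101)
  for (s in c(31, 32, 33)) {
    pk <- make_toy_pocket(mixed_spec(seed = s))
    for (res in pk$residues) {
      ab <- pair_interaction_energy(pk$ligand, res, cfg)
      ba <- pair_interaction_energy(res, pk$ligand, cfg)
      expect_equal(unclass(ab), unclass(ba), tolerance = 1e-12)
    }
    # same rigid motion applied to every fragment leaves all energies put
    m <- matrix(stats::rnorm(9), 3, 3); q <- qr.Q(qr(m))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    t_ <- stats::rnorm(3, sd = 5)
    move <- function(f) {
      xyz <- as.matrix(f$atoms[, c("x", "y", "z")]) %*% t(q)
      f$atoms$x <- xyz[, 1] + t_[1]; f$atoms$y <- xyz[, 2] + t_[2]
      f$atoms$z <- xyz[, 3] + t_[3]; f
    }
    e0 <- pair_interaction_energy(pk$ligand, pk$residues[[1]], cfg)
    e1 <- pair_interaction_energy(move(pk$ligand), move(pk$residues[[1]]), cfg)
    expect_lt(abs(e0[["total"]] - e1[["total"]]), 1e-9)
    f0 <- fragment_energy(pk$residues[[2]], cfg)
    f1 <- fragment_energy(move(pk$residues[[2]]), cfg)
    expect_lt(abs(f0[["total"]] - f1[["total"]]), 1e-9)
  }
})

test_that("the supermolecule formula is additive over residue unions", {
  cfg <- backend_config()
  pk <- make_toy_pocket(mixed_spec(seed = 47))
  r12 <- merge_fragments(pk$residues[[1]], pk$residues[[2]])
  lhs <- pair_interaction_energy(pk$ligand, r12, cfg)
  e1 <- pair_interaction_energy(pk$ligand, pk$residues[[1]], cfg)
  e2 <- pair_interaction_energy(pk$ligand, pk$residues[[2]], cfg)
  expect_equal(lhs[["total"]], e1[["total"]] + e2[["total"]], tolerance = 1e-8)
  # and equals the explicit supermolecule difference of fragment energies
  un <- merge_fragments(pk$ligand, pk$residues[[1]])
  direct <- fragment_energy(un, cfg)[["total"]] -
    fragment_energy(pk$ligand, cfg)[["total"]] -
    fragment_energy(pk$residues[[1]], cfg)[["total"]]
  expect_equal(e1[["total"]], direct, tolerance = 1e-8)
})

test_that("hydrogen-bond reattribution moves energy but conserves the total", {
  cfg <- backend_config()
  # linear O-H...O geometry: donor water points its H at an acceptor anion
  donor <- fragment("DON", atom_table(c("O", "H"), c(0, 0.96), c(0, 0), c(0, 0),
                                      charge = c(-0.4, 0.4)),
                    bonds = data.frame(i = 1, j = 2, k = NA_real_, r0 = NA_real_))
  donor <- resolve_parameters(donor)
  acceptor <- ion_fragment(-1, x = 2.8, element = "O", label = "ACC")
  e <- pair_interaction_energy(donor, acceptor, cfg)
  expect_true(e[["hbond"]] < 0)              # attractive H...A pair captured
  gate_off <- backend_config(hbond_distance = 1e-6)
  e_off <- pair_interaction_energy(donor, acceptor, gate_off)
  expect_equal(e_off[["hbond"]], 0)
  expect_equal(e[["total"]], e_off[["total"]], tolerance = 1e-12)
  sum_parent <- function(x) x[["electrostatic"]] + x[["dispersion"]] +
    x[["repulsion"]] + x[["hbond"]]
  expect_equal(sum_parent(e), sum_parent(e_off), tolerance = 1e-12)
  # bending the contact below 120 degrees un-gates it
  bent <- acceptor
  bent$atoms$x <- 0.96; bent$atoms$y <- 1.9   # ~90 degrees at the H
  expect_equal(pair_interaction_energy(donor, bent, cfg)[["hbond"]], 0)
})

test_that("overlapping atoms and unresolved parameters are refused", {
  cfg <- backend_config()
  a <- ion_fragment(1)
  b <- ion_fragment(-1, x = 0.05, element = "O")
  expect_error(pair_interaction_energy(a, b, cfg),
               class = "pocketedda_geometry_error")
  raw <- fragment("X", atom_table("C", 0, 0, 0))   # never resolved
  expect_error(fragment_energy(raw, cfg), class = "pocketedda_parameter_error")
})

test_that("the external-engine adapter parses, converts and reports failures", {
  frag <- resolve_parameters(fragment("A", atom_table("C", 0, 0, 0)))
  cfg <- backend_config(engine = "external",
                        external_command = mock_engine(c("1" = -0.5)))
  expect_equal(external_engine_energy(frag, cfg), -0.5 * 627.5095,
               tolerance = 1e-12)
  # unmatched pattern -> engine error carrying the captured output
  bad <- backend_config(engine = "external",
                        external_command = mock_engine(c("2" = -0.5)))
  err <- expect_error(external_engine_energy(frag, bad),
                      class = "pocketedda_engine_error")
  expect_false(is.null(err$output))
  # command failure -> engine error
  fail <- backend_config(engine = "external", external_command = "false # {xyz}")
  expect_error(external_engine_energy(frag, fail),
               class = "pocketedda_engine_error")
  expect_error(external_engine_energy(frag, backend_config(engine = "external")),
               class = "pocketedda_engine_error")
})

test_that("supermolecule interaction energies assemble from engine totals", {
  # E(LR) - E(L) - E(R) = (-1.0) - (-0.4) - (-0.5) Eh = -0.1 Eh
  lig <- resolve_parameters(fragment("L", atom_table("C", 0, 0, 0)))
  res <- resolve_parameters(
    fragment("R", atom_table(c("N", "O"), c(4, 5), c(0, 0), c(0, 0))))
  cfg <- backend_config(engine = "external",
                        external_command = mock_engine(c("1" = -0.4, "2" = -0.5,
                                                         "3" = -1.0)))
  e <- pair_interaction_energy(lig, res, cfg)
  expect_equal(e[["total"]], -0.1 * 627.5095, tolerance = 1e-9)
  expect_true(is.na(e[["electrostatic"]]))   # components honestly unset
})
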