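stretched_bond <- function(x2) {
  f <- resolve_parameters(
    fragment("TOY", atom_table(c("C", "C"), c(0, x2), c(0, 0), c(0, 0)),
             bonds = data.frame(i = 1, j = 2, k = 300, r0 = 1.0)))
  f$atoms$lj_epsilon <- 0
  f
}

test_that("deformation energy is the closed-form strain of a stretched bond", {
  cfg <- gas_config()
  expect_equal(deformation_energy(stretched_bond(1.1), stretched_bond(1.0), cfg),
               1.5, tolerance = 1e-12)     # 1/2 * 300 * 0.1^2
  expect_equal(deformation_energy(stretched_bond(1.1), stretched_bond(1.1), cfg),
               0, tolerance = 1e-12)       # bound == reference
  # reference from the backend's own minimization -> non-negative
  auto <- deformation_energy(stretched_bond(1.1), NULL, cfg)
  expect_equal(auto, 1.5, tolerance = 1e-6)
  expect_gte(auto, -1e-6)
  fx <- make_flip_fixture(asymmetry = 0.2, seed = 55)
  d <- deformation_energy(fx$mode_a$pocket$ligand, NULL, backend_config())
  expect_gte(d, -1e-6)
  expect_error(deformation_energy(stretched_bond(1.1),
                                  resolve_parameters(fragment("X", atom_table("C", 0, 0, 0)))),
               class = "pocketedda_argument_error")
})

test_that("decomposition components always sum to the score", {
  cfg <- backend_config()
  for (s in c(5, 6, 7)) {
    fx <- make_flip_fixture(asymmetry = 0.1, seed = s, n_residues = 3,
                            distances = c(4, 5, 6),
                            archetypes = c("point-ion", "water-like",
                                           "methylamine-like"))
    rep <- edda_decompose(fx$mode_a, cfg)
    expect_equal(rep$score, sum(rep$components), tolerance = 1e-9)
    expect_equal(rep$score, rep$interaction + rep$desolvation + rep$deformation,
                 tolerance = 1e-9)
    # per-residue desolvation shares sum exactly to the pocket-level term
    expect_equal(sum(rep$map$pairs$desolvation), rep$desolvation,
                 tolerance = 1e-9)
  }
})

test_that("a chargeless, LJ-free pocket decomposes to all zeros", {
  spec <- fixture_spec(n_residues = 2, distances = c(4, 5),
                       ligand_charges = rep(0, 5), ion_charges = 0, lj = FALSE)
  pk <- make_toy_pocket(spec)
  rep <- edda_decompose(binding_mode("null", pk), backend_config())
  expect_equal(rep$interaction, 0, tolerance = 1e-12)
  expect_equal(rep$desolvation, 0, tolerance = 1e-12)
  expect_equal(rep$deformation, 0, tolerance = 1e-9)
  expect_equal(rep$score, 0, tolerance = 1e-9)
})

test_that("a symmetric flip fixture gives componentwise-equal modes and 'dual'", {
  fx <- make_flip_fixture(asymmetry = 0, seed = 12, n_residues = 2,
                          distances = c(4, 5.2),
                          archetypes = c("point-ion", "water-like"))
  cfg <- backend_config()
  cmp <- compare_binding_modes(fx$mode_a, fx$mode_b, cfg)
  comp_cols <- c("electrostatic", "dispersion", "repulsion", "hbond",
                 "desolvation", "total")
  expect_true(max(abs(as.matrix(cmp$delta[, comp_cols]))) <= 1e-9)
  expect_lt(abs(cmp$total_delta), 1e-9)
  expect_equal(cmp$verdict, "dual")
})

test_that("an asymmetric flip reproduces the generator's closed-form delta", {
  cfg <- backend_config()
  fx <- make_flip_fixture(asymmetry = 0.1, seed = 9, config = cfg)
  cmp <- compare_binding_modes(fx$mode_a, fx$mode_b, cfg)
  expect_equal(cmp$total_delta, fx$expected_total_delta, tolerance = 1e-6)
  # identical pockets passed as both modes -> all deltas 0, dual
  same <- compare_binding_modes(fx$mode_a, fx$mode_a, cfg)
  expect_equal(same$total_delta, 0, tolerance = 1e-12)
  expect_equal(same$verdict, "dual")
})

test_that("comparative deltas are antisymmetric under swapping the modes", {
  cfg <- backend_config()
  fx <- make_flip_fixture(asymmetry = 0.15, seed = 21, n_residues = 2,
                          distances = c(4, 5), config = cfg)
  ab <- compare_binding_modes(fx$mode_a, fx$mode_b, cfg)
  ba <- compare_binding_modes(fx$mode_b, fx$mode_a, cfg)
  expect_equal(ab$total_delta, -ba$total_delta, tolerance = 1e-10)
  comp_cols <- c("electrostatic", "dispersion", "repulsion", "hbond",
                 "desolvation", "total")
  m_ab <- as.matrix(ab$delta[order(ab$delta$label), comp_cols])
  m_ba <- as.matrix(ba$delta[order(ba$delta$label), comp_cols])
  expect_equal(m_ab, -m_ba, tolerance = 1e-10)
})

test_that("a large asymmetry defeats 'dual' and names the preferred mode", {
  cfg <- backend_config()
  fx <- make_flip_fixture(asymmetry = 0.5, seed = 31, config = cfg)
  cmp <- compare_binding_modes(fx$mode_a, fx$mode_b, cfg, threshold = 0.05)
  expect_true(cmp$verdict %in% c(fx$mode_a$label, fx$mode_b$label))
  preferred <- if (cmp$total_delta < 0) fx$mode_a$label else fx$mode_b$label
  expect_equal(cmp$verdict, preferred)
  # with a generous threshold the same pair is called dual
  wide <- compare_binding_modes(fx$mode_a, fx$mode_b, cfg,
                                threshold = abs(cmp$total_delta) + 1)
  expect_equal(wide$verdict, "dual")
})

test_that("modes with differing residue fragments are refused by name", {
  fx <- make_flip_fixture(asymmetry = 0, seed = 41, n_residues = 2,
                          distances = c(4, 5))
  other <- fx$mode_b
  other$pocket$residues[[1]]$atoms$charge <-
    other$pocket$residues[[1]]$atoms$charge + 0.5
  other$pocket$residues[[1]]$formal_charge <-
    as.integer(round(sum(other$pocket$residues[[1]]$atoms$charge)))
  err <- expect_error(compare_binding_modes(fx$mode_a, other, backend_config()),
                      class = "pocketedda_comparison_error")
  expect_match(conditionMessage(err), fx$mode_a$pocket$residues[[1]]$label)
})
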