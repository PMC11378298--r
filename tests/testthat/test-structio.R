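test_that("PDB parsing preserves atoms, residue identity and hetero groups", {
  p <- write_pdb(c(
    pdb_line(1, "N", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "ALA", "A", 1, 1.5, 0, 0, elem = "C"),
    pdb_line(3, "C1", "LIG", "A", 900, 4, 0, 0, rec = "HETATM", elem = "C")
  ))
  s <- read_structure(p)
  expect_equal(nrow(s$atoms), 3)
  d <- sqrt(sum((s$atoms[2, c("x", "y", "z")] - s$atoms[1, c("x", "y", "z")])^2))
  expect_equal(d, 1.5)
  expect_equal(s$atoms$resnum, c(1, 1, 900))
  expect_equal(s$atoms$resname, c("ALA", "ALA", "LIG"))
  expect_equal(ligand_candidates(s), "LIG")
})

test_that("malformed coordinate fields raise a format error naming the line", {
  p <- write_pdb(c(
    pdb_line(1, "N", "ALA", "A", 1, 0, 0, 0),
    sub("0\\.000", "0.0xy", pdb_line(2, "CA", "ALA", "A", 1, 0, 0, 0, elem = "C"))
  ))
  err <- expect_error(read_structure(p), class = "pocketedda_format_error")
  expect_match(conditionMessage(err), "line 2")
  expect_error(read_structure(write_pdb(character(0))),
               class = "pocketedda_empty_structure_error")
})

test_that("altLoc conformers collapse to the highest occupancy, ties to first", {
  p <- write_pdb(c(
    pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.4, altloc = "A", elem = "C"),
    pdb_line(2, "CA", "ALA", "A", 1, 9, 0, 0, occ = 0.6, altloc = "B", elem = "C"),
    pdb_line(3, "CB", "ALA", "A", 1, 1, 0, 0, occ = 0.5, altloc = "A", elem = "C"),
    pdb_line(4, "CB", "ALA", "A", 1, 8, 0, 0, occ = 0.5, altloc = "B", elem = "C")
  ))
  s <- read_structure(p)
  expect_equal(nrow(s$atoms), 2)
  expect_equal(s$atoms$x[s$atoms$name == "CA"], 9)  # higher occupancy wins
  expect_equal(s$atoms$x[s$atoms$name == "CB"], 1)  # tie -> first listed
})

test_that("XYZ and SDF ligands load with file atom order and topology", {
  xyz <- system.file("extdata", "toy_ligand.xyz", package = "pocketedda")
  f <- read_ligand(xyz)
  expect_s3_class(f, "fragment")
  expect_equal(f$atoms$element, c("C", "N", "O"))
  expect_equal(f$atoms$charge, c(0, 0, 0))
  sdf <- system.file("extdata", "toy_ligand.sdf", package = "pocketedda")
  g <- read_ligand(sdf)
  expect_equal(g$atoms$element, c("C", "N", "O"))
  expect_equal(nrow(g$bonds), 2)
  expect_equal(g$atoms$x, f$atoms$x)
  expect_true(all(is.finite(g$atoms$lj_sigma)))
})

test_that("SDF counts-line mismatch and bad XYZ headers are format errors", {
  sdf <- system.file("extdata", "toy_ligand.sdf", package = "pocketedda")
  lines <- readLines(sdf)
  bad <- tempfile(fileext = ".sdf")
  writeLines(lines[-6], bad)  # drop one atom line, keep "3" in the counts
  expect_error(read_ligand(bad), class = "pocketedda_format_error")
  badxyz <- tempfile(fileext = ".xyz")
  writeLines(c("5", "comment", "C 0 0 0"), badxyz)
  expect_error(read_ligand(badxyz, format = "xyz"),
               class = "pocketedda_format_error")
})

test_that("interaction maps round-trip through the versioned report format", {
  fx <- make_toy_pocket(mixed_spec(seed = 91))
  map <- in_pocket_analysis(fx, backend_config(), refine = FALSE)
  path <- tempfile(fileext = ".csv")
  write_interaction_map(map, path)
  expect_equal(readLines(path, n = 1), "# pocketedda-map v1")
  back <- read_interaction_map(path)
  num_cols <- c("total", "electrostatic", "dispersion", "repulsion", "hbond",
                "desolvation", "closest_contact")
  want <- map$pairs[order(map$pairs$chain, map$pairs$resnum), num_cols]
  expect_true(max(abs(as.matrix(want) - as.matrix(back$pairs[, num_cols]))) <= 1e-12)
  expect_equal(back$pairs$label,
               map$pairs$label[order(map$pairs$chain, map$pairs$resnum)])
  expect_equal(back$summed[["total"]], map$summed[["total"]], tolerance = 1e-12)
  # second write is byte-identical: serialization is idempotent
  path2 <- tempfile(fileext = ".csv")
  write_interaction_map(back, path2)
  expect_identical(readLines(path)[-2], readLines(path2)[-2])
})

test_that("an empty map writes header plus zero-sum footer only", {
  empty <- in_pocket_analysis(make_toy_pocket(fixture_spec(n_residues = 0)),
                              backend_config())
  path <- tempfile(fileext = ".csv")
  write_interaction_map(empty, path)
  lines <- readLines(path)
  expect_length(lines, 4)  # version, mode, header, footer
  back <- read_interaction_map(path)
  expect_equal(nrow(back$pairs), 0)
  expect_equal(back$summed[["total"]], 0)
})

test_that("parameter tables override element defaults and reject bad rows", {
  tab <- read_parameter_table(system.file("extdata", "example_params.txt",
                                          package = "pocketedda"))
  expect_equal(tab$born_radius[tab$element == "O"], 1.52)
  custom <- tempfile()
  writeLines(c("# custom", "C 0.2 3.9 2.5"), custom)
  f <- fragment("X", atom_table(c("C", "N"), c(0, 2), c(0, 0), c(0, 0)))
  f <- resolve_parameters(f, read_parameter_table(custom))
  expect_equal(f$atoms$lj_sigma, c(3.9, 3.25))     # C overridden, N default
  expect_equal(f$atoms$born_radius, c(2.5, 1.55))
  bad <- tempfile()
  writeLines("C -0.2 3.9 2.5", bad)
  expect_error(read_parameter_table(bad), class = "pocketedda_parameter_error")
})
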