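toy_structure <- function() {
  read_structure(system.file("extdata", "toy_tripeptide.pdb",
                             package = "pocketedda"))
}

test_that("residue selection uses an inclusive any-atom distance cutoff", {
  # one ligand atom at the origin; single-atom residues at 4.9 / 5.0 / 5.1 A
  lig <- ion_fragment(0, 0, 0, 0, label = "LIG")
  p <- write_pdb(c(
    pdb_line(1, "CB", "GLY", "A", 1, 4.9, 0, 0, elem = "C"),
    pdb_line(2, "CB", "GLY", "A", 2, 0, 5.0, 0, elem = "C"),
    pdb_line(3, "CB", "GLY", "A", 3, 0, 0, 5.1, elem = "C")
  ))
  s <- read_structure(p)
  sel <- select_pocket_residues(s, lig, cutoff = 5.0)
  expect_equal(sel$resnum, c(1, 2))          # 5.0 included, 5.1 excluded
  expect_equal(sel$min_distance, c(4.9, 5.0))
  all_of_them <- select_pocket_residues(s, lig, cutoff = 100)
  expect_equal(all_of_them$resnum, 1:3)
})

test_that("selection is monotone in the cutoff and excludes waters by default", {
  s <- toy_structure()
  lig <- extract_ligand(s, "LIG")
  prev <- character(0)
  for (cutoff in c(2, 3, 4, 5, 8)) {
    sel <- select_pocket_residues(s, lig, cutoff = cutoff)
    ids <- paste(sel$chain, sel$resnum)
    expect_true(all(prev %in% ids))
    prev <- ids
  }
  expect_false("HOH" %in% select_pocket_residues(s, lig, cutoff = 8)$resname)
  with_w <- select_pocket_residues(s, lig, cutoff = 8, include_waters = TRUE)
  expect_true("HOH" %in% with_w$resname)
})

test_that("capping adds one hydrogen per severed peptide bond and fixes charge", {
  s <- toy_structure()
  lig <- extract_ligand(s, "LIG")
  sel <- select_pocket_residues(s, lig, cutoff = 6)
  pk <- cut_pocket(s, sel, lig)
  caps <- vapply(pk$residues, function(f) sum(f$atoms$is_cap), numeric(1))
  labels <- vapply(pk$residues, function(f) f$label, "")
  expect_equal(caps[labels == "ALA2"], 2, ignore_attr = TRUE)  # middle residue
  expect_equal(caps[labels == "ALA1"], 1, ignore_attr = TRUE)  # N-terminal
  expect_equal(caps[labels == "ALA3"], 1, ignore_attr = TRUE)  # C-terminal
  for (f in pk$residues) {
    expect_true(all(f$atoms$is_hydrogen[f$atoms$is_cap]))
    expect_equal(sum(f$atoms$charge), f$formal_charge, tolerance = 1e-12)
    # heavy atoms bitwise unchanged from the input structure
    orig <- s$atoms[s$atoms$resnum == f$source_residue_ids$resnum[1] &
                      !s$atoms$het, , drop = FALSE]
    heavy <- f$atoms[!f$atoms$is_cap, , drop = FALSE]
    expect_identical(heavy$x, orig$x)
    expect_identical(heavy$y, orig$y)
    expect_identical(heavy$z, orig$z)
  }
  # cap hydrogens sit at the standard X-H distance along the severed bond
  ala2 <- pk$residues[[which(labels == "ALA2")]]
  n_pos <- unlist(ala2$atoms[ala2$atoms$name == "N", c("x", "y", "z")])
  hn <- unlist(ala2$atoms[ala2$atoms$name == "HCAP_N", c("x", "y", "z")])
  expect_equal(sqrt(sum((hn - n_pos)^2)), 1.01, tolerance = 1e-9)
  c_pos <- unlist(ala2$atoms[ala2$atoms$name == "C", c("x", "y", "z")])
  hc <- unlist(ala2$atoms[ala2$atoms$name == "HCAP_C", c("x", "y", "z")])
  expect_equal(sqrt(sum((hc - c_pos)^2)), 1.09, tolerance = 1e-9)
})

test_that("residues missing backbone atoms fail capping with their name", {
  p <- write_pdb(c(
    pdb_line(1, "N", "ALA", "A", 1, 3, 0, 0),
    pdb_line(2, "CA", "ALA", "A", 1, 4.4, 0, 0, elem = "C")
  ))
  s <- read_structure(p)
  lig <- ion_fragment(0, 0, 0, 0, label = "LIG")
  err <- expect_error(
    cut_pocket(s, data.frame(chain = "A", resnum = 1), lig),
    class = "pocketedda_capping_error")
  expect_match(conditionMessage(err), "ALA1")
})

test_that("pair enumeration is a closest-contact-ordered bijection on residues", {
  pk <- make_toy_pocket(mixed_spec(seed = 17))
  pairs <- enumerate_pairs(pk)
  expect_equal(nrow(pairs), length(pk$residues))
  expect_setequal(pairs$index, seq_along(pk$residues))
  # brute-force closest contacts agree and the ordering is ascending
  bf <- vapply(pk$residues, function(f) {
    best <- Inf
    for (i in seq_len(nrow(pk$ligand$atoms))) for (j in seq_len(nrow(f$atoms))) {
      d <- sqrt(sum((unlist(pk$ligand$atoms[i, c("x", "y", "z")]) -
                       unlist(f$atoms[j, c("x", "y", "z")]))^2))
      best <- min(best, d)
    }
    best
  }, numeric(1))
  expect_equal(pairs$closest_contact, sort(bf), tolerance = 1e-12)
  expect_equal(pairs$closest_contact, bf[pairs$index], tolerance = 1e-12)
  empty <- enumerate_pairs(make_toy_pocket(fixture_spec(n_residues = 0)))
  expect_equal(nrow(empty), 0)
})

test_that("pocket models reject duplicate fragments and round-trip as JSON", {
  pk <- make_toy_pocket(mixed_spec(seed = 23))
  expect_error(pocket_model(pk$ligand, c(pk$residues, pk$residues[1])),
               class = "pocketedda_argument_error")
  path <- tempfile(fileext = ".json")
  write_pocket_json(pk, path)
  back <- read_pocket_json(path)
  expect_equal(length(back$residues), length(pk$residues))
  expect_equal(back$ligand$atoms, pk$ligand$atoms, tolerance = 1e-12)
  for (k in seq_along(pk$residues)) {
    expect_equal(back$residues[[k]]$atoms, pk$residues[[k]]$atoms, tolerance = 1e-12)
    expect_equal(back$residues[[k]]$formal_charge, pk$residues[[k]]$formal_charge)
  }
})
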