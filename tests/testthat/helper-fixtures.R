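# Shared test helpers: tiny fragments, gas-phase config, PDB line writer,
# and a scripted stand-in engine for the external-backend adapter.

gas_config <- function(...) backend_config(solvent_dielectric = 1, ...)

# Monatomic probe with LJ switched off: pure Coulomb (+ GB if solvated).
ion_fragment <- function(charge, x = 0, y = 0, z = 0, element = "N",
                         born_radius = NA_real_, label = "ION") {
  f <- fragment(label, atom_table(element, x, y, z, charge = charge,
                                  born_radius = born_radius),
                formal_charge = as.integer(round(charge)))
  f <- resolve_parameters(f)
  f$atoms$lj_epsilon <- 0
  f
}

# Fixed-column PDB ATOM/HETATM line.
pdb_line <- function(serial, name, resn, chain, resno, x, y, z,
                     rec = "ATOM", occ = 1, elem = substr(name, 1, 1),
                     altloc = " ") {
  sprintf("%-6s%5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, name, altloc, resn, chain, resno, x, y, z, occ, 0, elem)
}

write_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# Scripted engine: replies with a fixed energy keyed on the atom count of the
# incoming XYZ file, so monomers and the supermolecule get distinct totals.
mock_engine <- function(energies_by_natoms) {
  script <- tempfile(fileext = ".sh")
  cases <- paste(sprintf("  %s) echo \"TOTAL ENERGY %s Eh\";;",
                         names(energies_by_natoms),
                         vapply(energies_by_natoms, format, "")),
                 collapse = "\n")
  writeLines(c("#!/bin/sh", "n=$(head -1 \"$1\" | tr -d ' ')",
               "case $n in", cases,
               "  *) echo \"no energy for $n atoms\"; exit 1;;", "esac"),
             script)
  Sys.chmod(script, "0755")
  paste("sh", script, "{xyz}")
}

# Random rigid-body motion applied to a fragment (test-local implementation).
rigid_motion <- function(frag) {
  m <- matrix(stats::rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  t_ <- stats::rnorm(3, sd = 5)
  xyz <- as.matrix(frag$atoms[, c("x", "y", "z")]) %*% t(q)
  frag$atoms$x <- xyz[, 1] + t_[1]
  frag$atoms$y <- xyz[, 2] + t_[2]
  frag$atoms$z <- xyz[, 3] + t_[3]
  frag
}

mixed_spec <- function(seed, n = 3, lj = TRUE, asymmetry = 0) {
  fixture_spec(n_residues = n, distances = c(3.8, 4.6, 5.5)[seq_len(n)],
               archetypes = c("point-ion", "water-like", "methylamine-like")[seq_len(n)],
               lj = lj, asymmetry = asymmetry, seed = seed)
}
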