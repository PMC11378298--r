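#' Atom table constructor
#'
#' Builds the atom data.frame used inside every [fragment()]. One row per
#' atom: element symbol, atom name, Cartesian coordinates (Angstrom), partial
#' charge (e), Lennard-Jones parameters (kcal/mol, Angstrom), Born radius
#' (Angstrom), and the hydrogen / cap / mobility flags. `mobile` may only be
#' `TRUE` for hydrogens: heavy atoms are never moved by refinement.
#'
#' @param element Character vector of element symbols.
#' @param x,y,z Numeric coordinates in Angstrom.
#' @param name Atom names; defaults to `element` + index.
#' @param charge Partial charges in elementary charge units (default 0).
#' @param lj_epsilon,lj_sigma,born_radius Per-atom parameters; `NA` means
#'   "resolve from the element table" (see [resolve_parameters()]).
#' @param is_cap Logical, `TRUE` for cap hydrogens added by [cut_pocket()].
#' @param mobile Logical; defaults to `TRUE` for hydrogens, `FALSE` otherwise.
#' @return data.frame with the canonical atom columns.
#' @export
atom_table <- function(element, x, y, z,
                       name = NULL, charge = 0,
                       lj_epsilon = NA_real_, lj_sigma = NA_real_,
                       born_radius = NA_real_,
                       is_cap = FALSE, mobile = NULL) {
  n <- length(element)
  element <- toupper(element)
  known <- default_element_params()$element
  if (!all(element %in% known)) {
    bad <- setdiff(unique(element), known)
    stop_pocketedda(sprintf("unrecognized element symbol(s): %s",
                            paste(bad, collapse = ", ")), "argument_error")
  }
  if (is.null(name)) name <- paste0(element, seq_len(n))
  is_h <- element == "H"
  if (is.null(mobile)) mobile <- is_h
  if (any(mobile & !is_h)) {
    stop_pocketedda("only hydrogens may be flagged mobile", "argument_error")
  }
  data.frame(
    element = element, name = as.character(name),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    charge = rep_len(as.numeric(charge), n),
    lj_epsilon = rep_len(as.numeric(lj_epsilon), n),
    lj_sigma = rep_len(as.numeric(lj_sigma), n),
    born_radius = rep_len(as.numeric(born_radius), n),
    is_hydrogen = is_h,
    is_cap = rep_len(as.logical(is_cap), n),
    mobile = rep_len(as.logical(mobile), n),
    stringsAsFactors = FALSE
  )
}

#' Capped molecular fragment
#'
#' A fragment is one chemically consistent unit of the pocket model: the
#' ligand, or one (capped) residue. It carries an ordered atom table, a formal
#' charge, the source residue identifiers, and optionally a bond topology used
#' for intramolecular exclusions and toy harmonic bond terms.
#'
#' @param label Fragment label, e.g. `"LYS85"` or `"LIG"`.
#' @param atoms Atom data.frame from [atom_table()].
#' @param formal_charge Integer formal charge in e.
#' @param source_residue_ids data.frame with columns `chain`, `resnum`
#'   (empty for a ligand).
#' @param bonds Optional topology: data.frame with columns `i`, `j` (1-based
#'   atom indices) and optional `k` (kcal/mol/A^2), `r0` (Angstrom) harmonic
#'   parameters. Bonds with `NA` `k` contribute no energy but still define
#'   connectivity for nonbonded exclusions and hydrogen-donor lookup.
#' @return Object of class `fragment`.
#' @export
fragment <- function(label, atoms, formal_charge = 0L,
                     source_residue_ids = NULL, bonds = NULL) {
  if (!is.data.frame(atoms) || nrow(atoms) == 0) {
    stop_pocketedda(sprintf("fragment %s has an empty atom list", label),
                    "argument_error")
  }
  if (!is.null(bonds)) {
    bonds <- as.data.frame(bonds)
    if (!all(c("i", "j") %in% names(bonds))) {
      stop_pocketedda("bond table needs columns i, j", "argument_error")
    }
    if (is.null(bonds$k)) bonds$k <- NA_real_
    if (is.null(bonds$r0)) bonds$r0 <- NA_real_
    if (any(bonds$i < 1 | bonds$i > nrow(atoms) | bonds$j < 1 | bonds$j > nrow(atoms))) {
      stop_pocketedda("bond indices out of range", "argument_error")
    }
  }
  if (is.null(source_residue_ids)) {
    source_residue_ids <- data.frame(chain = character(), resnum = integer())
  }
  structure(list(label = as.character(label), atoms = atoms,
                 formal_charge = as.integer(formal_charge),
                 source_residue_ids = source_residue_ids,
                 bonds = bonds),
            class = "fragment")
}

#' @export
print.fragment <- function(x, ...) {
  cat(sprintf("<fragment> %s: %d atoms (%d H, %d caps), formal charge %+d e\n",
              x$label, nrow(x$atoms), sum(x$atoms$is_hydrogen),
              sum(x$atoms$is_cap), x$formal_charge))
  invisible(x)
}

coords_of <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

# All pairwise distances between two atom tables (rows of a x rows of b).
cross_distances <- function(atoms_a, atoms_b) {
  a <- coords_of(atoms_a); b <- coords_of(atoms_b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Merge two fragments into one
#'
#' Concatenates atoms (and topologies, with indices shifted) of two
#' atom-disjoint fragments. Used to build the supermolecule geometry for
#' refinement and whole-pocket solvation terms.
#'
#' @param a,b Fragments.
#' @param label Label for the union.
#' @return A [fragment()].
#' @export
merge_fragments <- function(a, b, label = paste(a$label, b$label, sep = "+")) {
  bonds <- NULL
  has_a <- !is.null(a$bonds); has_b <- !is.null(b$bonds)
  if (has_a || has_b) {
    ba <- if (has_a) a$bonds else data.frame(i = integer(), j = integer(),
                                             k = numeric(), r0 = numeric())
    bb <- if (has_b) b$bonds else data.frame(i = integer(), j = integer(),
                                             k = numeric(), r0 = numeric())
    bb$i <- bb$i + nrow(a$atoms); bb$j <- bb$j + nrow(a$atoms)
    bonds <- rbind(ba[, c("i", "j", "k", "r0")], bb[, c("i", "j", "k", "r0")])
  }
  fragment(label, rbind(a$atoms, b$atoms),
           formal_charge = a$formal_charge + b$formal_charge,
           source_residue_ids = rbind(a$source_residue_ids, b$source_residue_ids),
           bonds = bonds)
}

# Validate the fragment invariants the pocket model relies on.
validate_fragment <- function(frag, charge_tol = 1e-6) {
  at <- frag$atoms
  if (any(xor(at$is_hydrogen, at$element == "H"))) {
    stop_pocketedda(sprintf("fragment %s: is_hydrogen flag inconsistent with element",
                            frag$label), "argument_error")
  }
  if (abs(sum(at$charge) - frag$formal_charge) > charge_tol) {
    stop_pocketedda(sprintf("fragment %s: partial charges sum to %.6f, formal charge %d",
                            frag$label, sum(at$charge), frag$formal_charge),
                    "argument_error")
  }
  invisible(frag)
}
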