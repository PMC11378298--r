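#' Read a protein-ligand complex structure
#'
#' Parses a PDB file (fixed-column ATOM/HETATM records, 1-based residue
#' numbering preserved) into a `molecular_structure`: one atom table grouped
#' by (chain, residue number, residue name), with hetero flags so HETATM
#' groups can be retrieved as candidate ligands. Alternate locations are
#' collapsed to a single conformer: the highest-occupancy altLoc is kept,
#' ties going to the first listed.
#'
#' @param path Path to the structure file.
#' @param format Only `"pdb"` is supported.
#' @return Object of class `molecular_structure` with an `atoms` data.frame
#'   (`chain`, `resnum`, `resname`, `name`, `element`, `x`, `y`, `z`, `het`,
#'   `occupancy`) and the source path.
#' @export
#' @examples
#' pdb <- system.file("extdata", "toy_tripeptide.pdb", package = "pocketedda")
#' s <- read_structure(pdb)
#' ligand_candidates(s)
read_structure <- function(path, format = c("pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_pocketedda(sprintf("structure file not found: %s", path), "io_error")
  }
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM|HETATM)", lines)
  if (length(lines) == 0 || !any(is_atom)) {
    stop_pocketedda(sprintf("no ATOM/HETATM records in %s", path), "empty_structure_error")
  }
  # bio3d coerces malformed coordinate fields to numbers silently; validate
  # the fixed coordinate columns first so format errors carry a line number.
  atom_lines <- which(is_atom)
  for (ln in atom_lines) {
    for (cols in list(c(31, 38), c(39, 46), c(47, 54))) {
      fld <- trimws(substr(lines[ln], cols[1], cols[2]))
      if (fld == "" || is.na(suppressWarnings(as.numeric(fld)))) {
        stop_pocketedda(sprintf("unparsable coordinate field '%s' at line %d of %s",
                                fld, ln, path), "format_error", line = ln)
      }
    }
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE))
  at <- pdb$atom
  # altLoc policy: within each (chain, resnum, atom name), keep the
  # highest-occupancy alternate; ties resolved by file order.
  occ <- ifelse(is.na(at$o), 1, at$o)
  key <- paste(at$chain, at$resno, at$resid, at$elety, sep = "\r")
  pick <- vapply(split(seq_len(nrow(at)), key),
                 function(ix) ix[which.max(occ[ix])], integer(1))
  keep <- sort(unname(pick))
  at <- at[keep, , drop = FALSE]
  occ <- occ[keep]
  elem <- toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                         substr(trimws(at$elety), 1, 1), trimws(at$elesy)))
  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), "", at$chain),
    resnum = at$resno,
    resname = trimws(at$resid),
    name = trimws(at$elety),
    element = elem,
    x = at$x, y = at$y, z = at$z,
    het = at$type == "HETATM",
    occupancy = occ,
    stringsAsFactors = FALSE
  )
  dup <- duplicated(paste(atoms$chain, atoms$resnum, atoms$name, sep = "\r"))
  if (any(dup)) {
    stop_pocketedda(sprintf("duplicate (chain, resnum, atom name) keys: %s",
                            paste(unique(paste0(atoms$chain, atoms$resnum, ":", atoms$name)[dup]),
                                  collapse = ", ")), "format_error")
  }
  structure(list(atoms = atoms, source = path), class = "molecular_structure")
}

#' @export
print.molecular_structure <- function(x, ...) {
  nres <- nrow(unique(x$atoms[, c("chain", "resnum")]))
  cat(sprintf("<molecular_structure> %s: %d atoms, %d residues, %d HETATM\n",
              x$source, nrow(x$atoms), nres, sum(x$atoms$het)))
  invisible(x)
}

#' Candidate ligand residue names in a structure
#'
#' @param structure A [read_structure()] result.
#' @return Character vector of HETATM residue names (waters excluded).
#' @export
ligand_candidates <- function(structure) {
  het <- structure$atoms[structure$atoms$het, , drop = FALSE]
  setdiff(unique(het$resname), c("HOH", "WAT", "DOD"))
}

#' Extract a residue group from a structure as a fragment
#'
#' Pulls all atoms of the named HETATM group (default) or of a specific
#' (chain, resnum) and returns them as an uncapped [fragment()] with
#' parameters resolved from the element defaults.
#'
#' @param structure A `molecular_structure`.
#' @param resname Residue name to extract (e.g. the ligand code).
#' @param formal_charge Formal charge assigned to the fragment.
#' @param param_table Optional table from [read_parameter_table()].
#' @return A [fragment()].
#' @export
extract_ligand <- function(structure, resname, formal_charge = 0L,
                           param_table = NULL) {
  sel <- structure$atoms$resname == resname
  if (!any(sel)) {
    stop_pocketedda(sprintf("no residue named %s in %s", resname, structure$source),
                    "argument_error")
  }
  at <- structure$atoms[sel, , drop = FALSE]
  frag <- fragment(resname,
                   atom_table(at$element, at$x, at$y, at$z, name = at$name),
                   formal_charge = formal_charge,
                   source_residue_ids = unique(data.frame(chain = at$chain,
                                                          resnum = at$resnum)))
  resolve_parameters(frag, param_table)
}

#' Read a small-molecule ligand file
#'
#' Reads an SDF (V2000, first molecule) or a plain XYZ file into a
#' [fragment()]. Atoms keep file order. Partial charges are zero unless the
#' SDF carries `M  CHG` formal charges; per-atom nonbonded parameters are
#' resolved from the element table. SDF bond blocks become the fragment
#' topology (connectivity only, no harmonic parameters).
#'
#' @param path File path.
#' @param format `"sdf"` or `"xyz"`; guessed from the extension by default.
#' @param label Fragment label (default `"LIG"`).
#' @param param_table Optional [read_parameter_table()] result.
#' @return A [fragment()].
#' @export
read_ligand <- function(path, format = c("auto", "sdf", "xyz"),
                        label = "LIG", param_table = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf" else "xyz"
  }
  if (!file.exists(path)) {
    stop_pocketedda(sprintf("ligand file not found: %s", path), "io_error")
  }
  if (format == "xyz") {
    lines <- readLines(path, warn = FALSE)
    n <- suppressWarnings(as.integer(trimws(lines[1])))
    if (is.na(n)) {
      stop_pocketedda(sprintf("bad XYZ atom-count header in %s", path), "format_error")
    }
    body <- lines[seq(3, length.out = n)]
    if (length(body) < n || any(is.na(body)) || any(trimws(body) == "")) {
      stop_pocketedda(sprintf("XYZ declares %d atoms but fewer are listed in %s", n, path),
                      "format_error")
    }
    tok <- strsplit(trimws(body), "\\s+")
    el <- vapply(tok, `[[`, "", 1)
    xyz <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
    if (any(!is.finite(xyz))) {
      stop_pocketedda(sprintf("non-numeric coordinate in XYZ body of %s", path),
                      "format_error")
    }
    frag <- fragment(label, atom_table(el, xyz[, 1], xyz[, 2], xyz[, 3]))
  } else {
    lines <- readLines(path, warn = FALSE)
    if (length(lines) < 4) {
      stop_pocketedda(sprintf("truncated SDF: %s", path), "format_error")
    }
    n_at <- suppressWarnings(as.integer(substr(lines[4], 1, 3)))
    n_bd <- suppressWarnings(as.integer(substr(lines[4], 4, 6)))
    if (is.na(n_at) || is.na(n_bd)) {
      stop_pocketedda(sprintf("bad V2000 counts line in %s", path), "format_error")
    }
    block_end <- grep("^M  END", lines)[1]
    listed <- if (is.na(block_end)) length(lines) - 4 else block_end - 5 - n_bd
    if (listed < n_at) {
      stop_pocketedda(sprintf("SDF counts line declares %d atoms but %d are listed in %s",
                              n_at, max(listed, 0), path), "format_error")
    }
    sdf <- suppressWarnings(ChemmineR::read.SDFset(path))[[1]]
    ab <- ChemmineR::atomblock(sdf)
    el <- sub("_.*$", "", rownames(ab))
    frag <- fragment(label, atom_table(el, ab[, 1], ab[, 2], ab[, 3]))
    bb <- ChemmineR::bondblock(sdf)
    if (nrow(bb) > 0) {
      frag$bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                               k = NA_real_, r0 = NA_real_)
    }
    chg <- grep("^M  CHG", lines, value = TRUE)
    if (length(chg)) {
      for (line in chg) {
        tok <- as.integer(strsplit(trimws(sub("^M  CHG", "", line)), "\\s+")[[1]])
        npair <- tok[1]
        for (p in seq_len(npair)) {
          frag$atoms$charge[tok[2 * p]] <- tok[2 * p + 1]
        }
      }
      frag$formal_charge <- as.integer(round(sum(frag$atoms$charge)))
    }
  }
  resolve_parameters(frag, param_table)
}

#' Write a fragment as an XYZ file
#'
#' Standard xmol layout; the comment line carries the total charge as
#' `charge=<n>`, which the external-engine adapter passes on.
#'
#' @param fragment A [fragment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(fragment, path) {
  at <- fragment$atoms
  lines <- c(sprintf("%d", nrow(at)),
             sprintf("charge=%d %s", fragment$formal_charge, fragment$label),
             sprintf("%-2s %18.10f %18.10f %18.10f", at$element, at$x, at$y, at$z))
  writeLines(lines, path)
  invisible(path)
}

.map_header <- "pocketedda-map v1"
.map_cols <- c("chain", "resnum", "label", "total", "electrostatic", "dispersion",
               "repulsion", "hbond", "desolvation", "closest_contact")

#' Write an interaction map report
#'
#' Serializes an [in_pocket_analysis()] map as delimiter-separated text with a
#' versioned header line, one record per residue sorted by (chain, residue
#' number), and a footer record (`label = "SUM"`) carrying the summed
#' components. Numbers are written with 17 significant digits so the file
#' round-trips through [read_interaction_map()] exactly.
#'
#' @param map An `interaction_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interaction_map <- function(map, path) {
  stopifnot(inherits(map, "interaction_map"))
  p <- map$pairs
  if (nrow(p) > 0) p <- p[order(p$chain, p$resnum), , drop = FALSE]
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  rows <- character(0)
  if (nrow(p) > 0) {
    rows <- sprintf("%s,%d,%s,%s,%s,%s,%s,%s,%s,%s",
                    p$chain, p$resnum, p$label, fmt(p$total), fmt(p$electrostatic),
                    fmt(p$dispersion), fmt(p$repulsion), fmt(p$hbond),
                    fmt(p$desolvation), fmt(p$closest_contact))
  }
  s <- map$summed
  footer <- sprintf(",,SUM,%s,%s,%s,%s,%s,%s,",
                    fmt(s[["total"]]), fmt(s[["electrostatic"]]), fmt(s[["dispersion"]]),
                    fmt(s[["repulsion"]]), fmt(s[["hbond"]]), fmt(s[["desolvation"]]))
  out <- c(sprintf("# %s", .map_header),
           sprintf("# mode: %s", map$mode_label),
           paste(.map_cols, collapse = ","),
           rows, footer)
  ok <- tryCatch({ writeLines(out, path); TRUE }, error = function(e) FALSE,
                 warning = function(w) FALSE)
  if (!ok) stop_pocketedda(sprintf("cannot write interaction map to %s", path), "io_error")
  invisible(path)
}

#' Read an interaction map report
#'
#' Inverse of [write_interaction_map()]; validates the version header and the
#' footer-vs-rows sum.
#'
#' @param path Path written by [write_interaction_map()].
#' @return An `interaction_map`.
#' @export
read_interaction_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || !identical(lines[1], sprintf("# %s", .map_header))) {
    stop_pocketedda(sprintf("not a %s file: %s", .map_header, path), "format_error")
  }
  mode_label <- sub("^# mode: ", "", lines[2])
  body <- utils::read.csv(text = lines[-(1:2)], stringsAsFactors = FALSE,
                          colClasses = c(chain = "character", label = "character"))
  foot <- body[body$label == "SUM", , drop = FALSE]
  p <- body[body$label != "SUM", , drop = FALSE]
  summed <- energy_components(electrostatic = foot$electrostatic,
                              dispersion = foot$dispersion,
                              repulsion = foot$repulsion, hbond = foot$hbond,
                              desolvation = foot$desolvation, bonded = 0,
                              total = foot$total, check = FALSE)
  p$refined <- rep(NA, nrow(p))
  new_interaction_map(mode_label, p, summed)
}
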