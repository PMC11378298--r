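.water_names <- c("HOH", "WAT", "DOD")

# Formal charges of standard residues under the package's physiological
# defaults: Lys/Arg protonated, Asp/Glu deprotonated, His neutral (epsilon
# tautomer). Used when the input structure does not dictate otherwise.
.residue_formal_charge <- c(LYS = 1L, ARG = 1L, ASP = -1L, GLU = -1L, HIS = 0L)

#' Select residues within a distance shell of the ligand
#'
#' Returns the identifiers of all residues whose minimum any-atom distance
#' (hydrogens included) to any ligand atom is within `cutoff` (inclusive).
#' Waters are excluded unless `include_waters`; the ligand's own residues are
#' always excluded.
#'
#' @param structure A [read_structure()] result.
#' @param ligand A [fragment()] holding the ligand pose.
#' @param cutoff Shell radius in Angstrom (default 5.0, the usual contact
#'   shell for per-residue interaction maps).
#' @param include_waters Keep water residues as selectable single-residue
#'   fragments.
#' @return data.frame with columns `chain`, `resnum`, `resname`,
#'   `min_distance`, sorted by (chain, resnum).
#' @export
select_pocket_residues <- function(structure, ligand, cutoff = 5.0,
                                   include_waters = FALSE) {
  if (cutoff <= 0) stop_pocketedda("cutoff must be positive", "argument_error")
  if (!inherits(ligand, "fragment") || nrow(ligand$atoms) == 0) {
    stop_pocketedda("ligand fragment is empty", "argument_error")
  }
  at <- structure$atoms
  drop <- rep(FALSE, nrow(at))
  if (!include_waters) drop <- drop | at$resname %in% .water_names
  if (nrow(ligand$source_residue_ids) > 0) {
    lig_key <- paste(ligand$source_residue_ids$chain, ligand$source_residue_ids$resnum)
    drop <- drop | paste(at$chain, at$resnum) %in% lig_key
  }
  at <- at[!drop, , drop = FALSE]
  if (nrow(at) == 0) {
    return(data.frame(chain = character(), resnum = integer(),
                      resname = character(), min_distance = numeric()))
  }
  d <- cross_distances(at, ligand$atoms)
  mind <- apply(d, 1, min)
  key <- paste(at$chain, at$resnum, sep = "\r")
  per_res <- tapply(mind, key, min)
  sel <- names(per_res)[per_res <= cutoff]
  if (length(sel) == 0) {
    return(data.frame(chain = character(), resnum = integer(),
                      resname = character(), min_distance = numeric()))
  }
  first <- at[!duplicated(key) & key %in% sel, , drop = FALSE]
  out <- data.frame(chain = first$chain, resnum = first$resnum,
                    resname = first$resname,
                    min_distance = as.numeric(per_res[paste(first$chain, first$resnum,
                                                            sep = "\r")]),
                    stringsAsFactors = FALSE)
  out[order(out$chain, out$resnum), , drop = FALSE]
}

# Place a cap hydrogen along the severed bond vector from `from` toward
# `toward`, at the standard X-H length.
cap_hydrogen <- function(from, toward, length_a) {
  v <- toward - from
  from + v / sqrt(sum(v^2)) * length_a
}

#' Cut selected residues out of a structure and cap them
#'
#' Each selected residue becomes a chemically consistent [fragment()]:
#' severed peptide bonds are capped by replacing the neighboring backbone
#' atom with a hydrogen placed along the severed bond vector at the standard
#' X-H length (N-H 1.01 A at the residue's amide nitrogen, C-H 1.09 A at its
#' carbonyl carbon). Heavy-atom coordinates are never touched. Partial
#' charges (zero unless a charge table is supplied) are shifted uniformly so
#' each fragment's charge sum matches its formal charge.
#'
#' @param structure A `molecular_structure`.
#' @param residue_ids data.frame with `chain`, `resnum` (as returned by
#'   [select_pocket_residues()]).
#' @param ligand The ligand [fragment()] (stored in the model).
#' @param scheme Capping scheme; only `"hydrogen-cap"` is implemented.
#' @param cutoff,include_waters Provenance fields recorded in the model.
#' @param param_table Optional [read_parameter_table()] result.
#' @param charge_table Optional data.frame (`resname`, `name`, `charge`)
#'   assigning partial charges by residue and atom name.
#' @return Object of class `pocket_model`.
#' @export
cut_pocket <- function(structure, residue_ids, ligand,
                       scheme = c("hydrogen-cap"),
                       cutoff = 5.0, include_waters = FALSE,
                       param_table = NULL, charge_table = NULL) {
  scheme <- match.arg(scheme)
  at_all <- structure$atoms
  fragments <- vector("list", nrow(residue_ids))
  for (r in seq_len(nrow(residue_ids))) {
    ch <- residue_ids$chain[r]; rn <- residue_ids$resnum[r]
    sel <- at_all$chain == ch & at_all$resnum == rn
    if (!any(sel)) {
      stop_pocketedda(sprintf("residue %s%d not present in structure", ch, rn),
                      "argument_error")
    }
    res <- at_all[sel, , drop = FALSE]
    resname <- res$resname[1]
    label <- sprintf("%s%d", resname, rn)
    is_water <- resname %in% .water_names
    atoms <- atom_table(res$element, res$x, res$y, res$z, name = res$name)
    if (!is.null(charge_table)) {
      idx <- match(paste(resname, res$name), paste(charge_table$resname, charge_table$name))
      atoms$charge[!is.na(idx)] <- charge_table$charge[idx[!is.na(idx)]]
    }
    if (!is_water && !res$het[1]) {
      need <- c("N", "CA", "C")
      missing_bb <- setdiff(need, res$name)
      if (length(missing_bb) > 0) {
        stop_pocketedda(sprintf("residue %s is missing backbone atom(s) %s; cannot cap",
                                label, paste(missing_bb, collapse = ", ")),
                        "capping_error")
      }
      # Severed bond at this residue's N: previous residue's carbonyl C.
      bb_n <- res[res$name == "N", ]
      prev_c <- at_all[at_all$chain == ch & at_all$resnum == rn - 1 &
                         at_all$name == "C", , drop = FALSE]
      if (nrow(prev_c) == 1 &&
          sqrt(sum((c(prev_c$x, prev_c$y, prev_c$z) -
                      c(bb_n$x, bb_n$y, bb_n$z))^2)) < 1.8) {
        p <- cap_hydrogen(c(bb_n$x, bb_n$y, bb_n$z), c(prev_c$x, prev_c$y, prev_c$z), 1.01)
        atoms <- rbind(atoms, atom_table("H", p[1], p[2], p[3], name = "HCAP_N",
                                         is_cap = TRUE))
      }
      # Severed bond at this residue's C: next residue's amide N.
      bb_c <- res[res$name == "C", ]
      next_n <- at_all[at_all$chain == ch & at_all$resnum == rn + 1 &
                         at_all$name == "N", , drop = FALSE]
      if (nrow(next_n) == 1 &&
          sqrt(sum((c(next_n$x, next_n$y, next_n$z) -
                      c(bb_c$x, bb_c$y, bb_c$z))^2)) < 1.8) {
        p <- cap_hydrogen(c(bb_c$x, bb_c$y, bb_c$z), c(next_n$x, next_n$y, next_n$z), 1.09)
        atoms <- rbind(atoms, atom_table("H", p[1], p[2], p[3], name = "HCAP_C",
                                         is_cap = TRUE))
      }
    }
    fc <- if (is_water) 0L else unname(.residue_formal_charge[resname])
    if (is.na(fc) || is.null(fc)) fc <- 0L
    # Uniform charge repair: spread the residual over all atoms so the sum
    # matches the formal charge exactly.
    atoms$charge <- atoms$charge + (fc - sum(atoms$charge)) / nrow(atoms)
    frag <- fragment(label, atoms, formal_charge = fc,
                     source_residue_ids = data.frame(chain = ch, resnum = rn))
    fragments[[r]] <- resolve_parameters(frag, param_table)
  }
  pocket_model(ligand = ligand, residues = fragments, cutoff = cutoff,
               capping_scheme = scheme, source_id = structure$source,
               include_waters = include_waters)
}

#' Pocket model constructor
#'
#' Bundles the ligand and its capped residue fragments with the provenance of
#' how the pocket was built (source structure, shell cutoff, capping scheme,
#' water policy). Fragments must be atom-disjoint and residue labels unique.
#'
#' @param ligand Ligand [fragment()].
#' @param residues List of residue [fragment()]s.
#' @param cutoff Shell radius used for selection, Angstrom.
#' @param capping_scheme Capping scheme identifier.
#' @param source_id Identifier of the source structure or fixture.
#' @param include_waters Whether waters were eligible for selection.
#' @return Object of class `pocket_model`.
#' @export
pocket_model <- function(ligand, residues, cutoff = 5.0,
                         capping_scheme = "hydrogen-cap",
                         source_id = "", include_waters = FALSE) {
  stopifnot(inherits(ligand, "fragment"))
  labels <- vapply(residues, function(f) f$label, "")
  if (anyDuplicated(labels)) {
    stop_pocketedda(sprintf("duplicate residue fragment label(s): %s",
                            paste(unique(labels[duplicated(labels)]), collapse = ", ")),
                    "argument_error")
  }
  for (f in residues) validate_fragment(f)
  validate_fragment(ligand)
  structure(list(ligand = ligand, residues = residues, cutoff = cutoff,
                 capping_scheme = capping_scheme, source_id = source_id,
                 include_waters = include_waters),
            class = "pocket_model")
}

#' @export
print.pocket_model <- function(x, ...) {
  cat(sprintf("<pocket_model> %s: ligand %s (%d atoms) + %d residue fragment(s), cutoff %.1f A\n",
              x$source_id, x$ligand$label, nrow(x$ligand$atoms),
              length(x$residues), x$cutoff))
  invisible(x)
}

#' Enumerate ligand-residue pairs by closest contact
#'
#' One pair per residue fragment, annotated with the minimum interatomic
#' ligand-residue distance, ordered by ascending closest contact (ties broken
#' by residue number).
#'
#' @param pocket A [pocket_model()].
#' @return data.frame with columns `label`, `index` (into `pocket$residues`),
#'   `closest_contact` (Angstrom).
#' @export
enumerate_pairs <- function(pocket) {
  stopifnot(inherits(pocket, "pocket_model"))
  n <- length(pocket$residues)
  if (n == 0) {
    return(data.frame(label = character(), index = integer(),
                      closest_contact = numeric()))
  }
  cc <- vapply(pocket$residues, function(f) {
    min(cross_distances(pocket$ligand$atoms, f$atoms))
  }, numeric(1))
  resnum <- vapply(pocket$residues, function(f) {
    if (nrow(f$source_residue_ids) > 0) f$source_residue_ids$resnum[1] else NA_integer_
  }, integer(1))
  ord <- order(cc, resnum)
  data.frame(label = vapply(pocket$residues, function(f) f$label, "")[ord],
             index = ord, closest_contact = cc[ord],
             stringsAsFactors = FALSE)
}

#' Serialize a pocket model to JSON
#'
#' Documented schema: ligand and residue fragments with full atom tables
#' (caps flagged), formal charges, bond topologies, and the provenance block.
#'
#' @param pocket A [pocket_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pocket_json <- function(pocket, path) {
  frag_to_list <- function(f) {
    list(label = f$label, formal_charge = f$formal_charge,
         source_residue_ids = f$source_residue_ids,
         atoms = f$atoms,
         bonds = if (is.null(f$bonds)) NULL else f$bonds)
  }
  obj <- list(schema = "pocketedda-pocket v1",
              source_id = pocket$source_id, cutoff = pocket$cutoff,
              capping_scheme = pocket$capping_scheme,
              include_waters = pocket$include_waters,
              ligand = frag_to_list(pocket$ligand),
              residues = stats::setNames(lapply(pocket$residues, frag_to_list),
                                         vapply(pocket$residues, function(f) f$label, "")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a pocket model from JSON
#'
#' @param path A file written by [write_pocket_json()].
#' @return A [pocket_model()].
#' @export
read_pocket_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "pocketedda-pocket v1")) {
    stop_pocketedda(sprintf("not a pocketedda pocket file: %s", path), "format_error")
  }
  list_to_frag <- function(l) {
    srid <- if (length(l$source_residue_ids) == 0) NULL
            else as.data.frame(l$source_residue_ids)
    bonds <- if (is.null(l$bonds) || (is.data.frame(l$bonds) && nrow(l$bonds) == 0)) NULL
             else as.data.frame(l$bonds)
    fragment(l$label, as.data.frame(l$atoms), formal_charge = l$formal_charge,
             source_residue_ids = srid, bonds = bonds)
  }
  residues <- if (length(obj$residues) == 0) list()
              else unname(lapply(obj$residues, list_to_frag))
  pocket_model(ligand = list_to_frag(obj$ligand), residues = residues,
               cutoff = obj$cutoff, capping_scheme = obj$capping_scheme,
               source_id = obj$source_id, include_waters = obj$include_waters)
}
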