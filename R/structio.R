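## Structure containers and geometric primitives: everything downstream
## (screen mapping, docking, assembly) measures distances through here.

#' Construct a structure model
#'
#' A `structure_model` is the package's atomic-coordinate container: a data
#' frame of atoms in author (crystallographic) numbering plus provenance
#' metadata. Synthetic models are Calpha-only; models read from PDB/mmCIF
#' keep all ATOM/HETATM records.
#'
#' @param atoms data frame with columns `chain` (character), `resno`
#'   (integer, author numbering), `resid` (3-letter residue code), `elety`
#'   (atom name, e.g. `"CA"`), and coordinates `x`, `y`, `z` in Angstrom.
#' @param title free-text title.
#' @param source_id file name or PDB accession the model came from.
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms, title = "", source_id = "") {
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stopf("atoms is missing column(s): %s", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms)[, need]
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  atoms$resid <- as.character(atoms$resid)
  atoms$elety <- as.character(atoms$elety)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stopf("non-finite coordinates in atoms")
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key)) {
    stopf("duplicate (chain, resno, elety) records, e.g. %s", key[anyDuplicated(key)])
  }
  for (ch in unique(atoms$chain)) {
    rn <- atoms$resno[atoms$chain == ch]
    rn <- rn[!duplicated(rn)]
    if (is.unsorted(rn, strictly = TRUE)) {
      stopf("residue numbers in chain %s do not strictly increase in file order", ch)
    }
  }
  structure(list(atoms = atoms, title = title, source_id = source_id),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s%s\n",
              if (nzchar(x$source_id)) x$source_id else "(in memory)",
              if (nzchar(x$title)) paste0(" - ", x$title) else ""))
  ca <- x$atoms[x$atoms$elety == "CA", ]
  for (ch in unique(x$atoms$chain)) {
    n <- sum(ca$chain == ch)
    cat(sprintf("  chain %s: %d residues (CA), %d atoms\n",
                ch, n, sum(x$atoms$chain == ch)))
  }
  invisible(x)
}

#' List chain identifiers of a model
#' @param model a `structure_model`.
#' @return character vector of chain ids in file order.
#' @export
model_chains <- function(model) unique(model$atoms$chain)

## Calpha subset of the atom table, optionally one chain.
ca_atoms <- function(model, chain = NULL) {
  a <- model$atoms[model$atoms$elety == "CA", , drop = FALSE]
  if (!is.null(chain)) a <- a[a$chain == chain, , drop = FALSE]
  a
}

## n x 3 coordinate matrix (all atoms or CA-only).
coord_matrix <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

#' Read a structure file (PDB or mmCIF)
#'
#' Wraps the bio3d readers; author numbering is preserved and never
#' remapped, so residue labels match those used in the cross-linking
#' screen (e.g. S152, D193). Multi-model files return the first model with
#' a warning. For alternate locations the highest-occupancy conformer is
#' kept (ties broken by altloc label order, with a message).
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by extension).
#' @return a [structure_model()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      pdb = "pdb", ent = "pdb", cif = "mmcif", mmcif = "mmcif",
      stopf("cannot infer structure format from extension '.%s'; pass format=", ext))
  }
  parsed <- tryCatch(
    suppressWarnings(
      if (format == "pdb") bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
      else bio3d::read.cif(path, verbose = FALSE)),
    error = function(e) stopf("failed to parse %s as %s: %s", path, format,
                              conditionMessage(e)))
  at <- parsed$atom
  ## alternate locations: keep the highest-occupancy conformer per atom site
  if (!is.null(at$alt) && any(!is.na(at$alt) & at$alt != "")) {
    key <- paste(at$chain, at$resno, at$elety)
    occ <- at$o
    occ[is.na(occ)] <- 1
    keep <- rep(TRUE, nrow(at))
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      best <- idx[order(-occ[idx], as.character(at$alt[idx]))][1]
      keep[setdiff(idx, best)] <- FALSE
      message(sprintf("altloc at %s: kept conformer '%s' (occupancy %.2f)",
                      k, at$alt[best], occ[best]))
    }
    at <- at[keep, , drop = FALSE]
  }
  atoms <- data.frame(chain = as.character(at$chain),
                      resno = as.integer(at$resno),
                      resid = as.character(at$resid),
                      elety = as.character(at$elety),
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  atoms <- atoms[order(match(atoms$chain, unique(atoms$chain))), , drop = FALSE]
  structure_model(atoms, title = format, source_id = basename(path))
}

#' Write a structure model
#'
#' PDB output goes through `bio3d::write.pdb` (fixed-width, 3 decimals);
#' mmCIF output is a minimal `atom_site` loop sufficient for round-tripping
#' coordinates and author numbering.
#'
#' @param model a `structure_model`.
#' @param path output path.
#' @param format `"pdb"` or `"mmcif"` (default by extension).
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  a <- model$atoms
  if (format == "pdb") {
    xyz <- as.vector(t(coord_matrix(a)))
    bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", nrow(a)),
                     resno = a$resno, resid = a$resid, chain = a$chain,
                     elety = a$elety, o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("data_model", "#", "loop_",
                 paste0("_atom_site.",
                        c("group_PDB", "id", "type_symbol", "label_atom_id",
                          "label_alt_id", "label_comp_id", "label_asym_id",
                          "label_entity_id", "label_seq_id",
                          "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z",
                          "occupancy", "B_iso_or_equiv", "pdbx_formal_charge",
                          "auth_seq_id", "auth_comp_id", "auth_asym_id",
                          "auth_atom_id", "pdbx_PDB_model_num"))), con)
    elem <- substr(gsub("[0-9]", "", a$elety), 1, 1)
    writeLines(sprintf(
      "ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s %s %s 1",
      seq_len(nrow(a)), elem, a$elety, a$resid, a$chain, a$resno,
      a$x, a$y, a$z, a$resno, a$resid, a$chain, a$elety), con)
    writeLines("#", con)
  }
  invisible(path)
}

#' Extract Calpha coordinates for selected residues
#'
#' Residues absent from the model (e.g. crystallographically disordered)
#' are reported in the `missing` attribute, never silently dropped.
#'
#' @param model a `structure_model`.
#' @param chain chain id.
#' @param residues integer vector of author residue numbers; `NULL` selects
#'   every residue of the chain.
#' @return a `coord_selection`: data frame (chain, resno, x, y, z) in
#'   request order, with attribute `missing` (integer vector of unresolved
#'   residue numbers).
#' @export
extract_ca <- function(model, chain, residues = NULL) {
  ca <- ca_atoms(model)
  if (!chain %in% ca$chain) stopf("chain '%s' not present in model", chain)
  ca <- ca[ca$chain == chain, , drop = FALSE]
  if (is.null(residues)) residues <- ca$resno
  residues <- as.integer(residues)
  if (!length(residues)) stopf("empty residue selection for chain '%s'", chain)
  idx <- match(residues, ca$resno)
  found <- !is.na(idx)
  sel <- data.frame(chain = chain, resno = residues[found],
                    x = ca$x[idx[found]], y = ca$y[idx[found]], z = ca$z[idx[found]],
                    stringsAsFactors = FALSE)
  attr(sel, "missing") <- residues[!found]
  class(sel) <- c("coord_selection", "data.frame")
  sel
}

#' Export a coordinate selection as TSV
#' @param sel a `coord_selection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(sel, path) {
  write.table(as.data.frame(sel)[, c("chain", "resno", "x", "y", "z")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rigid-body transform
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation length-3 translation (Angstrom).
#' @return object of class `rigid_transform` applying `x -> R x + t`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3))) stopf("rotation must be 3x3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6) {
    stopf("rotation is not a proper rotation (orthonormal, det +1)")
  }
  structure(list(R = rotation, t = as.numeric(translation)),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param tr a `rigid_transform`.
#' @export
invert_transform <- function(tr) {
  rigid_transform(t(tr$R), -as.vector(t(tr$R) %*% tr$t))
}

#' @rdname rigid_transform
#' @param a,b transforms; returns the composition applying `b` first then `a`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.vector(a$R %*% b$t) + a$t)
}

#' Apply a rigid transform to coordinates or a model
#' @param x an n x 3 matrix, a `coord_selection`, or a `structure_model`.
#' @param tr a `rigid_transform`.
#' @return object of the same kind with transformed coordinates.
#' @export
apply_transform <- function(x, tr) {
  if (inherits(x, "structure_model")) {
    xyz <- coord_matrix(x$atoms) %*% t(tr$R)
    x$atoms$x <- xyz[, 1] + tr$t[1]
    x$atoms$y <- xyz[, 2] + tr$t[2]
    x$atoms$z <- xyz[, 3] + tr$t[3]
    return(x)
  }
  if (inherits(x, "coord_selection")) {
    xyz <- as.matrix(x[, c("x", "y", "z")]) %*% t(tr$R)
    x$x <- xyz[, 1] + tr$t[1]; x$y <- xyz[, 2] + tr$t[2]; x$z <- xyz[, 3] + tr$t[3]
    return(x)
  }
  sweep(as.matrix(x) %*% t(tr$R), 2, -tr$t)
}

sel_matrix <- function(sel) {
  if (inherits(sel, "coord_selection") || is.data.frame(sel)) {
    as.matrix(sel[, c("x", "y", "z")])
  } else as.matrix(sel)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation + translation minimizing the RMSD of paired
#' Calpha coordinates; the reflection case is handled by determinant
#' correction so the result is always a proper rotation.
#'
#' @param mobile,reference paired `coord_selection`s or n x 3 matrices,
#'   equal length n >= 3, not all collinear.
#' @return list with `transform` (a [rigid_transform()] mapping mobile onto
#'   reference), `rmsd` (Angstrom), and `n` (number of pairs).
#' @export
superpose <- function(mobile, reference) {
  P <- sel_matrix(mobile); Q <- sel_matrix(reference)
  if (nrow(P) != nrow(Q)) {
    stopf("superpose: pairing error, %d mobile vs %d reference points",
          nrow(P), nrow(Q))
  }
  if (nrow(P) < 3) stopf("superpose: need >= 3 paired points, got %d", nrow(P))
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  sv_p <- svd(Pc)$d; sv_q <- svd(Qc)$d
  if (sv_p[2] < 1e-8 * max(sv_p[1], 1) || sv_q[2] < 1e-8 * max(sv_q[1], 1)) {
    stopf("superpose: degenerate (collinear) point set")
  }
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tvec <- colMeans(Q) - as.vector(R %*% colMeans(P))
  tr <- rigid_transform(R, tvec)
  moved <- apply_transform(P, tr)
  list(transform = tr, rmsd = sqrt(mean(rowSums((moved - Q)^2))), n = nrow(P))
}

#' Calpha-Calpha distances between symmetry mates across a dimer
#'
#' For a residue number present in both chains, the distance between its
#' Calpha in chain A and the same residue's Calpha in chain B. In a
#' C2-symmetric dimer this equals twice the residue's perpendicular
#' distance from the 2-fold axis, which is what makes axial residues
#' cross-linkable.
#'
#' @param dimer a two-(or more-)chain `structure_model`.
#' @param chainA,chainB chain ids.
#' @param positions residue numbers; `NULL` means every residue resolved in
#'   both chains.
#' @return data frame (position, distance) with attribute `unresolved`.
#' @export
symmetry_pair_distances <- function(dimer, chainA = "A", chainB = "B",
                                    positions = NULL) {
  chains <- model_chains(dimer)
  for (ch in c(chainA, chainB)) {
    if (!ch %in% chains) stopf("chain '%s' not present in dimer", ch)
  }
  ca_a <- ca_atoms(dimer, chainA); ca_b <- ca_atoms(dimer, chainB)
  if (is.null(positions)) positions <- intersect(ca_a$resno, ca_b$resno)
  positions <- as.integer(positions)
  ia <- match(positions, ca_a$resno); ib <- match(positions, ca_b$resno)
  ok <- !is.na(ia) & !is.na(ib)
  da <- coord_matrix(ca_a)[ia[ok], , drop = FALSE]
  db <- coord_matrix(ca_b)[ib[ok], , drop = FALSE]
  out <- data.frame(position = positions[ok],
                    distance = sqrt(rowSums((da - db)^2)))
  attr(out, "unresolved") <- positions[!ok]
  out
}

#' Count Calpha steric clashes
#'
#' Counts Calpha pairs closer than `cutoff`, excluding intra-chain pairs
#' within `exclude_bonded` residues of each other (chain connectivity is
#' not a clash). Calpha-only at 4.0 A is the backbone-level criterion used
#' throughout the rod assembly.
#'
#' @param model a `structure_model`.
#' @param cutoff distance cutoff in Angstrom (> 0).
#' @param exclude_bonded intra-chain sequence-separation window to ignore.
#' @return integer number of clashing pairs.
#' @export
clash_count <- function(model, cutoff = 4.0, exclude_bonded = 2L) {
  if (cutoff <= 0) stopf("cutoff must be > 0")
  ca <- ca_atoms(model)
  n <- nrow(ca)
  if (n < 2) return(0L)
  xyz <- coord_matrix(ca)
  d <- as.matrix(dist(xyz))
  close <- d < cutoff
  same_chain <- outer(ca$chain, ca$chain, "==")
  sep <- abs(outer(ca$resno, ca$resno, "-"))
  excl <- same_chain & (sep <= exclude_bonded)
  sum(close[upper.tri(close)] & !excl[upper.tri(excl)])
}

## Pairwise clash count between two coordinate sets (used by the docking
## inner loop, where building a full model per pose would dominate).
clash_count_xy <- function(xyz_a, xyz_b, cutoff = 4.0) {
  d2 <- outer(rowSums(xyz_a^2), rowSums(xyz_b^2), "+") - 2 * tcrossprod(xyz_a, xyz_b)
  sum(d2 < cutoff^2)
}
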