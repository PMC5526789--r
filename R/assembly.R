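## Composite-model assembly: rigid placement of overlapping fragments into
## a full-length protomer, sequence threading between species, composition
## of the ATP-engaged open state, coiled-coil bending toward ring models,
## and screw decomposition of the rod-to-engaged transition.

#' Superpose one structure onto another over residue ranges
#'
#' The i-th residue of the expanded mobile range pairs with the i-th of
#' the reference range; pairs where either Calpha is unresolved are
#' dropped (and counted), so the returned `n_pairs` is the actual common
#' set the RMSD was computed over.
#'
#' @param mobile,reference `structure_model`s.
#' @param mobile_range,reference_range residue intervals: a `c(start, end)`
#'   pair, a list of such pairs, or an explicit residue vector. Expanded
#'   lengths must match.
#' @param mobile_chain,reference_chain chain ids.
#' @return list with `transform` (mapping mobile onto reference), `rmsd`,
#'   `n_pairs`.
#' @export
superpose_overlap <- function(mobile, reference, mobile_range, reference_range,
                              mobile_chain = model_chains(mobile)[1],
                              reference_chain = model_chains(reference)[1]) {
  mres <- expand_intervals(mobile_range)
  rres <- expand_intervals(reference_range)
  if (length(mres) != length(rres)) {
    stopf("ranges expand to different lengths (%d vs %d)", length(mres), length(rres))
  }
  mca <- ca_atoms(mobile, mobile_chain)
  rca <- ca_atoms(reference, reference_chain)
  mi <- match(mres, mca$resno); ri <- match(rres, rca$resno)
  ok <- !is.na(mi) & !is.na(ri)
  if (sum(ok) < 3) {
    stopf("under-determined: only %d common resolved pairs in the overlap", sum(ok))
  }
  fit <- superpose(coord_matrix(mca)[mi[ok], , drop = FALSE],
                   coord_matrix(rca)[ri[ok], , drop = FALSE])
  list(transform = fit$transform, rmsd = fit$rmsd, n_pairs = fit$n)
}

#' Relabel a model's residues through a sequence alignment
#'
#' Backbone coordinates are untouched; residue numbers (and, when a target
#' sequence is supplied, residue names) are rewritten in the target
#' species' numbering. Alignment insertions/deletions surface as numbering
#' gaps, annotated in the `numbering_gaps` attribute. Residues the map
#' does not cover are dropped and reported.
#'
#' @param model a `structure_model`.
#' @param map an [alignment_map()] from the model's numbering to the
#'   target's.
#' @param target_id identifier recorded as the model's new `source_id`.
#' @param target_resid optional named character vector (target position ->
#'   3-letter code) used to relabel residue names.
#' @param max_unpaired_frac error if more than this fraction of the
#'   model's residues has no aligned partner (default 0.2).
#' @return relabeled `structure_model` with attributes `numbering_gaps`
#'   and `dropped` (source residue numbers without a partner).
#' @export
thread_sequence <- function(model, map, target_id, target_resid = NULL,
                            max_unpaired_frac = 0.2) {
  a <- model$atoms
  res <- unique(a$resno)
  idx <- match(a$resno, map$pairs$source)
  unpaired <- unique(a$resno[is.na(idx)])
  if (length(unpaired) / length(res) > max_unpaired_frac) {
    stopf("coverage error: %d/%d residues unpaired in the alignment map",
          length(unpaired), length(res))
  }
  keep <- !is.na(idx)
  a <- a[keep, , drop = FALSE]
  a$resno <- map$pairs$target[idx[keep]]
  if (!is.null(target_resid)) {
    hit <- match(as.character(a$resno), names(target_resid))
    a$resid[!is.na(hit)] <- target_resid[hit[!is.na(hit)]]
  }
  out <- structure_model(a, title = model$title, source_id = target_id)
  newres <- unique(a$resno)
  gaps <- newres[c(diff(newres) > 1, FALSE)]
  attr(out, "numbering_gaps") <- gaps
  attr(out, "dropped") <- unpaired
  out
}

#' A rigidly placed fragment for composite assembly
#'
#' @param model fragment `structure_model` (single chain used).
#' @param placement [rigid_transform()] placing it in the composite frame.
#' @param role ordinal along the protomer (hinge -> head order).
#' @param donor_range residue interval(s) this fragment contributes to the
#'   composite; `NULL` means all its residues.
#' @param chain chain to take from the fragment.
#' @return object of class `placed_fragment`.
#' @export
placed_fragment <- function(model, placement = rigid_transform(), role = 1L,
                            donor_range = NULL, chain = model_chains(model)[1]) {
  if (!is.null(donor_range)) {
    dr <- expand_intervals(donor_range)
    have <- ca_atoms(model, chain)$resno
    if (!all(dr %in% have)) {
      stopf("donor_range includes residues unresolved in the fragment: %s",
            paste(setdiff(dr, have), collapse = ", "))
    }
  }
  structure(list(model = model, placement = placement, role = as.integer(role),
                 donor_range = donor_range, chain = chain),
            class = "placed_fragment")
}

#' Stitch placed fragments into a single-chain composite
#'
#' Fragments are taken in hinge-to-head order (by `role`); consecutive
#' fragments must share at least 3 resolved residues. In an overlap the
#' later fragment donates coordinates, with the earlier fragment blended
#' out linearly over the overlap's outer 3 residues so junctions do not
#' step. Each junction's local Calpha RMSD (earlier vs later fragment over
#' the shared residues, after placement) is reported; a junction above
#' `max_junction_rmsd` means the placements are incompatible and stitching
#' refuses rather than papering over it.
#'
#' @param fragments list of [placed_fragment()]s.
#' @param chain_id chain id of the composite.
#' @param max_junction_rmsd junction RMSD limit (Angstrom).
#' @return single-chain `structure_model` with attribute `junctions`
#'   (data frame: junction, n_shared, rmsd) and attribute `breaks`
#'   (residue numbers after which the Calpha step leaves [2.9, 4.5] A).
#' @export
stitch_fragments <- function(fragments, chain_id = "A", max_junction_rmsd = 5) {
  if (!length(fragments)) stopf("no fragments to stitch")
  fragments <- fragments[order(vapply(fragments, `[[`, integer(1), "role"))]
  placed <- lapply(fragments, function(f) {
    ca <- ca_atoms(apply_transform(f$model, f$placement), f$chain)
    if (!is.null(f$donor_range)) {
      ca <- ca[ca$resno %in% expand_intervals(f$donor_range), , drop = FALSE]
    }
    ca
  })
  junctions <- data.frame(junction = integer(), n_shared = integer(),
                          rmsd = numeric())
  comp <- placed[[1]]
  comp_weight <- rep(1, nrow(comp))
  for (k in seq_along(placed)[-1]) {
    nxt <- placed[[k]]
    shared <- intersect(comp$resno, nxt$resno)
    if (length(shared) < 3) {
      stopf("fragments %d and %d share only %d overlapping residues (need >= 3)",
            k - 1, k, length(shared))
    }
    ci <- match(shared, comp$resno); ni <- match(shared, nxt$resno)
    rmsd <- sqrt(mean(rowSums((coord_matrix(comp)[ci, , drop = FALSE] -
                                 coord_matrix(nxt)[ni, , drop = FALSE])^2)))
    junctions <- rbind(junctions,
                       data.frame(junction = k - 1L, n_shared = length(shared),
                                  rmsd = rmsd))
    if (rmsd > max_junction_rmsd) {
      stopf("incompatible fragments at junction %d: local RMSD %.2f A > %.2f A",
            k - 1, rmsd, max_junction_rmsd)
    }
    ## later fragment donates; earlier blended out over the outer 3
    ## overlap residues (the end facing the earlier-only region)
    shared <- sort(shared)
    w_early <- setNames(rep(0, length(shared)), shared)
    nblend <- min(3L, length(shared))
    w_early[seq_len(nblend)] <- rev(seq_len(nblend)) / (nblend + 1)
    merged_res <- sort(union(comp$resno, nxt$resno))
    ce <- match(merged_res, comp$resno); ne <- match(merged_res, nxt$resno)
    we <- ifelse(merged_res %in% shared, w_early[as.character(merged_res)],
                 ifelse(is.na(ne), 1, 0))
    xyz_c <- coord_matrix(comp); xyz_n <- coord_matrix(nxt)
    xyz <- matrix(0, length(merged_res), 3)
    for (j in seq_along(merged_res)) {
      a <- if (!is.na(ce[j])) xyz_c[ce[j], ] else c(0, 0, 0)
      b <- if (!is.na(ne[j])) xyz_n[ne[j], ] else c(0, 0, 0)
      xyz[j, ] <- we[j] * a + (1 - we[j]) * b
    }
    resid_src <- ifelse(!is.na(ne), nxt$resid[ifelse(is.na(ne), 1, ne)],
                        comp$resid[ifelse(is.na(ce), 1, ce)])
    comp <- data.frame(chain = chain_id, resno = merged_res, resid = resid_src,
                       elety = "CA", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                       stringsAsFactors = FALSE)
  }
  comp$chain <- chain_id
  out <- structure_model(comp[, c("chain", "resno", "resid", "elety", "x", "y", "z")],
                         title = "stitched composite", source_id = "stitch")
  step <- sqrt(rowSums(diff(coord_matrix(ca_atoms(out)))^2))
  consec <- diff(ca_atoms(out)$resno) == 1L
  breaks <- ca_atoms(out)$resno[which(consec & (step < 2.9 | step > 4.5))]
  attr(out, "junctions") <- junctions
  attr(out, "breaks") <- breaks
  out
}

#' Compose a two-protomer state model on a head-dimer template
#'
#' Places two copies of a protomer by superposing its head region onto
#' each chain of a template head dimer (e.g. an ATP-engaged head-dimer
#' structure), giving the corresponding whole-dimer state. The geometry of
#' the arms then follows rigidly; for an engaged template this produces
#' the open-arm V conformation.
#'
#' @param protomer single-chain `structure_model`.
#' @param head_template_dimer two-chain `structure_model`.
#' @param head_overlap residue interval(s) of the head region, present in
#'   both the protomer and each template chain.
#' @param template_chains length-2 chain ids of the template.
#' @param hinge_residue optional residue whose inter-protomer distance is
#'   reported as the arm opening.
#' @return two-chain `structure_model` (chains A/B) with attributes
#'   `head_rmsd` (per chain) and `opening` (hinge-hinge distance, or NA).
#' @export
compose_state_model <- function(protomer, head_template_dimer, head_overlap,
                                template_chains = c("A", "B"),
                                hinge_residue = NULL) {
  pchain <- model_chains(protomer)[1]
  rmsds <- numeric(2)
  copies <- vector("list", 2)
  for (i in 1:2) {
    fit <- superpose_overlap(protomer, head_template_dimer,
                             head_overlap, head_overlap,
                             mobile_chain = pchain,
                             reference_chain = template_chains[i])
    rmsds[i] <- fit$rmsd
    copies[[i]] <- apply_transform(protomer, fit$transform)$atoms
  }
  copies[[1]]$chain <- "A"; copies[[2]]$chain <- "B"
  out <- structure_model(rbind(copies[[1]], copies[[2]]),
                         title = "composed state model",
                         source_id = protomer$source_id)
  opening <- NA_real_
  if (!is.null(hinge_residue)) {
    d <- symmetry_pair_distances(out, "A", "B", hinge_residue)
    if (nrow(d)) opening <- d$distance[1]
  }
  attr(out, "head_rmsd") <- rmsds
  attr(out, "opening") <- opening
  out
}

## Local helix axis at a hinge: TLS line direction through the `window`
## residues ending at the hinge (already-final coordinates in a forward
## pass), oriented toward increasing residue number.
local_helix_axis <- function(xyz) {
  ctr <- colMeans(xyz)
  u <- prcomp(xyz, center = TRUE, scale. = FALSE)$rotation[, 1]
  if (sum((xyz[nrow(xyz), ] - xyz[1, ]) * u) < 0) u <- -u
  as.numeric(u)
}

#' Bend a coiled-coil region by incremental per-turn rotations
#'
#' Piecewise-rigid bending: hinge points are set every helical turn along
#' the region, and at each hinge everything downstream is rotated by
#' `angle_per_window` about an axis perpendicular to the local helix axis
#' (fit over the `fit_window` residues ending at the hinge). The bending
#' plane is intrinsic: it is derived from the hinge residue's radial
#' direction about the helix axis, de-rotated by the helical phase implied
#' by the residue numbers, so it is consistent from hinge to hinge and
#' equivariant under rigid motion. Rotations are cumulative, so the bend
#' is continuous; intra-window geometry is exactly preserved, and
#' applying the negative schedule afterwards restores the input exactly.
#' A 9-degree-per-six-turns ring-model bend is `angle_per_window = 1.5`.
#'
#' @param model single-chain `structure_model`.
#' @param region `c(start, end)` residue interval to bend (hinges fall
#'   inside it; residues after it follow rigidly).
#' @param angle_per_window degrees of bend added at each one-turn hinge.
#' @param window residues per helical turn (default 3.62).
#' @return bent `structure_model`; consecutive Calpha distances are
#'   checked to stay in [2.9, 4.5] A (geometry error otherwise).
#' @export
bend_coiled_coil <- function(model, region, angle_per_window, window = 3.62) {
  chain <- model_chains(model)
  if (length(chain) != 1) stopf("bend_coiled_coil expects a single-chain model")
  ca <- ca_atoms(model)
  res <- ca$resno
  r0 <- region[1]; r1 <- region[2]
  span <- res[res >= r0 & res <= r1]
  if (any(diff(span) != 1L)) stopf("bend region must be contiguous in the model")
  n_hinges <- floor(length(span) / window)
  if (n_hinges < 1) stopf("region shorter than one helical turn")
  hinge_idx <- r0 - 1L + round(seq_len(n_hinges) * window)
  hinge_idx <- hinge_idx[hinge_idx <= r1]
  atoms <- model$atoms
  xyz <- coord_matrix(atoms)
  if (abs(angle_per_window) < 1e-15) return(model)
  ang <- deg2rad(angle_per_window)
  prev_h <- r0 - 1L
  for (h in hinge_idx) {
    ## local helix axis from the rigid inter-hinge segment ending at this
    ## hinge: the segment is moved only as a whole by earlier hinges, so
    ## the axis estimate is exactly equivariant and the negative schedule
    ## inverts the bend exactly
    fit_res <- (prev_h + 1L):h
    prev_h <- h
    ci <- which(ca$resno %in% fit_res)
    if (length(ci) < 3) stopf("fewer than 3 residues in the hinge segment at %d", h)
    ca_xyz <- xyz[match(paste(ca$chain[ci], ca$resno[ci], "CA"),
                        paste(atoms$chain, atoms$resno, atoms$elety)), , drop = FALSE]
    t_axis <- local_helix_axis(ca_xyz)
    ## intrinsic bending-plane normal: each segment residue's radial
    ## vector about the local helix axis, de-rotated by the helical phase
    ## its residue number implies, then averaged -- the same direction (up
    ## to helix imperfection) at every hinge, and equivariant under rigid
    ## motion of the input, which is what makes the negative schedule an
    ## exact inverse
    hinge_pt <- xyz[which(atoms$resno == h & atoms$elety == "CA"), ]
    ctr <- colMeans(ca_xyz)
    n_acc <- c(0, 0, 0)
    for (k in seq_along(ci)) {
      rad_k <- ca_xyz[k, ] - ctr
      rad_k <- rad_k - sum(rad_k * t_axis) * t_axis
      if (vnorm(rad_k) < 1e-9) next
      phase_k <- 2 * pi * (fit_res[k] - r0) / window
      n_acc <- n_acc + as.vector(rotation_about_axis(t_axis, -phase_k) %*% unitize(rad_k))
    }
    if (vnorm(n_acc) < 1e-9) stopf("degenerate hinge geometry (no radial component)")
    n_cur <- unitize(n_acc)
    rot_axis <- unitize(cross3(t_axis, n_cur))
    R <- rotation_about_axis(rot_axis, ang)
    down <- atoms$resno > h
    xyz[down, ] <- sweep(sweep(xyz[down, , drop = FALSE], 2, hinge_pt) %*% t(R),
                         2, -hinge_pt)
  }
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  out <- structure_model(atoms, title = model$title, source_id = model$source_id)
  ca_out <- ca_atoms(out)
  step <- sqrt(rowSums(diff(coord_matrix(ca_out))^2))
  consec <- diff(ca_out$resno) == 1L
  if (any(consec & (step < 2.9 | step > 4.5))) {
    stopf("geometry error: bend breaks chain continuity (Calpha step outside [2.9, 4.5] A)")
  }
  attr(out, "hinges") <- hinge_idx
  out
}

#' Screw decomposition of the transition between two dimer states
#'
#' Superposes the fixed chains of the two states, then expresses the
#' residual rigid transform of the moving selection as a screw motion:
#' rotation angle about an axis plus translation along it. This is the
#' standard way to quantify, e.g., the head tilt and slide between the
#' rod-shaped and ATP-engaged dimer states.
#'
#' @param state1_dimer,state2_dimer two-chain `structure_model`s sharing
#'   chain ids and residue numbering over the selections.
#' @param fixed_chain chain superposed between states.
#' @param moving_chain chain whose residual motion is decomposed.
#' @param moving_range residue interval(s) of the moving selection.
#' @param fixed_range optional interval(s) for the fixed-chain
#'   superposition (default: all shared residues).
#' @return list of class `transition_decomposition`: `rotation_angle`
#'   (degrees, in [0, 180]), `screw_axis` (unit vector),
#'   `translation_along_axis` (Angstrom), `axis_point`, `transform` (the
#'   full residual [rigid_transform()]), `fixed_chain`, `fixed_rmsd`,
#'   `moving_rmsd_after` (residual RMSD of the moving selection after the
#'   decomposed motion is applied).
#' @export
decompose_transition <- function(state1_dimer, state2_dimer, fixed_chain = "A",
                                 moving_chain = "B", moving_range = NULL,
                                 fixed_range = NULL) {
  fx1 <- ca_atoms(state1_dimer, fixed_chain); fx2 <- ca_atoms(state2_dimer, fixed_chain)
  fres <- if (is.null(fixed_range)) intersect(fx1$resno, fx2$resno) else expand_intervals(fixed_range)
  f1 <- match(fres, fx1$resno); f2 <- match(fres, fx2$resno)
  ok <- !is.na(f1) & !is.na(f2)
  if (sum(ok) < 3) stopf("fixed-chain selection under-determined")
  fit_fix <- superpose(coord_matrix(fx2)[f2[ok], , drop = FALSE],
                       coord_matrix(fx1)[f1[ok], , drop = FALSE])
  state2_al <- apply_transform(state2_dimer, fit_fix$transform)

  mv1 <- ca_atoms(state1_dimer, moving_chain); mv2 <- ca_atoms(state2_al, moving_chain)
  mres <- if (is.null(moving_range)) intersect(mv1$resno, mv2$resno) else expand_intervals(moving_range)
  m1 <- match(mres, mv1$resno); m2 <- match(mres, mv2$resno)
  ok <- !is.na(m1) & !is.na(m2)
  if (sum(ok) < 3) stopf("moving selection under-determined")
  P <- coord_matrix(mv1)[m1[ok], , drop = FALSE]
  Q <- coord_matrix(mv2)[m2[ok], , drop = FALSE]
  fit_mv <- superpose(P, Q)          # transform taking state1's moving part to state2's
  tr <- fit_mv$transform

  ## axis-angle of the rotation part
  R <- tr$R
  cos_t <- (sum(diag(R)) - 1) / 2
  angle <- acos(pmin(1, pmax(-1, cos_t)))
  if (angle < 1e-6) {
    axis <- unitize(if (vnorm(tr$t) > 1e-12) tr$t else c(0, 0, 1))
  } else if (pi - angle < 1e-6) {
    ## 180 degrees: axis from the largest diagonal of (R + I)/2
    M <- (R + diag(3)) / 2
    axis <- unitize(M[, which.max(diag(M))])
  } else {
    axis <- unitize(c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
                      (2 * sin(angle)))
  }
  ## axis keeps the right-handed sense of the rotation (angle in [0, 180]);
  ## the translation along it carries its own sign so the screw motion
  ## recomposes exactly
  d_along <- sum(tr$t * axis)
  ## a point on the screw axis (solve (I - R) p = t_perp)
  t_perp <- tr$t - sum(tr$t * axis) * axis
  A <- diag(3) - R
  axis_point <- tryCatch(as.vector(qr.solve(A + tcrossprod(axis), t_perp)),
                         error = function(e) c(0, 0, 0))
  moved <- apply_transform(P, tr)
  structure(list(rotation_angle = rad2deg(angle), screw_axis = axis,
                 translation_along_axis = d_along, axis_point = axis_point,
                 transform = tr, fixed_chain = fixed_chain,
                 fixed_rmsd = fit_fix$rmsd,
                 moving_rmsd_after = sqrt(mean(rowSums((moved - Q)^2)))),
            class = "transition_decomposition")
}

#' @export
print.transition_decomposition <- function(x, ...) {
  cat(sprintf("<transition> rotation %.1f deg about (%.3f, %.3f, %.3f), slide %.2f A along the axis\n",
              x$rotation_angle, x$screw_axis[1], x$screw_axis[2], x$screw_axis[3],
              x$translation_along_axis))
  cat(sprintf("  fixed chain %s aligned at %.3f A RMSD; moving residual %.3f A\n",
              x$fixed_chain, x$fixed_rmsd, x$moving_rmsd_after))
  invisible(x)
}
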