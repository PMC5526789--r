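## Joining the cross-linking screen with structures: cross-species
## annotation transfer, efficiency-vs-distance profiles, restraint
## compatibility, and collinearity of axial residues on a monomer surface.

#' Construct an alignment map
#'
#' Ordered residue-number pairs from a pairwise sequence alignment,
#' used to carry screen annotations between species. Gap columns produce
#' no pair; both columns must be strictly increasing.
#'
#' @param source_position,target_position paired integer residue numbers.
#' @param source_id,target_id sequence identifiers (used to catch
#'   transfers with mismatched species).
#' @return object of class `alignment_map`.
#' @export
alignment_map <- function(source_position, target_position,
                          source_id = "", target_id = "") {
  sp <- as.integer(source_position); tp <- as.integer(target_position)
  if (length(sp) != length(tp)) stopf("unequal pair columns")
  if (is.unsorted(sp, strictly = TRUE) || is.unsorted(tp, strictly = TRUE)) {
    stopf("alignment map columns must strictly increase")
  }
  structure(list(pairs = data.frame(source = sp, target = tp),
                 source_id = source_id, target_id = target_id),
            class = "alignment_map")
}

#' Read an alignment map from pairwise aligned FASTA
#'
#' Expects exactly two aligned sequences of equal length (gaps `-` or `.`).
#' Residue numbering starts at `source_start`/`target_start` for the first
#' non-gap character of each sequence.
#'
#' @param path aligned FASTA with two records (source first).
#' @param source_start,target_start author number of each sequence's first
#'   residue.
#' @return an [alignment_map()].
#' @export
read_alignment_fasta <- function(path, source_start = 1L, target_start = 1L) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) != 2) stopf("expected exactly 2 sequences in %s", length(hdr))
  ids <- sub("^>\\s*(\\S+).*", "\\1", lines[hdr])
  seq1 <- paste(lines[(hdr[1] + 1):(hdr[2] - 1)], collapse = "")
  seq2 <- paste(lines[(hdr[2] + 1):length(lines)], collapse = "")
  seq1 <- gsub("\\s", "", seq1); seq2 <- gsub("\\s", "", seq2)
  if (nchar(seq1) != nchar(seq2)) stopf("aligned sequences differ in length")
  a <- strsplit(seq1, "")[[1]]; b <- strsplit(seq2, "")[[1]]
  gap <- c("-", ".")
  apos <- cumsum(!a %in% gap) + source_start - 1L
  bpos <- cumsum(!b %in% gap) + target_start - 1L
  keep <- !a %in% gap & !b %in% gap
  alignment_map(apos[keep], bpos[keep], source_id = ids[1], target_id = ids[2])
}

#' Globally align two sequences and return the residue map
#'
#' Convenience wrapper (Needleman-Wunsch via Biostrings, BLOSUM62, linear
#' gap penalty). Curated user-supplied alignments should take precedence
#' for real cross-species transfers; this exists so the pipeline can run
#' end to end without one.
#'
#' @param source_seq,target_seq character strings (one-letter amino acids).
#' @param source_id,target_id sequence identifiers.
#' @param source_start,target_start numbering of each sequence's first residue.
#' @param gap_penalty linear gap penalty (positive).
#' @return an [alignment_map()].
#' @export
align_sequences <- function(source_seq, target_seq,
                            source_id = "source", target_id = "target",
                            source_start = 1L, target_start = 1L,
                            gap_penalty = 8) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stopf("align_sequences needs the Biostrings package; supply a curated alignment instead")
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(source_seq), Biostrings::AAString(target_seq),
    substitutionMatrix = "BLOSUM62", gapOpening = gap_penalty,
    gapExtension = gap_penalty, type = "global")
  a <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  apos <- cumsum(a != "-") + source_start - 1L
  bpos <- cumsum(b != "-") + target_start - 1L
  keep <- a != "-" & b != "-"
  alignment_map(apos[keep], bpos[keep], source_id = source_id, target_id = target_id)
}

#' Transfer screen annotations to another species' numbering
#'
#' Positions aligned to a gap are dropped and reported in the `dropped`
#' attribute; efficiencies are carried unchanged.
#'
#' @param table a [crosslink_table()].
#' @param map an [alignment_map()] whose `source_id` matches the table's
#'   `protein_id` (when both are declared).
#' @return a [crosslink_table()] in target numbering, with attribute
#'   `dropped` (source positions lost to gaps).
#' @export
transfer_annotations <- function(table, map) {
  pid <- attr(table, "protein_id") %||% ""
  if (nzchar(pid) && nzchar(map$source_id) && pid != map$source_id) {
    stopf("identity mismatch: table is '%s' but map source is '%s'",
          pid, map$source_id)
  }
  idx <- match(table$position, map$pairs$source)
  kept <- !is.na(idx)
  out <- crosslink_table(map$pairs$target[idx[kept]],
                         table$efficiency[kept],
                         tested = table$tested[kept],
                         helix_label = table$helix_label[kept],
                         protein_id = map$target_id,
                         replicate = attr(table, "replicate") %||% "")
  attr(out, "dropped") <- table$position[!kept]
  out
}

#' Join efficiencies with symmetry-mate distances in a dimer
#'
#' The structural test of the screen: tested positions resolved in both
#' chains get their symmetry-mate Calpha-Calpha distance and a
#' within-reach flag at the cross-linker reach cutoff. The default 14 A
#' approximates the BMOE maleimide-maleimide spacer (~8 A) plus two
#' cysteine side-chain extents (~3 A each); it is a package default drawn
#' as the dashed reach line in efficiency-distance plots, configurable.
#'
#' @param table a [crosslink_table()].
#' @param dimer a two-chain `structure_model`.
#' @param chains length-2 chain ids.
#' @param reach_cutoff Calpha-Calpha reach of the cross-linker (Angstrom).
#' @param class_breaks passed to [classify_efficiency()].
#' @return a `restraint_profile`: data frame (position, efficiency, class,
#'   distance, within_reach) with attribute `unresolved` (tested positions
#'   absent from either chain).
#' @export
build_profile <- function(table, dimer, chains = c("A", "B"),
                          reach_cutoff = 14, class_breaks = c(0.05, 0.20, 0.40)) {
  tested <- table[table$tested, , drop = FALSE]
  dists <- symmetry_pair_distances(dimer, chains[1], chains[2], tested$position)
  if (!nrow(dists)) {
    if (!nrow(tested)) {
      out <- data.frame(position = integer(), efficiency = numeric(),
                        class = factor(character(), levels = c("none", "low", "medium", "high")),
                        distance = numeric(), within_reach = logical())
      attr(out, "unresolved") <- tested$position
      attr(out, "reach_cutoff") <- reach_cutoff
      class(out) <- c("restraint_profile", "data.frame")
      return(out)
    }
    stopf("no tested position is resolvable in both chains")
  }
  idx <- match(dists$position, tested$position)
  out <- data.frame(position = dists$position,
                    efficiency = tested$efficiency[idx],
                    class = classify_efficiency(tested$efficiency[idx], class_breaks),
                    distance = dists$distance,
                    within_reach = dists$distance <= reach_cutoff)
  attr(out, "unresolved") <- attr(dists, "unresolved")
  attr(out, "reach_cutoff") <- reach_cutoff
  class(out) <- c("restraint_profile", "data.frame")
  out
}

#' Cross-link compatibility of a dimer model
#'
#' Fraction of axial positions (efficiency above `axial_threshold`) whose
#' symmetry-mate distance is within the cross-linker reach, plus the list
#' of violating rows. This is the quantitative form of "the cross-linking
#' pattern agrees with the structure".
#'
#' @param profile a [build_profile()] result.
#' @param axial_threshold efficiency threshold for axial calling (strict).
#' @return list with `score` (fraction in \[0, 1\]), `n_axial`, and
#'   `violations` (axial rows beyond reach).
#' @export
compatibility_score <- function(profile, axial_threshold = 0.20) {
  if (!nrow(profile)) stopf("empty restraint profile")
  axial <- profile[!is.na(profile$efficiency) &
                     profile$efficiency > axial_threshold, , drop = FALSE]
  if (!nrow(axial)) stopf("no axial rows in profile; compatibility score undefined")
  list(score = mean(axial$within_reach), n_axial = nrow(axial),
       violations = axial[!axial$within_reach, , drop = FALSE])
}

#' Best-fit line through residue Calphas and its RMS deviation
#'
#' Total-least-squares 3-D line fit (first principal axis of the Calpha
#' set); the RMS of perpendicular distances quantifies how collinear the
#' residues are (axial residues on a rod monomer should fall on a line,
#' the presumptive two-fold axis).
#'
#' @param model a `structure_model`.
#' @param chain chain id.
#' @param positions residue numbers (>= 3 must be resolved).
#' @return list with `rms` (Angstrom), `point` (line centroid),
#'   `direction` (unit vector), `n`.
#' @export
collinearity <- function(model, chain, positions) {
  sel <- extract_ca(model, chain, positions)
  if (nrow(sel) < 3) stopf("collinearity needs >= 3 resolved positions, got %d", nrow(sel))
  xyz <- sel_matrix(sel)
  ctr <- colMeans(xyz)
  pc <- prcomp(xyz, center = TRUE, scale. = FALSE)
  u <- pc$rotation[, 1]
  rel <- sweep(xyz, 2, ctr)
  perp <- rel - (rel %*% u) %*% t(u)   # residual vector: no cancellation
  list(rms = sqrt(mean(rowSums(perp^2))), point = ctr,
       direction = as.numeric(u), n = nrow(sel))
}

#' Permutation test for collinearity
#'
#' Compares the observed RMS line deviation of a residue set against
#' same-size residue sets drawn at random from the chain: the claim that
#' axial residues "line up" is visual in origin, so significance is
#' assessed nonparametrically.
#'
#' @param model a `structure_model`.
#' @param chain chain id.
#' @param positions the residue set of interest.
#' @param n_perm number of random same-size sets.
#' @param seed RNG seed.
#' @return list with `observed_rms`, `perm_rms` (vector), and `p_value`
#'   (fraction of permutations at least as collinear, add-one corrected).
#' @export
collinearity_permutation <- function(model, chain, positions, n_perm = 1000,
                                     seed = 1L) {
  obs <- collinearity(model, chain, positions)
  all_res <- ca_atoms(model, chain)$resno
  k <- obs$n
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    collinearity(model, chain, sample(all_res, k))$rms
  }, numeric(1))
  list(observed_rms = obs$rms, perm_rms = perm,
       p_value = (1 + sum(perm <= obs$rms)) / (1 + n_perm))
}

#' Write a restraint profile as TSV
#' @param profile a [build_profile()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Export per-residue classes as a viewer attribute file
#'
#' Generic (chain, resnum, class) TSV consumable by molecular viewers for
#' surface coloring.
#'
#' @param table a [crosslink_table()].
#' @param chain chain id to attach.
#' @param path output path.
#' @param class_breaks passed to [classify_efficiency()].
#' @return `path`, invisibly.
#' @export
write_class_attributes <- function(table, chain, path,
                                   class_breaks = c(0.05, 0.20, 0.40)) {
  cls <- as.character(classify_efficiency(table$efficiency, class_breaks))
  cls[!table$tested] <- "untested"
  write.table(data.frame(chain = chain, resnum = table$position, class = cls),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
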