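## Synthetic data with the geometric and statistical structure the
## analysis assumes: idealized Crick-parameterized coiled-coil arms,
## rod dimers with a planted (ground-truth) C2 axis, sigmoidal
## efficiency-vs-distance simulation, and exponential exchange
## timecourses. Everything here is deterministic given (params, seed) and
## writes the same formats the pipeline consumes, so synthetic fixtures
## and real data are interchangeable.

#' Coiled-coil generator parameters
#'
#' Textbook coiled-coil geometry: ~3.62 residues per minor-helix turn,
#' 1.51 A rise per residue along the superhelical axis, superhelix radius
#' 4.9 A. These are idealization defaults, not measured values.
#'
#' @param n_residues residues per helix.
#' @param radius superhelix radius (A).
#' @param residues_per_turn minor-helix periodicity (in (3, 4)).
#' @param rise_per_residue axial rise per residue (A).
#' @param pitch superhelical pitch (A).
#' @param antiparallel hairpin (second helix runs back down) vs parallel.
#' @param minor_radius minor-helix radius (A).
#' @param seed integer seed (recorded; the generator itself is
#'   deterministic).
#' @return named list of class `coil_params`.
#' @export
coil_params <- function(n_residues = 110L, radius = 4.9, residues_per_turn = 3.62,
                        rise_per_residue = 1.51, pitch = 160,
                        antiparallel = TRUE, minor_radius = 2.26, seed = 1L) {
  if (residues_per_turn <= 3 || residues_per_turn >= 4) {
    stopf("residues_per_turn must lie in (3, 4)")
  }
  if (any(c(n_residues, radius, rise_per_residue, pitch, minor_radius) <= 0)) {
    stopf("geometric parameters must be positive")
  }
  structure(list(n_residues = as.integer(n_residues), radius = radius,
                 residues_per_turn = residues_per_turn,
                 rise_per_residue = rise_per_residue, pitch = pitch,
                 antiparallel = antiparallel, minor_radius = minor_radius,
                 seed = as.integer(seed)), class = "coil_params")
}

## Calpha positions of one ascending helix wound around the superhelical
## axis (z): the standard Crick composition of the superhelical path
## (radius R0, pitch P, left-handed) and the minor alpha-helix (radius
## R1, ~3.6 residues/turn) expressed in the local superhelix frame.
crick_helix <- function(n, radius, rpt, rise, pitch, minor_radius,
                        phase0 = 0, minor_phase0 = 0) {
  i <- seq_len(n) - 1L
  w0 <- -2 * pi * rise / pitch                 # superhelix step (left-handed)
  w1 <- 2 * pi / rpt                           # minor-helix step (right-handed)
  alpha <- -atan2(2 * pi * radius, pitch)      # signed superhelix pitch angle
  theta <- phase0 + w0 * i
  psi <- minor_phase0 + w1 * i
  x <- radius * cos(theta) +
    minor_radius * (cos(theta) * cos(psi) - cos(alpha) * sin(theta) * sin(psi))
  y <- radius * sin(theta) +
    minor_radius * (sin(theta) * cos(psi) + cos(alpha) * cos(theta) * sin(psi))
  z <- i * rise - minor_radius * sin(alpha) * sin(psi)
  cbind(x, y, z)
}

#' Generate a synthetic SMC-like arm monomer
#'
#' A Calpha-trace of a two-helix (hairpin) coiled coil: the N-helix runs
#' up the superhelical axis and, for `antiparallel = TRUE`, the C-helix
#' runs back down on the opposite azimuth, emulating the intramolecular
#' antiparallel coiled coil of an SMC arm. Residues are numbered 1..n
#' (N-helix, ascending) and n+1..2n (C-helix).
#'
#' @param params a [coil_params()].
#' @return single-chain Calpha-only `structure_model` (chain "A").
#' @export
make_monomer_arm <- function(params = coil_params()) {
  n <- params$n_residues
  h1 <- crick_helix(n, params$radius, params$residues_per_turn,
                    params$rise_per_residue, params$pitch,
                    params$minor_radius, phase0 = 0)
  h2 <- crick_helix(n, params$radius, params$residues_per_turn,
                    params$rise_per_residue, params$pitch,
                    params$minor_radius, phase0 = 0)
  if (params$antiparallel) {
    ## turn the second helix upside down with a proper rotation (chirality
    ## and local geometry preserved exactly), lift it back to the first
    ## helix's z-span, then set its azimuth opposite the first helix
    w0 <- -2 * pi * params$rise_per_residue / params$pitch
    h2 <- h2 %*% t(rotation_about_axis(c(1, 0, 0), pi))
    h2[, 3] <- h2[, 3] + (n - 1) * params$rise_per_residue
    ## azimuth: opposite the first helix at every height, accounting for
    ## the superhelical winding over the span
    h2 <- h2 %*% t(rotation_about_axis(c(0, 0, 1), pi + w0 * (n - 1)))
  } else {
    h2 <- h2 %*% t(rotation_about_axis(c(0, 0, 1), pi))
  }
  xyz <- rbind(h1, h2)
  atoms <- data.frame(chain = "A", resno = seq_len(2L * n), resid = "ALA",
                      elety = "CA", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  structure_model(atoms, title = "synthetic coiled-coil arm",
                  source_id = "synthgen")
}

#' Build a synthetic rod dimer with a planted C2 axis
#'
#' Places the two-fold axis parallel to the monomer's long (z) axis,
#' laterally offset from the monomer centroid by `axis_offset` and tilted
#' by `axis_tilt` about the y axis, and returns both the dimer and the
#' ground-truth axis for planted-truth recovery tests.
#'
#' @param monomer a [make_monomer_arm()] model.
#' @param axis_offset lateral offset of the axis from the monomer centroid
#'   (A); must leave the two protomers clash-free.
#' @param axis_tilt tilt of the axis away from z (degrees).
#' @param clash_cutoff placement is rejected if the dimer has Calpha
#'   clashes at this cutoff.
#' @param seed recorded seed (construction is deterministic).
#' @return list with `dimer` (chains A/B) and `axis` (the planted
#'   [c2_axis()]).
#' @export
make_rod_dimer <- function(monomer, axis_offset = 9.6, axis_tilt = 0,
                           clash_cutoff = 4, seed = 1L) {
  ctr <- colMeans(coord_matrix(ca_atoms(monomer)))
  u <- as.vector(rotation_about_axis(c(0, 1, 0), deg2rad(axis_tilt)) %*% c(0, 0, 1))
  axis <- c2_axis(u, ctr + c(axis_offset, 0, 0))
  dimer <- build_c2_dimer(monomer, axis)
  nc <- clash_count(dimer, clash_cutoff)
  if (nc > 0) {
    stopf("clash-saturated placement: %d Calpha clashes at %.1f A; increase axis_offset",
          nc, clash_cutoff)
  }
  list(dimer = dimer, axis = axis, seed = as.integer(seed))
}

#' Efficiency noise model
#'
#' Encodes the assumed monotone efficiency-distance relation: a sigmoid
#' of the symmetry-mate Calpha-Calpha distance with midpoint `d0` and
#' width `slope`, scaled to `E_max`, plus clamped additive Gaussian noise.
#'
#' @param E_max maximal efficiency (0, 1].
#' @param d0 sigmoid midpoint distance (A).
#' @param slope sigmoid width (A).
#' @param noise_sd additive Gaussian noise SD on the fraction scale.
#' @param seed integer RNG seed.
#' @return named list of class `efficiency_noise_model`.
#' @export
efficiency_noise_model <- function(E_max = 0.9, d0 = 14, slope = 2,
                                   noise_sd = 0, seed = 1L) {
  if (E_max <= 0 || E_max > 1) stopf("E_max must be in (0, 1]")
  structure(list(E_max = E_max, d0 = d0, slope = slope, noise_sd = noise_sd,
                 seed = as.integer(seed)), class = "efficiency_noise_model")
}

#' Simulate a cross-linking screen on a dimer
#'
#' `efficiency_i = clamp(E_max / (1 + exp((d_i - d0)/slope)) + eps_i, 0, 1)`
#' with `eps ~ N(0, noise_sd)`, seeded, where `d_i` is the symmetry-mate
#' Calpha-Calpha distance of position i in the dimer.
#'
#' @param dimer two-chain `structure_model`.
#' @param positions residue numbers to "screen" (resolved in both chains).
#' @param noise an [efficiency_noise_model()].
#' @param chains length-2 chain ids.
#' @return a [crosslink_table()] with attribute `true_distance`.
#' @export
simulate_efficiencies <- function(dimer, positions, noise = efficiency_noise_model(),
                                  chains = c("A", "B")) {
  d <- symmetry_pair_distances(dimer, chains[1], chains[2], positions)
  if (length(attr(d, "unresolved"))) {
    stopf("position(s) %s unresolved in both chains",
          paste(attr(d, "unresolved"), collapse = ", "))
  }
  eff <- noise$E_max / (1 + exp((d$distance - noise$d0) / noise$slope))
  if (noise$noise_sd > 0) {
    set.seed(noise$seed)
    eff <- eff + rnorm(length(eff), sd = noise$noise_sd)
  }
  eff <- pmin(1, pmax(0, eff))
  out <- crosslink_table(d$position, eff, protein_id = dimer$source_id)
  attr(out, "true_distance") <- d$distance[order(d$position)]
  out
}

#' Closed-form axial set of the zero-noise simulator
#'
#' At zero noise, a position is called axial (efficiency > threshold)
#' exactly when its symmetry-mate distance is below
#' `d0 + slope * log(E_max / threshold - 1)`; this analytic inverse of the
#' sigmoid is used to cross-check the whole simulate-then-call path.
#'
#' @param noise an [efficiency_noise_model()].
#' @param threshold axial-calling threshold.
#' @return the distance threshold (A); positions strictly below it are
#'   axial (`-Inf` when `threshold >= E_max`).
#' @export
axial_distance_threshold <- function(noise, threshold = 0.20) {
  if (threshold >= noise$E_max) return(-Inf)
  noise$d0 + noise$slope * log(noise$E_max / threshold - 1)
}

#' Simulate an exchange timecourse
#'
#' `fraction(t) = F_eq * (1 - exp(-k t)) + noise`, clamped to \[0, 1\].
#'
#' @param k exchange rate (per minute, > 0).
#' @param F_eq equilibrium plateau fraction.
#' @param times timepoints (minutes).
#' @param noise_sd Gaussian noise SD on fractions.
#' @param seed RNG seed.
#' @return an [exchange_timecourse()].
#' @export
simulate_exchange <- function(k, F_eq = 0.5, times = c(0, 5, 10, 20, 40, 80, 120, 160),
                              noise_sd = 0, seed = 1L) {
  if (k <= 0) stopf("k must be > 0")
  f <- F_eq * (1 - exp(-k * times))
  if (noise_sd > 0) {
    set.seed(seed)
    f <- f + rnorm(length(times), sd = noise_sd)
  }
  exchange_timecourse(times, pmin(1, pmax(0, f)))
}
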