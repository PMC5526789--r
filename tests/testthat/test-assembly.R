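arm_fixture <- function(n = 80) make_monomer_arm(coil_params(n_residues = n))

test_that("overlap superposition is exact on itself and rejoins split fragments", {
  m <- arm_fixture()
  self <- superpose_overlap(m, m, c(1, 160), c(1, 160))
  expect_lt(self$rmsd, 1e-12)
  expect_equal(self$n_pairs, 160)

  set.seed(3)
  f1 <- sub_model(m, 1:90)
  f2 <- apply_transform(sub_model(m, 71:160), random_rigid())
  fit <- superpose_overlap(f2, f1, c(71, 90), c(71, 90))
  expect_equal(fit$n_pairs, 20)
  rejoined <- apply_transform(f2, fit$transform)
  expect_equal(xyz_of(rejoined), xyz_of(sub_model(m, 71:160)),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(superpose_overlap(f2, f1, c(71, 90), c(71, 95)), "length")
  expect_error(superpose_overlap(f2, f1, c(1, 10), c(1, 10)), "under-determined")
})

test_that("sequence threading relabels numbering, annotates gaps, and round-trips", {
  m <- arm_fixture(30)
  ident <- alignment_map(1:60, 1:60, "Bs", "Bs")
  same <- thread_sequence(m, ident, "still-Bs")
  expect_equal(same$atoms$resno, m$atoms$resno)
  expect_equal(same$source_id, "still-Bs")

  ## one insertion in the target after position 20: downstream shifts +1
  ins <- alignment_map(1:60, c(1:20, 22:61), "Bs", "Pf")
  shifted <- thread_sequence(m, ins, "Pf")
  expect_equal(shifted$atoms$resno[shifted$atoms$resno > 21] -
                 m$atoms$resno[m$atoms$resno > 20], rep(1L, 40))
  expect_equal(attr(shifted, "numbering_gaps"), 20)
  expect_equal(xyz_of(shifted), xyz_of(m), ignore_attr = TRUE)

  back <- alignment_map(c(1:20, 22:61), 1:60, "Pf", "Bs")
  restored <- thread_sequence(shifted, back, "Bs")
  expect_equal(restored$atoms$resno, m$atoms$resno)

  sparse <- alignment_map(1:10, 1:10, "Bs", "Pf")
  expect_error(thread_sequence(m, sparse, "Pf"), "coverage")
})

test_that("split-scatter-rejoin stitching reconstructs the arm to 1e-6", {
  set.seed(8)
  m <- arm_fixture()
  pieces <- list(sub_model(m, 1:60), sub_model(m, 41:120), sub_model(m, 101:160))
  scattered <- list(pieces[[1]],
                    apply_transform(pieces[[2]], random_rigid()),
                    apply_transform(pieces[[3]], random_rigid()))
  p2 <- superpose_overlap(scattered[[2]], scattered[[1]], c(41, 60), c(41, 60))
  placed2 <- apply_transform(scattered[[2]], p2$transform)
  p3 <- superpose_overlap(scattered[[3]], placed2, c(101, 120), c(101, 120))
  frags <- list(placed_fragment(scattered[[1]], role = 1),
                placed_fragment(scattered[[2]], p2$transform, role = 2),
                placed_fragment(scattered[[3]], p3$transform, role = 3))
  comp <- stitch_fragments(frags)
  expect_equal(nrow(comp$atoms), 160)
  fit <- superpose(xyz_of(comp), xyz_of(m))
  expect_lt(fit$rmsd, 1e-6)
  expect_true(all(attr(comp, "junctions")$rmsd < 1e-6))
  ## the only continuity break is the unmodeled hairpin between the two
  ## helices of the arm (residues 80 -> 81), annotated, not an error
  expect_equal(attr(comp, "breaks"), 80)

  ## order in which overlapping placements are computed does not matter:
  ## anchor on the middle fragment instead and compare up to rigid motion
  q1 <- superpose_overlap(scattered[[1]], scattered[[2]], c(41, 60), c(41, 60))
  q3 <- superpose_overlap(scattered[[3]], scattered[[2]], c(101, 120), c(101, 120))
  alt <- stitch_fragments(list(placed_fragment(scattered[[1]], q1$transform, role = 1),
                               placed_fragment(scattered[[2]], role = 2),
                               placed_fragment(scattered[[3]], q3$transform, role = 3)))
  expect_lt(superpose(xyz_of(alt), xyz_of(comp))$rmsd, 1e-6)
})

test_that("stitching refuses disjoint or incompatible placements", {
  m <- arm_fixture()
  a <- sub_model(m, 1:60)
  b <- sub_model(m, 80:160)
  expect_error(stitch_fragments(list(placed_fragment(a, role = 1),
                                     placed_fragment(b, role = 2))),
               "overlapping residues")
  c_off <- apply_transform(sub_model(m, 41:120),
                           rigid_transform(diag(3), c(30, 0, 0)))
  expect_error(stitch_fragments(list(placed_fragment(a, role = 1),
                                     placed_fragment(c_off, role = 2))),
               "incompatible")
})

test_that("donor ranges restrict what a fragment contributes", {
  m <- arm_fixture(40)
  a <- sub_model(m, 1:50)
  b <- sub_model(m, 31:80)
  comp <- stitch_fragments(list(placed_fragment(a, role = 1, donor_range = c(1, 45)),
                                placed_fragment(b, role = 2)))
  expect_equal(range(comp$atoms$resno), c(1, 80))
  expect_error(placed_fragment(a, donor_range = c(1, 70)), "unresolved")
})

test_that("state composition on the rod's own head dimer reproduces the rod", {
  m <- arm_fixture(50)
  rod <- make_rod_dimer(m)
  comp <- compose_state_model(m, rod$dimer, c(95, 100), hinge_residue = 50)
  expect_equal(attr(comp, "head_rmsd"), c(0, 0), tolerance = 1e-9)
  expect_equal(attr(comp, "opening"),
               symmetry_pair_distances(rod$dimer, positions = 50)$distance,
               tolerance = 1e-9)
  expect_equal(xyz_of(comp), xyz_of(rod$dimer), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("state composition opens the arms by a planted template angle", {
  m <- arm_fixture(50)
  rod <- make_rod_dimer(m)
  ## template: take the rod's head dimer and swing each chain's head
  ## region outward by 30 degrees about the x axis through the heads'
  ## midpoint -- a 60-degree relative opening
  head_iv <- c(95, 100)
  heads <- structure_model(rod$dimer$atoms[rod$dimer$atoms$resno %in% 95:100, ,
                                           drop = FALSE])
  mid <- colMeans(xyz_of(heads))
  swing <- function(chain, ang) {
    at <- heads$atoms[heads$atoms$chain == chain, , drop = FALSE]
    xyz <- sweep(sweep(as.matrix(at[, c("x", "y", "z")]), 2, mid) %*%
                   t(rotation_about_axis(c(1, 0, 0), ang)), 2, -mid)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
    at
  }
  template <- structure_model(rbind(swing("A", deg2rad_ <- 30 * pi / 180),
                                    swing("B", -30 * pi / 180)))
  opened <- compose_state_model(m, template, head_iv, hinge_residue = 50)
  ## each arm's long axis should have rotated by ~30 degrees vs the rod
  arm_dir <- function(model, chain) {
    collinearity(model, chain, 1:50)$direction
  }
  a0 <- arm_dir(rod$dimer, "A"); a1 <- arm_dir(opened, "A")
  b0 <- arm_dir(rod$dimer, "B"); b1 <- arm_dir(opened, "B")
  expect_equal(axis_angle_deg(a0, a1), 30, tolerance = 1)
  expect_equal(axis_angle_deg(b0, b1), 30, tolerance = 1)
  ## and the composed state opens wider at the hinge than the rod
  expect_gt(attr(opened, "opening"), attr(compose_state_model(
    m, rod$dimer, head_iv, hinge_residue = 50), "opening"))
})

test_that("coiled-coil bending accumulates per turn and inverts exactly", {
  m <- arm_fixture(60)
  helix <- sub_model(m, 1:60)

  same <- bend_coiled_coil(helix, c(1, 22), 0)
  expect_identical(xyz_of(same), xyz_of(helix))

  bent <- bend_coiled_coil(helix, c(1, 22), 9)   # six one-turn hinges
  expect_equal(length(attr(bent, "hinges")), 6)
  expect_equal(nrow(bent$atoms), nrow(helix$atoms))
  ## rigid tail rotation ~ 6 x 9 = 54 degrees, less a few degrees of
  ## local-axis estimation wobble
  tail0 <- xyz_of(sub_model(helix, 30:60)); tail1 <- xyz_of(sub_model(bent, 30:60))
  fit <- superpose(tail0, tail1)
  total <- rotation_angle_deg(fit$transform$R)
  expect_gt(total, 45); expect_lt(total, 56)
  ## the tail segment itself moves rigidly (internal geometry exact)
  expect_lt(fit$rmsd, 1e-9)
  ## intra-window geometry preserved: pairwise distances within an
  ## inter-hinge segment are untouched
  seg0 <- xyz_of(sub_model(helix, 5:7)); seg1 <- xyz_of(sub_model(bent, 5:7))
  expect_equal(as.vector(dist(seg1)), as.vector(dist(seg0)), tolerance = 1e-12)
  ## chain continuity maintained
  step <- sqrt(rowSums(diff(xyz_of(bent))^2))
  expect_true(all(step > 2.9 & step < 4.5))

  unbent <- bend_coiled_coil(bent, c(1, 22), -9)
  expect_equal(xyz_of(unbent), xyz_of(helix), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("transition decomposition recovers a planted screw exactly", {
  m <- arm_fixture(40)
  rod <- make_rod_dimer(m)
  d1 <- rod$dimer

  ## identical states: no rotation, no slide
  dec0 <- decompose_transition(d1, d1, "A", "B")
  expect_lt(dec0$rotation_angle, 1e-9)
  expect_lt(abs(dec0$translation_along_axis), 1e-9)

  ## plant a 30-degree rotation about z plus a 5 A slide along z on chain B
  tr <- rigid_transform(rotation_about_axis(c(0, 0, 1), 30 * pi / 180), c(0, 0, 5))
  b <- d1$atoms[d1$atoms$chain == "B", , drop = FALSE]
  bx <- as.matrix(b[, c("x", "y", "z")]) %*% t(tr$R)
  b$x <- bx[, 1] + 0; b$y <- bx[, 2]; b$z <- bx[, 3] + 5
  d2 <- structure_model(rbind(d1$atoms[d1$atoms$chain == "A", ], b))
  dec <- decompose_transition(d1, d2, "A", "B")
  expect_equal(dec$rotation_angle, 30, tolerance = 1e-6)
  expect_equal(abs(dec$screw_axis), c(0, 0, 1), tolerance = 1e-6)
  expect_equal(dec$translation_along_axis, 5, tolerance = 1e-6)
  ## recomposition: rotation rebuilt from (axis, angle) matches the
  ## measured transform, and the decomposed motion maps state 1 onto 2
  expect_equal(rotation_about_axis(dec$screw_axis, dec$rotation_angle * pi / 180),
               dec$transform$R, tolerance = 1e-6)
  expect_lt(dec$moving_rmsd_after, 1e-6)
  expect_lt(dec$fixed_rmsd, 1e-9)
})
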